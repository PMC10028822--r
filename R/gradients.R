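# Cluster discreteness within subclasses and spatial expression gradients.

# standardize() lives in integrate.R; here expression is assumed already
# normalised (per-cell total + log1p) unless stated otherwise.

#' Neighbourhood purity in expression space
#'
#' For each cell, the fraction of its `k` nearest neighbours in expression
#' PCA space (top `dims` components of the standardised matrix) that share
#' its cluster label. 1 for perfectly discrete clusters, about the cluster's
#' frequency for fully interleaved ones. Invariant to global rescaling of
#' the expression matrix.
#'
#' @param expr Cells x genes normalised expression matrix.
#' @param cluster_labels Per-cell cluster labels.
#' @param k Neighbours (default 50).
#' @param dims PCA components used for the neighbour search (default 50).
#' @return Numeric vector of per-cell purities in \[0, 1\].
#' @export
neighbourhood_purity <- function(expr, cluster_labels, k = 50, dims = 50) {
  expr <- as.matrix(expr)
  if (nrow(expr) < k + 1) abort("need at least k + 1 cells")
  z <- zscore_cols(expr)
  dims <- min(dims, ncol(z), nrow(z) - 1)
  pcs <- prcomp(z, center = FALSE, rank. = dims)$x
  nn <- knn_index(pcs, pcs, k, self = FALSE)
  vapply(seq_len(nrow(expr)), function(i)
    mean(cluster_labels[nn[i, ]] == cluster_labels[i]), numeric(1))
}

#' Cluster discreteness and subclass medians
#'
#' Cluster discreteness is the mean neighbourhood purity over the cluster's
#' cells; a subclass's summary is the median of its clusters'
#' discreteness — low medians indicate within-subclass continua rather than
#' well-separated clusters.
#'
#' @param purity Per-cell purities from [neighbourhood_purity()].
#' @param cluster_labels Per-cell cluster labels.
#' @param subclass_of_cluster Named vector mapping cluster to subclass.
#' @return A list of tibbles: `clusters` (`cluster`, `subclass`,
#'   `discreteness`, `n_cells`) and `subclasses` (`subclass`,
#'   `median_discreteness`, `n_clusters`).
#' @export
discreteness <- function(purity, cluster_labels, subclass_of_cluster) {
  cl <- tibble(cluster = cluster_labels, purity = purity) |>
    group_by(.data$cluster) |>
    summarise(discreteness = mean(.data$purity), n_cells = dplyr::n()) |>
    mutate(subclass = unname(subclass_of_cluster[.data$cluster])) |>
    select("cluster", "subclass", "discreteness", "n_cells")
  sub <- cl |>
    filter(!is.na(.data$subclass)) |>
    group_by(.data$subclass) |>
    summarise(median_discreteness = median(.data$discreteness),
              n_clusters = dplyr::n())
  list(clusters = cl, subclasses = sub)
}

#' Principal gradient axis of an expression subset
#'
#' Scores each cell along the dominant axis of expression variation: the
#' first principal component of the standardised matrix by default, or a
#' PC1-seeded principal-curve style ordering ("pseudotime": rank of the PC1
#' score) as a variant. The sign is flipped so the Pearson correlation with
#' `orient_against` is non-negative.
#'
#' @param expr Cells x genes normalised expression matrix (>= 3 cells).
#' @param method `"pc1"` or `"pseudotime"`.
#' @param orient_against Per-cell spatial coordinate fixing the orientation.
#' @return Tibble `score` (per cell), with attributes `method` and `r`
#'   (Pearson correlation with `orient_against`).
#' @export
gradient_axis <- function(expr, method = c("pc1", "pseudotime"),
                          orient_against) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) abort("need at least 3 cells")
  z <- zscore_cols(expr)
  if (all(z == 0)) abort("zero-variance expression matrix")
  score <- prcomp(z, center = FALSE, rank. = 1)$x[, 1]
  if (method == "pseudotime")
    score <- (rank(score, ties.method = "first") - 1) / (length(score) - 1)
  r <- suppressWarnings(cor(score, orient_against))
  if (!is.na(r) && r < 0) {
    score <- if (method == "pseudotime") 1 - score else -score
    r <- -r
  }
  out <- tibble(score = as.numeric(score))
  attr(out, "method") <- method
  attr(out, "r") <- r
  out
}

#' Pearson correlation of a per-cell value with a spatial coordinate
#'
#' Standard Pearson r with a Fisher-z 95% confidence interval; zero-variance
#' input yields an `undefined` flag rather than an error.
#'
#' @param values Per-cell scalar (e.g. a gradient score).
#' @param coordinate Per-cell spatial coordinate.
#' @param conf_level Confidence level of the interval.
#' @return Tibble with `r`, `conf_low`, `conf_high`, `n`, `undefined`.
#' @export
spatial_correlation <- function(values, coordinate, conf_level = 0.95) {
  stopifnot(length(values) == length(coordinate))
  n <- length(values)
  if (n < 3) abort("need at least 3 cells")
  if (sd(values) == 0 || sd(coordinate) == 0)
    return(tibble(r = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                  n = n, undefined = TRUE))
  r <- cor(values, coordinate)
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  tibble(r = r, conf_low = tanh(z - zcrit * se),
         conf_high = tanh(z + zcrit * se), n = n, undefined = FALSE)
}
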