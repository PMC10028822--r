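# Spatial-module delineation: cluster cells on distance-weighted local
# cell-type-composition vectors, at two nested levels.

# Gaussian neighbour weight: 1 at distance 0, exp(-1) at the scaling
# distance d0, monotone decreasing.
neighbor_weight <- function(d, d0) exp(-(d / d0)^2)

#' Distance-weighted local cell-type-composition vectors
#'
#' For each eligible cell, its 50 spatially nearest eligible neighbours
#' (within the same section) are weighted by `exp(-(D/D0)^2)`, where `D0`
#' adapts to local density: twice the distance to the 5th nearest neighbour
#' at level 1, the 5th-nearest-neighbour distance itself at level 2 (finer
#' resolution). Each vector's elements sum the weights of neighbours per
#' type: subclasses at level 1; the subclass vector concatenated with the
#' cluster vector at level 2. Vectors are L2-normalised.
#'
#' Eligibility is the caller's: level-1 analyses conventionally exclude
#' vascular and immune cells (spatially unstructured), level-2 analyses keep
#' neurons only.
#'
#' @param cells A `cell_tbl` with `subclass_label` (and `cluster_label` for
#'   level 2).
#' @param level 1 or 2.
#' @param k Number of spatial neighbours (default 50).
#' @param eligible Optional logical vector: rows to include. Ineligible rows
#'   are dropped from the result.
#' @param d0_neighbor Which nearest neighbour sets the density scale
#'   (default 5).
#' @return The eligible rows of `cells` with a `composition` matrix column.
#' @export
composition_vectors <- function(cells, level = 1, k = 50, eligible = NULL,
                                d0_neighbor = 5) {
  if (!is.null(eligible)) cells <- cells[eligible, ]
  subclasses <- sort(unique(cells$subclass_label))
  clusters <- if (level == 2) sort(unique(cells$cluster_label)) else character()
  dims <- c(paste0("sub:", subclasses),
            if (level == 2) paste0("clu:", clusters))
  comp <- matrix(0, nrow(cells), length(dims), dimnames = list(NULL, dims))
  for (sec in unique(cells$section_id)) {
    idx <- which(cells$section_id == sec)
    if (length(idx) < d0_neighbor + 1)
      abort(paste0("section ", sec, ": fewer than ", d0_neighbor + 1,
                   " eligible cells; density scale undefined"))
    xy <- cbind(cells$x[idx], cells$y[idx])
    nn <- knn_index_dist(xy, xy, min(k, length(idx) - 1), self = FALSE)
    d0 <- nn$dist[, d0_neighbor]
    if (level == 1) d0 <- 2 * d0
    d0[d0 == 0] <- .Machine$double.eps
    w <- neighbor_weight(nn$dist, d0)
    sub_f <- match(cells$subclass_label[idx], subclasses)
    for (i in seq_along(idx)) {
      js <- nn$index[i, ]
      comp[idx[i], ] <- 0
      tw <- tapply(w[i, ], sub_f[js], sum)
      comp[idx[i], as.integer(names(tw))] <- tw
      if (level == 2) {
        clu_f <- match(cells$cluster_label[idx][js], clusters)
        tw2 <- tapply(w[i, ], clu_f, sum)
        comp[idx[i], length(subclasses) + as.integer(names(tw2))] <- tw2
      }
    }
  }
  nrm <- sqrt(rowSums(comp^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  cells$composition <- comp / nrm
  attr(cells, "zero_vector") <- zero
  cells
}

# merge module labels whose centroid composition vectors are nearly
# parallel (cosine similarity above the threshold), repeatedly
merge_similar_modules <- function(comp, labels, threshold) {
  repeat {
    levs <- sort(unique(labels))
    if (length(levs) < 2) break
    cent <- do.call(rbind, lapply(levs, function(l)
      colMeans(comp[labels == l, , drop = FALSE])))
    cent <- cent / sqrt(rowSums(cent^2))
    sim <- tcrossprod(cent)
    diag(sim) <- -Inf
    best <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    if (sim[best[1], best[2]] <= threshold) break
    labels[labels == levs[best[2]]] <- levs[best[1]]
  }
  match(labels, sort(unique(labels)))
}

#' Cluster composition vectors into spatial modules
#'
#' Leiden community detection (modularity objective) on the Euclidean k-NN
#' graph of the composition vectors, followed by merging of modules whose
#' centroid composition vectors have cosine similarity above
#' `merge_cosine` — the programmatic counterpart of curating away clusters
#' that do not form compositional boundaries. Set `merge_cosine = 1` to
#' disable merging.
#'
#' @param cells Output of [composition_vectors()].
#' @param knn Neighbours for the graph (default 15).
#' @param resolution Leiden resolution (default 0.1: level-1 modules are
#'   major-region-scale structures, so communities are kept coarse).
#' @param seed Integer seed (Leiden refinement is stochastic).
#' @param merge_cosine Centroid cosine-similarity merge threshold.
#' @return The `cell_tbl` with an integer `module` column.
#' @export
cluster_spatial_modules <- function(cells, knn = 15, resolution = 0.1,
                                    seed = 1, merge_cosine = 0.9) {
  comp <- cells$composition
  n <- nrow(comp)
  if (n <= knn) abort("need more cells than `knn`")
  nn <- knn_index(comp, comp, knn, self = FALSE)
  edges <- cbind(rep(seq_len(n), each = ncol(nn)), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  memb <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 3)))
  cells$module <- merge_similar_modules(comp, as.integer(memb), merge_cosine)
  cells
}

#' Level-2 spatial modules nested within level-1 modules
#'
#' Re-runs the composition-vector clustering separately inside each level-1
#' module, on neurons only, with the finer level-2 density scale and the
#' concatenated subclass + cluster vectors. Level-1 modules with fewer than
#' `d0_neighbor + 1` neurons become a single level-2 module.
#'
#' @param cells A `cell_tbl` with a level-1 `module` column.
#' @param neurons Logical vector: which rows are neurons.
#' @param k,knn,resolution,seed,merge_cosine,d0_neighbor As in
#'   [composition_vectors()] / [cluster_spatial_modules()].
#' @return The `cell_tbl` with a `module2` character column
#'   (`"<level1>.<local>"`; `NA` for non-neurons).
#' @export
level2_modules <- function(cells, neurons, k = 50, knn = 15,
                           resolution = 0.1, seed = 1, merge_cosine = 0.9,
                           d0_neighbor = 5) {
  if (!"module" %in% names(cells)) abort("level-1 `module` column required")
  out <- rep(NA_character_, nrow(cells))
  for (m in sort(unique(cells$module))) {
    idx <- which(cells$module == m & neurons)
    if (!length(idx)) next
    if (length(idx) < d0_neighbor + 1 || length(idx) <= knn) {
      out[idx] <- paste0(m, ".1")
      next
    }
    sub <- composition_vectors(cells[idx, ], level = 2, k = k,
                               d0_neighbor = d0_neighbor)
    sub <- cluster_spatial_modules(sub, knn = knn, resolution = resolution,
                                   seed = seed, merge_cosine = merge_cosine)
    out[idx] <- paste0(m, ".", sub$module)
  }
  cells$module2 <- out
  cells
}

#' Cell-type enrichment across spatial modules
#'
#' Fraction-mode enrichment of each type in each module (fold change of the
#' within-module fraction over the global fraction).
#'
#' @param cells A `cell_tbl` with a `module` column.
#' @param type_of Column giving the type (default `subclass_label`).
#' @return An `enrichment_tbl` (see [enrichment_scores()]).
#' @export
module_enrichment <- function(cells, type_of = "subclass_label") {
  enrichment_scores(cells, region_of = "module", type_of = type_of,
                    mode = "fraction")
}
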