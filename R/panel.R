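#' Differential-expression criteria for panel gene selection
#'
#' Defaults follow the panel-design rules: at least a 2-fold change between
#' the two clusters with p < 0.01, expressed in at least 50% of foreground
#' cells, and more than a 3.3-fold enrichment of the expressing fraction over
#' the background cluster; the 50 best genes by p-value are kept per
#' direction.
#'
#' @param min_fold Minimum fold change of normalised means (foreground over
#'   background).
#' @param max_p Maximum p-value (two-sided Wilcoxon rank-sum by default).
#' @param min_fg_expr_frac Minimum fraction of foreground cells expressing
#'   (count > 0).
#' @param min_frac_enrichment Minimum ratio of expressing fractions
#'   (strict >).
#' @param top_n Genes kept per direction, ranked by p.
#' @return A `de_criteria` list.
#' @export
de_criteria <- function(min_fold = 2, max_p = 0.01, min_fg_expr_frac = 0.5,
                        min_frac_enrichment = 3.3, top_n = 50) {
  stopifnot(min_fold > 0, max_p > 0, min_fg_expr_frac > 0,
            min_fg_expr_frac <= 1, min_frac_enrichment > 0, top_n > 0)
  structure(list(min_fold = min_fold, max_p = max_p,
                 min_fg_expr_frac = min_fg_expr_frac,
                 min_frac_enrichment = min_frac_enrichment, top_n = top_n),
            class = "de_criteria")
}

# per-cell total normalisation to the mean total (fold changes are invariant
# to the target constant)
norm_to_mean_total <- function(m) {
  tot <- rowSums(m)
  if (any(tot == 0)) abort("all-zero cell in reference counts")
  m / tot * mean(tot)
}

#' Differentially expressed genes between two reference clusters
#'
#' Ranks genes up in each direction under [de_criteria()]: fold change of
#' total-normalised means, two-sided Wilcoxon rank-sum p-value, foreground
#' expressing fraction, and expressing-fraction enrichment. The result is
#' antisymmetric: swapping the clusters swaps the two directions.
#'
#' @param ref A `ref_tbl`.
#' @param cluster_a,cluster_b Cluster labels (>= 2 cells each).
#' @param criteria A [de_criteria()].
#' @param test P-value function `function(x, y)` on normalised counts;
#'   defaults to the two-sided Wilcoxon rank-sum test.
#' @return A tibble with columns `direction` (`"a_up"` / `"b_up"`), `gene`,
#'   `fold`, `p`, `frac_fg`, `frac_bg`, ranked by `p` ascending within each
#'   direction and truncated to `top_n`.
#' @export
de_genes <- function(ref, cluster_a, cluster_b, criteria = de_criteria(),
                     test = function(x, y)
                       suppressWarnings(wilcox.test(x, y)$p.value)) {
  for (cl in c(cluster_a, cluster_b))
    if (!cl %in% ref$cluster_label) abort(paste0("unknown cluster label: ", cl))
  ia <- which(ref$cluster_label == cluster_a)
  ib <- which(ref$cluster_label == cluster_b)
  if (length(ia) < 2 || length(ib) < 2) abort("both clusters need >= 2 cells")
  m <- norm_to_mean_total(ref$counts[c(ia, ib), , drop = FALSE])
  a <- m[seq_along(ia), , drop = FALSE]
  b <- m[length(ia) + seq_along(ib), , drop = FALSE]
  raw_a <- ref$counts[ia, , drop = FALSE]
  raw_b <- ref$counts[ib, , drop = FALSE]
  genes <- colnames(m)
  mean_a <- colMeans(a); mean_b <- colMeans(b)
  frac_a <- colMeans(raw_a > 0); frac_b <- colMeans(raw_b > 0)
  p <- vapply(seq_along(genes), function(g) test(a[, g], b[, g]), numeric(1))

  one_dir <- function(fg_mean, bg_mean, fg_frac, bg_frac, label) {
    fold <- fg_mean / bg_mean
    frac_enr <- fg_frac / bg_frac
    keep <- !is.nan(fold) & fold >= criteria$min_fold &
      p < criteria$max_p &
      fg_frac >= criteria$min_fg_expr_frac &
      !is.nan(frac_enr) & frac_enr > criteria$min_frac_enrichment
    keep[is.na(keep)] <- FALSE
    out <- tibble(direction = label, gene = genes[keep], fold = fold[keep],
                  p = p[keep], frac_fg = fg_frac[keep], frac_bg = bg_frac[keep])
    out <- arrange(out, .data$p, .data$gene)
    head(out, criteria$top_n)
  }
  bind_rows(one_dir(mean_a, mean_b, frac_a, frac_b, "a_up"),
            one_dir(mean_b, mean_a, frac_b, frac_a, "b_up"))
}

#' Trim a candidate gene pool for imaging feasibility
#'
#' Removes genes that cannot accommodate enough encoding probes (fewer than
#' `min_probes` target regions, i.e. too short) or that are too abundant
#' (mean above `max_mean` counts in their highest-expressing cluster), both
#' read strictly.
#'
#' @param genes Candidate gene names.
#' @param probe_capacity Named integer vector: designable probes per gene.
#' @param cluster_max_mean Named numeric vector: each gene's mean expression
#'   in its highest-expressing cluster.
#' @param min_probes,max_mean Strict bounds (`< min_probes` or `> max_mean`
#'   removes).
#' @return The retained gene names.
#' @export
trim_pool <- function(genes, probe_capacity, cluster_max_mean,
                      min_probes = 40, max_mean = 3000) {
  if (!all(genes %in% names(probe_capacity)) ||
      !all(genes %in% names(cluster_max_mean)))
    abort("probe_capacity and cluster_max_mean must cover all genes")
  genes[probe_capacity[genes] >= min_probes & cluster_max_mean[genes] <= max_mean]
}

#' Assemble a gene panel with per-pair coverage guarantees
#'
#' Starts from a curated gene list and greedily adds differentially expressed
#' genes until every cluster pair is covered by at least `min_cover` panel
#' genes in each direction (or that pair's candidate pool is exhausted).
#' Pairs are visited worst-coverage-first; within a pair the best-p uncovered
#' gene is added.
#'
#' @param de_pool Tibble of per-pair ranked DE lists: columns `cluster_a`,
#'   `cluster_b`, `direction`, `gene`, `p` (the row-bound output of
#'   [de_genes()] over all cluster pairs, with the pair columns added).
#' @param curated Character vector of must-include genes.
#' @param min_cover Required panel genes per pair x direction.
#' @return A list with `panel` (character) and `uncovered` (tibble of pair x
#'   direction combinations whose pools ran out, with the coverage reached).
#' @export
assemble_panel <- function(de_pool, curated = character(), min_cover = 3) {
  panel <- unique(curated)
  if (min_cover == 0 || nrow(de_pool) == 0)
    return(list(panel = panel, uncovered = tibble(
      cluster_a = character(), cluster_b = character(),
      direction = character(), coverage = integer())))
  de_pool <- mutate(de_pool,
                    key = paste(.data$cluster_a, .data$cluster_b, .data$direction))
  pools <- split(de_pool, de_pool$key)
  pools <- lapply(pools, function(p) arrange(p, .data$p, .data$gene))
  coverage <- vapply(pools, function(p) sum(p$gene %in% panel), integer(1))
  exhausted <- rep(FALSE, length(pools)); names(exhausted) <- names(pools)
  repeat {
    open <- which(coverage < min_cover & !exhausted)
    if (!length(open)) break
    k <- open[order(coverage[open], names(coverage)[open])][1]
    candidates <- setdiff(pools[[k]]$gene, panel)
    if (!length(candidates)) { exhausted[k] <- TRUE; next }
    g <- candidates[1]  # pools are p-ranked
    panel <- c(panel, g)
    coverage <- coverage + vapply(pools, function(p) g %in% p$gene, logical(1))
  }
  short <- which(coverage < min_cover)
  uncovered <- if (length(short)) {
    info <- bind_rows(lapply(pools[short], function(p) p[1, c("cluster_a", "cluster_b", "direction")]))
    info$coverage <- as.integer(coverage[short])
    info
  } else tibble(cluster_a = character(), cluster_b = character(),
                direction = character(), coverage = integer())
  list(panel = panel, uncovered = as_tibble(uncovered))
}
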