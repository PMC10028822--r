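# Spatial-proximity cell-cell interaction testing with a local-randomization
# null, ligand-receptor co-expression scoring, and proximity-conditional
# gene upregulation.

#' Proximity-analysis parameters
#'
#' Strict calls use a 15 um centroid distance (about one soma); relaxed
#' calls use 30 um but additionally require a significantly upregulated
#' ligand-receptor pair. The null shifts every cell independently to a
#' uniform random position within 100 um of its original location, which
#' preserves the local density of every type while erasing fine-scale
#' pairing.
#'
#' @param r_proximal_strict,r_proximal_relaxed Proximity radii, um.
#' @param r_randomization Maximum local displacement, um.
#' @param n_rounds Randomization rounds (1000 in full analyses).
#' @param alpha BH-adjusted p-value threshold for interaction calls.
#' @param min_observed_pairs Minimum observed proximal pairs for a call.
#' @param seed Integer seed.
#' @return A `proximity_params` list.
#' @export
proximity_params <- function(r_proximal_strict = 15, r_proximal_relaxed = 30,
                             r_randomization = 100, n_rounds = 1000,
                             alpha = 0.05, min_observed_pairs = 20,
                             seed = 1) {
  stopifnot(r_proximal_strict < r_randomization,
            r_proximal_relaxed < r_randomization, n_rounds >= 2)
  structure(list(r_proximal_strict = r_proximal_strict,
                 r_proximal_relaxed = r_proximal_relaxed,
                 r_randomization = r_randomization, n_rounds = n_rounds,
                 alpha = alpha, min_observed_pairs = min_observed_pairs,
                 seed = seed), class = "proximity_params")
}

# grid-bucketed proximal pair count between coordinate sets; same_set
# counts unordered pairs once and never counts a cell with itself
count_proximal_xy <- function(xy_a, xy_b, r, same_set = FALSE) {
  na <- nrow(xy_a); nb <- nrow(xy_b)
  if (na == 0 || nb == 0) return(0L)
  ox <- min(xy_a[, 1], xy_b[, 1]); oy <- min(xy_a[, 2], xy_b[, 2])
  gx_a <- floor((xy_a[, 1] - ox) / r); gy_a <- floor((xy_a[, 2] - oy) / r)
  gx_b <- floor((xy_b[, 1] - ox) / r); gy_b <- floor((xy_b[, 2] - oy) / r)
  key_b <- split(seq_len(nb), paste(gx_b, gy_b))
  r2 <- r * r
  total <- 0L
  for (i in seq_len(na)) {
    for (dx in -1:1) for (dy in -1:1) {
      js <- key_b[[paste(gx_a[i] + dx, gy_a[i] + dy)]]
      if (is.null(js)) next
      if (same_set) js <- js[js > i]
      if (!length(js)) next
      d2 <- (xy_b[js, 1] - xy_a[i, 1])^2 + (xy_b[js, 2] - xy_a[i, 2])^2
      total <- total + sum(d2 < r2)
    }
  }
  total
}

#' Count proximal cell pairs between two cell sets
#'
#' Number of unordered pairs, one cell from each table, with centroid
#' distance strictly below `r`, summed over sections. When the two tables
#' are the same cells, each unordered pair is counted once.
#'
#' @param cells_a,cells_b `cell_tbl`s (may be identical).
#' @param r Proximity radius, um.
#' @return Integer pair count.
#' @export
count_proximal <- function(cells_a, cells_b, r) {
  same <- identical(cells_a$cell_id, cells_b$cell_id)
  total <- 0L
  for (sec in union(cells_a$section_id, cells_b$section_id)) {
    ia <- cells_a$section_id == sec
    ib <- cells_b$section_id == sec
    total <- total + count_proximal_xy(
      cbind(cells_a$x[ia], cells_a$y[ia]),
      cbind(cells_b$x[ib], cells_b$y[ib]), r, same_set = same)
  }
  total
}

# fold coordinates back into [lo, hi] by reflection at the bounds
reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(rep(lo, length(v)))
  u <- (v - lo) %% (2 * w)
  lo + ifelse(u > w, 2 * w - u, u)
}

# one randomization round: displace every cell uniformly within the disk,
# reflecting at the section bounding box. Reflection keeps the point
# density uniform (a spill-over null is biased low near tissue edges and
# makes the test anti-conservative) and never moves a cell further from
# its origin than the raw displacement, so positions stay within r_max.
displace <- function(x, y, r_max, xlim = range(x), ylim = range(y)) {
  n <- length(x)
  ang <- runif(n, 0, 2 * pi)
  rad <- r_max * sqrt(runif(n))
  list(x = reflect_into(x + rad * cos(ang), xlim[1], xlim[2]),
       y = reflect_into(y + rad * sin(ang), ylim[1], ylim[2]))
}

# all unordered proximal pair counts tabulated by type pair, in row blocks
# so memory stays bounded; counts land in the upper triangle (ta <= tb)
count_by_type <- function(x, y, type_idx, n_types, r, block = 2048L) {
  n <- length(x)
  counts <- matrix(0L, n_types, n_types)
  xy <- cbind(x, y)
  r2 <- r * r
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    d2 <- cross_dist2(xy[lo:hi, , drop = FALSE], xy)
    hit <- which(d2 < r2, arr.ind = TRUE)
    hit[, 1] <- hit[, 1] + lo - 1L
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit)) {
      ta <- pmin(type_idx[hit[, 1]], type_idx[hit[, 2]])
      tb <- pmax(type_idx[hit[, 1]], type_idx[hit[, 2]])
      counts <- counts + as.matrix(table(factor(ta, seq_len(n_types)),
                                         factor(tb, seq_len(n_types))))
    }
  }
  counts
}

# per-round proximal counts for a list of type pairs, sharing the rounds
randomized_counts <- function(cells, type_pairs, r, params) {
  types <- sort(unique(c(type_pairs$type_a, type_pairs$type_b)))
  type_idx <- match(cells$subclass_label, types)
  in_play <- !is.na(type_idx)
  sec <- cells$section_id[in_play]
  x0 <- cells$x[in_play]; y0 <- cells$y[in_play]; ti <- type_idx[in_play]
  ka <- match(type_pairs$type_a, types)
  kb <- match(type_pairs$type_b, types)
  out <- matrix(0L, params$n_rounds, nrow(type_pairs))
  secs <- unique(sec)
  # reflection bounds come from the full cell table, not just tested types
  lims <- lapply(secs, function(s) {
    i <- cells$section_id == s
    list(x = range(cells$x[i]), y = range(cells$y[i]))
  })
  names(lims) <- secs
  for (rd in seq_len(params$n_rounds)) {
    tab <- matrix(0L, length(types), length(types))
    for (s in secs) {
      i <- sec == s
      sh <- displace(x0[i], y0[i], params$r_randomization,
                     lims[[s]]$x, lims[[s]]$y)
      tab <- tab + count_by_type(sh$x, sh$y, ti[i], length(types), r)
    }
    out[rd, ] <- tab[cbind(pmin(ka, kb), pmax(ka, kb))]
  }
  out
}

#' Local-randomization null for one type pair
#'
#' Every cell of the region (all types, preserving local densities) is
#' shifted to a uniform random position within `r_randomization` um of its
#' original location; the proximal pair count between the two types is
#' recorded per round and summarised by a fitted normal (sample mean and
#' sd, sd floored at 1e-9).
#'
#' @param cells A `cell_tbl` (one region's cells, all types).
#' @param type_a,type_b Subclass labels.
#' @param r Proximity radius, um.
#' @param params A [proximity_params()].
#' @return List with `mean`, `sd` and the per-round `samples`.
#' @export
randomization_null <- function(cells, type_a, type_b,
                               r = NULL, params = proximity_params()) {
  r <- r %||% params$r_proximal_strict
  samples <- with_seed(params$seed, randomized_counts(
    cells, tibble(type_a = type_a, type_b = type_b), r, params))[, 1]
  list(mean = mean(samples), sd = max(sd(samples), 1e-9), samples = samples)
}

#' Test all type pairs of a region for spatial proximity enrichment
#'
#' Compares each pair's observed proximal count with the normal fit of its
#' local-randomization null: `p_raw` is the upper-tail probability (floored
#' at `1 / (n_rounds + 1)`), `fold` the observed count over the null mean.
#' BH correction runs across all type pairs of the region; a pair is called
#' when `p_adj < alpha` and the observed count reaches
#' `min_observed_pairs`. Self pairs are computed but flagged.
#'
#' @param cells A `cell_tbl` of one region.
#' @param types Subclass labels to test (defaults to all present).
#' @param r Proximity radius, um (defaults to the strict radius).
#' @param params A [proximity_params()].
#' @return Tibble of class `interaction_tbl`: `type_a`, `type_b`,
#'   `observed`, `null_mean`, `null_sd`, `fold`, `p_raw`, `p_adj`,
#'   `called`, `self_pair`.
#' @export
test_interactions <- function(cells, types = NULL, r = NULL,
                              params = proximity_params()) {
  types <- sort(types %||% unique(cells$subclass_label))
  types <- types[vapply(types, function(t)
    sum(cells$subclass_label == t) > 0, logical(1))]
  r <- r %||% params$r_proximal_strict
  if (length(types) == 0)
    return(tibble(type_a = character(), type_b = character(),
                  observed = integer(), null_mean = numeric(),
                  null_sd = numeric(), fold = numeric(), p_raw = numeric(),
                  p_adj = numeric(), called = logical(),
                  self_pair = logical()))
  pairs <- bind_rows(
    tibble(type_a = types, type_b = types),
    if (length(types) > 1) {
      cmb <- utils::combn(types, 2)
      tibble(type_a = cmb[1, ], type_b = cmb[2, ])
    })
  pairs <- arrange(pairs, .data$type_a, .data$type_b)
  observed <- map_int(seq_len(nrow(pairs)), function(k) {
    a <- cells[cells$subclass_label == pairs$type_a[k], ]
    b <- cells[cells$subclass_label == pairs$type_b[k], ]
    as.integer(count_proximal(a, b, r))
  })
  null <- with_seed(params$seed, randomized_counts(cells, pairs, r, params))
  mu <- colMeans(null)
  sdv <- pmax(apply(null, 2, sd), 1e-9)
  # continuity correction: the observed count is discrete, the null fit is
  # continuous; without it the right tail is anti-conservative
  p_raw <- pmax(pnorm(observed - 0.5, mu, sdv, lower.tail = FALSE),
                1 / (params$n_rounds + 1))
  out <- pairs |>
    mutate(observed = observed, null_mean = mu, null_sd = sdv,
           fold = ifelse(mu > 0, observed / mu, ifelse(observed > 0, Inf, 0)),
           p_raw = p_raw, p_adj = bh_adjust(p_raw),
           called = .data$p_adj < params$alpha &
             observed >= params$min_observed_pairs,
           self_pair = .data$type_a == .data$type_b)
  class(out) <- unique(c("interaction_tbl", class(out)))
  out
}

#' Eligible cell types of a region for interaction analysis
#'
#' Cells are first filtered to subclass-transfer confidence > 0.8. Neuronal
#' types are kept when their enrichment score in the region reaches 6 in
#' the subdivided (cell-type-dense) regions and 2 elsewhere; astrocyte
#' types at 1; remaining non-neuronal types when the region holds more than
#' 50 of their cells.
#'
#' @param cells A `cell_tbl` with `subclass_label`, `subclass_confidence`
#'   and region labels.
#' @param region Region to analyse.
#' @param enrichment An `enrichment_tbl` over the same regions and types.
#' @param type_class Named character vector: type -> `"neuronal"`,
#'   `"astrocyte"` or `"other"`.
#' @param subdivided_regions Regions using the stringent threshold of 6.
#' @param region_col Column holding region labels.
#' @param confidence_gate Subclass-confidence filter (strict >).
#' @return List with `cells` (the region's confident cells) and `types`
#'   (eligible subclass labels).
#' @export
eligible_types <- function(cells, region, enrichment, type_class,
                           subdivided_regions = character(),
                           region_col = "region_label",
                           confidence_gate = 0.8) {
  conf <- cells$subclass_confidence %||% rep(1, nrow(cells))
  conf[is.na(conf)] <- 0
  sub <- cells[cells[[region_col]] == region & conf > confidence_gate, ]
  counts <- table(sub$subclass_label)
  neuronal_thr <- if (region %in% subdivided_regions) 6 else 2
  scores <- enrichment[enrichment$region == region, ]
  score_of <- setNames(scores$score, scores$type)
  keep <- vapply(names(counts), function(t) {
    cls <- type_class[[t]] %||% "other"
    s <- score_of[[t]] %||% 0
    switch(cls,
           neuronal = s >= neuronal_thr,
           astrocyte = s >= 1,
           counts[[t]] > 50)
  }, logical(1))
  list(cells = sub, types = sort(names(counts)[keep]))
}

# ---- ligand-receptor scoring ------------------------------------------------

#' Ligand-receptor co-expression score for a cell pair
#'
#' `S = log(1 + prod(ligand subunits in the sender) * prod(receptor
#' subunits in the receiver))`, natural log, so S >= 0 and S = 0 when any
#' side is silent. The `literal` variant raises each side's product to the
#' other side's subunit count (the strict reading of a double product over
#' subunit index pairs).
#'
#' @param ligand_expr Expression of the ligand subunits in the sender cell.
#' @param receptor_expr Expression of the receptor subunits in the receiver.
#' @param literal Use the double-product-over-index-pairs variant.
#' @return Non-negative scalar score.
#' @export
lr_score <- function(ligand_expr, receptor_expr, literal = FALSE) {
  if (literal)
    log1p(prod(ligand_expr)^length(receptor_expr) *
            prod(receptor_expr)^length(ligand_expr))
  else
    log1p(prod(ligand_expr) * prod(receptor_expr))
}

# per-cell subunit products for one side of an LR pair
subunit_product <- function(expr, genes) {
  apply(expr[, genes, drop = FALSE], 1, prod)
}

#' Test ligand-receptor upregulation in proximal cell pairs
#'
#' For each database pair, scores all proximal (A, B) cell pairs (sender A,
#' receiver B, centroid distance < `r`) and an equal-size seeded random
#' sample of non-proximal pairs, then applies a one-sided Welch t-test
#' (proximal greater). Significance requires a fold of means >= 2,
#' BH-adjusted p < 0.01 within the type pair, and a positive score in at
#' least 40% of proximal pairs.
#'
#' @param cells_a,cells_b `cell_tbl`s of the two types (same section set).
#' @param lrdb An `lr_db`.
#' @param expr Expression matrix (cells x genes) with `cell_id` row names;
#'   imputed log-normalised profiles when available, measured normalised
#'   counts otherwise.
#' @param r Proximity radius, um (default: relaxed, 30).
#' @param params A [proximity_params()].
#' @param min_fold,max_p,min_frac_positive The three significance criteria.
#' @param literal Passed to [lr_score()].
#' @return Tibble of class `lr_tbl`: `pair_id`, `pathway`, `n_proximal`,
#'   `mean_proximal`, `mean_nonproximal`, `fold`, `frac_positive_proximal`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
lr_test <- function(cells_a, cells_b, lrdb, expr, r = NULL,
                    params = proximity_params(), min_fold = 2, max_p = 0.01,
                    min_frac_positive = 0.4, literal = FALSE) {
  r <- r %||% params$r_proximal_relaxed
  d2 <- cross_dist2(cbind(cells_a$x, cells_a$y), cbind(cells_b$x, cells_b$y))
  cross_section <- outer(cells_a$section_id, cells_b$section_id, "!=")
  d2[cross_section] <- Inf
  same <- identical(cells_a$cell_id, cells_b$cell_id)
  if (same) diag(d2) <- Inf
  prox <- which(d2 < r^2, arr.ind = TRUE)
  if (same) prox <- prox[prox[, 1] < prox[, 2], , drop = FALSE]
  if (nrow(prox) < 2) abort("need at least 2 proximal pairs")
  nonprox_all <- which(is.finite(d2) & d2 > r^2, arr.ind = TRUE)
  if (same) nonprox_all <- nonprox_all[nonprox_all[, 1] < nonprox_all[, 2], ,
                                       drop = FALSE]
  n_pick <- nrow(prox)
  if (nrow(nonprox_all) < n_pick) {
    warn("fewer non-proximal than proximal pairs; using all")
    n_pick <- nrow(nonprox_all)
  }
  nonprox <- with_seed(params$seed,
                       nonprox_all[sample(nrow(nonprox_all), n_pick), ,
                                   drop = FALSE])
  ea <- expr[cells_a$cell_id, , drop = FALSE]
  eb <- expr[cells_b$cell_id, , drop = FALSE]
  res <- map(seq_len(nrow(lrdb)), function(k) {
    lg <- lrdb$ligand_subunits[[k]]; rg <- lrdb$receptor_subunits[[k]]
    if (!all(c(lg, rg) %in% colnames(expr))) {
      warn(sprintf("pair %s: subunit gene missing from expression; skipped",
                   lrdb$pair_id[k]))
      return(NULL)
    }
    pl <- subunit_product(ea, lg)
    pr <- subunit_product(eb, rg)
    score_of <- function(idx) {
      raw <- pl[idx[, 1]] * pr[idx[, 2]]
      if (literal) log1p(pl[idx[, 1]]^length(rg) * pr[idx[, 2]]^length(lg))
      else log1p(raw)
    }
    s_prox <- score_of(prox)
    s_non <- score_of(nonprox)
    tibble(pair_id = lrdb$pair_id[k], pathway = lrdb$pathway[k],
           n_proximal = length(s_prox),
           mean_proximal = mean(s_prox), mean_nonproximal = mean(s_non),
           fold = ifelse(mean(s_non) > 0, mean(s_prox) / mean(s_non), Inf),
           frac_positive_proximal = mean(s_prox > 0),
           p_raw = welch_greater(s_prox, s_non))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) return(out)
  out <- mutate(out, p_adj = bh_adjust(.data$p_raw),
                significant = .data$fold >= min_fold & .data$p_adj < max_p &
                  .data$frac_positive_proximal >= min_frac_positive)
  class(out) <- unique(c("lr_tbl", class(out)))
  out
}

#' Genes upregulated in proximity-exposed cells
#'
#' Splits type-A cells by whether they lie within `r` of any type-B cell
#' and tests each highly variable gene for higher mean expression in the
#' proximal group (one-sided Welch, BH within this type pair and
#' direction); kept genes need fold >= 2 and adjusted p < 0.01.
#'
#' @param cells_a,cells_b `cell_tbl`s of the two types.
#' @param expr Expression matrix with `cell_id` row names.
#' @param hvgs Highly variable genes of type A to test (defaults to
#'   positive-log-dispersion genes of the A cells).
#' @param r Proximity radius, um.
#' @param min_fold,max_p Significance criteria.
#' @return Tibble `gene`, `mean_proximal`, `mean_nonproximal`, `fold`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
upregulated_genes <- function(cells_a, cells_b, expr, hvgs = NULL, r = 30,
                              min_fold = 2, max_p = 0.01) {
  if (nrow(cells_b) == 0)
    return(tibble(gene = character(), mean_proximal = numeric(),
                  mean_nonproximal = numeric(), fold = numeric(),
                  p_raw = numeric(), p_adj = numeric(),
                  significant = logical()))
  d2 <- cross_dist2(cbind(cells_a$x, cells_a$y), cbind(cells_b$x, cells_b$y))
  d2[outer(cells_a$section_id, cells_b$section_id, "!=")] <- Inf
  exposed <- rowSums(d2 < r^2) > 0
  ea <- expr[cells_a$cell_id, , drop = FALSE]
  hvgs <- hvgs %||% positive_dispersion_genes(
    pmax(ea, 0), min_genes = min(5, ncol(ea)))
  hvgs <- intersect(hvgs, colnames(ea))
  if (!any(exposed) || all(exposed)) {
    warn("one proximity group is empty; no genes testable")
    return(tibble(gene = character(), mean_proximal = numeric(),
                  mean_nonproximal = numeric(), fold = numeric(),
                  p_raw = numeric(), p_adj = numeric(),
                  significant = logical()))
  }
  res <- map(hvgs, function(g) {
    xp <- ea[exposed, g]; xn <- ea[!exposed, g]
    tibble(gene = g, mean_proximal = mean(xp), mean_nonproximal = mean(xn),
           fold = ifelse(mean(xn) > 0, mean(xp) / mean(xn),
                         ifelse(mean(xp) > 0, Inf, 1)),
           p_raw = welch_greater(xp, xn))
  })
  bind_rows(res) |>
    mutate(p_adj = bh_adjust(.data$p_raw),
           significant = .data$fold >= min_fold & .data$p_adj < max_p)
}

#' Full interaction-calling pipeline for one or more regions
#'
#' Runs the strict (15 um) and relaxed (30 um) proximity tests per region;
#' relaxed-only candidate pairs are kept only when at least one
#' ligand-receptor pair is significantly upregulated in their proximal cell
#' pairs. The merged call set is deduplicated (a strict call also found at
#' the relaxed radius appears once, in strict mode).
#'
#' @param cells A `cell_tbl` with region labels.
#' @param lrdb An `lr_db`.
#' @param expr Expression matrix with `cell_id` row names (imputed when
#'   available).
#' @param params A [proximity_params()].
#' @param types Optional eligible types per region (named list); defaults
#'   to all types present.
#' @param region_col Column holding region labels.
#' @return List of class `interaction_calls`: `interactions` (all tested
#'   pairs, both modes), `calls` (deduplicated called pairs with mode),
#'   `lr_hits` (LR tests of relaxed candidates).
#' @export
call_pipeline <- function(cells, lrdb, expr, params = proximity_params(),
                          types = NULL, region_col = "region_label") {
  regions <- sort(unique(cells[[region_col]]))
  all_int <- list(); all_lr <- list(); calls <- list()
  for (rg in regions) {
    rc <- cells[cells[[region_col]] == rg, ]
    tps <- if (is.null(types)) NULL else types[[rg]]
    strict <- test_interactions(rc, types = tps,
                                r = params$r_proximal_strict, params = params)
    relaxed <- test_interactions(rc, types = tps,
                                 r = params$r_proximal_relaxed, params = params)
    strict$mode <- "strict15"; relaxed$mode <- "relaxed30"
    strict$region <- rg; relaxed$region <- rg
    all_int[[rg]] <- bind_rows(strict, relaxed)
    called_strict <- strict[strict$called, ]
    # relaxed candidates not already called strictly need an LR hit
    key <- function(d) paste(d$type_a, d$type_b)
    cand <- relaxed[relaxed$called & !(key(relaxed) %in% key(called_strict)), ]
    lr_ok <- logical(nrow(cand))
    if (nrow(cand)) for (k in seq_len(nrow(cand))) {
      a <- rc[rc$subclass_label == cand$type_a[k], ]
      b <- rc[rc$subclass_label == cand$type_b[k], ]
      hit <- tryCatch(
        lr_test(a, b, lrdb, expr, r = params$r_proximal_relaxed,
                params = params),
        error = function(e) NULL)
      if (!is.null(hit) && nrow(hit)) {
        hit$region <- rg; hit$type_a <- cand$type_a[k]; hit$type_b <- cand$type_b[k]
        all_lr[[length(all_lr) + 1L]] <- hit
        lr_ok[k] <- any(hit$significant)
      }
    }
    calls[[rg]] <- bind_rows(called_strict,
                             cand[lr_ok, , drop = FALSE])
  }
  out <- list(interactions = bind_rows(all_int),
              calls = bind_rows(calls),
              lr_hits = bind_rows(all_lr))
  class(out) <- "interaction_calls"
  out
}
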