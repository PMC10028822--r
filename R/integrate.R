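# Anchor-based integration of measured (in situ) cells with a dissociated
# single-cell reference: CCA co-embedding, mutual-nearest-neighbour anchors,
# two-round label transfer with multiplicative confidence scores, and
# transcriptome-wide imputation.

#' Standardise a count matrix for integration
#'
#' Normalises each cell's total to `total` (1000), log1p-transforms, and
#' scales each gene to zero mean and unit variance. Constant genes become
#' all-zero columns.
#'
#' @param m Cells x genes non-negative matrix.
#' @param total Per-cell total before the log transform.
#' @param log1p,zscore Toggles for the later stages (z-scoring off gives the
#'   log-normalised matrix used for imputation and profiles).
#' @return Matrix of the same shape.
#' @export
standardize <- function(m, total = 1000, log1p = TRUE, zscore = TRUE) {
  m <- as.matrix(m)
  tot <- rowSums(m)
  if (any(tot == 0)) abort("all-zero cell: cannot normalise")
  m <- m / tot * total
  if (log1p) m <- log1p(m)
  if (zscore) m <- zscore_cols(m)
  m
}

joint_pca <- function(z_ref, z_meas, dims) {
  z <- rbind(z_ref, z_meas)
  dims <- min(dims, ncol(z), nrow(z) - 1)
  p <- prcomp(z, center = FALSE, rank. = dims)
  list(ref = p$x[seq_len(nrow(z_ref)), , drop = FALSE],
       meas = p$x[nrow(z_ref) + seq_len(nrow(z_meas)), , drop = FALSE])
}

# deterministic sign convention for singular vectors
fix_signs <- function(u, v) {
  s <- vapply(seq_len(ncol(u)), function(j) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) -1 else 1
  }, numeric(1))
  list(u = sweep(u, 2, s, "*"), v = sweep(v, 2, s, "*"))
}

#' Co-embed two standardised datasets by canonical correlation analysis
#'
#' The canonical vectors are the singular vectors of the cross-product of
#' the two (optionally downsampled) standardised matrices over shared genes.
#' Full datasets are then projected through fitted gene-space linear maps,
#' and each cell's embedding vector is L2-normalised.
#'
#' @param ref_z,meas_z Standardised matrices (see [standardize()]) with
#'   aligned gene columns.
#' @param dims Embedding dimensionality (<= min(genes, cells per side)).
#' @param downsample Maximum cells per side entering the decomposition.
#' @param seed Seed for the downsampling draw.
#' @return List with `ref` and `meas` embedding matrices (rows
#'   L2-normalised).
#' @export
cca_coembed <- function(ref_z, meas_z, dims = 100, downsample = 100000,
                        seed = 1) {
  stopifnot(ncol(ref_z) == ncol(meas_z))
  max_dims <- min(ncol(ref_z), nrow(ref_z), nrow(meas_z))
  if (dims > max_dims)
    abort(sprintf("dims = %d exceeds min(genes, cells) = %d", dims, max_dims))
  with_seed(seed, {
    xi <- if (nrow(ref_z) > downsample) sort(sample(nrow(ref_z), downsample))
          else seq_len(nrow(ref_z))
    yi <- if (nrow(meas_z) > downsample) sort(sample(nrow(meas_z), downsample))
          else seq_len(nrow(meas_z))
    xd <- ref_z[xi, , drop = FALSE]
    yd <- meas_z[yi, , drop = FALSE]
    # With xd = Ux Dx Vx', yd = Uy Dy Vy', the cross-product xd yd' has the
    # same singular structure as the small core Dx (Vx' Vy) Dy, so the
    # canonical vectors come from the g x g core; the gene-space maps
    # Vx Dx^-1 u project the full datasets into the CCA space.
    sx <- svd(xd); sy <- svd(yd)
    kx <- sx$d > 1e-10 * sx$d[1]
    ky <- sy$d > 1e-10 * sy$d[1]
    core <- svd(sx$d[kx] * (crossprod(sx$v[, kx, drop = FALSE],
                                      sy$v[, ky, drop = FALSE]) %*%
                              diag(sy$d[ky], sum(ky))))
    dims <- min(dims, sum(kx), sum(ky))
    fs <- fix_signs(core$u[, seq_len(dims), drop = FALSE],
                    core$v[, seq_len(dims), drop = FALSE])
    wx <- sx$v[, kx, drop = FALSE] %*% (fs$u / sx$d[kx])
    wy <- sy$v[, ky, drop = FALSE] %*% (fs$v / sy$d[ky])
    ref_emb <- ref_z %*% wx
    meas_emb <- meas_z %*% wy
    l2 <- function(m) {
      nrm <- sqrt(rowSums(m^2)); nrm[nrm == 0] <- 1; m / nrm
    }
    list(ref = l2(ref_emb), meas = l2(meas_emb))
  })
}

#' Find integration anchors as mutual nearest neighbours
#'
#' Cross-dataset pairs (reference cell, measured cell) that are within each
#' other's `k` nearest neighbours in the co-embedded space. Ties break by
#' cell index.
#'
#' @param emb_ref,emb_meas Embedding matrices with equal dimensionality.
#' @param k Neighbours per side (default 5).
#' @return Tibble `ref_index`, `meas_index` of class `anchor_set`.
#' @export
find_anchors <- function(emb_ref, emb_meas, k = 5) {
  if (nrow(emb_ref) == 0 || nrow(emb_meas) == 0)
    abort("both datasets must be non-empty")
  stopifnot(ncol(emb_ref) == ncol(emb_meas))
  k <- min(k, nrow(emb_ref), nrow(emb_meas))
  nn_rm <- knn_index(emb_ref, emb_meas, k)   # for each ref cell: meas NNs
  nn_mr <- knn_index(emb_meas, emb_ref, k)   # for each meas cell: ref NNs
  pairs <- tibble(
    ref_index = rep(seq_len(nrow(emb_ref)), each = k),
    meas_index = as.vector(t(nn_rm)))
  mutual <- vapply(seq_len(nrow(pairs)), function(i)
    pairs$ref_index[i] %in% nn_mr[pairs$meas_index[i], ], logical(1))
  out <- arrange(pairs[mutual, ], .data$ref_index, .data$meas_index)
  class(out) <- unique(c("anchor_set", class(out)))
  out
}

#' Transfer labels through anchors
#'
#' Each measured cell takes the majority label among its `k_anchor` nearest
#' anchor reference-cells in the joint space; the confidence score is the
#' fraction of those carrying the assigned label (argmax, lexicographic
#' tie-break).
#'
#' @param anchors An `anchor_set`.
#' @param ref_labels Per-reference-cell labels.
#' @param joint_ref,joint_meas Joint-space coordinates (e.g. combined PCA)
#'   for reference and measured cells.
#' @param k_anchor Anchor neighbours used per cell (default 100).
#' @return Tibble `label`, `confidence` (one row per measured cell).
#' @export
transfer_labels <- function(anchors, ref_labels, joint_ref, joint_meas,
                            k_anchor = 100) {
  if (nrow(anchors) == 0) abort("no anchors")
  anchor_cells <- sort(unique(anchors$ref_index))
  k <- min(k_anchor, length(anchor_cells))
  nn <- knn_index(joint_meas, joint_ref[anchor_cells, , drop = FALSE], k)
  labs <- ref_labels[anchor_cells]
  res <- apply(nn, 1, function(js) {
    tab <- table(labs[js])
    top <- sort(names(tab)[tab == max(tab)])[1]
    c(top, max(tab) / length(js))
  })
  tibble(label = res[1, ], confidence = as.numeric(res[2, ]))
}

# ---- reference partitioning -------------------------------------------------

# balanced k-way partition of a weighted subclass graph: exhaustive for
# small 2-way instances, otherwise greedy packing + Kernighan-Lin style
# refinement under a +/-1 subclass-count balance constraint
partition_graph <- function(w, sizes, n_parts) {
  n <- nrow(w)
  if (n_parts == 1) return(rep(1L, n))
  if (n_parts > n) abort("n_parts exceeds the number of subclasses")
  cut_weight <- function(assign) {
    tot <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      if (assign[i] != assign[j]) tot <- tot + w[i, j]
    tot
  }
  if (n_parts == 2 && n <= 14) {
    half <- floor(n / 2)
    combos <- utils::combn(n, half)
    best <- NULL; best_cut <- Inf
    for (ci in seq_len(ncol(combos))) {
      assign <- rep(2L, n); assign[combos[, ci]] <- 1L
      cw <- cut_weight(assign)
      if (cw < best_cut) { best_cut <- cw; best <- assign }
    }
    return(best)
  }
  target <- ceiling(n / n_parts)
  assign <- ((order(-sizes) - 1L) %% n_parts) + 1L
  assign <- assign[order(order(-sizes))]
  # refinement: move/swap while cut decreases and balance holds
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) for (p in seq_len(n_parts)) {
      if (assign[i] == p) next
      if (sum(assign == p) >= target) next
      old <- assign[i]
      gain <- sum(w[i, assign == old]) - sum(w[i, assign == p])
      if (gain > 0) { assign[i] <- p; improved <- TRUE }
    }
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (assign[i] == assign[j]) next
      a <- assign
      a[i] <- assign[j]; a[j] <- assign[i]
      if (cut_weight(a) < cut_weight(assign)) { assign <- a; improved <- TRUE }
    }
    if (!improved) break
  }
  assign
}

#' Partition reference subclasses for two-round integration
#'
#' Builds the subclass connectivity graph — nodes are subclasses, edge
#' weights count nearest-neighbour-graph edges (15-NN in 100-dimensional
#' PCA of the standardised counts) joining cells of the two subclasses —
#' and splits it into `n_parts` balanced groups minimising the cut weight.
#' Transcriptionally close subclasses stay together, so each partition's
#' second-round integration sees a coherent expression neighbourhood.
#'
#' @param ref A `ref_tbl`.
#' @param n_parts Number of partitions (defaults to about one per 6.4
#'   subclasses, mirroring 306 subclasses -> 48 partitions; minimum 1).
#' @param panel Optional gene subset (the measured panel).
#' @param pca_dims,knn Graph-construction parameters.
#' @return The `ref_tbl` with an integer `partition_label` column, plus
#'   attribute `partition_of_subclass` (named vector).
#' @export
build_partitions <- function(ref, n_parts = NULL, panel = NULL,
                             pca_dims = 100, knn = 15) {
  subclasses <- sort(unique(ref$subclass_label))
  if (is.null(n_parts)) n_parts <- max(1L, ceiling(length(subclasses) / 6.4))
  if (n_parts > length(subclasses))
    abort("n_parts exceeds the number of subclasses")
  m <- ref$counts
  if (!is.null(panel)) m <- m[, intersect(panel, colnames(m)), drop = FALSE]
  z <- standardize(m)
  dims <- min(pca_dims, ncol(z), nrow(z) - 1)
  pcs <- prcomp(z, center = FALSE, rank. = dims)$x
  nn <- knn_index(pcs, pcs, min(knn, nrow(pcs) - 1), self = FALSE)
  sub_idx <- match(ref$subclass_label, subclasses)
  w <- matrix(0, length(subclasses), length(subclasses))
  for (i in seq_len(nrow(nn))) {
    si <- sub_idx[i]
    for (j in nn[i, ]) {
      sj <- sub_idx[j]
      if (si != sj) w[si, sj] <- w[si, sj] + 1
    }
  }
  w <- w + t(w)
  sizes <- as.numeric(table(factor(ref$subclass_label, subclasses)))
  assign <- partition_graph(w, sizes, n_parts)
  names(assign) <- subclasses
  ref$partition_label <- unname(assign[ref$subclass_label])
  attr(ref, "partition_of_subclass") <- assign
  ref
}

# partition-local gene choice: keep genes whose dispersion (variance over
# mean of total-normalised counts) has positive log
positive_dispersion_genes <- function(counts, total = 1000, min_genes = 5) {
  m <- standardize(counts, total = total, log1p = FALSE, zscore = FALSE)
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  genes <- colnames(counts)[disp > 1]
  if (length(genes) < min_genes) genes <- colnames(counts)
  genes
}

#' Two-round anchor-based label transfer
#'
#' Round 1 transfers integration-partition labels on the measured gene
#' panel; round 2 runs independently within each partition on the
#' partition's positive-log-dispersion genes, transferring subclass and
#' cluster labels. Because a subclass or cluster label is only right when
#' the partition label was too, final confidences are the round-2 scores
#' multiplied by the partition confidence; cells pass at > 0.8 (subclass)
#' and > 0.5 (cluster).
#'
#' @param meas A `cell_tbl`.
#' @param ref A `ref_tbl`; `partition_label` is built with
#'   [build_partitions()] if absent.
#' @param dims Embedding dimensionality cap for PCA and CCA.
#' @param anchor_k Mutual-nearest-neighbour order for anchors.
#' @param k_anchor Anchor neighbours per transferred cell.
#' @param downsample Maximum cells per side entering the CCA decomposition.
#' @param seed Integer seed.
#' @param subclass_gate,cluster_gate Confidence gates (strict >).
#' @return A `transfer_result` tibble: per measured cell the partition,
#'   subclass and cluster labels with raw and adjusted confidences and pass
#'   flags. Attributes `anchors`, `joint_ref`, `joint_meas` carry the
#'   round-1 anchor set and joint PCA coordinates for downstream imputation.
#' @export
two_round_transfer <- function(meas, ref, dims = 100, anchor_k = 5,
                               k_anchor = 100, downsample = 100000,
                               seed = 1, subclass_gate = 0.8,
                               cluster_gate = 0.5) {
  panel <- intersect(gene_names(meas), colnames(ref$counts))
  if (length(panel) < 2) abort("measured panel shares too few genes with the reference")
  if (!"partition_label" %in% names(ref)) ref <- build_partitions(ref, panel = panel)
  part_of_sub <- attr(ref, "partition_of_subclass") %||%
    with(distinct(tibble(s = ref$subclass_label, p = ref$partition_label)),
         setNames(p, s))

  ref_m <- ref$counts[, panel, drop = FALSE]
  meas_m <- meas$counts[, panel, drop = FALSE]
  ref_z <- standardize(ref_m)
  meas_z <- standardize(meas_m)
  d1 <- min(dims, length(panel), nrow(ref_z) - 1, nrow(meas_z) - 1)
  jp <- joint_pca(ref_z, meas_z, d1)
  emb <- cca_coembed(ref_z, meas_z, dims = d1, downsample = downsample,
                     seed = seed)
  anchors <- find_anchors(emb$ref, emb$meas, k = anchor_k)
  r1 <- transfer_labels(anchors, as.character(ref$partition_label),
                        jp$ref, jp$meas, k_anchor = k_anchor)

  out <- tibble(cell_id = meas$cell_id,
                partition_label = as.integer(r1$label),
                partition_confidence = r1$confidence,
                subclass_label = NA_character_, subclass_confidence = NA_real_,
                cluster_label = NA_character_, cluster_confidence = NA_real_)

  for (p in sort(unique(unname(part_of_sub)))) {
    ref_idx <- which(ref$partition_label == p)
    meas_idx <- which(out$partition_label == p)
    if (!length(meas_idx)) {
      warn(sprintf("partition %s has no measured cells; skipped", p))
      next
    }
    sub_ref <- ref[ref_idx, ]
    genes <- positive_dispersion_genes(sub_ref$counts[, panel, drop = FALSE])
    rz <- standardize(sub_ref$counts[, genes, drop = FALSE])
    mz <- standardize(meas$counts[meas_idx, genes, drop = FALSE])
    d2 <- min(dims, length(genes), nrow(rz) - 1, nrow(mz) - 1)
    jp2 <- joint_pca(rz, mz, d2)
    emb2 <- cca_coembed(rz, mz, dims = d2, downsample = downsample,
                        seed = seed + 1)
    a2 <- tryCatch(find_anchors(emb2$ref, emb2$meas, k = anchor_k),
                   error = function(e) NULL)
    if (is.null(a2) || nrow(a2) == 0) {
      warn(sprintf("partition %s produced no anchors; skipped", p))
      next
    }
    t_sub <- transfer_labels(a2, sub_ref$subclass_label, jp2$ref, jp2$meas,
                             k_anchor = k_anchor)
    t_clu <- transfer_labels(a2, sub_ref$cluster_label, jp2$ref, jp2$meas,
                             k_anchor = k_anchor)
    out$subclass_label[meas_idx] <- t_sub$label
    out$subclass_confidence[meas_idx] <- t_sub$confidence
    out$cluster_label[meas_idx] <- t_clu$label
    out$cluster_confidence[meas_idx] <- t_clu$confidence
  }
  out <- mutate(out,
    subclass_confidence = .data$subclass_confidence * .data$partition_confidence,
    cluster_confidence = .data$cluster_confidence * .data$partition_confidence,
    subclass_pass = !is.na(.data$subclass_confidence) &
      .data$subclass_confidence > subclass_gate,
    cluster_pass = !is.na(.data$cluster_confidence) &
      .data$cluster_confidence > cluster_gate)
  attr(out, "anchors") <- anchors
  attr(out, "joint_ref") <- jp$ref
  attr(out, "joint_meas") <- jp$meas
  attr(out, "gates") <- c(subclass = subclass_gate, cluster = cluster_gate)
  class(out) <- unique(c("transfer_result", class(out)))
  out
}

#' Impute transcriptome-wide expression through anchors
#'
#' Each measured cell's profile is a convex combination of the
#' log-normalised reference profiles of its `k` nearest anchor reference-
#' cells in the joint space, with Gaussian kernel weights whose bandwidth
#' adapts to the distance of the k-th anchor.
#'
#' @param transfer A `transfer_result` (carries anchors and joint
#'   coordinates).
#' @param ref The `ref_tbl` used in the transfer.
#' @param k Anchor neighbours averaged per cell (default 30; fewer anchors
#'   than `k` uses all, with a warning).
#' @param genes Genes to impute (default: the reference's full universe).
#' @return Matrix (measured cells x genes) of imputed log-normalised
#'   expression; row names are cell ids.
#' @export
impute_expression <- function(transfer, ref, k = 30, genes = NULL) {
  anchors <- attr(transfer, "anchors")
  joint_ref <- attr(transfer, "joint_ref")
  joint_meas <- attr(transfer, "joint_meas")
  if (is.null(anchors)) abort("transfer result carries no anchors")
  genes <- genes %||% colnames(ref$counts)
  expr <- standardize(ref$counts[, genes, drop = FALSE], zscore = FALSE)
  anchor_cells <- sort(unique(anchors$ref_index))
  if (length(anchor_cells) < k) {
    warn(sprintf("only %d anchor cells available; using all", length(anchor_cells)))
    k <- length(anchor_cells)
  }
  nn <- knn_index_dist(joint_meas, joint_ref[anchor_cells, , drop = FALSE], k)
  out <- matrix(0, nrow(joint_meas), length(genes),
                dimnames = list(transfer$cell_id, genes))
  for (i in seq_len(nrow(out))) {
    d <- nn$dist[i, ]
    bw <- d[k]
    w <- if (bw == 0) rep(1, k) else exp(-(d / bw)^2)
    w <- w / sum(w)
    out[i, ] <- w %*% expr[anchor_cells[nn$index[i, ]], , drop = FALSE]
  }
  out
}

#' Nearest-centroid assignment by cosine distance
#'
#' The independent cross-check of the anchor transfer: each measured cell is
#' assigned the cluster whose mean log-normalised profile has the smallest
#' cosine distance to the cell's profile. Scale-invariant; all-zero cells
#' are flagged unassigned.
#'
#' @param meas A `cell_tbl` (or a cells x genes matrix).
#' @param cluster_profiles Clusters x genes matrix of mean log-normalised
#'   expression over the shared panel.
#' @return Tibble `cluster`, `cosine_dist`, `unassigned`.
#' @export
cosine_assign <- function(meas, cluster_profiles) {
  m <- if (is.matrix(meas)) meas else
    standardize(meas$counts[, colnames(cluster_profiles), drop = FALSE],
                zscore = FALSE)
  m <- m[, colnames(cluster_profiles), drop = FALSE]
  cn <- sqrt(rowSums(cluster_profiles^2))
  mn <- sqrt(rowSums(m^2))
  sim <- tcrossprod(m, cluster_profiles) / outer(mn, cn)
  unassigned <- mn == 0
  sim[unassigned, ] <- -Inf
  best <- max.col(sim, ties.method = "first")
  tibble(cluster = rownames(cluster_profiles)[best],
         cosine_dist = 1 - sim[cbind(seq_len(nrow(sim)), best)],
         unassigned = unassigned)
}
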