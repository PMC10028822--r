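# Fixtures built in code; nothing is read from disk except through the
# readers under test (which write into tempfiles first).

# minimal valid cell table; counts supplied or drawn deterministically
toy_cells <- function(n = 3, genes = c("ga", "gb", "gc"), counts = NULL,
                      x = seq_len(n) * 10, y = rep(0, n),
                      volume = rep(200, n), z_planes = 3L,
                      section_id = "s1", ...) {
  if (is.null(counts)) {
    counts <- matrix(seq_len(n * length(genes)), n, length(genes),
                     dimnames = list(NULL, genes))
  }
  meta <- tibble::tibble(cell_id = sprintf("c%03d", seq_len(n)),
                         section_id = section_id, x = x, y = y,
                         z_planes = z_planes, volume = volume, ...)
  cell_table(meta, counts)
}

# two-cluster reference with a planted differential gene structure:
# `gene1` up in cluster a (mean 8, 90% expressing) vs cluster b (mean 2,
# 10% expressing); remaining genes exchangeable noise
toy_de_reference <- function(n_per = 200, n_noise = 5, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per
    g1 <- c(rpois(n_per, 8) + 1L, rbinom(n_per, 1, 0.1) * (rpois(n_per, 18) + 1L))
    g1[seq_len(round(0.1 * n_per))] <- 0L  # 90% expressing in foreground
    noise <- matrix(rpois(n * n_noise, 5), n, n_noise)
    counts <- cbind(gene1 = g1, noise)
    colnames(counts) <- c("gene1", sprintf("noise%d", seq_len(n_noise)))
    meta <- tibble::tibble(cell_id = sprintf("r%04d", seq_len(n)),
                           subclass_label = rep(c("SA", "SB"), each = n_per),
                           cluster_label = rep(c("a", "b"), each = n_per))
    reference_dataset(meta, counts)
  })
}

# two well-separated expression blobs (>= k + 1 cells each)
blob_expression <- function(n_per = 60, n_genes = 10, shift = 50, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_per * n_genes, 0), n_per, n_genes)
    b <- matrix(rnorm(n_per * n_genes, shift), n_per, n_genes)
    list(expr = rbind(a, b),
         cluster = rep(c("A", "B"), each = n_per))
  })
}

# brute-force O(n^2) proximal pair counter (the oracle)
oracle_count_proximal <- function(cells_a, cells_b, r) {
  same <- identical(cells_a$cell_id, cells_b$cell_id)
  total <- 0L
  for (i in seq_len(nrow(cells_a))) {
    js <- if (same) seq_len(nrow(cells_b)) > i else seq_len(nrow(cells_b)) > 0
    for (j in which(js)) {
      if (cells_a$section_id[i] != cells_b$section_id[j]) next
      d <- sqrt((cells_a$x[i] - cells_b$x[j])^2 + (cells_a$y[i] - cells_b$y[j])^2)
      if (d < r) total <- total + 1L
    }
  }
  total
}

# brute-force mutual k-NN anchor oracle
oracle_anchors <- function(emb_ref, emb_meas, k) {
  d <- sqrt(outer(rowSums(emb_ref^2), rowSums(emb_meas^2), "+") -
              2 * tcrossprod(emb_ref, emb_meas))
  out <- NULL
  for (i in seq_len(nrow(emb_ref))) for (j in seq_len(nrow(emb_meas))) {
    i_in <- rank(d[, j], ties.method = "first")[i] <= k
    j_in <- rank(d[i, ], ties.method = "first")[j] <= k
    if (i_in && j_in) out <- rbind(out, c(i, j))
  }
  tibble::tibble(ref_index = out[, 1], meas_index = out[, 2])
}
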