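test_that("standardisation normalises totals, logs and z-scores", {
  m <- rbind(c(4, 6), c(1, 1))
  z <- standardize(m, zscore = FALSE, log1p = FALSE)
  expect_equal(rowSums(z), c(1000, 1000))
  # hand-computed 2 x 2 example: totals to 1000 -> log1p -> z-score
  lg <- log1p(rbind(c(400, 600), c(500, 500)))
  expected <- apply(lg, 2, function(col) (col - mean(col)) / sd(col))
  expect_equal(unname(standardize(m)), unname(expected))
  # constant genes become zero columns
  const <- cbind(a = c(5, 5), b = c(5, 5))
  expect_true(all(standardize(const) == 0))
  expect_error(standardize(rbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("CCA co-embedding aligns copies and is seed-deterministic", {
  withr::with_seed(21, {
    ref <- matrix(rnorm(60 * 8), 60, 8)
  })
  emb <- cca_coembed(ref, ref, dims = 4, seed = 2)
  d2 <- brainatlas:::cross_dist2(emb$ref, emb$meas)
  expect_identical(unname(apply(d2, 1, which.min)), seq_len(60))
  emb2 <- cca_coembed(ref, ref, dims = 4, seed = 2)
  expect_identical(emb, emb2)
  expect_error(cca_coembed(ref, ref, dims = 50), "exceeds")
})

test_that("the first CCA direction maximises the cross-product objective", {
  # brute-force oracle on a 2 + 2 cell toy: grid over unit vectors p, q of
  # p' M q with M the cross-product of the standardised matrices
  withr::with_seed(22, {
    xz <- matrix(rnorm(2 * 5), 2, 5)
    yz <- matrix(rnorm(2 * 5), 2, 5)
  })
  m <- tcrossprod(xz, yz)
  ang <- seq(0, 2 * pi, length.out = 2000)
  best <- -Inf; best_p <- NULL; best_q <- NULL
  for (a in ang) {
    p <- c(cos(a), sin(a))
    v <- p %*% m                 # optimal q is the normalised image
    val <- sqrt(sum(v^2))
    if (val > best) { best <- val; best_p <- p; best_q <- v / val }
  }
  emb <- cca_coembed(xz, yz, dims = 2)
  # the implementation's first embedding dimension must align with the
  # oracle maximiser on both sides
  align <- function(emb_col, target) abs(sum(emb_col * target) /
                                           sqrt(sum(emb_col^2)))
  expect_gt(align(emb$ref[, 1], best_p), 0.999)
  expect_gt(align(emb$meas[, 1], as.vector(best_q)), 0.999)
})

test_that("anchors equal the brute-force mutual nearest neighbour oracle", {
  withr::with_seed(23, {
    er <- matrix(rnorm(10 * 3), 10, 3)
    em <- er + matrix(rnorm(10 * 3, sd = 0.05), 10, 3)
  })
  anchors <- find_anchors(er, em, k = 3)
  expect_equal(as.data.frame(anchors),
               as.data.frame(oracle_anchors(er, em, k = 3)))
  # identical point sets anchor every cell to its copy
  self <- find_anchors(er, er, k = 2)
  expect_true(all(vapply(seq_len(10), function(i)
    any(self$ref_index == i & self$meas_index == i), logical(1))))
  # an outlier measured point beyond every reference cell's k-NN appears
  # in no anchor
  em_out <- rbind(em, c(100, 100, 100))
  far <- find_anchors(er, em_out, k = 2)
  expect_false(11L %in% far$meas_index)
  expect_error(find_anchors(er[0, , drop = FALSE], em), "non-empty")

  # a larger randomised instance against the O(n^2) oracle
  withr::with_seed(24, {
    er2 <- matrix(rnorm(120 * 4), 120, 4)
    em2 <- matrix(rnorm(90 * 4), 90, 4)
  })
  expect_equal(as.data.frame(find_anchors(er2, em2, k = 5)),
               as.data.frame(oracle_anchors(er2, em2, k = 5)))
})

test_that("label transfer reports majority labels with exact confidences", {
  withr::with_seed(25, {
    joint_ref <- rbind(matrix(rnorm(85 * 2, mean = 0, sd = 0.3), 85, 2),
                       matrix(rnorm(15 * 2, mean = 0, sd = 0.3), 15, 2))
  })
  labels <- rep(c("S", "T"), c(85, 15))
  anchors <- tibble::tibble(ref_index = 1:100, meas_index = 1)
  joint_meas <- matrix(0, 1, 2)
  res <- transfer_labels(anchors, labels, joint_ref, joint_meas,
                         k_anchor = 100)
  expect_identical(res$label, "S")
  expect_equal(res$confidence, 0.85)
  # unanimous anchors give confidence exactly 1
  res1 <- transfer_labels(anchors, rep("S", 100), joint_ref, joint_meas)
  expect_equal(res1$confidence, 1)
})

test_that("balanced graph partitioning matches the exhaustive optimum", {
  # two zero-cross-edge groups split into their components
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 5; w[3, 4] <- w[4, 3] <- 7
  comp <- brainatlas:::partition_graph(w, rep(1, 4), 2)
  expect_identical(comp[1], comp[2])
  expect_identical(comp[3], comp[4])
  expect_false(comp[1] == comp[3])
  # 6-node toy against an independent exhaustive search over balanced
  # bipartitions
  withr::with_seed(26, {
    w6 <- matrix(runif(36), 6, 6); w6 <- w6 + t(w6); diag(w6) <- 0
  })
  got <- brainatlas:::partition_graph(w6, rep(1, 6), 2)
  cutw <- function(assign) sum(w6[outer(assign, assign, "!=")]) / 2
  best <- min(apply(utils::combn(6, 3), 2, function(s)
    cutw(ifelse(seq_len(6) %in% s, 1, 2))))
  expect_equal(cutw(got), best)
  expect_identical(brainatlas:::partition_graph(w6, rep(1, 6), 1), rep(1L, 6))
})

test_that("reference partitions separate disconnected expression groups", {
  spec <- default_specs()$integration
  ref <- simulate_reference(spec, 30, seed = 27)
  ref <- build_partitions(ref, n_parts = 2, panel = spec$panel)
  parts <- attr(ref, "partition_of_subclass")
  expect_identical(sort(unique(unname(parts))), c(1L, 2L))
  # every cluster's subclass sits in exactly one partition
  expect_identical(anyDuplicated(names(parts)), 0L)
  expect_error(build_partitions(ref, n_parts = 99), "exceeds")
})

test_that("self-transfer recovers isolated clusters with full confidence", {
  # five well-separated one-cluster subclasses, each larger than the anchor
  # neighbourhood, transferred onto themselves
  genes <- sprintf("g%02d", 1:40)
  prof <- matrix(1, 5, 40, dimnames = list(sprintf("S%d.c1", 1:5), genes))
  for (i in 1:5) prof[i, ((i - 1) * 8 + 1):(i * 8)] <- 60
  spec <- simulation_spec(
    prof, setNames(sprintf("S%d", 1:5), rownames(prof)),
    regions = tibble::tibble(region = "R1", xmin = 0, xmax = 100,
                             ymin = 0, ymax = 100),
    intensity = matrix(1, 1, 5, dimnames = list("R1", sprintf("S%d", 1:5))),
    dispersion = 50)
  ref <- simulate_reference(spec, 120, seed = 28)
  meas <- cell_table(
    tibble::tibble(cell_id = paste0("m_", ref$cell_id), section_id = "s1",
                   x = runif(nrow(ref)), y = runif(nrow(ref)),
                   z_planes = 3L, volume = 200),
    ref$counts)
  res <- suppressWarnings(two_round_transfer(meas, ref, seed = 29))
  expect_identical(res$subclass_label, ref$subclass_label)
  expect_identical(res$cluster_label, ref$cluster_label)
  expect_true(all(res$subclass_confidence == 1))
  expect_true(all(res$cluster_confidence == 1))
  # adjusted confidence never exceeds either factor
  expect_true(all(res$subclass_confidence <= res$partition_confidence + 1e-12))
  expect_true(all(res$subclass_pass == (res$subclass_confidence > 0.8)))
})

test_that("imputation is a convex combination of anchor profiles", {
  spec <- default_specs()$integration
  ref <- simulate_reference(spec, 25, seed = 30)
  meas <- cell_table(
    tibble::tibble(cell_id = paste0("m_", ref$cell_id), section_id = "s1",
                   x = runif(nrow(ref)), y = runif(nrow(ref)),
                   z_planes = 3L, volume = 200),
    ref$counts[, spec$panel])
  res <- suppressWarnings(two_round_transfer(meas, ref, seed = 31))
  imp <- impute_expression(res, ref, k = 10)
  expr <- standardize(ref$counts, zscore = FALSE)
  expect_true(all(imp >= min(expr) - 1e-9 & imp <= max(expr) + 1e-9))
  # identical anchor profiles impute exactly that profile
  const_ref <- ref
  const_ref$counts <- matrix(rep(ref$counts[1, ], each = nrow(ref)),
                             nrow(ref), dimnames = dimnames(ref$counts))
  imp2 <- impute_expression(res, const_ref, k = 10)
  target <- standardize(const_ref$counts, zscore = FALSE)[1, ]
  expect_equal(unname(imp2[5, ]), unname(target))
})

test_that("cosine assignment is scale-invariant and flags zero cells", {
  profiles <- rbind(c1 = c(1, 0, 1), c2 = c(0, 1, 0))
  colnames(profiles) <- c("ga", "gb", "gc")
  m <- rbind(c(2, 0, 2), c(0, 7, 0), c(0, 0, 0))
  colnames(m) <- colnames(profiles)
  res <- cosine_assign(m, profiles)
  expect_identical(res$cluster[1:2], c("c1", "c2"))
  expect_equal(res$cosine_dist[1], 0)
  expect_true(res$unassigned[3])
  res10 <- cosine_assign(m * 10, profiles)
  expect_identical(res$cluster[1:2], res10$cluster[1:2])
})
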