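params_fast <- proximity_params(n_rounds = 200, seed = 7)

test_that("proximal pair counting is strict and matches the O(n^2) oracle", {
  two <- toy_cells(2, x = c(0, 10), y = c(0, 0))
  expect_identical(count_proximal(two[1, ], two[2, ], 15), 1L)
  expect_identical(count_proximal(two[1, ], two[2, ], 10), 0L)  # ties out
  # grid-bucketed counter equals brute force on a random fixture, for
  # cross-type and same-set counting
  withr::with_seed(71, {
    cells <- toy_cells(200, x = runif(200, 0, 300), y = runif(200, 0, 300),
                       subclass_label = sample(c("A", "B"), 200, TRUE))
  })
  a <- cells[cells$subclass_label == "A", ]
  b <- cells[cells$subclass_label == "B", ]
  for (r in c(5, 15, 40)) {
    expect_identical(count_proximal(a, b, r), oracle_count_proximal(a, b, r))
    expect_identical(count_proximal(a, a, r), oracle_count_proximal(a, a, r))
  }
  # cells in different sections never pair
  b2 <- b
  b2$section_id <- "other"
  expect_identical(count_proximal(a, b2, 1e6), 0L)
})

test_that("randomization keeps displacements local and type counts fixed", {
  withr::with_seed(72, {
    cells <- toy_cells(150, x = runif(150, 0, 500), y = runif(150, 0, 500),
                       subclass_label = sample(c("A", "B"), 150, TRUE))
  })
  sh <- withr::with_seed(73, {
    brainatlas:::displace(cells$x, cells$y, 100)
  })
  moved <- sqrt((sh$x - cells$x)^2 + (sh$y - cells$y)^2)
  expect_true(all(moved <= 100))
  null <- randomization_null(cells, "A", "B", r = 15, params = params_fast)
  expect_length(null$samples, 200)
  expect_gte(null$sd, 1e-9)
})

test_that("null calibration covers the observed count under CSR", {
  sim <- simulate_section(default_specs()$csr, seed = 74)
  obs <- count_proximal(sim$cells[sim$cells$subclass_label == "A", ],
                        sim$cells[sim$cells$subclass_label == "B", ], 15)
  null <- randomization_null(sim$cells, "A", "B", r = 15,
                             params = params_fast)
  expect_lt(abs(obs - null$mean), 4 * null$sd)
})

test_that("interaction tests gate on adjusted p and observed pair count", {
  sim <- simulate_section(default_specs()$attraction, seed = 75)
  res <- test_interactions(sim$cells, params = params_fast)
  ab <- res[!res$self_pair, ]
  expect_true(ab$called)
  expect_gt(ab$fold, 1.5)
  expect_lt(ab$p_adj, 0.05)
  expect_true(all(res$p_raw >= 1 / (params_fast$n_rounds + 1)))
  # the same enrichment fails the call with a prohibitive pair threshold
  strict <- proximity_params(n_rounds = 200, seed = 7,
                             min_observed_pairs = ab$observed + 1)
  res2 <- test_interactions(sim$cells, params = strict)
  expect_false(any(res2$called))
  # A <-> B relabelling leaves fold and p unchanged (unordered counting)
  flipped <- sim$cells
  flipped$subclass_label <- chartr("AB", "BA", flipped$subclass_label)
  res3 <- test_interactions(flipped, params = params_fast)
  expect_equal(res3$fold[!res3$self_pair], ab$fold)
  expect_equal(res3$p_raw[!res3$self_pair], ab$p_raw)
})

test_that("eligibility combines confidence, enrichment and abundance rules", {
  withr::with_seed(76, {
    n <- 300
    cells <- toy_cells(
      n, x = runif(n, 0, 500), y = runif(n, 0, 500),
      subclass_label = sample(c("Neu1", "Neu2", "Astro", "Oligo"), n, TRUE,
                              prob = c(0.4, 0.1, 0.2, 0.3)),
      region_label = sample(c("CTX", "HY_ant"), n, TRUE),
      subclass_confidence = runif(n, 0.85, 1))
  })
  enr <- enrichment_scores(cells)
  enr$score[enr$type == "Neu1"] <- 3
  enr$score[enr$type == "Neu2"] <- 1.5
  enr$score[enr$type == "Astro"] <- 1
  cls <- c(Neu1 = "neuronal", Neu2 = "neuronal", Astro = "astrocyte",
           Oligo = "other")
  el <- eligible_types(cells, "CTX", enr, cls)
  expect_true("Neu1" %in% el$types)        # 3 >= 2
  expect_false("Neu2" %in% el$types)       # 1.5 < 2
  expect_true("Astro" %in% el$types)       # 1 >= 1
  oligo_n <- sum(el$cells$subclass_label == "Oligo")
  expect_identical("Oligo" %in% el$types, oligo_n > 50)
  # the same neuronal score fails in a subdivided region (threshold 6)
  el2 <- eligible_types(cells, "HY_ant", enr, cls,
                        subdivided_regions = "HY_ant")
  expect_false("Neu1" %in% el2$types)
  # low-confidence cells are excluded before counting
  lowc <- cells
  lowc$subclass_confidence <- 0.5
  el3 <- eligible_types(lowc, "CTX", enr, cls)
  expect_identical(nrow(el3$cells), 0L)
})

test_that("ligand-receptor scores follow the log product formula", {
  expect_identical(lr_score(0, 0), 0)
  expect_equal(lr_score(2, 3), log(7))
  expect_equal(lr_score(c(2, 3), 1), log(1 + 6))
  # literal double-product reading: (prod L)^|q| * (prod R)^|p|
  expect_equal(lr_score(c(2, 3), c(1, 4), literal = TRUE),
               log1p(6^2 * 4^2))
})

test_that("lr tests apply the three significance criteria", {
  sim <- simulate_section(default_specs()$lr_effect, seed = 77)
  cells <- sim$cells
  expr <- standardize(cells$counts, log1p = FALSE, zscore = FALSE)
  rownames(expr) <- cells$cell_id
  a <- cells[cells$subclass_label == "A", ]
  b <- cells[cells$subclass_label == "B", ]
  res <- lr_test(a, b, default_lr_database(), expr, params = params_fast)
  pos <- res[res$pair_id == "LRpos", ]
  expect_true(pos$significant)
  expect_gte(pos$fold, 2)
  expect_lt(pos$p_adj, 0.01)
  expect_gte(pos$frac_positive_proximal, 0.4)
  expect_false(any(res$significant[res$pair_id != "LRpos"]))
  # identical expression everywhere: nothing is significant
  flat <- expr
  flat[] <- 1
  res_flat <- lr_test(a, b, default_lr_database(), flat, params = params_fast)
  expect_false(any(res_flat$significant))
  expect_true(all(abs(res_flat$fold - 1) < 1e-9))
  # a pair positive in under 40% of proximal pairs is rejected even with a
  # huge fold: zero out the ligand in most sender cells
  sparse <- expr
  sparse[, "Lig1"] <- 0
  keep <- a$cell_id[seq_len(ceiling(nrow(a) * 0.1))]
  sparse[keep, "Lig1"] <- 1000
  res_sparse <- lr_test(a, b, default_lr_database(), sparse,
                        params = params_fast)
  expect_false(res_sparse$significant[res_sparse$pair_id == "LRpos"])
  # missing subunit genes skip the pair with a warning
  db_bad <- lr_database("X1", "P", list("NotAGene"), list("Rec1"))
  expect_warning(lr_test(a, b, db_bad, expr, params = params_fast), "missing")
})

test_that("proximity-conditional gene upregulation is detected and gated", {
  withr::with_seed(78, {
    n <- 160
    a <- toy_cells(n, genes = c("up", "flat"),
                   counts = cbind(up = rpois(n, 2), flat = rpois(n, 10)),
                   x = runif(n, 0, 800), y = runif(n, 0, 800),
                   subclass_label = "A")
    b <- toy_cells(40, genes = c("up", "flat"),
                   counts = cbind(up = rpois(40, 2), flat = rpois(40, 10)),
                   x = runif(40, 0, 800), y = runif(40, 0, 800),
                   subclass_label = "B")
    b$cell_id <- paste0("b_", b$cell_id)
    d2 <- brainatlas:::cross_dist2(cbind(a$x, a$y), cbind(b$x, b$y))
    exposed <- rowSums(d2 < 30^2) > 0
    counts <- a$counts
    counts[exposed, "up"] <- counts[exposed, "up"] + rpois(sum(exposed), 8)
    a$counts <- counts
    expr <- rbind(a$counts, b$counts)
    rownames(expr) <- c(a$cell_id, b$cell_id)
  })
  res <- upregulated_genes(a, b, expr, hvgs = c("up", "flat"), r = 30)
  expect_true(res$significant[res$gene == "up"])
  expect_false(res$significant[res$gene == "flat"])
  # no partner cells: empty result
  empty <- upregulated_genes(a, b[0, ], expr, hvgs = c("up", "flat"))
  expect_identical(nrow(empty), 0L)
})

test_that("the pipeline merges strict and LR-gated relaxed calls once", {
  sim <- simulate_section(default_specs()$attraction, seed = 79)
  cells <- sim$cells
  expr <- standardize(cells$counts, log1p = FALSE, zscore = FALSE)
  rownames(expr) <- cells$cell_id
  res <- call_pipeline(cells, default_lr_database(), expr,
                       params = params_fast)
  key <- paste(res$calls$type_a, res$calls$type_b, res$calls$region)
  expect_identical(anyDuplicated(key), 0L)
  # the planted A-B attraction is called in strict mode
  expect_true(any(res$calls$type_a == "A" & res$calls$type_b == "B" &
                    res$calls$mode == "strict15"))
  gl <- glance(res)
  expect_identical(gl$n_called, nrow(res$calls))
  expect_s3_class(tidy(res), "tbl_df")
})
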