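# ---- differential expression ------------------------------------------------

test_that("identical clusters yield no differential genes", {
  ref <- toy_de_reference()
  dup <- ref
  dup$cluster_label <- rep(c("a", "b"), length.out = nrow(ref))  # same cells mixed
  res <- de_genes(dup, "a", "b")
  expect_identical(nrow(res), 0L)
})

test_that("a strongly shifted gene is selected with the stated criteria", {
  ref <- toy_de_reference()
  res <- de_genes(ref, "a", "b")
  up <- res[res$direction == "a_up", ]
  expect_true("gene1" %in% up$gene)
  row <- up[up$gene == "gene1", ]
  expect_gte(row$fold, 2)
  expect_lt(row$p, 0.01)
  expect_gte(row$frac_fg, 0.5)
  expect_gt(row$frac_fg / row$frac_bg, 3.3)
  # independent oracle for the p-value: two-sided rank-sum on the
  # normalised counts of that gene
  m <- brainatlas:::norm_to_mean_total(ref$counts)
  p_oracle <- suppressWarnings(
    wilcox.test(m[ref$cluster_label == "a", "gene1"],
                m[ref$cluster_label == "b", "gene1"])$p.value)
  expect_equal(row$p, p_oracle)
  expect_error(de_genes(ref, "a", "zzz"), "unknown cluster")
})

test_that("ranked lists truncate at top_n and are antisymmetric", {
  # 60 qualifying genes -> exactly 50 returned, best p first
  withr::with_seed(7, {
    n <- 80
    up <- matrix(rpois(n * 60, 12), n, 60)
    dn <- matrix(rbinom(n * 60, 1, 0.05), n, 60)
    counts <- rbind(cbind(up, matrix(rpois(n * 3, 5), n, 3)),
                    cbind(dn, matrix(rpois(n * 3, 5), n, 3)))
    colnames(counts) <- c(sprintf("de%02d", 1:60), sprintf("n%d", 1:3))
    meta <- tibble::tibble(cell_id = sprintf("c%04d", seq_len(2 * n)),
                           subclass_label = "S",
                           cluster_label = rep(c("a", "b"), each = n))
    ref <- reference_dataset(meta, counts)
  })
  res <- de_genes(ref, "a", "b")
  aup <- res[res$direction == "a_up", ]
  expect_identical(nrow(aup), 50L)
  expect_false(is.unsorted(aup$p))
  # swapping the clusters swaps the directions
  swapped <- de_genes(ref, "b", "a")
  expect_identical(aup$gene, swapped$gene[swapped$direction == "b_up"])
})

test_that("pool trimming removes short and over-abundant genes strictly", {
  genes <- c("ok", "short", "abundant", "at40", "at3000")
  cap <- c(ok = 64, short = 39, abundant = 64, at40 = 40, at3000 = 64)
  mx <- c(ok = 10, short = 10, abundant = 3001, at40 = 10, at3000 = 3000)
  expect_identical(trim_pool(genes, cap, mx), c("ok", "at40", "at3000"))
  expect_error(trim_pool(c("ok", "unknown"), cap, mx), "cover")
})

test_that("greedy panel assembly covers every pair and direction", {
  res <- assemble_panel(tibble::tibble(), curated = c("x", "y"), min_cover = 0)
  expect_identical(res$panel, c("x", "y"))
  pool <- dplyr::bind_rows(
    tibble::tibble(cluster_a = "a", cluster_b = "b", direction = "a_up",
                   gene = sprintf("u%d", 1:5), p = (1:5) * 1e-4),
    tibble::tibble(cluster_a = "a", cluster_b = "b", direction = "b_up",
                   gene = sprintf("d%d", 1:5), p = (1:5) * 1e-4))
  res <- assemble_panel(pool, curated = "marker", min_cover = 3)
  # greedy oracle on the 2-cluster instance: best three p-values per
  # direction plus the curated gene
  expect_setequal(res$panel, c("marker", "u1", "u2", "u3", "d1", "d2", "d3"))
  expect_identical(nrow(res$uncovered), 0L)
  # an exhausted pool is reported, not raised
  res2 <- assemble_panel(pool[pool$direction == "a_up", ][1:2, ],
                         min_cover = 3)
  expect_identical(res2$uncovered$coverage, 2L)
})

# ---- codebooks --------------------------------------------------------------

test_that("codebook validation reports weight and distance violations", {
  one <- codebook("g1", paste0(strrep("1", 4), strrep("0", 28)),
                  is_blank = FALSE)
  expect_true(validate_codebook(one)$pass)
  # two words sharing 3 set bits are at distance 2
  two <- codebook(c("g1", "g2"), c("11110000", "11101000"),
                  is_blank = c(FALSE, FALSE))
  rep2 <- validate_codebook(two)
  expect_identical(rep2$min_distance, 2)
  expect_false(rep2$pass)
})

test_that("doubling construction attains the Steiner packing bound", {
  cb4 <- construct_codebook(4)
  expect_identical(nrow(cb4), 1L)
  expect_identical(cb4$barcode, "1111")

  cb8 <- construct_codebook(8)
  expect_identical(nrow(cb8), 14L)
  expect_true(validate_codebook(cb8)$pass)
  # every 3-subset of bit positions is covered exactly once
  W <- brainatlas:::barcode_matrix(cb8)
  cover <- apply(utils::combn(8, 3), 2, function(t) sum(rowSums(W[, t]) == 3))
  expect_true(all(cover == 1))

  cb32 <- construct_codebook(32)
  expect_identical(nrow(cb32), 1240L)
  rep32 <- validate_codebook(cb32)
  expect_true(rep32$pass)
  expect_identical(rep32$min_distance, 4)
  expect_identical(nrow(cb32), as.integer(max_code_size(32)))
  expect_error(construct_codebook(12), "power of two")
})

test_that("packing numbers are exact for the Steiner orders", {
  expect_identical(as.integer(max_code_size(4)), 1L)  # only one weight-4 word
  expect_identical(as.integer(max_code_size(8)), 14L)
  expect_identical(as.integer(max_code_size(32)), 1240L)
  expect_true(attr(max_code_size(32), "exact"))
  expect_false(attr(max_code_size(9), "exact"))  # bound only
  # exhaustive branch-and-bound confirmation at n = 8
  m8 <- max_code_size(8, exhaustive = TRUE)
  expect_identical(as.integer(m8), 14L)
  expect_true(attr(m8, "exact"))
})

test_that("barcode assignment is seeded, exhaustive and capacity-checked", {
  cb <- construct_codebook(16)  # 140 words
  asg <- assign_barcodes(sprintf("g%03d", 1:100), cb, seed = 3)
  expect_identical(sum(asg$is_blank), 40L)
  expect_identical(sort(asg$name[!asg$is_blank]), sprintf("g%03d", 1:100))
  expect_identical(asg, assign_barcodes(sprintf("g%03d", 1:100), cb, seed = 3))
  all_blank <- assign_barcodes(character(), cb, seed = 1)
  expect_true(all(all_blank$is_blank))
  full <- assign_barcodes(sprintf("g%03d", 1:140), cb, seed = 1)
  expect_identical(sum(full$is_blank), 0L)
  expect_error(assign_barcodes(sprintf("g%03d", 1:141), cb, seed = 1),
               "capacity")
})

# ---- probe target regions ---------------------------------------------------

test_that("target-region design filters GC, homology and length", {
  # poly-A fails the GC filter everywhere
  polya <- strrep("A", 100)
  res <- design_target_regions(polya, seed = 1)
  expect_identical(nrow(res), 0L)
  expect_identical(attr(res, "rule_set"), "rejected")
  # shorter than one window is rejected, not raised
  short <- design_target_regions(strrep("ACGT", 5), seed = 1)
  expect_identical(attr(short, "rule_set"), "rejected")
})

test_that("windows containing an excluded 16-mer are removed", {
  # periodic transcript: every window has GC 0.5 and contains the repeat
  # 16-mer, so indexing that 16-mer must reject the whole transcript
  tx <- strrep("ACGT", 750)
  stub_tm <- function(seq) 70
  without <- design_target_regions(tx, seed = 2, tm_fun = stub_tm)
  expect_identical(attr(without, "rule_set"), "primary")
  expect_identical(nrow(without), 64L)
  with_idx <- design_target_regions(tx, excluded_index = "ACGTACGTACGTACGT",
                                    seed = 2, tm_fun = stub_tm)
  expect_identical(nrow(with_idx), 0L)
  expect_identical(attr(with_idx, "rule_set"), "rejected")
  # the index builder enumerates every k-mer of the abundant sequences
  idx <- build_excluded_index(c("ACGTTGCA"), k = 4)
  expect_setequal(idx, c("ACGT", "CGTT", "GTTG", "TTGC", "TGCA"))
})

test_that("long balanced transcripts host 64 non-overlapping primary windows", {
  withr::with_seed(12, {
    tx <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  })
  stub_tm <- function(seq) 70  # mid-range, isolates the GC/overlap logic
  res <- design_target_regions(tx, seed = 3, tm_fun = stub_tm)
  expect_identical(attr(res, "rule_set"), "primary")
  expect_identical(nrow(res), 64L)
  s <- sort(res$start)
  expect_true(all(diff(s) >= 30))
  expect_true(all(res$gc >= 0.40 & res$gc <= 0.60))
  # enumeration oracle: every selected window passes the primary GC filter
  gcs <- vapply(seq_len(nrow(res)), function(i) {
    w <- substr(tx, res$start[i] + 1, res$end[i])
    mean(strsplit(w, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  expect_equal(res$gc, gcs)
  expect_identical(res, design_target_regions(tx, seed = 3, tm_fun = stub_tm))
})

test_that("nearest-neighbour Tm behaves physically", {
  gc_rich <- strrep("GC", 15)
  at_rich <- strrep("AT", 15)
  expect_gt(tm_nn(gc_rich), tm_nn(at_rich))
  expect_lt(tm_nn(gc_rich, formamide_pct = 10), tm_nn(gc_rich))
})
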