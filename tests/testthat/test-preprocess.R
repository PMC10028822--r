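test_that("volume filter applies strict per-z-plane bounds", {
  cells <- toy_cells(7,
                     volume = c(40, 50, 1500, 1501, 1000, 80, 79),
                     z_planes = c(3L, 3L, 3L, 3L, 5L, 5L, 5L))
  out <- filter_by_volume(cells)
  # 40 at 3z removed; exact bounds kept; 1000 at 5z kept; 79 at 5z removed
  expect_identical(out$volume, c(50, 1500, 1000, 80))
  expect_identical(attr(out, "n_removed"), 3L)
  bad <- toy_cells(1, z_planes = 4L)
  expect_error(filter_by_volume(bad), "z_planes = 4")
})

test_that("normalisation divides by volume and corrects the mean to 250", {
  counts <- rbind(c(60, 40, 0), c(100, 100, 100))
  colnames(counts) <- c("ga", "gb", "gc")
  cells <- toy_cells(2, counts = counts, volume = c(100, 100))
  out <- normalize_counts(cells)
  expect_equal(rowSums(out$counts), c(125, 375))
  expect_equal(mean(rowSums(out$counts)), 250, tolerance = 1e-9)
  # one cell: total becomes exactly the target
  one <- normalize_counts(toy_cells(1, counts = counts[1, , drop = FALSE]))
  expect_equal(sum(one$counts), 250)
  # doubling all volumes changes nothing
  dbl <- cells
  dbl$volume <- dbl$volume * 2
  expect_equal(normalize_counts(dbl)$counts, out$counts)
  expect_error(normalize_counts(toy_cells(0, counts = counts[0, , drop = FALSE])),
               "empty")
})

test_that("quantile filter follows the interpolated-quantile convention", {
  # oracle: type-7 quantiles of 1..8 at 0.25/0.75 are 2.75 and 6.25
  counts <- matrix(1:8, 8, 1, dimnames = list(NULL, "ga"))
  cells <- toy_cells(8, genes = "ga", counts = counts)
  out <- filter_count_quantiles(cells, q = 0.25)
  expect_identical(as.vector(out$counts), 3:6)
  # 200 distinct totals at q = 0.01: the type-7 bounds sit between the 2nd
  # and 3rd order statistics on each side, removing two cells per tail
  counts <- matrix(seq_len(200), 200, 1, dimnames = list(NULL, "ga"))
  cells <- toy_cells(200, genes = "ga", counts = counts)
  out <- filter_count_quantiles(cells, q = 0.01)
  bounds <- quantile(seq_len(200), c(0.01, 0.99))  # oracle
  expect_identical(nrow(out), sum(seq_len(200) >= bounds[1] &
                                    seq_len(200) <= bounds[2]))
  expect_identical(nrow(out), 196L)
  # equal totals: nothing removed
  same <- toy_cells(5, counts = matrix(3, 5, 1, dimnames = list(NULL, "ga")),
                    genes = "ga")
  expect_identical(nrow(filter_count_quantiles(same)), 5L)
})

test_that("neurotransmitter labels gate on raw counts at n >= 2", {
  genes <- c("Slc17a7", "Slc17a6", "Slc32a1", "other")
  counts <- rbind(c(2, 0, 0, 5),   # Glut via Slc17a7 = 2
                  c(0, 2, 3, 5),   # dual Glut + Gaba
                  c(1, 1, 1, 5))   # unassigned
  colnames(counts) <- genes
  rules <- neurotransmitter_rules(markers = list(
    Glut = c("Slc17a7", "Slc17a6", "Slc17a8"), Gaba = "Slc32a1"))
  cells <- assign_neurotransmitters(toy_cells(3, genes = genes,
                                              counts = counts), rules)
  expect_identical(cells$neurotransmitter_labels[[1]], "Glut")
  expect_setequal(cells$neurotransmitter_labels[[2]], c("Glut", "Gaba"))
  expect_identical(cells$neurotransmitter_labels[[3]], character())
  # markers absent from the panel skip their group with a warning
  expect_warning(
    assign_neurotransmitters(
      toy_cells(2), neurotransmitter_rules(markers = list(Gaba = "Slc32a1"))),
    "absent")
})

test_that("doublet hook removes only cells strictly above the cutoff", {
  cells <- toy_cells(3)
  expect_identical(doublet_hook(cells), cells)
  out <- doublet_hook(cells, scores = c(0.3, 0.25, 0.1))
  expect_identical(out$cell_id, c("c002", "c003"))
})

test_that("the preprocessing pipeline preserves gene order and logs removals", {
  withr::with_seed(8, {
    counts <- matrix(rpois(400, 20), 100, 4,
                     dimnames = list(NULL, c("gd", "ga", "gc", "gb")))
    cells <- toy_cells(100, genes = colnames(counts), counts = counts,
                       volume = c(40, rep(200, 99)))
  })
  out <- preprocess_cells(cells)
  expect_identical(gene_names(out), c("gd", "ga", "gc", "gb"))
  log <- attr(out, "removal_log")
  expect_identical(log[["volume"]], 1L)
  expect_identical(nrow(out), 100L - log[["volume"]] - log[["quantile"]])
  expect_equal(mean(total_counts(normalize_counts(filter_by_volume(cells)))),
               250, tolerance = 1e-9)
})
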