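# Cell-table QC and normalisation. Pipeline order: volume filter -> volume
# normalisation + mean correction -> quantile filter -> doublet hook. Every
# step only removes rows or rescales counts, never reorders genes. All
# threshold comparisons are strict, matching the stated "<" / ">" / ">=" rules.

#' Volume QC thresholds by z-plane count
#'
#' Cells outside these imaged-volume windows are segmentation artefacts
#' (too small) or unresolved z-overlaps (too large). Defaults: 3 z-planes
#' keep (50, 1500) um^3, 5 keep (80, 2500), 6 keep (100, 3000), strict
#' inequalities.
#'
#' @param thresholds Named list mapping z-plane count to `c(min, max)` um^3.
#' @return A `volume_thresholds` object.
#' @export
volume_thresholds <- function(thresholds = list(`3` = c(50, 1500),
                                                `5` = c(80, 2500),
                                                `6` = c(100, 3000))) {
  for (v in thresholds) if (v[1] >= v[2]) abort("volume min must be < max")
  structure(thresholds, class = "volume_thresholds")
}

#' Filter cells by imaged volume
#'
#' Removes cells with volume strictly below the minimum or strictly above
#' the maximum for their z-plane count. A cell exactly at a bound is kept.
#'
#' @param cells A `cell_tbl`.
#' @param thresholds A [volume_thresholds()].
#' @return The filtered `cell_tbl`, with attribute `n_removed`.
#' @export
filter_by_volume <- function(cells, thresholds = volume_thresholds()) {
  key <- as.character(cells$z_planes)
  unknown <- setdiff(unique(key), names(thresholds))
  if (length(unknown))
    abort(paste0("no volume thresholds for z_planes = ",
                 paste(unknown, collapse = ", ")))
  lo <- map_dbl(thresholds[key], 1)
  hi <- map_dbl(thresholds[key], 2)
  keep <- !(cells$volume < lo | cells$volume > hi)
  out <- cells[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Volume-normalise counts and correct the mean total
#'
#' Divides each cell's counts by its imaged volume (removing soma-size
#' differences), then rescales globally so the mean per-cell total equals
#' `target_mean` (250 by default). Doubling all volumes leaves the output
#' unchanged.
#'
#' @param cells A `cell_tbl` (volumes > 0).
#' @param target_mean Mean per-cell total after correction.
#' @return The `cell_tbl` with real-valued normalised counts.
#' @export
normalize_counts <- function(cells, target_mean = 250) {
  if (nrow(cells) == 0) abort("cannot normalise an empty cell table")
  m <- cells$counts / cells$volume
  m <- m * (target_mean / mean(rowSums(m)))
  cells$counts <- m
  cells
}

#' Remove cells in the extreme total-count quantiles
#'
#' Drops cells whose total counts fall strictly below the `q` quantile or
#' strictly above the `1 - q` quantile of per-cell totals (linear-
#' interpolation quantiles, the R type-7 default).
#'
#' @param cells A `cell_tbl`.
#' @param q Tail mass per side, `0 < q < 0.5` (default 0.01).
#' @return The filtered `cell_tbl`, with attribute `n_removed`.
#' @export
filter_count_quantiles <- function(cells, q = 0.01) {
  stopifnot(q > 0, q < 0.5)
  tot <- total_counts(cells)
  bounds <- quantile(tot, c(q, 1 - q), names = FALSE)
  keep <- tot >= bounds[1] & tot <= bounds[2]
  out <- cells[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Neurotransmitter marker rules
#'
#' Canonical transporter/synthesis markers per neurotransmitter group, with
#' the raw-count threshold (n >= 2 RNA counts). Groups may overlap: a neuron
#' co-expressing vesicular glutamate and GABA transporters carries both
#' labels.
#'
#' @param markers Named list group -> marker genes.
#' @param threshold Minimum raw RNA count (inclusive).
#' @return A `neurotransmitter_rules` object.
#' @export
neurotransmitter_rules <- function(
    markers = list(Glut = c("Slc17a7", "Slc17a6", "Slc17a8"),
                   Gaba = "Slc32a1", Sero = "Slc6a4", Dopa = "Slc6a3",
                   Choli = "Slc18a3", Glycine = "Slc6a5", Nora = "Slc6a2",
                   Hist = "Hdc"),
    threshold = 2) {
  stopifnot(threshold >= 1)
  structure(list(markers = markers, threshold = threshold),
            class = "neurotransmitter_rules")
}

#' Assign neurotransmitter identities from marker counts
#'
#' A cell carries a group label iff any of the group's marker genes has raw
#' count >= the threshold. Raw (pre-normalisation) integer counts are used:
#' the threshold is a copy-number statement. Groups whose markers are absent
#' from the panel are skipped with a warning.
#'
#' @param cells A `cell_tbl` with raw counts.
#' @param rules A [neurotransmitter_rules()].
#' @return The `cell_tbl` with a `neurotransmitter_labels` list column.
#' @export
assign_neurotransmitters <- function(cells, rules = neurotransmitter_rules()) {
  panel <- gene_names(cells)
  labels <- rep(list(character()), nrow(cells))
  for (grp in names(rules$markers)) {
    genes <- intersect(rules$markers[[grp]], panel)
    if (!length(genes)) {
      warn(paste0("markers for group ", grp, " absent from panel; skipped"))
      next
    }
    hit <- rowSums(cells$counts[, genes, drop = FALSE] >= rules$threshold) > 0
    labels[hit] <- map(labels[hit], c, grp)
  }
  cells$neurotransmitter_labels <- labels
  cells
}

#' Remove doublets given external scores
#'
#' Doublet scoring itself is out of scope (it belongs to the upstream
#' segmentation QC); this hook removes cells whose supplied score exceeds
#' the cutoff, strictly. With no scores it is the identity.
#'
#' @param cells A `cell_tbl`.
#' @param scores Optional named numeric vector (by `cell_id`) or vector
#'   aligned with rows.
#' @param cutoff Removal threshold (score strictly greater removed).
#' @return The filtered `cell_tbl`.
#' @export
doublet_hook <- function(cells, scores = NULL, cutoff = 0.25) {
  if (is.null(scores)) return(cells)
  if (!is.null(names(scores))) scores <- scores[cells$cell_id]
  keep <- !(scores > cutoff)
  keep[is.na(keep)] <- TRUE
  out <- cells[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Full preprocessing pipeline
#'
#' Volume filter, volume normalisation with mean correction, extreme-
#' quantile filter and doublet hook, in that order, with per-step removal
#' counts recorded.
#'
#' @param cells A `cell_tbl` with raw counts.
#' @param thresholds A [volume_thresholds()].
#' @param target_mean Mean total after correction.
#' @param q Quantile tail mass.
#' @param doublet_scores,doublet_cutoff Passed to [doublet_hook()].
#' @return The processed `cell_tbl` with attribute `removal_log` (named
#'   integer vector).
#' @export
preprocess_cells <- function(cells, thresholds = volume_thresholds(),
                             target_mean = 250, q = 0.01,
                             doublet_scores = NULL, doublet_cutoff = 0.25) {
  log <- integer()
  cells <- filter_by_volume(cells, thresholds)
  log["volume"] <- attr(cells, "n_removed")
  cells <- normalize_counts(cells, target_mean)
  cells <- filter_count_quantiles(cells, q)
  log["quantile"] <- attr(cells, "n_removed")
  n_before <- nrow(cells)
  cells <- doublet_hook(cells, doublet_scores, doublet_cutoff)
  log["doublet"] <- n_before - nrow(cells)
  attr(cells, "removal_log") <- log
  cells
}
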