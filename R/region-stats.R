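# Region-level composition summaries: enrichment scores, local cell-type
# complexity, the rostral-caudal region split, and composition fractions.

#' Cell-type enrichment scores by region or spatial module
#'
#' Fraction mode (default): fold change of the fraction of cells of a type
#' within a region relative to its fraction over the whole dataset,
#' `(n_tr / n_.r) / (n_t. / n_..)`. Density mode: fold change of the type's
#' density (cells per region volume) relative to its whole-dataset density;
#' requires `region_volume`. Empty regions score 0 and are flagged.
#'
#' @param cells A `cell_tbl`.
#' @param region_of Column name (or vector) giving each cell's region (or
#'   module) label; defaults to `region_label`.
#' @param type_of Column name (or vector) giving each cell's type; defaults
#'   to `subclass_label`.
#' @param mode `"fraction"` or `"density"`.
#' @param region_volume Named numeric vector of region volumes (mm^3),
#'   density mode only.
#' @return A tibble `type`, `region`, `score` of class `enrichment_tbl`,
#'   with attributes `mode` and `empty_regions`.
#' @export
enrichment_scores <- function(cells, region_of = "region_label",
                              type_of = "subclass_label",
                              mode = c("fraction", "density"),
                              region_volume = NULL) {
  mode <- match.arg(mode)
  region <- if (is.character(region_of) && length(region_of) == 1)
    cells[[region_of]] else region_of
  type <- if (is.character(type_of) && length(type_of) == 1)
    cells[[type_of]] else type_of
  regions <- sort(unique(region))
  types <- sort(unique(type))
  tab <- table(factor(type, types), factor(region, regions))
  n_tr <- as.matrix(tab)
  n_t <- rowSums(n_tr); n_r <- colSums(n_tr); n <- sum(n_tr)
  if (mode == "fraction") {
    score <- sweep(n_tr, 2, n_r, "/") / (n_t / n)
  } else {
    if (is.null(region_volume)) abort("density mode requires region_volume")
    missing <- setdiff(regions, names(region_volume))
    if (length(missing))
      abort(paste0("unknown region in volume map: ", paste(missing, collapse = ", ")))
    v_tot <- sum(region_volume[regions])
    score <- sweep(n_tr, 2, region_volume[regions], "/") / (n_t / v_tot)
  }
  score[!is.finite(score)] <- 0
  out <- as_tibble(as.data.frame.table(score, responseName = "score",
                                       stringsAsFactors = FALSE))
  names(out) <- c("type", "region", "score")
  attr(out, "mode") <- mode
  attr(out, "empty_regions") <- regions[n_r == 0]
  class(out) <- unique(c("enrichment_tbl", class(out)))
  out
}

# wide type x region matrix view of an enrichment table
enrichment_matrix <- function(enr) {
  wide <- tidyr::pivot_wider(enr, names_from = "region", values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$type
  m
}

#' Local cell-type complexity
#'
#' For each neuron, the number of distinct subclasses among its k nearest
#' neighbouring neurons (within the same section, Euclidean, ties by index).
#' Sections with fewer than `k + 1` neurons are flagged (`NA`), not scored.
#'
#' @param cells A `cell_tbl` of neurons with `subclass_label`.
#' @param k Neighbourhood size (default 50).
#' @return The `cell_tbl` with an integer `local_complexity` column.
#' @export
local_complexity <- function(cells, k = 50) {
  out <- rep(NA_integer_, nrow(cells))
  for (sec in unique(cells$section_id)) {
    idx <- which(cells$section_id == sec)
    if (length(idx) <= k) next
    nn <- knn_index(cbind(cells$x[idx], cells$y[idx]),
                    cbind(cells$x[idx], cells$y[idx]), k, self = FALSE)
    lab <- cells$subclass_label[idx]
    out[idx] <- apply(nn, 1, function(js) length(unique(lab[js])))
  }
  cells$local_complexity <- out
  cells
}

#' Split a region into anterior and posterior halves along ccfx
#'
#' The cut is the midpoint of the minimum and maximum ccfx of the region's
#' cells; cells with `ccfx < cut` are anterior, `>= cut` posterior.
#'
#' @param cells A `cell_tbl` with a `ccfx` column.
#' @param region Region label to split (rows of other regions pass through).
#' @param region_col Column holding region labels.
#' @return The `cell_tbl` with the region label replaced by
#'   `"<region>:anterior"` / `"<region>:posterior"`.
#' @export
split_by_ccfx <- function(cells, region, region_col = "region_label") {
  if (!"ccfx" %in% names(cells)) abort("missing ccfx coordinates")
  idx <- which(cells[[region_col]] == region)
  if (!length(idx)) return(cells)
  v <- cells$ccfx[idx]
  if (anyNA(v)) abort("missing ccfx coordinates")
  cut <- (min(v) + max(v)) / 2
  cells[[region_col]][idx] <-
    ifelse(v < cut, paste0(region, ":anterior"), paste0(region, ":posterior"))
  cells
}

#' Cell-type composition fractions by group
#'
#' @param cells A `cell_tbl`.
#' @param group_by Column defining the groups (e.g. `region_label`).
#' @param type_of Column defining the types.
#' @return Tibble `group`, `type`, `n`, `fraction`; fractions sum to 1
#'   within each group; empty groups are dropped.
#' @export
composition_fractions <- function(cells, group_by = "region_label",
                                  type_of = "subclass_label") {
  df <- tibble(group = cells[[group_by]], type = cells[[type_of]])
  df |>
    count(.data$group, .data$type, name = "n") |>
    group_by(.data$group) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}
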