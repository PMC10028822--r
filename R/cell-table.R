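#' Build a cell table
#'
#' The central per-cell container of the package: a tibble with one row per
#' segmented cell and a matrix column `counts` holding the cell-by-gene count
#' matrix over the measured gene panel. All analysis functions take and return
#' this shape, so calls chain with the pipe.
#'
#' @param meta A data frame of per-cell metadata. Required columns: `cell_id`
#'   (unique character), `section_id`, `x`, `y` (in-section coordinates, um),
#'   `z_planes` (integer count of imaged z-stacks) and `volume` (um^3, > 0).
#'   Optional columns: `subclass_label`, `cluster_label`,
#'   `subclass_confidence`, `cluster_confidence` (in \[0, 1\]), `ccfx`, `ccfy`,
#'   `ccfz`, `region_label`, `neurotransmitter_labels` (list column of
#'   character vectors).
#' @param counts Numeric matrix, cells x genes, with column names; row order
#'   must match `meta`. Raw counts are non-negative integers; after volume
#'   normalisation they become non-negative reals.
#'
#' @return A `cell_tbl`: a tibble with the metadata columns plus the `counts`
#'   matrix column.
#' @export
#' @examples
#' counts <- matrix(rpois(6, 5), 2, 3, dimnames = list(NULL, c("a", "b", "c")))
#' meta <- tibble::tibble(cell_id = c("c1", "c2"), section_id = "s1",
#'                        x = c(0, 10), y = c(0, 0), z_planes = 3L,
#'                        volume = c(200, 300))
#' cells <- cell_table(meta, counts)
cell_table <- function(meta, counts) {
  meta <- as_tibble(meta)
  counts <- as.matrix(counts)
  if (nrow(meta) != nrow(counts))
    abort("`meta` and `counts` must have the same number of rows")
  if (nrow(counts) > 0 && is.null(colnames(counts)))
    abort("`counts` must have gene names as column names")
  rownames(counts) <- NULL
  out <- meta
  out$counts <- counts
  out <- new_cell_table(out)
  validate_cell_table(out)
  out
}

new_cell_table <- function(x) {
  class(x) <- unique(c("cell_tbl", class(x)))
  x
}

#' Validate a cell table
#'
#' Checks the structural invariants: unique `cell_id`, positive volumes,
#' finite coordinates, confidences in \[0, 1\], counts matrix present with
#' named genes.
#'
#' @param cells A `cell_tbl`.
#' @return `cells`, invisibly; aborts with an informative message otherwise.
#' @export
validate_cell_table <- function(cells) {
  for (col in c("cell_id", "section_id", "x", "y", "z_planes", "volume", "counts"))
    if (!col %in% names(cells)) abort(paste0("missing column: ", col))
  if (anyDuplicated(cells$cell_id)) abort("duplicate cell_id")
  if (nrow(cells) > 0) {
    if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
      abort("coordinates must be finite")
    if (any(cells$volume <= 0)) abort("volume must be > 0")
  }
  for (col in c("subclass_confidence", "cluster_confidence")) {
    if (col %in% names(cells)) {
      v <- cells[[col]]
      v <- v[!is.na(v)]
      if (length(v) && (any(v < 0) || any(v > 1)))
        abort(paste0(col, " must lie in [0, 1]"))
    }
  }
  if (!is.matrix(cells$counts)) abort("`counts` must be a matrix column")
  if (any(cells$counts < 0)) abort("counts must be non-negative")
  invisible(cells)
}

#' Gene names of a cell table or reference
#' @param x A `cell_tbl` or `ref_tbl`.
#' @return Character vector of panel gene names.
#' @export
gene_names <- function(x) colnames(x$counts)

#' Extract the counts matrix
#' @param x A `cell_tbl` or `ref_tbl`.
#' @return The cells x genes matrix (row names set to `cell_id`).
#' @export
counts_matrix <- function(x) {
  m <- x$counts
  rownames(m) <- x$cell_id
  m
}

#' Per-cell total counts
#' @param cells A `cell_tbl`.
#' @return Numeric vector of per-cell totals over the panel.
#' @export
total_counts <- function(cells) rowSums(cells$counts)

# ---- readers / writers ------------------------------------------------------

meta_cols <- function(cells) {
  keep <- setdiff(names(cells), c("counts", "imputed"))
  out <- as_tibble(cells)[keep]
  if ("neurotransmitter_labels" %in% names(out))
    out$neurotransmitter_labels <-
      map_chr(out$neurotransmitter_labels, paste, collapse = ";")
  out
}

mtx_sidecars <- function(matrix_path) {
  stem <- sub("\\.mtx$", "", matrix_path)
  list(rows = paste0(stem, ".rows.txt"), cols = paste0(stem, ".cols.txt"))
}

read_matrix_any <- function(matrix_path) {
  if (grepl("\\.mtx$", matrix_path)) {
    side <- mtx_sidecars(matrix_path)
    m <- as.matrix(Matrix::readMM(matrix_path))
    ids <- readLines(side$rows)
    genes <- readLines(side$cols)
    if (length(ids) != nrow(m) || length(genes) != ncol(m))
      abort("MTX sidecar row/column name files do not match matrix dimensions")
    dimnames(m) <- list(ids, genes)
    m
  } else {
    df <- readr::read_csv(matrix_path, show_col_types = FALSE, progress = FALSE)
    if (!"cell_id" %in% names(df)) abort("missing column: cell_id")
    m <- as.matrix(df[setdiff(names(df), "cell_id")])
    rownames(m) <- df$cell_id
    m
  }
}

#' Read a cell table from disk
#'
#' The count matrix may be a dense CSV (first column `cell_id`, remaining
#' columns one per gene) or a MatrixMarket `.mtx` file with `<stem>.rows.txt`
#' (cell ids) and `<stem>.cols.txt` (gene names) sidecars. Metadata is a CSV
#' keyed by `cell_id`. Cells present in only one of the two files are
#' rejected.
#'
#' @param matrix_path Path to the count matrix (`.csv` or `.mtx`).
#' @param metadata_path Path to the metadata CSV.
#' @return A `cell_tbl`.
#' @export
read_cell_table <- function(matrix_path, metadata_path) {
  m <- read_matrix_any(matrix_path)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  for (col in c("cell_id", "section_id", "x", "y", "z_planes", "volume"))
    if (!col %in% names(meta)) abort(paste0("missing column: ", col))
  if (anyDuplicated(meta$cell_id)) abort("duplicate cell_id in metadata")
  if (anyDuplicated(rownames(m))) abort("duplicate cell_id in matrix")
  if (!setequal(meta$cell_id, rownames(m)))
    abort("cell ids differ between matrix and metadata")
  m <- m[match(meta$cell_id, rownames(m)), , drop = FALSE]
  if ("neurotransmitter_labels" %in% names(meta))
    meta$neurotransmitter_labels <- map(
      strsplit(ifelse(is.na(meta$neurotransmitter_labels), "",
                      meta$neurotransmitter_labels), ";", fixed = TRUE),
      function(v) v[nzchar(v)])
  cell_table(meta, m)
}

#' Write a cell table to disk
#'
#' Inverse of [read_cell_table()]: integer counts round-trip bit-exactly.
#' Matrix format follows the `matrix_path` extension (`.csv` dense, `.mtx`
#' sparse MatrixMarket with name sidecars).
#'
#' @param cells A `cell_tbl`.
#' @inheritParams read_cell_table
#' @return Invisibly, `cells`.
#' @export
write_cell_table <- function(cells, matrix_path, metadata_path) {
  validate_cell_table(cells)
  m <- counts_matrix(cells)
  if (grepl("\\.mtx$", matrix_path)) {
    side <- mtx_sidecars(matrix_path)
    Matrix::writeMM(Matrix::Matrix(unname(m), sparse = TRUE), matrix_path)
    writeLines(cells$cell_id, side$rows)
    writeLines(colnames(m) %||% character(), side$cols)
  } else {
    df <- tibble(cell_id = cells$cell_id)
    df <- bind_cols(df, as_tibble(m, .name_repair = "minimal"))
    readr::write_csv(df, matrix_path, progress = FALSE)
  }
  readr::write_csv(meta_cols(cells), metadata_path, progress = FALSE)
  invisible(cells)
}

# ---- reference dataset ------------------------------------------------------

#' Build a reference (scRNA-seq) dataset
#'
#' @param meta Data frame with `cell_id`, `subclass_label`, `cluster_label`
#'   and optionally `partition_label`.
#' @param counts Cells x genes count matrix over the full gene universe,
#'   with unique gene names.
#' @return A `ref_tbl` tibble with a `counts` matrix column.
#' @export
reference_dataset <- function(meta, counts) {
  meta <- as_tibble(meta)
  counts <- as.matrix(counts)
  if (nrow(meta) != nrow(counts))
    abort("`meta` and `counts` must have the same number of rows")
  for (col in c("cell_id", "subclass_label", "cluster_label"))
    if (!col %in% names(meta)) abort(paste0("missing column: ", col))
  if (anyDuplicated(meta$cell_id)) abort("duplicate cell_id")
  if (anyDuplicated(colnames(counts))) abort("gene names must be unique")
  nest <- distinct(tibble(cluster = meta$cluster_label,
                          subclass = meta$subclass_label))
  if (anyDuplicated(nest$cluster))
    abort("each cluster must nest within exactly one subclass")
  rownames(counts) <- NULL
  out <- meta
  out$counts <- counts
  class(out) <- unique(c("ref_tbl", class(out)))
  out
}

# ---- codebook ---------------------------------------------------------------

#' Construct a codebook object
#'
#' @param name Character vector of entry names (genes or `Blank-<k>`).
#' @param barcode Character vector of equal-length 0/1 strings.
#' @param is_blank Logical; defaults to names matching `Blank-`.
#' @return A `codebook` tibble with attribute `n_bits`.
#' @export
codebook <- function(name, barcode, is_blank = grepl("^Blank-", name)) {
  if (length(barcode) && any(grepl("[^01]", barcode)))
    abort("barcodes must contain only 0/1 characters")
  lens <- unique(nchar(barcode))
  if (length(lens) > 1) abort("all barcodes must have the same length")
  if (anyDuplicated(barcode)) abort("barcodes must be unique")
  out <- tibble(name = name, barcode = barcode, is_blank = is_blank)
  attr(out, "n_bits") <- if (length(lens)) lens else 0L
  class(out) <- unique(c("codebook", class(out)))
  out
}

#' Number of bits of a codebook
#' @param cb A `codebook`.
#' @return Integer barcode length.
#' @export
n_bits <- function(cb) attr(cb, "n_bits")

# barcode strings -> n x n_bits 0/1 integer matrix
barcode_matrix <- function(cb) {
  if (nrow(cb) == 0) return(matrix(0L, 0, n_bits(cb)))
  do.call(rbind, lapply(strsplit(cb$barcode, ""), as.integer))
}

#' Read / write codebooks
#'
#' CSV dialect: columns `name,barcode` with barcode a 0/1 string; blank
#' entries are named `Blank-<k>`.
#'
#' @param path File path.
#' @return [read_codebook()] returns a `codebook`.
#' @export
read_codebook <- function(path) {
  df <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  for (col in c("name", "barcode"))
    if (!col %in% names(df)) abort(paste0("missing column: ", col))
  codebook(df$name, df$barcode)
}

#' @rdname read_codebook
#' @param cb A `codebook`.
#' @export
write_codebook <- function(cb, path) {
  readr::write_csv(tibble(name = cb$name, barcode = cb$barcode), path,
                   progress = FALSE)
  invisible(cb)
}

# ---- ligand-receptor database -----------------------------------------------

#' Build a ligand-receptor pair database
#'
#' Multi-subunit ligand-receptor pairs grouped by signalling pathway, the
#' shape of the CellChat database.
#'
#' @param pair_id Unique pair identifiers.
#' @param pathway Pathway name per pair.
#' @param ligand_subunits,receptor_subunits Lists of non-empty character
#'   vectors of subunit gene names.
#' @return An `lr_db` tibble with list columns for the subunits.
#' @export
lr_database <- function(pair_id, pathway, ligand_subunits, receptor_subunits) {
  if (anyDuplicated(pair_id)) abort("duplicate pair_id")
  if (any(lengths(ligand_subunits) == 0) || any(lengths(receptor_subunits) == 0))
    abort("subunit lists must be non-empty")
  out <- tibble(pair_id = pair_id, pathway = pathway,
                ligand_subunits = as.list(ligand_subunits),
                receptor_subunits = as.list(receptor_subunits))
  class(out) <- unique(c("lr_db", class(out)))
  out
}

#' Read / write a ligand-receptor database
#'
#' CSV columns `pair_id,pathway,ligand_subunits,receptor_subunits`, subunit
#' gene lists `;`-separated. Genes absent from a given expression table are
#' handled downstream, not at read time.
#'
#' @param path File path.
#' @return [read_lr_database()] returns an `lr_db`.
#' @export
read_lr_database <- function(path) {
  df <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
  for (col in c("pair_id", "pathway", "ligand_subunits", "receptor_subunits"))
    if (!col %in% names(df)) abort(paste0("missing column: ", col))
  split_genes <- function(s) {
    v <- strsplit(ifelse(is.na(s), "", s), ";", fixed = TRUE)
    lapply(v, function(g) g[nzchar(g)])
  }
  lr_database(df$pair_id, df$pathway,
              split_genes(df$ligand_subunits), split_genes(df$receptor_subunits))
}

#' @rdname read_lr_database
#' @param db An `lr_db`.
#' @export
write_lr_database <- function(db, path) {
  readr::write_csv(
    tibble(pair_id = db$pair_id, pathway = db$pathway,
           ligand_subunits = map_chr(db$ligand_subunits, paste, collapse = ";"),
           receptor_subunits = map_chr(db$receptor_subunits, paste, collapse = ";")),
    path, progress = FALSE)
  invisible(db)
}

# ---- analysis configuration -------------------------------------------------

#' Default analysis configuration
#'
#' Every tunable of the pipeline with its default. Radii are um; `n_rounds`
#' counts randomization rounds; confidence gates are fractions.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `atlas_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    target_mean = 250, quantile_q = 0.01, doublet_cutoff = 0.25,
    nt_threshold = 2,
    norm_total = 1000, pca_dims = 100, knn_graph_k = 15,
    anchor_k = 5, k_anchor = 100, impute_k = 30, downsample = 100000,
    subclass_gate = 0.8, cluster_gate = 0.5,
    composition_k = 50, d0_neighbor = 5, leiden_knn = 15,
    leiden_resolution = 0.1, merge_cosine = 0.9,
    purity_k = 50, purity_dims = 50,
    r_proximal_strict = 15, r_proximal_relaxed = 30,
    r_randomization = 100, n_rounds = 1000, alpha = 0.05,
    min_observed_pairs = 20,
    lr_min_fold = 2, lr_max_p = 0.01, lr_min_frac_positive = 0.4,
    enrich_threshold_default = 2, enrich_threshold_subdivided = 6,
    enrich_threshold_astrocyte = 1, min_nonneuronal_cells = 50,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("unknown config field: ", paste(bad, collapse = ", ")))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$r_proximal_strict > 0, cfg$r_randomization > cfg$r_proximal_strict,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_rounds >= 2)
  structure(cfg, class = "atlas_config")
}

#' Read an analysis configuration from YAML
#' @param path YAML file of overrides.
#' @return An `atlas_config`.
#' @export
read_analysis_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}
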