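#' Specify a synthetic spatial transcriptomics experiment
#'
#' Describes everything the generator needs to emulate one MERFISH-style
#' experiment with known ground truth: a rectangular region layout with
#' per-subclass cell intensities, per-cluster negative-binomial expression
#' profiles, optional planted spatial expression gradients, optional planted
#' pairwise spatial attraction between cell types, and optional planted
#' ligand-receptor upregulation in proximal cell pairs.
#'
#' @param profiles Cluster x gene matrix of mean expression (non-negative),
#'   row names are cluster names, column names the gene universe.
#' @param cluster_subclass Named character vector mapping each cluster to its
#'   subclass.
#' @param regions Tibble with columns `region`, `xmin`, `xmax`, `ymin`,
#'   `ymax` (um). Rectangles must not overlap.
#' @param intensity Region x subclass matrix of intensities in cells per mm^2.
#' @param panel Character vector: the gene subset measured in situ. Defaults
#'   to the whole universe.
#' @param dispersion Negative-binomial dispersion `theta`
#'   (variance = mean + mean^2 / theta); `Inf` gives Poisson counts.
#' @param gradients Optional tibble with columns `subclass`, `genes` (list
#'   column), `axis` ("x" or "y") and `slope`: the listed genes' means are
#'   multiplied by `1 + slope * u`, `u` the cell's normalised position along
#'   the axis (0 at the low edge, 1 at the high edge). `slope >= -1` required
#'   (means stay non-negative); slope 0 plants no gradient.
#' @param attractions Optional tibble with columns `type_a`, `type_b`,
#'   `radius` (um) and `attach_prob`: each type-A cell spawns one extra
#'   type-B cell uniformly within `radius` with probability `attach_prob`
#'   (a Thomas-like attractive process).
#' @param lr_effects Optional tibble with columns `pair_id`, `type_a`,
#'   `type_b`, `ligand_genes`, `receptor_genes` (list columns), `radius` (um)
#'   and `fold` (>= 1): ligand gene means are multiplied by `fold` in type-A
#'   cells that lie within `radius` of a type-B cell, and receptor gene means
#'   likewise in the partnered type-B cells.
#' @param volume_meanlog,volume_sdlog Log-normal per-cell volume model
#'   (um^3). Counts scale proportionally to volume before any QC
#'   normalisation, so the volume normalisation step is exercised.
#' @param z_planes Number of imaged z-stacks recorded in the metadata.
#'
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(profiles, cluster_subclass, regions, intensity,
                            panel = colnames(profiles), dispersion = 10,
                            gradients = NULL, attractions = NULL,
                            lr_effects = NULL,
                            volume_meanlog = log(250), volume_sdlog = 0.25,
                            z_planes = 3L) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) abort("profiles must be non-negative")
  if (is.null(rownames(profiles)) || is.null(colnames(profiles)))
    abort("profiles needs cluster row names and gene column names")
  if (!setequal(names(cluster_subclass), rownames(profiles)))
    abort("cluster_subclass must name every profile row")
  if (!all(panel %in% colnames(profiles)))
    abort("panel must be a subset of the gene universe")
  intensity <- as.matrix(intensity)
  if (any(intensity < 0)) abort("intensities must be >= 0")
  regions <- as_tibble(regions)
  if (!is.null(lr_effects) && any(lr_effects$fold < 1))
    abort("lr_effects folds must be >= 1")
  if (!is.null(gradients) && any(gradients$slope < -1))
    abort("gradient slopes must be >= -1")
  structure(list(
    profiles = profiles, cluster_subclass = cluster_subclass,
    regions = regions, intensity = intensity, panel = panel,
    dispersion = dispersion,
    gradients = if (is.null(gradients)) NULL else as_tibble(gradients),
    attractions = if (is.null(attractions)) NULL else as_tibble(attractions),
    lr_effects = if (is.null(lr_effects)) NULL else as_tibble(lr_effects),
    volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
    z_planes = as.integer(z_planes)), class = "simulation_spec")
}

draw_counts <- function(mu, theta) {
  n <- length(mu)
  if (is.infinite(theta)) rpois(n, mu) else rnbinom(n, size = theta, mu = mu)
}

#' Simulate a single-cell reference dataset
#'
#' Draws `n_per_cluster` cells per cluster with negative-binomial counts over
#' the full gene universe around each cluster's mean profile. This stands in
#' for the dissociated-cell reference that labels are transferred from.
#'
#' @param spec A [simulation_spec()].
#' @param n_per_cluster Cells per cluster (>= 2).
#' @param seed Integer seed.
#' @return A `ref_tbl` (see [reference_dataset()]).
#' @export
simulate_reference <- function(spec, n_per_cluster, seed) {
  if (n_per_cluster < 2) abort("n_per_cluster must be >= 2")
  with_seed(seed, {
    clusters <- rownames(spec$profiles)
    counts <- do.call(rbind, lapply(clusters, function(cl) {
      mu <- spec$profiles[cl, ]
      t(replicate(n_per_cluster, draw_counts(mu, spec$dispersion)))
    }))
    colnames(counts) <- colnames(spec$profiles)
    meta <- tibble(
      cell_id = sprintf("ref_%05d", seq_len(nrow(counts))),
      subclass_label = rep(unname(spec$cluster_subclass[clusters]),
                           each = n_per_cluster),
      cluster_label = rep(clusters, each = n_per_cluster))
    reference_dataset(meta, counts)
  })
}

rect_area_mm2 <- function(r) (r$xmax - r$xmin) * (r$ymax - r$ymin) / 1e6

rects_overlap <- function(regions) {
  n <- nrow(regions)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    a <- regions[i, ]; b <- regions[j, ]
    if (a$xmin < b$xmax && b$xmin < a$xmax &&
        a$ymin < b$ymax && b$ymin < a$ymax) return(TRUE)
  }
  FALSE
}

#' Simulate one tissue section with planted ground truth
#'
#' Parent cells form a homogeneous Poisson point process within each region
#' at the per-subclass intensity; each attraction row lets type-A cells spawn
#' a type-B companion uniformly within its radius with the stated
#' probability; counts (restricted to the panel) are negative-binomial around
#' cluster profiles, modulated by planted gradients, proximity-conditional
#' ligand-receptor folds, and the per-cell volume.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @param section_id Section identifier written into the table.
#' @return A list with elements `cells` (a `cell_tbl`, with `subclass_label`
#'   / `cluster_label` / `region_label` set to the planted truth and
#'   confidences 1) and `truth` (a list: per-cell true labels, the attraction
#'   and ligand-receptor specs that were planted, the per-cell flags of which
#'   cells received the ligand/receptor fold, and the gradient axes).
#' @export
simulate_section <- function(spec, seed, section_id = "sec1") {
  if (rects_overlap(spec$regions)) abort("regions must partition space (rectangles overlap)")
  with_seed(seed, {
    subclasses <- colnames(spec$intensity)
    cl_by_sub <- split(names(spec$cluster_subclass), unname(spec$cluster_subclass))
    pts <- list()
    for (ri in seq_len(nrow(spec$regions))) {
      r <- spec$regions[ri, ]
      area <- rect_area_mm2(r)
      for (sc in subclasses) {
        lam <- spec$intensity[ri, sc] * area
        n <- rpois(1, lam)
        if (n == 0) next
        pts[[length(pts) + 1L]] <- tibble(
          x = runif(n, r$xmin, r$xmax), y = runif(n, r$ymin, r$ymax),
          subclass = sc,
          cluster = sample(cl_by_sub[[sc]], n, replace = TRUE),
          region = r$region)
      }
    }
    cells <- if (length(pts)) bind_rows(pts) else
      tibble(x = numeric(), y = numeric(), subclass = character(),
             cluster = character(), region = character())

    # planted attraction: daughters spawned in a disk around type-A parents
    if (!is.null(spec$attractions)) {
      for (ai in seq_len(nrow(spec$attractions))) {
        a <- spec$attractions[ai, ]
        parents <- which(cells$subclass == a$type_a)
        spawn <- parents[runif(length(parents)) < a$attach_prob]
        if (!length(spawn)) next
        ang <- runif(length(spawn), 0, 2 * pi)
        rad <- a$radius * sqrt(runif(length(spawn)))
        daughters <- tibble(
          x = cells$x[spawn] + rad * cos(ang),
          y = cells$y[spawn] + rad * sin(ang),
          subclass = a$type_b,
          cluster = sample(cl_by_sub[[a$type_b]], length(spawn), replace = TRUE),
          region = cells$region[spawn])
        cells <- bind_rows(cells, daughters)
      }
    }
    n <- nrow(cells)
    mu <- spec$profiles[cells$cluster, , drop = FALSE]

    # planted gradients: linear modulation along a spatial axis
    if (!is.null(spec$gradients)) {
      xr <- range(c(spec$regions$xmin, spec$regions$xmax))
      yr <- range(c(spec$regions$ymin, spec$regions$ymax))
      for (gi in seq_len(nrow(spec$gradients))) {
        g <- spec$gradients[gi, ]
        idx <- which(cells$subclass == g$subclass)
        if (!length(idx)) next
        coord <- if (g$axis == "x") cells$x[idx] else cells$y[idx]
        rng <- if (g$axis == "x") xr else yr
        u <- (coord - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
        genes <- intersect(g$genes[[1]], colnames(mu))
        mu[idx, genes] <- mu[idx, genes] * (1 + g$slope * u)
      }
    }

    # planted ligand-receptor upregulation in proximal pairs
    lig_flag <- rep(FALSE, n); rec_flag <- rep(FALSE, n)
    if (!is.null(spec$lr_effects) && n > 0) {
      for (li in seq_len(nrow(spec$lr_effects))) {
        e <- spec$lr_effects[li, ]
        ia <- which(cells$subclass == e$type_a)
        ib <- which(cells$subclass == e$type_b)
        if (!length(ia) || !length(ib)) next
        d2 <- cross_dist2(cbind(cells$x[ia], cells$y[ia]),
                          cbind(cells$x[ib], cells$y[ib]))
        prox <- d2 < e$radius^2
        if (identical(e$type_a, e$type_b)) diag(prox) <- FALSE
        a_hit <- ia[rowSums(prox) > 0]
        b_hit <- ib[colSums(prox) > 0]
        lg <- intersect(e$ligand_genes[[1]], colnames(mu))
        rg <- intersect(e$receptor_genes[[1]], colnames(mu))
        mu[a_hit, lg] <- mu[a_hit, lg] * e$fold
        mu[b_hit, rg] <- mu[b_hit, rg] * e$fold
        lig_flag[a_hit] <- TRUE; rec_flag[b_hit] <- TRUE
      }
    }

    # volume effect: counts scale with imaged volume before QC normalisation
    volume <- stats::rlnorm(n, spec$volume_meanlog, spec$volume_sdlog)
    vol_scale <- volume / exp(spec$volume_meanlog + spec$volume_sdlog^2 / 2)
    mu_panel <- mu[, spec$panel, drop = FALSE] * vol_scale
    counts <- matrix(draw_counts(as.vector(mu_panel), spec$dispersion),
                     nrow = n, dimnames = list(NULL, spec$panel))

    meta <- tibble(
      cell_id = sprintf("cell_%05d", seq_len(n)),
      section_id = section_id, x = cells$x, y = cells$y,
      z_planes = spec$z_planes, volume = volume,
      subclass_label = cells$subclass, cluster_label = cells$cluster,
      subclass_confidence = rep(1, n), cluster_confidence = rep(1, n),
      region_label = cells$region)
    truth <- list(
      subclass = cells$subclass, cluster = cells$cluster,
      region = cells$region,
      interacting_pairs = spec$attractions,
      lr_pairs = spec$lr_effects,
      ligand_upregulated = lig_flag, receptor_upregulated = rec_flag,
      gradients = spec$gradients)
    list(cells = cell_table(meta, counts), truth = truth)
  })
}

#' Write the planted-truth sidecar
#' @param truth The `truth` element of [simulate_section()].
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  ser <- truth
  for (nm in c("interacting_pairs", "lr_pairs", "gradients"))
    if (!is.null(ser[[nm]])) ser[[nm]] <- as.data.frame(tidyr::unnest(
      ser[[nm]], cols = dplyr::any_of(c("genes", "ligand_genes", "receptor_genes"))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Catalogue of named simulation fixtures
#'
#' The study conditions used throughout the test and acceptance suites:
#' \describe{
#'   \item{csr}{Two cell types at 200 cells/mm^2 each in a 1 x 1 mm section,
#'     completely spatially random; no planted structure. The no-interaction
#'     baseline.}
#'   \item{attraction}{As `csr` plus planted attraction: each type-A cell
#'     spawns a type-B companion within 10 um with probability 0.5.}
#'   \item{two_region}{Two adjacent 1 x 1 mm regions with disjoint dominant
#'     neuronal subclasses (500 cells/mm^2 each) over a sparse shared
#'     background; ground truth for spatial-module recovery.}
#'   \item{gradient}{One 1 x 1 mm region with a "Grad" subclass whose two
#'     clusters share a profile modulated linearly along x (seven-fold across
#'     the section on 10 genes), and a "Sep" subclass with two well-separated
#'     clusters.}
#'   \item{lr_effect}{Two sparse types (70 cells/mm^2, 2.5 x 2.5 mm section)
#'     with a planted 3-fold ligand/receptor upregulation for pair `LRpos` in
#'     A-B cell pairs within 30 um; three matched null pairs are expressed
#'     but unmodulated. Sparsity keeps proximity exposure rare, preserving
#'     the proximal vs non-proximal contrast.}
#'   \item{integration}{Expression-only spec: 10 subclasses x 3 clusters over
#'     a 150-gene universe with a 100-gene panel; used with
#'     [simulate_reference()] and [simulate_section()] for label-transfer and
#'     imputation benchmarks.}
#' }
#'
#' @return Named list of `simulation_spec` objects.
#' @export
default_specs <- function() {
  specs <- list()
  # ---- shared small universe for the spatial fixtures ----
  genes20 <- sprintf("g%03d", 1:20)
  prof2 <- rbind(A.c1 = c(rep(20, 10), rep(1, 10)),
                 B.c1 = c(rep(1, 10), rep(20, 10)))
  colnames(prof2) <- genes20
  square <- tibble(region = "R1", xmin = 0, xmax = 1000, ymin = 0, ymax = 1000)
  int2 <- matrix(200, 1, 2, dimnames = list("R1", c("A", "B")))

  specs$csr <- simulation_spec(
    profiles = prof2, cluster_subclass = c(A.c1 = "A", B.c1 = "B"),
    regions = square, intensity = int2)

  specs$attraction <- simulation_spec(
    profiles = prof2, cluster_subclass = c(A.c1 = "A", B.c1 = "B"),
    regions = square, intensity = int2,
    attractions = tibble(type_a = "A", type_b = "B",
                         radius = 10, attach_prob = 0.5))

  # ---- two-region fixture for spatial modules ----
  prof4 <- matrix(1, 4, 20, dimnames = list(c("S1.c1", "S2.c1", "S3.c1", "S4.c1"),
                                            genes20))
  for (i in 1:4) prof4[i, ((i - 1) * 5 + 1):(i * 5)] <- 20
  two_regions <- tibble(region = c("left", "right"),
                        xmin = c(0, 1000), xmax = c(1000, 2000),
                        ymin = 0, ymax = 1000)
  int4 <- rbind(left = c(S1 = 500, S2 = 500, S3 = 10, S4 = 10),
                right = c(S1 = 10, S2 = 10, S3 = 500, S4 = 500))
  specs$two_region <- simulation_spec(
    profiles = prof4,
    cluster_subclass = c(S1.c1 = "S1", S2.c1 = "S2", S3.c1 = "S3", S4.c1 = "S4"),
    regions = two_regions, intensity = int4)

  # ---- gradient fixture ----
  genes30 <- sprintf("g%03d", 1:30)
  base <- rep(10, 30)
  grad_prof <- rbind(
    Grad.c1 = base, Grad.c2 = base,
    Sep.c1 = c(rep(30, 10), rep(1, 10), rep(5, 10)),
    Sep.c2 = c(rep(1, 10), rep(30, 10), rep(5, 10)))
  colnames(grad_prof) <- genes30
  # a strong laminar-style gradient: about seven-fold across the section
  specs$gradient <- simulation_spec(
    profiles = grad_prof,
    cluster_subclass = c(Grad.c1 = "Grad", Grad.c2 = "Grad",
                         Sep.c1 = "Sep", Sep.c2 = "Sep"),
    regions = square,
    intensity = matrix(c(500, 500), 1, 2,
                       dimnames = list("R1", c("Grad", "Sep"))),
    gradients = tibble(subclass = "Grad",
                       genes = list(sprintf("g%03d", 21:30)),
                       axis = "x", slope = 6))

  # ---- ligand-receptor fixture ----
  # ligand/receptor transcripts are lowly expressed (well below one copy
  # per cell on average), as is typical of signalling genes
  lr_genes <- c("Lig1", "Rec1", "Lig2", "Rec2a", "Rec2b",
                "Lig3", "Rec3", "Lig4", "Rec4")
  genesLR <- c(genes20, lr_genes)
  profLR <- rbind(A.c1 = c(rep(20, 10), rep(1, 10), rep(0.5, length(lr_genes))),
                  B.c1 = c(rep(1, 10), rep(20, 10), rep(0.5, length(lr_genes))))
  colnames(profLR) <- genesLR
  # sparse populations in a wide section keep proximity exposure rare (about
  # one in five sender cells) while leaving enough proximal pairs for the
  # Welch contrast; a dense field would upregulate most cells and erase the
  # proximal / non-proximal distinction the analysis relies on
  specs$lr_effect <- simulation_spec(
    profiles = profLR, cluster_subclass = c(A.c1 = "A", B.c1 = "B"),
    regions = tibble(region = "R1", xmin = 0, xmax = 2500,
                     ymin = 0, ymax = 2500),
    intensity = matrix(70, 1, 2, dimnames = list("R1", c("A", "B"))),
    dispersion = 20,
    lr_effects = tibble(pair_id = "LRpos", type_a = "A", type_b = "B",
                        ligand_genes = list("Lig1"),
                        receptor_genes = list("Rec1"),
                        radius = 30, fold = 3))

  # ---- integration benchmark spec ----
  n_sub <- 10; n_cl <- 3; n_genes <- 150
  genesI <- sprintf("g%03d", seq_len(n_genes))
  profI <- matrix(1, n_sub * n_cl, n_genes)
  rn <- character(n_sub * n_cl)
  submap <- character(n_sub * n_cl)
  # frozen structural randomness: part of the fixture definition, not a run
  with_seed(20260920, {
    k <- 0
    for (s in seq_len(n_sub)) {
      sub_genes <- sample(n_genes, 18)
      for (cl in seq_len(n_cl)) {
        k <- k + 1
        rn[k] <- sprintf("S%02d.c%d", s, cl)
        submap[k] <- sprintf("S%02d", s)
        profI[k, sub_genes] <- 15
        profI[k, sample(sub_genes, 6)] <- 40  # cluster-specific accents
      }
    }
  })
  dimnames(profI) <- list(rn, genesI)
  names(submap) <- rn
  specs$integration <- simulation_spec(
    profiles = profI, cluster_subclass = submap,
    regions = square,
    intensity = matrix(150, 1, n_sub, dimnames = list("R1", unique(submap))),
    panel = genesI[1:100], dispersion = 20)
  specs
}

#' Ligand-receptor database matching the `lr_effect` fixture
#'
#' One planted pair (`LRpos`), one multi-subunit pair and two null
#' single-subunit pairs, all over genes present in the fixture's panel.
#'
#' @return An `lr_db`.
#' @export
default_lr_database <- function() {
  lr_database(
    pair_id = c("LRpos", "LRnull_multi", "LRnull_a", "LRnull_b"),
    pathway = c("PlantedPathway", "NullPathway", "NullPathway", "NullPathway"),
    ligand_subunits = list("Lig1", "Lig2", "Lig3", "Lig4"),
    receptor_subunits = list("Rec1", c("Rec2a", "Rec2b"), "Rec3", "Rec4"))
}
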