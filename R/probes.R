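# Encoding-probe target-region design: 30-nt windows filtered on GC, melting
# temperature and rRNA/tRNA homology, then thinned to a non-overlapping
# random draw.

#' Probe design parameters
#'
#' Primary rules: 30-nt windows, GC in \[0.40, 0.60\], Tm in \[66, 76\] degC,
#' no shared 16-mer with the rRNA/tRNA index (no homology longer than 15 nt),
#' non-overlapping windows, 64 targets drawn at random. For transcripts that
#' cannot host 64 such windows, relaxed rules allow GC \[0.30, 0.70\], Tm
#' \[61, 81\] and up to 20 nt of overlap, down to a floor of 40 probes.
#'
#' @param window_len Target length, nt.
#' @param gc_range,gc_range_relaxed GC-fraction bounds (inclusive).
#' @param tm_range,tm_range_relaxed Melting-temperature bounds, degC.
#' @param max_homology Longest tolerated exact match to the excluded set, nt.
#' @param n_target Number of target regions drawn per gene.
#' @param min_probes Minimum acceptable number of probes after relaxation.
#' @param max_overlap_relaxed Maximum window overlap under relaxed rules, nt.
#' @return A `probe_params` list.
#' @export
probe_params <- function(window_len = 30,
                         gc_range = c(0.40, 0.60),
                         gc_range_relaxed = c(0.30, 0.70),
                         tm_range = c(66, 76),
                         tm_range_relaxed = c(61, 81),
                         max_homology = 15,
                         n_target = 64, min_probes = 40,
                         max_overlap_relaxed = 20) {
  stopifnot(window_len > max_homology, gc_range[1] < gc_range[2],
            tm_range[1] < tm_range[2], min_probes <= n_target)
  structure(list(window_len = window_len, gc_range = gc_range,
                 gc_range_relaxed = gc_range_relaxed, tm_range = tm_range,
                 tm_range_relaxed = tm_range_relaxed,
                 max_homology = max_homology, n_target = n_target,
                 min_probes = min_probes,
                 max_overlap_relaxed = max_overlap_relaxed),
            class = "probe_params")
}

#' Nearest-neighbour DNA melting temperature
#'
#' Unified nearest-neighbour thermodynamics (dinucleotide enthalpy/entropy
#' sums with terminal initiation terms) with monovalent-salt and formamide
#' corrections. Probe-design filters accept any Tm function of the same
#' signature, so this model is a default, not a contract.
#'
#' @param seq DNA string (ACGT).
#' @param conc_nM Oligo concentration, nM.
#' @param na_M Monovalent cation concentration, M.
#' @param formamide_pct Formamide percentage (0.65 degC penalty per percent).
#' @return Tm in degC.
#' @export
tm_nn <- function(seq, conc_nM = 5, na_M = 0.3, formamide_pct = 0) {
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  comp <- c(AA = "TT", AT = "AT", TA = "TA", CA = "TG", GT = "AC", CT = "AG",
            GA = "TC", CG = "CG", GC = "GC", GG = "CC")
  lut_h <- c(dH, setNames(dH, comp))
  lut_s <- c(dS, setNames(dS, comp))
  s <- toupper(seq)
  chars <- strsplit(s, "")[[1]]
  if (length(chars) < 2) abort("sequence too short for a nearest-neighbour Tm")
  steps <- paste0(chars[-length(chars)], chars[-1])
  h <- sum(lut_h[steps]) * 1000  # cal/mol
  sv <- sum(lut_s[steps])
  for (term in c(chars[1], chars[length(chars)])) {
    if (term %in% c("G", "C")) { h <- h + 100;  sv <- sv - 2.8 }
    else                       { h <- h + 2300; sv <- sv + 4.1 }
  }
  tm_k <- h / (sv + 1.987 * log(conc_nM * 1e-9 / 4))
  tm_k - 273.15 + 16.6 * log10(na_M) - 0.65 * formamide_pct
}

#' Build the excluded k-mer index from abundant-RNA sequences
#'
#' Every k-mer (`k = max_homology + 1`, default 16) of the supplied rRNA and
#' tRNA sequences; a candidate window containing any of them shares a longer-
#' than-`max_homology` exact match and is discarded.
#'
#' @param seqs Character vector of sequences (e.g. from [read_fasta()]).
#' @param k K-mer length.
#' @return Character vector of unique k-mers.
#' @export
build_excluded_index <- function(seqs, k = 16) {
  kmers <- unlist(lapply(toupper(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }))
  unique(kmers)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

window_stats <- function(chars, window_len) {
  n <- length(chars)
  starts <- seq_len(n - window_len + 1)
  gc_cum <- cumsum(chars %in% c("G", "C"))
  gc <- (gc_cum[starts + window_len - 1] -
           c(0, gc_cum)[starts]) / window_len
  list(starts = starts, gc = gc)
}

#' Design probe target regions within a transcript
#'
#' Enumerates all windows of `window_len`, filters on GC, Tm and the excluded
#' k-mer index, then draws a seeded random non-overlapping subset of
#' `n_target` windows. If the primary rules cannot host `n_target` windows,
#' the relaxed GC/Tm bounds and partial overlap are used down to
#' `min_probes`; below that the transcript is rejected (flagged, not raised).
#'
#' @param transcript DNA string.
#' @param excluded_index K-mer set from [build_excluded_index()].
#' @param params A [probe_params()].
#' @param seed Integer seed for the random draw.
#' @param tm_fun Tm function `function(seq) -> degC`; defaults to [tm_nn()].
#' @return Tibble of selected windows with 0-based half-open `start`, `end`
#'   and `gc`, plus attributes `rule_set` (`"primary"`, `"relaxed"` or
#'   `"rejected"`) and `n_candidates`.
#' @export
design_target_regions <- function(transcript, excluded_index = character(),
                                  params = probe_params(), seed = 1,
                                  tm_fun = tm_nn) {
  empty <- tibble(start = integer(), end = integer(), gc = numeric())
  wl <- params$window_len
  chars <- strsplit(toupper(transcript), "")[[1]]
  if (length(chars) < wl) {
    attr(empty, "rule_set") <- "rejected"; attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  ws <- window_stats(chars, wl)
  seqs <- substring(paste(chars, collapse = ""), ws$starts, ws$starts + wl - 1)
  tm <- vapply(seqs, tm_fun, numeric(1), USE.NAMES = FALSE)

  # homology: window keeps no k-mer of the excluded set
  k <- params$max_homology + 1
  bad_start <- rep(FALSE, length(chars))
  if (length(excluded_index) && length(chars) >= k) {
    kmers <- substring(paste(chars, collapse = ""),
                       1:(length(chars) - k + 1), k:length(chars))
    bad_start[seq_along(kmers)] <- kmers %in% excluded_index
  }
  has_hit <- vapply(ws$starts, function(s)
    any(bad_start[s:(s + wl - k)]), logical(1))

  pick <- function(gc_range, tm_range, min_gap) {
    ok <- ws$gc >= gc_range[1] & ws$gc <= gc_range[2] &
      tm >= tm_range[1] & tm <= tm_range[2] & !has_hit
    cand <- ws$starts[ok]
    if (!length(cand)) return(list(sel = integer(), n_cand = 0L))
    sel <- integer()
    for (s in sample(cand)) {
      if (all(abs(s - sel) >= min_gap)) sel <- c(sel, s)
      if (length(sel) == params$n_target) break
    }
    list(sel = sort(sel), n_cand = length(cand))
  }

  with_seed(seed, {
    primary <- pick(params$gc_range, params$tm_range, wl)
    if (length(primary$sel) >= params$n_target) {
      out <- tibble(start = primary$sel - 1L, end = primary$sel + wl - 1L,
                    gc = ws$gc[match(primary$sel, ws$starts)])
      attr(out, "rule_set") <- "primary"
      attr(out, "n_candidates") <- primary$n_cand
      return(out)
    }
    relaxed <- pick(params$gc_range_relaxed, params$tm_range_relaxed,
                    wl - params$max_overlap_relaxed)
    if (length(relaxed$sel) >= params$min_probes) {
      out <- tibble(start = relaxed$sel - 1L, end = relaxed$sel + wl - 1L,
                    gc = ws$gc[match(relaxed$sel, ws$starts)])
      attr(out, "rule_set") <- "relaxed"
      attr(out, "n_candidates") <- relaxed$n_cand
      return(out)
    }
    attr(empty, "rule_set") <- "rejected"
    attr(empty, "n_candidates") <- max(primary$n_cand, relaxed$n_cand)
    empty
  })
}
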