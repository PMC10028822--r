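# Error-robust barcode codebooks: constant-weight-4, minimum-Hamming-
# distance-4 binary codes. Distance 4 between two weight-4 words is
# equivalent to their set supports sharing at most 2 positions, i.e. the
# supports form a packing of 4-subsets in which every 3-subset occurs at most
# once. The maximal such packing on n points (n = 2 or 4 mod 6) is a Steiner
# quadruple system SQS(n) with C(n,3)/4 blocks.

# Round-robin (circle method) one-factorization of the complete graph K_n,
# n even: n-1 perfect matchings partitioning all edges. 1-based points.
one_factorization <- function(n) {
  stopifnot(n %% 2 == 0)
  m <- n - 1L
  lapply(seq_len(m) - 1L, function(r) {
    edges <- matrix(0L, nrow = n / 2, ncol = 2)
    edges[1, ] <- c(n, r + 1L)
    for (k in seq_len(n / 2 - 1)) {
      edges[k + 1L, ] <- c((r + k) %% m + 1L, (r - k) %% m + 1L)
    }
    edges
  })
}

# Block list of an SQS(n) for n a power of two >= 4, by recursive doubling:
# SQS(2n) blocks are (i) each SQS(n) block replayed inside each point copy
# and (ii) cross blocks {a0, b0, c1, d1} for every ordered pair of edges
# ({a,b}, {c,d}) lying in the same one-factor of K_n.
sqs_blocks <- function(n) {
  if (n == 4) return(list(1:4))
  stopifnot(n %% 2 == 0)
  half <- sqs_blocks(n / 2)
  blocks <- c(half, lapply(half, function(b) b + n / 2L))
  for (factor in one_factorization(n / 2)) {
    for (i in seq_len(nrow(factor))) for (j in seq_len(nrow(factor))) {
      blocks[[length(blocks) + 1L]] <-
        c(factor[i, ], factor[j, ] + n / 2L)
    }
  }
  blocks
}

#' Construct a maximal constant-weight-4, distance-4 codebook
#'
#' Builds the full Steiner-quadruple-system codebook on `n_bits` bits by
#' recursive doubling from the single-block system on 4 points. Every word
#' has Hamming weight 4, every pair of words has Hamming distance >= 4, and
#' the code is maximal: its size is `choose(n_bits, 3) / 4` (1240 words at 32
#' bits), with every 3-subset of bit positions covered by exactly one word.
#'
#' @param n_bits Barcode length; a power of two >= 4.
#' @return A `codebook` of unnamed words (`word_<k>`), none blank; pass it to
#'   [assign_barcodes()] to attach gene names.
#' @export
#' @examples
#' cb <- construct_codebook(8)
#' nrow(cb)  # 14 = choose(8, 3) / 4
construct_codebook <- function(n_bits) {
  if (n_bits < 4 || bitwAnd(n_bits, n_bits - 1L) != 0)
    abort("n_bits must be a power of two >= 4")
  blocks <- sqs_blocks(as.integer(n_bits))
  words <- vapply(blocks, function(b) {
    w <- rep("0", n_bits); w[b] <- "1"; paste(w, collapse = "")
  }, character(1))
  codebook(name = sprintf("word_%04d", seq_along(words)),
           barcode = sort(words), is_blank = rep(FALSE, length(words)))
}

#' Validate a codebook's weight and distance guarantees
#'
#' Exhaustive O(n^2) check of per-word Hamming weight, global minimum
#' pairwise Hamming distance and duplicate words. Failures are reported in
#' the returned object, never raised.
#'
#' @param cb A `codebook`.
#' @param weight Required Hamming weight per word.
#' @param min_distance Required minimum pairwise distance.
#' @return A list with `weights` (per-entry tibble), `min_distance`,
#'   `n_duplicates` and `pass`.
#' @export
validate_codebook <- function(cb, weight = 4, min_distance = 4) {
  W <- barcode_matrix(cb)
  w <- rowSums(W)
  dup <- sum(duplicated(cb$barcode))
  mind <- Inf
  if (nrow(W) >= 2) {
    # distance(i, j) = w_i + w_j - 2 * overlap(i, j)
    ov <- tcrossprod(W)
    d <- outer(w, w, "+") - 2 * ov
    mind <- min(d[upper.tri(d)])
  }
  list(weights = tibble(name = cb$name, weight = as.integer(w)),
       min_distance = mind, n_duplicates = dup,
       pass = all(w == weight) && mind >= min_distance && dup == 0)
}

#' Maximum size of a constant-weight binary code
#'
#' For weight 4 and minimum distance 4 on `n = 2 or 4 (mod 6)` bits the
#' exact packing number is `choose(n, 3) / 4` (the Steiner quadruple system
#' size, attained by [construct_codebook()]). Other parameter combinations
#' return the first Johnson bound, flagged as non-exact. Setting
#' `exhaustive = TRUE` (small `n` only) confirms the value by a
#' branch-and-bound search over weight-4 words.
#'
#' @param n_bits Code length.
#' @param weight,min_distance Code parameters; exact only for (4, 4).
#' @param exhaustive Run the branch-and-bound confirmation (n_bits <= 12).
#' @return Integer size with attribute `exact` (logical).
#' @export
max_code_size <- function(n_bits, weight = 4, min_distance = 4,
                          exhaustive = FALSE) {
  exact <- FALSE
  if (weight == 4 && min_distance == 4 && n_bits %% 6 %in% c(2, 4)) {
    size <- choose(n_bits, 3) / 4
    exact <- TRUE
  } else {
    # Johnson bound floor(n/w floor((n-1)/(w-1) ... )) down to distance level
    size <- floor(n_bits / weight *
                    floor((n_bits - 1) / (weight - 1) *
                            floor((n_bits - 2) / (weight - 2))))
  }
  if (exhaustive) {
    if (n_bits > 12) abort("exhaustive search supported only for n_bits <= 12")
    found <- max_packing_search(n_bits)
    if (exact && found != size)
      abort("exhaustive search disagrees with the closed-form packing number")
    size <- found
    exact <- TRUE
  }
  structure(as.integer(size), exact = exact)
}

# Branch-and-bound maximum packing of 4-subsets of [n] with every 3-subset
# used at most once (equivalently: max constant-weight-4 distance-4 code).
# Branches on the first undecided triple - either one of the still-feasible
# quadruples covering it is chosen, or the triple is marked never-covered.
# Bound: chosen + floor(#undecided triples / 4).
max_packing_search <- function(n) {
  triples <- utils::combn(n, 3)
  n_tri <- ncol(triples)
  tri_id <- function(t) which(colSums(triples == t) == 3)
  quads <- utils::combn(n, 4)
  quad_tris <- apply(quads, 2, function(q)
    vapply(seq_len(4), function(i) tri_id(sort(q[-i])), integer(1)))
  tris_to_quads <- vector("list", n_tri)
  for (qi in seq_len(ncol(quads)))
    for (t in quad_tris[, qi])
      tris_to_quads[[t]] <- c(tris_to_quads[[t]], qi)

  best <- 0L
  covered <- rep(FALSE, n_tri)
  excluded <- rep(FALSE, n_tri)
  recurse <- function(size) {
    undecided <- sum(!covered & !excluded)
    if (size + undecided %/% 4L <= best) return(invisible())
    t <- which(!covered & !excluded)[1]
    if (is.na(t)) { best <<- max(best, size); return(invisible()) }
    for (qi in tris_to_quads[[t]]) {
      ts <- quad_tris[, qi]
      if (any(covered[ts]) || any(excluded[ts])) next
      covered[ts] <<- TRUE
      if (size + 1L > best && sum(!covered & !excluded) == 0) best <<- size + 1L
      recurse(size + 1L)
      covered[ts] <<- FALSE
    }
    excluded[t] <<- TRUE
    recurse(size)
    excluded[t] <<- FALSE
    invisible()
  }
  recurse(0L)
  best
}

#' Assign gene names to codebook words
#'
#' Gives each gene a distinct barcode by seeded random draw from the
#' codebook; the remaining words become blank controls named `Blank-<k>`,
#' which carry no probes and measure the false-positive call rate.
#'
#' @param genes Character vector of gene names (`length(genes) <= nrow(cb)`).
#' @param cb A `codebook` (e.g. from [construct_codebook()]).
#' @param seed Integer seed for the assignment draw.
#' @return A `codebook` with `name` set to genes or `Blank-<k>` and
#'   `is_blank` flags.
#' @export
assign_barcodes <- function(genes, cb, seed) {
  if (anyDuplicated(genes)) abort("gene names must be unique")
  if (length(genes) > nrow(cb))
    abort(sprintf("codebook capacity exceeded: %d genes > %d words",
                  length(genes), nrow(cb)))
  with_seed(seed, {
    take <- sample(nrow(cb), length(genes))
    name <- sprintf("Blank-%d", seq_len(nrow(cb)))
    blank <- rep(TRUE, nrow(cb))
    name[take] <- genes
    blank[take] <- FALSE
    name[blank] <- sprintf("Blank-%d", seq_len(sum(blank)))
    codebook(name = name, barcode = cb$barcode, is_blank = blank)
  })
}
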