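# Internal numerical helpers shared across modules.

#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr unnest pivot_longer
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap keep
#' @importFrom stats p.adjust prcomp quantile rnbinom rpois runif rnorm
#'   setNames cor median sd var pt pnorm wilcox.test qnorm complete.cases
#' @importFrom utils head modifyList
NULL

# Squared Euclidean cross-distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Indices (into rows of `ref`) of the k nearest neighbours of each row of
# `query`. Ties broken by index. If `self` is TRUE and query is ref, each
# point may be its own neighbour; otherwise the diagonal is masked.
knn_index <- function(query, ref, k, self = TRUE) {
  d2 <- cross_dist2(query, ref)
  if (!self) {
    stopifnot(nrow(query) == nrow(ref))
    diag(d2) <- Inf
  }
  k <- min(k, ncol(d2) - (!self) * 0L)
  t(apply(d2, 1L, function(row) order(row)[seq_len(k)]))
}

# k smallest distances alongside indices; returns list(index, dist).
knn_index_dist <- function(query, ref, k, self = TRUE) {
  d2 <- cross_dist2(query, ref)
  if (!self) {
    stopifnot(nrow(query) == nrow(ref))
    diag(d2) <- Inf
  }
  k <- min(k, ncol(d2))
  idx <- t(apply(d2, 1L, function(row) order(row)[seq_len(k)]))
  dst <- matrix(0, nrow(idx), ncol(idx))
  for (i in seq_len(nrow(idx))) dst[i, ] <- sqrt(d2[i, idx[i, ]])
  list(index = idx, dist = dst)
}

# column z-scores as a clean matrix: constant columns become zero and the
# scale() attributes are stripped (they confuse downstream prcomp calls)
zscore_cols <- function(m) {
  z <- scale(m)
  z[!is.finite(z)] <- 0
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

# Benjamini-Hochberg wrapper kept in one place so the family definition is
# explicit at each call site.
bh_adjust <- function(p) p.adjust(p, method = "BH")

# One-sided Welch t-test (greater) from two numeric vectors, vector-safe on
# degenerate inputs: returns p = 1 when either group has < 2 values or both
# variances are zero with equal means.
welch_greater <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) return(1)
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  if (se2 <= 0) return(if (mx > my) 0 else 1)
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  pt(tstat, df = df, lower.tail = FALSE)
}

# Deterministic seeded RNG scope.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjusted Rand index between two label vectors (Hubert & Arabie).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}
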