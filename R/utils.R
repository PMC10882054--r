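# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Best-permutation label agreement
#'
#' Fraction of elements on which two cluster labelings agree, maximized over
#' all relabelings of `b`. Used to score recovery of planted partitions where
#' cluster identities are arbitrary. Exhaustive over permutations, so intended
#' for small numbers of clusters (<= 8).
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return Agreement fraction in \[0, 1\].
#' @export
label_agreement <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  ka <- max(a); kb <- max(b)
  if (kb > 8) stop("label_agreement: too many clusters for exhaustive matching")
  # confusion matrix; pad so permutations are well defined
  k <- max(ka, kb)
  conf <- matrix(0L, k, k)
  for (i in seq_along(a)) conf[a[i], b[i]] <- conf[a[i], b[i]] + 1L
  perms <- permutations_of(k)
  best <- 0L
  for (p in perms) {
    hits <- sum(conf[cbind(p, seq_len(k))])
    if (hits > best) best <- hits
  }
  best / length(a)
}

# All permutations of 1..n as a list (n <= 8).
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) for (pos in seq_len(n)) {
    out[[idx]] <- append(p, n, after = pos - 1L)
    idx <- idx + 1L
  }
  out
}

# Global Otsu threshold for a numeric array (flattened; EBImage's otsu treats
# a 3D array slice-wise, so we hand it a single column).
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(matrix(v, ncol = 1), range = rng)
}

# Stable greedy selection: given an n x n logical "conflict" matrix and a
# priority order, retain items in priority order, rejecting any item that
# conflicts with an already-retained one. Returns retained indices in the
# original order.
greedy_retain <- function(order_idx, conflicts_with) {
  retained <- integer(0)
  for (i in order_idx) {
    if (!any(conflicts_with(i, retained))) retained <- c(retained, i)
  }
  sort(retained)
}
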