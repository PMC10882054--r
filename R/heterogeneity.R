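# Wiring-heterogeneity statistics: pairwise cosine similarity of input
# profiles, per-input variation, rank order, and nonparametric group tests.

#' Pairwise cosine similarity of input profiles, by group
#'
#' Computes cos(u, v) = u.v / (|u||v|) for every unordered pair of target-cell
#' rows within each group (each unordered pair counted once, self-pairs
#' excluded), plus optionally a mixed group formed by all cross-group pairs.
#' Because every row is non-negative the values lie in \[0, 1\], and because
#' cosine is scale-invariant per row, absolute and relative matrices give
#' identical similarities. Rows with zero norm are excluded with a warning.
#'
#' @param matrix a `connectivity_matrix` (absolute or relative mode), or any
#'   non-negative numeric matrix.
#' @param grouping factor/character vector along rows; defaults to the
#'   matrix's hemisphere attribute. Use a constant to get a single group.
#' @param mixed_pairs if TRUE and there are exactly two groups, also emit the
#'   mixed set (all cross-group pairs) labelled by the concatenated group
#'   names (e.g. "RL").
#' @return data.frame of class `similarity_distribution`: `group`, `row_i`,
#'   `row_j`, `similarity`.
#' @export
cosine_similarity_groups <- function(matrix, grouping = NULL,
                                     mixed_pairs = TRUE) {
  m <- unclass(matrix)
  if (is.null(grouping)) {
    grouping <- attr(matrix, "hemisphere")
    if (is.null(grouping)) grouping <- rep("all", nrow(m))
  }
  stopifnot(length(grouping) == nrow(m))
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    warning("excluding ", sum(nrm == 0), " zero-norm row(s)")
    keep <- nrm > 0
    m <- m[keep, , drop = FALSE]
    grouping <- grouping[keep]
    nrm <- nrm[keep]
  }
  unit <- m / nrm
  sim <- tcrossprod(unit)
  sim <- pmin(pmax(sim, 0), 1)
  rn <- rownames(m)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(m)))
  grouping <- as.character(grouping)
  res <- list()
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) < 2) next
    pr <- which(upper.tri(diag(length(idx))), arr.ind = TRUE)
    res[[g]] <- data.frame(
      group = g, row_i = rn[idx[pr[, 1]]], row_j = rn[idx[pr[, 2]]],
      similarity = sim[cbind(idx[pr[, 1]], idx[pr[, 2]])],
      stringsAsFactors = FALSE)
  }
  gs <- unique(grouping)
  if (mixed_pairs && length(gs) == 2) {
    i1 <- which(grouping == gs[1]); i2 <- which(grouping == gs[2])
    gr <- expand.grid(a = i1, b = i2)
    lab <- paste0(toupper(substr(gs[1], 1, 1)), toupper(substr(gs[2], 1, 1)))
    res[[lab]] <- data.frame(
      group = lab, row_i = rn[gr$a], row_j = rn[gr$b],
      similarity = sim[cbind(gr$a, gr$b)], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("similarity_distribution", "data.frame")
  out
}

#' Per-input-type variation summary
#'
#' Mean, standard deviation and coefficient of variation (c.v. = std/mean) of
#' the synapse count of each input type across target cells. The population
#' (divide by n) standard deviation is the default; sample (n - 1) is
#' switchable. The c.v. is reported as NA when the mean is 0.
#'
#' @param matrix absolute-mode `connectivity_matrix` or numeric count matrix.
#' @param sample_sd use the n - 1 denominator (default FALSE).
#' @return data.frame: `type`, `mean`, `std`, `cv`; attribute `sd_type`.
#' @export
input_variation <- function(matrix, sample_sd = FALSE) {
  m <- unclass(matrix)
  if (is.null(colnames(m))) colnames(m) <- paste0("type_", seq_len(ncol(m)))
  mu <- colMeans(m)
  n <- nrow(m)
  ss <- colSums(sweep(m, 2, mu)^2)
  std <- sqrt(ss / if (sample_sd) max(1, n - 1) else n)
  cv <- ifelse(mu == 0, NA_real_, std / mu)
  structure(data.frame(type = colnames(m), mean = mu, std = std, cv = cv,
                       row.names = NULL, stringsAsFactors = FALSE),
            sd_type = if (sample_sd) "sample" else "population")
}

#' Rank inputs within each target cell
#'
#' For each row, ranks the present input types by synapse count (1 = largest).
#' Ties share the minimum rank ("1224" competition ranking); absent inputs
#' (count 0) are unranked (NA). Also reports each type's rank range across
#' rows, the readout used to show that input order varies from column to
#' column.
#'
#' @param matrix absolute-mode count matrix.
#' @param ties tie policy passed to [rank()] (default `"min"`).
#' @return list: `ranks` (row x type matrix with NA for absent), `range`
#'   (data.frame `type`, `min_rank`, `max_rank`, `modal_rank`, `n_present`).
#' @export
rank_order <- function(matrix, ties = "min") {
  m <- unclass(matrix)
  ranks <- t(apply(m, 1, function(r) {
    out <- rep(NA_real_, length(r))
    pos <- r > 0
    if (any(pos)) out[pos] <- rank(-r[pos], ties.method = ties)
    out
  }))
  dimnames(ranks) <- dimnames(m)
  rng <- data.frame(
    type = colnames(m),
    min_rank = suppressWarnings(apply(ranks, 2, min, na.rm = TRUE)),
    max_rank = suppressWarnings(apply(ranks, 2, max, na.rm = TRUE)),
    modal_rank = apply(ranks, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      tb <- table(x)
      as.numeric(names(tb)[which.max(tb)])
    }),
    n_present = colSums(!is.na(ranks)),
    row.names = NULL, stringsAsFactors = FALSE)
  rng$min_rank[!is.finite(rng$min_rank)] <- NA
  rng$max_rank[!is.finite(rng$max_rank)] <- NA
  list(ranks = ranks, range = rng)
}

#' Omnibus and pairwise comparison of similarity distributions
#'
#' Two-sided Kruskal-Wallis test across the groups, followed by Dunn's
#' pairwise z tests on the pooled mean ranks (with tie correction) and
#' Bonferroni adjustment over the number of pairwise comparisons.
#'
#' @param values numeric vector of similarity values, or a
#'   `similarity_distribution` data.frame (in which case `groups` is taken
#'   from its `group` column).
#' @param groups group label per value (ignored for a
#'   `similarity_distribution`).
#' @return list of class `group_comparison`: `kruskal` (`statistic`, `df`,
#'   `p_value`), `pairwise` (data.frame `group1`, `group2`, `z`, `p`,
#'   `p_adj`), `n` per group.
#' @export
compare_groups <- function(values, groups = NULL) {
  if (inherits(values, "similarity_distribution") ||
      (is.data.frame(values) && all(c("group", "similarity") %in%
                                    names(values)))) {
    groups <- values$group
    values <- values$similarity
  }
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  tab <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 values")

  kw <- stats::kruskal.test(values, groups)

  # Dunn's post-hoc z statistics from pooled mean ranks
  n <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / tab[[a]] + 1 / tab[[b]]))
    z[i] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
                   p_adj = pmin(1, p * ncol(pairs)),
                   stringsAsFactors = FALSE)
  structure(list(
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = kw$p.value),
    pairwise = pw,
    n = as.integer(tab)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Kruskal-Wallis: H =", format(x$kruskal$statistic, digits = 4),
      ", df =", x$kruskal$df,
      ", p =", format(x$kruskal$p_value, digits = 3), "\n")
  cat("Dunn pairwise (Bonferroni-adjusted):\n")
  print(x$pairwise, digits = 3)
  invisible(x)
}
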