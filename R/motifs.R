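# Motif discovery in input profiles: input-input correlations, count-based
# k-means and PCA, and Hamming-distance clustering of binarized presence.

#' Pearson correlations between input-type counts
#'
#' Pairwise Pearson correlation of input-type synapse counts across target
#' cells, with two-sided p values from t = r * sqrt(n - 2) / sqrt(1 - r^2)
#' and Bonferroni adjustment over the m(m - 1)/2 unique pairs. Pairs
#' involving a constant (zero-variance) type are reported as NA.
#'
#' @param matrix absolute-mode `connectivity_matrix` or count matrix with at
#'   least 3 rows.
#' @return list of class `correlation_result`: `r`, `p`, `p_adj` (type x type
#'   matrices), `n`.
#' @export
input_correlation <- function(matrix) {
  m <- unclass(matrix)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 rows")
  const <- apply(m, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(m))
  r[const, ] <- NA; r[, const] <- NA
  diag(r) <- ifelse(const, NA, 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA
  npairs <- ncol(m) * (ncol(m) - 1) / 2
  p_adj <- pmin(p * npairs, 1)
  structure(list(r = r, p = p, p_adj = p_adj, n = n, n_pairs = npairs),
            class = "correlation_result")
}

#' K-means clustering of target cells by input profile
#'
#' Euclidean k-means on the rows of the connectivity matrix (counts by
#' default), with 10 seed-derived restarts; the best-inertia solution is kept,
#' so the result is deterministic given `seed`. Used with k = 2 to expose the
#' two GABAergic-input-dominated subtypes (CT1- vs Mi4-dominated) and with
#' k = 6 for finer structure.
#'
#' @param matrix `connectivity_matrix` or numeric matrix (rows clustered).
#' @param k number of clusters (>= 2, <= number of rows).
#' @param seed integer seed.
#' @param nstart number of restarts (default 10).
#' @return list of class `kmeans_inputs`: `labels` (named), `centers`
#'   (per-cluster mean input profile), `inertia`, `k`, `seed`.
#' @export
kmeans_inputs <- function(matrix, k, seed = 1L, nstart = 10) {
  m <- unclass(matrix)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(m)) stop("k exceeds the number of rows")
  if (k == nrow(m)) {
    # trivial partition: every row its own cluster
    labels <- stats::setNames(seq_len(nrow(m)), rownames(m))
    return(structure(list(labels = labels, centers = m, inertia = 0,
                          k = k, seed = seed), class = "kmeans_inputs"))
  }
  fit <- with_seed(seed, stats::kmeans(m, centers = k, nstart = nstart,
                                       iter.max = 100))
  labels <- stats::setNames(fit$cluster, rownames(m))
  structure(list(labels = labels, centers = fit$centers,
                 inertia = fit$tot.withinss, k = k, seed = seed),
            class = "kmeans_inputs")
}

#' Principal component analysis of standardized input profiles
#'
#' Standardizes each input-type column to mean 0 / variance 1 (zero-variance
#' columns are dropped with a warning), takes the eigenvectors of the
#' covariance matrix, and projects the rows onto the top two components.
#' Sign convention: within each component, the largest-magnitude loading is
#' made positive.
#'
#' @param matrix `connectivity_matrix` (relative mode by convention) or
#'   numeric matrix with >= 2 rows and >= 2 non-constant types.
#' @param n_components components to retain (default 2).
#' @return list of class `pca_result`: `scores` (rows x components),
#'   `loadings` (types x components), `explained` (variance fractions for all
#'   components), `dropped_types`.
#' @export
pca_project <- function(matrix, n_components = 2) {
  m <- unclass(matrix)
  if (nrow(m) < 2) stop("need at least 2 rows")
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance type(s): ",
            paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 non-constant types")
  z <- scale(m)
  cv <- stats::cov(z)
  eg <- eigen(cv, symmetric = TRUE)
  explained <- pmax(eg$values, 0) / sum(pmax(eg$values, 0))
  k <- min(n_components, ncol(m))
  load <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(m)
  colnames(load) <- paste0("PC", seq_len(k))
  scores <- z %*% load
  structure(list(scores = scores, loadings = load, explained = explained,
                 dropped_types = dropped),
            class = "pca_result")
}

#' Binarize presence and drop core inputs
#'
#' Converts counts to a presence/absence indicator and removes the given core
#' input types (by default L3, Mi4 and CT1, which are present everywhere and
#' therefore uninformative for presence motifs).
#'
#' @param matrix count or relative `connectivity_matrix` / numeric matrix.
#' @param exclude_types columns to remove after binarization; types absent
#'   from the matrix trigger a warning, not an error.
#' @return binary matrix (0/1).
#' @export
binarize_presence <- function(matrix, exclude_types = c("L3", "Mi4", "CT1")) {
  m <- unclass(matrix)
  b <- (m > 0) + 0
  missing <- setdiff(exclude_types, colnames(b))
  if (length(missing))
    warning("exclude_types not in matrix: ", paste(missing, collapse = ", "))
  b[, setdiff(colnames(b), exclude_types), drop = FALSE]
}

# Pairwise Hamming distances (counts of differing bits) between rows.
hamming_distances <- function(binary, normalized = FALSE) {
  b <- as.matrix(binary)
  # for 0/1 data: differing bits = x(1-y) + y(1-x)
  d <- tcrossprod(b, 1 - b)
  d <- d + t(d)
  if (normalized) d <- d / ncol(b)
  stats::as.dist(d)
}

#' Cluster binary presence profiles by Hamming distance
#'
#' Computes pairwise Hamming distances (number of differing bits) between
#' binarized input profiles, builds an agglomerative (average-linkage by
#' default) tree, cuts it at every candidate cluster number, scores each cut
#' by the mean silhouette coefficient computed on the same Hamming distances,
#' and picks the cluster number maximizing it (ties to the smallest k).
#'
#' @param binary 0/1 matrix (rows = target cells).
#' @param k_range candidate cluster numbers (default 4:15).
#' @param linkage `hclust` method for the precomputed distances (default
#'   `"complete"`, which keeps motif clusters compact in the bounded Hamming
#'   metric and reliably recovers planted partitions; `"average"` and the
#'   Ward variants are also accepted).
#' @param normalized divide distances by the number of bits (default FALSE).
#' @return list of class `motif_result`: `dist`, `tree`, `labels` (rows x
#'   candidate k matrix), `silhouette` (data.frame `k`, `mean_silhouette`),
#'   `chosen_k`, `labels_chosen`.
#' @export
hamming_cluster <- function(binary, k_range = 4:15, linkage = "complete",
                            normalized = FALSE) {
  b <- as.matrix(binary)
  k_range <- sort(unique(as.integer(k_range)))
  if (nrow(b) < max(k_range) + 1)
    stop("need more rows than the largest candidate k")
  if (nrow(unique(b)) == 1)
    stop("all profiles identical: silhouette undefined; ",
         "supply more variable inputs or skip motif clustering")
  d <- hamming_distances(b, normalized = normalized)
  tree <- stats::hclust(d, method = linkage)
  labels <- matrix(NA_integer_, nrow(b), length(k_range),
                   dimnames = list(rownames(b), paste0("k", k_range)))
  sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    lab <- stats::cutree(tree, k = k_range[i])
    labels[, i] <- lab
    sil[i] <- mean(cluster::silhouette(lab, d)[, "sil_width"])
  }
  chosen <- k_range[which.max(sil)]  # which.max takes the first (smallest k)
  structure(list(
    dist = d, tree = tree, labels = labels,
    silhouette = data.frame(k = k_range, mean_silhouette = sil),
    chosen_k = chosen,
    labels_chosen = labels[, paste0("k", chosen)]),
    class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat("Presence-motif clustering (Hamming + agglomerative)\n")
  cat("  rows:", length(x$labels_chosen),
      "| candidate k:", paste(range(x$silhouette$k), collapse = "-"),
      "| chosen k:", x$chosen_k, "\n")
  cat("  mean silhouette at chosen k:",
      format(x$silhouette$mean_silhouette[x$silhouette$k == x$chosen_k],
             digits = 3), "\n")
  invisible(x)
}

#' @export
plot.motif_result <- function(x, ...) {
  graphics::plot(x$silhouette$k, x$silhouette$mean_silhouette, type = "b",
                 xlab = "number of clusters",
                 ylab = "mean silhouette coefficient", ...)
  graphics::abline(v = x$chosen_k, lty = 2)
  invisible(x)
}

#' Summarize presence motifs per cluster
#'
#' For each cluster of binarized profiles: number of rows and per-type
#' presence fraction, flagging types whose fraction is at least
#' `dominate_high` ("present in essentially all rows") or at most
#' `dominate_low` ("absent from essentially all rows") as dominating that
#' motif.
#'
#' @param binary 0/1 matrix.
#' @param labels cluster label per row.
#' @param dominate_high,dominate_low dominance cutoffs (defaults 0.9 / 0.1).
#' @return list: `fractions` (cluster x type), `n` (rows per cluster),
#'   `dominating` (data.frame `cluster`, `type`, `fraction`, `direction`).
#' @export
summarize_motifs <- function(binary, labels, dominate_high = 0.9,
                             dominate_low = 0.1) {
  b <- as.matrix(binary)
  stopifnot(length(labels) == nrow(b))
  labs <- sort(unique(labels))
  frac <- t(vapply(labs, function(l) colMeans(b[labels == l, , drop = FALSE]),
                   numeric(ncol(b))))
  rownames(frac) <- as.character(labs)
  n <- vapply(labs, function(l) sum(labels == l), integer(1))
  dom <- which(frac >= dominate_high | frac <= dominate_low, arr.ind = TRUE)
  dominating <- data.frame(
    cluster = labs[dom[, 1]],
    type = colnames(b)[dom[, 2]],
    fraction = frac[dom],
    direction = ifelse(frac[dom] >= dominate_high, "present", "absent"),
    stringsAsFactors = FALSE)
  dominating <- dominating[order(dominating$cluster, dominating$type), ]
  rownames(dominating) <- NULL
  list(fractions = frac, n = stats::setNames(n, as.character(labs)),
       dominating = dominating)
}
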