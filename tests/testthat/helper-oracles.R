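# Independent brute-force oracles used to validate the package's greedy and
# clustering routines on small fixtures. Deliberately naive implementations.

# Greedy redundancy removal per (pre, post) pair: exhaustive all-pairs
# version, retaining rows in descending cleft score (stable for ties) and
# rejecting any row strictly closer than radius to an already-retained row of
# the same pair.
oracle_dedup <- function(table, radius_nm = 100) {
  keep <- logical(nrow(table))
  ord <- order(-table$cleft_score, seq_len(nrow(table)))
  retained <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in retained) {
      if (table$pre_segment_id[i] == table$pre_segment_id[j] &&
          table$post_cell_id[i] == table$post_cell_id[j]) {
        d <- sqrt((table$x_nm[i] - table$x_nm[j])^2 +
                    (table$y_nm[i] - table$y_nm[j])^2 +
                    (table$z_nm[i] - table$z_nm[j])^2)
        if (d < radius_nm) { ok <- FALSE; break }
      }
    }
    if (ok) retained <- c(retained, i)
  }
  keep[retained] <- TRUE
  table[keep, , drop = FALSE]
}

# Greedy minimum-separation selection of point detections by descending
# intensity (anisotropic positions already in nm).
oracle_separate_points <- function(pos_nm, intensity, min_sep) {
  ord <- order(-intensity, seq_along(intensity))
  retained <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in retained) {
      if (sqrt(sum((pos_nm[i, ] - pos_nm[j, ])^2)) < min_sep) {
        ok <- FALSE; break
      }
    }
    if (ok) retained <- c(retained, i)
  }
  sort(retained)
}

# Naive agglomerative clustering on a precomputed distance matrix.
# Returns the partition (cluster membership lists) at each requested k.
# `method` is "average" or "complete". Returns NULL when any merge step has a
# tied minimum (order would be arbitrary).
oracle_agglomerative <- function(d, ks, method = "complete") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  cluster_dist <- function(a, b) {
    dd <- d[a, b, drop = FALSE]
    if (method == "complete") max(dd) else mean(dd)
  }
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- Inf; pair <- NULL; nbest <- 0L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- cluster_dist(clusters[[i]], clusters[[j]])
      if (dij < best - 1e-12) { best <- dij; pair <- c(i, j); nbest <- 1L }
      else if (abs(dij - best) <= 1e-12) nbest <- nbest + 1L
    }
    if (nbest > 1L) return(NULL)  # tie: merge order arbitrary
    clusters[[pair[1]]] <- c(clusters[[pair[1]]], clusters[[pair[2]]])
    clusters[[pair[2]]] <- NULL
    if ((length(clusters)) %in% ks) {
      lab <- integer(n)
      for (c in seq_along(clusters)) lab[clusters[[c]]] <- c
      partitions[[as.character(length(clusters))]] <- lab
    }
  }
  partitions
}

# TRUE when two label vectors describe the same partition.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Exhaustive punctum-to-mask minimum distance (double loop).
oracle_mask_distance <- function(p_nm, mask, voxel_size_nm) {
  idx <- which(mask, arr.ind = TRUE)
  best <- Inf
  for (r in seq_len(nrow(idx))) {
    v <- (idx[r, ] - 0.5) * voxel_size_nm
    best <- min(best, sqrt(sum((v - p_nm)^2)))
  }
  best
}

# Minimal valid synapse table builder.
make_synapses <- function(pre, post, x, y, z, score,
                          compartment = "dendritic") {
  data.frame(pre_segment_id = pre, post_cell_id = post,
             x_nm = x, y_nm = y, z_nm = z, cleft_score = score,
             compartment = compartment, stringsAsFactors = FALSE)
}

# Kruskal-Wallis H from first principles (tie-corrected), for tiny samples.
oracle_kruskal_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
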