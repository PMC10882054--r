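# Calcium-trace normalization and response-time-course clustering.

#' Construct a fluorescence trace set
#'
#' @param F matrix ROI x time of raw fluorescence (arbitrary units).
#' @param sampling_rate_hz acquisition rate in Hz.
#' @param epochs data.frame with `label`, `start`, `end` (seconds from record
#'   start); must include the background/baseline stimulus epochs.
#' @param trials optional data.frame with `start`, `end` (seconds) marking
#'   repeats of the same stimulus sequence; used for trial averaging.
#' @return list of class `trace_set`.
#' @export
trace_set <- function(F, sampling_rate_hz, epochs, trials = NULL) {
  F <- as.matrix(F)
  stopifnot(all(is.finite(F)), sampling_rate_hz > 0)
  dur <- ncol(F) / sampling_rate_hz
  stopifnot(all(epochs$start >= 0), all(epochs$end <= dur + 1e-9),
            all(epochs$end > epochs$start))
  if (!is.null(trials))
    stopifnot(all(trials$start >= 0), all(trials$end <= dur + 1e-9))
  structure(list(F = F, sampling_rate_hz = sampling_rate_hz,
                 epochs = as.data.frame(epochs),
                 trials = if (is.null(trials)) NULL else as.data.frame(trials)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("Trace set:", nrow(x$F), "ROIs x", ncol(x$F), "frames @",
      x$sampling_rate_hz, "Hz\n")
  cat("  epochs:", paste(unique(x$epochs$label), collapse = ", "), "\n")
  if (!is.null(x$trials)) cat("  trials:", nrow(x$trials), "\n")
  invisible(x)
}

# frames whose center falls inside [start, end)
frames_in <- function(start, end, rate, n) {
  centers <- (seq_len(n) - 0.5) / rate
  which(centers >= start & centers < end)
}

#' Mean-augmented dF/F normalization
#'
#' Per ROI: (1) optional high-pass filtering by subtracting a running-median
#' baseline with the given window ("cutoff period" of 150 frames by
#' convention); (2) baseline F0 = mean fluorescence during all background-
#' epoch presentations; (3) dF/F = (F - F0) / (F0 + Fmean), where Fmean is
#' the full-trace mean fluorescence - the augmented denominator damps
#' blow-ups when F0 is near 0; (4) optional trial averaging over the repeats
#' in `traces$trials`; (5) linear-interpolation resampling to
#' `target_rate_hz`, so recordings acquired at different frame rates can be
#' averaged together.
#'
#' @param traces a [trace_set()].
#' @param highpass_period_frames running-median window in frames (rounded to
#'   the nearest odd value); `NULL` or 0 disables high-pass filtering.
#'   Default 150.
#' @param target_rate_hz output sampling rate (default 10); `NULL` keeps the
#'   input rate.
#' @param background_label epoch label of the baseline stimulus (default
#'   `"background"`).
#' @param trial_average average over `traces$trials` when present (default
#'   TRUE).
#' @return A `trace_set` of normalized traces (dF/F units); epochs/trials are
#'   rebased to the first trial when trial averaging is applied.
#' @export
delta_f_over_f <- function(traces, highpass_period_frames = 150,
                           target_rate_hz = 10,
                           background_label = "background",
                           trial_average = TRUE) {
  stopifnot(inherits(traces, "trace_set"))
  F <- traces$F
  rate <- traces$sampling_rate_hz
  bg <- traces$epochs[traces$epochs$label == background_label, , drop = FALSE]
  if (!nrow(bg)) stop("no background epoch labelled '", background_label, "'")
  bg_idx <- unique(unlist(lapply(seq_len(nrow(bg)), function(i)
    frames_in(bg$start[i], bg$end[i], rate, ncol(F)))))
  if (!length(bg_idx)) stop("background epochs contain no frames")

  if (!is.null(highpass_period_frames) && highpass_period_frames > 0) {
    k <- as.integer(highpass_period_frames)
    if (k %% 2 == 0) k <- k + 1L
    k <- min(k, if (ncol(F) %% 2 == 0) ncol(F) - 1L else ncol(F))
    F <- t(apply(F, 1, function(x) x - stats::runmed(x, k) + mean(x)))
    # the trace mean is restored so F0 and Fmean keep their raw-scale meaning
  }

  f0 <- rowMeans(F[, bg_idx, drop = FALSE])
  fmean <- rowMeans(F)
  denom <- f0 + fmean
  if (any(denom == 0))
    stop("F0 + Fmean is zero for ROI(s): ",
         paste(utils::head(which(denom == 0)), collapse = ", "))
  dff <- sweep(sweep(F, 1, f0), 1, denom, "/")

  epochs <- traces$epochs
  trials <- traces$trials
  if (trial_average && !is.null(trials) && nrow(trials) > 1) {
    len <- min(round((trials$end - trials$start) * rate))
    acc <- 0
    for (i in seq_len(nrow(trials))) {
      s <- round(trials$start[i] * rate)
      acc <- acc + dff[, (s + 1):(s + len), drop = FALSE]
    }
    dff <- acc / nrow(trials)
    t0 <- trials$start[1]
    in_trial <- epochs$start >= t0 - 1e-9 &
      epochs$end <= trials$end[1] + 1e-9
    epochs <- epochs[in_trial, , drop = FALSE]
    epochs$start <- epochs$start - t0
    epochs$end <- epochs$end - t0
    trials <- NULL
  }

  if (!is.null(target_rate_hz) && target_rate_hz != rate) {
    t_in <- (seq_len(ncol(dff)) - 1) / rate
    t_out <- seq(0, max(t_in), by = 1 / target_rate_hz)
    dff <- t(apply(dff, 1, function(x)
      stats::approx(t_in, x, xout = t_out)$y))
    rate <- target_rate_hz
  }
  out <- list(F = dff, sampling_rate_hz = rate, epochs = epochs,
              trials = trials)
  class(out) <- "trace_set"
  out
}

#' Z-score traces
#'
#' Normalizes each trace to mean 0 and standard deviation 1, removing
#' response-amplitude differences so that clustering sees only the time
#' course. Errors on zero-variance traces, naming the ROI.
#'
#' @param traces a `trace_set` or numeric ROI x time matrix.
#' @return matrix of z-scored traces.
#' @export
zscore_traces <- function(traces) {
  m <- if (inherits(traces, "trace_set")) traces$F else as.matrix(traces)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance trace(s): ",
         paste(utils::head(which(sds == 0)), collapse = ", "))
  z <- (m - rowMeans(m)) / sds
  # sd() uses n-1; rescale so the population sd is exactly 1, matching the
  # "mean 0, std 1" normalization convention
  z * sqrt(ncol(m) / (ncol(m) - 1))
}

#' Cluster response time courses with correlation-distance k-means
#'
#' K-means under the correlation distance d(u, v) = 1 - corr(u, v). On
#' z-scored traces the correlation distance is proportional to the squared
#' Euclidean distance (|u - v|^2 = 2 T (1 - corr) for population-z-scored
#' length-T traces), so standard Euclidean k-means on the z-scored traces
#' optimizes the correlation-distance objective. Deterministic given `seed`
#' (50 restarts, best inertia kept; correlation-distance objectives on many
#' short traces have shallow local optima, so restarts are cheap insurance).
#' The conventional cluster number for
#' response-time-course diversity is 6.
#'
#' @param traces `trace_set` or matrix; rows are z-scored internally if not
#'   already.
#' @param k number of clusters (default 6).
#' @param seed integer seed.
#' @param nstart restarts (default 50).
#' @return list of class `trace_clusters`: `labels`, `cluster_means` (k x
#'   time, means of the z-scored members), `k`, `inertia`.
#' @export
cluster_traces <- function(traces, k = 6, seed = 1L, nstart = 50) {
  z <- zscore_traces(traces)
  if (k < 2) stop("k must be >= 2")
  if (nrow(z) < k) stop("fewer traces than clusters")
  fit <- with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                       iter.max = 100))
  structure(list(labels = stats::setNames(fit$cluster, rownames(z)),
                 cluster_means = fit$centers, k = k,
                 inertia = fit$tot.withinss),
            class = "trace_clusters")
}

#' @export
plot.trace_clusters <- function(x, ...) {
  graphics::matplot(t(x$cluster_means), type = "l", lty = 1,
                    xlab = "frame", ylab = "z-scored dF/F", ...)
  graphics::legend("topright", legend = paste("cluster", seq_len(x$k)),
                   col = seq_len(x$k), lty = 1, cex = 0.7)
  invisible(x)
}
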