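# Synthetic fluorescence trace sets: templated response time courses with
# per-ROI amplitude scaling and additive noise, plus known cluster labels.

#' Default response time-course templates
#'
#' Six qualitatively distinct dF/F response shapes to a 2 s OFF / 2 s ON
#' full-field flash embedded in a 4 s gray background (the standard contrast
#' stimulus): sustained-OFF, transient-OFF, slow integrating OFF, ON
#' responding, biphasic OFF-ON, and slow inhibited. Sampled at `rate` Hz over
#' one `4 + 2 + 2 + 4` s trial.
#'
#' @param rate sampling rate in Hz (default 20).
#' @return matrix template x time.
#' @export
response_templates <- function(rate = 20) {
  t <- seq(0, 12 - 1 / rate, by = 1 / rate)
  off <- t >= 4 & t < 6
  on <- t >= 6 & t < 8
  ramp <- function(tt, from, tau) pmax(0, 1 - exp(-(tt - from) / tau))
  tmpl <- rbind(
    sustained_off = ifelse(off, ramp(t, 4, 0.2), 0) +
      ifelse(t >= 6, 0.6 * exp(-(t - 6) / 0.8), 0),
    transient_off = ifelse(off, exp(-(t - 4) / 0.3), 0),
    slow_off = ifelse(t >= 4, ramp(t, 4, 1.5) * exp(-pmax(0, t - 8) / 2), 0),
    on_resp = ifelse(on, ramp(t, 6, 0.3), 0) +
      ifelse(t >= 8, 0.8 * exp(-(t - 8) / 1), 0),
    biphasic = ifelse(off, ramp(t, 4, 0.2), 0) -
      ifelse(on, ramp(t, 6, 0.3), 0) * 0.8,
    inhibited = -ifelse(t >= 4, ramp(t, 4, 1) * exp(-pmax(0, t - 8) / 3), 0)
  )
  tmpl
}

#' Simulate a trace set with known cluster structure
#'
#' Each ROI's raw fluorescence is `baseline + amplitude * template(cluster) +
#' noise`, repeated over `n_trials` identical trials; the planted cluster
#' label of every ROI is returned. The default templates emulate the response
#' diversity of a heterogeneously wired columnar neuron to full-field
#' contrast steps.
#'
#' @param n_rois_per_cluster ROIs per template (scalar or per-template
#'   vector).
#' @param templates template x time matrix sharing one time base; default
#'   [response_templates()].
#' @param amplitude_mean,amplitude_sd per-ROI response amplitude distribution
#'   (truncated at 0.2 to keep responses positive-gain).
#' @param baseline raw fluorescence baseline added to every trace.
#' @param noise_sd additive Gaussian noise sd, in template units.
#' @param sampling_rate_hz sampling rate matching the templates (default 20).
#' @param n_trials identical stimulus repeats (default 3).
#' @param background_s length of the gray background at the start of each
#'   trial, used to mark background epochs (default 4 s, matching the default
#'   templates).
#' @param seed integer seed.
#' @return list of class `synthetic_traces`: `traces` (a [trace_set()] with
#'   background epochs and trial structure), `labels` (planted cluster per
#'   ROI), `templates`.
#' @export
simulate_trace_set <- function(n_rois_per_cluster = 20,
                               templates = response_templates(),
                               amplitude_mean = 1, amplitude_sd = 0.2,
                               baseline = 50,
                               noise_sd = 0.1,
                               sampling_rate_hz = 20,
                               n_trials = 3,
                               background_s = 4,
                               seed = 1L) {
  templates <- as.matrix(templates)
  if (!nrow(templates)) stop("need at least one template")
  k <- nrow(templates)
  nper <- rep(n_rois_per_cluster, length.out = k)
  labels <- rep(seq_len(k), times = nper)
  n <- length(labels)
  trial_len <- ncol(templates)
  trial_s <- trial_len / sampling_rate_hz

  with_seed(seed, {
    amp <- rnorm_floor(n, amplitude_mean, amplitude_sd, 0.2)
    one_trial <- templates[labels, , drop = FALSE] * amp
    F <- one_trial[, rep(seq_len(trial_len), n_trials), drop = FALSE]
    if (noise_sd > 0)
      F <- F + matrix(stats::rnorm(length(F), sd = noise_sd), nrow = n)
    F <- F + baseline
    rownames(F) <- sprintf("roi_%03d", seq_len(n))

    trials <- data.frame(start = (seq_len(n_trials) - 1) * trial_s,
                         end = seq_len(n_trials) * trial_s)
    epochs <- data.frame(
      label = "background",
      start = trials$start,
      end = trials$start + background_s)
    ts <- trace_set(F, sampling_rate_hz, epochs, trials)
    structure(list(traces = ts, labels = labels, templates = templates),
              class = "synthetic_traces")
  })
}
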