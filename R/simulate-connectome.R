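# Synthetic connectome generator: hex-lattice columns in two mirrored
# hemispheres, core + variable presynaptic input types, near-duplicate
# detections, sub-threshold partners and low-confidence decoy rows, with full
# ground-truth bookkeeping so downstream filters can be checked exactly.

#' Configure a synthetic columnar connectome
#'
#' Builds the parameter set consumed by [simulate_connectome()]. The defaults
#' (`preset = "tm9"`) emulate the presynaptic wiring of a Tm9-like target:
#' three core inputs present in every column with per-column synapse counts of
#' about 25 (L3), 13.3 (Mi4) and 15 (CT1), plus many variable input types with
#' Bernoulli presence and low counts, two mirrored hemispheres of 170 and 150
#' columns, near-duplicate synapse detections and sub-threshold partners.
#' `preset = "tm1"` emulates a Tm1-like target: a single dominant ~100-synapse
#' input (L2) and mostly high-presence secondary inputs, i.e. far more
#' stereotyped wiring.
#'
#' @param preset `"tm9"` or `"tm1"`; starting point for all defaults.
#' @param n_columns_per_hemisphere integer vector of length 1 or 2
#'   (right, left). A single value is used for both hemispheres.
#' @param core_types data.frame with columns `name`, `count_mean`, `count_sd`,
#'   `compartment` (`"dendritic"` or `"axonal"`); presence probability is 1.
#' @param variable_types data.frame with columns `name`, `presence_prob`,
#'   `count_mean`, `count_sd`, `max_cells`, `compartment`.
#' @param duplicate_rate fraction of synapses re-emitted as a near-duplicate
#'   detection (< 100 nm positional jitter, lower cleft score).
#' @param subthreshold_rate expected number of sub-threshold partner cells per
#'   column (Poisson); each makes 1 to `min_count - 1` synapses. The default
#'   (18) makes traced above-threshold cells account for roughly three
#'   quarters of a column's synapses, the completeness regime typical of
#'   backbone-proofread reconstructions.
#' @param low_cleft_rate fraction of synapses re-emitted as low-confidence
#'   decoy rows with cleft score < 50.
#' @param unknown_rate fraction of planted input cells left unannotated
#'   (type label `UNKNOWN` in the annotation table).
#' @param cleft_mean,cleft_sd,cleft_floor cleft-score distribution for genuine
#'   synapses: normal(`cleft_mean`, `cleft_sd`) resampled to stay at or above
#'   `cleft_floor`.
#' @param column_spacing_nm hex-lattice pitch between neighbouring columns.
#' @param min_count truncation floor of the discretized-normal per-cell synapse
#'   count; matches the partner threshold used downstream (3 for Tm9-style
#'   analyses, 4 for Tm1/Tm2), so every planted cell survives that threshold.
#' @param multi_cell_prob probability parameter governing how many cells of a
#'   multi-cell (wide-field) type connect in one column: 1 + Binomial(max_cells
#'   - 1, multi_cell_prob) given presence.
#' @param axon_offset_nm z-offset of the axon-terminal layer where axonal-
#'   compartment inputs (CT1-like) synapse.
#' @param seed integer seed; the generator is deterministic given the config.
#' @return A list of class `connectome_config`.
#' @export
connectome_config <- function(preset = c("tm9", "tm1"),
                              n_columns_per_hemisphere = NULL,
                              core_types = NULL,
                              variable_types = NULL,
                              duplicate_rate = 0.05,
                              subthreshold_rate = 18,
                              low_cleft_rate = 0.05,
                              unknown_rate = 0.033,
                              cleft_mean = 100, cleft_sd = 25, cleft_floor = 50,
                              column_spacing_nm = 5000,
                              min_count = NULL,
                              multi_cell_prob = 0.25,
                              axon_offset_nm = 8000,
                              seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(n_columns_per_hemisphere))
    n_columns_per_hemisphere <- c(right = 170L, left = 150L)
  n <- as.integer(n_columns_per_hemisphere)
  if (length(n) == 1) n <- c(n, n)
  if (length(n) != 2 || any(is.na(n)) || any(n < 1))
    stop("n_columns_per_hemisphere must be 1 or 2 positive integers")
  names(n) <- c("right", "left")

  if (is.null(core_types)) {
    core_types <- if (preset == "tm9") data.frame(
      name = c("L3", "Mi4", "CT1"),
      count_mean = c(25, 13.3, 15.0),
      count_sd = c(7.3, 7.0, 5.7),
      compartment = c("dendritic", "dendritic", "axonal"),
      stringsAsFactors = FALSE
    ) else data.frame(
      name = "L2", count_mean = 110, count_sd = 18,
      compartment = "dendritic", stringsAsFactors = FALSE
    )
  }
  if (is.null(variable_types)) {
    variable_types <- if (preset == "tm9") data.frame(
      name = c("Tm16", "Dm12", "C3", "Tm20", "C2", "OA-AL2b2", "Tm1", "Tm2",
               "Tm4", "TmY15", "Mi13", "Dm2", "Y3", "Tm5Y", "TmY5a", "T2a",
               "T4c"),
      presence_prob = c(0.60, 0.45, 0.45, 0.30, 0.35, 0.35, 0.35, 0.25,
                        0.25, 0.25, 0.25, 0.20, 0.20, 0.10, 0.10, 0.10,
                        0.10),
      count_mean = c(4, 3.5, 4, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5,
                     3.5, 3.5, 3.5, 3.5, 3.5, 3.5),
      count_sd = c(2, 1.5, 2, 1.5, 1.5, 1, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5,
                   1.5, 1.5, 1.5, 1.5, 1.5),
      max_cells = c(4L, 4L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L,
                    1L, 1L, 1L),
      compartment = "dendritic",
      stringsAsFactors = FALSE
    ) else data.frame(
      name = c("C2", "C3", "L5", "Mi1", "Tm9", "Tm4", "Mi13", "T2", "Tm20",
               "Mi9", "Tm2", "Dm2", "TmY5a", "Y3", "T4c", "Tm16"),
      presence_prob = c(0.95, 0.95, 0.92, 0.90, 0.90, 0.88, 0.85, 0.85, 0.85,
                        0.82, 0.82, 0.30, 0.25, 0.20, 0.15, 0.15),
      count_mean = c(9, 9, 8, 8, 8, 7, 7, 7, 6, 6, 6, 4, 4, 4, 4, 4),
      count_sd = c(3, 3, 3, 3, 3, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5, 2, 2, 2, 2, 2),
      max_cells = 1L,
      compartment = "dendritic",
      stringsAsFactors = FALSE
    )
  }
  if (is.null(min_count)) min_count <- if (preset == "tm9") 3L else 4L

  p <- variable_types$presence_prob
  if (any(p <= 0 | p > 1)) stop("presence_prob must lie in (0, 1]")
  for (prob in c(duplicate_rate, subthreshold_rate, low_cleft_rate,
                 unknown_rate))
    if (prob < 0) stop("rates must be non-negative")
  if (any(c(core_types$count_mean, variable_types$count_mean) <= 0))
    stop("count means must be positive")
  if (column_spacing_nm <= 0) stop("column_spacing_nm must be positive")
  if (any(variable_types$max_cells < 1)) stop("max_cells must be >= 1")

  structure(list(
    preset = preset,
    n_columns_per_hemisphere = n,
    core_types = core_types,
    variable_types = variable_types,
    duplicate_rate = duplicate_rate,
    subthreshold_rate = subthreshold_rate,
    low_cleft_rate = low_cleft_rate,
    unknown_rate = unknown_rate,
    cleft_mean = cleft_mean, cleft_sd = cleft_sd, cleft_floor = cleft_floor,
    column_spacing_nm = column_spacing_nm,
    min_count = as.integer(min_count),
    multi_cell_prob = multi_cell_prob,
    axon_offset_nm = axon_offset_nm,
    seed = as.integer(seed)
  ), class = "connectome_config")
}

# Discretized normal, resampled until >= lo.
rcount_trunc <- function(n, mean, sd, lo) {
  x <- round(stats::rnorm(n, mean, sd))
  bad <- which(x < lo)
  while (length(bad)) {
    x[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] < lo]
  }
  as.integer(x)
}

# Normal resampled until >= lo.
rnorm_floor <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo]
  }
  x
}

# Roughly rectangular hex lattice of n points, wider than tall (the medulla
# sheet is elongated, which also pins down the first principal axis of the
# dorsoventral projection). Even row count keeps the centroid off any row.
hex_lattice <- function(n, pitch, aspect = 1.6) {
  # rows spaced at sqrt(3)/2 * pitch; pick an even row count so the centroid
  # falls between rows, with x span >= aspect * y span
  nr <- max(2L, 2L * floor(sqrt(n / (aspect * sqrt(3) / 2)) / 2))
  nc <- ceiling(n / nr)
  dy <- pitch * sqrt(3) / 2
  pts <- matrix(NA_real_, n, 2)
  idx <- 1L
  for (j in seq_len(nr)) {
    for (i in seq_len(nc)) {
      if (idx > n) break
      pts[idx, 1] <- (i - (nc + 1) / 2) * pitch + (j %% 2) * pitch / 2
      pts[idx, 2] <- (j - (nr + 1) / 2) * dy
      idx <- idx + 1L
    }
  }
  pts
}

# Sample m synapse positions around a column center with isotropic Gaussian
# jitter, resampled so that no two positions are closer than min_sep (keeps
# genuine same-connection synapses outside the deduplication radius).
sample_positions <- function(m, center, jitter_sd, min_sep = 100) {
  pos <- matrix(stats::rnorm(m * 3, sd = jitter_sd), m, 3)
  pos <- sweep(pos, 2, center, "+")
  if (m > 1) {
    for (iter in 1:200) {
      d <- as.matrix(stats::dist(pos))
      d[upper.tri(d, diag = TRUE)] <- Inf
      # resample the later point of every offending pair
      resample <- unique(which(d < min_sep, arr.ind = TRUE)[, 1])
      if (!length(resample)) break
      pos[resample, ] <- sweep(
        matrix(stats::rnorm(length(resample) * 3, sd = jitter_sd),
               length(resample), 3), 2, center, "+")
    }
  }
  pos
}

#' Simulate a synthetic columnar connectome with ground truth
#'
#' Generates a synapse table (one row per detected synapse), a cell-annotation
#' table and a ground-truth record. Columns are laid out on a hex lattice in
#' two mirrored hemispheres; each (column, input type) pair is drawn
#' Bernoulli(presence probability); per-cell synapse counts follow a
#' discretized normal truncated at the configured minimum; synapse positions
#' are jittered isotropically around the column center (axonal-compartment
#' inputs at the axon-terminal layer). Near-duplicate detections (< 100 nm from
#' their source, lower cleft score), sub-threshold partner cells, and
#' low-confidence rows (cleft score < 50) are injected at the configured rates
#' and recorded, so the filtering pipeline's bookkeeping can be verified
#' exactly. Deterministic given the config seed.
#'
#' @param config a [connectome_config()].
#' @param seed optional override of `config$seed`.
#' @return A list of class `synthetic_connectome` with elements
#'   \describe{
#'     \item{synapses}{data.frame: `pre_segment_id`, `post_cell_id`, `x_nm`,
#'       `y_nm`, `z_nm`, `cleft_score`, `compartment`.}
#'     \item{annotations}{data.frame: `segment_id`, `type_label`,
#'       `hemisphere`.}
#'     \item{truth}{ground truth: `presence`, `planted_counts`,
#'       `cell_multiplicity` (column x type matrices over annotated cells),
#'       `columns` (per-column table with lattice position, hemisphere and
#'       dorsoventral label), per-column bookkeeping counts
#'       (`unknown_synapses`, `subthreshold_synapses`, `planted_synapses`),
#'       and the numbers of injected duplicates and low-cleft rows.}
#'   }
#' @export
simulate_connectome <- function(config = connectome_config(), seed = NULL) {
  stopifnot(inherits(config, "connectome_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, simulate_connectome_impl(config))
}

simulate_connectome_impl <- function(cfg) {
  pitch <- cfg$column_spacing_nm
  jitter_sd <- pitch / 4
  types <- c(cfg$core_types$name, cfg$variable_types$name)
  all_types <- data.frame(
    name = types,
    presence_prob = c(rep(1, nrow(cfg$core_types)),
                      cfg$variable_types$presence_prob),
    count_mean = c(cfg$core_types$count_mean, cfg$variable_types$count_mean),
    count_sd = c(cfg$core_types$count_sd, cfg$variable_types$count_sd),
    max_cells = c(rep(1L, nrow(cfg$core_types)), cfg$variable_types$max_cells),
    compartment = c(cfg$core_types$compartment,
                    cfg$variable_types$compartment),
    stringsAsFactors = FALSE
  )

  # -- column layout ---------------------------------------------------------
  cols <- list()
  for (h in c("right", "left")) {
    n <- cfg$n_columns_per_hemisphere[[h]]
    xy <- hex_lattice(n, pitch)
    offs <- 1.2 * pitch * sqrt(max(cfg$n_columns_per_hemisphere))
    x <- if (h == "right") xy[, 1] + offs else -xy[, 1] - offs
    cid <- sprintf("%s_%03d", toupper(substr(h, 1, 1)), seq_len(n))
    cols[[h]] <- data.frame(
      column_id = cid,
      target_cell_id = paste0("T_", cid),
      hemisphere = h,
      x_nm = x, y_nm = xy[, 2], z_nm = 0,
      dv_label = ifelse(xy[, 2] > mean(xy[, 2]), "dorsal", "ventral"),
      stringsAsFactors = FALSE
    )
  }
  columns <- rbind(cols$right, cols$left)
  ncol_total <- nrow(columns)
  ntype <- nrow(all_types)

  # -- plant cells and synapses ---------------------------------------------
  presence <- matrix(0L, ncol_total, ntype,
                     dimnames = list(columns$target_cell_id, all_types$name))
  planted <- presence
  multiplicity <- presence
  unknown_syn <- stats::setNames(integer(ncol_total), columns$target_cell_id)
  sub_syn <- unknown_syn
  planted_syn <- unknown_syn

  syn <- vector("list", 4096); si <- 0L
  ann <- vector("list", 4096); ai <- 0L
  push_syn <- function(df) { si <<- si + 1L; syn[[si]] <<- df }
  push_ann <- function(df) { ai <<- ai + 1L; ann[[ai]] <<- df }

  for (ci in seq_len(ncol_total)) {
    col <- columns[ci, ]
    center <- c(col$x_nm, col$y_nm, col$z_nm)
    for (ti in seq_len(ntype)) {
      tp <- all_types[ti, ]
      if (stats::runif(1) > tp$presence_prob) next
      n_cells <- if (tp$max_cells > 1L)
        1L + stats::rbinom(1, tp$max_cells - 1L, cfg$multi_cell_prob) else 1L
      for (cell in seq_len(n_cells)) {
        seg <- sprintf("seg_%s_%s_%d", col$column_id, tp$name, cell)
        cnt <- rcount_trunc(1, tp$count_mean, tp$count_sd, cfg$min_count)
        ctr <- center
        if (tp$compartment == "axonal") ctr[3] <- ctr[3] + cfg$axon_offset_nm
        pos <- sample_positions(cnt, ctr, jitter_sd)
        unknown <- stats::runif(1) < cfg$unknown_rate
        push_syn(data.frame(
          pre_segment_id = seg, post_cell_id = col$target_cell_id,
          x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
          cleft_score = rnorm_floor(cnt, cfg$cleft_mean, cfg$cleft_sd,
                                    cfg$cleft_floor),
          compartment = tp$compartment, stringsAsFactors = FALSE))
        push_ann(data.frame(
          segment_id = seg,
          type_label = if (unknown) "UNKNOWN" else tp$name,
          hemisphere = col$hemisphere, stringsAsFactors = FALSE))
        planted_syn[ci] <- planted_syn[ci] + cnt
        if (unknown) {
          unknown_syn[ci] <- unknown_syn[ci] + cnt
        } else {
          presence[ci, ti] <- 1L
          planted[ci, ti] <- planted[ci, ti] + cnt
          multiplicity[ci, ti] <- multiplicity[ci, ti] + 1L
        }
      }
    }
    # sub-threshold partner cells (annotated, but below the partner threshold)
    if (cfg$subthreshold_rate > 0 && cfg$min_count > 1L) {
      n_sub <- stats::rpois(1, cfg$subthreshold_rate)
      if (n_sub > 0) for (s in seq_len(n_sub)) {
        ti <- sample(which(all_types$presence_prob < 1), 1)
        tp <- all_types[ti, ]
        seg <- sprintf("seg_%s_sub%d", col$column_id, s)
        cnt <- sample.int(cfg$min_count - 1L, 1)
        pos <- sample_positions(cnt, center, jitter_sd)
        push_syn(data.frame(
          pre_segment_id = seg, post_cell_id = col$target_cell_id,
          x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
          cleft_score = rnorm_floor(cnt, cfg$cleft_mean, cfg$cleft_sd,
                                    cfg$cleft_floor),
          compartment = tp$compartment, stringsAsFactors = FALSE))
        push_ann(data.frame(segment_id = seg, type_label = tp$name,
                            hemisphere = col$hemisphere,
                            stringsAsFactors = FALSE))
        sub_syn[ci] <- sub_syn[ci] + cnt
        planted_syn[ci] <- planted_syn[ci] + cnt
      }
    }
  }
  synapses <- do.call(rbind, syn[seq_len(si)])
  annotations <- do.call(rbind, ann[seq_len(ai)])
  rownames(synapses) <- rownames(annotations) <- NULL
  n_real <- nrow(synapses)

  # -- near-duplicate detections (< 100 nm from source, lower cleft score) ---
  n_dup <- round(cfg$duplicate_rate * n_real)
  if (n_dup > 0) {
    src <- sample.int(n_real, n_dup)
    u <- matrix(stats::rnorm(n_dup * 3), n_dup, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- stats::runif(n_dup, 20, 90)
    dup <- synapses[src, ]
    dup$x_nm <- dup$x_nm + u[, 1] * r
    dup$y_nm <- dup$y_nm + u[, 2] * r
    dup$z_nm <- dup$z_nm + u[, 3] * r
    dup$cleft_score <- pmax(cfg$cleft_floor,
                            dup$cleft_score - stats::runif(n_dup, 5, 20))
    synapses <- rbind(synapses, dup)
  }

  # -- low-confidence decoy rows (cleft score < 50) --------------------------
  n_low <- round(cfg$low_cleft_rate * n_real)
  if (n_low > 0) {
    src <- sample.int(n_real, n_low)
    low <- synapses[src, ]
    low$x_nm <- low$x_nm + stats::rnorm(n_low, sd = jitter_sd)
    low$y_nm <- low$y_nm + stats::rnorm(n_low, sd = jitter_sd)
    low$z_nm <- low$z_nm + stats::rnorm(n_low, sd = jitter_sd)
    low$cleft_score <- stats::runif(n_low, 5, 49.5)
    synapses <- rbind(synapses, low)
  }
  rownames(synapses) <- NULL

  truth <- list(
    presence = presence, planted_counts = planted,
    cell_multiplicity = multiplicity,
    columns = columns,
    dv_label = stats::setNames(columns$dv_label, columns$target_cell_id),
    planted_synapses = planted_syn,
    unknown_synapses = unknown_syn,
    subthreshold_synapses = sub_syn,
    n_duplicates = n_dup, n_low_cleft = n_low,
    types = all_types
  )
  structure(list(synapses = synapses, annotations = annotations,
                 truth = truth, config = cfg),
            class = "synthetic_connectome")
}

#' @export
print.synthetic_connectome <- function(x, ...) {
  cat("Synthetic columnar connectome (", x$config$preset, " preset)\n",
      sep = "")
  cat("  columns: ", nrow(x$truth$columns), " (",
      paste(x$config$n_columns_per_hemisphere, collapse = " right / "),
      " left)\n", sep = "")
  cat("  synapse rows:", nrow(x$synapses),
      "| annotated segments:", nrow(x$annotations), "\n")
  cat("  injected duplicates:", x$truth$n_duplicates,
      "| low-cleft decoys:", x$truth$n_low_cleft, "\n")
  invisible(x)
}

#' Simulate binary presence profiles with planted motifs
#'
#' Draws `n_rows` binary presence profiles over `n_types` variable input types
#' from `n_motifs` equally sized planted motifs (random prototype bit
#' patterns), flipping each bit independently with probability `flip_rate`.
#' Used to validate presence-motif clustering with a known partition.
#'
#' @param n_rows number of profiles (columns of the eye).
#' @param n_motifs number of planted motifs; prototypes are resampled until
#'   all are distinct.
#' @param n_types number of binary input types.
#' @param flip_rate per-bit noise probability.
#' @param seed integer seed.
#' @return list with `profiles` (binary matrix), `labels` (planted motif of
#'   each row) and `prototypes`.
#' @export
simulate_motif_profiles <- function(n_rows = 320, n_motifs = 4, n_types = 17,
                                    flip_rate = 0.05, seed = 1L) {
  stopifnot(n_motifs >= 1, n_rows >= n_motifs, flip_rate >= 0, flip_rate < 0.5)
  with_seed(seed, {
    repeat {
      proto <- matrix(stats::rbinom(n_motifs * n_types, 1, 0.5),
                      n_motifs, n_types)
      if (nrow(unique(proto)) == n_motifs &&
          min(stats::dist(proto, method = "manhattan")) >= max(2, n_types / 4))
        break
    }
    labels <- rep(seq_len(n_motifs), length.out = n_rows)
    prof <- proto[labels, , drop = FALSE]
    flips <- matrix(stats::rbinom(n_rows * n_types, 1, flip_rate),
                    n_rows, n_types)
    prof <- abs(prof - flips)
    dimnames(prof) <- list(sprintf("row_%03d", seq_len(n_rows)),
                           sprintf("type_%02d", seq_len(n_types)))
    list(profiles = prof, labels = labels, prototypes = proto)
  })
}
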