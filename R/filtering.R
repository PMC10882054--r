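# Synapse-table quality filtering and connectivity-matrix construction.
#
# Fixed pipeline order: cleft filter -> deduplication -> aggregation ->
# per-cell partner threshold -> matrix -> presence filter. Every stage is
# idempotent on its own output.

validate_synapse_table <- function(table) {
  need <- c("pre_segment_id", "post_cell_id", "x_nm", "y_nm", "z_nm",
            "cleft_score")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("synapse table lacks columns: ", paste(missing, collapse = ", "))
  if (!"compartment" %in% names(table)) table$compartment <- "unknown"
  if (any(!is.finite(as.matrix(table[, c("x_nm", "y_nm", "z_nm")]))))
    stop("synapse positions must be finite")
  if (any(table$cleft_score < 0)) stop("cleft scores must be non-negative")
  table
}

#' Filter synapses by cleft score
#'
#' Retains detected synapses whose cleft (detection confidence) score is at
#' least `min_score`; the conventional cutoff for automatically detected
#' synapses in the FAFB/FlyWire volume is 50. Row order is preserved.
#'
#' @param table synapse data.frame (`pre_segment_id`, `post_cell_id`, `x_nm`,
#'   `y_nm`, `z_nm`, `cleft_score`, optional `compartment`).
#' @param min_score inclusive threshold (default 50).
#' @return The filtered synapse table.
#' @export
filter_cleft_score <- function(table, min_score = 50) {
  table <- validate_synapse_table(table)
  out <- table[table$cleft_score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove redundant (near-duplicate) synapse detections
#'
#' Within each (presynaptic segment, postsynaptic cell) pair, removes
#' detections so that no two retained synapses lie closer than `radius_nm`
#' (exclusive: a pair exactly `radius_nm` apart is kept). Retention is greedy
#' in descending cleft score, ties broken by input order, which keeps the most
#' confident detection of each redundant group. Idempotent.
#'
#' @param table synapse data.frame.
#' @param radius_nm redundancy radius in nanometres (default 100).
#' @return The deduplicated synapse table (original row order).
#' @export
deduplicate_synapses <- function(table, radius_nm = 100) {
  if (radius_nm < 0) stop("radius_nm must be non-negative")
  table <- validate_synapse_table(table)
  if (nrow(table) < 2 || radius_nm == 0) {
    rownames(table) <- NULL
    return(table)
  }
  key <- paste(table$pre_segment_id, table$post_cell_id, sep = "\r")
  keep <- logical(nrow(table))
  for (idx in split(seq_len(nrow(table)), key)) {
    if (length(idx) == 1) { keep[idx] <- TRUE; next }
    pos <- as.matrix(table[idx, c("x_nm", "y_nm", "z_nm")])
    ord <- order(-table$cleft_score[idx], seq_along(idx))
    d <- as.matrix(stats::dist(pos))
    retained <- integer(0)
    for (i in ord) {
      if (!length(retained) || all(d[i, retained] >= radius_nm))
        retained <- c(retained, i)
    }
    keep[idx[retained]] <- TRUE
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate synapse counts per input cell and input type
#'
#' Joins the (filtered) synapse table with the cell-type annotations and
#' counts synapses per (target cell, input segment). Segments without an
#' annotation are mapped to type `UNKNOWN`, never dropped. The result is the
#' unit on which the per-cell partner threshold operates.
#'
#' @param table filtered synapse data.frame.
#' @param annotations data.frame with `segment_id`, `type_label`, and
#'   optionally `hemisphere` (of the input cell).
#' @param targets optional character vector fixing the target-cell universe
#'   (rows); defaults to the targets observed in `table`.
#' @return A list of class `synapse_counts`: `cells` (data.frame
#'   `post_cell_id`, `pre_segment_id`, `type_label`, `n_synapses`),
#'   `targets`, `target_hemisphere` (named, from the annotation of the target
#'   cell if present, else NA), and `total_synapses` per target.
#' @export
aggregate_counts <- function(table, annotations, targets = NULL) {
  table <- validate_synapse_table(table)
  if (anyDuplicated(annotations$segment_id))
    stop("annotations must contain one row per segment")
  if (is.null(targets)) targets <- unique(table$post_cell_id)
  type_of <- stats::setNames(as.character(annotations$type_label),
                             annotations$segment_id)
  tl <- type_of[table$pre_segment_id]
  tl[is.na(tl)] <- "UNKNOWN"
  if (nrow(table)) {
    agg <- stats::aggregate(
      list(n_synapses = rep(1L, nrow(table))),
      by = list(post_cell_id = table$post_cell_id,
                pre_segment_id = table$pre_segment_id,
                type_label = tl),
      FUN = sum)
    agg <- agg[order(agg$post_cell_id, agg$type_label, agg$pre_segment_id), ]
  } else {
    agg <- data.frame(post_cell_id = character(0),
                      pre_segment_id = character(0),
                      type_label = character(0), n_synapses = integer(0))
  }
  rownames(agg) <- NULL
  hemi <- rep(NA_character_, length(targets))
  if ("hemisphere" %in% names(annotations) && nrow(table)) {
    h <- stats::setNames(as.character(annotations$hemisphere),
                         annotations$segment_id)
    # hemisphere of a target = hemisphere of its input cells (they agree)
    first_in <- tapply(table$pre_segment_id, table$post_cell_id,
                       function(s) s[1])
    hemi <- unname(h[first_in[targets]])
  }
  totals <- tapply(agg$n_synapses, factor(agg$post_cell_id, levels = targets),
                   sum, default = 0L)
  structure(list(cells = agg, targets = targets,
                 target_hemisphere = stats::setNames(hemi, targets),
                 total_synapses = totals,
                 threshold = NULL, dropped = NULL),
            class = "synapse_counts")
}

#' Zero out sub-threshold input cells
#'
#' Applies the per-cell partner threshold: input cells (segments) making fewer
#' than `min_synapses` synapses onto a target have their counts set to 0
#' (conventionally 3 for Tm9-style analyses, 4 for Tm1/Tm2). Thresholding acts
#' at the input-cell level, before any aggregation to types. Idempotent.
#'
#' @param counts a `synapse_counts` object from [aggregate_counts()].
#' @param min_synapses integer >= 1.
#' @return The thresholded `synapse_counts`, with per-target `dropped` synapse
#'   tallies recorded for conservation checks.
#' @export
apply_partner_threshold <- function(counts, min_synapses = 3) {
  stopifnot(inherits(counts, "synapse_counts"))
  if (min_synapses < 1) stop("min_synapses must be >= 1")
  drop <- counts$cells$n_synapses < min_synapses
  dropped_new <- tapply(
    counts$cells$n_synapses[drop],
    factor(counts$cells$post_cell_id[drop], levels = counts$targets),
    sum, default = 0L)
  prev <- if (is.null(counts$dropped))
    stats::setNames(rep(0L, length(counts$targets)), counts$targets)
  else counts$dropped
  counts$cells$n_synapses[drop] <- 0L
  counts$dropped <- prev + dropped_new
  counts$threshold <- min_synapses
  counts
}

#' Build a connectivity matrix from thresholded counts
#'
#' Rows are target cells (one per column of the eye), columns are input
#' cell-type labels. `absolute` gives integer synapse counts, `relative`
#' divides each row by its full post-threshold synapse total (including
#' UNKNOWN inputs, so dropping rare types later does not inflate fractions),
#' `binary` is the presence indicator (count > 0). The UNKNOWN type is not a
#' matrix column; its per-row synapse count is kept in the `unknown`
#' attribute, and sub-threshold synapses in `dropped`, so that
#' absolute-matrix row sums + unknown + dropped reproduce the post-dedup
#' totals exactly.
#'
#' @param counts a thresholded `synapse_counts`.
#' @param mode `"absolute"`, `"relative"` or `"binary"`.
#' @return A matrix of class `connectivity_matrix` with attributes `mode`,
#'   `unknown`, `dropped`, `row_total`, `hemisphere`, `multiplicity` (input
#'   cells per type), and `threshold`.
#' @export
build_connectivity_matrix <- function(counts,
                                      mode = c("absolute", "relative",
                                               "binary")) {
  stopifnot(inherits(counts, "synapse_counts"))
  mode <- match.arg(mode)
  cells <- counts$cells[counts$cells$n_synapses > 0, , drop = FALSE]
  types <- sort(setdiff(unique(cells$type_label), "UNKNOWN"))
  targets <- counts$targets
  mat <- matrix(0, length(targets), length(types),
                dimnames = list(targets, types))
  mult <- mat
  is_known <- cells$type_label != "UNKNOWN"
  if (any(is_known)) {
    kn <- cells[is_known, ]
    ri <- match(kn$post_cell_id, targets)
    ci <- match(kn$type_label, types)
    for (i in seq_len(nrow(kn))) {
      mat[ri[i], ci[i]] <- mat[ri[i], ci[i]] + kn$n_synapses[i]
      mult[ri[i], ci[i]] <- mult[ri[i], ci[i]] + 1L
    }
  }
  unknown <- tapply(cells$n_synapses[!is_known],
                    factor(cells$post_cell_id[!is_known], levels = targets),
                    sum, default = 0L)
  dropped <- if (is.null(counts$dropped))
    stats::setNames(rep(0L, length(targets)), targets) else counts$dropped
  row_total <- rowSums(mat) + as.numeric(unknown)

  values <- switch(mode,
    absolute = mat,
    binary = (mat > 0) + 0,
    relative = {
      zero <- row_total == 0
      if (any(zero))
        warning("relative mode: ", sum(zero),
                " target(s) with zero total synapses; rows set to 0")
      sweep(mat, 1, ifelse(row_total == 0, 1, row_total), "/")
    })
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            mode_flag = mode,
            unknown = stats::setNames(as.numeric(unknown), targets),
            dropped = stats::setNames(as.numeric(dropped), targets),
            row_total = stats::setNames(row_total, targets),
            hemisphere = counts$target_hemisphere,
            multiplicity = mult,
            threshold = counts$threshold)
}

#' Drop rarely present input types
#'
#' Removes input-type columns whose presence fraction (share of target rows
#' with a nonzero count) is below `min_fraction`; the conventional cut keeps
#' types present in at least 5% of columns. Bookkeeping attributes (UNKNOWN,
#' dropped, row totals) are preserved, so relative rows keep their original
#' denominator.
#'
#' @param matrix a `connectivity_matrix`.
#' @param min_fraction presence cut in \[0, 1\] (default 0.05); types with
#'   presence >= `min_fraction` are kept.
#' @return The column-filtered `connectivity_matrix`.
#' @export
filter_by_presence <- function(matrix, min_fraction = 0.05) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  pres <- colMeans(matrix > 0)
  keep <- pres >= min_fraction
  out <- matrix[, keep, drop = FALSE]
  for (a in c("mode_flag", "unknown", "dropped", "row_total", "hemisphere",
              "threshold"))
    attr(out, a) <- attr(matrix, a)
  attr(out, "multiplicity") <- attr(matrix, "multiplicity")[, keep,
                                                            drop = FALSE]
  class(out) <- class(matrix)
  out
}

#' Run the full filtering pipeline
#'
#' Convenience wrapper applying the stages in their fixed order:
#' cleft filter -> deduplication -> aggregation -> per-cell partner
#' threshold -> matrix construction -> presence filter.
#'
#' @param table raw synapse data.frame.
#' @param annotations cell-annotation data.frame.
#' @param min_cleft cleft-score cutoff (default 50).
#' @param dedup_nm redundancy radius (default 100).
#' @param min_synapses per-cell partner threshold (default 3).
#' @param presence_cut presence fraction cut (default 0.05).
#' @param mode matrix mode (default `"absolute"`).
#' @param targets optional fixed target universe.
#' @return A `connectivity_matrix`.
#' @export
connectivity_pipeline <- function(table, annotations, min_cleft = 50,
                                  dedup_nm = 100, min_synapses = 3,
                                  presence_cut = 0.05, mode = "absolute",
                                  targets = NULL) {
  tab <- filter_cleft_score(table, min_cleft)
  tab <- deduplicate_synapses(tab, dedup_nm)
  cnt <- aggregate_counts(tab, annotations, targets = targets)
  cnt <- apply_partner_threshold(cnt, min_synapses)
  mat <- build_connectivity_matrix(cnt, mode = mode)
  filter_by_presence(mat, presence_cut)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Connectivity matrix (", attr(x, "mode_flag"), " mode): ",
      nrow(x), " target cells x ", ncol(x), " input types\n", sep = "")
  thr <- attr(x, "threshold")
  if (!is.null(thr)) cat("  partner threshold: >=", thr, "synapses/cell\n")
  cat("  UNKNOWN synapses:", sum(attr(x, "unknown")),
      "| sub-threshold dropped:", sum(attr(x, "dropped")), "\n")
  utils::str(unclass(x)[seq_len(min(5, nrow(x))),
                        seq_len(min(8, ncol(x))), drop = FALSE])
  invisible(x)
}
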