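# Plain-text and TIFF exchange formats for every pipeline stage.
#
# Synapse and annotation tables are CSV with fixed headers; connectivity
# matrices are CSV with target-cell row labels; volumes are multi-directory
# TIFF (channel-major slice order); ROI sets integer label TIFF; ground truth
# JSON; generator configs YAML.

#' Read and write synapse tables
#'
#' CSV with header `pre_segment_id, post_cell_id, x_nm, y_nm, z_nm,
#' cleft_score, compartment` (positions as three separate numeric fields, in
#' nanometres).
#'
#' @param table synapse data.frame.
#' @param path file path.
#' @return `read_synapse_table` returns the validated data.frame.
#' @export
write_synapse_table <- function(table, path) {
  table <- validate_synapse_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synapse_table
#' @export
read_synapse_table <- function(path) {
  validate_synapse_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read and write cell annotations
#'
#' CSV with header `segment_id, type_label, hemisphere`.
#'
#' @param annotations annotation data.frame.
#' @param path file path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write connectivity matrices
#'
#' CSV with target-cell ids in the first column (`post_cell_id`) and one
#' column per input type. Mode and bookkeeping attributes are stored in a
#' JSON sidecar `<path>.meta.json` and restored on read when present.
#'
#' @param matrix a `connectivity_matrix`.
#' @param path file path.
#' @export
write_connectivity_matrix <- function(matrix, path) {
  df <- data.frame(post_cell_id = rownames(matrix),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(mode = attr(matrix, "mode_flag"),
               threshold = attr(matrix, "threshold"),
               unknown = as.list(attr(matrix, "unknown")),
               dropped = as.list(attr(matrix, "dropped")),
               row_total = as.list(attr(matrix, "row_total")),
               hemisphere = as.list(attr(matrix, "hemisphere")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_connectivity_matrix
#' @export
read_connectivity_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta_path <- paste0(path, ".meta.json")
  attrs <- list(mode_flag = "absolute")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attrs <- list(mode_flag = meta$mode, threshold = meta$threshold,
                  unknown = unlist(meta$unknown),
                  dropped = unlist(meta$dropped),
                  row_total = unlist(meta$row_total),
                  hemisphere = unlist(meta$hemisphere))
  }
  structure(m, class = c("connectivity_matrix", "matrix", "array"),
            mode_flag = attrs$mode_flag, threshold = attrs$threshold,
            unknown = attrs$unknown, dropped = attrs$dropped,
            row_total = attrs$row_total, hemisphere = attrs$hemisphere)
}

#' Read and write two-channel volumes as TIFF
#'
#' Multi-directory 32-bit float TIFF: all z-slices of channel 1 (puncta)
#' followed by all z-slices of channel 2 (membrane). Intensities are scaled
#' to \[0, 1\] on write (scale factor recorded in a YAML sidecar with voxel
#' size and expansion factor).
#'
#' @param volume a `puncta_volume`.
#' @param path TIFF path (`<path>.meta.yaml` sidecar written next to it).
#' @export
write_puncta_volume <- function(volume, path) {
  stopifnot(inherits(volume, "puncta_volume"))
  nz <- dim(volume$puncta)[3]
  lo <- min(volume$puncta, volume$mask)
  hi <- max(volume$puncta, volume$mask)
  scale <- max(hi - lo, 1e-12)
  norm <- function(x) (x - lo) / scale
  slices <- c(lapply(seq_len(nz), function(k) norm(volume$puncta[, , k])),
              lapply(seq_len(nz), function(k) norm(volume$mask[, , k])))
  tiff::writeTIFF(slices, path, bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(list(voxel_size_nm = volume$voxel_size_nm,
                        expansion_factor = volume$expansion_factor,
                        n_z = nz, intensity_scale = scale,
                        intensity_offset = lo),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_puncta_volume
#' @export
read_puncta_volume <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  slices <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_z
  stopifnot(length(slices) == 2 * nz)
  offset <- if (is.null(meta$intensity_offset)) 0 else meta$intensity_offset
  stack <- function(lst) {
    arr <- array(0, c(dim(lst[[1]]), length(lst)))
    for (k in seq_along(lst)) arr[, , k] <- lst[[k]]
    arr * meta$intensity_scale + offset
  }
  puncta_volume(stack(slices[seq_len(nz)]), stack(slices[nz + seq_len(nz)]),
                meta$voxel_size_nm, meta$expansion_factor)
}

#' Read and write ROI label volumes as TIFF
#'
#' Integer labels stored as 16-bit grayscale (label/65535 per TIFF
#' convention); 0 means outside all ROIs.
#'
#' @param roi_labels integer 3D array.
#' @param path TIFF path.
#' @export
write_roi_labels <- function(roi_labels, path) {
  stopifnot(length(dim(roi_labels)) == 3, max(roi_labels) < 65536)
  nz <- dim(roi_labels)[3]
  slices <- lapply(seq_len(nz), function(k) roi_labels[, , k] / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' @rdname write_roi_labels
#' @export
read_roi_labels <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- as.integer(round(slices[[k]] *
                                                                65535))
  arr
}

#' Write ground truth as JSON
#'
#' Serializes a generator's ground-truth record (matrices become row-major
#' lists of rows with dimnames preserved).
#'
#' @param truth ground-truth list from a simulator.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", dataframe = "columns")
  invisible(path)
}

#' Read and write connectome generator configs as YAML
#'
#' @param config a `connectome_config`.
#' @param path YAML path.
#' @export
write_connectome_config <- function(config, path) {
  stopifnot(inherits(config, "connectome_config"))
  lst <- unclass(config)
  lst$core_types <- as.list(lst$core_types)
  lst$variable_types <- as.list(lst$variable_types)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_connectome_config
#' @export
read_connectome_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(connectome_config, c(
    list(preset = lst$preset,
         n_columns_per_hemisphere = unlist(lst$n_columns_per_hemisphere),
         core_types = as.data.frame(lst$core_types,
                                    stringsAsFactors = FALSE),
         variable_types = as.data.frame(lst$variable_types,
                                        stringsAsFactors = FALSE)),
    lst[c("duplicate_rate", "subthreshold_rate", "low_cleft_rate",
          "unknown_rate", "cleft_mean", "cleft_sd", "cleft_floor",
          "column_spacing_nm", "min_count", "multi_cell_prob",
          "axon_offset_nm", "seed")]))
}
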