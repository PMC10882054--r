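# Expansion-microscopy synapse quantification: presynaptic puncta detection,
# dendrite-mask binarization, and distance-thresholded apposition counting
# per column ROI. All distances are image-space (post-expansion) nanometres;
# the expansion factor is carried as metadata only.

#' Construct a two-channel puncta volume
#'
#' Lightweight container for a two-channel 3D image: a presynaptic puncta
#' channel (e.g. Brp-short::mCherry) and a dendrite-membrane channel (e.g.
#' rCD2::GFP), with voxel size and expansion factor.
#'
#' @param puncta_channel,mask_channel 3D numeric arrays of equal shape.
#' @param voxel_size_nm numeric length-3 voxel size (nm per voxel along each
#'   array dimension, image space).
#' @param expansion_factor physical magnification of the expanded sample.
#' @return list of class `puncta_volume`.
#' @export
puncta_volume <- function(puncta_channel, mask_channel, voxel_size_nm,
                          expansion_factor = 1) {
  stopifnot(length(dim(puncta_channel)) == 3,
            identical(dim(puncta_channel), dim(mask_channel)),
            length(voxel_size_nm) == 3, all(voxel_size_nm > 0),
            expansion_factor > 0)
  structure(list(puncta = puncta_channel, mask = mask_channel,
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 expansion_factor = expansion_factor),
            class = "puncta_volume")
}

#' @export
print.puncta_volume <- function(x, ...) {
  cat("Two-channel volume:", paste(dim(x$puncta), collapse = " x "),
      "voxels,", paste(x$voxel_size_nm, collapse = "/"),
      "nm/voxel, expansion factor", x$expansion_factor, "\n")
  invisible(x)
}

# voxel index (i,j,k) -> image-space nm position of the voxel center
voxel_to_nm <- function(ijk, voxel_size_nm) {
  sweep(ijk - 0.5, 2, voxel_size_nm, "*")
}

#' Detect presynaptic puncta as separated local maxima
#'
#' Finds local intensity maxima (26-connected neighborhood) above a threshold
#' in the puncta channel, then greedily enforces a minimum separation in
#' nanometres (anisotropy-aware), keeping the brighter punctum of any pair
#' closer than `min_separation_nm` (ties broken by array order). The
#' conventional separation for resolvable Brp puncta is 200 nm.
#'
#' @param volume a `puncta_volume` (or a 3D array, in which case
#'   `voxel_size_nm` must be supplied).
#' @param min_separation_nm minimum center-to-center distance (default 200).
#' @param intensity_threshold absolute threshold; `NULL` (default) uses the
#'   global Otsu threshold of the channel.
#' @param voxel_size_nm used when `volume` is a bare array.
#' @return data.frame of class `puncta_set`: voxel indices `i`, `j`, `k`,
#'   positions `x_nm`, `y_nm`, `z_nm`, `intensity`; attribute `threshold`.
#' @export
detect_puncta <- function(volume, min_separation_nm = 200,
                          intensity_threshold = NULL, voxel_size_nm = NULL) {
  if (inherits(volume, "puncta_volume")) {
    arr <- volume$puncta
    voxel_size_nm <- volume$voxel_size_nm
  } else {
    arr <- volume
    if (is.null(voxel_size_nm)) stop("voxel_size_nm required for bare arrays")
  }
  if (length(dim(arr)) != 3) stop("puncta detection requires a 3D volume")
  if (min_separation_nm <= 0) stop("min_separation_nm must be positive")
  if (is.null(intensity_threshold)) intensity_threshold <- otsu_threshold(arr)

  dm <- dim(arr)
  cand <- which(arr > intensity_threshold)
  if (length(cand)) {
    # compare against all 26 shifted copies; border voxels compare against
    # an -Inf pad
    pad <- array(-Inf, dm + 2)
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- arr
    is_max <- rep(TRUE, length(cand))
    ijk <- arrayInd(cand, dm)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- pad[cbind(ijk[, 1] + 1 + dx, ijk[, 2] + 1 + dy,
                      ijk[, 3] + 1 + dz)]
      is_max <- is_max & (arr[cand] >= nb)
      # strict on the lexicographically earlier side to avoid plateau twins
      tie <- arr[cand] == nb & (dx < 0 | (dx == 0 & (dy < 0 |
                                                     (dy == 0 & dz < 0))))
      is_max <- is_max & !tie
    }
    cand <- cand[is_max]
  }
  if (!length(cand)) {
    out <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
                      intensity = numeric(0))
  } else {
    ijk <- arrayInd(cand, dm)
    pos <- voxel_to_nm(ijk, voxel_size_nm)
    val <- arr[cand]
    ord <- order(-val, cand)
    retained <- integer(0)
    for (i in ord) {
      if (!length(retained) ||
          all(sqrt(colSums((t(pos[retained, , drop = FALSE]) - pos[i, ])^2))
              >= min_separation_nm))
        retained <- c(retained, i)
    }
    retained <- sort(retained)
    out <- data.frame(i = ijk[retained, 1], j = ijk[retained, 2],
                      k = ijk[retained, 3],
                      x_nm = pos[retained, 1], y_nm = pos[retained, 2],
                      z_nm = pos[retained, 3],
                      intensity = val[retained])
  }
  attr(out, "threshold") <- intensity_threshold
  attr(out, "min_separation_nm") <- min_separation_nm
  class(out) <- c("puncta_set", "data.frame")
  out
}

#' Binarize the dendrite-membrane channel
#'
#' @param mask_channel 3D numeric array (or a `puncta_volume`, in which case
#'   its mask channel is used).
#' @param threshold absolute threshold; `NULL` (default) uses the global Otsu
#'   threshold. Voxels strictly above threshold are TRUE.
#' @return logical array; attributes `threshold` and `n_voxels` (TRUE count).
#'   An empty mask triggers a warning (all distances become infinite).
#' @export
binarize_mask <- function(mask_channel, threshold = NULL) {
  arr <- if (inherits(mask_channel, "puncta_volume")) mask_channel$mask
  else mask_channel
  if (is.null(threshold)) threshold <- otsu_threshold(arr)
  out <- arr > threshold
  if (!any(out)) warning("binarized mask is empty; all distances infinite")
  attr(out, "threshold") <- threshold
  attr(out, "n_voxels") <- sum(out)
  out
}

# Exact minimum anisotropy-aware distance (nm) from each punctum to any TRUE
# mask voxel center. Vectorized scan over the mask voxel list.
puncta_mask_distances <- function(puncta_xyz, mask, voxel_size_nm) {
  if (!any(mask)) return(rep(Inf, nrow(puncta_xyz)))
  mv <- voxel_to_nm(arrayInd(which(mask), dim(mask)), voxel_size_nm)
  apply(puncta_xyz, 1, function(p) {
    sqrt(min((mv[, 1] - p[1])^2 + (mv[, 2] - p[2])^2 + (mv[, 3] - p[3])^2))
  })
}

#' Count puncta apposed to the dendrite mask, per column ROI
#'
#' For each detected punctum, computes the exact minimum Euclidean distance
#' (anisotropy-aware, in image-space nm) to any true voxel of the binarized
#' dendrite mask. Puncta within `max_distance_nm` (inclusive; conventionally
#' 300 nm, a literature apposition criterion scaled by the expansion factor)
#' are counted as synapses and assigned to the ROI containing their center
#' voxel; apposed puncta outside every ROI go to an `unassigned` bucket.
#'
#' @param puncta a `puncta_set` from [detect_puncta()] (or a data.frame with
#'   `i`, `j`, `k`, `x_nm`, `y_nm`, `z_nm`).
#' @param mask logical array from [binarize_mask()].
#' @param roi_labels integer array of the same shape (0 = outside all ROIs).
#' @param voxel_size_nm length-3 voxel size in nm.
#' @param max_distance_nm apposition threshold (default 300, inclusive).
#' @return list of class `apposition_result`: `puncta` (input plus
#'   `distance_nm`, `apposed`, `roi`), `roi_counts` (named vector over all
#'   ROI labels present in `roi_labels`), `unassigned`, `histogram`
#'   (data.frame `n_connections`, `n_rois`, `percent` across ROIs),
#'   `max_distance_nm`.
#' @export
count_appositions <- function(puncta, mask, roi_labels, voxel_size_nm,
                              max_distance_nm = 300) {
  stopifnot(identical(dim(mask), dim(roi_labels)))
  xyz <- as.matrix(as.data.frame(puncta)[, c("x_nm", "y_nm", "z_nm"),
                                         drop = FALSE])
  dists <- if (nrow(xyz)) puncta_mask_distances(xyz, mask, voxel_size_nm)
  else numeric(0)
  apposed <- dists <= max_distance_nm
  roi <- if (nrow(xyz))
    roi_labels[cbind(puncta$i, puncta$j, puncta$k)] else integer(0)
  all_rois <- sort(setdiff(unique(as.vector(roi_labels)), 0))
  counts <- stats::setNames(rep(0L, length(all_rois)),
                            as.character(all_rois))
  tab <- table(roi[apposed & roi > 0])
  counts[names(tab)] <- as.integer(tab)
  unassigned <- sum(apposed & roi == 0)
  hist_tab <- table(factor(counts, levels = 0:max(c(counts, 0))))
  histogram <- data.frame(
    n_connections = as.integer(names(hist_tab)),
    n_rois = as.integer(hist_tab),
    percent = 100 * as.integer(hist_tab) / max(1, length(all_rois)))
  pd <- as.data.frame(puncta)
  pd$distance_nm <- dists
  pd$apposed <- apposed
  pd$roi <- roi
  structure(list(puncta = pd, roi_counts = counts, unassigned = unassigned,
                 histogram = histogram, max_distance_nm = max_distance_nm),
            class = "apposition_result")
}

#' @export
print.apposition_result <- function(x, ...) {
  cat("Apposition counts (threshold", x$max_distance_nm, "nm):",
      sum(x$roi_counts), "puncta in", length(x$roi_counts), "ROIs,",
      x$unassigned, "apposed outside ROIs\n")
  print(x$histogram)
  invisible(x)
}
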