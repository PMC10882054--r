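# Synthetic two-channel expansion-microscopy volume: Gaussian presynaptic
# puncta in channel 1, tubular dendrite masks in channel 2, column ROI
# labels, and exact ground-truth distances for every planted punctum.

#' Simulate a two-channel puncta/dendrite volume with ground truth
#'
#' Renders Gaussian spots at the planted punctum positions in the puncta
#' channel and vertical (z-axis) dendrite tubes at the given column centers in
#' the membrane channel; column ROIs are rectangular prisms around each tube.
#' Each planted punctum is tagged with its containing ROI and its true
#' minimum distance to the binarized mask (computed voxel-exactly), so
#' apposition counting can be validated exactly on noise-free volumes.
#'
#' Puncta positions snap to voxel centers so that noise-free local-maximum
#' detection recovers them exactly.
#'
#' @param shape_voxels integer length-3 volume shape.
#' @param voxel_size_nm numeric length-3, nm per voxel (image space).
#' @param expansion_factor recorded metadata (default 4, a typical protein-
#'   retention ExM magnification).
#' @param puncta data.frame with `x_nm`, `y_nm`, `z_nm` (image-space nm) and
#'   optional `amplitude`; positions outside the volume are an error.
#' @param tube_centers_nm matrix/data.frame of x/y tube centers (one dendrite
#'   column per row); default: a single tube at the volume center.
#' @param tube_radius_nm dendrite tube radius (default 500).
#' @param roi_halfwidth_nm half-width of the square ROI prism around each
#'   tube (default 1500).
#' @param spot_sigma_nm Gaussian spot sigma (default 120).
#' @param noise_sd additive Gaussian noise sd on both channels (default 0).
#' @param seed integer seed (noise only).
#' @return list of class `synthetic_volume`: `volume` (a
#'   [puncta_volume()]), `roi_labels` (integer array), `truth` (data.frame of
#'   planted puncta with `roi` and `true_distance_nm`, plus `mask_threshold`).
#' @export
simulate_puncta_volume <- function(shape_voxels = c(96, 96, 48),
                                   voxel_size_nm = c(100, 100, 200),
                                   expansion_factor = 4,
                                   puncta = NULL,
                                   tube_centers_nm = NULL,
                                   tube_radius_nm = 500,
                                   roi_halfwidth_nm = 1500,
                                   spot_sigma_nm = 120,
                                   noise_sd = 0,
                                   seed = 1L) {
  stopifnot(length(shape_voxels) == 3, all(shape_voxels >= 4),
            all(voxel_size_nm > 0), expansion_factor > 0)
  dm <- as.integer(shape_voxels)
  extent <- dm * voxel_size_nm
  if (is.null(tube_centers_nm))
    tube_centers_nm <- matrix(extent[1:2] / 2, 1, 2)
  tube_centers_nm <- as.matrix(tube_centers_nm)

  if (is.null(puncta))
    puncta <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                         z_nm = numeric(0))
  puncta <- as.data.frame(puncta)
  if (!"amplitude" %in% names(puncta))
    puncta$amplitude <- rep(1, nrow(puncta))
  if (nrow(puncta)) {
    inb <- puncta$x_nm > 0 & puncta$x_nm < extent[1] &
      puncta$y_nm > 0 & puncta$y_nm < extent[2] &
      puncta$z_nm > 0 & puncta$z_nm < extent[3]
    if (!all(inb)) stop("planted puncta outside the volume")
    # snap to voxel centers
    for (a in 1:3) {
      col <- c("x_nm", "y_nm", "z_nm")[a]
      puncta[[col]] <- (ceiling(puncta[[col]] / voxel_size_nm[a]) - 0.5) *
        voxel_size_nm[a]
    }
  }

  ax <- ((seq_len(dm[1])) - 0.5) * voxel_size_nm[1]
  ay <- ((seq_len(dm[2])) - 0.5) * voxel_size_nm[2]
  az <- ((seq_len(dm[3])) - 0.5) * voxel_size_nm[3]

  # channel 1: Gaussian spots (rendered on local patches)
  ch1 <- array(0, dm)
  if (nrow(puncta)) {
    r_vox <- ceiling(4 * spot_sigma_nm / voxel_size_nm)
    for (p in seq_len(nrow(puncta))) {
      ci <- c(ceiling(puncta$x_nm[p] / voxel_size_nm[1]),
              ceiling(puncta$y_nm[p] / voxel_size_nm[2]),
              ceiling(puncta$z_nm[p] / voxel_size_nm[3]))
      ir <- max(1, ci[1] - r_vox[1]):min(dm[1], ci[1] + r_vox[1])
      jr <- max(1, ci[2] - r_vox[2]):min(dm[2], ci[2] + r_vox[2])
      kr <- max(1, ci[3] - r_vox[3]):min(dm[3], ci[3] + r_vox[3])
      gx <- exp(-(ax[ir] - puncta$x_nm[p])^2 / (2 * spot_sigma_nm^2))
      gy <- exp(-(ay[jr] - puncta$y_nm[p])^2 / (2 * spot_sigma_nm^2))
      gz <- exp(-(az[kr] - puncta$z_nm[p])^2 / (2 * spot_sigma_nm^2))
      ch1[ir, jr, kr] <- ch1[ir, jr, kr] +
        puncta$amplitude[p] * outer(outer(gx, gy), gz)
    }
  }

  # channel 2 + ROI labels: vertical tubes and their square ROI prisms
  ch2 <- array(0, dm)
  roi <- array(0L, dm)
  dx2 <- outer(ax, tube_centers_nm[, 1], "-")^2
  dy2 <- outer(ay, tube_centers_nm[, 2], "-")^2
  for (t in seq_len(nrow(tube_centers_nm))) {
    in_tube <- outer(dx2[, t], dy2[, t], "+") <= tube_radius_nm^2
    if (any(in_tube)) {
      idx <- which(in_tube, arr.ind = TRUE)
      for (k in seq_len(dm[3])) ch2[cbind(idx, k)] <- 1
    }
    in_roi <- outer(abs(ax - tube_centers_nm[t, 1]) <= roi_halfwidth_nm,
                    abs(ay - tube_centers_nm[t, 2]) <= roi_halfwidth_nm,
                    FUN = "&")
    if (any(in_roi)) {
      idx <- which(in_roi, arr.ind = TRUE)
      for (k in seq_len(dm[3])) roi[cbind(idx, k)] <- t
    }
  }

  mask_threshold <- 0.5
  mask <- ch2 > mask_threshold

  truth <- puncta
  truth$roi <- if (nrow(puncta))
    roi[cbind(ceiling(puncta$x_nm / voxel_size_nm[1]),
              ceiling(puncta$y_nm / voxel_size_nm[2]),
              ceiling(puncta$z_nm / voxel_size_nm[3]))] else integer(0)
  truth$true_distance_nm <- if (nrow(puncta))
    puncta_mask_distances(as.matrix(puncta[, c("x_nm", "y_nm", "z_nm")]),
                          mask, voxel_size_nm) else numeric(0)

  if (noise_sd > 0) {
    noise <- with_seed(seed, list(
      a = array(stats::rnorm(prod(dm), sd = noise_sd), dm),
      b = array(stats::rnorm(prod(dm), sd = noise_sd), dm)))
    ch1 <- ch1 + noise$a
    ch2 <- ch2 + noise$b
  }

  structure(list(
    volume = puncta_volume(ch1, ch2, voxel_size_nm, expansion_factor),
    roi_labels = roi,
    truth = truth,
    mask_threshold = mask_threshold),
    class = "synthetic_volume")
}
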