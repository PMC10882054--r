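# Spatial mapping: per-column coordinates, SVD-based dorsoventral split,
# presence maps, and a join-count test of spatial randomness.

#' Assign a spatial coordinate to each target cell (column)
#'
#' For each target cell, takes the center of mass of its dendritic-compartment
#' synapse positions and returns the position of the synapse nearest (in
#' Euclidean distance) to that centroid, i.e. an actual presynaptic site
#' serves as the column coordinate. Ties are broken by input order.
#'
#' @param table synapse data.frame with a `compartment` column.
#' @param targets target cells to map; defaults to all in the table.
#' @return data.frame: `post_cell_id`, `x_nm`, `y_nm`, `z_nm`.
#' @export
assign_column_coordinates <- function(table, targets = NULL) {
  table <- validate_synapse_table(table)
  if (is.null(targets)) targets <- unique(table$post_cell_id)
  out <- data.frame(post_cell_id = targets, x_nm = NA_real_, y_nm = NA_real_,
                    z_nm = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    rows <- table[table$post_cell_id == targets[i] &
                    table$compartment == "dendritic", , drop = FALSE]
    if (!nrow(rows))
      stop("target cell ", targets[i], " has no dendritic-compartment synapses")
    pos <- as.matrix(rows[, c("x_nm", "y_nm", "z_nm")])
    ctr <- colMeans(pos)
    d2 <- rowSums(sweep(pos, 2, ctr)^2)
    best <- which.min(d2)  # first minimum = stable tie-break
    out[i, c("x_nm", "y_nm", "z_nm")] <- pos[best, ]
  }
  out
}

#' Split columns into dorsal and ventral halves
#'
#' Per hemisphere: centers the 3D column coordinates, projects them onto the
#' plane spanned by the top-2 right singular vectors (SVD), and draws the
#' midline through the 2D centroid along the first principal axis. Columns
#' are labelled by the sign of the second in-plane coordinate; orientation is
#' anchored so that the supplied dorsal reference point lands in the dorsal
#' half.
#'
#' @param coords data.frame from [assign_column_coordinates()] (or any table
#'   with `post_cell_id`, `x_nm`, `y_nm`, `z_nm`).
#' @param hemisphere hemisphere label per row (a single hemisphere is fine).
#' @param dorsal_ref numeric length-3 reference point (one per call) known to
#'   lie dorsally, or a list/matrix giving one reference per hemisphere
#'   (named by hemisphere).
#' @return data.frame: input columns plus `u` (along midline), `v` (across
#'   midline, positive = dorsal) and `dv_label`.
#' @export
dorsoventral_split <- function(coords, hemisphere = NULL, dorsal_ref) {
  if (is.null(hemisphere)) hemisphere <- rep("all", nrow(coords))
  stopifnot(length(hemisphere) == nrow(coords))
  out <- cbind(coords,
               data.frame(hemisphere = hemisphere, u = NA_real_,
                          v = NA_real_, dv_label = NA_character_,
                          stringsAsFactors = FALSE))
  ref_for <- function(h) {
    if (is.list(dorsal_ref)) {
      if (is.null(dorsal_ref[[h]])) stop("no dorsal_ref for hemisphere ", h)
      dorsal_ref[[h]]
    } else if (is.matrix(dorsal_ref)) dorsal_ref[h, ] else dorsal_ref
  }
  for (h in unique(hemisphere)) {
    idx <- which(hemisphere == h)
    if (length(idx) < 3) stop("hemisphere ", h, " has fewer than 3 columns")
    pos <- as.matrix(out[idx, c("x_nm", "y_nm", "z_nm")])
    ctr <- colMeans(pos)
    cen <- sweep(pos, 2, ctr)
    sv <- svd(cen)
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
      stop("hemisphere ", h, " coordinates are collinear: plane undefined")
    basis <- sv$v[, 1:2]
    uv <- cen %*% basis
    uv <- sweep(uv, 2, colMeans(uv))  # midline through the 2D centroid
    ref_v <- sum((ref_for(h) - ctr) * basis[, 2]) - mean((cen %*% basis)[, 2])
    if (ref_v < 0) uv[, 2] <- -uv[, 2]
    out$u[idx] <- uv[, 1]
    out$v[idx] <- uv[, 2]
    out$dv_label[idx] <- ifelse(uv[, 2] > 0, "dorsal", "ventral")
  }
  out
}

#' Map presence (and multiplicity) of an input type across the eye
#'
#' Joins one input type's presence and cell multiplicity with the column
#' coordinates, yielding one record per analyzed column. Optionally summarizes
#' a spatial patch (polygon in the x/y plane, e.g. the densely analyzed set of
#' contiguous columns) by its presence fraction.
#'
#' @param matrix absolute-mode `connectivity_matrix` (multiplicity is read
#'   from its attribute when available).
#' @param coords coordinates data.frame covering every matrix row.
#' @param type_label input type to map.
#' @param patch_polygon optional 2-column matrix of polygon vertices (nm, x/y
#'   plane).
#' @return data.frame of per-column records: `post_cell_id`, `x_nm`, `y_nm`,
#'   `z_nm`, `present`, `multiplicity`, `in_patch` (if a polygon is given);
#'   attributes `presence_fraction` and, with a polygon, `patch_fraction`.
#' @export
presence_map <- function(matrix, coords, type_label, patch_polygon = NULL) {
  m <- unclass(matrix)
  if (!type_label %in% colnames(m))
    stop("type ", type_label, " not in matrix")
  idx <- match(rownames(m), coords$post_cell_id)
  if (anyNA(idx))
    stop("rows without coordinates: ",
         paste(utils::head(rownames(m)[is.na(idx)]), collapse = ", "))
  mult_attr <- attr(matrix, "multiplicity")
  mult <- if (!is.null(mult_attr) && type_label %in% colnames(mult_attr))
    mult_attr[, type_label] else as.numeric(m[, type_label] > 0)
  out <- data.frame(
    post_cell_id = rownames(m),
    x_nm = coords$x_nm[idx], y_nm = coords$y_nm[idx],
    z_nm = coords$z_nm[idx],
    present = m[, type_label] > 0,
    multiplicity = as.numeric(mult),
    stringsAsFactors = FALSE)
  attr(out, "presence_fraction") <- mean(out$present)
  if (!is.null(patch_polygon)) {
    inp <- mgcv::in.out(as.matrix(patch_polygon),
                        as.matrix(out[, c("x_nm", "y_nm")]))
    out$in_patch <- inp
    attr(out, "patch_fraction") <-
      if (any(inp)) mean(out$present[inp]) else NA_real_
  }
  out
}

#' Join-count test of spatial randomness of a binary label
#'
#' Tests whether presence/absence of an input type is spatially structured:
#' the statistic is the number of nearest-neighbor column pairs sharing the
#' same label, compared with its permutation null (labels shuffled across
#' columns). A statistic inside the null's central interval supports spatially
#' random wiring; planted spatial bias (e.g. dorsal enrichment) pushes it
#' outside. This is an explicit quantification of a claim usually made by eye;
#' it is an addition to the standard readouts.
#'
#' @param present logical/0-1 vector per column.
#' @param coords matrix or data.frame of column positions (x/y used).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param level central null interval mass (default 0.95).
#' @return list: `statistic` (observed same-label join count), `null`
#'   (permutation values), `interval`, `outside` (logical), `p_value`
#'   (two-sided permutation p).
#' @export
join_count_test <- function(present, coords, n_perm = 999, seed = 1L,
                            level = 0.95) {
  present <- as.logical(present)
  xy <- as.matrix(as.data.frame(coords)[, c("x_nm", "y_nm")])
  stopifnot(nrow(xy) == length(present), n_perm >= 99)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  same <- function(lab) sum(lab == lab[nn])
  obs <- same(present)
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) same(sample(present)),
                                 numeric(1)))
  qs <- stats::quantile(null, c((1 - level) / 2, 1 - (1 - level) / 2))
  p <- (1 + sum(abs(null - mean(null)) >= abs(obs - mean(null)))) /
    (n_perm + 1)
  list(statistic = obs, null = null, interval = unname(qs),
       outside = obs < qs[1] || obs > qs[2], p_value = p)
}
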