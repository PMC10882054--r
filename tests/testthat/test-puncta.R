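# Puncta detection, mask binarization and apposition counting, validated
# against exhaustive oracles and noise-free ground truth.

test_that("well-separated spots are recovered at their planted centers", {
  sv <- simulate_puncta_volume(
    shape_voxels = c(40, 40, 20), voxel_size_nm = c(100, 100, 200),
    puncta = data.frame(x_nm = c(1000, 1500), y_nm = c(1000, 1000),
                        z_nm = c(2000, 2000)),  # 500 nm apart
    noise_sd = 0)
  pk <- detect_puncta(sv$volume, intensity_threshold = 0.3)
  expect_equal(nrow(pk), 2)
  ord <- order(pk$x_nm)
  expect_equal(pk$x_nm[ord], sv$truth$x_nm, tolerance = 100)
  expect_equal(pk$y_nm[ord], sv$truth$y_nm, tolerance = 100)
})

test_that("spots closer than the separation threshold merge to the brighter one", {
  sv <- simulate_puncta_volume(
    shape_voxels = c(40, 40, 20), voxel_size_nm = c(50, 50, 100),
    puncta = data.frame(x_nm = c(1000, 1150), y_nm = 1000, z_nm = 1000,
                        amplitude = c(1, 0.6)),  # 150 nm apart
    spot_sigma_nm = 60, noise_sd = 0)
  pk <- detect_puncta(sv$volume, min_separation_nm = 200,
                      intensity_threshold = 0.3)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$x_nm - 1000), 100)  # the brighter spot
})

test_that("zero puncta and zero noise give a flat channel; 2D input rejected", {
  sv <- simulate_puncta_volume(shape_voxels = c(16, 16, 8), noise_sd = 0)
  expect_true(all(sv$volume$puncta == 0))
  expect_equal(nrow(detect_puncta(sv$volume, intensity_threshold = 0.1)), 0)
  expect_error(detect_puncta(matrix(1, 4, 4), voxel_size_nm = c(1, 1, 1)),
               "3D")
})

test_that("greedy separation matches the all-pairs oracle on spike volumes", {
  set.seed(12)
  vox <- c(100, 100, 250)  # anisotropic
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    dm <- c(24, 24, 12)
    # distinct-intensity delta spikes on a coarse sub-grid: every spike is a
    # 26-neighborhood local maximum
    sub <- expand.grid(i = seq(2, 22, by = 2), j = seq(2, 22, by = 2),
                       k = seq(2, 12, by = 2))
    pick <- sub[sample(nrow(sub), n), ]
    arr <- array(0, dm)
    inten <- sample(seq(1, 2, length.out = n))
    arr[as.matrix(pick)] <- inten
    pk <- detect_puncta(arr, min_separation_nm = 450,
                        intensity_threshold = 0.5, voxel_size_nm = vox)
    pos <- sweep(as.matrix(pick) - 0.5, 2, vox, "*")
    want <- oracle_separate_points(pos, inten, 450)
    got_keys <- sort(paste(pk$i, pk$j, pk$k))
    want_keys <- sort(paste(pick$i[want], pick$j[want], pick$k[want]))
    expect_identical(got_keys, want_keys)
  }
})

test_that("mask binarization thresholds exactly and recovers planted tubes", {
  sv <- simulate_puncta_volume(shape_voxels = c(24, 24, 10), noise_sd = 0,
                               tube_centers_nm = matrix(c(1200, 1200), 1))
  mk <- binarize_mask(sv$volume, threshold = 0.5)
  expect_identical(unname(mk > 0), unname(sv$volume$mask > 0.5))
  expect_gt(attr(mk, "n_voxels"), 0)
  arr <- sv$volume$mask
  expect_true(all(binarize_mask(arr + 1, threshold = 0)))
  expect_warning(empty <- binarize_mask(arr, threshold = max(arr) + 1),
                 "empty")
  expect_false(any(empty))
})

test_that("apposition counts equal ground truth exactly on noise-free volumes", {
  tubes <- as.matrix(expand.grid(x = c(2400, 5600), y = c(2400, 5600)))
  pts <- data.frame(
    x_nm = c(2400, 2400, 5600, 5600, 4000, 3180, 5600),
    y_nm = c(2400, 3100, 5600, 6700, 4000, 2400, 7600),
    z_nm = c(1000, 2000, 3000, 4000, 5000, 6000, 7000))
  sv <- simulate_puncta_volume(
    shape_voxels = c(80, 80, 48), voxel_size_nm = c(100, 100, 200),
    puncta = pts, tube_centers_nm = tubes, tube_radius_nm = 500,
    roi_halfwidth_nm = 1500, noise_sd = 0)
  pk <- detect_puncta(sv$volume, intensity_threshold = 0.3)
  expect_equal(nrow(pk), nrow(pts))
  mk <- binarize_mask(sv$volume, threshold = sv$mask_threshold)
  ap <- count_appositions(pk, mk, sv$roi_labels, sv$volume$voxel_size_nm, 300)
  # recomputed per-ROI counts against the generator's bookkeeping
  tr <- sv$truth
  want <- table(factor(tr$roi[tr$true_distance_nm <= 300 & tr$roi > 0],
                       levels = sort(unique(as.vector(sv$roi_labels)[
                         as.vector(sv$roi_labels) > 0]))))
  expect_equal(as.integer(ap$roi_counts), as.integer(want))
  # distances agree with the planted truth (same punctum order by position)
  ord_got <- order(ap$puncta$z_nm)
  expect_equal(ap$puncta$distance_nm[ord_got], tr$true_distance_nm,
               tolerance = 1e-9)
  # conservation: total apposed = ROI counts + unassigned bucket
  expect_equal(sum(ap$puncta$apposed), sum(ap$roi_counts) + ap$unassigned)
  # inclusive boundary: punctum exactly at threshold distance is counted
  d_exact <- ap$puncta$distance_nm[ord_got][6]
  ap_b <- count_appositions(pk, mk, sv$roi_labels, sv$volume$voxel_size_nm,
                            max_distance_nm = d_exact)
  expect_true(ap_b$puncta$apposed[ord_got][6])
  # monotonicity: shrinking the threshold never increases any ROI count
  for (thr in c(250, 150, 50, 0)) {
    ap_s <- count_appositions(pk, mk, sv$roi_labels,
                              sv$volume$voxel_size_nm, thr)
    expect_true(all(ap_s$roi_counts <= ap$roi_counts))
  }
  # percent-of-columns histogram columns sum to the ROI count
  expect_equal(sum(ap$histogram$n_rois), length(ap$roi_counts))
  expect_equal(sum(ap$histogram$percent), 100)
})

test_that("distance computation agrees with the exhaustive voxel scan", {
  sv <- simulate_puncta_volume(
    shape_voxels = c(20, 20, 10), voxel_size_nm = c(120, 120, 300),
    puncta = data.frame(x_nm = c(500, 1800, 2300), y_nm = c(400, 2000, 900),
                        z_nm = c(600, 1500, 2700)),
    tube_centers_nm = matrix(c(1200, 1200), 1), tube_radius_nm = 300,
    noise_sd = 0)
  mk <- sv$volume$mask > 0.5
  p <- as.matrix(sv$truth[, c("x_nm", "y_nm", "z_nm")])
  got <- colwire:::puncta_mask_distances(p, mk, sv$volume$voxel_size_nm)
  for (i in seq_len(nrow(p)))
    expect_equal(got[i], oracle_mask_distance(p[i, ], mk,
                                              sv$volume$voxel_size_nm),
                 tolerance = 1e-9)
})

test_that("automatic Otsu threshold separates strong spots from background", {
  sv <- simulate_puncta_volume(
    shape_voxels = c(32, 32, 16), voxel_size_nm = c(100, 100, 200),
    puncta = data.frame(x_nm = c(800, 2400), y_nm = c(800, 2400),
                        z_nm = c(1600, 1600)),
    noise_sd = 0.02, seed = 3)
  pk <- detect_puncta(sv$volume)  # Otsu default
  expect_equal(nrow(pk), 2)
})
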