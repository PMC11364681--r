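test_that("threshold_mask matches an exhaustive scan and handles extremes", {
  set.seed(12)
  img <- image_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  for (thr in c(-0.7, 0, 0.9)) {
    m <- threshold_mask(img, thr)
    expect_identical(m$data, array(as.integer(img$data > thr), dim(img$data)))
  }
  expect_true(all(threshold_mask(img, min(img$data) - 1)$data == 1L))
  expect_true(all(threshold_mask(img, max(img$data))$data == 0L))
  expect_error(threshold_mask(img, Inf), "finite")
})

test_that("restrict_above_plane keeps strictly-above slices only", {
  m <- random_mask(c(6, 5, 7), p = 0.5, seed = 8)
  expect_identical(restrict_above_plane(m, 0)$data, m$data)
  expect_true(all(restrict_above_plane(m, 7)$data == 0L))
  for (z in c(2L, 4L)) {
    got <- restrict_above_plane(m, z)
    want <- m$data
    want[, , seq_len(z)] <- 0L
    expect_identical(got$data, want)
    # brute-force count of voxels with axial index > z
    idx <- which(m$data == 1L, arr.ind = TRUE)
    expect_equal(sum(got$data), sum(idx[, 3] > z))
  }
  expect_error(restrict_above_plane(m, 9), "within the grid")
})

test_that("diameter filter agrees with the brute-force inscribed-disc oracle", {
  # analytic discs at the acquisition's in-plane spacing
  expect_gt(sum(filter_by_inplane_diameter(disc_mask(1.2), 2)$data), 0)
  expect_equal(sum(filter_by_inplane_diameter(disc_mask(0.8), 2)$data), 0)
  sv <- binary_mask(array(c(1L, rep(0L, 24)), c(5, 5, 1)),
                    spacing = c(0.3125, 0.3125, 1))
  expect_equal(sum(filter_by_inplane_diameter(sv, 2)$data), 0)

  # randomized slices, anisotropic in-plane spacing
  for (rep in 1:12) {
    set.seed(rep + 100)
    sp <- c(runif(1, 0.3, 1.2), runif(1, 0.3, 1.2), 1)
    m <- binary_mask(array(as.integer(runif(24 * 24 * 2) < 0.35), c(24, 24, 2)),
                     spacing = sp)
    mind <- runif(1, 0.5, 3)
    got <- filter_by_inplane_diameter(m, mind)
    expect_identical(got$data, brute_diameter_filter(m, mind))
    # idempotence
    expect_identical(filter_by_inplane_diameter(got, mind)$data, got$data)
  }
})

test_that("diameter filter is inclusive at exactly the threshold", {
  # 3-voxel-wide strip at 0.5 mm: center pixels sit exactly 1.0 mm from the
  # background, so the inscribed-disc diameter is exactly 2.0 mm
  a <- array(0L, c(9, 12, 1)); a[4:6, 2:11, 1] <- 1L
  m <- binary_mask(a, spacing = c(0.5, 0.5, 1))
  expect_identical(filter_by_inplane_diameter(m, 2.0)$data, a)  # retained at >=
  expect_equal(sum(filter_by_inplane_diameter(m, 2.0 + 1e-6)$data), 0)
})

test_that("measure_dv_volume recovers phantom sheath truth", {
  ph <- small_phantom()
  zmin <- ph$truth$ventricle_top_z
  cfg <- dv_config(PHANTOM_DV_THRESHOLD, zmin,
                   exclusion_masks = list(ph$truth$masks$psd))
  res <- measure_dv_volume(ph$image, cfg)
  truth <- mask_volume_mm3(restrict_above_plane(ph$truth$masks$sheath, zmin))
  expect_gt(truth, 0)
  expect_equal(res$volume_mm3, truth, tolerance = 0.10)
  expect_equal(res$volume_mm3, mask_volume_mm3(res$mask))
  expect_equal(res$n_components + sum(unlist(res$n_removed)), res$n_components_total)

  empty <- measure_dv_volume(ph$image, dv_config(1e6, zmin))
  expect_equal(empty$volume_mm3, 0)
  expect_equal(sum(empty$mask$data), 0)
})

test_that("exclusion masks subtract exactly when diameter classes are unchanged", {
  # one fat disc; exclude a boundary notch that leaves the inscribed disc intact
  img_data <- array(0, c(41, 41, 3))
  img_data[, , 2][disc_mask(5, spacing = 0.5)$data[, , 1] == 1L] <- 10
  img <- image_volume(img_data, spacing = c(0.5, 0.5, 1))
  base <- measure_dv_volume(img, dv_config(5, 0, min_diameter_mm = 2))
  ex <- array(0L, dim(img_data)); ex[20:21, 12, 2] <- 1L  # 2 voxels on the rim
  k <- sum(ex & img_data > 5)
  expect_gt(k, 0)
  res <- measure_dv_volume(img, dv_config(5, 0, min_diameter_mm = 2,
                                          exclusion_masks = list(binary_mask(ex, reference = img))))
  expect_equal(base$volume_mm3 - res$volume_mm3, k * prod(img$spacing))
})

test_that("the segmentation chain is anti-extensive and monotone in threshold", {
  ph <- small_phantom(noise_sd = 5, seed = 6)
  zmin <- ph$truth$ventricle_top_z
  img <- ph$image
  m0 <- threshold_mask(img, PHANTOM_DV_THRESHOLD)
  m1 <- mask_diff(m0, ph$truth$masks$psd)
  m2 <- restrict_above_plane(m1, zmin)
  m3 <- filter_by_inplane_diameter(m2, 2)
  vols <- vapply(list(m0, m1, m2, m3), mask_volume_mm3, numeric(1))
  expect_true(all(diff(vols) <= 0))
  # each stage output is a subset of its input
  expect_true(all(m1$data <= m0$data))
  expect_true(all(m2$data <= m1$data))
  expect_true(all(m3$data <= m2$data))
  # raising the threshold never increases the measured volume
  thresholds <- c(80, 110, 140, 170, 200)
  v <- vapply(thresholds, function(t)
    measure_dv_volume(img, dv_config(t, zmin))$volume_mm3, numeric(1))
  expect_true(all(diff(v) <= 0))
})

test_that("the 3d diameter variant behaves on obvious cases", {
  # a 1-voxel-thick plate: large in-plane, thin in 3D only along z
  a <- array(0L, c(20, 20, 5)); a[4:16, 4:16, 3] <- 1L
  m <- binary_mask(a, spacing = c(1, 1, 0.5))
  expect_gt(sum(filter_by_inplane_diameter(m, 2, mode = "2d")$data), 0)
  got3 <- filter_by_inplane_diameter(m, 2, mode = "3d")
  # in 3D the plate's inscribed ball is limited by its 0.5 mm thickness
  expect_equal(sum(got3$data), 0)
})
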