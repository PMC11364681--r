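test_that("NIfTI write/read round-trips grids, spacing and affine", {
  set.seed(42)
  aff <- rbind(cbind(diag(c(0.3125, 0.3125, 1)), c(-12.5, 4, 7)), c(0, 0, 0, 1))
  v <- image_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                    spacing = c(0.3125, 0.3125, 1), affine = aff)
  for (ext in c(".nii", ".nii.gz")) {
    p <- tempfile(fileext = ext)
    write_nifti(v, p)
    v2 <- read_nifti(p)
    expect_identical(v2$data, v$data)                 # float64 storage is lossless
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(v2$affine, v$affine, tolerance = 1e-5, ignore_attr = TRUE)
    unlink(p)
  }
})

test_that("masks round-trip as uint8 and invalid values are rejected", {
  m <- random_mask(c(5, 4, 3), p = 0.4, spacing = c(0.5, 0.5, 2), seed = 2)
  p <- tempfile(fileext = ".nii.gz")
  write_nifti(m, p)
  m2 <- read_nifti(p)
  expect_equal(array(as.integer(m2$data), dim(m$data)), m$data)
  unlink(p)

  zero <- binary_mask(array(0L, c(3, 3, 3)))
  p2 <- tempfile(fileext = ".nii")
  write_nifti(zero, p2)
  expect_true(all(read_nifti(p2)$data == 0))
  unlink(p2)

  expect_error(binary_mask(array(2L, c(2, 2, 2))), "0 or 1")
  expect_error(read_nifti(tempfile(fileext = ".nii")), "not found")
})

test_that("nibabel agrees on files we write and we read files nibabel writes", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(1)
  v <- image_volume(array(rnorm(6 * 7 * 4), c(6, 7, 4)),
                    spacing = c(0.3125, 0.3125, 1),
                    affine = rbind(cbind(diag(c(0.3125, 0.3125, 1)), c(-10, 5, 2)),
                                   c(0, 0, 0, 1)))
  p <- tempfile(fileext = ".nii.gz")
  write_nifti(v, p)
  out <- system2("python", c("-c", shQuote(sprintf(
    "import nibabel, numpy; i = nibabel.load('%s'); d = numpy.asarray(i.dataobj); print(repr(float(d.sum()))); print(' '.join(str(float(z)) for z in i.header.get_zooms()))",
    p))), stdout = TRUE)
  expect_equal(as.numeric(out[1]), sum(v$data), tolerance = 1e-12)
  expect_equal(scan(text = out[2], quiet = TRUE), v$spacing, tolerance = 1e-6)
  unlink(p)

  # nibabel writes an LPS-oriented volume; read_nifti must reorient to RAS
  # so that world positions are preserved
  p2 <- tempfile(fileext = ".nii.gz")
  system2("python", c("-c", shQuote(sprintf(paste0(
    "import nibabel, numpy; rng = numpy.random.default_rng(5); ",
    "d = rng.normal(size=(5,6,7)).astype(numpy.float64); ",
    "aff = numpy.array([[-0.5,0,0,4],[0,-0.7,0,6],[0,0,1.1,-2],[0,0,0,1]]); ",
    "nibabel.save(nibabel.Nifti1Image(d, aff), '%s'); print(repr(float(d[0,0,0])))"),
    p2))), stdout = TRUE) -> out2
  v2 <- read_nifti(p2)
  expect_equal(diag(v2$affine[1:3, 1:3]), c(0.5, 0.7, 1.1), tolerance = 1e-5)
  # original voxel (0,0,0) sits at world (4,6,-2) -> reoriented index (5,6,1)
  expect_equal(v2$data[5, 6, 1], as.numeric(out2[1]), tolerance = 1e-12)
  unlink(p2)
})

test_that("non-3D payloads are rejected", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  p <- tempfile(fileext = ".nii")
  system2("python", c("-c", shQuote(sprintf(
    "import nibabel, numpy; nibabel.save(nibabel.Nifti1Image(numpy.zeros((3,3,3,2), dtype=numpy.float32), numpy.eye(4)), '%s')",
    p))))
  expect_error(read_nifti(p), "not 3D")
  unlink(p)
})

test_that("mask volume is the voxel count times the voxel volume", {
  one <- array(0L, c(4, 4, 2)); one[2, 3, 1] <- 1L
  m <- binary_mask(one, spacing = c(0.3125, 0.3125, 1))
  expect_equal(mask_volume_mm3(m), 0.09765625)
  expect_equal(mask_volume_mm3(binary_mask(array(0L, c(3, 3, 3)))), 0)
})

test_that("mask volume is additive over disjoint masks and monotone under inclusion", {
  set.seed(3)
  for (rep in 1:5) {
    a <- random_mask(c(7, 6, 5), p = 0.3, spacing = c(0.4, 0.9, 1.3), seed = rep)
    b <- binary_mask(a$data & random_mask(c(7, 6, 5), p = 0.5, seed = rep + 50)$data,
                     reference = a)                       # b is a subset of a
    expect_lte(mask_volume_mm3(b), mask_volume_mm3(a))
    comp <- mask_diff(a, b)
    expect_equal(mask_volume_mm3(b) + mask_volume_mm3(comp), mask_volume_mm3(a))
  }
})

test_that("rasterized sphere volume approaches the analytic value", {
  # radius 5 mm on a 0.5 mm isotropic grid vs 4/3 pi r^3
  n <- 31L; sp <- 0.5
  ctr <- (n - 1) / 2 * sp
  g <- expand.grid(x = (0:(n - 1)) * sp, y = (0:(n - 1)) * sp, z = (0:(n - 1)) * sp)
  inside <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 25
  m <- binary_mask(array(as.integer(inside), c(n, n, n)), spacing = rep(sp, 3))
  expect_equal(mask_volume_mm3(m), 4 / 3 * pi * 125, tolerance = 0.05)
})
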