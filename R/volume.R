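# Core containers: image volumes and binary masks on a common voxel grid.
# The third array axis is the transverse (axial) stack direction, index
# increasing toward the vertex; all physical quantities are in mm.

#' Construct a 3D image volume
#'
#' An `image_volume` couples a 3D intensity array with its voxel spacing and a
#' voxel-to-world affine. The third axis is the axial (transverse) direction,
#' with index increasing toward the vertex.
#'
#' @param data 3D numeric array of intensities (finite values).
#' @param spacing numeric length-3 voxel spacing `(dx, dy, dz)` in mm.
#' @param affine 4x4 voxel-to-world transform in mm; defaults to
#'   `diag(c(spacing, 1))` (RAS axes, origin at the first voxel center,
#'   0-based voxel indices).
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `affine`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 2)), spacing = c(0.3125, 0.3125, 1))
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  v <- structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
                 class = "image_volume")
  validate_image_volume(v)
  v
}

validate_image_volume <- function(v) {
  if (!is.array(v$data) || length(dim(v$data)) != 3L)
    stop("image data must be a 3D array", call. = FALSE)
  if (length(v$spacing) != 3L || any(!is.finite(v$spacing)) || any(v$spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  if (!is.matrix(v$affine) || any(dim(v$affine) != c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (abs(det(v$affine)) < .Machine$double.eps)
    stop("affine must be invertible", call. = FALSE)
  if (any(!is.finite(v$data)))
    stop("intensity values must be finite", call. = FALSE)
  invisible(v)
}

#' Construct a binary mask aligned to an image grid
#'
#' @param data 3D array with values in `{0, 1}` (logical arrays are accepted).
#' @param spacing,affine grid geometry; ignored when `reference` is given.
#' @param reference optional `image_volume` or `binary_mask` supplying the
#'   geometry; shapes must match exactly.
#' @return An object of class `binary_mask` (fields as in [image_volume()],
#'   `data` stored as an integer array).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL, reference = NULL) {
  if (!is.null(reference)) {
    if (!identical(dim(data), dim(reference$data)))
      stop("mask shape does not match the reference grid", call. = FALSE)
    spacing <- reference$spacing
    affine <- reference$affine
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  storage <- array(as.integer(data), dim(data))
  m <- structure(list(data = storage, spacing = as.numeric(spacing), affine = affine),
                 class = c("binary_mask", "image_volume"))
  validate_binary_mask(m)
  m
}

validate_binary_mask <- function(m, reference = NULL) {
  if (!is.array(m$data) || length(dim(m$data)) != 3L)
    stop("mask data must be a 3D array", call. = FALSE)
  bad <- !(m$data %in% c(0L, 1L))
  if (any(bad))
    stop("mask values must be 0 or 1", call. = FALSE)
  if (length(m$spacing) != 3L || any(!is.finite(m$spacing)) || any(m$spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  if (!is.null(reference)) {
    if (!identical(dim(m$data), dim(reference$data)))
      stop("mask grid shape does not match the paired image", call. = FALSE)
    if (!isTRUE(all.equal(m$spacing, reference$spacing, tolerance = 1e-6)))
      stop("mask spacing does not match the paired image", call. = FALSE)
  }
  invisible(m)
}

#' Is an object an image volume / binary mask?
#' @param x object to test.
#' @return logical.
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

#' @rdname is_image_volume
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Physical volume of a binary mask
#'
#' Converts a voxel count to a physical volume:
#' `sum(mask) * dx * dy * dz` in mm^3. Additive over disjoint masks and
#' monotone under mask inclusion.
#'
#' @param mask a [binary_mask()].
#' @return volume in mm^3 (scalar).
#' @examples
#' m <- binary_mask(array(c(1, rep(0, 7)), c(2, 2, 2)), spacing = c(0.3125, 0.3125, 1))
#' mask_volume_mm3(m) # 0.09765625
#' @export
mask_volume_mm3 <- function(mask) {
  validate_binary_mask(mask)
  sum(mask$data) * prod(mask$spacing)
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (is_binary_mask(x)) "binary_mask" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 6), collapse = " x ")))
  if (is_binary_mask(x))
    cat(sprintf("  %d foreground voxels, %.3f mm^3\n", sum(x$data), mask_volume_mm3(x)))
  else
    cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

# elementwise set operations used throughout the segmentation chains
mask_and <- function(a, b) binary_mask(a$data & b$data, reference = a)
mask_or <- function(a, b) binary_mask(a$data | b$data, reference = a)
mask_diff <- function(a, b) binary_mask(a$data & !b$data, reference = a)
mask_not <- function(a) binary_mask(!a$data, reference = a)
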