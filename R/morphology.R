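# Morphological primitives on binary masks, anisotropy-aware: all distances are
# Euclidean in mm between voxel centers (exact separable EDT in C++), so the
# same structuring radius means the same physical ball on any grid.

#' Connected-component labelling
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26 (3D). For a single-slice grid, 26 reduces
#'   to in-plane 8-connectivity.
#' @return integer array of labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  validate_binary_mask(mask)
  lab <- .cc_label(as.integer(mask$data), dim(mask$data), as.integer(connectivity))
  out <- array(lab, dim(mask$data))
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

#' Euclidean distance transform (mm)
#'
#' Per-voxel Euclidean distance, in physical units, from each voxel center to
#' the nearest foreground voxel center of `mask` (0 on the foreground itself).
#'
#' @param mask a [binary_mask()] marking the feature set.
#' @return numeric array of distances in mm (Inf if the mask is empty).
#' @export
edt_mm <- function(mask) {
  validate_binary_mask(mask)
  d2 <- .edt_sq(as.integer(mask$data), dim(mask$data), mask$spacing)
  d2[d2 >= 1e29] <- Inf  # no feature voxel anywhere
  array(sqrt(d2), dim(mask$data))
}

#' Morphological dilation / erosion / closing with a Euclidean ball
#'
#' `dilate_mm` adds all voxels within `radius_mm` of the foreground;
#' `erode_mm` keeps voxels farther than `radius_mm` from the background;
#' `close_mm` is dilation followed by erosion (fills gaps and concavities up
#' to the ball scale without shrinking the object).
#'
#' @param mask a [binary_mask()].
#' @param radius_mm ball radius in mm (>= 0).
#' @return a [binary_mask()] on the same grid.
#' @export
dilate_mm <- function(mask, radius_mm) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  d <- edt_mm(mask)
  binary_mask(d <= radius_mm, reference = mask)
}

#' @rdname dilate_mm
#' @export
erode_mm <- function(mask, radius_mm) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  d <- edt_mm(mask_not(mask))
  binary_mask(mask$data == 1L & d > radius_mm, reference = mask)
}

#' @rdname dilate_mm
#' @export
close_mm <- function(mask, radius_mm) {
  erode_mm(dilate_mm(mask, radius_mm), radius_mm)
}

#' Keep the largest connected component
#'
#' @param mask a [binary_mask()].
#' @param connectivity passed to [label_components()] (default 26).
#' @return a [binary_mask()]; empty input yields an empty mask.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L) return(mask)
  counts <- tabulate(lab[lab > 0L], nbins = ncomp)
  binary_mask(lab == which.max(counts), reference = mask)
}

#' Fill interior cavities of a mask
#'
#' Background voxels not 6-connected to the grid border become foreground.
#'
#' @param mask a [binary_mask()].
#' @return a [binary_mask()] with all enclosed cavities filled.
#' @export
fill_holes <- function(mask) {
  validate_binary_mask(mask)
  bg <- mask_not(mask)
  lab <- label_components(bg, connectivity = 6L)
  n <- dim(mask$data)
  border_labels <- unique(c(
    lab[c(1, n[1]), , ], lab[, c(1, n[2]), ], lab[, , c(1, n[3])]))
  border_labels <- border_labels[border_labels > 0L]
  holes <- lab > 0L & !(lab %in% border_labels)
  binary_mask(mask$data == 1L | holes, reference = mask)
}

#' Otsu threshold over the nonzero voxels of an image
#'
#' Maximizes between-class variance on a 256-bin histogram of the nonzero
#' intensities. Offered as a helper (e.g. for [estimate_icv()]); segmentation
#' functions never apply it silently.
#'
#' @param image an [image_volume()].
#' @return threshold on the intensity scale.
#' @export
otsu_threshold <- function(image) {
  validate_image_volume(image)
  x <- image$data[image$data != 0]
  if (length(x) == 0 || diff(range(x)) == 0)
    stop("image has no nonzero intensity range", call. = FALSE)
  nb <- 256L
  br <- seq(min(x), max(x), length.out = nb + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nb)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}
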