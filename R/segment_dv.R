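# Volumetry of the contrast-enhanced space surrounding the diploic veins:
# intensity threshold -> subtract operator-supplied exclusion masks (the
# manually excluded reticular regions) -> keep only transverse slices above
# the superior border of the lateral ventricles -> keep only components whose
# in-plane inscribed-disc diameter is >= 2 mm. Every stage is anti-extensive,
# so the measured volume is monotone non-increasing along the chain.

#' Threshold an image into a binary mask
#'
#' A voxel is foreground iff its intensity strictly exceeds `threshold` (the
#' "predetermined value" of the extraction rule). The threshold is a required
#' input; see [otsu_threshold()] for a data-driven suggestion, which is never
#' applied silently.
#'
#' @param image an [image_volume()].
#' @param threshold finite intensity cutoff (signal units).
#' @return a [binary_mask()].
#' @export
threshold_mask <- function(image, threshold) {
  validate_image_volume(image)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  binary_mask(image$data > threshold, reference = image)
}

#' Restrict a mask to slices above an axial plane
#'
#' Keeps voxels with axial index strictly greater than `z_min` (1-based); the
#' plane's own slice is excluded — "above the superior border of the lateral
#' ventricles" is read exclusively. Pass `z_min = 0` to keep everything.
#'
#' @param mask a [binary_mask()].
#' @param z_min axial slice index of the superior border of the lateral
#'   ventricles (0 .. nz).
#' @return a [binary_mask()].
#' @export
restrict_above_plane <- function(mask, z_min) {
  validate_binary_mask(mask)
  nz <- dim(mask$data)[3]
  if (z_min < 0 || z_min > nz)
    stop("z_min must lie within the grid (0 .. nz)", call. = FALSE)
  out <- mask$data
  if (z_min >= 1) out[, , seq_len(min(z_min, nz))] <- 0L
  binary_mask(out, reference = mask)
}

#' Filter mask components by in-plane inscribed-disc diameter
#'
#' Per transverse slice, 8-connected 2D components are retained iff their
#' maximum inscribed-disc diameter — twice the maximum of the in-plane
#' Euclidean distance transform to the background, computed with physical
#' spacing — is at least `min_diameter_mm` (inclusive at the threshold,
#' matching the ">= 2 mm" rule). A 3D variant (26-connected components, 3D
#' EDT) is available via `mode = "3d"` but is not the default: the ROIs are
#' defined on transverse slices and the axial spacing is coarse relative to
#' the 2 mm criterion.
#'
#' @param mask a [binary_mask()].
#' @param min_diameter_mm minimum retained diameter (mm), default 2.
#' @param mode `"2d"` (slice-wise, default) or `"3d"`.
#' @return a [binary_mask()] with attributes `n_components_total` and
#'   `n_components_removed`.
#' @export
filter_by_inplane_diameter <- function(mask, min_diameter_mm = 2.0, mode = c("2d", "3d")) {
  validate_binary_mask(mask)
  mode <- match.arg(mode)
  if (min_diameter_mm <= 0) stop("min_diameter_mm must be > 0", call. = FALSE)
  eps <- 1e-9
  out <- mask$data
  total <- 0L; removed <- 0L
  if (mode == "3d") {
    lab <- label_components(mask, 26L)
    total <- attr(lab, "n_components")
    if (total > 0L) {
      d <- edt_mm(mask_not(mask))
      dmax <- vapply(seq_len(total), function(l) max(d[lab == l]), numeric(1))
      drop <- which(2 * dmax < min_diameter_mm - eps)
      removed <- length(drop)
      out[lab %in% drop] <- 0L
    }
  } else {
    dims <- dim(mask$data)
    sl_dim <- c(dims[1], dims[2], 1L)
    sp2 <- c(mask$spacing[1], mask$spacing[2], 1)
    for (k in seq_len(dims[3])) {
      sl <- mask$data[, , k]
      if (!any(sl == 1L)) next
      lab <- .cc_label(as.integer(sl), sl_dim, 26L)  # 8-connectivity in-plane
      ncomp <- attr(lab, "n_components")
      total <- total + ncomp
      d <- sqrt(.edt_sq(as.integer(sl == 0L), sl_dim, sp2))
      dmax <- vapply(seq_len(ncomp), function(l) max(d[lab == l]), numeric(1))
      drop <- which(2 * dmax < min_diameter_mm - eps)
      removed <- removed + length(drop)
      if (length(drop)) {
        sl[array(lab, dims[1:2]) %in% drop] <- 0L
        out[, , k] <- sl
      }
    }
  }
  res <- binary_mask(out, reference = mask)
  attr(res, "n_components_total") <- total
  attr(res, "n_components_removed") <- removed
  res
}

#' Configuration for perivenous-space volumetry
#'
#' @param intensity_threshold required intensity cutoff (signal units).
#' @param z_min axial index of the superior border of the lateral ventricles
#'   (slices strictly above it are measured).
#' @param min_diameter_mm minimum in-plane component diameter (default 2 mm).
#' @param exclusion_masks list of [binary_mask()]s to subtract after
#'   thresholding (reticular high-signal regions, other non-target
#'   enhancement); models the operator's manual exclusions.
#' @param diameter_mode `"2d"` or `"3d"`, see [filter_by_inplane_diameter()].
#' @return a `dv_config` list.
#' @export
dv_config <- function(intensity_threshold, z_min, min_diameter_mm = 2.0,
                      exclusion_masks = list(), diameter_mode = "2d") {
  stopifnot(is.finite(intensity_threshold), min_diameter_mm > 0)
  structure(list(intensity_threshold = intensity_threshold, z_min = z_min,
                 min_diameter_mm = min_diameter_mm,
                 exclusion_masks = exclusion_masks,
                 diameter_mode = diameter_mode),
            class = "dv_config")
}

volume_result <- function(mask, n_total, n_removed, config) {
  structure(list(volume_mm3 = mask_volume_mm3(mask), mask = mask,
                 n_components = n_total - sum(unlist(n_removed)),
                 n_components_total = n_total, n_removed = n_removed,
                 config = config),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %.3f mm^3; %d/%d components retained\n",
              x$volume_mm3, x$n_components, x$n_components_total))
  for (nm in names(x$n_removed))
    cat(sprintf("  removed by %s: %d\n", nm, x$n_removed[[nm]]))
  invisible(x)
}

#' Measure the volume of the space surrounding the diploic veins
#'
#' Full measurement chain: [threshold_mask()] -> subtract all
#' `exclusion_masks` -> [restrict_above_plane()] ->
#' [filter_by_inplane_diameter()]. Deterministic; component bookkeeping is
#' returned alongside the volume.
#'
#' @param image an [image_volume()].
#' @param config a [dv_config()].
#' @return a `volume_result`: `volume_mm3`, retained `mask`, component
#'   counts, and the config echo.
#' @export
measure_dv_volume <- function(image, config) {
  stopifnot(inherits(config, "dv_config"))
  m <- threshold_mask(image, config$intensity_threshold)
  for (ex in config$exclusion_masks) {
    validate_binary_mask(ex, reference = m)
    m <- mask_diff(m, ex)
  }
  m <- restrict_above_plane(m, config$z_min)
  f <- filter_by_inplane_diameter(m, config$min_diameter_mm,
                                  mode = config$diameter_mode)
  volume_result(f, attr(f, "n_components_total"),
                list(diameter_filter = attr(f, "n_components_removed")),
                config)
}
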