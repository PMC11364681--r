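# Parasagittal-dura volumetry: the same threshold rule, restricted to a 1 cm
# Euclidean band around the outer edge of the superior sagittal sinus, with
# parenchymal and intra-skull enhancement removed by caller-supplied masks
# (the protocol's manual clean-up step, kept explicit and reproducible). No diameter
# filter is applied to the PSD.

#' Band of voxels within a distance of the SSS surface
#'
#' Returns the voxels outside the SSS whose 3D Euclidean distance (physical
#' units, anisotropy-aware) to the SSS is at most `band_width_mm`; SSS voxels
#' themselves are excluded ("from the outer edge of the SSS").
#'
#' @param sss_mask non-empty [binary_mask()] of the superior sagittal sinus.
#' @param band_width_mm band width in mm (default 10 = the 1 cm rule).
#' @return a [binary_mask()], disjoint from `sss_mask`.
#' @export
sss_band <- function(sss_mask, band_width_mm = 10.0) {
  validate_binary_mask(sss_mask)
  if (sum(sss_mask$data) == 0L) stop("sss_mask is empty", call. = FALSE)
  if (band_width_mm <= 0) stop("band_width_mm must be > 0", call. = FALSE)
  d <- edt_mm(sss_mask)
  binary_mask(d > 0 & d <= band_width_mm, reference = sss_mask)
}

#' Configuration for PSD volumetry
#'
#' @param intensity_threshold intensity cutoff (signal units).
#' @param z_min axial index of the superior border of the lateral ventricles.
#' @param band_width_mm distance band around the SSS (default 10 mm).
#' @param brain_mask,skull_mask optional [binary_mask()]s subtracted from the
#'   result (high signal in the parenchyma / within the skull).
#' @return a `psd_config` list.
#' @export
psd_config <- function(intensity_threshold, z_min, band_width_mm = 10.0,
                       brain_mask = NULL, skull_mask = NULL) {
  stopifnot(is.finite(intensity_threshold), band_width_mm > 0)
  structure(list(intensity_threshold = intensity_threshold, z_min = z_min,
                 band_width_mm = band_width_mm,
                 brain_mask = brain_mask, skull_mask = skull_mask),
            class = "psd_config")
}

#' Measure the parasagittal-dura volume
#'
#' Chain: [threshold_mask()] -> intersect with [sss_band()] ->
#' [restrict_above_plane()] -> subtract `brain_mask` and `skull_mask`.
#' The output mask is contained in the band and disjoint from the SSS, brain
#' and skull masks by construction.
#'
#' @param image an [image_volume()].
#' @param sss_mask non-empty [binary_mask()] of the SSS, aligned to `image`.
#' @param config a [psd_config()].
#' @return a `volume_result` (see [measure_dv_volume()]).
#' @export
measure_psd_volume <- function(image, sss_mask, config) {
  stopifnot(inherits(config, "psd_config"))
  validate_binary_mask(sss_mask, reference = image)
  m <- threshold_mask(image, config$intensity_threshold)
  m <- mask_and(m, sss_band(sss_mask, config$band_width_mm))
  m <- restrict_above_plane(m, config$z_min)
  for (nm in c("brain_mask", "skull_mask")) {
    ex <- config[[nm]]
    if (!is.null(ex)) {
      validate_binary_mask(ex, reference = m)
      m <- mask_diff(m, ex)
    }
  }
  n_total <- attr(label_components(m, 26L), "n_components")
  volume_result(m, n_total, list(), config)
}
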