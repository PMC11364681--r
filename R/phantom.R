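# Synthetic cranial phantom: an ellipsoidal skull (outer table / diploe /
# inner table) around a brain + CSF interior, tubular diploic veins whose
# lumen is signal-suppressed and whose surrounding sheath is high-signal, a
# dark midline SSS tube under the vertex, and high-signal PSD blobs in the
# dural gap next to the SSS. Every structure is recorded as a ground-truth
# mask so segmentation output can be compared voxel-for-voxel.

# evaluate `code` under a temporary RNG state (restores the caller's stream)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Default cranial phantom specification
#'
#' Geometry and signal model for [build_phantom()]. Defaults describe a
#' head-sized vault on a 0.625 x 0.625 x 1 mm grid: skull outer semi-axes
#' 54/58/72 mm with 1.5 mm tables around a 7 mm diploe; four diploic veins
#' (0.6 mm suppressed lumen inside a 2.4 mm high-signal sheath, so every
#' sheath cross-section comfortably exceeds the 2 mm diameter criterion, as
#' the measured perivenous spaces do by definition); a 4 mm-radius midline
#' SSS tube; and four PSD blobs in the 4 mm dural gap beside the SSS.
#' Intensities are compartment means in arbitrary signal units with the
#' ordering high-signal > CSF/brain > diploe > tables > lumen; noise is
#' additive Gaussian.
#'
#' @param shape grid size in voxels (x, y, z); z is axial.
#' @param spacing voxel spacing in mm.
#' @param outer_semiaxes skull outer ellipsoid semi-axes (mm).
#' @param outer_table,diploe,inner_table skull layer thicknesses (mm).
#' @param dural_gap CSF/dura gap between brain surface and inner table (mm).
#' @param vein_azimuth_deg azimuths of the vein meridian arcs (degrees).
#' @param vein_theta_deg polar-angle span of each vein arc (degrees from the
#'   vertex).
#' @param lumen_radius,sheath_thickness vein lumen radius and perivenous
#'   sheath thickness (mm).
#' @param sss_radius SSS tube radius (mm).
#' @param sss_arc_deg polar span of the SSS arc in the midsagittal plane.
#' @param psd_arc_deg polar positions of the PSD blobs along the SSS.
#' @param psd_offset_mm lateral distance of blob centers from the SSS axis.
#' @param psd_radius PSD blob radius (mm).
#' @param ventricle_top_offset_mm height of the lateral-ventricle superior
#'   border above the grid's axial mid-plane (mm); sets `ventricle_top_z`.
#' @param intensities named compartment means (signal units).
#' @param noise_sd additive Gaussian noise SD (signal units).
#' @param seed RNG seed for the noise draw.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(184L, 196L, 160L),
                         spacing = c(0.625, 0.625, 1.0),
                         outer_semiaxes = c(54, 58, 72),
                         outer_table = 1.5, diploe = 7, inner_table = 1.5,
                         dural_gap = 4,
                         vein_azimuth_deg = c(40, 130, 220, 310),
                         vein_theta_deg = c(14, 55),
                         lumen_radius = 0.6, sheath_thickness = 2.4,
                         sss_radius = 4, sss_arc_deg = c(-60, 60),
                         psd_arc_deg = c(-28, -12, 6, 22),
                         psd_offset_mm = 7, psd_radius = 2.6,
                         ventricle_top_offset_mm = 12,
                         intensities = c(air = 0, table = 20, diploe = 60,
                                         brain = 100, csf = 90, sheath = 180,
                                         lumen = 10, sss = 10, psd = 180),
                         noise_sd = 0, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            all(spacing > 0), all(outer_semiaxes > 0),
            sheath_thickness > 0, lumen_radius >= 0)
  ints <- intensities
  if (!(ints["sheath"] > ints["diploe"] && ints["diploe"] > ints["lumen"]))
    stop("intensity ordering must satisfy sheath > diploe > lumen", call. = FALSE)
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               outer_semiaxes = outer_semiaxes, outer_table = outer_table,
               diploe = diploe, inner_table = inner_table, dural_gap = dural_gap,
               vein_azimuth_deg = vein_azimuth_deg, vein_theta_deg = vein_theta_deg,
               lumen_radius = lumen_radius, sheath_thickness = sheath_thickness,
               sss_radius = sss_radius, sss_arc_deg = sss_arc_deg,
               psd_arc_deg = psd_arc_deg, psd_offset_mm = psd_offset_mm,
               psd_radius = psd_radius,
               ventricle_top_offset_mm = ventricle_top_offset_mm,
               intensities = ints, noise_sd = noise_sd, seed = seed)
  center <- (spec$shape - 1) * spec$spacing / 2
  spec$center <- center
  t_total <- outer_table + diploe + inner_table
  if (any(outer_semiaxes <= t_total + dural_gap + 2))
    stop("skull semi-axes too small for the configured layer thicknesses", call. = FALSE)
  spec$ventricle_top_z <- as.integer(round((center[3] + ventricle_top_offset_mm) /
                                             spec$spacing[3]) + 1L)  # 1-based axial index
  if (spec$ventricle_top_z < 1L || spec$ventricle_top_z > spec$shape[3])
    stop("ventricle_top_z falls outside the grid", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

# boolean array: inside the ellipsoid with semi-axes `semi` centered at `center`
rasterize_ellipsoid <- function(shape, spacing, center, semi) {
  cx <- (seq_len(shape[1]) - 1) * spacing[1]
  cy <- (seq_len(shape[2]) - 1) * spacing[2]
  cz <- (seq_len(shape[3]) - 1) * spacing[3]
  e1 <- ((cx - center[1]) / semi[1])^2
  e2 <- ((cy - center[2]) / semi[2])^2
  e3 <- ((cz - center[3]) / semi[3])^2
  outer(outer(e1, e2, "+"), e3, "+") <= 1
}

grid_origin <- function(geometry) geometry$affine[1:3, 4]

#' Rasterize a tube (capsule chain) into a voxel grid
#'
#' Marks every voxel whose center lies within `radius` of the polyline
#' interpolated between consecutive control points (capsules, i.e. cylinders
#' with spherical caps). Requires an axis-aligned affine.
#'
#' @param centerline numeric matrix (>= 2 rows) of control points in mm
#'   (world coordinates).
#' @param radius tube radius in mm; `0` gives an empty mask.
#' @param geometry an [image_volume()] or [binary_mask()] providing the grid.
#' @return a [binary_mask()] on `geometry`'s grid.
#' @export
rasterize_tube <- function(centerline, radius, geometry) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L)
    stop("centerline must have at least 2 points", call. = FALSE)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  A <- geometry$affine[1:3, 1:3]
  if (max(abs(A - diag(geometry$spacing))) > 1e-6)
    stop("rasterize_tube requires an axis-aligned (RAS) grid", call. = FALSE)
  shape <- dim(geometry$data)
  if (radius == 0)
    return(binary_mask(array(0L, shape), reference = geometry))
  segs <- cbind(centerline[-nrow(centerline), , drop = FALSE],
                centerline[-1, , drop = FALSE])
  m <- .raster_capsules(shape, geometry$spacing, grid_origin(geometry),
                        segs, radius)
  binary_mask(array(m, shape), reference = geometry)
}

# points on the ellipsoid with semi-axes `semi`, polar angle theta (from +z),
# azimuth phi (from +x in the xy plane), all in radians
ellipsoid_point <- function(center, semi, theta, phi) {
  cbind(center[1] + semi[1] * sin(theta) * cos(phi),
        center[2] + semi[2] * sin(theta) * sin(phi),
        center[3] + semi[3] * cos(theta))
}

#' Build a cranial phantom with ground truth
#'
#' Synthesizes the intensity image and all ground-truth masks for a
#' [phantom_spec()]. Structures are painted as a disjoint partition (lumen
#' and SSS override their surroundings last), so truth masks are pairwise
#' disjoint where anatomy demands and the noiseless image is exactly
#' piecewise-constant at the compartment means. The same spec and seed give
#' voxel-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom` with elements `image`
#'   ([image_volume()]), `truth` (masks `sheath`, `lumen`, `sss`, `psd`,
#'   `brain`, `skull`, `ventricle`; `true_volumes` in mm^3 with an
#'   `icv_analytic_mm3` closed form; `ventricle_top_z`), and `spec`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; sp <- spec$spacing; ctr <- spec$center
  a <- spec$outer_semiaxes
  lv <- list(outer = a,
             diploe_top = a - spec$outer_table,
             diploe_bot = a - spec$outer_table - spec$diploe,
             inner = a - spec$outer_table - spec$diploe - spec$inner_table)
  lv$brain <- lv$inner - spec$dural_gap

  inside <- lapply(lv, function(s) rasterize_ellipsoid(shape, sp, ctr, s))
  # region codes, painted outside-in
  AIR <- 0L; TABLE <- 1L; DIPLOE <- 2L; CSF <- 3L; BRAIN <- 4L
  SHEATH <- 5L; LUMEN <- 6L; PSD <- 7L; SSS <- 8L
  reg <- array(AIR, shape)
  reg[inside$outer] <- TABLE
  reg[inside$diploe_top] <- DIPLOE
  reg[inside$diploe_bot] <- TABLE
  reg[inside$inner] <- CSF
  reg[inside$brain] <- BRAIN

  geom <- binary_mask(array(0L, shape), spacing = sp)

  # diploic veins: meridian arcs at mid-diploe depth
  semi_mid <- a - spec$outer_table - spec$diploe / 2
  th <- seq(spec$vein_theta_deg[1], spec$vein_theta_deg[2], length.out = 24) * pi / 180
  outer_tube <- array(FALSE, shape); lumen_tube <- array(FALSE, shape)
  for (phi_deg in spec$vein_azimuth_deg) {
    line <- ellipsoid_point(ctr, semi_mid, th, phi_deg * pi / 180)
    outer_tube <- outer_tube |
      rasterize_tube(line, spec$lumen_radius + spec$sheath_thickness, geom)$data == 1L
    if (spec$lumen_radius > 0)
      lumen_tube <- lumen_tube | rasterize_tube(line, spec$lumen_radius, geom)$data == 1L
  }
  in_diploe <- reg == DIPLOE
  sheath <- outer_tube & !lumen_tube
  lumen <- lumen_tube
  if (any(sheath & !in_diploe) || any(lumen & !in_diploe))
    warning("vein tube extends outside the diploe; clipped", call. = FALSE)
  sheath <- sheath & in_diploe
  lumen <- lumen & in_diploe
  reg[sheath] <- SHEATH
  reg[lumen] <- LUMEN

  # SSS: midsagittal arc tangent to the brain surface under the vertex
  phs <- seq(spec$sss_arc_deg[1], spec$sss_arc_deg[2], length.out = 40) * pi / 180
  sss_line <- cbind(ctr[1],
                    ctr[2] + (lv$inner[2] - spec$sss_radius) * sin(phs),
                    ctr[3] + (lv$inner[3] - spec$sss_radius) * cos(phs))
  sss <- rasterize_tube(sss_line, spec$sss_radius, geom)$data == 1L & inside$inner

  # PSD blobs in the dural gap, alternating sides of the SSS
  side <- rep(c(1, -1), length.out = length(spec$psd_arc_deg))
  psd <- array(FALSE, shape)
  for (i in seq_along(spec$psd_arc_deg)) {
    ph <- spec$psd_arc_deg[i] * pi / 180
    cen <- c(ctr[1] + side[i] * spec$psd_offset_mm,
             ctr[2] + (lv$inner[2] - spec$sss_radius) * sin(ph),
             ctr[3] + (lv$inner[3] - spec$sss_radius) * cos(ph))
    blob <- rasterize_tube(rbind(cen, cen + 1e-9), spec$psd_radius, geom)$data == 1L
    psd <- psd | blob
  }
  psd <- psd & reg == CSF & !sss
  reg[psd] <- PSD
  reg[sss] <- SSS

  ints <- spec$intensities
  lut <- c(ints["air"], ints["table"], ints["diploe"], ints["csf"], ints["brain"],
           ints["sheath"], ints["lumen"], ints["psd"], ints["sss"])
  img_data <- array(lut[reg + 1L], shape)
  if (spec$noise_sd > 0)
    img_data <- img_data + with_seed(spec$seed,
                                     array(rnorm(length(img_data), 0, spec$noise_sd), shape))
  image <- image_volume(img_data, spacing = sp)

  # ventricle landmark: small sphere whose superior border sits at ventricle_top_z
  zv_world <- (spec$ventricle_top_z - 1) * sp[3]
  vcen <- c(ctr[1], ctr[2], zv_world - 6)
  vent <- rasterize_tube(rbind(vcen, vcen + 1e-9), 6, geom)$data == 1L & reg == BRAIN

  msk <- function(x) binary_mask(x, reference = geom)
  masks <- list(sheath = msk(reg == SHEATH), lumen = msk(reg == LUMEN),
                sss = msk(reg == SSS), psd = msk(reg == PSD),
                brain = msk(reg == BRAIN),
                skull = msk(inside$outer & !inside$inner),
                ventricle = msk(vent))
  true_volumes <- lapply(masks, mask_volume_mm3)
  true_volumes$icv_analytic_mm3 <- 4 / 3 * pi * prod(lv$inner)
  true_volumes$icv_rasterized_mm3 <- mask_volume_mm3(msk(inside$inner))

  structure(list(image = image, truth = list(masks = masks,
                                             true_volumes = true_volumes,
                                             ventricle_top_z = spec$ventricle_top_z),
                 spec = spec),
            class = "phantom")
}
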