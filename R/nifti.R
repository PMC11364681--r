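# Minimal NIfTI-1 reader/writer in base R. The frozen toolchain ships no NIfTI
# package, so the single-file format (.nii / .nii.gz) is handled directly:
# sform/qform affines, the common datatypes, scl_slope/scl_inter scaling, and
# both byte orders on read. Written files use float64 for images (lossless
# round trip) and uint8 for masks, sform_code = 2, little-endian.

NIFTI_HDR_SIZE <- 348L

nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`), applies
#' `scl_slope`/`scl_inter` scaling when present, and reorients the array so
#' its axes follow the RAS convention (third axis axial, increasing toward
#' the vertex). Spacing is derived from the affine column norms.
#'
#' @param path path to an existing `.nii` / `.nii.gz` file.
#' @return an [image_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  raw_hdr <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(raw_hdr) < NIFTI_HDR_SIZE) stop("not a NIfTI-1 file (short header): ", path, call. = FALSE)

  parse_hdr <- function(endian) {
    rc <- rawConnection(raw_hdr)
    on.exit(close(rc), add = TRUE)
    rd <- function(what, n, size, signed = TRUE)
      readBin(rc, what, n = n, size = size, endian = endian, signed = signed)
    h <- list()
    h$sizeof_hdr <- rd("integer", 1, 4)
    invisible(rd("raw", 35, 1))             # data_type, db_name, extents, session_error, regular
    h$dim_info <- rd("raw", 1, 1)
    h$dim <- rd("integer", 8, 2)
    invisible(rd("double", 3, 4))           # intent_p1..3
    invisible(rd("integer", 1, 2))          # intent_code
    h$datatype <- rd("integer", 1, 2)
    h$bitpix <- rd("integer", 1, 2)
    invisible(rd("integer", 1, 2))          # slice_start
    h$pixdim <- rd("double", 8, 4)
    h$vox_offset <- rd("double", 1, 4)
    h$scl_slope <- rd("double", 1, 4)
    h$scl_inter <- rd("double", 1, 4)
    invisible(rd("integer", 1, 2)); invisible(rd("raw", 2, 1))  # slice_end, slice_code, xyzt_units
    invisible(rd("double", 4, 4))           # cal_max, cal_min, slice_duration, toffset
    invisible(rd("integer", 2, 4))          # glmax, glmin
    invisible(rd("raw", 104, 1))            # descrip, aux_file
    h$qform_code <- rd("integer", 1, 2)
    h$sform_code <- rd("integer", 1, 2)
    h$quatern <- rd("double", 3, 4)
    h$qoffset <- rd("double", 3, 4)
    h$srow <- rbind(rd("double", 4, 4), rd("double", 4, 4), rd("double", 4, 4))
    invisible(rd("raw", 16, 1))             # intent_name
    h$magic <- rawToChar(rd("raw", 3, 1))
    h$endian <- endian
    h
  }
  h <- parse_hdr("little")
  if (h$sizeof_hdr != NIFTI_HDR_SIZE) h <- parse_hdr("big")
  if (h$sizeof_hdr != NIFTI_HDR_SIZE)
    stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  if (!h$magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)

  nd <- h$dim[1]
  if (nd < 3L) stop("NIfTI payload is not 3D (ndim = ", nd, ")", call. = FALSE)
  if (nd > 3L && any(h$dim[5:(1 + nd)] > 1L))
    stop("NIfTI payload is not 3D (trailing dims > 1)", call. = FALSE)
  shape <- h$dim[2:4]
  dt <- nifti_dtypes[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", h$datatype, call. = FALSE)

  skip <- round(h$vox_offset) - NIFTI_HDR_SIZE
  if (skip > 0) invisible(readBin(con, "raw", skip))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = h$endian, signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data payload: ", path, call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter

  affine <- nifti_affine(h, shape)
  vol <- image_volume(array(vals, shape),
                      spacing = sqrt(colSums(affine[1:3, 1:3]^2)),
                      affine = affine)
  reorient_ras(vol)
}

# affine from header: sform preferred, then qform (quaternion), then pixdim diag
nifti_affine <- function(h, shape) {
  if (h$sform_code > 0) {
    return(rbind(h$srow, c(0, 0, 0, 1)))
  }
  pd <- h$pixdim[2:4]
  pd[pd == 0] <- 1
  if (h$qform_code > 0) {
    b <- h$quatern[1]; c_ <- h$quatern[2]; d <- h$quatern[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
    ), 3, 3, byrow = TRUE)
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    R <- R %*% diag(c(pd[1], pd[2], qfac * pd[3]))
    return(rbind(cbind(R, h$qoffset), c(0, 0, 0, 1)))
  }
  diag(c(pd, 1))
}

#' Reorient a volume to canonical RAS axes
#'
#' Permutes and flips the array axes so the affine becomes as close to a
#' positive diagonal as possible (x right, y anterior, z superior). After
#' reorientation the third axis is the axial stack direction with index
#' increasing toward the vertex, which is what the slice-restriction rule
#' assumes. A no-op for already-canonical volumes.
#'
#' @param vol an [image_volume()] or [binary_mask()].
#' @return the reoriented object (same class).
#' @export
reorient_ras <- function(vol) {
  A <- vol$affine[1:3, 1:3]
  perm <- integer(3)   # perm[j]: world axis that voxel axis j mostly moves along
  Aw <- abs(A)
  for (j in 1:3) {
    i <- which.max(Aw[, j])
    perm[j] <- i
    Aw[i, ] <- -Inf    # keep it a permutation
  }
  ord <- match(1:3, perm)            # new axis i comes from old axis ord[i]
  flip <- vapply(1:3, function(i) A[i, ord[i]] < 0, logical(1))
  if (identical(ord, 1:3) && !any(flip)) return(vol)

  d <- vol$data
  if (!identical(ord, 1:3)) d <- aperm(d, ord)
  n <- dim(d)
  idx <- lapply(1:3, function(i) if (flip[i]) rev(seq_len(n[i])) else seq_len(n[i]))
  d <- d[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

  A2 <- matrix(0, 3, 3)
  t2 <- vol$affine[1:3, 4]
  n_old <- dim(vol$data)
  for (i in 1:3) {
    col <- vol$affine[1:3, ord[i]]
    if (flip[i]) {
      t2 <- t2 + col * (n_old[ord[i]] - 1)
      col <- -col
    }
    A2[, i] <- col
  }
  affine <- rbind(cbind(A2, t2), c(0, 0, 0, 1))
  spacing <- sqrt(colSums(A2^2))
  if (is_binary_mask(vol)) binary_mask(d, spacing = spacing, affine = affine)
  else image_volume(d, spacing = spacing, affine = affine)
}

#' Write a volume or mask as NIfTI-1
#'
#' Images are written as float64 (lossless round trip), masks as uint8. The
#' affine is stored in the sform (`sform_code = 2`); files ending in `.gz`
#' are gzip-compressed.
#'
#' @param volume an [image_volume()] or [binary_mask()].
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  if (is_binary_mask(volume)) validate_binary_mask(volume) else validate_image_volume(volume)
  is_mask <- is_binary_mask(volume)
  datatype <- if (is_mask) 2L else 64L
  bitpix <- if (is_mask) 8L else 64L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(x, size) writeBin(x, con, size = size, endian = "little")
  zeros <- function(n) writeBin(raw(n), con)

  shape <- dim(volume$data)
  wr(NIFTI_HDR_SIZE, 4L)                       # sizeof_hdr
  zeros(36L)                                   # data_type..regular, dim_info
  wr(as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), 2L)  # dim
  wr(c(0, 0, 0), 4L)                           # intent_p*
  wr(0L, 2L)                                   # intent_code
  wr(datatype, 2L)
  wr(bitpix, 2L)
  wr(0L, 2L)                                   # slice_start
  wr(c(1, volume$spacing, 0, 0, 0, 0), 4L)     # pixdim (qfac = 1)
  wr(352, 4L)                                  # vox_offset
  wr(1, 4L); wr(0, 4L)                         # scl_slope, scl_inter
  wr(0L, 2L); zeros(2L)                        # slice_end, slice_code, xyzt_units
  wr(c(0, 0, 0, 0), 4L)                        # cal_max..toffset
  wr(c(0L, 0L), 4L)                            # glmax, glmin
  zeros(104L)                                  # descrip, aux_file
  wr(0L, 2L)                                   # qform_code
  wr(2L, 2L)                                   # sform_code
  wr(c(0, 0, 0), 4L)                           # quatern
  wr(c(0, 0, 0), 4L)                           # qoffset
  wr(as.numeric(t(volume$affine[1:3, ])), 4L)  # srow_x/y/z
  zeros(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  zeros(4L)                                    # extension flag

  if (is_mask) {
    writeBin(as.integer(volume$data), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(volume$data), con, size = 8L, endian = "little")
  }
  invisible(path)
}
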