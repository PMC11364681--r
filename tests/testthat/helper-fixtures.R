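# Shared fixtures and independent brute-force oracles. Phantoms are built in
# code (no stored image fixtures) and cached per (noise_sd, seed) within a
# test run.

small_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(noise_sd = 0, seed = 1L) {
    key <- paste0("p", noise_sd, "_", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- build_phantom(phantom_spec(
        shape = c(96L, 100L, 80L), spacing = c(1, 1, 1),
        outer_semiaxes = c(40, 44, 36), noise_sd = noise_sd, seed = seed))
    cache[[key]]
  }
})

# threshold used against the small/default phantom (between diploe 60 and
# sheath/PSD 180 compartment means)
PHANTOM_DV_THRESHOLD <- 120
# ICV threshold between diploe (60) and CSF (90): keeps the intracranial
# compartment while excluding the skull
PHANTOM_ICV_THRESHOLD <- 75

random_mask <- function(dims, p = 0.3, spacing = c(1, 1, 1), seed = 1L) {
  set.seed(seed)
  binary_mask(array(as.integer(runif(prod(dims)) < p), dims), spacing = spacing)
}

# in-plane disc rasterized on a single-slice grid
disc_mask <- function(r_mm, spacing = 0.3125, n = 41L) {
  c0 <- (n - 1) / 2 * spacing
  g <- expand.grid(x = (0:(n - 1)) * spacing, y = (0:(n - 1)) * spacing)
  inside <- (g$x - c0)^2 + (g$y - c0)^2 <= r_mm^2
  binary_mask(array(as.integer(inside), c(n, n, 1L)), spacing = c(spacing, spacing, 1))
}

# oracle: per-slice 8-connected components kept iff twice the brute-force
# max-inscribed-disc radius (min distance to any background pixel center,
# physical units) reaches min_d
brute_diameter_filter <- function(mask, min_d) {
  dims <- dim(mask$data)
  sp <- mask$spacing
  out <- array(0L, dims)
  for (k in seq_len(dims[3])) {
    sl <- mask$data[, , k]
    if (!any(sl == 1L)) next
    lab <- array(perivene:::.cc_label(as.integer(sl), c(dims[1:2], 1L), 26L), dims[1:2])
    bg <- which(sl == 0L, arr.ind = TRUE)
    bgw <- cbind((bg[, 1] - 1) * sp[1], (bg[, 2] - 1) * sp[2])
    for (l in seq_len(max(lab))) {
      px <- which(lab == l, arr.ind = TRUE)
      if (nrow(px) == 0) next
      pw <- cbind((px[, 1] - 1) * sp[1], (px[, 2] - 1) * sp[2])
      dmax <- if (nrow(bg) == 0) Inf else
        max(apply(pw, 1, function(p) sqrt(min((bgw[, 1] - p[1])^2 + (bgw[, 2] - p[2])^2))))
      if (2 * dmax >= min_d - 1e-9) out[, , k][lab == l] <- 1L
    }
  }
  out
}

# oracle: exact two-sided Mann-Whitney p by full enumeration of rank subsets
brute_mw_pvalue <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  rk <- rank(c(x, y))
  U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(N, n1)
  U_all <- colSums(matrix(seq_len(N)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(U_all <= U_obs + 1e-9), mean(U_all >= U_obs - 1e-9))
  min(1, p)
}
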