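# Synthetic cohort and rater-table generators. Volume marginals are
# log-normal (the reference protocol reports medians with IQRs and non-normal
# distributions); rank dependence with age comes from a Gaussian copula whose
# Pearson parameter is chosen so the implied Spearman coefficient equals the
# calibration target, r = 2 sin(pi * rho_s / 6). Calibration constants live
# in inst/extdata/cohort_calibration.json — one versioned source of truth.

#' Default generator calibration
#'
#' Reads the versioned calibration file shipped with the package: cohort
#' size and sex split, age range, corrected and uncorrected volume
#' medians/IQRs, Spearman age correlations, sex ratios, ICV parameters and
#' ICC targets.
#'
#' @param path optional path to an alternative JSON calibration file.
#' @return a nested list of calibration constants.
#' @export
default_calibration <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_calibration.json", package = "perivene")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# log-normal parameters reproducing a target median and (q25, q75) span
lognormal_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, iqr[2] > iqr[1], iqr[1] > 0)
  list(mu = log(median),
       sigma = log(iqr[2] / iqr[1]) / (2 * qnorm(0.75)))
}

#' Cohort generator parameters
#'
#' Assembles the parameter set for [generate_cohort()] from a calibration
#' list (by default the shipped one), with optional overrides.
#'
#' @param n number of subjects (default: the calibrated cohort size, 98).
#' @param calibration a list as returned by [default_calibration()].
#' @param seed RNG seed (generation is deterministic given the seed).
#' @param ... named overrides for top-level fields (`age_range`,
#'   `sex_proportions`, `cross_spearman`, `structures`, `icv`).
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n = NULL, calibration = default_calibration(),
                          seed = NULL, ...) {
  p <- calibration
  p$n <- if (is.null(n)) calibration$n else n
  p$seed <- seed
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  stopifnot(abs(sum(unlist(p$sex_proportions)) - 1) < 1e-8)
  for (s in p$structures) {
    stopifnot(s$median_corrected > 0, abs(s$spearman_age) <= 1, s$sex_ratio > 0)
  }
  stopifnot(abs(p$cross_spearman) <= 1)
  class(p) <- "cohort_params"
  p
}

# Pearson copula parameter giving a target Spearman coefficient
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic cohort table
#'
#' Draws one record per subject: age (uniform over the calibrated range),
#' sex, ICV-corrected perivenous and PSD volumes (log-normal marginals
#' matching the calibrated medians/IQRs, Gaussian-copula rank dependence
#' with age at the calibrated Spearman levels, multiplicative sex shift
#' split symmetrically between the sexes so the overall median is
#' preserved), a log-normal ICV, and the uncorrected volumes
#' (corrected x ICV). Deterministic under a fixed seed.
#'
#' @param params a [cohort_params()].
#' @return a `data.frame` with columns `id`, `age` (years), `sex`
#'   (`"M"`/`"F"`), `dv_volume` (mm^3), `psd_volume` (mm^3), `icv` (cm^3).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  st <- params$structures
  r_da <- spearman_to_pearson(st$dv$spearman_age)
  r_pa <- spearman_to_pearson(st$psd$spearman_age)
  r_dp <- spearman_to_pearson(params$cross_spearman)
  R <- matrix(c(1, r_da, r_pa,
                r_da, 1, r_dp,
                r_pa, r_dp, 1), 3, 3)
  U <- chol(R)  # fails if the target correlations are jointly infeasible

  with_seed(params$seed, {
    sex <- ifelse(runif(n) < params$sex_proportions$M, "M", "F")
    Z <- matrix(rnorm(3 * n), n, 3) %*% U
    age <- params$age_range[1] + pnorm(Z[, 1]) * diff(params$age_range)

    sex_mult <- function(ratio) ifelse(sex == "M", sqrt(ratio), 1 / sqrt(ratio))
    corr_vol <- function(z, s) {
      lp <- lognormal_from_median_iqr(s$median_corrected, s$iqr_corrected)
      qlnorm(pnorm(z), lp$mu, lp$sigma) * sex_mult(s$sex_ratio)
    }
    dv_c <- corr_vol(Z[, 2], st$dv)
    psd_c <- corr_vol(Z[, 3], st$psd)
    icv <- qlnorm(pnorm(rnorm(n)), log(params$icv$median_cm3),
                  params$icv$sigma_log) * sex_mult(params$icv$sex_ratio)
    data.frame(id = sprintf("S%03d", seq_len(n)),
               age = age, sex = sex,
               dv_volume = dv_c * icv,
               psd_volume = psd_c * icv,
               icv = icv)
  })
}

#' Rater-table generator parameters
#'
#' Variance components on the Ln(x+1) scale for [generate_rater_pairs()].
#' The population ICC(2,1) implied by the components is
#' `s2_subject / (s2_subject + s2_rater + s2_residual)`.
#'
#' @param n_subjects number of subjects (default 10, the reliability
#'   sub-study design).
#' @param k_raters number of raters (default 2).
#' @param mu mean of Ln(volume + 1) across subjects.
#' @param s2_subject,s2_rater,s2_residual variance components (>= 0, not all
#'   zero).
#' @param seed RNG seed.
#' @return a `rater_params` list with a `population_icc` field.
#' @export
rater_params <- function(n_subjects = 10, k_raters = 2, mu = 5,
                         s2_subject = 1, s2_rater = 0.01, s2_residual = 0.01,
                         seed = NULL) {
  stopifnot(s2_subject >= 0, s2_rater >= 0, s2_residual >= 0)
  if (s2_subject + s2_rater + s2_residual == 0)
    stop("all variance components are zero; ICC undefined", call. = FALSE)
  structure(list(n_subjects = n_subjects, k_raters = k_raters, mu = mu,
                 s2_subject = s2_subject, s2_rater = s2_rater,
                 s2_residual = s2_residual,
                 population_icc = s2_subject / (s2_subject + s2_rater + s2_residual),
                 seed = seed),
            class = "rater_params")
}

#' Rater parameters calibrated to a target ICC
#'
#' Sets the subject variance from the log-normal spread implied by the
#' calibrated uncorrected-volume IQR (the reliability analysis runs on
#' Ln(x+1) of raw volumes), then splits the remaining variance equally
#' between rater bias and residual so the population ICC equals the
#' calibrated target.
#'
#' @param structure `"dv"` or `"psd"`.
#' @param n_subjects,seed passed through to [rater_params()].
#' @param calibration a [default_calibration()] list.
#' @return a `rater_params` list.
#' @export
rater_params_from_calibration <- function(structure = c("dv", "psd"),
                                          n_subjects = NULL, seed = NULL,
                                          calibration = default_calibration()) {
  structure <- match.arg(structure)
  s <- calibration$structures[[structure]]
  lp <- lognormal_from_median_iqr(s$median_uncorrected, s$iqr_uncorrected)
  s2b <- lp$sigma^2
  noise <- s2b * (1 - s$icc) / s$icc
  if (is.null(n_subjects)) n_subjects <- calibration$rater_design$n_subjects
  rater_params(n_subjects = n_subjects,
               k_raters = calibration$rater_design$k_raters,
               mu = log1p(s$median_uncorrected),
               s2_subject = s2b, s2_rater = noise / 2, s2_residual = noise / 2,
               seed = seed)
}

#' Generate a two-rater measurement table
#'
#' Draws an `n_subjects x k_raters` matrix of positive volumes whose
#' Ln(x+1) values decompose into subject + rater-bias + residual Gaussian
#' components. Deterministic under a fixed seed.
#'
#' @param params a [rater_params()].
#' @return numeric matrix (subjects x raters) of volumes, with attribute
#'   `population_icc`.
#' @export
generate_rater_pairs <- function(params) {
  stopifnot(inherits(params, "rater_params"))
  n <- params$n_subjects; k <- params$k_raters
  with_seed(params$seed, {
    subj <- rnorm(n, params$mu, sqrt(params$s2_subject))
    bias <- rnorm(k, 0, sqrt(params$s2_rater))
    eps <- matrix(rnorm(n * k, 0, sqrt(params$s2_residual)), n, k)
    y <- outer(subj, rep(1, k)) + outer(rep(1, n), bias) + eps
    vols <- pmax(expm1(y), 1e-12)
    attr(vols, "population_icc") <- params$population_icc
    vols
  })
}
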