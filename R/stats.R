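# Cohort statistics: ICV correction, Kolmogorov-Smirnov-gated dispatch
# between parametric and nonparametric association/group tests, and ICC(2,1)
# inter-rater reliability on Ln(x+1) volumes. Every test is two-sided at
# alpha = 0.05 with no multiplicity correction; ties are handled by average
# ranks throughout.

stat_result <- function(method, estimate, p_value, n, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(method = method, estimate = estimate,
                 p_value = min(p_value, 1), n = n, ...),
            class = "perivene_stat")
}

#' @export
print.perivene_stat <- function(x, ...) {
  cat(sprintf("<%s> estimate = %.4g, p = %.4g (n = %s)\n",
              x$method, x$estimate, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Correct a volume for intracranial volume
#'
#' Simple division by the intracranial volume: a volume in mm^3 divided by an
#' ICV in cm^3 yields a corrected volume in mm^3 cm^-3.
#'
#' @param volume_mm3 measured volume(s), mm^3.
#' @param icv_cm3 intracranial volume(s), cm^3 (> 0).
#' @return corrected volume(s), mm^3 cm^-3.
#' @examples
#' correct_for_icv(100, 1000) # 0.1
#' @export
correct_for_icv <- function(volume_mm3, icv_cm3) {
  if (any(icv_cm3 <= 0)) stop("icv_cm3 must be > 0", call. = FALSE)
  volume_mm3 / icv_cm3
}

# Lilliefors D: one-sample KS statistic against N(mean(x), sd(x))
lilliefors_D <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean(x), sd(x))
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

# Dallal-Wilkinson (1986) analytic p-value with Stephens' polynomial for the
# upper tail -- the approximation used by the common lillie implementations.
lilliefors_p_dw <- function(D, n) {
  if (n > 100) { Kd <- D * (n / 100)^0.49; nd <- 100 } else { Kd <- D; nd <- n }
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) -
             0.122119 + 0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p <- if (KK <= 0.302) 1
    else if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
      138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
      94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
      12.234627 * KK^3 + 2.423045 * KK^4
    else 0
  }
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov normality test with estimated parameters (Lilliefors)
#'
#' One-sample KS statistic of `x` against a normal with the sample's own mean
#' and SD. Because the parameters are estimated, the naive KS null is
#' anticonservative; the p-value therefore uses Lilliefors-corrected critical
#' values — by default the deterministic Dallal–Wilkinson analytic
#' approximation, optionally a seeded Monte-Carlo null
#' (`p_method = "monte-carlo"`). A sample is classified normal iff
#' `p >= alpha`.
#'
#' @param x numeric sample, n >= 4, no missing values, nonzero variance.
#' @param alpha classification level (default 0.05).
#' @param p_method `"dallal-wilkinson"` (default) or `"monte-carlo"`.
#' @param mc_reps,mc_seed Monte-Carlo null size and seed.
#' @return a `perivene_stat` with `method = "ks"`, `estimate` = D, `p_value`,
#'   and logical `normal`.
#' @export
ks_normality <- function(x, alpha = 0.05,
                         p_method = c("dallal-wilkinson", "monte-carlo"),
                         mc_reps = 2000L, mc_seed = 20240426L) {
  p_method <- match.arg(p_method)
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (sd(x) == 0) stop("sample has zero variance", call. = FALSE)
  D <- lilliefors_D(x)
  p <- if (p_method == "dallal-wilkinson") lilliefors_p_dw(D, n)
  else {
    null_D <- with_seed(mc_seed,
                        vapply(seq_len(mc_reps), function(i) lilliefors_D(rnorm(n)), numeric(1)))
    (1 + sum(null_D >= D)) / (mc_reps + 1)
  }
  stat_result("ks", estimate = D, p_value = p, n = n, normal = p >= alpha)
}

avg_rank <- function(x) rank(x, ties.method = "average")

#' Correlation with normality-gated method dispatch
#'
#' Pearson's product-moment correlation for normally distributed variables,
#' Spearman's rank correlation otherwise: with `method = "auto"` Spearman is
#' used unless [ks_normality()] passes for *both* variables. Spearman uses
#' average ranks for ties. The two-sided p-value comes from the
#' t-approximation for n > 10 and from exact enumeration of all permutations
#' for n <= 10. Swapping `x` and `y` leaves estimate and p unchanged, and the
#' Spearman branch is invariant under strictly monotone transforms.
#'
#' @param x,y numeric samples of equal length, n >= 3, non-constant.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return a `perivene_stat` with the method actually dispatched.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)
  if (method == "auto")
    method <- if (ks_normality(x)$normal && ks_normality(y)$normal) "pearson" else "spearman"
  u <- if (method == "spearman") avg_rank(x) else x
  v <- if (method == "spearman") avg_rank(y) else y
  r <- cor(u, v)
  p <- if (n <= 10) {
    .perm_corr_pvalue(u, v)
  } else if (abs(r) >= 1) {
    0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  stat_result(method, estimate = r, p_value = p, n = n)
}

# exact null counts of the rank sum of n1 items among ranks 1..N (no ties)
rank_sum_counts <- function(n1, N) {
  smax <- sum((N - n1 + 1):N)
  dp <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (r in seq_len(N)) {
    kmax <- min(n1, r)
    for (k in kmax:1) {
      shifted <- c(rep(0, r), dp[k, seq_len(smax + 1 - r)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  dp[n1 + 1, ]  # counts indexed by rank sum 0..smax (impossible sums are 0)
}

#' Two-sample comparison with normality-gated method dispatch
#'
#' Welch's t test for normally distributed groups, the Mann–Whitney U test
#' otherwise: with `method = "auto"` the U test is used unless
#' [ks_normality()] passes for both groups. U is computed from rank sums with
#' average ranks for ties. The two-sided p-value is exact (full enumeration
#' of the null rank-sum distribution) when `min(n, m) <= 8` and there are no
#' ties, and otherwise uses the normal approximation with continuity and tie
#' correction. Swapping the groups maps U to `n*m - U` and leaves p
#' unchanged.
#'
#' @param x,y the two groups (each n >= 2 for `"t"`/gating; non-empty).
#' @param method `"auto"`, `"t"` or `"mann_whitney"`.
#' @return a `perivene_stat`; for the U test `estimate` is U (for `x`), with
#'   fields `exact` and group sizes in `n`.
#' @export
compare_groups <- function(x, y, method = c("auto", "t", "mann_whitney")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) stop("empty group", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (method == "auto")
    method <- if (ks_normality(x)$normal && ks_normality(y)$normal) "t" else "mann_whitney"
  if (method == "t") {
    tt <- stats::t.test(x, y)  # Welch
    return(stat_result("t", estimate = unname(tt$statistic),
                       p_value = tt$p.value, n = c(n1, n2),
                       df = unname(tt$parameter)))
  }
  pooled <- c(x, y)
  rk <- avg_rank(pooled)
  R1 <- sum(rk[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  exact <- min(n1, n2) <= 8 && !ties
  if (exact) {
    counts <- rank_sum_counts(n1, N)
    total <- sum(counts)
    s_obs <- R1
    u_all <- seq(0, length(counts) - 1) - n1 * (n1 + 1) / 2  # U per rank sum index
    pu <- counts / total
    cdf_lo <- sum(pu[u_all <= U + 1e-9])
    cdf_hi <- sum(pu[u_all >= U - 1e-9])
    p <- min(1, 2 * min(cdf_lo, cdf_hi))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) stop("degenerate pooled sample (all values tied)", call. = FALSE)
    cc <- if (U == mu) 0 else 0.5 * sign(U - mu)
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  stat_result("mann_whitney", estimate = U, p_value = min(p, 1),
              n = c(n1, n2), exact = exact)
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`,
#' where MSR, MSC and MSE are the subject, rater and residual mean squares.
#' The optional `ln1p` transform applies `log(x + 1)` first (volumes are
#' log-transformed before reliability assessment when non-normal). The
#' confidence interval uses the standard F-based bounds for this form.
#'
#' @param measurements numeric matrix, subjects in rows (n >= 2), raters in
#'   columns (k >= 2), complete.
#' @param transform `"none"` or `"ln1p"` (requires all values >= 0).
#' @param conf_level confidence level (default 0.95).
#' @return an `icc_result`: `icc`, `ci_low`, `ci_high`, `transform`, `n`,
#'   `k`, and the mean squares `ms = c(MSR, MSC, MSE)`.
#' @examples
#' icc_2_1(cbind(1:4, 2:5)) # icc = 10/13
#' @export
icc_2_1 <- function(measurements, transform = c("none", "ln1p"), conf_level = 0.95) {
  transform <- match.arg(transform)
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("measurement matrix must be complete", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters", call. = FALSE)
  if (transform == "ln1p") {
    if (any(m < 0)) stop("ln1p transform requires non-negative values", call. = FALSE)
    m <- log1p(m)
  }
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom <= 0) stop("all variance components are zero; ICC undefined", call. = FALSE)
  icc <- (MSR - MSE) / denom
  alpha <- 1 - conf_level
  if (MSE == 0 && MSC == 0) {
    ci <- c(icc, icc)  # perfect agreement, no sampling variability in the ratio
  } else {
    a <- (k * icc) / (n * (1 - icc)); b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(icc, icc)
    } else {
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      FL <- qf(1 - alpha / 2, n - 1, v)
      FU <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (MSR - FL * MSE) / (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (FU * MSR - MSE) / (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
      ci <- c(min(lo, icc), max(hi, icc))
    }
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 transform = transform, n = n, k = k,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.4f [%.4f, %.4f], n = %d, k = %d, transform = %s\n",
              x$icc, x$ci_low, x$ci_high, x$n, x$k, x$transform))
  invisible(x)
}

#' Run the full cohort statistical battery
#'
#' For each structure (perivenous space, PSD) and for both the uncorrected
#' (mm^3) and ICV-corrected (mm^3 cm^-3) volumes: KS normality, association
#' with age ([correlate()] with auto dispatch), sex comparison
#' ([compare_groups()] with auto dispatch), and the median with IQR. Adds the
#' cross-correlation between the two corrected volumes. Significance is
#' flagged at `p < alpha`.
#'
#' @param cohort data frame with columns `age`, `sex` (`"M"`/`"F"`),
#'   `dv_volume`, `psd_volume` (mm^3) and `icv` (cm^3), one row per subject
#'   (see [generate_cohort()]).
#' @param alpha significance threshold (default 0.05).
#' @return a `cohort_analysis` list: one entry per structure x correction
#'   holding the test results, plus `cross_correlation` and `age_normality`.
#' @export
run_cohort_analysis <- function(cohort, alpha = 0.05) {
  req <- c("age", "sex", "dv_volume", "psd_volume", "icv")
  if (!all(req %in% names(cohort)))
    stop("cohort must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(cohort$icv <= 0)) stop("icv must be > 0", call. = FALSE)
  if (any(cohort$dv_volume < 0) || any(cohort$psd_volume < 0))
    stop("volumes must be >= 0", call. = FALSE)
  male <- cohort$sex == "M"

  one <- function(v) {
    ks <- ks_normality(v)
    age_assoc <- correlate(cohort$age, v, method = "auto")
    sex_cmp <- compare_groups(v[male], v[!male], method = "auto")
    list(normality = ks,
         age_association = age_assoc,
         sex_comparison = sex_cmp,
         median = median(v),
         iqr = unname(quantile(v, c(0.25, 0.75))),
         significant_age = age_assoc$p_value < alpha,
         significant_sex = sex_cmp$p_value < alpha)
  }
  dv_c <- correct_for_icv(cohort$dv_volume, cohort$icv)
  psd_c <- correct_for_icv(cohort$psd_volume, cohort$icv)
  res <- list(
    dv_uncorrected = one(cohort$dv_volume),
    dv_corrected = one(dv_c),
    psd_uncorrected = one(cohort$psd_volume),
    psd_corrected = one(psd_c),
    cross_correlation = correlate(dv_c, psd_c, method = "auto"),
    age_normality = ks_normality(cohort$age),
    n = nrow(cohort), alpha = alpha)
  class(res) <- "cohort_analysis"
  res
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> n = %d, alpha = %.2f\n", x$n, x$alpha))
  for (nm in c("dv_uncorrected", "dv_corrected", "psd_uncorrected", "psd_corrected")) {
    a <- x[[nm]]
    cat(sprintf("  %-16s median %.3f [%.3f, %.3f]; age %s r = %.3f (p = %.3g); sex %s p = %.3g\n",
                nm, a$median, a$iqr[1], a$iqr[2],
                a$age_association$method, a$age_association$estimate,
                a$age_association$p_value,
                a$sex_comparison$method, a$sex_comparison$p_value))
  }
  cat(sprintf("  cross-correlation (corrected): %s r = %.3f (p = %.3g)\n",
              x$cross_correlation$method, x$cross_correlation$estimate,
              x$cross_correlation$p_value))
  invisible(x)
}
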