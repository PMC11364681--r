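test_that("ICV correction is plain division with guarded domain", {
  expect_equal(correct_for_icv(100, 1000), 0.1)
  expect_equal(correct_for_icv(0, 1234), 0)
  expect_equal(correct_for_icv(c(10, 20), c(1000, 2000)), c(0.01, 0.01))
  expect_error(correct_for_icv(10, 0), "> 0")
  expect_error(correct_for_icv(10, -5), "> 0")
})

test_that("KS/Lilliefors classifies normal and non-normal samples", {
  set.seed(1)
  x <- rnorm(1000)
  y <- rexp(1000)
  rx <- ks_normality(x)
  ry <- ks_normality(y)
  expect_true(rx$normal); expect_gte(rx$p_value, 0.05)
  expect_false(ry$normal); expect_lt(ry$p_value, 0.05)
  # the seeded Monte-Carlo alternative agrees on classification
  expect_true(ks_normality(x, p_method = "monte-carlo")$normal)
  expect_false(ks_normality(y, p_method = "monte-carlo")$normal)
  expect_error(ks_normality(rep(3, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("correlation estimates and p-values match the oracles", {
  # closed form: rho = 1 - 6*sum(d^2)/(n(n^2-1)), sum(d^2) = 4
  r <- correlate(1:5, c(2, 1, 4, 3, 5), method = "spearman")
  expect_equal(r$estimate, 0.8)
  # monotone invariance at the boundaries
  x <- c(0.3, 1.1, 2.7, 3.4, 5.9, 7.2)
  expect_equal(correlate(x, x^2, method = "spearman")$estimate, 1)
  expect_equal(correlate(x, rev(x)^3, method = "spearman")$estimate, -1)
  # exact permutation p equals the reference exact null (n <= 10, no ties)
  for (s in 1:5) {
    set.seed(s)
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(correlate(a, b, method = "spearman")$p_value,
                 cor.test(a, b, method = "spearman", exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # t-approximation branch against the reference implementation
  set.seed(9)
  a <- rnorm(40); b <- 0.4 * a + rnorm(40)
  expect_equal(correlate(a, b, method = "pearson")$p_value,
               cor.test(a, b)$p.value, tolerance = 1e-10)
  expect_equal(correlate(a, b, method = "spearman")$p_value,
               suppressWarnings(cor.test(a, b, method = "spearman",
                                         exact = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("correlation is symmetric in its arguments and validates input", {
  set.seed(4)
  x <- rlnorm(30); y <- rlnorm(30)
  r1 <- correlate(x, y, method = "spearman")
  r2 <- correlate(y, x, method = "spearman")
  expect_equal(r1$estimate, r2$estimate)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(correlate(1:5, 1:6), "equal length")
  expect_error(correlate(rep(1, 5), 1:5), "constant")
  expect_error(correlate(1:2, 2:1), "at least 3")
})

test_that("auto dispatch follows the normality gate", {
  set.seed(4)   # a draw whose two samples both pass the Lilliefors gate
  gx <- rnorm(100, 50, 5); gy <- rnorm(100, 30, 4)
  expect_identical(correlate(gx, gy, method = "auto")$method, "pearson")
  expect_identical(correlate(gx, rlnorm(100, 0, 1.5), method = "auto")$method,
                   "spearman")
  expect_identical(compare_groups(gx, gy, method = "auto")$method, "t")
  expect_identical(compare_groups(rlnorm(100, 0, 1.5), gy, method = "auto")$method,
                   "mann_whitney")
})

test_that("Mann-Whitney U matches full enumeration and the reference", {
  m <- compare_groups(c(1, 2, 3), c(4, 5, 6), method = "mann_whitney")
  expect_equal(m$estimate, 0)
  expect_equal(m$p_value, 0.1)   # 2/20 rank assignments are as extreme
  expect_true(m$exact)
  # swap symmetry: U -> n*m - U, p unchanged
  ms <- compare_groups(c(4, 5, 6), c(1, 2, 3), method = "mann_whitney")
  expect_equal(ms$estimate, 9)
  expect_equal(ms$p_value, m$p_value)
  # exact branch vs independent enumeration oracle, multiple shapes
  for (s in 1:6) {
    set.seed(s + 30)
    a <- rnorm(sample(3:7, 1)); b <- rnorm(sample(3:9, 1)) + runif(1, -1, 1)
    got <- compare_groups(a, b, method = "mann_whitney")
    expect_true(got$exact)
    expect_equal(got$p_value, brute_mw_pvalue(a, b), tolerance = 1e-12)
    expect_equal(got$p_value, wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # approximate branch (ties / large groups) vs reference with continuity + ties
  set.seed(77)
  a <- round(rlnorm(40, 0, 1), 1); b <- round(rlnorm(35, 0.4, 1), 1)
  got <- compare_groups(a, b, method = "mann_whitney")
  expect_false(got$exact)
  expect_equal(got$p_value,
               suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value),
               tolerance = 1e-10)
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(5)
  a <- rlnorm(20); b <- rlnorm(25, 0.5)
  p0 <- compare_groups(a, b, method = "mann_whitney")$p_value
  expect_equal(compare_groups(log(a), log(b), method = "mann_whitney")$p_value, p0)
  expect_equal(compare_groups(a^2, b^2, method = "mann_whitney")$p_value, p0)
})

test_that("Welch t branch matches the reference", {
  set.seed(6)
  a <- rnorm(20, 1); b <- rnorm(30, 1.5, 2)
  got <- compare_groups(a, b, method = "t")
  ref <- t.test(a, b)
  expect_equal(got$estimate, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("ICC(2,1) reproduces the hand-computed ANOVA example", {
  res <- icc_2_1(cbind(1:4, 2:5))
  expect_equal(unname(res$ms), c(10 / 3, 2, 0))
  expect_equal(res$icc, 10 / 13)
  expect_lte(res$ci_low, res$icc); expect_gte(res$ci_high, res$icc)
  expect_lte(res$ci_high, 1 + 1e-12)

  perfect <- icc_2_1(cbind(c(3, 1, 4), c(3, 1, 4)))
  expect_equal(perfect$icc, 1)

  expect_error(icc_2_1(cbind(c(-1, 2), c(0, 3)), transform = "ln1p"), "non-negative")
  expect_error(icc_2_1(cbind(c(1, NA), c(2, 3))), "complete")
  expect_error(icc_2_1(matrix(1:4, 4, 1)), "at least 2")
  expect_error(icc_2_1(matrix(5, 3, 2)), "undefined")
})

test_that("ICC confidence interval behaves on the reliability design (n=10, k=2)", {
  set.seed(8)
  p <- rater_params_from_calibration("dv", seed = 21)
  tab <- generate_rater_pairs(p)
  res <- icc_2_1(tab, transform = "ln1p")
  expect_identical(res$n, 10L)
  expect_true(res$ci_low < res$icc && res$icc < res$ci_high)
  expect_lt(res$ci_high, 1)

  # frozen cross-validation: estimate and F-based CI for the seed-1 table
  # agree with an independent reference implementation (pingouin ICC(A,1)
  # on the identical Ln(x+1) matrix: 0.964036 [0.24, 0.99])
  tab1 <- generate_rater_pairs(rater_params_from_calibration("dv", seed = 1))
  res1 <- icc_2_1(tab1, transform = "ln1p")
  expect_equal(res1$icc, 0.9640363, tolerance = 1e-6)
  expect_equal(res1$ci_low, 0.238251, tolerance = 1e-5)
  expect_equal(res1$ci_high, 0.9937945, tolerance = 1e-6)
})

test_that("run_cohort_analysis produces the full report with correct gating", {
  co <- generate_cohort(cohort_params(seed = 123))
  rep <- run_cohort_analysis(co)
  expect_s3_class(rep, "cohort_analysis")
  blocks <- c("dv_uncorrected", "dv_corrected", "psd_uncorrected", "psd_corrected")
  expect_true(all(blocks %in% names(rep)))
  expect_s3_class(rep$cross_correlation, "perivene_stat")
  for (b in blocks) {
    a <- rep[[b]]
    # log-normal volumes fail the normality gate -> nonparametric branch
    expect_false(a$normality$normal)
    expect_identical(a$age_association$method, "spearman")
    expect_identical(a$sex_comparison$method, "mann_whitney")
    expect_true(a$iqr[1] <= a$median && a$median <= a$iqr[2])
  }
  # normal synthetic volumes dispatch the parametric branch
  set.seed(11)
  con <- data.frame(age = rnorm(80, 50, 10), sex = rep(c("M", "F"), 40),
                    dv_volume = rnorm(80, 200, 20),
                    psd_volume = rnorm(80, 700, 50),
                    icv = rnorm(80, 1450, 40))
  rep2 <- run_cohort_analysis(con)
  expect_identical(rep2$dv_uncorrected$age_association$method, "pearson")
  expect_identical(rep2$dv_uncorrected$sex_comparison$method, "t")
  expect_error(run_cohort_analysis(data.frame(age = 1:5)), "columns")
})

test_that("large calibrated cohorts recover the configured rank correlations", {
  co <- generate_cohort(cohort_params(n = 20000, seed = 31))
  rep <- run_cohort_analysis(co)
  calib <- default_calibration()
  expect_equal(rep$dv_corrected$age_association$estimate,
               calib$structures$dv$spearman_age, tolerance = 0.1)
  expect_equal(rep$psd_corrected$age_association$estimate,
               calib$structures$psd$spearman_age, tolerance = 0.1)
  # the copula cross-dependence is zero; only the shared sex effect induces a
  # small residual correlation between the two corrected volumes
  expect_lt(abs(rep$cross_correlation$estimate), 0.1)
})
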