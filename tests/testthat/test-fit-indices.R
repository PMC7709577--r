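# Chi-square, df, baseline, CFI/TLI, RMSEA with CI, AIC/BIC, labels.

test_that("chi-square scaling is (N-1) F and linear in F", {
  expect_equal(chi_square(0, 100), 0)
  expect_equal(chi_square(129.96 / 1111, 1112), 129.96)
  expect_equal(chi_square(0.4, 51), 2 * chi_square(0.2, 51))
})

test_that("degrees of freedom follow the counting rules", {
  expect_equal(degrees_of_freedom(wais_bifactor()), 75L)     # 120 - 45
  full <- matrix(TRUE, 15, 15); diag(full) <- FALSE
  expect_equal(degrees_of_freedom(ggm_model(full)), 0L)      # saturated
  # a 53-edge 15-node GGM: 120 - 15 - 53 = 52
  set.seed(5)
  sk <- matrix(FALSE, 15, 15)
  edges <- sample(which(upper.tri(sk)), 53)
  sk[edges] <- TRUE; sk <- sk | t(sk)
  expect_equal(degrees_of_freedom(ggm_model(sk)), 52L)
  # over-parameterized is an error
  fm <- factor_model("multi_general", loading_pattern = matrix(TRUE, 3, 1),
                     general_pattern = matrix(TRUE, 3, 2),
                     G = matrix(.3, 3, 2))
  expect_error(degrees_of_freedom(fm), "over-parameterized")
})

test_that("baseline chi-square matches the -ln|R| closed form", {
  m0 <- sample_moments(diag(5), 200)
  b0 <- baseline_chi_square(m0)
  expect_equal(b0$chi2, 0, tolerance = 1e-12)
  expect_equal(b0$df, 10L)

  S <- matrix(c(1, .5, .5, 1), 2)
  b <- baseline_chi_square(sample_moments(S, 101))
  expect_equal(b$chi2, -100 * log(0.75), tolerance = 1e-10)
  expect_equal(b$chi2, 28.768, tolerance = 1e-3)
  expect_equal(b$df, 1L)

  expect_equal(baseline_chi_square(sample_moments(diag(15), 100))$df, 105L)
})

test_that("CFI and TLI formulas and edge cases", {
  expect_equal(cfi_tli(52, 52, 1000, 105)$cfi, 1)
  r <- cfi_tli(129.96, 52, 1000, 105)
  expect_equal(r$cfi, 1 - 77.96 / 895, tolerance = 1e-12)
  expect_equal(r$cfi, 0.9129, tolerance = 1e-4)
  expect_equal(cfi_tli(500, 105, 500, 105)$tli, 0)
  # saturated model: perfect by convention
  expect_equal(cfi_tli(0, 0, 800, 105)$tli, 1)
  expect_equal(cfi_tli(0, 0, 800, 105)$cfi, 1)
  # degenerate baseline
  expect_warning(out <- cfi_tli(40, 50, 100, 105), "degenerate baseline")
  expect_equal(out$tli, 1)
})

test_that("RMSEA point estimates and CI bounds invert the noncentral chi-square", {
  r <- rmsea_with_ci(129.96, 52, 1112)
  expect_equal(round(r$rmsea, 3), 0.037)
  expect_equal(round(r$upper, 3), 0.045)
  expect_equal(round(r$lower, 3), 0.029)
  expect_equal(round(rmsea_with_ci(263.41, 75, 1112)$rmsea, 3), 0.048)
  expect_equal(round(rmsea_with_ci(376.56, 84, 1112)$rmsea, 3), 0.056)

  # chi2 <= df collapses the point estimate and lower bound to 0
  r0 <- rmsea_with_ci(40, 52, 500)
  expect_equal(r0$rmsea, 0)
  expect_equal(r0$lower, 0)
  expect_true(r0$lower <= r0$rmsea && r0$rmsea <= r0$upper)

  # CI inversion property: plugging lambda back into the noncentral CDF
  # returns the target probabilities
  r2 <- rmsea_with_ci(200, 80, 900, level = 0.90)
  lam_L <- r2$lower^2 * 80 * 899
  lam_U <- r2$upper^2 * 80 * 899
  expect_equal(pchisq(200, 80, ncp = lam_L), 0.95, tolerance = 1e-6)
  expect_equal(pchisq(200, 80, ncp = lam_U), 0.05, tolerance = 1e-6)

  # df = 0: undefined with explanation
  und <- rmsea_with_ci(0, 0, 100)
  expect_true(is.na(und$rmsea))
  expect_match(attr(und, "explanation"), "df = 0")
})

test_that("AIC/BIC: penalty identity and constant-free differences", {
  S <- random_pd_correlation(4, 8)
  N <- 500
  a1 <- aic_bic(0.10, N, k = 10, S = S)
  a2 <- aic_bic(0.25, N, k = 7, S = S)
  # dAIC = dchi2 + 2 dk regardless of the likelihood constant
  expect_equal(a2$aic - a1$aic, (N - 1) * (0.25 - 0.10) + 2 * (7 - 10),
               tolerance = 1e-10)
  expect_equal(a2$bic - a1$bic, (N - 1) * (0.25 - 0.10) + log(N) * (7 - 10),
               tolerance = 1e-10)
  # the ordering is invariant to dropping the constant
  b1 <- aic_bic(0.10, N, k = 10)
  b2 <- aic_bic(0.25, N, k = 7)
  expect_equal(a2$aic - a1$aic, b2$aic - b1$aic, tolerance = 1e-10)
  # k = 0: AIC = BIC = -2lnL
  z <- aic_bic(0.3, N, k = 0, S = S)
  expect_equal(z$aic, z$minus2loglik)
  expect_equal(z$bic, z$minus2loglik)
})

test_that("qualitative labels follow the threshold boundaries exactly", {
  lab <- function(x) qualify_fit(list(rmsea = x, cfi = .99, tli = .99))$rmsea
  expect_equal(lab(0.037), "good")
  expect_equal(lab(0.05), "good")
  expect_equal(lab(0.056), "adequate")
  expect_equal(lab(0.08), "adequate")
  expect_equal(lab(0.10), "mediocre")
  expect_equal(lab(0.101), "unacceptable")
  clab <- function(x) qualify_fit(list(rmsea = .04, cfi = x, tli = x))$cfi
  expect_equal(clab(0.98), "good")
  expect_equal(clab(0.97), "acceptable")
  expect_equal(clab(0.95), "acceptable")
  expect_equal(clab(0.949), "below-acceptable")
})

test_that("fit_indices gives a saturated model CFI = TLI = 1 and RMSEA 0", {
  S <- random_pd_correlation(4, 11)
  m <- sample_moments(S, 300)
  full <- matrix(TRUE, 4, 4); diag(full) <- FALSE
  ix <- fit_indices(fit_ggm(m, full))
  expect_equal(ix$cfi, 1)
  expect_equal(ix$tli, 1)
  expect_equal(ix$rmsea, 0)
  expect_equal(ix$df, 0L)
})
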