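# ML discrepancy, GGM and factor fitting, standard errors.

test_that("fml_discrepancy: identity, closed form, monotonic path", {
  S <- random_pd_correlation(4, 1)
  expect_equal(fml_discrepancy(S, S), 0, tolerance = 1e-12)

  S2 <- matrix(c(1, .5, .5, 1), 2)
  # ln|I| - ln|S| + tr(S) - 2 = -ln(0.75)
  expect_equal(fml_discrepancy(S2, diag(2)), -log(0.75), tolerance = 1e-12)

  # F strictly decreases along (1-t) I + t S toward S
  ts <- seq(0, 1, by = 0.1)
  vals <- sapply(ts, function(t) fml_discrepancy(S2, (1 - t) * diag(2) + t * S2))
  expect_true(all(diff(vals) < 0))

  expect_error(fml_discrepancy(S2, diag(3)), "dimension mismatch")
  expect_error(fml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "not positive definite")
})

test_that("analytic gradients match central differences for every model family", {
  S <- random_pd_correlation(15, 9)
  models <- list(
    ggm = {
      set.seed(9)
      sk <- matrix(FALSE, 15, 15)
      sk[upper.tri(sk)] <- runif(105) < .3
      sk <- sk | t(sk)
      ggm_model(sk, omega = sk * 0.1, delta = runif(15, .8, 1.2))
    },
    measurement = wais_measurement(),
    hierarchical = wais_hierarchical_g(),
    bifactor = wais_bifactor(),
    penta = wais_pentafactor())
  for (nm in names(models)) {
    model <- models[[nm]]
    theta <- netlatent:::free_params(model)
    ga <- netlatent:::fml_gradient_natural(model, theta, S)
    gn <- netlatent:::num_gradient(function(th) {
      fml_discrepancy(S, netlatent:::implied_from_params(model, th))
    }, theta)
    expect_lt(max(abs(ga - gn)), 1e-6)
  }
})

test_that("fit_ggm: saturated, empty-skeleton, and nesting behavior", {
  S <- random_pd_correlation(5, 2)
  m <- sample_moments(S, 200)
  full <- matrix(TRUE, 5, 5); diag(full) <- FALSE
  f_full <- fit_ggm(m, full)
  expect_lt(f_full$F_ml, 1e-10)
  expect_true(f_full$converged)
  expect_equal(degrees_of_freedom(f_full$model), 0L)
  expect_lt(max(abs(implied_covariance(f_full$model) - S)), 1e-8)
  # saturated closed-form oracle
  sat <- saturated_ggm(S)
  expect_equal(f_full$model$omega, sat$omega, tolerance = 1e-6,
               ignore_attr = TRUE)

  m_id <- sample_moments(diag(3), 100)
  f_empty <- fit_ggm(m_id, matrix(FALSE, 3, 3))
  expect_equal(f_empty$F_ml, 0, tolerance = 1e-12)
  expect_equal(f_empty$model$delta, rep(1, 3), tolerance = 1e-8,
               ignore_attr = TRUE)

  # nesting: removing an edge can only increase minimized F
  m3 <- sample_moments(chain_misfit_S(), 500)
  f_chain <- fit_ggm(m3, chain_skeleton())
  expect_gt(f_chain$F_ml, 0)
  full3 <- matrix(TRUE, 3, 3); diag(full3) <- FALSE
  expect_gt(f_chain$F_ml, fit_ggm(m3, full3)$F_ml)
})

test_that("fit_factor: just-identified closed form and df counting", {
  S <- matrix(.5, 3, 3); diag(S) <- 1
  m <- sample_moments(S, 500)
  fm <- factor_model("correlated_factors",
                     loading_pattern = matrix(TRUE, 3, 1))
  fit <- fit_factor(m, fm)
  expect_lt(fit$F_ml, 1e-10)
  expect_equal(abs(as.numeric(fit$model$Lambda)), rep(sqrt(.5), 3),
               tolerance = 1e-5)
  # sign canonicalization: largest loading positive
  expect_gt(max(fit$model$Lambda), 0)
  expect_equal(degrees_of_freedom(fit$model), 0L)  # 3*4/2 - 6
})

test_that("a Heywood-prone one-factor problem stays inside Theta > 0", {
  # the unconstrained just-identified solution would need theta_1 < 0; the
  # log-parameterized fit pushes theta_1 to the boundary instead and misfits
  S <- matrix(c(1, .9, .8,
                .9, 1, .5,
                .8, .5, 1), 3, 3)
  m <- sample_moments(S, 400)
  fm <- factor_model("correlated_factors", loading_pattern = matrix(TRUE, 3, 1))
  fit <- fit_factor(m, fm)
  expect_gt(fit$F_ml, 0)
  expect_true(all(fit$model$Theta > 0))
  expect_lt(fit$model$Theta[1], 1e-6)
})

test_that("fitting a generating factor model to its population matrix recovers truth", {
  pop <- random_population("factor", p = 8, m = 2, phi_offdiag = 0.4, seed = 13)
  m <- sample_moments(pop$sigma, 100000)
  fit <- fit_factor(m, pop$model)
  expect_lt(fit$F_ml, 1e-12)
  expect_equal(abs(fit$model$Lambda), abs(pop$model$Lambda), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fit$model$Phi[1, 2], 0.4, tolerance = 1e-4)
  expect_equal(fit$model$Theta, pop$model$Theta, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("fitting a generating GGM to its population matrix recovers truth", {
  pop <- chain_population(p = 6, omega = 0.3)
  m <- sample_moments(pop$sigma, 100000)
  fit <- fit_ggm(m, pop$model$skeleton)
  expect_lt(fit$F_ml, 1e-12)
  expect_equal(fit$model$omega, pop$model$omega, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("standard errors match the Fisher-z oracle and the 1/sqrt(N-1) law", {
  S <- matrix(c(1, .5, .5, 1), 2)
  sk <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
  fit <- fit_ggm(sample_moments(S, 1000), sk)
  se <- standard_errors(fit)
  expect_false(se$singular)
  fisher <- (1 - .5^2) / sqrt(1000 - 3)   # atanh-scale SE transformed back
  expect_equal(as.numeric(se$se["omega_V1.V2"]), fisher, tolerance = 0.1)

  # doubling N - 1 scales SEs by 1/sqrt(2)
  fit2 <- fit_ggm(sample_moments(S, 1999), sk)
  se2 <- standard_errors(fit2)
  expect_equal(as.numeric(se$se / se2$se), rep(sqrt(2), 3), tolerance = 1e-4)

  expect_error(standard_errors(structure(list(converged = FALSE),
                                         class = "netlatent_fit")),
               "converged")
})

test_that("nonidentified factor models are refused unless overridden", {
  pop <- random_population("factor", p = 15, m = 4, seed = 5)
  dimnames(pop$sigma) <- list(wais_labels(), wais_labels())
  m <- sample_moments(pop$sigma, 1112)
  expect_error(fit_factor(m, wais_pentafactor()), "nonidentified")
  fit <- suppressWarnings(
    fit_factor(m, wais_pentafactor(), override_identification = TRUE,
               settings = estimation_settings(n_starts = 1)))
  expect_true(fit$nonidentified)
  expect_warning(
    fit_factor(m, wais_pentafactor(), override_identification = TRUE,
               settings = estimation_settings(n_starts = 1)),
    "NONIDENTIFIED")
})
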