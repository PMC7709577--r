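# Domain types and the implied-covariance maps.

test_that("GGM implied covariance: diagonal, two-variable and chain cases", {
  # Omega = 0: Sigma = diag(delta^2)
  m <- ggm_model(matrix(FALSE, 3, 3), delta = c(1, 2, 3))
  expect_equal(implied_covariance(m), diag(c(1, 4, 9)),
               ignore_attr = TRUE)

  # p = 2: the partial correlation equals the zero-order correlation
  sk2 <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
  om2 <- matrix(c(0, .5, .5, 0), 2)
  A <- solve(diag(2) - om2)
  m2 <- ggm_model(sk2, omega = om2, delta = 1 / sqrt(diag(A)))
  Sigma2 <- implied_covariance(m2)
  expect_equal(diag(Sigma2), c(1, 1), ignore_attr = TRUE)
  expect_equal(Sigma2[1, 2], 0.5)

  # p = 3 chain with omega = 0.4: compare against a direct inversion oracle
  sk <- chain_skeleton()
  om <- matrix(0, 3, 3); om[1, 2] <- om[2, 1] <- om[2, 3] <- om[3, 2] <- 0.4
  Ainv <- solve(diag(3) - om)                      # oracle route
  delta <- 1 / sqrt(diag(Ainv))
  oracle <- diag(delta) %*% Ainv %*% diag(delta)
  m3 <- ggm_model(sk, omega = om, delta = delta)
  expect_equal(implied_covariance(m3), oracle, ignore_attr = TRUE,
               tolerance = 1e-12)
  # the 1-3 entry is the product path through the standardization
  expect_gt(oracle[1, 3], 0)
})

test_that("invalid GGM parameters are rejected with the offending eigenvalue", {
  # three mutual partials of .9 make I - Omega indefinite
  sk3 <- matrix(TRUE, 3, 3); diag(sk3) <- FALSE
  om3 <- matrix(.9, 3, 3); diag(om3) <- 0
  m <- ggm_model(sk3, omega = om3)
  expect_error(implied_covariance(m), "not positive definite")
  sk2 <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
  expect_error(ggm_model(sk2, omega = matrix(c(0, 1.2, 1.2, 0), 2)),
               "strictly in")
  expect_error(ggm_model(matrix(FALSE, 2, 2),
                         omega = matrix(c(0, .5, .5, 0), 2)),
               "no edge")
})

test_that("factor implied covariance matches closed forms for each kind", {
  # single factor, loadings sqrt(.5), Theta .5: all off-diagonals 0.5
  fm <- factor_model("correlated_factors",
                     loading_pattern = matrix(TRUE, 3, 1),
                     Lambda = matrix(sqrt(.5), 3, 1), Theta = rep(.5, 3))
  Sigma <- implied_covariance(fm)
  expect_equal(Sigma, matrix(.5, 3, 3) + diag(.5, 3), ignore_attr = TRUE)

  # null model: Lambda = 0, Theta = 1 -> identity
  fm0 <- factor_model("bifactor",
                      loading_pattern = matrix(TRUE, 4, 1),
                      Lambda = matrix(0, 4, 1),
                      general_pattern = matrix(TRUE, 4, 1),
                      G = matrix(0, 4, 1), Theta = rep(1, 4))
  expect_equal(implied_covariance(fm0), diag(4), ignore_attr = TRUE)

  # second-order, m = 2, Gamma = (.6, .8): inter-factor correlation .48,
  # checked against an explicit matrix-product oracle
  pat <- cbind(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE, TRUE))
  L <- ifelse(pat, .7, 0)
  fm2 <- factor_model("second_order", loading_pattern = pat,
                      Lambda = L, Gamma = c(.6, .8), Theta = rep(.51, 4))
  B <- c(.6, .8) %*% t(c(.6, .8)) + diag(c(1 - .36, 1 - .64))
  expect_equal(B[1, 2], 0.48)
  oracle <- L %*% B %*% t(L) + diag(.51, 4)
  expect_equal(implied_covariance(fm2), oracle, ignore_attr = TRUE,
               tolerance = 1e-12)
  # first-order factor variances are 1 under the standardized convention
  expect_equal(diag(B), c(1, 1), ignore_attr = TRUE)

  # bifactor: Lambda Lambda' + G G' + Theta
  gm <- wais_bifactor()
  oracle_b <- tcrossprod(gm$Lambda) + tcrossprod(gm$G) +
    diag(gm$Theta, 15)
  expect_equal(implied_covariance(gm), oracle_b, ignore_attr = TRUE)
})

test_that("factor model specification errors are caught", {
  pat <- matrix(TRUE, 3, 1)
  expect_error(factor_model("correlated_factors", pat,
                            Lambda = matrix(1, 4, 1)), "must be 3 x 1")
  expect_error(factor_model("correlated_factors", pat, Theta = rep(-1, 3)),
               "nonnegative")
  expect_error(factor_model("second_order", pat, Gamma = 1.5), "\\(-1, 1\\)")
  expect_error(factor_model("multi_general", pat), "general_pattern")
})

test_that("partial correlations: independence, closed form, p = 2", {
  expect_equal(partial_correlations(diag(4)), matrix(0, 4, 4),
               ignore_attr = TRUE)

  S <- chain_exact_S()
  w <- partial_correlations(S)
  # closed-form first-order partial: (r12 - r13 r23)/sqrt((1-r13^2)(1-r23^2))
  expect_equal(w[1, 3], 0, tolerance = 1e-12)
  expect_equal(w[1, 2], (.5 - .25 * .5) / sqrt((1 - .25^2) * (1 - .5^2)),
               tolerance = 1e-10)
  expect_equal(w[1, 2], 0.4472136, tolerance = 1e-6)

  S2 <- matrix(c(1, .7, .7, 1), 2)
  expect_equal(partial_correlations(S2)[1, 2], 0.7, tolerance = 1e-12)

  expect_error(partial_correlations(matrix(c(1, 1, 1, 1), 2)),
               "singular|not positive definite")
})

test_that("saturated GGM reproduces any PD matrix (round trip)", {
  m <- saturated_ggm(diag(4))
  expect_equal(m$omega, matrix(0, 4, 4), ignore_attr = TRUE)
  expect_equal(m$delta, rep(1, 4), ignore_attr = TRUE)

  for (seed in 1:5) {
    S <- random_pd_correlation(5, seed)
    g <- saturated_ggm(S)
    expect_lt(max(abs(implied_covariance(g) - S)), 1e-10)
  }

  # delta equals 1/sqrt(diag(S^-1)) (oracle inversion)
  S <- chain_exact_S()
  g <- saturated_ggm(S)
  expect_equal(g$delta, 1 / sqrt(diag(solve(S))), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("implied covariance is equivariant under variable permutation", {
  set.seed(31)
  S <- random_pd_correlation(6, 31)
  g <- saturated_ggm(S)
  perm <- sample(6)
  g_perm <- ggm_model(g$skeleton[perm, perm], omega = g$omega[perm, perm],
                      delta = g$delta[perm], labels = g$labels[perm])
  expect_equal(implied_covariance(g_perm),
               implied_covariance(g)[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("implied covariances are symmetric PD whenever preconditions hold", {
  set.seed(7)
  for (rep in 1:10) {
    theta <- netlatent:::random_interior_point(wais_bifactor())
    Sigma <- netlatent:::implied_from_params(wais_bifactor(), theta)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    expect_equal(Sigma, t(Sigma))
  }
})

test_that("sample_moments enforces its invariants", {
  S <- chain_exact_S()
  expect_error(sample_moments(S, N = 4), "p \\+ 2")
  expect_error(sample_moments(S, N = 10.5), "integer")
  expect_error(sample_moments(S[, c(1, 2)], 100), "square")
  expect_error(sample_moments(S, 100, labels = c("a", "a", "b")), "duplicate")
  Sbad <- S; Sbad[1, 2] <- .6   # asymmetric beyond tolerance
  expect_error(sample_moments(Sbad, 100), "asymmetric")
  Sneg <- matrix(c(1, .999999, .999999, 1e-18), 2)
  expect_error(sample_moments((Sneg + t(Sneg)) / 2, 100),
               "not positive definite")
  m <- sample_moments(S, 100)
  expect_s3_class(m, "sample_moments")
  expect_equal(m$labels, c("x", "y", "z"))
})
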