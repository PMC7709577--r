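# Fit indices: chi-square, df, CFI/TLI, RMSEA with noncentral-chi-square CI,
# AIC/BIC, and the qualitative labels used to read them.

#' Number of free covariance-structure parameters of a model
#'
#' GGM: p scaling values plus one partial correlation per edge. Correlated
#' factors: free loadings + m(m-1)/2 factor correlations + p residuals.
#' Second-order: free loadings + m second-order loadings + p residuals (the
#' first-order disturbances are determined as 1 - gamma^2 under the
#' standardized convention). Bifactor / multi-general: group loadings +
#' general loadings + p residuals.
#'
#' @param model a [ggm_model()] or [factor_model()].
#' @return Integer count.
#' @export
n_free_cov <- function(model) n_free_params(model)

#' Degrees of freedom of a covariance-structure model
#'
#' `p(p+1)/2` distinct covariance moments minus [n_free_cov()]. Negative df
#' means the model is over-parameterized and is an error.
#'
#' @inheritParams n_free_cov
#' @return Nonnegative integer.
#' @export
degrees_of_freedom <- function(model) {
  p <- length(model$labels)
  df <- p * (p + 1) / 2 - n_free_cov(model)
  if (df < 0) {
    stop("model is over-parameterized: ", n_free_cov(model),
         " free parameters exceed ", p * (p + 1) / 2, " covariance moments")
  }
  as.integer(df)
}

#' Model chi-square from the ML discrepancy
#'
#' \eqn{\chi^2 = (N - 1) F_{ML}}.
#'
#' @param F_ml nonnegative discrepancy value.
#' @param N sample size (>= 2).
#' @return Nonnegative scalar.
#' @export
chi_square <- function(F_ml, N) {
  stopifnot(F_ml >= 0, N >= 2)
  (N - 1) * F_ml
}

#' Independence-baseline chi-square
#'
#' The baseline for CFI/TLI is the independence model, a diagonal implied
#' covariance matching `diag(S)`; its minimized discrepancy is
#' \eqn{F_B = -\ln|R|} with `R` the correlation form of `S`.
#'
#' @param moments a [sample_moments()] object.
#' @return List with `chi2` and `df` (`p(p-1)/2`).
#' @export
baseline_chi_square <- function(moments) {
  stopifnot(inherits(moments, "sample_moments"))
  R <- stats::cov2cor(moments$S)
  p <- nrow(R)
  F_B <- -logdet_pd(R)
  list(chi2 = chi_square(F_B, moments$N), df = as.integer(p * (p - 1) / 2))
}

#' Comparative and Tucker-Lewis fit indices
#'
#' \deqn{CFI = 1 - \frac{\max(\chi^2_M - df_M, 0)}
#'                       {\max(\chi^2_B - df_B,\ \chi^2_M - df_M,\ 0)}}
#' (1 when both noncentralities are nonpositive), and
#' \deqn{TLI = \frac{\chi^2_B/df_B - \chi^2_M/df_M}{\chi^2_B/df_B - 1}.}
#' A saturated model (`df_M = 0`) gets CFI = TLI = 1. A degenerate baseline
#' (\eqn{\chi^2_B/df_B \le 1}) yields TLI = 1 with a warning.
#'
#' @param chi2_M,df_M model chi-square and df.
#' @param chi2_B,df_B baseline chi-square and df (`df_B > 0`).
#' @return List with `cfi` and `tli`.
#' @export
cfi_tli <- function(chi2_M, df_M, chi2_B, df_B) {
  stopifnot(df_M >= 0, df_B > 0)
  ncp_M <- chi2_M - df_M
  ncp_B <- chi2_B - df_B
  denom <- max(ncp_B, ncp_M, 0)
  cfi <- if (denom <= 0) 1 else 1 - max(ncp_M, 0) / denom
  ratio_B <- chi2_B / df_B
  if (df_M == 0) {
    tli <- 1
  } else if (ratio_B <= 1) {
    warning("degenerate baseline (chi2_B/df_B <= 1); TLI reported as 1")
    tli <- 1
  } else {
    tli <- (ratio_B - chi2_M / df_M) / (ratio_B - 1)
  }
  list(cfi = cfi, tli = tli)
}

#' RMSEA with its noncentral chi-square confidence interval
#'
#' Point estimate \eqn{\sqrt{\max(\chi^2 - df, 0) / (df (N-1))}}. The CI
#' bounds come from inverting the noncentral chi-square distribution: the
#' noncentralities \eqn{\lambda_L, \lambda_U} solving
#' \eqn{P(\chi^2_{df,\lambda} \le \chi^2) = (1+level)/2} and
#' \eqn{(1-level)/2} (clamped at 0 when no solution exists), transformed by
#' \eqn{\sqrt{\lambda / (df (N-1))}}. Solved by bracketing and bisection on
#' \eqn{[0, 10\chi^2]} to tolerance 1e-8.
#'
#' @param chi2 model chi-square.
#' @param df model degrees of freedom; `df = 0` returns `NA`s with an
#'   explanatory message attribute (RMSEA is undefined for a saturated model).
#' @param N sample size.
#' @param level confidence level of the interval (default 0.90).
#' @return List with `rmsea`, `lower`, `upper`.
#' @export
rmsea_with_ci <- function(chi2, df, N, level = 0.90) {
  stopifnot(N >= 2, level > 0, level < 1)
  if (df == 0) {
    out <- list(rmsea = NA_real_, lower = NA_real_, upper = NA_real_)
    attr(out, "explanation") <- "RMSEA is undefined at df = 0 (saturated model)"
    return(out)
  }
  scale <- df * (N - 1)
  point <- sqrt(max(chi2 - df, 0) / scale)
  lambda_for <- function(target) {
    # largest lambda with P(chi2_{df,lambda} <= chi2) >= target; 0 if none
    if (stats::pchisq(chi2, df, ncp = 0) < target) return(0)
    hi <- max(10 * chi2, df + 10)
    while (stats::pchisq(chi2, df, ncp = hi) > target) hi <- hi * 2
    stats::uniroot(function(l) stats::pchisq(chi2, df, ncp = l) - target,
                   lower = 0, upper = hi, tol = 1e-8)$root
  }
  lambda_L <- lambda_for((1 + level) / 2)
  lambda_U <- lambda_for((1 - level) / 2)
  list(rmsea = point,
       lower = sqrt(max(lambda_L, 0) / scale),
       upper = sqrt(max(lambda_U, 0) / scale))
}

#' Information criteria from the full Gaussian likelihood
#'
#' Computes \eqn{-2\ln L} of the covariance-structure model at its solution,
#' including the constant term so absolute values are comparable across runs
#' on the same data: \eqn{-2\ln L = (N-1)(F_{ML} + \ln|S| + p) + Np\ln 2\pi}.
#' Then \eqn{AIC = -2\ln L + 2k} and \eqn{BIC = -2\ln L + k \ln N}, where `k`
#' defaults to the covariance-structure parameter count ([n_free_cov()]).
#' Because the data-dependent terms are shared, differences between models on
#' the same sample obey \eqn{\Delta AIC = \Delta\chi^2 + 2\Delta k}.
#'
#' @param F_ml minimized discrepancy.
#' @param N sample size.
#' @param k parameter count penalized.
#' @param S the observed matrix (for the likelihood constant), or `NULL` to
#'   drop the constant (differences are unaffected).
#' @return List with `aic`, `bic`, `minus2loglik`.
#' @export
aic_bic <- function(F_ml, N, k, S = NULL) {
  stopifnot(k >= 0, F_ml >= 0)
  const <- 0
  if (!is.null(S)) {
    S <- as.matrix(S)
    p <- nrow(S)
    const <- (N - 1) * (logdet_pd(S) + p) + N * p * log(2 * pi)
  }
  m2ll <- (N - 1) * F_ml + const
  list(aic = m2ll + 2 * k, bic = m2ll + k * log(N), minus2loglik = m2ll)
}

#' Full index set for a converged fit
#'
#' Convenience wrapper assembling chi-square, df, p-value, CFI, TLI, RMSEA
#' with its 90% CI, AIC and BIC for a `netlatent_fit`.
#'
#' @param fit a `netlatent_fit`.
#' @param level RMSEA confidence level.
#' @return An object of class `fit_indices`: a list with fields `chi2`, `df`,
#'   `p_value`, `cfi`, `tli`, `rmsea`, `rmsea_lower`, `rmsea_upper`, `aic`,
#'   `bic`, `n_free_cov`.
#' @export
fit_indices <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "netlatent_fit"))
  moments <- fit$moments
  N <- moments$N
  chi2 <- chi_square(fit$F_ml, N)
  df <- degrees_of_freedom(fit$model)
  base <- baseline_chi_square(moments)
  ct <- cfi_tli(chi2, df, base$chi2, base$df)
  rm_ci <- if (df > 0) rmsea_with_ci(chi2, df, N, level)
           else list(rmsea = 0, lower = 0, upper = 0)
  ic <- aic_bic(fit$F_ml, N, k = fit$n_free_cov, S = moments$S)
  structure(list(chi2 = chi2, df = df,
                 p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else 1,
                 cfi = ct$cfi, tli = ct$tli,
                 rmsea = rm_ci$rmsea, rmsea_lower = rm_ci$lower,
                 rmsea_upper = rm_ci$upper,
                 aic = ic$aic, bic = ic$bic,
                 n_free_cov = fit$n_free_cov),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.2f, p %s\n", x$df, x$chi2,
              format_pvalue(x$p_value)))
  cat(sprintf("CFI = %.3f, TLI = %.3f, RMSEA = %.3f [%.3f-%.3f]\n",
              x$cfi, x$tli, x$rmsea, x$rmsea_lower, x$rmsea_upper))
  cat(sprintf("AIC = %.2f, BIC = %.2f (k = %d)\n", x$aic, x$bic, x$n_free_cov))
  invisible(x)
}

format_pvalue <- function(p) if (is.na(p)) "NA" else if (p < 0.001) "<0.001" else sprintf("= %.3f", p)

#' Qualitative fit labels
#'
#' Applies the standard evaluation thresholds: RMSEA `<= 0.05` good,
#' `(0.05, 0.08]` adequate, `(0.08, 0.10]` mediocre, `> 0.10` unacceptable;
#' CFI/TLI `> 0.97` good, `[0.95, 0.97]` acceptable, `< 0.95`
#' below-acceptable.
#'
#' @param indices a [fit_indices()] object (or any list with `rmsea`, `cfi`,
#'   `tli`).
#' @return List of labels `rmsea`, `cfi`, `tli`.
#' @export
qualify_fit <- function(indices) {
  rmsea_label <- function(x) {
    if (is.na(x)) NA_character_
    else if (x <= 0.05) "good"
    else if (x <= 0.08) "adequate"
    else if (x <= 0.10) "mediocre"
    else "unacceptable"
  }
  cfi_label <- function(x) {
    if (is.na(x)) NA_character_
    else if (x > 0.97) "good"
    else if (x >= 0.95) "acceptable"
    else "below-acceptable"
  }
  list(rmsea = rmsea_label(indices$rmsea),
       cfi = cfi_label(indices$cfi),
       tli = cfi_label(indices$tli))
}
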