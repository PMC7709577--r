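#' Standard errors from the observed information, with singularity diagnosis
#'
#' Computes standard errors for a converged fit from the inverse of the
#' observed information of the discrepancy: the Hessian of
#' \eqn{\tfrac{N-1}{2} F_{ML}} at the solution is the (observed) Fisher
#' information of the covariance-structure likelihood, and its inverse
#' diagonal gives the squared standard errors. SEs therefore scale as
#' \eqn{1/\sqrt{N-1}}.
#'
#' When the information matrix is singular beyond tolerance the function does
#' **not** fall back to a pseudo-inverse: it returns `NA` standard errors,
#' sets `singular = TRUE`, and names the parameters implicated in the
#' near-null space. Uncomputable standard errors are symptomatic of a
#' nonidentified model, so this pathway is itself a diagnostic, not an error.
#'
#' @param fit a converged `netlatent_fit` (from [fit_ggm()] or
#'   [fit_factor()]).
#' @param moments the [sample_moments()] the model was fitted to; defaults to
#'   the moments stored in `fit`.
#' @param sv_tolerance eigenvalues of the information below `sv_tolerance`
#'   times the largest are treated as zero.
#' @return A list with `se` (named vector, `NA` where uncomputable),
#'   `singular` (logical), `null_space_params` (names of parameters with
#'   appreciable weight in the near-null space; empty when nonsingular), and
#'   `information` (the information matrix itself).
#' @export
standard_errors <- function(fit, moments = fit$moments, sv_tolerance = 1e-8) {
  stopifnot(inherits(fit, "netlatent_fit"))
  if (!isTRUE(fit$converged)) {
    stop("standard errors require a converged fit (converged = FALSE)")
  }
  model <- fit$model
  tab <- param_table(model)
  theta <- free_params(model)
  S <- moments$S
  p <- nrow(S)
  ldS <- logdet_pd(S)

  fn <- function(th) {
    Sigma <- implied_from_params(model, th)
    if (is.null(Sigma)) return(NA_real_)
    fml_value(S, Sigma, ldS, p)
  }
  H <- num_hessian(fn, theta)
  info <- (moments$N - 1) / 2 * H
  info <- (info + t(info)) / 2
  dimnames(info) <- list(tab$name, tab$name)

  eg <- eigen(info, symmetric = TRUE)
  ev <- eg$values
  singular <- min(ev) <= sv_tolerance * max(abs(ev))
  if (singular) {
    null_idx <- which(ev <= sv_tolerance * max(abs(ev)))
    weights <- sqrt(rowSums(eg$vectors[, null_idx, drop = FALSE]^2))
    implicated <- tab$name[weights > 1 / sqrt(length(theta))]
    se <- stats::setNames(rep(NA_real_, length(theta)), tab$name)
    return(list(se = se, singular = TRUE, null_space_params = implicated,
                information = info))
  }
  covm <- eg$vectors %*% diag(1 / ev, length(ev)) %*% t(eg$vectors)
  d <- diag(covm)
  se <- stats::setNames(ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_), tab$name)
  list(se = se, singular = FALSE, null_space_params = character(0),
       information = info)
}

# central-difference Hessian (O(n^2) evaluations), step scaled per parameter
num_hessian <- function(fn, x, h = 1e-4) {
  n <- length(x)
  hs <- pmax(abs(x), 1) * h
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- xp[i] + hs[i]
        xm <- x; xm[i] <- xm[i] - hs[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / hs[i]^2
      } else {
        xpp <- x; xpp[i] <- xpp[i] + hs[i]; xpp[j] <- xpp[j] + hs[j]
        xpm <- x; xpm[i] <- xpm[i] + hs[i]; xpm[j] <- xpm[j] - hs[j]
        xmp <- x; xmp[i] <- xmp[i] - hs[i]; xmp[j] <- xmp[j] + hs[j]
        xmm <- x; xmm[i] <- xmm[i] - hs[i]; xmm[j] <- xmm[j] - hs[j]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * hs[i] * hs[j])
      }
    }
  }
  if (anyNA(H)) stop("Hessian evaluation hit an invalid parameter region")
  H
}
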