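#' Local identification check via the Jacobian of the implied covariance
#'
#' A covariance-structure model is locally identified when distinct parameter
#' values near a point imply distinct covariance matrices, which holds iff the
#' Jacobian of the half-vectorized implied covariance with respect to the free
#' parameters has full column rank there. The check evaluates that Jacobian
#' numerically at `n_points` random interior parameter points and takes the
#' maximum observed rank (rank can only drop on a measure-zero set, so the
#' maximum over several generic points is the generic rank).
#'
#' A model with more free parameters than distinct covariance moments
#' (`n_free > p(p+1)/2`) is never identified.
#'
#' This is the diagnostic that separates the bifactor model (one general
#' factor: identified) from multi-general-factor extensions such as the
#' four-general-factor "penta" structure, whose general-factor block can be
#' rotated without changing the implied covariance, making the model
#' nonidentified and its fit statistics invalid.
#'
#' @param model a [ggm_model()] or [factor_model()].
#' @param n_points number of random parameter points to probe.
#' @param seed integer seed for the random draws.
#' @param sv_tolerance singular values below `sv_tolerance` times the largest
#'   are treated as zero when computing the rank.
#' @return A list with `identified` (logical), `rank`, `n_free`,
#'   `deficiency = n_free - rank`, and `n_moments = p(p+1)/2`.
#' @export
check_identification <- function(model, n_points = 5L, seed = 1L,
                                 sv_tolerance = 1e-8) {
  stopifnot(inherits(model, c("ggm_model", "factor_model")))
  tab <- param_table(model)
  n_free <- nrow(tab)
  p <- length(model$labels)
  n_moments <- p * (p + 1) / 2

  set.seed(seed)
  best_rank <- 0L
  for (pt in seq_len(n_points)) {
    theta <- random_interior_point(model, tab)
    J <- implied_jacobian(model, theta)
    sv <- svd(J, nu = 0, nv = 0)$d
    r <- sum(sv > sv_tolerance * max(sv))
    best_rank <- max(best_rank, r)
    if (best_rank == n_free) break
  }
  list(identified = best_rank == n_free && n_free <= n_moments,
       rank = best_rank,
       n_free = n_free,
       deficiency = n_free - best_rank,
       n_moments = n_moments)
}

# Draw a random valid interior parameter point for the Jacobian probe.
# Redraws (up to a cap) until the implied covariance is positive definite.
random_interior_point <- function(model, tab = param_table(model),
                                  max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    theta <- vapply(tab$type, function(tp) {
      switch(tp,
             delta   = stats::runif(1, 0.8, 1.2),
             omega   = stats::runif(1, -0.25, 0.25),
             loading = stats::runif(1, 0.3, 0.9),
             phi     = stats::runif(1, -0.4, 0.4),
             gamma   = stats::runif(1, 0.4, 0.9),
             general = stats::runif(1, 0.2, 0.6),
             theta   = stats::runif(1, 0.3, 0.7))
    }, numeric(1))
    Sigma <- implied_from_params(model, theta)
    if (!is.null(Sigma) && is_positive_definite(Sigma)) return(theta)
  }
  stop("could not draw a valid interior parameter point in ", max_tries,
       " tries; the model structure may be degenerate")
}

# Numeric Jacobian of vech(Sigma(theta)) wrt the natural free parameters.
implied_jacobian <- function(model, theta, h = 1e-6) {
  n_free <- length(theta)
  p <- length(model$labels)
  J <- matrix(0, p * (p + 1) / 2, n_free)
  for (k in seq_len(n_free)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    Sp <- implied_from_params(model, tp)
    Sm <- implied_from_params(model, tm)
    if (is.null(Sp) || is.null(Sm)) {
      # one-sided fallback at a constraint boundary
      S0 <- implied_from_params(model, theta)
      if (!is.null(Sp))      J[, k] <- (vech(Sp) - vech(S0)) / h
      else if (!is.null(Sm)) J[, k] <- (vech(S0) - vech(Sm)) / h
      else stop("Jacobian evaluation failed at parameter ", k)
    } else {
      J[, k] <- (vech(Sp) - vech(Sm)) / (2 * h)
    }
  }
  J
}
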