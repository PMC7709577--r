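#' Estimation settings
#'
#' Bundles the knobs shared by the fitting, pruning, and identification
#' routines.
#'
#' @param gradient_tolerance convergence criterion: a fit is declared
#'   converged when the maximum absolute gradient of the discrepancy (in the
#'   optimizer's unconstrained coordinates) falls below this value.
#' @param max_iterations iteration cap for the quasi-Newton optimizer.
#' @param alpha two-sided significance level used when pruning edges.
#' @param prune_recursive if `TRUE`, [prune()] refits the constrained GGM and
#'   repeats the significance test until no further edge is removed; the
#'   default is a single calculate-then-prune pass.
#' @param n_starts number of optimizer starts (the first is data-informed,
#'   the rest are jittered).
#' @param seed integer seed driving the jittered starts and the random points
#'   of the identification check.
#' @return A list of class `estimation_settings`.
#' @export
estimation_settings <- function(gradient_tolerance = 1e-6,
                                max_iterations = 10000L,
                                alpha = 0.01,
                                prune_recursive = FALSE,
                                n_starts = 3L,
                                seed = 1L) {
  stopifnot(gradient_tolerance > 0, max_iterations > 0,
            alpha > 0, alpha < 1, n_starts >= 1)
  structure(list(gradient_tolerance = gradient_tolerance,
                 max_iterations = as.integer(max_iterations),
                 alpha = alpha,
                 prune_recursive = isTRUE(prune_recursive),
                 n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "estimation_settings")
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The standard SEM fitting function
#' \deqn{F_{ML} = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p,}
#' which is zero if and only if \eqn{\Sigma = S} and is the quantity both
#' model families minimize, so that every model — network or latent variable —
#' is judged against the same observed matrix. \eqn{(N-1) F_{ML}} is the model
#' chi-square.
#'
#' @param S observed symmetric positive-definite p x p matrix.
#' @param Sigma model-implied symmetric positive-definite p x p matrix.
#' @return Nonnegative scalar discrepancy.
#' @export
fml_discrepancy <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  if (!all(dim(S) == dim(Sigma))) {
    stop("dimension mismatch: S is ", nrow(S), " x ", ncol(S),
         ", Sigma is ", nrow(Sigma), " x ", ncol(Sigma))
  }
  p <- nrow(S)
  ldS <- logdet_pd(S)
  if (is.na(ldS)) stop("S is not positive definite")
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("Sigma is not positive definite")
  ldSigma <- 2 * sum(log(diag(ch)))
  Sigma_inv <- chol2inv(ch)
  max(ldSigma - ldS + sum(Sigma_inv * S) - p, 0)
}

# fast unguarded version used inside the optimizer: returns a large penalty
# (gently sloped away from the boundary) when Sigma is not PD
fml_value <- function(S, Sigma, ldS, p) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ev_min <- min(eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values)
    return(1e10 + 1e10 * abs(ev_min))
  }
  2 * sum(log(diag(ch))) - ldS + sum(chol2inv(ch) * S) - p
}

# central-difference gradient in unconstrained coordinates
num_gradient <- function(fn, u, h = 1e-6) {
  g <- numeric(length(u))
  for (k in seq_along(u)) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    g[k] <- (fn(up) - fn(um)) / (2 * h)
  }
  g
}

# Core quasi-Newton fit over a model's free parameters.
# Returns the elements shared by fit_ggm and fit_factor.
fit_covstruct <- function(moments, model, settings) {
  S <- moments$S
  p <- nrow(S)
  ldS <- logdet_pd(S)
  tab <- param_table(model)
  types <- tab$type
  theta0 <- free_params(model)

  objective <- function(u) {
    Sigma <- implied_from_params(model, to_natural(u, types))
    if (is.null(Sigma)) return(1e12)
    fml_value(S, Sigma, ldS, p)
  }
  gradient <- function(u) fml_gradient_unconstrained(model, u, types, S)

  u0 <- to_unconstrained(theta0, types)
  starts <- list(u0)
  if (settings$n_starts > 1) {
    set.seed(settings$seed)
    for (s in seq_len(settings$n_starts - 1L)) {
      starts[[s + 1L]] <- u0 + stats::rnorm(length(u0), sd = 0.25)
    }
  }

  best <- NULL
  for (u_start in starts) {
    res <- tryCatch(
      stats::optim(u_start, objective, gradient, method = "BFGS",
                   control = list(maxit = settings$max_iterations,
                                  reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    # restart BFGS (fresh Hessian approximation) until the gradient is flat
    for (r in 1:5) {
      if (max(abs(gradient(res$par))) <= settings$gradient_tolerance) break
      res2 <- tryCatch(
        stats::optim(res$par, objective, gradient, method = "BFGS",
                     control = list(maxit = settings$max_iterations,
                                    reltol = 1e-14)),
        error = function(e) NULL)
      if (is.null(res2) || res2$value > res$value + 1e-15) break
      res <- res2
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimizer starts failed; the model/starting values may be degenerate")
  }

  grad <- gradient(best$par)
  theta_hat <- stats::setNames(to_natural(best$par, types), tab$name)
  fitted_model <- set_free_params(model, theta_hat)
  F_ml <- max(best$value, 0)
  gradient_norm <- max(abs(grad))

  list(model = fitted_model,
       theta_hat = stats::setNames(free_params(fitted_model), tab$name),
       F_ml = F_ml,
       converged = gradient_norm <= settings$gradient_tolerance &&
                   F_ml < 1e9,
       gradient_norm = gradient_norm)
}

new_fit_result <- function(core, moments, model_name) {
  structure(list(model = core$model,
                 theta_hat = core$theta_hat,
                 F_ml = core$F_ml,
                 converged = core$converged,
                 gradient_norm = core$gradient_norm,
                 n_free_cov = n_free_params(core$model),
                 se = NULL,
                 nonidentified = isTRUE(core$nonidentified),
                 moments = moments,
                 model_name = model_name),
            class = "netlatent_fit")
}

#' @export
print.netlatent_fit <- function(x, ...) {
  cat("<netlatent_fit> ", x$model_name, "\n", sep = "")
  cat("  F_ml = ", format(x$F_ml, digits = 8),
      ", free parameters = ", x$n_free_cov,
      ", converged = ", x$converged,
      " (max |grad| = ", format(x$gradient_norm, digits = 3), ")\n", sep = "")
  if (isTRUE(x$nonidentified)) {
    cat("  WARNING: model flagged NONIDENTIFIED; fit statistics are not",
        "interpretable\n")
  }
  invisible(x)
}

#' Fit a Gaussian graphical model with a fixed skeleton
#'
#' Minimizes [fml_discrepancy()] over the free partial correlations (the
#' skeleton's edges) and the scaling values delta. With a complete skeleton
#' the model is saturated and reproduces `S` exactly (the closed form
#' [saturated_ggm()] is used as the starting point, so `F_ml` is numerically
#' zero); removing edges can only increase the minimized discrepancy.
#'
#' @param moments a [sample_moments()] object.
#' @param skeleton symmetric logical adjacency matrix (or a `ggm_model` whose
#'   skeleton is used).
#' @param settings an [estimation_settings()] object.
#' @return A `netlatent_fit` object; `$model` holds the fitted `ggm_model`.
#' @export
fit_ggm <- function(moments, skeleton, settings = estimation_settings()) {
  stopifnot(inherits(moments, "sample_moments"))
  if (inherits(skeleton, "ggm_model")) skeleton <- skeleton$skeleton
  skeleton <- as.matrix(skeleton)
  mode(skeleton) <- "logical"
  p <- length(moments$labels)
  if (!all(dim(skeleton) == p)) stop("skeleton must be ", p, " x ", p)

  # complete skeleton: the saturated model has the closed-form ML solution
  # Omega = partial_correlations(S), Delta = diag(S^-1)^(-1/2); no iteration
  if (all(skeleton[upper.tri(skeleton)])) {
    sat <- saturated_ggm(moments$S)
    core <- list(model = sat,
                 theta_hat = free_params(sat),
                 F_ml = fml_discrepancy(moments$S, implied_covariance(sat)),
                 converged = TRUE,
                 gradient_norm = 0)
    return(new_fit_result(core, moments, model_name = "network"))
  }

  # data-informed start: saturated solution projected onto the skeleton
  sat <- saturated_ggm(moments$S)
  omega0 <- sat$omega
  omega0[!skeleton] <- 0
  # projection can leave I - Omega non-PD for dense skeletons; shrink if so
  shrink <- 1
  while (!is_positive_definite(diag(p) - shrink * omega0) && shrink > 1e-3) {
    shrink <- shrink / 2
  }
  start <- ggm_model(skeleton, omega = shrink * omega0, delta = sat$delta,
                     labels = moments$labels)
  core <- fit_covstruct(moments, start, settings)
  new_fit_result(core, moments, model_name = "network")
}

#' Fit a confirmatory factor model
#'
#' Minimizes [fml_discrepancy()] over the free loadings, factor correlations
#' (or second-order loadings) and residual variances under the standardized
#' convention (all factor variances fixed to 1). Before fitting, the model's
#' local identification is checked with [check_identification()]; a
#' nonidentified model is refused, because its fit statistics are not
#' interpretable, unless `override_identification = TRUE`, in which case the
#' returned fit carries a `nonidentified` flag.
#'
#' After convergence each factor's sign is canonicalized so its
#' largest-magnitude loading is positive (factor loadings are only identified
#' up to a column sign flip).
#'
#' @param moments a [sample_moments()] object.
#' @param model a [factor_model()]; its parameter values seed the first
#'   optimizer start.
#' @param settings an [estimation_settings()] object.
#' @param override_identification fit even if the identification check fails.
#' @return A `netlatent_fit` object; `$model` holds the fitted `factor_model`.
#' @export
fit_factor <- function(moments, model, settings = estimation_settings(),
                       override_identification = FALSE) {
  stopifnot(inherits(moments, "sample_moments"),
            inherits(model, "factor_model"))
  p <- length(moments$labels)
  if (length(model$labels) != p) {
    stop("model has ", length(model$labels), " indicators but the sample has ", p)
  }
  ident <- check_identification(model, seed = settings$seed)
  if (!ident$identified && !override_identification) {
    stop("the factor model is locally nonidentified (Jacobian rank ",
         ident$rank, " < ", ident$n_free, " free parameters, deficiency ",
         ident$deficiency, "); its fit statistics would be invalid. ",
         "Set override_identification = TRUE to fit anyway (results will ",
         "carry a NONIDENTIFIED flag).")
  }
  core <- fit_covstruct(moments, model, settings)
  core$model <- canonicalize_signs(core$model)
  core$theta_hat <- free_params(core$model)
  core$nonidentified <- !ident$identified
  fit <- new_fit_result(core, moments, model_name = model$kind)
  if (fit$nonidentified) {
    warning("NONIDENTIFIED model fitted on explicit override; ",
            "fit statistics are not interpretable")
  }
  fit
}

# flip factor columns so the largest-|loading| per factor is positive
canonicalize_signs <- function(model) {
  if (!inherits(model, "factor_model")) return(model)
  m <- length(model$factor_names)
  for (f in seq_len(m)) {
    col <- model$Lambda[, f]
    if (all(col == 0)) next
    if (col[which.max(abs(col))] < 0) {
      model$Lambda[, f] <- -col
      if (model$kind == "correlated_factors" && m > 1) {
        model$Phi[f, ] <- -model$Phi[f, ]
        model$Phi[, f] <- -model$Phi[, f]
        model$Phi[f, f] <- 1
      }
      if (model$kind == "second_order") model$Gamma[f] <- -model$Gamma[f]
    }
  }
  if (model$kind == "second_order" && any(model$Gamma != 0)) {
    if (model$Gamma[which.max(abs(model$Gamma))] < 0) model$Gamma <- -model$Gamma
  }
  if (!is.null(model$G)) {
    for (q in seq_len(ncol(model$G))) {
      col <- model$G[, q]
      if (all(col == 0)) next
      if (col[which.max(abs(col))] < 0) model$G[, q] <- -col
    }
  }
  model
}
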