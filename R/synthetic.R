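# Synthetic populations and finite samples with the statistical structure the
# analysis assumes: population covariances generated either by a sparse GGM
# (Sigma = Delta (I - Omega)^-1 Delta) or by a factor model, then multivariate
# normal sampling at configurable N. Used by the test suite and by users who
# want calibration/power experiments without any external data.

#' Random population model and its exact covariance matrix
#'
#' `mechanism = "ggm"`: draws a random skeleton (each of the p(p-1)/2
#' possible edges present independently with probability `density`), edge
#' weights uniform in `weight_range` (positive by default, emulating the
#' predominantly positive edges that produce a positive manifold of
#' correlations), and chooses delta to standardize the implied covariance to
#' a correlation matrix. Draws are rejected until `I - Omega` is positive
#' definite (up to `max_tries`).
#'
#' `mechanism = "factor"`: `m` factors with simple structure (indicators
#' assigned round-robin), loadings uniform in `loading_range`, factor
#' correlations all `phi_offdiag`, and residual variances `1 - communality`
#' so the population matrix is a correlation matrix.
#'
#' @param mechanism `"ggm"` or `"factor"`.
#' @param p number of observed variables.
#' @param density edge probability of the GGM skeleton, in (0, 1]; `0` gives
#'   the empty network (identity covariance).
#' @param weight_range range of |omega| for present edges.
#' @param positive_only if `TRUE` (default) edge weights are positive;
#'   otherwise signs are random.
#' @param m number of factors (factor mechanism).
#' @param loading_range range of factor loadings.
#' @param phi_offdiag common factor correlation (factor mechanism, m > 1).
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap for a positive-definite draw.
#' @return List with `model` (a [ggm_model()] or [factor_model()]) and
#'   `sigma` (the population correlation matrix it implies, exactly).
#' @export
random_population <- function(mechanism = c("ggm", "factor"), p = 15,
                              density = 0.35, weight_range = c(0.1, 0.4),
                              positive_only = TRUE,
                              m = 3, loading_range = c(0.5, 0.8),
                              phi_offdiag = 0.3,
                              seed = 1L, max_tries = 2000L) {
  mechanism <- match.arg(mechanism)
  set.seed(seed)
  if (mechanism == "ggm") {
    for (try in seq_len(max_tries)) {
      skeleton <- matrix(FALSE, p, p)
      n_pairs <- p * (p - 1) / 2
      edges <- stats::runif(n_pairs) < density
      skeleton[upper.tri(skeleton)] <- edges
      skeleton <- skeleton | t(skeleton)
      omega <- matrix(0, p, p)
      w <- stats::runif(n_pairs, weight_range[1], weight_range[2])
      if (!positive_only) w <- w * sign(stats::runif(n_pairs) - 0.5)
      omega[upper.tri(omega)] <- ifelse(edges, w, 0)
      omega <- omega + t(omega)
      if (!is_positive_definite(diag(p) - omega)) next
      A <- solve(diag(p) - omega)
      delta <- 1 / sqrt(diag(A))      # standardizes Sigma to correlation scale
      model <- ggm_model(skeleton, omega = omega, delta = delta)
      return(list(model = model, sigma = implied_covariance(model)))
    }
    stop("no positive-definite GGM draw in ", max_tries,
         " tries; lower density or the weight range")
  }
  # factor mechanism
  assignment <- rep(seq_len(m), length.out = p)
  pattern <- matrix(FALSE, p, m,
                    dimnames = list(paste0("V", seq_len(p)), paste0("F", seq_len(m))))
  pattern[cbind(seq_len(p), assignment)] <- TRUE
  lambda <- matrix(0, p, m)
  lambda[pattern] <- stats::runif(p, loading_range[1], loading_range[2])
  Phi <- matrix(phi_offdiag, m, m); diag(Phi) <- 1
  if (m > 1) check_positive_definite(Phi, context = "factor correlation matrix")
  communality <- rowSums((lambda %*% Phi) * lambda)
  if (any(communality >= 1)) stop("communalities reach 1; narrow loading_range")
  model <- factor_model("correlated_factors", loading_pattern = pattern,
                        Lambda = lambda, Phi = Phi, Theta = 1 - communality)
  list(model = model, sigma = implied_covariance(model))
}

#' Draw sample moments from a population covariance
#'
#' Draws `N` independent multivariate normal vectors (zero mean, covariance
#' `sigma`) and returns their sample covariance or correlation matrix as a
#' [sample_moments()] object. Same seed, same sample, bit for bit.
#'
#' @param sigma population covariance (positive definite).
#' @param N sample size; `N <= p` triggers a singular-risk warning but
#'   proceeds.
#' @param seed integer seed.
#' @param type `"correlation"` (default, matching correlation-matrix input
#'   conventions) or `"covariance"`.
#' @return A [sample_moments()] with attribute `seed`.
#' @export
draw_sample_moments <- function(sigma, N, seed = 1L,
                                type = c("correlation", "covariance")) {
  type <- match.arg(type)
  sigma <- as.matrix(sigma)
  p <- nrow(sigma)
  if (N <= p) warning("N <= p: the sample matrix is at risk of singularity")
  set.seed(seed)
  Z <- matrix(stats::rnorm(N * p), N, p)
  X <- Z %*% chol(sigma)
  S <- if (type == "correlation") stats::cor(X) else stats::cov(X)
  if (!is_positive_definite(S)) {
    stop("the sampled moment matrix is not positive definite (N = ", N,
         ", p = ", p, "); it is reported, not silently fixed")
  }
  labels <- if (!is.null(rownames(sigma))) rownames(sigma) else paste0("V", seq_len(p))
  out <- sample_moments(S, N, labels = labels)
  attr(out, "seed") <- seed
  out
}

#' Edge-recovery and calibration experiment
#'
#' Repeats generate-sample-prune(-fit) against a fixed population model and
#' summarizes skeleton recovery: edge sensitivity (true edges found),
#' specificity (true non-edges kept out), the per-test false-edge rate
#' (which should approximate `alpha` when the null holds), the proportion of
#' replications recovering the skeleton exactly, and (with `refit = TRUE`)
#' the RMSE of the re-estimated partial correlations against truth.
#'
#' `N = Inf` skips sampling and fits the population matrix directly
#' (population-recovery mode: the pruned skeleton and refitted parameters
#' should reproduce the truth to optimizer tolerance).
#'
#' @param population output of [random_population()] (or a list with `model`
#'   and `sigma` built by hand) with a GGM mechanism.
#' @param N per-replication sample size (or `Inf`).
#' @param n_reps number of replications.
#' @param alpha pruning significance level.
#' @param seed integer seed; replication r uses `1009 * seed + r` so distinct
#'   master seeds give disjoint replication streams.
#' @param refit refit the pruned GGM each replication to measure omega RMSE
#'   (slower; off by default).
#' @return List of summary statistics plus the per-replication edge counts.
#' @export
recovery_experiment <- function(population, N, n_reps = 100, alpha = 0.01,
                                seed = 1L, refit = FALSE) {
  model <- population$model
  stopifnot(inherits(model, "ggm_model"))
  sigma <- population$sigma
  p <- nrow(sigma)
  true_edges <- model$skeleton[upper.tri(model$skeleton)]
  settings <- estimation_settings(alpha = alpha, seed = seed)

  if (is.infinite(N)) {
    # population-recovery mode: no sampling error, single pass
    moments <- sample_moments(sigma, N = 100000L,
                              labels = model$labels)
    skeleton <- prune(moments, settings)
    fit <- fit_ggm(moments, skeleton, settings)
    rmse <- sqrt(mean((fit$model$omega - model$omega)^2))
    found <- skeleton[upper.tri(skeleton)]
    return(list(sensitivity = mean(found[true_edges]),
                specificity = if (any(!true_edges)) mean(!found[!true_edges]) else NA,
                false_edge_rate = if (any(!true_edges)) mean(found[!true_edges]) else NA,
                exact_recovery_rate = as.numeric(identical(found, true_edges)),
                omega_rmse = rmse, n_reps = 1))
  }

  hits <- misses <- false_pos <- true_neg <- 0
  exact <- 0
  rmse_acc <- c()
  for (r in seq_len(n_reps)) {
    moments <- draw_sample_moments(sigma, N, seed = 1009L * seed + r)
    skeleton <- prune(moments, settings)
    found <- skeleton[upper.tri(skeleton)]
    hits <- hits + sum(found & true_edges)
    misses <- misses + sum(!found & true_edges)
    false_pos <- false_pos + sum(found & !true_edges)
    true_neg <- true_neg + sum(!found & !true_edges)
    if (identical(found, true_edges)) exact <- exact + 1
    if (refit) {
      fit <- fit_ggm(moments, skeleton, settings)
      rmse_acc <- c(rmse_acc, sqrt(mean((fit$model$omega - model$omega)^2)))
    }
  }
  list(sensitivity = if (hits + misses > 0) hits / (hits + misses) else NA,
       specificity = if (false_pos + true_neg > 0) true_neg / (false_pos + true_neg) else NA,
       false_edge_rate = if (false_pos + true_neg > 0) false_pos / (false_pos + true_neg) else NA,
       exact_recovery_rate = exact / n_reps,
       omega_rmse = if (refit) mean(rmse_acc) else NA,
       n_reps = n_reps)
}
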