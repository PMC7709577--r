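# Shared fixtures and independent oracles. Everything is built in code; no
# data files.

# 3-variable correlation matrix in which r13 = r12 * r23 exactly, so the
# partial correlation between 1 and 3 vanishes and a 1-2-3 chain fits
# perfectly.
chain_exact_S <- function() {
  S <- matrix(c(1, .5, .25,
                .5, 1, .5,
                .25, .5, 1), 3, 3)
  dimnames(S) <- list(c("x", "y", "z"), c("x", "y", "z"))
  S
}

# 3-variable matrix where the 1-3 partial is NOT zero, so the chain model
# misfits and the minimized discrepancy is strictly positive.
chain_misfit_S <- function() {
  S <- matrix(c(1, .5, .4,
                .5, 1, .5,
                .4, .5, 1), 3, 3)
  dimnames(S) <- list(c("x", "y", "z"), c("x", "y", "z"))
  S
}

chain_skeleton <- function() {
  sk <- matrix(c(FALSE, TRUE, FALSE,
                 TRUE, FALSE, TRUE,
                 FALSE, TRUE, FALSE), 3, 3)
  dimnames(sk) <- list(c("x", "y", "z"), c("x", "y", "z"))
  sk
}

random_pd_correlation <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  stats::cov2cor(crossprod(A) + diag(p))
}

# Independent brute-force minimizer: iterative zooming grid search over a
# parameter box. builder(par) must return the implied covariance or NULL
# outside the valid region. Never calls the package's optimizer.
grid_search_fml <- function(S, builder, lower, upper, rounds = 5, points = 9) {
  n <- length(lower)
  best_par <- (lower + upper) / 2
  best_val <- Inf
  width <- upper - lower
  for (round in seq_len(rounds)) {
    grids <- lapply(seq_len(n), function(k) {
      seq(max(lower[k], best_par[k] - width[k] / 2),
          min(upper[k], best_par[k] + width[k] / 2), length.out = points)
    })
    combos <- as.matrix(expand.grid(grids))
    for (r in seq_len(nrow(combos))) {
      Sigma <- builder(combos[r, ])
      if (is.null(Sigma)) next
      val <- tryCatch(fml_discrepancy(S, Sigma), error = function(e) Inf)
      if (val < best_val) {
        best_val <- val
        best_par <- combos[r, ]
      }
    }
    width <- width * (2 / (points - 1))  # zoom in around the incumbent
  }
  list(value = best_val, par = best_par)
}

# population chain GGM on p nodes, omega on consecutive pairs
chain_population <- function(p = 6, omega = 0.3) {
  sk <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1)) sk[i, i + 1] <- sk[i + 1, i] <- TRUE
  om <- matrix(0, p, p)
  for (i in seq_len(p - 1)) om[i, i + 1] <- om[i + 1, i] <- omega
  A <- solve(diag(p) - om)
  delta <- 1 / sqrt(diag(A))
  model <- ggm_model(sk, omega = om, delta = delta)
  list(model = model, sigma = implied_covariance(model))
}
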