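# Free-parameter bookkeeping for both model families.
#
# Every fit-related computation (optimization, standard errors, Jacobian rank)
# works on the *natural* free-parameter vector defined here. The optimizer
# additionally maps each parameter to an unconstrained scale so iterates stay
# in the valid region without projection:
#   - partial correlations, factor correlations, second-order loadings: atanh
#   - scaling values delta and residual variances theta: log
#   - factor loadings: identity (unbounded)

param_table <- function(model) UseMethod("param_table")

#' @export
param_table.ggm_model <- function(model) {
  p <- length(model$labels)
  ut <- which(upper.tri(model$skeleton) & model$skeleton, arr.ind = TRUE)
  rbind(
    data.frame(name = paste0("delta_", model$labels), type = "delta",
               i = seq_len(p), j = 0L, stringsAsFactors = FALSE),
    if (nrow(ut) > 0)
      data.frame(name = paste0("omega_", model$labels[ut[, 1]], ".",
                               model$labels[ut[, 2]]),
                 type = "omega", i = ut[, 1], j = ut[, 2],
                 stringsAsFactors = FALSE)
  )
}

#' @export
param_table.factor_model <- function(model) {
  p <- length(model$labels)
  m <- length(model$factor_names)
  tabs <- list()
  lp <- which(model$loading_pattern, arr.ind = TRUE)
  tabs$lambda <- data.frame(
    name = paste0("lambda_", model$labels[lp[, 1]], ".",
                  model$factor_names[lp[, 2]]),
    type = "loading", i = lp[, 1], j = lp[, 2], stringsAsFactors = FALSE)
  if (model$kind == "correlated_factors" && m > 1) {
    ut <- which(upper.tri(diag(m)), arr.ind = TRUE)
    tabs$phi <- data.frame(
      name = paste0("phi_", model$factor_names[ut[, 1]], ".",
                    model$factor_names[ut[, 2]]),
      type = "phi", i = ut[, 1], j = ut[, 2], stringsAsFactors = FALSE)
  }
  if (model$kind == "second_order") {
    tabs$gamma <- data.frame(
      name = paste0("gamma_", model$factor_names),
      type = "gamma", i = seq_len(m), j = 0L, stringsAsFactors = FALSE)
  }
  if (!is.null(model$general_pattern)) {
    gp <- which(model$general_pattern, arr.ind = TRUE)
    tabs$g <- data.frame(
      name = paste0("g_", model$labels[gp[, 1]], ".",
                    colnames(model$general_pattern)[gp[, 2]]),
      type = "general", i = gp[, 1], j = gp[, 2], stringsAsFactors = FALSE)
  }
  tabs$theta <- data.frame(
    name = paste0("theta_", model$labels), type = "theta",
    i = seq_len(p), j = 0L, stringsAsFactors = FALSE)
  do.call(rbind, tabs)
}

free_params <- function(model) {
  tab <- param_table(model)
  vals <- vapply(seq_len(nrow(tab)), function(k) {
    i <- tab$i[k]; j <- tab$j[k]
    switch(tab$type[k],
           delta   = model$delta[i],
           omega   = model$omega[i, j],
           loading = model$Lambda[i, j],
           phi     = model$Phi[i, j],
           gamma   = model$Gamma[i],
           general = model$G[i, j],
           theta   = model$Theta[i])
  }, numeric(1))
  stats::setNames(vals, tab$name)
}

set_free_params <- function(model, theta) {
  tab <- param_table(model)
  stopifnot(length(theta) == nrow(tab))
  for (k in seq_len(nrow(tab))) {
    i <- tab$i[k]; j <- tab$j[k]; v <- theta[k]
    switch(tab$type[k],
           delta   = { model$delta[i] <- v },
           omega   = { model$omega[i, j] <- v; model$omega[j, i] <- v },
           loading = { model$Lambda[i, j] <- v },
           phi     = { model$Phi[i, j] <- v; model$Phi[j, i] <- v },
           gamma   = { model$Gamma[i] <- v },
           general = { model$G[i, j] <- v },
           theta   = { model$Theta[i] <- v })
  }
  model
}

n_free_params <- function(model) nrow(param_table(model))

# natural <-> unconstrained, vectorized by parameter type
to_unconstrained <- function(theta, types) {
  ifelse(types %in% c("delta", "theta"), log(pmax(theta, 1e-12)),
         ifelse(types %in% c("omega", "phi", "gamma"),
                atanh(pmin(pmax(theta, -1 + 1e-12), 1 - 1e-12)), theta))
}

to_natural <- function(u, types) {
  ifelse(types %in% c("delta", "theta"), exp(u),
         ifelse(types %in% c("omega", "phi", "gamma"), tanh(u), u))
}

# implied covariance as a plain function of the natural parameter vector;
# returns NULL when the parameters leave the valid region (non-PD Phi etc.)
implied_from_params <- function(model, theta) {
  m2 <- set_free_params(model, theta)
  tryCatch(implied_covariance(m2), error = function(e) NULL)
}
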