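# Analytic gradients of the ML discrepancy.
#
# With G = dF/dSigma = Sigma^-1 - Sigma^-1 S Sigma^-1 (symmetric), the chain
# rule gives closed forms for every parameter block of both families, so a
# full gradient costs O(p^3) regardless of the number of free parameters:
#
#   GGM (Sigma = D A D, A = (I - Omega)^-1, D = diag(delta)):
#     dF/domega_ij = 2 (A D G D A)_ij          (i < j, edge present)
#     dF/ddelta_i  = 2 (A D G)_ii
#   correlated factors (Sigma = L Phi L' + diag(Theta)):
#     dF/dL        = 2 G L Phi
#     dF/dphi_ij   = 2 (L' G L)_ij             (i < j)
#     dF/dtheta_i  = G_ii
#   second-order (Sigma = L B L' + diag(Theta), B = Gamma Gamma' + diag(1 - Gamma^2)):
#     dF/dL        = 2 G L B
#     dF/dgamma_f  = 2 (L' G L Gamma)_f - 2 gamma_f (L' G L)_ff
#     dF/dtheta_i  = G_ii
#   bifactor / multi-general (Sigma = L L' + Gg Gg' + diag(Theta)):
#     dF/dL = 2 G L,  dF/dGg = 2 G Gg,  dF/dtheta_i = G_ii
#
# Gradients are returned on the natural parameter scale in param_table order;
# the optimizer chains them through the unconstrained transforms.

fml_gradient_natural <- function(model, theta, S) {
  m2 <- set_free_params(model, theta)
  Sigma <- tryCatch(implied_covariance(m2), error = function(e) NULL)
  if (is.null(Sigma)) return(NULL)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Sigma_inv <- chol2inv(ch)
  G <- Sigma_inv - Sigma_inv %*% S %*% Sigma_inv
  tab <- param_table(m2)
  g <- numeric(nrow(tab))

  if (inherits(m2, "ggm_model")) {
    p <- length(m2$labels)
    A <- solve(diag(p) - m2$omega)
    D <- m2$delta
    ADG <- A %*% (D * G)                 # A D G
    M <- ADG %*% (D * A)                 # A D G D A (symmetric)
    for (k in seq_len(nrow(tab))) {
      i <- tab$i[k]; j <- tab$j[k]
      g[k] <- switch(tab$type[k],
                     delta = 2 * ADG[i, i],
                     omega = 2 * M[i, j])
    }
    return(g)
  }

  L <- m2$Lambda
  LtGL <- crossprod(L, G) %*% L
  dL <- switch(m2$kind,
    correlated_factors = 2 * G %*% L %*% m2$Phi,
    second_order = {
      B <- tcrossprod(m2$Gamma) + diag(1 - m2$Gamma^2, length(m2$Gamma))
      2 * G %*% L %*% B
    },
    bifactor = ,
    multi_general = 2 * G %*% L
  )
  for (k in seq_len(nrow(tab))) {
    i <- tab$i[k]; j <- tab$j[k]
    g[k] <- switch(tab$type[k],
                   loading = dL[i, j],
                   phi     = 2 * LtGL[i, j],
                   gamma   = 2 * sum(LtGL[i, ] * m2$Gamma) -
                             2 * m2$Gamma[i] * LtGL[i, i],
                   general = 2 * sum(G[i, ] * m2$G[, j]),
                   theta   = G[i, i])
  }
  g
}

# gradient in unconstrained coordinates (chained through the transforms)
fml_gradient_unconstrained <- function(model, u, types, S) {
  theta <- to_natural(u, types)
  g <- fml_gradient_natural(model, theta, S)
  if (is.null(g)) return(rep(0, length(u)))  # invalid region: flat (value is penalized)
  jac <- ifelse(types %in% c("delta", "theta"), theta,
                ifelse(types %in% c("omega", "phi", "gamma"), 1 - theta^2, 1))
  g * jac
}
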