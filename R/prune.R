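#' Significance pruning of the saturated partial-correlation network
#'
#' Computes the full (saturated) partial-correlation matrix of the sample and
#' removes every edge whose partial correlation is not statistically
#' distinguishable from zero: each off-diagonal entry is tested two-sidedly
#' at level `alpha` with the Fisher-z statistic for a partial correlation of
#' order \eqn{p - 2},
#' \deqn{z = \mathrm{atanh}(\omega_{ij}) \sqrt{N - (p - 2) - 3},}
#' compared against the standard normal. Edges whose statistic lands exactly
#' on the critical value are retained (conservative toward the saturated
#' truth). The surviving edges form the skeleton — "the network model" — which
#' is then refitted confirmatorily by [fit_ggm()].
#'
#' With `settings$prune_recursive = TRUE`, the constrained GGM is refitted
#' after each pass and the surviving edges re-tested with Wald statistics
#' (estimate over standard error) until no further edge is removed. The
#' default is a single calculate-then-prune pass.
#'
#' @param moments a [sample_moments()] object; requires `N > p + 3` so the
#'   Fisher-z variance is positive.
#' @param settings an [estimation_settings()] object; `alpha` and
#'   `prune_recursive` are used.
#' @return Symmetric logical adjacency matrix (the skeleton) with the sample's
#'   labels as dimnames.
#' @export
prune <- function(moments, settings = estimation_settings()) {
  stopifnot(inherits(moments, "sample_moments"))
  p <- length(moments$labels)
  N <- moments$N
  if (N <= p + 3) {
    stop("pruning needs N > p + 3 (minimal N = ", p + 4,
         ") for the Fisher-z statistic; got N = ", N)
  }
  crit <- stats::qnorm(1 - settings$alpha / 2)
  w <- partial_correlations(moments$S)
  z <- atanh(w) * sqrt(N - (p - 2) - 3)
  skeleton <- abs(z) >= crit
  diag(skeleton) <- FALSE
  dimnames(skeleton) <- list(moments$labels, moments$labels)

  if (settings$prune_recursive) {
    repeat {
      if (!any(skeleton)) break
      fit <- fit_ggm(moments, skeleton, settings)
      se <- standard_errors(fit, moments)
      if (se$singular) {
        warning("information matrix singular during recursive pruning; ",
                "stopping at the current skeleton")
        break
      }
      tab <- param_table(fit$model)
      est <- free_params(fit$model)
      drop_any <- FALSE
      for (k in which(tab$type == "omega")) {
        zk <- abs(est[k]) / se$se[k]
        if (is.finite(zk) && zk < crit) {
          skeleton[tab$i[k], tab$j[k]] <- FALSE
          skeleton[tab$j[k], tab$i[k]] <- FALSE
          drop_any <- TRUE
        }
      }
      if (!drop_any) break
    }
  }
  skeleton
}
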