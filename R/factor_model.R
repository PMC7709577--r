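#' Construct a confirmatory factor model
#'
#' Represents the four factor-model topologies used when comparing latent
#' variable accounts of a correlation matrix:
#'
#' * `correlated_factors` — first-order factors with a free correlation matrix
#'   `Phi`: \eqn{\Sigma = \Lambda \Phi \Lambda' + \Theta}.
#' * `second_order` — a single higher-order g factor explains the first-order
#'   factor covariances: \eqn{\Sigma = \Lambda(\Gamma\Gamma' +
#'   \mathrm{diag}(\Psi))\Lambda' + \Theta} with first-order disturbances
#'   \eqn{\Psi = 1 - \Gamma^2} under the standardized convention.
#' * `bifactor` — one general factor loading on every indicator plus
#'   orthogonal group factors: \eqn{\Sigma = \Lambda\Lambda' + GG' + \Theta}.
#' * `multi_general` — like bifactor but with several mutually orthogonal
#'   general factors (e.g. the four-general-factor "penta" structure); this
#'   topology is locally nonidentified (see [check_identification()]).
#'
#' All factors have unit variance (standardized convention, appropriate when
#' a correlation matrix is analyzed); `Theta` holds the residual variances.
#'
#' @param kind one of `"correlated_factors"`, `"second_order"`, `"bifactor"`,
#'   `"multi_general"`.
#' @param loading_pattern p x m logical matrix; `TRUE` marks a free first-order
#'   (group) loading. Row names are the indicator labels, column names the
#'   factor names.
#' @param Lambda optional p x m numeric start/parameter values (0 where the
#'   pattern is `FALSE`). Defaults to 0.7 on free entries.
#' @param Phi optional m x m factor correlation matrix
#'   (`correlated_factors` only); unit diagonal, positive definite.
#' @param Gamma optional length-m second-order loadings (`second_order` only),
#'   each strictly inside (-1, 1).
#' @param general_pattern p x q logical pattern of general-factor loadings
#'   (`bifactor`: q = 1, defaults to all `TRUE`; `multi_general`: q > 1).
#' @param G optional p x q general loading values.
#' @param Theta optional length-p residual variances, all > 0. Defaults to 0.5.
#' @param labels optional indicator labels (default: pattern row names).
#' @return An object of class `factor_model`.
#' @seealso [implied_covariance()], [fit_factor()], [wais_templates()]
#' @export
factor_model <- function(kind = c("correlated_factors", "second_order",
                                  "bifactor", "multi_general"),
                         loading_pattern, Lambda = NULL, Phi = NULL,
                         Gamma = NULL, general_pattern = NULL, G = NULL,
                         Theta = NULL, labels = NULL) {
  kind <- match.arg(kind)
  loading_pattern <- as.matrix(loading_pattern)
  mode(loading_pattern) <- "logical"
  p <- nrow(loading_pattern)
  m <- ncol(loading_pattern)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(loading_pattern))) rownames(loading_pattern)
              else paste0("V", seq_len(p))
  }
  if (length(labels) != p) stop("labels must have length ", p)
  factor_names <- if (!is.null(colnames(loading_pattern))) colnames(loading_pattern)
                  else paste0("F", seq_len(m))

  if (is.null(Lambda)) Lambda <- ifelse(loading_pattern, 0.7, 0)
  Lambda <- as.matrix(Lambda)
  if (!all(dim(Lambda) == c(p, m))) {
    stop("Lambda must be ", p, " x ", m, " to match loading_pattern, got ",
         nrow(Lambda), " x ", ncol(Lambda))
  }
  if (any(Lambda[!loading_pattern] != 0)) {
    stop("Lambda has nonzero entries where loading_pattern is FALSE")
  }

  if (kind == "correlated_factors") {
    if (is.null(Phi)) Phi <- diag(m)
    Phi <- as.matrix(Phi)
    if (!all(dim(Phi) == m)) stop("Phi must be ", m, " x ", m)
    Phi <- symmetrize(Phi, context = "Phi")
    if (any(abs(diag(Phi) - 1) > 1e-10)) {
      stop("Phi must have a unit diagonal (standardized factors)")
    }
    check_positive_definite(Phi, context = "Phi")
  } else if (!is.null(Phi)) {
    stop("Phi is only meaningful for kind = 'correlated_factors'")
  }

  if (kind == "second_order") {
    if (is.null(Gamma)) Gamma <- rep(0.7, m)
    if (length(Gamma) != m) stop("Gamma must have length ", m)
    if (any(abs(Gamma) >= 1)) {
      stop("second-order loadings must lie in (-1, 1) so that the ",
           "first-order disturbances Psi = 1 - Gamma^2 stay positive")
    }
  } else if (!is.null(Gamma)) {
    stop("Gamma is only meaningful for kind = 'second_order'")
  }

  if (kind %in% c("bifactor", "multi_general")) {
    if (is.null(general_pattern)) {
      if (kind == "multi_general") stop("multi_general requires general_pattern")
      general_pattern <- matrix(TRUE, p, 1, dimnames = list(labels, "g"))
    }
    general_pattern <- as.matrix(general_pattern)
    mode(general_pattern) <- "logical"
    if (nrow(general_pattern) != p) stop("general_pattern must have ", p, " rows")
    q <- ncol(general_pattern)
    if (kind == "bifactor" && q != 1) stop("bifactor has exactly one general factor")
    if (kind == "multi_general" && q < 2) {
      stop("multi_general needs at least two general factors; use bifactor for one")
    }
    if (is.null(G)) G <- ifelse(general_pattern, 0.5, 0)
    G <- as.matrix(G)
    if (!all(dim(G) == dim(general_pattern))) stop("G must match general_pattern")
    if (any(G[!general_pattern] != 0)) {
      stop("G has nonzero entries where general_pattern is FALSE")
    }
  } else {
    if (!is.null(general_pattern) || !is.null(G)) {
      stop("general factors are only meaningful for bifactor / multi_general")
    }
    general_pattern <- NULL
    G <- NULL
  }

  if (is.null(Theta)) Theta <- rep(0.5, p)
  if (length(Theta) != p) stop("Theta must have length ", p)
  if (any(Theta < 0)) stop("residual variances Theta must be nonnegative")

  dimnames(loading_pattern) <- dimnames(Lambda) <- list(labels, factor_names)
  if (!is.null(general_pattern)) {
    gn <- if (!is.null(colnames(general_pattern))) colnames(general_pattern)
          else paste0("g", seq_len(ncol(general_pattern)))
    dimnames(general_pattern) <- dimnames(G) <- list(labels, gn)
  }
  names(Theta) <- labels
  if (kind == "correlated_factors") dimnames(Phi) <- list(factor_names, factor_names)
  if (kind == "second_order") names(Gamma) <- factor_names

  structure(list(kind = kind, loading_pattern = loading_pattern,
                 Lambda = Lambda, Phi = Phi, Gamma = Gamma,
                 general_pattern = general_pattern, G = G,
                 Theta = as.numeric(Theta), labels = as.character(labels),
                 factor_names = factor_names),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> kind = ", x$kind, ", ", length(x$labels),
      " indicators, ", length(x$factor_names), " group factor(s)", sep = "")
  if (!is.null(x$general_pattern)) {
    cat(", ", ncol(x$general_pattern), " general factor(s)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname implied_covariance
#' @export
implied_covariance.factor_model <- function(model, ...) {
  L <- model$Lambda
  Sigma <- switch(model$kind,
    correlated_factors = L %*% model$Phi %*% t(L),
    second_order = {
      B <- tcrossprod(model$Gamma) + diag(1 - model$Gamma^2, length(model$Gamma))
      L %*% B %*% t(L)
    },
    bifactor = ,
    multi_general = tcrossprod(L) + tcrossprod(model$G)
  )
  Sigma <- Sigma + diag(model$Theta, length(model$Theta))
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(model$labels, model$labels)
  Sigma
}
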