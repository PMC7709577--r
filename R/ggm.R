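#' Construct a Gaussian graphical model
#'
#' A Gaussian graphical model (GGM) parameterizes a covariance matrix through
#' partial correlations: \deqn{\Sigma = \Delta (I - \Omega)^{-1} \Delta,}
#' where \eqn{\Omega} holds the partial correlations on its off-diagonal (zero
#' diagonal), \eqn{\Delta} is a diagonal scaling matrix with positive entries,
#' and \eqn{I} is the identity. Absent edges in the `skeleton` force the
#' corresponding \eqn{\omega_{ij}} to zero, encoding conditional independence
#' of the two variables given all others.
#'
#' @param skeleton symmetric logical p x p adjacency matrix with a `FALSE`
#'   diagonal; `TRUE` marks a free edge.
#' @param omega symmetric numeric p x p matrix of partial correlations, zero
#'   diagonal, entries strictly inside (-1, 1), and zero wherever `skeleton`
#'   is `FALSE`. Defaults to all zeros.
#' @param delta length-p vector of strictly positive scaling values (the
#'   diagonal of \eqn{\Delta}). Defaults to ones.
#' @param labels optional character vector of p variable names.
#' @return An object of class `ggm_model`.
#' @seealso [implied_covariance()], [saturated_ggm()], [fit_ggm()]
#' @export
ggm_model <- function(skeleton, omega = NULL, delta = NULL, labels = NULL) {
  skeleton <- as.matrix(skeleton)
  if (nrow(skeleton) != ncol(skeleton)) stop("skeleton must be square")
  p <- nrow(skeleton)
  mode(skeleton) <- "logical"
  if (any(is.na(skeleton))) stop("skeleton must not contain NA")
  if (!identical(skeleton, t(skeleton))) stop("skeleton must be symmetric")
  if (any(diag(skeleton))) stop("skeleton diagonal must be FALSE (no self-loops)")
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(skeleton))) rownames(skeleton) else paste0("V", seq_len(p))
  }
  if (length(labels) != p) stop("labels must have length ", p)
  if (is.null(omega)) omega <- matrix(0, p, p)
  omega <- as.matrix(omega)
  if (!all(dim(omega) == p)) stop("omega must be ", p, " x ", p)
  omega <- symmetrize(omega, tol = 1e-8, context = "omega")
  if (any(abs(diag(omega)) > 1e-12)) stop("omega must have a zero diagonal")
  diag(omega) <- 0
  if (any(abs(omega) >= 1)) stop("partial correlations must lie strictly in (-1, 1)")
  if (any(omega[!skeleton & upper.tri(omega)] != 0)) {
    stop("omega has nonzero entries where the skeleton has no edge")
  }
  if (is.null(delta)) delta <- rep(1, p)
  if (length(delta) != p) stop("delta must have length ", p)
  if (any(delta <= 0)) stop("delta entries must be strictly positive")
  dimnames(skeleton) <- dimnames(omega) <- list(labels, labels)
  names(delta) <- labels
  structure(list(skeleton = skeleton, omega = omega, delta = as.numeric(delta),
                 labels = as.character(labels)),
            class = "ggm_model")
}

#' @export
print.ggm_model <- function(x, ...) {
  p <- length(x$labels)
  n_edges <- sum(x$skeleton[upper.tri(x$skeleton)])
  cat("<ggm_model> ", p, " nodes, ", n_edges, " edges\n", sep = "")
  invisible(x)
}

#' Model-implied covariance matrix
#'
#' Maps a model's parameters to the covariance matrix it implies among the
#' observed variables. For a [ggm_model()] this is
#' \eqn{\Delta (I - \Omega)^{-1} \Delta}; for a [factor_model()] it is the
#' standard confirmatory factor algebra of its kind (see
#' [implied_covariance.factor_model()]).
#'
#' @param model a fitted or hand-constructed model object.
#' @param ... unused.
#' @return Symmetric positive-(semi)definite p x p matrix with the model's
#'   variable labels as dimnames.
#' @export
implied_covariance <- function(model, ...) UseMethod("implied_covariance")

#' @rdname implied_covariance
#' @export
implied_covariance.ggm_model <- function(model, ...) {
  p <- length(model$labels)
  IO <- diag(p) - model$omega
  ev <- eigen(IO, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) {
    stop("I - Omega is not positive definite (smallest eigenvalue ",
         signif(min(ev), 6), "); the GGM parameters are invalid")
  }
  A <- solve(IO)
  Sigma <- model$delta * t(model$delta * A)  # Delta %*% A %*% Delta
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(model$labels, model$labels)
  Sigma
}

#' Partial correlations of a positive-definite matrix
#'
#' Computes the matrix of partial correlations — the correlation of each pair
#' of variables after controlling for all remaining variables — from the
#' standardized negative inverse of `S`: with \eqn{K = S^{-1}},
#' \eqn{\omega_{ij} = -\kappa_{ij} / \sqrt{\kappa_{ii}\kappa_{jj}}} off the
#' diagonal and zero on it.
#'
#' @param S symmetric positive-definite matrix (covariance or correlation).
#' @return Symmetric matrix with zero diagonal and off-diagonal entries in
#'   (-1, 1).
#' @export
partial_correlations <- function(S) {
  S <- as.matrix(S)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop("S is singular or not positive definite; partial correlations are ",
         "undefined. Check the data, or apply an explicit ridge before ",
         "calling (no silent regularization is done).")
  }
  K <- chol2inv(ch)
  d <- 1 / sqrt(diag(K))
  W <- -(d * t(d * K))      # -D K D with D = diag(d)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(S)
  W
}

#' Saturated (complete-skeleton) GGM reproducing a matrix exactly
#'
#' Builds the GGM whose implied covariance equals `S` exactly: the skeleton is
#' complete, `omega` is [partial_correlations()] of `S`, and `delta` is
#' \eqn{\mathrm{diag}(S^{-1})^{-1/2}}. This is the starting point of pruning:
#' the full partial-correlation matrix before any edge is removed.
#'
#' @param S symmetric positive-definite matrix, or a [sample_moments()] object.
#' @return A `ggm_model` with a complete skeleton.
#' @export
saturated_ggm <- function(S) {
  if (inherits(S, "sample_moments")) S <- S$S
  S <- as.matrix(S)
  p <- nrow(S)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop("S is singular or not positive definite; cannot form the saturated ",
         "GGM. Check the data, or apply an explicit ridge before calling.")
  }
  K <- chol2inv(ch)
  delta <- 1 / sqrt(diag(K))
  skeleton <- matrix(TRUE, p, p)
  diag(skeleton) <- FALSE
  labels <- if (!is.null(rownames(S))) rownames(S) else paste0("V", seq_len(p))
  ggm_model(skeleton, omega = partial_correlations(S), delta = delta,
            labels = labels)
}
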