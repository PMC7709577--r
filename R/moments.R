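#' Bundle an observed covariance or correlation matrix with its sample size
#'
#' A `sample_moments` object is the unit of observed data in netlatent: a
#' symmetric positive-definite matrix `S` (covariance or correlation units),
#' the number of observations `N` it was computed from, and the variable
#' labels. All fitting functions consume this object; raw case-level data are
#' never needed because the maximum-likelihood discrepancy depends on the data
#' only through `S` and `N`.
#'
#' @param S symmetric positive-definite numeric matrix (p x p). Asymmetry up
#'   to `1e-8` (max absolute difference) is averaged away; anything larger is
#'   an error.
#' @param N positive integer sample size; must be at least `p + 2` so that
#'   partial correlations can be tested.
#' @param labels character vector of p unique variable names. Defaults to the
#'   dimnames of `S`, or `V1..Vp` if `S` carries none.
#' @return An object of class `sample_moments` with fields `S`, `N`, `labels`.
#' @examples
#' S <- diag(3); dimnames(S) <- list(c("a","b","c"), c("a","b","c"))
#' m <- sample_moments(S, N = 100)
#' m$labels
#' @export
sample_moments <- function(S, N, labels = NULL) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) {
    stop("S must be square, got ", nrow(S), " x ", ncol(S))
  }
  p <- nrow(S)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(S))) rownames(S) else paste0("V", seq_len(p))
  }
  labels <- as.character(labels)
  if (length(labels) != p) {
    stop("labels must have length ", p, ", got ", length(labels))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate variable labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  S <- symmetrize(S, tol = 1e-8, context = "sample matrix S")
  check_positive_definite(S, context = "sample matrix S")
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N <= 0) {
    stop("N must be a single positive integer")
  }
  N <- as.integer(N)
  if (N < p + 2L) {
    stop("N must be at least p + 2 = ", p + 2L,
         " for partial-correlation inference, got N = ", N)
  }
  dimnames(S) <- list(labels, labels)
  structure(list(S = S, N = N, labels = labels), class = "sample_moments")
}

#' @export
print.sample_moments <- function(x, ...) {
  p <- length(x$labels)
  cat("<sample_moments> ", p, " variables, N = ", x$N, "\n", sep = "")
  cat("  labels: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
format.sample_moments <- function(x, ...) {
  paste0("sample_moments(p = ", length(x$labels), ", N = ", x$N, ")")
}

# --- internal matrix helpers ------------------------------------------------

# Average away asymmetry within tol; error (naming the worst cell) beyond it.
symmetrize <- function(S, tol = 1e-8, context = "matrix") {
  d <- abs(S - t(S))
  worst <- max(d)
  if (worst > tol) {
    idx <- which(d == worst, arr.ind = TRUE)[1, ]
    stop(context, " is asymmetric beyond tolerance ", tol, ": cells (",
         idx[1], ",", idx[2], ") and (", idx[2], ",", idx[1],
         ") differ by ", signif(worst, 4))
  }
  (S + t(S)) / 2
}

# Relative PD check: smallest eigenvalue must exceed 1e-10 x largest.
check_positive_definite <- function(S, context = "matrix", tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(abs(ev))) {
    stop(context, " is not positive definite: smallest eigenvalue ",
         signif(min(ev), 6), " (largest ", signif(max(ev), 6), ")")
  }
  invisible(ev)
}

is_positive_definite <- function(S, tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev))
}

# log-determinant via Cholesky; NA if not PD
logdet_pd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch)))
}

# half-vectorization (lower triangle including diagonal), fixed order
vech <- function(M) M[lower.tri(M, diag = TRUE)]
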