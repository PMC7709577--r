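# Headline workflows: extract a network on one sample and confirm it on
# another, and compare network and factor models on a single index table.

#' Extract a network on sample A and confirm it on sample B
#'
#' The network analogue of factor-model cross-validation: the skeleton is
#' estimated by [prune()] on `moments_A`, then held fixed while its parameters
#' are re-estimated freely on `moments_B` (a truly confirmatory fit). The
#' self-fit on `moments_A` is returned for reference. Samples are matched by
#' label (order-normalized); a label mismatch is an error that reports the
#' difference of the two label sets.
#'
#' @param moments_A discovery sample ([sample_moments()]).
#' @param moments_B confirmation sample with the same variables.
#' @param settings an [estimation_settings()].
#' @return List with `skeleton`, `fit_self`, `indices_self`, `fit_confirm`,
#'   `indices_confirm`, of class `replication_result`.
#' @export
extract_and_confirm <- function(moments_A, moments_B,
                                settings = estimation_settings()) {
  stopifnot(inherits(moments_A, "sample_moments"),
            inherits(moments_B, "sample_moments"))
  if (!setequal(moments_A$labels, moments_B$labels)) {
    only_A <- setdiff(moments_A$labels, moments_B$labels)
    only_B <- setdiff(moments_B$labels, moments_A$labels)
    stop("label mismatch between samples; only in A: {",
         paste(only_A, collapse = ", "), "}, only in B: {",
         paste(only_B, collapse = ", "), "}")
  }
  if (!identical(moments_A$labels, moments_B$labels)) {
    ord <- match(moments_A$labels, moments_B$labels)
    moments_B <- sample_moments(moments_B$S[ord, ord], moments_B$N,
                                labels = moments_A$labels)
  }
  skeleton <- prune(moments_A, settings)
  fit_self <- fit_ggm(moments_A, skeleton, settings)
  fit_confirm <- fit_ggm(moments_B, skeleton, settings)
  structure(list(skeleton = skeleton,
                 fit_self = fit_self,
                 indices_self = fit_indices(fit_self),
                 fit_confirm = fit_confirm,
                 indices_confirm = fit_indices(fit_confirm)),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  n_edges <- sum(x$skeleton[upper.tri(x$skeleton)])
  cat("<replication_result> skeleton with", n_edges, "edges\n")
  cat("self-fit (discovery sample):\n"); print(x$indices_self)
  cat("confirmatory fit (target sample):\n"); print(x$indices_confirm)
  invisible(x)
}

#' Compare network and factor models on one sample
#'
#' Fits each supplied model to the same observed matrix, assembles the
#' fit-index table, and marks the lowest-AIC and lowest-BIC rows. Factor
#' models that fail the local identification check are listed with a refusal
#' note instead of indices (a nonidentified model's fit statistics are
#' invalid, so they are never reported). A fit that does not converge renders
#' its row with a NON-CONVERGED marker, never fabricated indices. Rows are
#' sorted by model name so the report does not depend on the order in which
#' models are supplied.
#'
#' @param moments a [sample_moments()].
#' @param models named list; each element is a [factor_model()], a
#'   [ggm_model()], or a bare logical skeleton matrix (fitted as a GGM).
#' @param settings an [estimation_settings()].
#' @return A `comparison_report`: list with `rows` (each holding `name`,
#'   `fit`, `indices`, `labels`, `note`), `best_aic`, `best_bic`.
#' @export
compare_models <- function(moments, models,
                           settings = estimation_settings()) {
  stopifnot(inherits(moments, "sample_moments"))
  if (length(models) < 1) stop("at least one model is required")
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("models must be a fully named list")
  }
  rows <- lapply(names(models), function(nm) {
    mod <- models[[nm]]
    row <- list(name = nm, fit = NULL, indices = NULL, labels = NULL,
                note = NA_character_)
    if (is.matrix(mod) || inherits(mod, "ggm_model")) {
      fit <- fit_ggm(moments, mod, settings)
    } else if (inherits(mod, "factor_model")) {
      ident <- check_identification(mod, seed = settings$seed)
      if (!ident$identified) {
        row$note <- paste0("NONIDENTIFIED (Jacobian rank ", ident$rank, " < ",
                           ident$n_free, " free parameters); not fitted")
        return(row)
      }
      fit <- fit_factor(moments, mod, settings)
    } else {
      stop("model '", nm, "' is neither a factor_model, a ggm_model, ",
           "nor a skeleton matrix")
    }
    if (!fit$converged) {
      row$fit <- fit
      row$note <- "NON-CONVERGED"
      return(row)
    }
    row$fit <- fit
    row$indices <- fit_indices(fit)
    row$labels <- qualify_fit(row$indices)
    row
  })
  names(rows) <- names(models)
  rows <- rows[order(names(rows))]
  fitted <- Filter(function(r) !is.null(r$indices), rows)
  if (length(fitted) == 0) {
    best_aic <- best_bic <- NA_character_
  } else {
    aics <- vapply(fitted, function(r) r$indices$aic, numeric(1))
    bics <- vapply(fitted, function(r) r$indices$bic, numeric(1))
    best_aic <- names(fitted)[which.min(aics)]
    best_bic <- names(fitted)[which.min(bics)]
  }
  structure(list(rows = rows, best_aic = best_aic, best_bic = best_bic,
                 moments = moments),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

# aligned-text rendering shared by print and write_report
format_report_text <- function(report) {
  header <- sprintf("%-16s %-14s %-8s %-6s %-6s %-22s %-12s %-12s",
                    "Model", "chi2 (df)", "p", "CFI", "TLI",
                    "RMSEA [CI90]", "AIC", "BIC")
  lines <- vapply(report$rows, function(r) {
    star <- if (!is.na(report$best_aic) && r$name == report$best_aic &&
                r$name == report$best_bic) "*" else ""
    if (is.null(r$indices)) {
      return(sprintf("%-16s %s", paste0(r$name, star), r$note))
    }
    ix <- r$indices
    sprintf("%-16s %-14s %-8s %-6.2f %-6.2f %-22s %-12.2f %-12.2f",
            paste0(r$name, star),
            sprintf("%.2f (%d)", ix$chi2, ix$df),
            sub("^= ", "", format_pvalue(ix$p_value)),
            ix$cfi, ix$tli,
            sprintf("%.3f [%.3f-%.3f]", ix$rmsea, ix$rmsea_lower,
                    ix$rmsea_upper),
            ix$aic, ix$bic)
  }, character(1))
  c(header, lines,
    sprintf("preferred (lowest AIC): %s; (lowest BIC): %s",
            report$best_aic, report$best_bic),
    "* marks the model preferred by both criteria")
}
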