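# Shipped WAIS-IV model templates: the 15 subtests and the four factor-model
# topologies compared against the network (measurement model with correlated
# index factors, hierarchical/second-order g, bifactor, and the nonidentified
# four-general-factor "penta" structure used as the identification demo).

#' The fifteen WAIS-IV subtest abbreviations
#'
#' SI Similarities, VC Vocabulary, IN Information, CO Comprehension,
#' BD Block Design, MR Matrix Reasoning, VP Visual Puzzles, FW Figure
#' Weights, PC Picture Completion, DS Digit Span, AR Arithmetic, LN
#' Letter-Number Sequencing, SS Symbol Search, CD Coding, CA Cancelation.
#'
#' @return Character vector of length 15.
#' @export
wais_labels <- function() {
  c("SI", "VC", "IN", "CO", "BD", "MR", "VP", "FW",
    "PC", "DS", "AR", "LN", "SS", "CD", "CA")
}

# indicator -> factor map; FW sits under Perceptual or Working Memory
# depending on the variant (both assignments circulate for the WAIS-IV)
wais_assignment <- function(fw = c("perceptual", "working_memory")) {
  fw <- match.arg(fw)
  map <- list(
    V  = c("SI", "VC", "IN", "CO"),
    P  = c("BD", "MR", "VP", "PC"),
    WM = c("DS", "AR", "LN"),
    S  = c("SS", "CD", "CA")
  )
  if (fw == "perceptual") map$P <- c(map$P, "FW") else map$WM <- c(map$WM, "FW")
  map
}

wais_pattern <- function(fw = "perceptual", cross_loadings = NULL) {
  labels <- wais_labels()
  map <- wais_assignment(fw)
  pat <- matrix(FALSE, 15, 4, dimnames = list(labels, names(map)))
  for (f in names(map)) pat[map[[f]], f] <- TRUE
  if (!is.null(cross_loadings)) {
    for (cl in cross_loadings) {
      if (length(cl) != 2 || !cl[1] %in% labels || !cl[2] %in% names(map)) {
        stop("each cross-loading must be c(subtest, factor); got ",
             paste(cl, collapse = ", "))
      }
      pat[cl[1], cl[2]] <- TRUE
    }
  }
  pat
}

#' WAIS-IV factor-model templates
#'
#' Constructors for the factor models fitted against the WAIS network:
#'
#' * `wais_measurement()` — four correlated index factors (Verbal,
#'   Perceptual, Working Memory, Speed); simple structure by default
#'   (df = 84). Published versions of this model carry two extra
#'   cross-loadings (df = 82); supply them via `cross_loadings`, e.g.
#'   `list(c("AR", "V"), c("FW", "WM"))`, to reproduce that variant.
#' * `wais_hierarchical_g()` — the same first-order factors with a
#'   second-order g factor explaining their covariances (df = 86 simple
#'   structure).
#' * `wais_bifactor()` — one general factor on all 15 subtests plus four
#'   orthogonal group factors (df = 75).
#' * `wais_pentafactor()` — four general factors plus the four group factors,
#'   all orthogonal. This structure is locally nonidentified (the general
#'   block can be rotated freely) and is shipped for the identification
#'   demonstration, not for fitting.
#'
#' The FW (Figure Weights) subtest is assigned to the Perceptual factor by
#' default; `fw = "working_memory"` switches to the alternative grouping.
#'
#' @param fw which factor FW loads on: `"perceptual"` (default) or
#'   `"working_memory"`.
#' @param cross_loadings optional list of `c(subtest, factor)` pairs adding
#'   free loadings beyond simple structure (measurement and hierarchical
#'   templates only).
#' @return A [factor_model()].
#' @name wais_templates
NULL

#' @rdname wais_templates
#' @export
wais_measurement <- function(fw = "perceptual", cross_loadings = NULL) {
  factor_model("correlated_factors",
               loading_pattern = wais_pattern(fw, cross_loadings),
               Phi = diag(4) * 0.7 + 0.3)
}

#' @rdname wais_templates
#' @export
wais_hierarchical_g <- function(fw = "perceptual", cross_loadings = NULL) {
  factor_model("second_order",
               loading_pattern = wais_pattern(fw, cross_loadings),
               Gamma = rep(0.7, 4))
}

#' @rdname wais_templates
#' @export
wais_bifactor <- function(fw = "perceptual") {
  labels <- wais_labels()
  factor_model("bifactor",
               loading_pattern = wais_pattern(fw),
               Lambda = ifelse(wais_pattern(fw), 0.4, 0),
               general_pattern = matrix(TRUE, 15, 1,
                                        dimnames = list(labels, "g")),
               G = matrix(0.6, 15, 1, dimnames = list(labels, "g")))
}

#' @rdname wais_templates
#' @export
wais_pentafactor <- function(fw = "perceptual") {
  labels <- wais_labels()
  gp <- matrix(TRUE, 15, 4,
               dimnames = list(labels, paste0("g", 1:4)))
  factor_model("multi_general",
               loading_pattern = wais_pattern(fw),
               Lambda = ifelse(wais_pattern(fw), 0.4, 0),
               general_pattern = gp,
               G = matrix(0.3, 15, 4, dimnames = dimnames(gp)))
}

#' @rdname wais_templates
#' @export
wais_templates <- function(fw = "perceptual") {
  list(measurement = wais_measurement(fw),
       hierarchical_g = wais_hierarchical_g(fw),
       bifactor = wais_bifactor(fw),
       pentafactor = wais_pentafactor(fw))
}
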