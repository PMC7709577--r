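# Readers and writers: labeled matrix files, skeleton edge lists, and the
# model-comparison report. A matrix file never carries the sample size N; N is
# always supplied separately so chi-square scaling cannot be silently wrong.

#' Read a labeled square matrix from a text file
#'
#' Accepts a CSV (header row of labels, leading label column) or a
#' whitespace-delimited variant; the delimiter is auto-detected from the
#' first line. Symmetry is enforced on read: asymmetry up to `1e-8` is
#' averaged, anything larger is an error naming the offending cell pair.
#' Non-square layouts, non-numeric cells, duplicate labels, and nonpositive
#' diagonal entries are each distinct errors with row/column context.
#'
#' @param path file to read.
#' @return Numeric matrix with labels as dimnames. Combine with a sample size
#'   via [sample_moments()].
#' @export
read_labeled_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e)))
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) {
    stop(path, " is not square: ", nrow(M), " rows x ", ncol(M), " columns")
  }
  if (!is.numeric(M)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(M), nrow(M)))) &
                 !is.na(M), arr.ind = TRUE)
    ctx <- if (nrow(bad) > 0) paste0(" (first at row ", bad[1, 1], ", column ",
                                     bad[1, 2], ")") else ""
    stop(path, " contains non-numeric cells", ctx)
  }
  labels <- rownames(M)
  if (!identical(labels, colnames(M))) {
    if (setequal(labels, colnames(M))) {
      stop(path, ": row and column labels are ordered differently")
    }
    stop(path, ": row labels and column labels disagree")
  }
  if (anyDuplicated(labels)) {
    stop(path, ": duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  M <- symmetrize(M, tol = 1e-8, context = paste0("matrix in ", path))
  if (any(diag(M) <= 0)) {
    stop(path, ": nonpositive diagonal at ", labels[which(diag(M) <= 0)[1]])
  }
  M
}

#' Write a labeled square matrix to CSV
#'
#' Inverse of [read_labeled_matrix()]: header row of labels plus a leading
#' label column, full precision.
#'
#' @param M labeled numeric matrix (or a [sample_moments()], whose `S` is
#'   written).
#' @param path destination file.
#' @export
write_labeled_matrix <- function(M, path) {
  if (inherits(M, "sample_moments")) M <- M$S
  df <- as.data.frame(M)
  utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a skeleton as a plain-text edge list
#'
#' One `from,to` pair per line with a header; labels, not indices, so the
#' file is robust to variable reordering. [read_skeleton()] restores the
#' adjacency matrix given the label set.
#'
#' @param skeleton symmetric logical adjacency matrix with dimnames.
#' @param path destination file.
#' @export
write_skeleton <- function(skeleton, path) {
  labels <- rownames(skeleton)
  idx <- which(skeleton & upper.tri(skeleton), arr.ind = TRUE)
  df <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_skeleton
#' @param labels the full variable label set the adjacency should span.
#' @export
read_skeleton <- function(path, labels) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(df))) {
    stop(path, " is not a skeleton edge list (needs 'from' and 'to' columns)")
  }
  unknown <- setdiff(c(df$from, df$to), labels)
  if (length(unknown) > 0) {
    stop(path, " references labels not in the sample: ",
         paste(unknown, collapse = ", "))
  }
  p <- length(labels)
  skeleton <- matrix(FALSE, p, p, dimnames = list(labels, labels))
  for (k in seq_len(nrow(df))) {
    skeleton[df$from[k], df$to[k]] <- TRUE
    skeleton[df$to[k], df$from[k]] <- TRUE
  }
  skeleton
}

#' Write a model-comparison report
#'
#' `format = "tsv"` writes one row per model with full-precision numeric
#' columns (chi2, df, p_value, cfi, tli, rmsea and its CI bounds, aic, bic,
#' a note column, and preferred-model flags), so parsing the file recovers
#' the indices exactly. `format = "text"` writes the aligned human-readable
#' table (chi-square to 2 decimals, indices to 2-3, p-values below 0.001 as
#' "<0.001", preferred model starred).
#'
#' @param report a `comparison_report` from [compare_models()].
#' @param path destination file.
#' @param format `"tsv"` or `"text"`.
#' @export
write_report <- function(report, path, format = c("tsv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "comparison_report"))
  if (length(report$rows) == 0) stop("report has no rows; nothing to write")
  if (format == "text") {
    writeLines(format_report_text(report), path)
    return(invisible(path))
  }
  num <- function(r, field) if (is.null(r$indices)) NA_real_ else r$indices[[field]]
  df <- data.frame(
    model = vapply(report$rows, `[[`, character(1), "name"),
    chi2 = vapply(report$rows, num, numeric(1), "chi2"),
    df = vapply(report$rows, num, numeric(1), "df"),
    p_value = vapply(report$rows, num, numeric(1), "p_value"),
    cfi = vapply(report$rows, num, numeric(1), "cfi"),
    tli = vapply(report$rows, num, numeric(1), "tli"),
    rmsea = vapply(report$rows, num, numeric(1), "rmsea"),
    rmsea_lower = vapply(report$rows, num, numeric(1), "rmsea_lower"),
    rmsea_upper = vapply(report$rows, num, numeric(1), "rmsea_upper"),
    aic = vapply(report$rows, num, numeric(1), "aic"),
    bic = vapply(report$rows, num, numeric(1), "bic"),
    note = vapply(report$rows, function(r)
      if (is.na(r$note)) "" else r$note, character(1)),
    best_aic = vapply(report$rows, function(r)
      identical(r$name, report$best_aic), logical(1)),
    best_bic = vapply(report$rows, function(r)
      identical(r$name, report$best_bic), logical(1)),
    stringsAsFactors = FALSE)
  # %.17g guarantees that reading the TSV back reproduces each double exactly
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) {
      df[[cn]] <- ifelse(is.na(df[[cn]]), "NA", sprintf("%.17g", df[[cn]]))
    }
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
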