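#' Filter miRNAs by detection frequency
#'
#' Keeps the miRNAs detected (defined Ct strictly below the ceiling) in at
#' least `min_detected` samples, the expression criterion used for TLDA
#' profiling cohorts (e.g. detected in at least 21 of 26 samples). The
#' filter is applied cohort-wide by default; pass a column subset first to
#' filter per group.
#'
#' @param ct a [ct_matrix()] object.
#' @param min_detected minimum number of samples with a detected Ct.
#' @param ct_max detection ceiling; defaults to the matrix's own `ct_max`.
#' @return A [ct_matrix()]-like object restricted to the passing miRNAs
#'   (possibly zero rows, in which case a message is emitted).
#' @export
detection_filter <- function(ct, min_detected, ct_max = ct$ct_max) {
  stopifnot(inherits(ct, "CtMatrix"))
  n <- length(ct$sample_ids)
  if (!(min_detected >= 1 && min_detected <= n))
    stop("min_detected must be between 1 and the number of samples (", n, ")")
  detected <- !is.na(ct$ct) & ct$ct < ct_max
  keep <- rowSums(detected) >= min_detected
  if (!any(keep))
    message("detection_filter: no miRNA passes the ", min_detected, "/",
            n, " detection criterion")
  out <- ct
  out$ct <- ct$ct[keep, , drop = FALSE]
  out$mirna_ids <- ct$mirna_ids[keep]
  out
}

#' Normalize Ct values to a reference assay
#'
#' Converts Ct values to relative expression on the linear scale,
#' `expr[i, s] = 2^-(Ct[i, s] - Ct[ref, s])`, the standard delta-Ct
#' quantification against a stable endogenous reference (U6 for plasma
#' TLDA data, hsa-miR-24 for microparticle RNA). Undetected wells
#' propagate as missing. The reference must be detected in every sample.
#'
#' @param ct a [ct_matrix()] object.
#' @param reference_id row identifier of the reference assay.
#' @param drop_reference drop the reference row (identically 1) from the
#'   output? Default `TRUE`.
#' @return An object of class `ExpressionMatrix`: list with `expr` (linear
#'   relative expression, `NA` where undetected), `log10_expr` (filled by
#'   [log_transform()], otherwise `NULL`), `mirna_ids`, `sample_ids`, and
#'   `reference_id`.
#' @export
normalize_to_reference <- function(ct, reference_id, drop_reference = TRUE) {
  stopifnot(inherits(ct, "CtMatrix"))
  if (!reference_id %in% ct$mirna_ids)
    stop("reference assay '", reference_id, "' not present in Ct matrix")
  ref <- ct$ct[reference_id, ]
  if (anyNA(ref))
    stop("reference '", reference_id, "' undetected in sample(s): ",
         paste(ct$sample_ids[is.na(ref)], collapse = ", "))
  expr <- 2^(-sweep(ct$ct, 2L, ref, `-`))
  if (drop_reference)
    expr <- expr[rownames(expr) != reference_id, , drop = FALSE]
  structure(
    list(expr = expr, log10_expr = NULL, mirna_ids = rownames(expr),
         sample_ids = colnames(expr), reference_id = reference_id),
    class = "ExpressionMatrix"
  )
}

#' Fill the log10 view of an expression matrix
#'
#' Expression values are reported and modeled on the `log10(2^-dCt)` scale
#' downstream (SAM statistic, ROC cut-offs, logistic regression units).
#' Missing cells stay missing.
#'
#' @param expr an `ExpressionMatrix` from [normalize_to_reference()].
#' @return The same object with `log10_expr` filled.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (any(expr$expr <= 0, na.rm = TRUE))
    stop("nonpositive expression value; cannot take log10")
  expr$log10_expr <- log10(expr$expr)
  expr
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d miRNAs x %d samples (reference %s, %d missing cells)\n",
              nrow(x$expr), ncol(x$expr), x$reference_id, sum(is.na(x$expr))))
  invisible(x)
}

#' Write an expression matrix view to a delimited text file
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @param what which view to write, `"expr"` (linear) or `"log10"`.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, what = c("expr", "log10"),
                                    sep = "\t") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  what <- match.arg(what)
  m <- if (what == "expr") x$expr else x$log10_expr
  if (is.null(m)) stop("log10 view not filled; call log_transform() first")
  cells <- matrix("NA", nrow = nrow(m), ncol = ncol(m))
  ok <- !is.na(m)
  cells[ok] <- sprintf("%.17g", m[ok])
  lines <- c(paste(c("mirna_id", x$sample_ids), collapse = sep),
             paste(x$mirna_ids, apply(cells, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}
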