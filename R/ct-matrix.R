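#' Construct a Ct matrix
#'
#' A `CtMatrix` holds raw qPCR cycle-threshold values, one row per miRNA
#' assay and one column per sample. Undetected wells (instrument
#' "Undetermined", or any Ct at or above the detection ceiling) are stored
#' as `NA`. The detection criterion is strict: a well counts as detected
#' only when `Ct < ct_max`, so a value exactly at the ceiling is treated as
#' undetected.
#'
#' @param ct numeric matrix of Ct values with miRNA row names and sample
#'   column names; `NA` marks undetected wells.
#' @param ct_max detection ceiling in cycles (default 40). Values at or
#'   above the ceiling are converted to `NA`.
#' @return An object of class `CtMatrix`: a list with elements `ct`
#'   (numeric matrix), `mirna_ids`, `sample_ids`, and `ct_max`.
#' @export
ct_matrix <- function(ct, ct_max = 40) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric matrix")
  if (nrow(ct) == 0L) stop("no miRNAs: Ct matrix has zero rows")
  if (ncol(ct) == 0L) stop("no samples: Ct matrix has zero columns")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' must have miRNA row names and sample column names")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate miRNA identifiers: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  stopifnot(is.numeric(ct_max), length(ct_max) == 1L, ct_max > 0)
  ct[!is.na(ct) & ct >= ct_max] <- NA_real_
  if (any(ct < 0, na.rm = TRUE))
    stop("negative Ct values are not allowed")
  structure(
    list(ct = ct, mirna_ids = rownames(ct), sample_ids = colnames(ct),
         ct_max = ct_max),
    class = "CtMatrix"
  )
}

#' @export
print.CtMatrix <- function(x, ...) {
  cat(sprintf("CtMatrix: %d miRNAs x %d samples (ct_max = %g, %d undetected wells)\n",
              nrow(x$ct), ncol(x$ct), x$ct_max, sum(is.na(x$ct))))
  invisible(x)
}

#' @export
dim.CtMatrix <- function(x) dim(x$ct)

# Guess the field separator of a delimited text file from its header line.
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read a Ct matrix from a delimited text file
#'
#' Reads a TSV or CSV table (delimiter auto-detected from the header line)
#' whose first column holds miRNA identifiers and whose header row holds
#' sample identifiers. Cells equal to `undetected_token`, and numeric cells
#' at or above `ct_max`, become undetected (`NA`). Decimal separator is
#' always the dot, independent of locale.
#'
#' @param path file path.
#' @param undetected_token sentinel string marking undetected wells
#'   (default `"Undetermined"`, the instrument export convention).
#' @param ct_max detection ceiling in cycles (default 40).
#' @return A [ct_matrix()] object.
#' @export
read_ct_matrix <- function(path, undetected_token = "Undetermined",
                           ct_max = 40) {
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no miRNAs: data section of ", path, " is empty")
  if (ncol(raw) < 2L) stop("no samples: ", path, " has no sample columns")
  mirna_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(mirna_ids))
    stop("duplicate miRNA identifiers in ", path, ": ",
         paste(unique(mirna_ids[duplicated(mirna_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  ct <- matrix(NA_real_, nrow = nrow(cells), ncol = ncol(cells),
               dimnames = list(mirna_ids, sample_ids))
  is_sent <- cells == undetected_token | is.na(cells) | cells == ""
  num <- suppressWarnings(as.numeric(cells[!is_sent]))
  bad <- which(is.na(num))
  if (length(bad)) {
    idx <- which(!is_sent)[bad[1L]]
    rc <- arrayInd(idx, dim(cells))
    stop(sprintf("non-numeric cell '%s' at miRNA '%s', sample '%s' in %s",
                 cells[idx], mirna_ids[rc[1L]], sample_ids[rc[2L]], path))
  }
  ct[!is_sent] <- num
  ct_matrix(ct, ct_max = ct_max)
}

#' Write a Ct matrix to a delimited text file
#'
#' Inverse of [read_ct_matrix()]: numeric cells are printed with 17
#' significant digits so that reading the file back reproduces the stored
#' doubles bit for bit; undetected cells are written as `undetected_token`.
#'
#' @param x a [ct_matrix()] object.
#' @param path output file path.
#' @param undetected_token sentinel string for undetected wells.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(x, path, undetected_token = "Undetermined",
                            sep = "\t") {
  stopifnot(inherits(x, "CtMatrix"))
  cells <- matrix(undetected_token, nrow = nrow(x$ct), ncol = ncol(x$ct))
  ok <- !is.na(x$ct)
  cells[ok] <- sprintf("%.17g", x$ct[ok])
  lines <- c(paste(c("mirna_id", x$sample_ids), collapse = sep),
             paste(x$mirna_ids, apply(cells, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

.GROUP_LEVELS <- c("UA", "SA", "CONTROL")

#' Read a sample annotation table
#'
#' Reads a TSV/CSV table with mandatory columns `sample_id` and `group`
#' (one of `UA`, `SA`, `CONTROL`, case-insensitive) plus any number of
#' covariate columns (age, sex, hypertension, dyslipidemia, diabetes,
#' smoking, statin, antiplatelet, ...). Missing covariate values are kept
#' as `NA`; only operations that need a covariate reject its absence.
#'
#' @param path file path.
#' @return A data frame of class `SampleAnnotation`, with `group` a factor
#'   with levels `UA`, `SA`, `CONTROL`.
#' @export
read_sample_annotation <- function(path) {
  sep <- detect_delimiter(path)
  ann <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  sample_annotation(ann)
}

#' Construct a sample annotation object from a data frame
#'
#' @param ann data frame with columns `sample_id` and `group`; any
#'   additional columns are covariates.
#' @return A data frame of class `SampleAnnotation`.
#' @export
sample_annotation <- function(ann) {
  if (!all(c("sample_id", "group") %in% colnames(ann)))
    stop("annotation must contain columns 'sample_id' and 'group'")
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample_id in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
               collapse = ", "))
  grp <- toupper(trimws(as.character(ann$group)))
  bad <- setdiff(unique(grp), .GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s) ", paste(bad, collapse = ", "),
         "; allowed levels: ", paste(.GROUP_LEVELS, collapse = ", "))
  ann$group <- factor(grp, levels = .GROUP_LEVELS)
  class(ann) <- c("SampleAnnotation", "data.frame")
  ann
}

#' Match a Ct matrix with its sample annotation
#'
#' Restricts both the Ct matrix and the annotation to their common sample
#' set, reorders the annotation to the matrix column order, and reports any
#' dropped samples. The result carries the per-group sample counts used by
#' downstream stages.
#'
#' @param ct a [ct_matrix()] object.
#' @param ann a [sample_annotation()] object.
#' @return An object of class `ValidatedDataset`: list with `ct`, `ann`,
#'   and `group_sizes` (named integer vector over group levels present).
#' @export
validate_dataset <- function(ct, ann) {
  stopifnot(inherits(ct, "CtMatrix"), inherits(ann, "SampleAnnotation"))
  common <- intersect(ct$sample_ids, ann$sample_id)
  if (length(common) == 0L)
    stop("no samples shared between Ct matrix and annotation")
  dropped <- c(setdiff(ct$sample_ids, common), setdiff(ann$sample_id, common))
  if (length(dropped))
    message("validate_dataset: dropping unmatched sample(s): ",
            paste(dropped, collapse = ", "))
  keep <- ct$sample_ids[ct$sample_ids %in% common]
  ct2 <- ct
  ct2$ct <- ct$ct[, keep, drop = FALSE]
  ct2$sample_ids <- keep
  ann2 <- ann[match(keep, ann$sample_id), , drop = FALSE]
  rownames(ann2) <- NULL
  gs <- table(droplevels(ann2$group))
  structure(
    list(ct = ct2, ann = ann2,
         group_sizes = stats::setNames(as.integer(gs), names(gs))),
    class = "ValidatedDataset"
  )
}

#' @export
print.ValidatedDataset <- function(x, ...) {
  cat(sprintf("ValidatedDataset: %d miRNAs x %d samples; groups: %s\n",
              nrow(x$ct$ct), ncol(x$ct$ct),
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}
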