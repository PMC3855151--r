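#' Flow-cytometry microparticle event table
#'
#' One row per acquired event with boolean flags: `in_mp_gate` (inside the
#' 0.1-1 um size gate), `annexinV` (phosphatidylserine exposure), `cd31`
#' (endothelial/platelet marker). Counting-bead calibration parameters
#' convert event ratios to absolute concentrations.
#'
#' @param events data frame with logical (or 0/1) columns `in_mp_gate`,
#'   `annexinV`, `cd31`.
#' @param bead_events number of counting-bead events acquired (>= 1).
#' @param beads_per_tube known number of beads added per tube.
#' @param test_volume analyzed plasma volume in microliters (> 0).
#' @return A list of class `MpEventTable`.
#' @export
mp_event_table <- function(events, bead_events, beads_per_tube,
                           test_volume) {
  events <- as.data.frame(events)
  need <- c("in_mp_gate", "annexinV", "cd31")
  if (!all(need %in% colnames(events)))
    stop("event table needs columns: ", paste(need, collapse = ", "))
  for (cl in need) {
    v <- events[[cl]]
    if (is.numeric(v)) v <- v != 0
    if (!is.logical(v) || anyNA(v))
      stop("event flag column '", cl, "' must be boolean without NA")
    events[[cl]] <- v
  }
  if (bead_events < 1) stop("no calibration beads acquired (bead_events < 1)")
  stopifnot(beads_per_tube > 0, test_volume > 0)
  structure(list(events = events, bead_events = bead_events,
                 beads_per_tube = beads_per_tube,
                 test_volume = test_volume),
            class = "MpEventTable")
}

.MP_SUBTYPES <- c("annexinV", "annexinV_cd31pos", "annexinV_cd31neg")

subtype_predicate <- function(subtype) {
  switch(subtype,
         annexinV = function(e) e$annexinV,
         annexinV_cd31pos = function(e) e$annexinV & e$cd31,
         annexinV_cd31neg = function(e) e$annexinV & !e$cd31,
         stop("unknown MP subtype '", subtype, "'; use one of: ",
              paste(.MP_SUBTYPES, collapse = ", ")))
}

#' Bead-calibrated microparticle concentration
#'
#' `concentration = (#matching gated events / bead events) *
#' (beads per tube / test volume)`, the standard TruCount counting-bead
#' conversion of event ratios to particles per microliter of plasma.
#' Events outside the MP size gate never count.
#'
#' @param tab an [mp_event_table()].
#' @param subtype one of `"annexinV"`, `"annexinV_cd31pos"`,
#'   `"annexinV_cd31neg"`, or a predicate function on the event table.
#' @return Concentration in events per microliter (numeric scalar).
#' @export
mp_concentration <- function(tab, subtype = "annexinV") {
  stopifnot(inherits(tab, "MpEventTable"))
  pred <- if (is.function(subtype)) subtype else subtype_predicate(subtype)
  n <- sum(pred(tab$events) & tab$events$in_mp_gate)
  (n / tab$bead_events) * (tab$beads_per_tube / tab$test_volume)
}

#' Microparticle subtype panel with group comparison
#'
#' Computes the three subtype concentrations (Annexin V+, Annexin V+CD31+,
#' Annexin V+CD31-) for every sample, group means with standard error of
#' the mean, and the two-group test for each subtype via [group_compare()]
#' (continuous). The CD31+/CD31- concentrations partition the Annexin V+
#' total exactly.
#'
#' @param tables named list of [mp_event_table()] objects, one per sample.
#' @param groups factor/character vector over samples (two levels).
#' @return A list of class `MpPanel`: `per_sample` (data frame sample,
#'   group, one column per subtype), `summary` (group x subtype mean and
#'   SEM), `tests` (per-subtype test name and p-value).
#' @export
subtype_panel <- function(tables, groups) {
  stopifnot(is.list(tables), length(tables) == length(groups))
  groups <- as.character(groups)
  ids <- names(tables)
  if (is.null(ids)) ids <- paste0("S", seq_along(tables))
  conc <- t(vapply(tables, function(tb)
    vapply(.MP_SUBTYPES, function(st) mp_concentration(tb, st), numeric(1)),
    numeric(length(.MP_SUBTYPES))))
  per_sample <- data.frame(sample = ids, group = groups, conc,
                           stringsAsFactors = FALSE, row.names = NULL)
  lev <- unique(groups)
  summary_df <- do.call(rbind, lapply(lev, function(g) {
    sub <- conc[groups == g, , drop = FALSE]
    data.frame(group = g, subtype = .MP_SUBTYPES,
               mean = colMeans(sub),
               sem = apply(sub, 2L, stats::sd) / sqrt(nrow(sub)),
               n = nrow(sub), stringsAsFactors = FALSE, row.names = NULL)
  }))
  tests <- NULL
  if (length(lev) == 2L) {
    tests <- do.call(rbind, lapply(.MP_SUBTYPES, function(st) {
      gc <- group_compare(conc[, st], groups, kind = "continuous")
      data.frame(subtype = st, test = gc$test_name, p = gc$p,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_sample = per_sample, summary = summary_df,
                 tests = tests),
            class = "MpPanel")
}

#' MP miRNA expression normalized to miR-24 and adjusted to MP counts
#'
#' `adjusted[i, s] = 2^-(Ct[i, s] - Ct[miR-24, s]) / mp_count[s]`:
#' relative expression against the stable hsa-miR-24 reference, divided by
#' the sample's microparticle concentration so that expression differences
#' are not merely particle-count differences.
#'
#' @param ct a [ct_matrix()] of MP-derived RNA.
#' @param mp_counts named numeric vector of MP concentrations per sample
#'   (per microliter; must be positive), aligned with the matrix samples.
#' @param reference_id reference assay (default `"hsa-miR-24"`).
#' @return A list of class `MpMirnaExpression`: `adjusted` (matrix),
#'   `reference_id`, `mp_counts`.
#' @export
mp_mirna_expression <- function(ct, mp_counts, reference_id = "hsa-miR-24") {
  stopifnot(inherits(ct, "CtMatrix"))
  if (!is.null(names(mp_counts)))
    mp_counts <- mp_counts[ct$sample_ids]
  stopifnot(length(mp_counts) == length(ct$sample_ids))
  if (anyNA(mp_counts) || any(mp_counts <= 0))
    stop("MP counts must be positive for every sample")
  expr <- normalize_to_reference(ct, reference_id)
  adjusted <- sweep(expr$expr, 2L, as.numeric(mp_counts), `/`)
  structure(list(adjusted = adjusted, reference_id = reference_id,
                 mp_counts = stats::setNames(as.numeric(mp_counts),
                                             ct$sample_ids)),
            class = "MpMirnaExpression")
}
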