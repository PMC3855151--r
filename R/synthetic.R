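#' Specification of a synthetic plasma miRNA profiling cohort
#'
#' Defines the generative model for a TLDA-style Ct matrix: per-miRNA
#' baseline Ct levels, a planted upregulated signature in the case group,
#' miRNA-specific detection dropout increasing with Ct, group-specific
#' latent-factor correlation blocks, a stable reference assay, and a
#' covariate model with the marginal frequencies of a typical angina
#' cohort.
#'
#' Effects are planted on the Ct scale as `-log2(FC)` shifts in the case
#' group, so linear-scale fold changes are exact in expectation under the
#' `2^-dCt` measurement model.
#'
#' @param n_mirnas number of miRNA assays, excluding the reference
#'   (default 754, a TLDA card A+B panel).
#' @param group_sizes named vector of per-group sample counts (default
#'   `c(UA = 13, CONTROL = 13)`, the derivation design).
#' @param baseline_mean,baseline_sd distribution of per-miRNA baseline Ct
#'   across assays (cycles; default 28 and 3).
#' @param within_sd within-miRNA between-sample Ct standard deviation
#'   (cycles, default 0.6).
#' @param reference_id,reference_ct,reference_sd stable reference assay
#'   (default `"U6"` at Ct 25 with SD 0.15 across samples).
#' @param ct_max detection ceiling (default 40).
#' @param n_planted number of planted upregulated miRNAs in the case
#'   group (default 30).
#' @param fc_range true linear fold-change range of the planted signature
#'   (default `c(8.702, 24.2)`, the printed extremes of a strong plasma
#'   signature; keeping the lower end above the strict 8-fold calling
#'   threshold avoids planting effects exactly on the decision boundary).
#' @param planted_fc optional explicit vector of fold changes (length
#'   `n_planted`), overriding `fc_range`.
#' @param case group receiving the planted effect (default `"UA"`).
#' @param dropout_center,dropout_scale logistic detection model: a well
#'   with true Ct `c` is detected with probability
#'   `plogis((dropout_center - c)/dropout_scale)` (defaults 37 and 3.5,
#'   calibrated so roughly 5-15% of assays fail a 21-of-26 detection
#'   filter at the default baseline distribution).
#' @param block_cor target within-block pairwise correlation of the
#'   latent-factor blocks (default 0.9; factor loading `sqrt(block_cor)`).
#' @param blocks named list (per group) of lists of miRNA index vectors
#'   forming correlated blocks in that group; `NULL` installs the default
#'   when `n_mirnas >= 45`: a 15-miRNA block over the top of the planted
#'   signature (indices 16-30) active in both groups — signature members
#'   behave like coexpressed cluster/family members — plus a UA-specific
#'   block (indices 31-45); otherwise no blocks.
#' @param seed integer RNG seed.
#' @return A list of class `CohortSpec`.
#' @export
cohort_spec <- function(n_mirnas = 754,
                        group_sizes = c(UA = 13, CONTROL = 13),
                        baseline_mean = 28, baseline_sd = 3,
                        within_sd = 0.6,
                        reference_id = "U6", reference_ct = 25,
                        reference_sd = 0.15,
                        ct_max = 40,
                        n_planted = 30, fc_range = c(8.702, 24.2),
                        planted_fc = NULL,
                        case = "UA",
                        dropout_center = 37, dropout_scale = 3.5,
                        block_cor = 0.9, blocks = NULL,
                        seed = 1L) {
  stopifnot(n_mirnas >= 1, all(group_sizes >= 1),
            !is.null(names(group_sizes)),
            all(names(group_sizes) %in% .GROUP_LEVELS),
            case %in% names(group_sizes),
            n_planted >= 0, n_planted <= n_mirnas,
            block_cor >= 0, block_cor < 1, within_sd > 0)
  if (!is.null(planted_fc)) {
    stopifnot(length(planted_fc) == n_planted, all(planted_fc > 0))
  }
  if (is.null(blocks)) {
    blocks <- if (n_mirnas >= 45 && all(c("UA", "CONTROL") %in% names(group_sizes))) {
      list(UA = list(16:30, 31:45), CONTROL = list(16:30))
    } else {
      stats::setNames(rep(list(list()), length(group_sizes)),
                      names(group_sizes))
    }
  }
  for (g in names(blocks))
    for (b in blocks[[g]])
      if (any(b < 1 | b > n_mirnas))
        stop("block member index outside the miRNA universe")
  structure(list(n_mirnas = n_mirnas, group_sizes = group_sizes,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 within_sd = within_sd, reference_id = reference_id,
                 reference_ct = reference_ct, reference_sd = reference_sd,
                 ct_max = ct_max, n_planted = n_planted,
                 fc_range = fc_range, planted_fc = planted_fc, case = case,
                 dropout_center = dropout_center,
                 dropout_scale = dropout_scale,
                 block_cor = block_cor, blocks = blocks,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Validation-cohort preset
#'
#' Three-group design (45 UA, 31 SA, 37 controls) with a small
#' PCR-measured panel: 7 planted signature miRNAs upregulated in UA, and
#' a larger between-subject Ct dispersion reflecting single-assay PCR on
#' a heterogeneous clinical cohort.
#'
#' @param ... overrides passed to [cohort_spec()].
#' @return A `CohortSpec`.
#' @export
validation_cohort_spec <- function(...) {
  defaults <- list(n_mirnas = 7,
                   group_sizes = c(UA = 45, SA = 31, CONTROL = 37),
                   n_planted = 7, fc_range = c(8.702, 24.2), within_sd = 1.5,
                   blocks = NULL)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_spec, args)
}

# Per-group covariate model: marginal frequencies of a typical
# angina/control clinical cohort (sex as fraction male; age mean/sd in
# years; binary risk factors and drugs as prevalences, coded 0/1).
.COVARIATE_MODEL <- list(
  CONTROL = list(male = 22 / 37, age = c(59, 6), hypertension = 0.568,
                 dyslipidemia = 0.459, diabetes = 0.162, smoking = 0.459,
                 statin = 0.486, antiplatelet = 0.351),
  SA = list(male = 18 / 31, age = c(62, 11), hypertension = 0.742,
            dyslipidemia = 0.452, diabetes = 0.290, smoking = 0.387,
            statin = 0.516, antiplatelet = 0.516),
  UA = list(male = 25 / 45, age = c(63, 12), hypertension = 0.756,
            dyslipidemia = 0.667, diabetes = 0.267, smoking = 0.467,
            statin = 0.422, antiplatelet = 0.533)
)

simulate_covariates <- function(groups) {
  n <- length(groups)
  out <- data.frame(age = numeric(n), sex = integer(n),
                    hypertension = integer(n), dyslipidemia = integer(n),
                    diabetes = integer(n), smoking = integer(n),
                    statin = integer(n), antiplatelet = integer(n))
  for (g in unique(groups)) {
    m <- .COVARIATE_MODEL[[g]]
    idx <- which(groups == g)
    out$age[idx] <- round(stats::rnorm(length(idx), m$age[1], m$age[2]))
    out$sex[idx] <- stats::rbinom(length(idx), 1, m$male)
    for (cv in c("hypertension", "dyslipidemia", "diabetes", "smoking",
                 "statin", "antiplatelet"))
      out[[cv]][idx] <- stats::rbinom(length(idx), 1, m[[cv]])
  }
  out
}

#' Simulate a plasma miRNA profiling cohort
#'
#' Draws a Ct matrix, sample annotation, and ground truth from a
#' [cohort_spec()]. The observed Ct is
#' `baseline_i - log2(FC_i) * [sample in case group] + block factor +
#' noise`; wells are censored at the detection ceiling and additionally
#' dropped out with the logistic detection model; the reference row is
#' always detected. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List with `ct` ([ct_matrix()]), `ann` ([sample_annotation()]),
#'   and `truth` (class `GroundTruth`: `planted` data frame of
#'   `mirna_id` and `true_fc`, `blocks` as id lists per group, `spec`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  with_seed(spec$seed, {
    p <- spec$n_mirnas
    ids <- sprintf("mir-%04d", seq_len(p))
    groups <- rep(names(spec$group_sizes), spec$group_sizes)
    n <- length(groups)
    sample_ids <- sprintf("%s_%02d", groups, stats::ave(seq_len(n), groups,
                                                        FUN = seq_along))
    baseline <- stats::rnorm(p, spec$baseline_mean, spec$baseline_sd)
    fc <- rep(1, p)
    if (spec$n_planted > 0) {
      fc[seq_len(spec$n_planted)] <- if (!is.null(spec$planted_fc))
        spec$planted_fc
      else stats::runif(spec$n_planted, spec$fc_range[1], spec$fc_range[2])
    }
    is_case <- groups == spec$case
    true_ct <- matrix(baseline, nrow = p, ncol = n)
    true_ct[, is_case] <- true_ct[, is_case] - log2(fc)
    # latent-factor correlation blocks, per group
    lambda <- sqrt(spec$block_cor)
    noise <- matrix(stats::rnorm(p * n), nrow = p, ncol = n)
    for (g in names(spec$blocks)) {
      cols <- which(groups == g)
      for (b in spec$blocks[[g]]) {
        f <- stats::rnorm(length(cols))
        noise[b, cols] <- lambda * rep(f, each = length(b)) +
          sqrt(1 - spec$block_cor) * noise[b, cols]
      }
    }
    obs_ct <- true_ct + spec$within_sd * noise
    detected <- stats::runif(p * n) <
      stats::plogis((spec$dropout_center - obs_ct) / spec$dropout_scale)
    obs_ct[!detected] <- NA_real_
    obs_ct[!is.na(obs_ct) & obs_ct >= spec$ct_max] <- NA_real_
    obs_ct[!is.na(obs_ct) & obs_ct < 0] <- 0
    ref <- stats::rnorm(n, spec$reference_ct, spec$reference_sd)
    mat <- rbind(obs_ct, ref)
    dimnames(mat) <- list(c(ids, spec$reference_id), sample_ids)
    ct <- ct_matrix(mat, ct_max = spec$ct_max)
    ann <- sample_annotation(cbind(
      data.frame(sample_id = sample_ids, group = groups,
                 stringsAsFactors = FALSE),
      simulate_covariates(groups)))
    truth <- structure(
      list(planted = data.frame(mirna_id = ids[seq_len(spec$n_planted)],
                                true_fc = fc[seq_len(spec$n_planted)],
                                stringsAsFactors = FALSE),
           blocks = lapply(spec$blocks, function(bl)
             lapply(bl, function(b) ids[b])),
           spec = spec),
      class = "GroundTruth")
    list(ct = ct, ann = ann, truth = truth)
  })
}

#' Specification of a synthetic microparticle study
#'
#' Two groups of flow-cytometry samples with subtype concentrations drawn
#' around the group means of a vulnerable-CAD MP study (Annexin V+CD31+
#' and Annexin V+CD31- per microliter of plasma; totals follow by
#' partition additivity), plus an MP-RNA Ct matrix with a planted
#' fold change on the count-adjusted expression scale. Printed
#' mean +/- SEM summaries convert to per-sample SDs via `SD = SEM *
#' sqrt(n)`.
#'
#' @param n_per_group samples per group (default 5).
#' @param ua_cd31pos,ua_cd31neg,control_cd31pos,control_cd31neg group
#'   means (events/uL; defaults 4318, 895, 1646, 594 — a UA-like preset
#'   whose Annexin V+ totals are 5213 and 2240).
#' @param ua_cd31pos_sem,ua_cd31neg_sem,control_cd31pos_sem,control_cd31neg_sem
#'   printed SEMs (defaults 988, 287, 462, 280).
#' @param mirna_ids MP-RNA panel (default the 7-member validated
#'   signature).
#' @param mp_fc planted case/control fold change of count-adjusted
#'   expression (default 2).
#' @param log10_adj_base mean log10 count-adjusted expression in controls
#'   (default -5).
#' @param log10_adj_sd between-sample SD of log10 adjusted expression
#'   (default 0.12).
#' @param reference_id,reference_ct MP-RNA reference assay (default
#'   `"hsa-miR-24"` at Ct 24, SD 0.15).
#' @param bead_events,beads_per_tube,test_volume counting-bead calibration
#'   (defaults 5000 bead events, 25000 beads per tube, 100 uL).
#' @param seed integer RNG seed.
#' @return A list of class `MpStudySpec`.
#' @export
mp_study_spec <- function(n_per_group = 5,
                          ua_cd31pos = 4318, ua_cd31neg = 895,
                          control_cd31pos = 1646, control_cd31neg = 594,
                          ua_cd31pos_sem = 988, ua_cd31neg_sem = 287,
                          control_cd31pos_sem = 462,
                          control_cd31neg_sem = 280,
                          mirna_ids = c("hsa-miR-106b", "hsa-miR-25",
                                        "hsa-miR-92a", "hsa-miR-21",
                                        "hsa-miR-590-5p", "hsa-miR-126*",
                                        "hsa-miR-451"),
                          mp_fc = 2, log10_adj_base = -5,
                          log10_adj_sd = 0.12,
                          reference_id = "hsa-miR-24", reference_ct = 24,
                          bead_events = 5000, beads_per_tube = 25000,
                          test_volume = 100, seed = 1L) {
  stopifnot(n_per_group >= 1, mp_fc > 0, bead_events >= 1)
  structure(list(n_per_group = n_per_group,
                 means = list(UA = c(cd31pos = ua_cd31pos,
                                     cd31neg = ua_cd31neg),
                              CONTROL = c(cd31pos = control_cd31pos,
                                          cd31neg = control_cd31neg)),
                 sds = list(UA = sqrt(n_per_group) *
                              c(cd31pos = ua_cd31pos_sem,
                                cd31neg = ua_cd31neg_sem),
                            CONTROL = sqrt(n_per_group) *
                              c(cd31pos = control_cd31pos_sem,
                                cd31neg = control_cd31neg_sem)),
                 mirna_ids = mirna_ids, mp_fc = mp_fc,
                 log10_adj_base = log10_adj_base,
                 log10_adj_sd = log10_adj_sd,
                 reference_id = reference_id, reference_ct = reference_ct,
                 bead_events = bead_events,
                 beads_per_tube = beads_per_tube,
                 test_volume = test_volume, seed = as.integer(seed)),
            class = "MpStudySpec")
}

# Normal draws redrawn until positive (keeps group means near target
# without a point mass at zero; deterministic under the active seed).
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a microparticle flow-cytometry + MP-RNA study
#'
#' Draws per-sample subtype concentrations, converts them to event counts
#' through the bead calibration (Poisson event sampling, fixed bead
#' parameters, plus Annexin V-negative and out-of-gate nuisance events),
#' and generates the MP-RNA Ct matrix so that count-adjusted expression
#' has the planted case/control fold change.
#'
#' @param spec an [mp_study_spec()].
#' @return List with `tables` (named list of [mp_event_table()]), `groups`
#'   (character vector), `ct` (MP-RNA [ct_matrix()]), `mp_counts` (true
#'   simulated Annexin V+ concentrations), and `truth` (class
#'   `GroundTruth`: planted `mp_fc` per miRNA, group concentration means,
#'   `spec`).
#' @export
simulate_mp_study <- function(spec) {
  stopifnot(inherits(spec, "MpStudySpec"))
  with_seed(spec$seed, {
    groups <- rep(c("UA", "CONTROL"), each = spec$n_per_group)
    sample_ids <- sprintf("%s_MP%d", groups,
                          rep(seq_len(spec$n_per_group), 2))
    scale_f <- spec$beads_per_tube / spec$test_volume / spec$bead_events
    tables <- vector("list", length(groups))
    names(tables) <- sample_ids
    conc_total <- numeric(length(groups))
    for (i in seq_along(groups)) {
      g <- groups[i]
      cpos <- rnorm_pos(1, spec$means[[g]]["cd31pos"], spec$sds[[g]]["cd31pos"])
      cneg <- rnorm_pos(1, spec$means[[g]]["cd31neg"], spec$sds[[g]]["cd31neg"])
      n_pos <- stats::rpois(1, cpos / scale_f)
      n_neg <- stats::rpois(1, cneg / scale_f)
      n_annneg <- stats::rpois(1, 300)   # gated, Annexin V- debris
      n_out <- stats::rpois(1, 200)      # outside the size gate
      events <- data.frame(
        in_mp_gate = c(rep(TRUE, n_pos + n_neg + n_annneg),
                       rep(FALSE, n_out)),
        annexinV = c(rep(TRUE, n_pos + n_neg), rep(FALSE, n_annneg),
                     rep(TRUE, n_out)),
        cd31 = c(rep(TRUE, n_pos), rep(FALSE, n_neg + n_annneg),
                 rep(TRUE, n_out)))
      tables[[i]] <- mp_event_table(events, spec$bead_events,
                                    spec$beads_per_tube, spec$test_volume)
      conc_total[i] <- mp_concentration(tables[[i]], "annexinV")
    }
    conc_total[conc_total <= 0] <- 1   # degenerate sample: floor at 1/uL
    # MP-RNA Ct matrix: Ct = Ct_ref - log2(adjusted * count)
    ref <- stats::rnorm(length(groups), spec$reference_ct, 0.15)
    p <- length(spec$mirna_ids)
    log10_adj <- matrix(spec$log10_adj_base +
                          stats::rnorm(p * length(groups), 0,
                                       spec$log10_adj_sd),
                        nrow = p)
    log10_adj[, groups == "UA"] <- log10_adj[, groups == "UA"] +
      log10(spec$mp_fc)
    ctm <- matrix(0, nrow = p, ncol = length(groups))
    for (s in seq_along(groups))
      ctm[, s] <- ref[s] - log2(10^log10_adj[, s] * conc_total[s])
    mat <- rbind(ctm, ref)
    dimnames(mat) <- list(c(spec$mirna_ids, spec$reference_id), sample_ids)
    ct <- ct_matrix(mat, ct_max = 40)
    truth <- structure(
      list(planted = data.frame(mirna_id = spec$mirna_ids,
                                true_adjusted_fc = spec$mp_fc,
                                stringsAsFactors = FALSE),
           group_means = spec$means, spec = spec),
      class = "GroundTruth")
    list(tables = tables, groups = groups, ct = ct,
         mp_counts = stats::setNames(conc_total, sample_ids),
         truth = truth)
  })
}

#' Compare analysis results with the generator's ground truth
#'
#' Computes recovery metrics for a selected miRNA set against the planted
#' signature: sensitivity (fraction of planted miRNAs selected), false
#' selections (selected but not planted), and — when estimated fold
#' changes are supplied — the mean relative fold-change estimation error
#' over recovered planted miRNAs.
#'
#' @param truth a `GroundTruth` from a generator.
#' @param selected character vector of selected miRNA ids (or a
#'   `DeregulatedSet`).
#' @param estimated_fc optional named vector of estimated fold changes.
#' @return List with `sensitivity`, `false_selections`, `n_planted`,
#'   `n_selected`, and `fc_relative_error` (`NA` if not computable).
#' @export
ground_truth_report <- function(truth, selected, estimated_fc = NULL) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (inherits(selected, "DeregulatedSet")) selected <- selected$mirna_id
  selected <- as.character(selected)
  universe <- sprintf("mir-%04d", seq_len(truth$spec$n_mirnas))
  if (!is.null(truth$spec$mirna_ids)) universe <- truth$spec$mirna_ids
  unknown <- setdiff(selected, c(universe, truth$planted$mirna_id))
  if (length(unknown))
    stop("selected identifier(s) not in the simulated universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  planted <- truth$planted$mirna_id
  hits <- intersect(selected, planted)
  fc_err <- NA_real_
  if (!is.null(estimated_fc) && length(hits)) {
    est <- estimated_fc[hits]
    tru <- truth$planted$true_fc[match(hits, planted)]
    fc_err <- mean(abs(est - tru) / tru, na.rm = TRUE)
  }
  list(sensitivity = if (length(planted)) length(hits) / length(planted)
       else NA_real_,
       false_selections = length(setdiff(selected, planted)),
       n_planted = length(planted), n_selected = length(selected),
       fc_relative_error = fc_err)
}
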