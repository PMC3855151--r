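#' Pipeline run configuration
#'
#' Bundles the stage parameters of the end-to-end analyses: detection
#' filter, reference assay, SAM configuration, network thresholds, PCA
#' dimensionality, and either input file paths or a simulation spec.
#'
#' @param ct_path,annotation_path input files read with
#'   [read_ct_matrix()] / [read_sample_annotation()]; ignored when
#'   `simulate` is given.
#' @param simulate a [cohort_spec()] (or [mp_study_spec()] for
#'   [run_mp()]) to generate the inputs instead of reading files.
#' @param min_detected detection-filter threshold (default 21, the
#'   21-of-26 expression criterion; capped at the sample count at run
#'   time).
#' @param reference_id normalization reference (default `"U6"`).
#' @param sam a [sam_config()].
#' @param r_min,p_max coexpression network thresholds (defaults 0.79 and
#'   0.02).
#' @param pca_k principal components retained (default 3).
#' @param case,control contrast labels (defaults `"UA"`, `"CONTROL"`).
#' @param seeds seed miRNAs for the first-neighbor subnetwork; `NULL`
#'   uses the SAM-selected signature.
#' @param out_dir output directory for the report bundle; `NULL` disables
#'   file output.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(ct_path = NULL, annotation_path = NULL,
                       simulate = NULL, min_detected = 21,
                       reference_id = "U6", sam = sam_config(),
                       r_min = 0.79, p_max = 0.02, pca_k = 3,
                       case = "UA", control = "CONTROL", seeds = NULL,
                       out_dir = NULL) {
  stopifnot(r_min >= -1, r_min <= 1, p_max > 0, p_max <= 1, pca_k >= 1)
  if (is.null(simulate) && (is.null(ct_path) || is.null(annotation_path)))
    stop("provide either input paths or a simulation spec")
  structure(list(ct_path = ct_path, annotation_path = annotation_path,
                 simulate = simulate, min_detected = min_detected,
                 reference_id = reference_id, sam = sam, r_min = r_min,
                 p_max = p_max, pca_k = pca_k, case = case,
                 control = control, seeds = seeds, out_dir = out_dir),
            class = "RunConfig")
}

load_or_simulate <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- simulate_cohort(cfg$simulate)
    list(ct = sim$ct, ann = sim$ann, truth = sim$truth)
  } else {
    list(ct = read_ct_matrix(cfg$ct_path),
         ann = read_sample_annotation(cfg$annotation_path),
         truth = NULL)
  }
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the derivation-cohort profiling analysis
#'
#' Fixed stage order: load/simulate -> validate -> detection filter ->
#' reference normalization -> log transform -> SAM -> signature selection
#' -> hierarchical clustering + PCA classification -> per-group
#' coexpression networks -> seed/first-neighbor subnetworks -> network
#' comparison. When `cfg$out_dir` is set, every table is written as TSV
#' together with a JSON manifest of parameters, seed, and per-stage
#' counts.
#'
#' @param cfg a [run_config()].
#' @return A report list: `dataset`, `filtered`, `expr`, `sam`,
#'   `signature`, `clustering`, `pca`, `pca_classification`, `networks`,
#'   `subnetworks`, `comparison`, `subnet_comparison`, `manifest`,
#'   `truth` (generator runs only).
#' @export
run_derivation <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  inp <- run_stage("load", load_or_simulate(cfg))
  ds <- run_stage("validate", validate_dataset(inp$ct, inp$ann))
  n_samples <- length(ds$ct$sample_ids)
  min_det <- min(cfg$min_detected, n_samples)
  filtered <- run_stage("filter", detection_filter(ds$ct, min_det))
  expr <- run_stage("normalize",
                    normalize_to_reference(filtered, cfg$reference_id))
  expr <- run_stage("log", log_transform(expr))
  groups <- as.character(ds$ann$group)
  sam <- run_stage("sam", sam_analysis(expr, groups, case = cfg$case,
                                       control = cfg$control,
                                       cfg = cfg$sam))
  sig <- run_stage("select", select_signature(sam, cfg$sam))
  clus <- run_stage("cluster", hierarchical_cluster(expr))
  pca <- run_stage("pca", pca_reduce(expr, k = min(cfg$pca_k,
                                                   n_samples - 1L)))
  use2 <- groups %in% c(cfg$case, cfg$control)
  pcls <- run_stage("pca", {
    sc2 <- pca
    sc2$scores <- pca$scores[use2, , drop = FALSE]
    pca_classify(sc2, groups[use2])
  })
  nets <- list()
  subnets <- list()
  seeds <- if (!is.null(cfg$seeds)) cfg$seeds else sig$mirna_id
  for (g in c(cfg$case, cfg$control)) {
    x <- expr$log10_expr[, groups == g, drop = FALSE]
    pp <- run_stage("network", pairwise_pearson(x))
    nets[[g]] <- run_stage("network",
                           build_network(pp$r, pp$p, cfg$r_min, cfg$p_max,
                                         group = g))
    subnets[[g]] <- if (length(seeds))
      run_stage("subnetwork", first_neighbor_subnetwork(nets[[g]], seeds))
    else nets[[g]]
  }
  comp <- run_stage("compare",
                    compare_networks(nets[[cfg$case]], nets[[cfg$control]]))
  subcomp <- run_stage("compare",
                       compare_networks(subnets[[cfg$case]],
                                        subnets[[cfg$control]]))
  manifest <- list(
    analysis = "derivation",
    parameters = list(min_detected = min_det,
                      reference_id = cfg$reference_id,
                      n_permutations = cfg$sam$n_permutations,
                      s0 = attr(sam, "s0"), pi0 = attr(sam, "pi0"),
                      fc_min = cfg$sam$fc_min, q_max = cfg$sam$q_max,
                      r_min = cfg$r_min, p_max = cfg$p_max,
                      pca_k = pca$k, seed = cfg$sam$seed),
    stages = c("load", "validate", "filter", "normalize", "sam", "select",
               "cluster_pca", "network"),
    counts = list(n_samples = n_samples,
                  group_sizes = as.list(ds$group_sizes),
                  n_mirnas_input = length(ds$ct$mirna_ids),
                  n_mirnas_filtered = length(filtered$mirna_ids),
                  n_mirnas_sam = nrow(sam),
                  n_selected = nrow(sig),
                  pca_overall_rate = pcls$overall_rate,
                  edges_case = comp$n_edges_A,
                  edges_control = comp$n_edges_B,
                  subnet_nodes_case = length(subnets[[cfg$case]]$nodes),
                  subnet_nodes_control = length(subnets[[cfg$control]]$nodes),
                  subnet_shared_links = subcomp$n_shared))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sam_table(sam, file.path(cfg$out_dir, "sam_result.tsv"))
    write_sam_table(sig, file.path(cfg$out_dir, "deregulated_set.tsv"))
    write_expression_matrix(expr, file.path(cfg$out_dir,
                                            "expression_log10.tsv"),
                            what = "log10")
    for (g in names(nets)) {
      export_network(nets[[g]],
                     file.path(cfg$out_dir, paste0("network_", g, ".tsv")))
      export_network(subnets[[g]],
                     file.path(cfg$out_dir, paste0("subnetwork_", g, ".sif")),
                     format = "sif")
    }
    write_manifest(manifest, cfg$out_dir)
  }
  list(dataset = ds, filtered = filtered, expr = expr, sam = sam,
       signature = sig, clustering = clus, pca = pca,
       pca_classification = pcls, networks = nets, subnetworks = subnets,
       comparison = comp, subnet_comparison = subcomp,
       manifest = manifest, truth = inp$truth)
}

#' Run the validation-cohort evaluation
#'
#' Requires a three-group annotation (UA, SA, CONTROL). For each miRNA:
#' ROC for UA versus non-UA (SA and controls pooled) on the log10
#' expression scale, and covariate-adjusted logistic regression for the
#' UA-vs-SA and UA-vs-CONTROL contrasts. Also reports the PCA
#' classification of UA against the pooled non-UA samples. The logistic
#' stage records a per-miRNA failure (rather than aborting the run) if
#' covariates are missing.
#'
#' @param cfg a [run_config()] whose data carry all three groups.
#' @param covariate_names covariates entering the logistic adjustment.
#' @return A report list: `dataset`, `expr`, `roc` (named list of
#'   `RocResult`), `logit` (named list per miRNA of per-contrast
#'   `LogitResult` or error message), `pca_classification`, `manifest`,
#'   `truth`.
#' @export
run_validation <- function(cfg,
                           covariate_names = c("age", "sex", "hypertension",
                                               "dyslipidemia", "diabetes",
                                               "smoking", "statin",
                                               "antiplatelet")) {
  stopifnot(inherits(cfg, "RunConfig"))
  inp <- run_stage("load", load_or_simulate(cfg))
  ds <- run_stage("validate", validate_dataset(inp$ct, inp$ann))
  groups <- as.character(ds$ann$group)
  for (g in c("UA", "SA", "CONTROL"))
    if (!any(groups == g)) stop("validation cohort lacks group '", g, "'")
  n_samples <- length(ds$ct$sample_ids)
  filtered <- run_stage("filter",
                        detection_filter(ds$ct,
                                         min(cfg$min_detected, n_samples)))
  expr <- run_stage("normalize",
                    normalize_to_reference(filtered, cfg$reference_id))
  expr <- run_stage("log", log_transform(expr))
  is_ua <- groups == "UA"
  rocs <- list()
  logits <- list()
  for (id in expr$mirna_ids) {
    vals <- expr$log10_expr[id, ]
    rocs[[id]] <- run_stage("roc", roc_analysis(vals, is_ua))
    logits[[id]] <- list()
    for (ctr in c("UA_vs_SA", "UA_vs_CONTROL")) {
      other <- if (ctr == "UA_vs_SA") "SA" else "CONTROL"
      use <- groups %in% c("UA", other)
      res <- tryCatch(
        logistic_adjusted(vals[use], is_ua[use],
                          ds$ann[use, covariate_names, drop = FALSE]),
        error = function(e) conditionMessage(e))
      logits[[id]][[ctr]] <- res
    }
  }
  pca <- run_stage("pca", pca_reduce(expr, k = min(cfg$pca_k,
                                                   n_samples - 1L)))
  pcls <- run_stage("pca",
                    pca_classify(pca, ifelse(is_ua, "UA", "nonUA")))
  manifest <- list(
    analysis = "validation",
    parameters = list(reference_id = cfg$reference_id, pca_k = pca$k,
                      covariates = covariate_names),
    counts = list(n_samples = n_samples,
                  group_sizes = as.list(ds$group_sizes),
                  n_mirnas = length(expr$mirna_ids),
                  pca_overall_rate = pcls$overall_rate))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_roc_table(rocs, file.path(cfg$out_dir, "roc_table.tsv"))
    ok_logits <- lapply(logits, function(l) Filter(Negate(is.character), l))
    write_logit_table(ok_logits, file.path(cfg$out_dir, "logit_table.tsv"))
    write_manifest(manifest, cfg$out_dir)
  }
  list(dataset = ds, expr = expr, roc = rocs, logit = logits,
       pca_classification = pcls, manifest = manifest, truth = inp$truth)
}

#' Run the microparticle study analysis
#'
#' Computes the bead-calibrated subtype panel with group comparisons and
#' the miR-24-normalized, MP-count-adjusted miRNA expression with a
#' per-miRNA two-group test on the log10 adjusted scale.
#'
#' @param cfg a [run_config()] whose `simulate` is an [mp_study_spec()],
#'   or `mp_data` given directly.
#' @param mp_data optional list as returned by [simulate_mp_study()]
#'   (`tables`, `groups`, `ct`, `mp_counts`).
#' @return A report list: `panel` (`MpPanel`), `adjusted`
#'   (`MpMirnaExpression`), `mirna_tests` (data frame), `manifest`,
#'   `truth`.
#' @export
run_mp <- function(cfg = NULL, mp_data = NULL) {
  if (is.null(mp_data)) {
    stopifnot(inherits(cfg, "RunConfig"),
              inherits(cfg$simulate, "MpStudySpec"))
    mp_data <- run_stage("load", simulate_mp_study(cfg$simulate))
  }
  panel <- run_stage("panel", subtype_panel(mp_data$tables, mp_data$groups))
  counts <- vapply(mp_data$tables, mp_concentration, numeric(1),
                   subtype = "annexinV")
  counts[counts <= 0] <- NA_real_
  if (anyNA(counts)) {
    keep <- !is.na(counts)
    message("run_mp: dropping ", sum(!keep),
            " sample(s) with zero Annexin V+ concentration")
    mp_data$ct$ct <- mp_data$ct$ct[, keep, drop = FALSE]
    mp_data$ct$sample_ids <- mp_data$ct$sample_ids[keep]
    mp_data$groups <- mp_data$groups[keep]
    counts <- counts[keep]
  }
  adj <- run_stage("adjust", mp_mirna_expression(mp_data$ct, counts))
  tests <- do.call(rbind, lapply(rownames(adj$adjusted), function(id) {
    gc <- group_compare(log10(adj$adjusted[id, ]), mp_data$groups,
                        kind = "continuous")
    data.frame(mirna_id = id, test = gc$test_name, p = gc$p,
               stringsAsFactors = FALSE)
  }))
  manifest <- list(analysis = "mp",
                   counts = list(n_samples = length(mp_data$groups),
                                 n_mirnas = nrow(adj$adjusted)))
  if (!is.null(cfg) && !is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(panel$per_sample,
                       file.path(cfg$out_dir, "mp_panel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tests, file.path(cfg$out_dir, "mp_mirna_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(manifest, cfg$out_dir)
  }
  list(panel = panel, adjusted = adj, mirna_tests = tests,
       manifest = manifest, truth = mp_data$truth)
}
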