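#' Unsupervised hierarchical clustering of samples and miRNAs
#'
#' Clusters both axes of a log10 expression matrix, the layout of a
#' two-way heat map. Distances use pairwise-complete observations
#' (`stats::dist` rescales for missing pairs); merging is deterministic
#' given the input order.
#'
#' @param x numeric matrix (miRNAs x samples) of log10 expression, or an
#'   `ExpressionMatrix`.
#' @param linkage agglomeration rule passed to [stats::hclust()]
#'   (default `"average"`).
#' @param distance distance measure passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @return List with `samples` and `mirnas` ([stats::hclust] trees) and
#'   their leaf orders `sample_order`, `mirna_order`.
#' @export
hierarchical_cluster <- function(x, linkage = "average",
                                 distance = "euclidean") {
  if (inherits(x, "ExpressionMatrix")) {
    if (is.null(x$log10_expr)) x <- log_transform(x)
    x <- x$log10_expr
  }
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  if (all(apply(x, 1L, function(r) {
    v <- r[!is.na(r)]
    length(v) < 2L || stats::var(v) == 0
  })))
    stop("zero variance: all miRNAs are constant across samples")
  hs <- stats::hclust(stats::dist(t(x), method = distance), method = linkage)
  hm <- stats::hclust(stats::dist(x, method = distance), method = linkage)
  list(samples = hs, mirnas = hm,
       sample_order = colnames(x)[hs$order],
       mirna_order = rownames(x)[hm$order])
}

#' Principal component reduction of expression profiles
#'
#' Reduces the samples-by-miRNA data to `k` uncorrelated components
#' (default 3, the dimensionality used for visual classification of
#' expression profiles). Data are centered, not scaled. Missing cells are
#' imputed with the miRNA's cohort mean on the log10 scale before the
#' decomposition. Component signs follow the convention that the
#' largest-magnitude loading is positive.
#'
#' @param x numeric matrix (miRNAs x samples) of log10 expression, or an
#'   `ExpressionMatrix`.
#' @param k number of components (default 3).
#' @return A list of class `PcaResult`: `scores` (samples x k),
#'   `loadings` (miRNAs x k), `variance_explained` (length k,
#'   proportions of total variance), `k`.
#' @export
pca_reduce <- function(x, k = 3L) {
  if (inherits(x, "ExpressionMatrix")) {
    if (is.null(x$log10_expr)) x <- log_transform(x)
    x <- x$log10_expr
  }
  stopifnot(is.matrix(x))
  if (anyNA(x)) {
    mu <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 1L]]
  }
  kmax <- min(ncol(x) - 1L, nrow(x))
  if (k > kmax)
    stop("k = ", k, " exceeds the maximum of ", kmax,
         " components for this matrix")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve[seq_len(k)], k = k),
            class = "PcaResult")
}

#' Classify samples from principal component scores
#'
#' Default rule: leave-one-out nearest group centroid in the k-dimensional
#' score space (Euclidean distance); each sample is assigned to the group
#' whose centroid — computed without that sample — is closest. Reports
#' per-group and overall correct-classification fractions.
#'
#' @param pca a `PcaResult` from [pca_reduce()].
#' @param groups factor/character vector over samples (matrix row order).
#' @param rule classification rule; only `"loo_centroid"` is built in.
#' @return List with `assigned` (character vector), `per_group` (data
#'   frame: group, n, correct, rate), and `overall_rate`.
#' @export
pca_classify <- function(pca, groups, rule = "loo_centroid") {
  stopifnot(inherits(pca, "PcaResult"), identical(rule, "loo_centroid"))
  groups <- as.character(groups)
  sc <- pca$scores
  stopifnot(length(groups) == nrow(sc))
  lev <- unique(groups)
  if (any(table(groups) < 2L))
    stop("leave-one-out centroid classification needs >= 2 samples per group")
  assigned <- character(nrow(sc))
  for (i in seq_len(nrow(sc))) {
    dists <- vapply(lev, function(g) {
      idx <- which(groups == g)
      idx <- setdiff(idx, i)
      cen <- colMeans(sc[idx, , drop = FALSE])
      sqrt(sum((sc[i, ] - cen)^2))
    }, numeric(1))
    assigned[i] <- lev[which.min(dists)]
  }
  per_group <- do.call(rbind, lapply(lev, function(g) {
    idx <- groups == g
    data.frame(group = g, n = sum(idx),
               correct = sum(assigned[idx] == g),
               rate = mean(assigned[idx] == g),
               stringsAsFactors = FALSE)
  }))
  list(assigned = assigned, per_group = per_group,
       overall_rate = mean(assigned == groups))
}

#' ROC analysis of a single marker
#'
#' AUC by the rank (Mann-Whitney) method with midrank tie handling,
#' 95% confidence interval by the Hanley-McNeil variance formula, p-value
#' against AUC = 0.5 from the normal approximation of the U statistic, and
#' the Youden-optimal cut-off (maximizing sensitivity + specificity - 1,
#' ties broken toward higher specificity). The polarity is "case high": a
#' sample is called positive when its value is at or above the cut-off.
#'
#' @param values numeric vector (e.g. one miRNA's log10 expression).
#' @param is_case logical vector; `TRUE` for cases.
#' @return A list of class `RocResult`: `auc`, `ci95` (length 2),
#'   `p_value`, `cutoff`, `sensitivity`, `specificity`, `n_case`,
#'   `n_control`.
#' @export
roc_analysis <- function(values, is_case) {
  stopifnot(is.numeric(values), is.logical(is_case),
            length(values) == length(is_case))
  ok <- !is.na(values) & !is.na(is_case)
  values <- values[ok]; is_case <- is_case[ok]
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 == 0L || n2 == 0L) stop("both classes must be non-empty")
  if (length(unique(values)) == 1L) {
    warning("constant marker values: AUC degenerate at 0.5, no cut-off")
    return(structure(list(auc = 0.5, ci95 = c(0.5, 0.5), p_value = 1,
                          cutoff = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, n_case = n1,
                          n_control = n2), class = "RocResult"))
  }
  r <- rank(values)                      # midranks handle ties
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  se0 <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
  p <- 2 * stats::pnorm(-abs(auc - 0.5) / se0)
  v <- sort(unique(values))
  cuts <- c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  sens <- vapply(cuts, function(cc) mean(values[is_case] >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(values[!is_case] < cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[order(-spec[best], -cuts[best])][1L]
  structure(list(auc = auc, ci95 = ci, p_value = p, cutoff = cuts[best],
                 sensitivity = sens[best], specificity = spec[best],
                 n_case = n1, n_control = n2),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), p = %.3g; cut-off %.3f: sens %.1f%%, spec %.1f%%\n",
              x$auc, x$ci95[1], x$ci95[2], x$p_value, x$cutoff,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Covariate-adjusted logistic regression for a marker
#'
#' Fits a maximum-likelihood logistic model of a binary outcome on the
#' marker level (log10 expression, so the odds ratio is per 10-fold
#' expression change) plus covariates, via iteratively reweighted least
#' squares (tolerance 1e-8, at most 100 iterations). Wald 95% CI and
#' p-value are reported for the marker coefficient. Perfect separation or
#' non-convergence is flagged (infinite odds-ratio sentinel), not an
#' error.
#'
#' @param values numeric marker vector over samples.
#' @param outcome logical vector (`TRUE` = event, e.g. UA).
#' @param covariates optional data frame of adjustment covariates (no
#'   missing values allowed among used samples).
#' @return A list of class `LogitResult`: `odds_ratio`, `ci95`, `p_value`,
#'   `coef`, `se`, `flagged` (TRUE on separation/non-convergence), `n`.
#' @export
logistic_adjusted <- function(values, outcome, covariates = NULL) {
  stopifnot(is.numeric(values), is.logical(outcome),
            length(values) == length(outcome))
  df <- data.frame(.y = outcome, .x = values)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(values))
    miss <- vapply(covariates, anyNA, logical(1))
    if (any(miss))
      stop("missing values in covariate(s): ",
           paste(names(covariates)[miss], collapse = ", "))
    df <- cbind(df, covariates)
  }
  if (length(unique(values)) == 1L)
    return(structure(list(odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                          p_value = NA_real_, coef = NA_real_, se = NA_real_,
                          flagged = TRUE, n = nrow(df)),
                     class = "LogitResult"))
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  co <- summary(fit)$coefficients
  b <- co[".x", "Estimate"]
  se <- co[".x", "Std. Error"]
  flagged <- !fit$converged || abs(b) > 15 || se > 1e3
  or <- exp(b)
  if (flagged && abs(b) > 15) or <- ifelse(b > 0, Inf, 0)
  structure(list(odds_ratio = or,
                 ci95 = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = co[".x", "Pr(>|z|)"], coef = b, se = se,
                 flagged = flagged, n = nrow(df)),
            class = "LogitResult")
}

#' Two-group comparison with automatic test selection
#'
#' Continuous data: Shapiro-Wilk normality gate at alpha 0.05 in each
#' group chooses between the pooled two-sided t-test and the Mann-Whitney
#' U test. Categorical data (a 2x2 or larger contingency table with groups
#' in rows): Pearson chi-squared without continuity correction, switching
#' to the two-sided Fisher exact test when any expected cell count is
#' below 5.
#'
#' @param x numeric vector (with `labels`) for `kind = "continuous"`, or a
#'   contingency table/matrix for `kind = "categorical"`.
#' @param labels logical or two-level vector over `x` (continuous only).
#' @param kind `"continuous"` or `"categorical"`.
#' @return List with `test_name`, `statistic` (`NA` for Fisher), `p`.
#' @export
group_compare <- function(x, labels = NULL,
                          kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    tab <- as.matrix(x)
    stopifnot(all(tab >= 0), nrow(tab) >= 2L, ncol(tab) >= 2L)
    exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_cells < 5)) {
      ft <- stats::fisher.test(tab)
      return(list(test_name = "fisher", statistic = NA_real_, p = ft$p.value))
    }
    ct <- stats::chisq.test(tab, correct = FALSE)
    return(list(test_name = "chisq", statistic = unname(ct$statistic),
                p = ct$p.value))
  }
  stopifnot(!is.null(labels), length(labels) == length(x))
  if (is.logical(labels)) labels <- ifelse(labels, "g1", "g0")
  labels <- as.character(labels)
  lev <- unique(labels[!is.na(labels)])
  if (length(lev) != 2L) stop("continuous comparison needs exactly 2 groups")
  ok <- !is.na(x) & !is.na(labels)
  x <- x[ok]; labels <- labels[ok]
  g1 <- x[labels == lev[1]]; g2 <- x[labels == lev[2]]
  if (length(g1) == 0L || length(g2) == 0L) stop("empty group")
  normal <- vapply(list(g1, g2), function(g) {
    if (length(unique(g)) == 1L) return(TRUE)   # constant: cannot reject
    if (length(g) < 3L) return(FALSE)
    stats::shapiro.test(g)$p.value >= 0.05
  }, logical(1))
  if (all(normal)) {
    sp <- sqrt(((length(g1) - 1) * stats::var(g1) +
                  (length(g2) - 1) * stats::var(g2)) /
                 (length(g1) + length(g2) - 2))
    if (sp == 0) {
      tstat <- if (mean(g1) == mean(g2)) 0 else sign(mean(g1) - mean(g2)) * Inf
      return(list(test_name = "t", statistic = tstat,
                  p = if (tstat == 0) 1 else 0))
    }
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    return(list(test_name = "t", statistic = unname(tt$statistic),
                p = tt$p.value))
  }
  wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                            correct = TRUE))
  list(test_name = "mann-whitney", statistic = unname(wt$statistic),
       p = wt$p.value)
}

#' Write a per-marker ROC table
#'
#' @param rocs named list of `RocResult` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_roc_table <- function(rocs, path) {
  out <- do.call(rbind, lapply(names(rocs), function(id) {
    r <- rocs[[id]]
    data.frame(mirna_id = id, auc = sprintf("%.6g", r$auc),
               ci_low = sprintf("%.6g", r$ci95[1]),
               ci_high = sprintf("%.6g", r$ci95[2]),
               p_value = sprintf("%.6g", r$p_value),
               cutoff = sprintf("%.6g", r$cutoff),
               sensitivity = sprintf("%.6g", r$sensitivity),
               specificity = sprintf("%.6g", r$specificity),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-marker logistic regression table
#'
#' @param logits named list (marker) of named lists (contrast) of
#'   `LogitResult` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_logit_table <- function(logits, path) {
  rows <- list()
  for (id in names(logits)) for (ctr in names(logits[[id]])) {
    r <- logits[[id]][[ctr]]
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_id = id, contrast = ctr,
      odds_ratio = sprintf("%.6g", r$odds_ratio),
      ci_low = sprintf("%.6g", r$ci95[1]),
      ci_high = sprintf("%.6g", r$ci95[2]),
      p_value = sprintf("%.6g", r$p_value),
      flagged = r$flagged, stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
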