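#' SAM configuration
#'
#' Parameters for the two-class unpaired significance analysis of
#' microarrays: number of balanced label permutations, RNG seed, fudge
#' factor selection, and the signature-calling thresholds (fold change
#' strictly above 8 and q-value below 0.0001% = 1e-6 as a proportion).
#'
#' @param n_permutations number of balanced label permutations (default
#'   1000). When the number of distinct balanced relabelings is no larger,
#'   all of them are enumerated instead.
#' @param seed integer seed for permutation sampling.
#' @param s0_percentile `"auto"` to select the fudge factor by the
#'   coefficient-of-variation criterion, or a fixed percentile in `[0,100]`
#'   of the per-miRNA standard errors.
#' @param fc_min fold-change threshold (strict, case/control on the linear
#'   scale; default 8).
#' @param q_max q-value threshold as a proportion (default 1e-6, i.e.
#'   0.0001%).
#' @return A list of class `SamConfig`.
#' @export
sam_config <- function(n_permutations = 1000, seed = 1L,
                       s0_percentile = "auto", fc_min = 8, q_max = 1e-6) {
  stopifnot(n_permutations >= 1, fc_min > 0, q_max > 0, q_max < 1)
  if (!identical(s0_percentile, "auto"))
    stopifnot(is.numeric(s0_percentile), s0_percentile >= 0,
              s0_percentile <= 100)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), s0_percentile = s0_percentile,
                 fc_min = fc_min, q_max = q_max),
            class = "SamConfig")
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Core two-sample statistic: d_i = (mean_case - mean_control) / (s_i + s0)
# with s_i the pooled standard error sqrt((1/n1 + 1/n2) * SS / (n1+n2-2)).
# Rows with fewer than 2 defined values in either group get NA.
sam_dstat <- function(x, is_case, s0) {
  xc <- x[, is_case, drop = FALSE]
  xk <- x[, !is_case, drop = FALSE]
  n1 <- rowSums(!is.na(xc))
  n2 <- rowSums(!is.na(xk))
  m1 <- rowMeans(xc, na.rm = TRUE)
  m2 <- rowMeans(xk, na.rm = TRUE)
  ss <- rowSums((xc - m1)^2, na.rm = TRUE) + rowSums((xk - m2)^2, na.rm = TRUE)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  num <- m1 - m2
  d <- num / (s + s0)
  d[s + s0 == 0 & num == 0] <- 0       # identical constant groups
  ok <- n1 >= 2 & n2 >= 2
  d[!ok] <- NA_real_
  s[!ok] <- NA_real_
  list(d = d, s = s, mean_case = m1, mean_control = m2, n1 = n1, n2 = n2)
}

#' SAM d statistic
#'
#' Computes the SAM score per miRNA on the log10 expression scale:
#' `d = (mean_case - mean_control) / (s + s0)` where `s` is the pooled
#' standard error of the mean difference. miRNAs with fewer than two
#' defined values in either group get `NA` (excluded from calling).
#'
#' @param x numeric matrix (miRNAs x samples) of log10 expression.
#' @param is_case logical vector over columns; `TRUE` marks the case group.
#' @param s0 fudge factor added to the standard error (>= 0).
#' @return Named numeric vector of d scores.
#' @export
sam_statistic <- function(x, is_case, s0 = 0) {
  stopifnot(is.matrix(x), is.logical(is_case), length(is_case) == ncol(x),
            s0 >= 0)
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("each group needs at least 2 samples")
  st <- sam_dstat(x, is_case, s0)
  if (all(is.na(st$d)))
    stop("no miRNA has >= 2 defined values in both groups")
  stats::setNames(st$d, rownames(x))
}

#' Choose the SAM fudge factor s0
#'
#' Evaluates candidate values of s0 at the percentiles 0, 5, ..., 100 of
#' the per-miRNA standard errors and returns the candidate minimizing the
#' coefficient of variation of the median absolute deviation of d within
#' standard-error quantile windows. This stabilizes d for low-variance
#' miRNAs, which otherwise dominate the extremes of the score
#' distribution. Deterministic; ties break toward the smaller candidate.
#'
#' @param x numeric matrix (miRNAs x samples) of log10 expression.
#' @param is_case logical vector over columns.
#' @param n_windows number of standard-error quantile windows (default 10).
#' @return The selected s0 (numeric scalar) with attribute `percentile`.
#' @export
choose_s0 <- function(x, is_case, n_windows = 10L) {
  st <- sam_dstat(x, is_case, 0)
  ok <- !is.na(st$d) & !is.na(st$s)
  if (sum(ok) < 20L)
    stop("too few features: need >= 20 miRNAs with a defined d score, got ",
         sum(ok))
  s <- st$s[ok]
  num <- (st$mean_case - st$mean_control)[ok]
  if (diff(range(s)) < .Machine$double.eps^0.5 * max(1, max(s))) {
    message("choose_s0: all standard errors equal; using s0 = 0")
    return(structure(0, percentile = NA_real_))
  }
  pcts <- seq(0, 100, by = 5)
  cand <- as.numeric(stats::quantile(s, pcts / 100, names = FALSE))
  breaks <- unique(stats::quantile(s, seq(0, 1, length.out = n_windows + 1L),
                                   names = FALSE))
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    da <- num / (s + a)
    mads <- tapply(da, win, stats::mad)
    mads <- mads[!is.na(mads)]
    mu <- mean(mads)
    if (mu == 0) return(Inf)
    stats::sd(mads) / mu
  }, numeric(1))
  best <- which.min(cv)    # ties resolve to the smallest candidate
  structure(cand[best], percentile = pcts[best])
}

# All or a seeded without-replacement sample of balanced relabelings:
# each relabeling is the index set of columns assigned the case label.
balanced_relabelings <- function(n, n1, n_permutations, seed) {
  total <- choose(n, n1)
  if (total <= n_permutations) {
    sets <- utils::combn(n, n1, simplify = FALSE)
    return(list(sets = sets, exhaustive = TRUE))
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    sets <- vector("list", n_permutations)
    k <- 0L
    while (k < n_permutations) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        k <- k + 1L
        sets[[k]] <- cand
      }
    }
    list(sets = sets, exhaustive = FALSE)
  })
}

#' Permutation null distribution of the SAM statistic
#'
#' For each balanced relabeling of the samples (all of them when there are
#' no more than `cfg$n_permutations`, otherwise a seeded sample drawn
#' without replacement), recomputes the d scores with the same s0 and
#' stores them sorted. The elementwise mean of the sorted null scores is
#' the expected order statistic vector used in SAM diagnostic plots.
#'
#' @param x numeric matrix (miRNAs x samples) of log10 expression.
#' @param is_case logical vector over columns.
#' @param cfg a [sam_config()].
#' @param s0 fudge factor (as used for the observed scores).
#' @return A list of class `SamNull`: `null_d` (permutations x miRNAs,
#'   each row sorted ascending, `NA` last), `expected_order_stats`,
#'   `n_permutations_used`, `exhaustive`.
#' @export
permutation_null <- function(x, is_case, cfg = sam_config(), s0 = 0) {
  stopifnot(is.matrix(x), is.logical(is_case), length(is_case) == ncol(x))
  n <- ncol(x)
  n1 <- sum(is_case)
  rel <- balanced_relabelings(n, n1, cfg$n_permutations, cfg$seed)
  p <- nrow(x)
  null_d <- matrix(NA_real_, nrow = length(rel$sets), ncol = p)
  for (b in seq_along(rel$sets)) {
    ic <- seq_len(n) %in% rel$sets[[b]]
    null_d[b, ] <- sort(sam_dstat(x, ic, s0)$d, na.last = TRUE)
  }
  eos <- colMeans(null_d, na.rm = TRUE)
  eos[is.nan(eos)] <- NA_real_
  structure(list(null_d = null_d, expected_order_stats = eos,
                 n_permutations_used = length(rel$sets),
                 exhaustive = rel$exhaustive),
            class = "SamNull")
}

#' Permutation q-values for SAM scores
#'
#' For each candidate threshold (each observed absolute score), the false
#' discovery rate is `pi0 * median_b #\{|d_null,b| >= t\} / #\{|d_obs| >= t\}`,
#' where `pi0` is estimated as the fraction of observed scores falling
#' inside the interquartile range of the null scores divided by 0.5
#' (capped at 1). The q-value of a miRNA is the minimum FDR over all
#' thresholds at which it would be called, which makes q monotone
#' non-increasing in `|d|` by construction; values are clipped to `[0,1]`.
#'
#' @param d named vector of observed scores (`NA` allowed).
#' @param null a `SamNull` from [permutation_null()].
#' @return Numeric vector of q-values aligned with `d` (`NA` where d is
#'   `NA`), with attribute `pi0`.
#' @export
sam_qvalues <- function(d, null) {
  stopifnot(inherits(null, "SamNull"))
  all_null <- null$null_d[!is.na(null$null_d)]
  qs <- stats::quantile(all_null, c(0.25, 0.75), names = FALSE)
  def <- !is.na(d)
  pi0 <- min(1, mean(d[def] >= qs[1] & d[def] <= qs[2]) / 0.5)
  q <- rep(NA_real_, length(d))
  if (!any(def)) return(structure(q, pi0 = pi0))
  abs_obs <- abs(d[def])
  ord <- order(abs_obs)                       # thresholds ascending
  thr <- abs_obs[ord]
  n_def <- sum(def)
  obs_ge <- n_def + 1L - rank(thr, ties.method = "min")  # #{|d_obs| >= t}
  B <- nrow(null$null_d)
  cnt <- matrix(0L, nrow = B, ncol = length(thr))
  for (b in seq_len(B)) {
    row <- sort(abs(null$null_d[b, !is.na(null$null_d[b, ])]))
    cnt[b, ] <- length(row) - findInterval(thr, row, left.open = TRUE)
  }
  med_null <- apply(cnt, 2L, stats::median)
  fdr <- pi0 * med_null / obs_ge
  qv <- cummin(fdr)                 # min over thresholds <= |d_i|
  qv <- pmin(pmax(qv, 0), 1)
  q[def][ord] <- qv
  structure(q, pi0 = pi0)
}

#' Group fold changes on the linear expression scale
#'
#' `FC_i = mean_case(expr_i) / mean_control(expr_i)` using the linear
#' `2^-dCt` values and pairwise-available samples. An undefined or zero
#' control mean yields a missing fold change (excluded from selection).
#'
#' @param expr numeric matrix (miRNAs x samples) of linear expression, or
#'   an `ExpressionMatrix`.
#' @param is_case logical vector over columns.
#' @param method `"mean_ratio"` (ratio of arithmetic group means, default)
#'   or `"geometric"` (2 to the difference of group mean log2 values).
#' @return Named numeric vector of fold changes.
#' @export
fold_changes <- function(expr, is_case, method = c("mean_ratio", "geometric")) {
  method <- match.arg(method)
  m <- if (inherits(expr, "ExpressionMatrix")) expr$expr else expr
  stopifnot(is.matrix(m), length(is_case) == ncol(m))
  if (method == "mean_ratio") {
    mc <- rowMeans(m[, is_case, drop = FALSE], na.rm = TRUE)
    mk <- rowMeans(m[, !is_case, drop = FALSE], na.rm = TRUE)
    fc <- mc / mk
    bad <- is.na(mk) | is.nan(mk) | mk <= 0 | is.nan(mc)
  } else {
    l2 <- log2(m)
    mc <- rowMeans(l2[, is_case, drop = FALSE], na.rm = TRUE)
    mk <- rowMeans(l2[, !is_case, drop = FALSE], na.rm = TRUE)
    fc <- 2^(mc - mk)
    bad <- is.nan(mc) | is.nan(mk)
  }
  if (any(bad)) {
    message("fold_changes: ", sum(bad),
            " miRNA(s) with undefined group mean; fold change set missing")
    fc[bad] <- NA_real_
  }
  stats::setNames(fc, rownames(m))
}

#' Full SAM analysis of an expression matrix
#'
#' Runs the complete two-class unpaired SAM: fudge-factor selection,
#' observed d scores on the log10 scale, balanced permutation null,
#' q-values, and linear-scale fold changes.
#'
#' @param expr an `ExpressionMatrix` (log10 view filled automatically).
#' @param groups factor/character vector over samples.
#' @param case,control group labels defining the contrast (defaults
#'   `"UA"` vs `"CONTROL"`). Samples in other groups are ignored.
#' @param cfg a [sam_config()].
#' @return A data frame of class `SamResult` with columns `mirna_id`, `d`,
#'   `s`, `mean_case`, `mean_control`, `fold_change`, `q_value`; attributes
#'   `s0`, `pi0`, `expected_order_stats`, `cfg`, `case`, `control`.
#' @export
sam_analysis <- function(expr, groups, case = "UA", control = "CONTROL",
                         cfg = sam_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(expr$log10_expr)) expr <- log_transform(expr)
  groups <- as.character(groups)
  stopifnot(length(groups) == length(expr$sample_ids))
  use <- groups %in% c(case, control)
  if (sum(groups == case) < 2L || sum(groups == control) < 2L)
    stop("need at least 2 samples in each of '", case, "' and '", control, "'")
  x <- expr$log10_expr[, use, drop = FALSE]
  lin <- expr$expr[, use, drop = FALSE]
  is_case <- groups[use] == case
  s0 <- if (identical(cfg$s0_percentile, "auto")) {
    as.numeric(choose_s0(x, is_case))
  } else {
    st0 <- sam_dstat(x, is_case, 0)
    as.numeric(stats::quantile(st0$s[!is.na(st0$s)],
                               cfg$s0_percentile / 100, names = FALSE))
  }
  st <- sam_dstat(x, is_case, s0)
  if (all(is.na(st$d)))
    stop("no miRNA has >= 2 defined values in both groups")
  null <- permutation_null(x, is_case, cfg, s0)
  q <- sam_qvalues(st$d, null)
  fc <- fold_changes(lin, is_case)
  res <- data.frame(mirna_id = rownames(x), d = st$d, s = st$s,
                    mean_case = st$mean_case, mean_control = st$mean_control,
                    fold_change = fc, q_value = as.numeric(q),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "s0") <- s0
  attr(res, "pi0") <- attr(q, "pi0")
  attr(res, "expected_order_stats") <- null$expected_order_stats
  attr(res, "cfg") <- cfg
  attr(res, "case") <- case
  attr(res, "control") <- control
  class(res) <- c("SamResult", "data.frame")
  res
}

#' Select the deregulated miRNA signature
#'
#' Applies the signature calling rule: fold change strictly above `fc_min`
#' (or strictly below `1/fc_min` for downregulation) and q-value strictly
#' below `q_max`. The result is ordered by decreasing `|d|` and carries an
#' up/down direction flag.
#'
#' @param sam a `SamResult` from [sam_analysis()].
#' @param cfg a [sam_config()] supplying `fc_min` and `q_max`; defaults to
#'   the configuration stored in `sam`.
#' @return A data frame of class `DeregulatedSet` (subset of `sam` plus a
#'   `direction` column).
#' @export
select_signature <- function(sam, cfg = attr(sam, "cfg")) {
  stopifnot(inherits(sam, "SamResult"))
  if (is.null(cfg)) cfg <- sam_config()
  ok <- !is.na(sam$fold_change) & !is.na(sam$q_value) &
    (sam$fold_change > cfg$fc_min | sam$fold_change < 1 / cfg$fc_min) &
    sam$q_value < cfg$q_max
  sel <- sam[ok, , drop = FALSE]
  sel$direction <- ifelse(sel$fold_change > 1, "up", "down")
  sel <- sel[order(-abs(sel$d)), , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("DeregulatedSet", "data.frame")
  sel
}

#' Write a SAM result as a deregulated-miRNA table
#'
#' Columns: `mirna_id`, `score` (d), `fold_change`, `q_value_percent`
#' (q-value as a percentage), the layout such tables are usually
#' reported in.
#'
#' @param sam a `SamResult` or `DeregulatedSet`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sam_table <- function(sam, path) {
  out <- data.frame(mirna_id = sam$mirna_id,
                    score = sprintf("%.6g", sam$d),
                    fold_change = sprintf("%.6g", sam$fold_change),
                    q_value_percent = sprintf("%.6g", sam$q_value * 100),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
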