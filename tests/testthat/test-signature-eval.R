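test_that("hierarchical clustering separates duplicated sample blocks and ignores input order", {
  set.seed(21)
  base <- matrix(rnorm(20 * 4), nrow = 20,
                 dimnames = list(paste0("m", 1:20), NULL))
  x <- cbind(base + 10, base)   # two well-separated blocks of 4
  colnames(x) <- paste0("S", 1:8)
  hc <- hierarchical_cluster(x)
  top <- stats::cutree(hc$samples, k = 2)
  expect_equal(length(unique(top[1:4])), 1L)
  expect_equal(length(unique(top[5:8])), 1L)
  expect_false(top[1] == top[5])
  perm <- sample(8)
  hc2 <- hierarchical_cluster(x[, perm])
  d1 <- as.matrix(stats::cophenetic(hc$samples))
  d2 <- as.matrix(stats::cophenetic(hc2$samples))[colnames(x), colnames(x)]
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_error(hierarchical_cluster(matrix(1, 3, 4,
                                           dimnames = list(letters[1:3],
                                                           LETTERS[1:4]))),
               "zero variance")
})

test_that("average-linkage clustering on 4 one-dimensional points merges the close pairs first", {
  x <- matrix(c(0, 0.1, 10, 10.1), nrow = 1,
              dimnames = list("m1", c("A", "B", "C", "D")))
  x <- rbind(x, x)   # two identical features so variance is defined
  rownames(x) <- c("m1", "m2")
  hc <- hierarchical_cluster(x)$samples
  # first two merges join {A,B} and {C,D} (tied heights, either order)
  first_two <- list(sort(abs(hc$merge[1, ])), sort(abs(hc$merge[2, ])))
  expect_true(any(vapply(first_two, function(p) all(p == c(1, 2)),
                         logical(1))))
  expect_true(any(vapply(first_two, function(p) all(p == c(3, 4)),
                         logical(1))))
})

test_that("PCA reduction: rank-1 data, variance bookkeeping, duplicated samples", {
  set.seed(22)
  direction <- rnorm(15)
  t_par <- rnorm(6)
  x <- outer(direction, t_par)           # all samples on one line
  dimnames(x) <- list(paste0("m", 1:15), paste0("S", 1:6))
  pc <- pca_reduce(x, k = 2)
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-10)
  expect_equal(colMeans(pc$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-10)
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  y <- matrix(rnorm(15 * 6), nrow = 15,
              dimnames = list(paste0("m", 1:15), paste0("S", 1:6)))
  y2 <- cbind(y, dup = y[, 3])
  pc2 <- pca_reduce(y2, k = 3)
  expect_equal(unname(pc2$scores["S3", ]), unname(pc2$scores["dup", ]),
               tolerance = 1e-10)
  expect_error(pca_reduce(y, k = 10), "exceeds")
})

test_that("leave-one-out centroid classification is perfect on separated clouds and ~chance on nulls", {
  set.seed(23)
  x <- matrix(rnorm(30 * 20), nrow = 30,
              dimnames = list(paste0("m", 1:30), paste0("S", 1:20)))
  grp <- rep(c("UA", "CONTROL"), each = 10)
  x[, grp == "UA"] <- x[, grp == "UA"] + 5   # 5-SD separation per feature
  pc <- pca_reduce(x, k = 3)
  cls <- pca_classify(pc, grp)
  expect_equal(cls$overall_rate, 1)
  expect_equal(cls$per_group$correct, c(10L, 10L))
  # shuffled labels on symmetric data: near-chance over repeats
  y <- matrix(rnorm(30 * 20), nrow = 30,
              dimnames = list(paste0("m", 1:30), paste0("S", 1:20)))
  pcy <- pca_reduce(y, k = 3)
  rates <- replicate(40, pca_classify(pcy, sample(grp))$overall_rate)
  expect_lt(abs(mean(rates) - 0.5), 0.15)
  expect_error(pca_classify(pc, c("UA", rep("CONTROL", 19))),
               ">= 2 samples")
})

test_that("AUC equals the exhaustive concordant-pair count on small inputs, with ties", {
  set.seed(24)
  for (rep_i in 1:30) {
    n <- sample(4:8, 1)
    n1 <- sample(2:(n - 2), 1)
    vals <- sample(seq(0, 2, by = 0.5), n, replace = TRUE)  # forces ties
    is_case <- seq_len(n) %in% sample(n, n1)
    if (length(unique(vals)) == 1L) next
    r <- roc_analysis(vals, is_case)
    expect_equal(r$auc, brute_force_auc(vals, is_case), tolerance = 1e-12)
  }
})

test_that("ROC known cases: perfect separation, the 3/4-concordant example, label swap", {
  r <- roc_analysis(c(4, 5, 6, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$cutoff, 3); expect_lt(r$cutoff, 4)
  r2 <- roc_analysis(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)
  r3 <- roc_analysis(c(2, 4, 1, 3), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r3$auc, 1 - r2$auc)
  expect_true(r2$ci95[1] <= r2$auc && r2$auc <= r2$ci95[2])
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(25)
  vals <- rnorm(20)
  is_case <- rep(c(TRUE, FALSE), 10)
  a1 <- roc_analysis(vals, is_case)$auc
  a2 <- roc_analysis(exp(vals), is_case)$auc
  a3 <- roc_analysis(vals^3, is_case)$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  vals <- rnorm(40)
  is_case <- rep(c(TRUE, FALSE), each = 20)
  vals[is_case] <- vals[is_case] + 1
  ours <- roc_analysis(vals, is_case)
  ref <- pROC::roc(response = is_case, predictor = vals, quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("constant marker values degrade to AUC 0.5 with a warning", {
  expect_warning(r <- roc_analysis(rep(1, 6), rep(c(TRUE, FALSE), 3)),
                 "constant")
  expect_equal(r$auc, 0.5)
  expect_true(is.na(r$cutoff))
})

test_that("logistic regression reproduces the 2x2 cross-product odds ratio", {
  # exposed/outcome counts 10/10 vs 5/15 -> OR = (10*15)/(5*10) = 3
  xb <- c(rep(1, 20), rep(0, 20))
  y <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 15))
  fit <- logistic_adjusted(xb, y)
  expect_equal(fit$odds_ratio, 3, tolerance = 1e-6)
  expect_false(fit$flagged)
  expect_true(fit$ci95[1] <= fit$odds_ratio &&
                fit$odds_ratio <= fit$ci95[2])
})

test_that("an orthogonal covariate leaves the marker odds ratio unchanged", {
  set.seed(27)
  x <- rnorm(200)
  y <- runif(200) < stats::plogis(0.8 * x)
  z <- rnorm(200)                      # independent of both
  f0 <- logistic_adjusted(x, y)
  f1 <- logistic_adjusted(x, y, data.frame(z = z))
  expect_equal(f1$coef, f0$coef, tolerance = 0.05)
})

test_that("degenerate logistic inputs are flagged, missing covariates are errors", {
  y <- rep(c(TRUE, FALSE), 10)
  expect_true(logistic_adjusted(rep(1, 20), y)$flagged)
  sep <- logistic_adjusted(c(rep(1, 10), rep(0, 10)),
                           c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_true(sep$flagged)
  expect_true(is.infinite(sep$odds_ratio))
  expect_error(logistic_adjusted(rnorm(20), y,
                                 data.frame(age = c(NA, rnorm(19)))),
               "age")
})

test_that("categorical group comparison matches the closed-form chi-squared and published p-values", {
  tab <- matrix(c(5, 8, 7, 6), nrow = 2, byrow = TRUE)
  res <- group_compare(tab, kind = "categorical")
  expect_equal(res$test_name, "chisq")
  a <- 5; b <- 8; cc <- 7; d <- 6; n <- 26
  closed <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(res$statistic, closed, tolerance = 1e-12)
  expect_equal(res$p, 0.431, tolerance = 2e-3)   # printed 3-decimal precision
  # low expected counts switch to Fisher's exact test
  tab2 <- matrix(c(1, 12, 3, 10), nrow = 2, byrow = TRUE)
  res2 <- group_compare(tab2, kind = "categorical")
  expect_equal(res2$test_name, "fisher")
  expect_equal(res2$p, 0.593, tolerance = 2e-3)
})

test_that("continuous comparison gates on normality and handles identical samples", {
  res <- group_compare(c(1, 1, 1, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  set.seed(28)
  norm_res <- group_compare(c(rnorm(15), rnorm(15) + 1),
                            rep(c("a", "b"), each = 15))
  expect_equal(norm_res$test_name, "t")
  skewed <- c(rexp(15)^3, rexp(15)^3 + 2)
  skew_res <- group_compare(skewed, rep(c("a", "b"), each = 15))
  expect_equal(skew_res$test_name, "mann-whitney")
})
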