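test_that("d statistic matches the pooled-standard-error formula", {
  x <- rbind(m1 = c(1, 2, 3, 3, 4, 5))
  is_case <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  d <- sam_statistic(x, is_case, s0 = 0)
  # case (1,2,3) vs control (3,4,5): s = sqrt((2/3)*(4/4)), d = -2/s
  expect_equal(unname(d), -2.4494897, tolerance = 1e-6)
})

test_that("d is symmetric, antisymmetric under label swap, and shift-invariant", {
  set.seed(4)
  x <- matrix(rnorm(25 * 10), nrow = 25,
              dimnames = list(paste0("m", 1:25), NULL))
  is_case <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(unname(sam_statistic(cbind(x[, 1:5], x[, 1:5]), is_case)),
               rep(0, 25))                               # identical groups
  d1 <- sam_statistic(x, is_case, s0 = 0.1)
  d2 <- sam_statistic(x, !is_case, s0 = 0.1)
  expect_equal(d1, -d2)                                  # antisymmetry
  d3 <- sam_statistic(x + 7, is_case, s0 = 0.1)
  expect_equal(d1, d3, tolerance = 1e-10)                # location shift
})

test_that("miRNAs with fewer than 2 defined values per group are excluded", {
  x <- rbind(m1 = c(1, NA, NA, 4, 5, 6), m2 = 1:6)
  is_case <- rep(c(TRUE, FALSE), each = 3)
  d <- sam_statistic(x, is_case)
  expect_true(is.na(d["m1"]))
  expect_false(is.na(d["m2"]))
  x_all_bad <- rbind(m1 = c(1, NA, NA, 4, 5, 6))
  expect_error(sam_statistic(x_all_bad, is_case), "no miRNA")
})

test_that("choose_s0 is deterministic, needs enough features, and handles degenerate spread", {
  set.seed(11)
  x <- matrix(rnorm(50 * 12), nrow = 50,
              dimnames = list(paste0("m", 1:50), NULL))
  is_case <- rep(c(TRUE, FALSE), each = 6)
  s0a <- choose_s0(x, is_case)
  s0b <- choose_s0(x, is_case)
  expect_identical(s0a, s0b)
  expect_gte(as.numeric(s0a), 0)
  expect_error(choose_s0(x[1:10, ], is_case), "too few features")
  # all rows identical up to location: equal standard errors -> s0 = 0
  xc <- matrix(rep(c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4, 5, 6), each = 25),
               nrow = 25, byrow = FALSE)
  xc <- sweep(xc, 1L, seq_len(25), `+`)
  rownames(xc) <- paste0("m", 1:25)
  expect_message(s0c <- choose_s0(xc, is_case), "s0 = 0")
  expect_equal(as.numeric(s0c), 0)
})

test_that("permutation null enumerates all balanced relabelings at small n", {
  set.seed(2)
  x <- matrix(rnorm(30 * 6), nrow = 30,
              dimnames = list(paste0("m", 1:30), NULL))
  is_case <- rep(c(TRUE, FALSE), each = 3)
  null1 <- permutation_null(x, is_case, sam_config(n_permutations = 1000,
                                                   seed = 1), s0 = 0.05)
  null2 <- permutation_null(x, is_case, sam_config(n_permutations = 20,
                                                   seed = 99), s0 = 0.05)
  expect_true(null1$exhaustive)
  expect_equal(null1$n_permutations_used, choose(6, 3))
  # exhaustive result is seed-independent and equals the brute-force oracle
  expect_identical(null1$null_d, null2$null_d)
  oracle <- brute_force_null(x, 3, 0.05)
  expect_equal(null1$null_d, oracle, tolerance = 1e-12)
  expect_equal(null1$expected_order_stats, colMeans(oracle),
               tolerance = 1e-12)
})

test_that("sampled permutation null is reproducible and distinct per relabeling", {
  set.seed(5)
  x <- matrix(rnorm(40 * 20), nrow = 40,
              dimnames = list(paste0("m", 1:40), NULL))
  is_case <- rep(c(TRUE, FALSE), each = 10)
  cfg <- sam_config(n_permutations = 50, seed = 7)
  n1 <- permutation_null(x, is_case, cfg, s0 = 0)
  n2 <- permutation_null(x, is_case, cfg, s0 = 0)
  expect_identical(n1$null_d, n2$null_d)
  expect_false(n1$exhaustive)
  expect_equal(nrow(unique(as.data.frame(n1$null_d))), 50L)
})

test_that("null data give sorted d close to the expected order statistics", {
  set.seed(31)
  x <- matrix(rnorm(100 * 12), nrow = 100,
              dimnames = list(paste0("m", 1:100), NULL))
  is_case <- rep(c(TRUE, FALSE), each = 6)
  null <- permutation_null(x, is_case, sam_config(n_permutations = 300,
                                                  seed = 2), s0 = 0)
  d_obs <- sort(sam_statistic(x, is_case, 0))
  expect_lt(mean(abs(d_obs - null$expected_order_stats)), 0.35)
})

test_that("q-values: zero null exceedance gives q = 0, ties share q, monotone in |d|", {
  set.seed(8)
  x <- matrix(rnorm(30 * 10, sd = 0.2), nrow = 30,
              dimnames = list(paste0("m", 1:30), NULL))
  is_case <- rep(c(TRUE, FALSE), each = 5)
  x[1, is_case] <- x[1, is_case] + 50    # overwhelming separation
  d <- sam_statistic(x, is_case, 0.05)
  null <- permutation_null(x, is_case, sam_config(n_permutations = 200,
                                                  seed = 3), s0 = 0.05)
  q <- sam_qvalues(d, null)
  expect_equal(as.numeric(q[1]), 0)
  ord <- order(abs(d))
  expect_true(all(diff(as.numeric(q[ord])) <= 1e-12))
  # duplicated feature row -> identical |d| -> identical q
  x2 <- rbind(x, dup = x[1, ])
  d2 <- sam_statistic(x2, is_case, 0.05)
  null2 <- permutation_null(x2, is_case, sam_config(n_permutations = 200,
                                                    seed = 3), s0 = 0.05)
  q2 <- sam_qvalues(d2, null2)
  expect_equal(as.numeric(q2[1]), as.numeric(q2[31]))
})

test_that("label-permuted data yield mostly large q-values", {
  set.seed(12)
  x <- matrix(rnorm(150 * 12), nrow = 150,
              dimnames = list(paste0("m", 1:150), NULL))
  is_case <- rep(c(TRUE, FALSE), each = 6)
  d <- sam_statistic(x, is_case, 0.05)
  null <- permutation_null(x, is_case, sam_config(n_permutations = 200,
                                                  seed = 4), s0 = 0.05)
  q <- sam_qvalues(d, null)
  expect_gt(stats::median(q, na.rm = TRUE), 0.5)
})

test_that("fold changes are linear-scale mean ratios, scale invariant", {
  expr <- rbind(m1 = c(0.4, 0.4, 0.02, 0.02),
                m2 = c(0.1, 0.1, 0.1, 0.1))
  is_case <- c(TRUE, TRUE, FALSE, FALSE)
  fc <- fold_changes(expr, is_case)
  expect_equal(unname(fc), c(20, 1))
  expect_equal(fold_changes(expr * 10, is_case), fc)
})

test_that("signature selection is a strict conjunction of fold-change and q thresholds", {
  sam <- data.frame(mirna_id = c("a", "b", "c", "d"),
                    d = c(2.9, 2.0, 3.0, -3.5),
                    s = 1, mean_case = 1, mean_control = 1,
                    fold_change = c(24.2, 7.9, 20, 1 / 9),
                    q_value = c(0, 0, 0.01, 0))
  class(sam) <- c("SamResult", "data.frame")
  sel <- select_signature(sam, sam_config(fc_min = 8, q_max = 1e-6))
  expect_equal(sel$mirna_id, c("d", "a"))   # ordered by |d| descending
  expect_equal(sel$direction, c("down", "up"))
  # b fails the strict >8-fold rule; c fails the q threshold
  expect_false(any(c("b", "c") %in% sel$mirna_id))
})
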