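test_that("pairwise Pearson r and p match the t transform", {
  x13 <- seq_len(13)
  x <- rbind(a = x13, b = 2 * x13 + 1,                 # exact line
             c = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11, 14))
  colnames(x) <- paste0("S", 1:13)
  pp <- pairwise_pearson(x)
  expect_equal(pp$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(pp$p["a", "b"], 0)
  # analytic check of the p transform at the published edge threshold
  r <- 0.79; m <- 13
  tt <- r * sqrt((m - 2) / (1 - r^2))
  expect_equal(tt, 4.2735, tolerance = 1e-4)
  expect_equal(2 * pt(-tt, m - 2), 1.3129e-3, tolerance = 1e-3)
  # matches cor.test on a non-trivial pair
  ct <- cor.test(x["a", ], x["c", ])
  expect_equal(pp$r["a", "c"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pp$p["a", "c"], ct$p.value, tolerance = 1e-10)
})

test_that("constant rows and tiny groups are handled", {
  x <- rbind(a = rep(1, 5), b = rnorm(5))
  colnames(x) <- paste0("S", 1:5)
  pp <- pairwise_pearson(x)
  expect_true(is.na(pp$r["a", "b"]))
  expect_error(pairwise_pearson(x[, 1:2]), "at least 3 samples")
})

test_that("network construction applies r >= threshold AND p < threshold, positive only", {
  r <- matrix(c(NA, 0.79, -0.95, 0.79, NA, 0.95, -0.95, 0.95, NA), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- matrix(c(NA, 0.001, 1e-5, 0.001, NA, 0.03, 1e-5, 0.03, NA), 3,
              dimnames = dimnames(r))
  net <- build_network(r, p, r_min = 0.79, p_max = 0.02)
  expect_equal(nrow(net$edges), 1L)              # a-b kept: r at 0.79 inclusive
  expect_equal(net$edges$source, "a")
  expect_equal(net$edges$target, "b")            # b-c fails p; a-c negative r
  expect_equal(net$nodes, c("a", "b"))           # only degree >= 1 endpoints
  net_abs <- build_network(r, p, r_min = 0.79, p_max = 0.02, use_abs = TRUE)
  expect_equal(nrow(net_abs$edges), 2L)          # a-c enters with |r|
})

test_that("network construction is monotone in both thresholds", {
  set.seed(41)
  x <- matrix(rnorm(20 * 13), nrow = 20,
              dimnames = list(paste0("m", 1:20), paste0("S", 1:13)))
  x[1:8, ] <- 0.9 * matrix(rep(rnorm(13), each = 8), nrow = 8) +
    0.45 * x[1:8, ]
  pp <- pairwise_pearson(x)
  grid_r <- c(0.4, 0.6, 0.79, 0.9)
  grid_p <- c(0.001, 0.02, 0.2)
  for (i in seq_along(grid_r)[-1]) for (j in seq_along(grid_p)) {
    e_tight <- circmir:::edge_keys(build_network(pp$r, pp$p, grid_r[i], grid_p[j]))
    e_loose <- circmir:::edge_keys(build_network(pp$r, pp$p, grid_r[i - 1], grid_p[j]))
    expect_true(all(e_tight %in% e_loose))
  }
  for (i in seq_along(grid_r)) for (j in seq_along(grid_p)[-1]) {
    e_tight <- circmir:::edge_keys(build_network(pp$r, pp$p, grid_r[i], grid_p[j - 1]))
    e_loose <- circmir:::edge_keys(build_network(pp$r, pp$p, grid_r[i], grid_p[j]))
    expect_true(all(e_tight %in% e_loose))
  }
})

make_net <- function(edges) {
  # edges: list of c(source, target) pairs
  df <- do.call(rbind, lapply(edges, function(e)
    data.frame(source = min(e), target = max(e), r = 0.9, p = 0.001,
               stringsAsFactors = FALSE)))
  df <- df[order(df$source, df$target), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(group = NA_character_,
                 nodes = sort(unique(c(df$source, df$target))),
                 edges = df), class = "CoexNetwork")
}

test_that("first-neighbor subnetwork: path induction, identity, idempotence", {
  net <- make_net(list(c("a", "b"), c("b", "c")))
  sub <- first_neighbor_subnetwork(net, "a")
  expect_equal(sub$nodes, c("a", "b"))          # c is a second neighbor
  expect_equal(nrow(sub$edges), 1L)             # b-c not induced
  all_sub <- first_neighbor_subnetwork(net, net$nodes)
  expect_equal(all_sub$edges, net$edges)
  again <- first_neighbor_subnetwork(sub, sub$nodes)
  expect_equal(again$edges, sub$edges)
  expect_message(none <- first_neighbor_subnetwork(net, c("a", "zzz")),
                 "zzz")
  expect_equal(none$nodes, c("a", "b"))
})

test_that("network comparison performs exact edge-set arithmetic", {
  netA <- make_net(list(c("a", "b"), c("b", "c")))
  netB <- make_net(list(c("b", "c"), c("c", "d")))
  cmp <- compare_networks(netA, netB)
  expect_equal(cmp$shared_edges, "b|c")
  expect_equal(cmp$unique_to_A, "a|b")
  expect_equal(cmp$unique_to_B, "c|d")
  expect_equal(cmp$n_edges_A, cmp$n_shared + cmp$n_unique_A)
  expect_equal(cmp$n_edges_B, cmp$n_shared + cmp$n_unique_B)
  same <- compare_networks(netA, netA)
  expect_equal(same$n_shared, 2L)
  expect_equal(same$n_unique_A, 0L)
  disjoint <- compare_networks(make_net(list(c("a", "b"))),
                               make_net(list(c("x", "y"))))
  expect_equal(disjoint$n_shared, 0L)
})

test_that("exports: SIF rows, GraphML round trip, stable ordering, empty networks", {
  net <- make_net(list(c("b", "c"), c("a", "b")))
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, format = "sif")
  expect_equal(readLines(sif), c("a coexp b", "b coexp c"))
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, format = "graphml")
  back <- read_network_graphml(gml)
  expect_equal(back$edges$source, net$edges$source)
  expect_equal(back$edges$target, net$edges$target)
  expect_equal(back$edges$r, net$edges$r)
  empty <- structure(list(group = NA_character_, nodes = character(),
                          edges = data.frame(source = character(),
                                             target = character(),
                                             r = numeric(), p = numeric())),
                     class = "CoexNetwork")
  sif2 <- tempfile(fileext = ".sif")
  export_network(empty, sif2, format = "sif")
  expect_equal(length(readLines(sif2)), 0L)
  expect_error(export_network(net, tempfile(), format = "xlsx"))
})

test_that("planted correlation blocks are recovered as dense within-block edges", {
  recalls <- vapply(1:5, function(sd_i) {
    spec <- cohort_spec(n_mirnas = 80, n_planted = 0, seed = 100 + sd_i,
                        dropout_center = 60,
                        blocks = list(UA = list(11:25), CONTROL = list()))
    sim <- simulate_cohort(spec)
    expr <- log_transform(normalize_to_reference(sim$ct, "U6"))
    ua <- expr$log10_expr[, as.character(sim$ann$group) == "UA"]
    pp <- pairwise_pearson(ua)
    net <- build_network(pp$r, pp$p, 0.79, 0.02)
    block <- sprintf("mir-%04d", 11:25)
    keys <- circmir:::edge_keys(net)
    within_pairs <- utils::combn(sort(block), 2)
    within_keys <- paste(within_pairs[1, ], within_pairs[2, ], sep = "|")
    mean(within_keys %in% keys)
  }, numeric(1))
  expect_gte(stats::median(recalls), 0.8)
})
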