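test_that("group statistic: median of absolute fold changes", {
  u <- fc_universe(c(-1, 1, 0, 0.3, 0.4))
  expect_equal(group_statistic(u, c("g1", "g2", "g3")), 1)  # |..| = 0,1,1
  expect_equal(group_statistic(u, "g1"), 1)
  expect_equal(group_statistic(u, c("g4", "g5")), 0.35)     # even-n midpoint
  expect_equal(group_statistic(u, c("g1", "g2", "g3"), center = "mean"), 2 / 3)
  expect_error(group_statistic(u, c("g1", "gX", "gY")), "gX, gY")
})

test_that("degenerate groups: whole universe or constant universe give p = 1", {
  u <- fc_universe(c(0.5, -0.2, 1.1, 0.9))
  pr <- permutation_test(u, gene_group("all", names(u)), B = 200, seed = 1)
  expect_equal(pr$p_empirical, 1)
  uc <- fc_universe(rep(0.7, 10))
  pr2 <- permutation_test(uc, gene_group("g", c("g2", "g5")), B = 200, seed = 1)
  expect_equal(pr2$p_empirical, 1)
})

test_that("Monte Carlo p matches the exhaustive enumeration oracle", {
  # all 6 two-gene subsets of |fc| {0.1, 0.2, 0.3, 0.4} have null medians
  # (0.15, 0.2, 0.25, 0.25, 0.3, 0.35); z_true = 0.35 -> exact p = 1/6
  u <- fc_universe(c(0.1, 0.2, 0.3, 0.4))
  ex <- exact_permutation_test(u, gene_group("top", c("g3", "g4")))
  expect_equal(ex$p_exact, 1 / 6)
  expect_equal(ex$n_subsets, 6)
  pr <- permutation_test(u, gene_group("top", c("g3", "g4")),
                         B = 10000, seed = 7)
  expect_lt(abs(pr$p_empirical - 1 / 6), 0.02)

  # single largest-|fc| gene in a k-gene all-distinct universe -> p = 1/k
  u2 <- fc_universe(c(0.3, -0.9, 0.1, 0.5, -0.2, 0.05, 0.7))
  ex2 <- exact_permutation_test(u2, gene_group("max", "g2"))
  expect_equal(ex2$p_exact, 1 / 7)
  expect_error(exact_permutation_test(fc_universe(rnorm(500)),
                                      gene_group("big", paste0("g", 1:10))),
               "1e\\+?06|Monte Carlo|permutation_test")
})

test_that("permutation p is reproducible and seed-sensitive", {
  u <- fc_universe(rnorm(100))
  g <- gene_group("grp", paste0("g", 1:8))
  p1 <- permutation_test(u, g, B = 500, seed = 3)
  p2 <- permutation_test(u, g, B = 500, seed = 3)
  expect_identical(p1$z_null, p2$z_null)
  expect_equal(p1$z_true, group_statistic(u, g$members))
  expect_length(p1$z_null, 500)
  p3 <- permutation_test(u, g, B = 500, seed = 4)
  expect_false(identical(p1$z_null, p3$z_null))
})

test_that("p is invariant under strictly monotone transforms of |log2fc|", {
  set.seed(21)
  vals <- rnorm(60)
  u1 <- fc_universe(vals)
  u2 <- fc_universe(sign(vals) * abs(vals)^1.7)  # monotone on |fc|
  g <- gene_group("grp", paste0("g", c(3, 11, 25, 40, 59)))
  p1 <- permutation_test(u1, g, B = 2000, seed = 5)$p_empirical
  p2 <- permutation_test(u2, g, B = 2000, seed = 5)$p_empirical
  expect_equal(p1, p2)
})

test_that("plus-one estimator has resolution 1/(B+1)", {
  u <- fc_universe(rnorm(30))
  pr <- permutation_test(u, gene_group("g", paste0("g", 1:3)), B = 10, seed = 2)
  expect_true(pr$p_empirical %in% ((1:11) / 11))
  expect_gte(pr$p_empirical, 1 / 11)
  u3 <- fc_universe(rnorm(3))
  expect_error(
    permutation_test(u3, gene_group("g", paste0("g", 1:4)), B = 10, seed = 1),
    "larger than universe")
})

test_that("Monte Carlo stays within 3 binomial SEs of exact p (small scan)", {
  set.seed(31)
  fails <- 0; trials <- 60
  for (i in seq_len(trials)) {
    m <- sample(5:8, 1); n <- sample(2:3, 1)
    u <- fc_universe(rnorm(m))
    g <- gene_group("g", sample(names(u), n))
    ex <- exact_permutation_test(u, g)$p_exact
    pr <- permutation_test(u, g, B = 10000, seed = 1000 + i)
    p_mc <- (pr$p_empirical * (pr$B + 1) - 1) / pr$B  # raw hit fraction
    se <- sqrt(ex * (1 - ex) / pr$B)
    if (abs(p_mc - ex) > 3 * se) fails <- fails + 1
  }
  # scaled-down smoke check; the full 500-instance >= 99% agreement bound is
  # exercised in the acceptance suite
  expect_lte(fails / trials, 0.05)
})

test_that("group panel: order independence, NA rows, missing members", {
  set.seed(41)
  u <- fc_universe(rnorm(200))
  gA <- gene_group("A", paste0("g", 1:10))
  gB <- gene_group("B", paste0("g", 51:70))
  pan1 <- run_group_panel(list(skin = u), list(gA, gB), B = 300, seed = 9)
  pan2 <- run_group_panel(list(skin = u), list(gB, gA), B = 300, seed = 9)
  expect_equal(pan1$p_empirical[pan1$group == "A"],
               pan2$p_empirical[pan2$group == "A"])
  expect_equal(pan1$B, rep(300L, 2), ignore_attr = TRUE)

  gM <- gene_group("mixed", c("g1", "g2", "nope1", "nope2"))
  gE <- gene_group("absent", c("x1", "x2"))
  expect_warning(run_group_panel(list(skin = u), list(gM, gE), B = 100,
                                 seed = 2), "empty")
  pan3 <- suppressWarnings(
    run_group_panel(list(skin = u), list(gM, gE), B = 100, seed = 2))
  expect_equal(pan3$n_missing[pan3$group == "mixed"], 2)
  expect_true(is.na(pan3$p_empirical[pan3$group == "absent"]))
  expect_equal(nrow(pan3), 2)
})

test_that("null calibration: random groups give near-uniform p", {
  set.seed(51)
  u <- fc_universe(rnorm(800))
  ps <- vapply(1:60, function(i) {
    g <- gene_group("r", sample(names(u), 12))
    permutation_test(u, g, B = 2000, seed = 7000 + i)$p_empirical
  }, 0)
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.2)
  expect_lte(mean(ps <= 0.05), 0.15)
})

test_that("literal direction flag reports the complementary proportion", {
  u <- fc_universe(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  g <- gene_group("top", c("g5", "g6"))
  a <- permutation_test(u, g, B = 999, seed = 1)
  b <- permutation_test(u, g, B = 999, seed = 1, literal = TRUE)
  # the two directions count complementary events (ties overlap)
  expect_lt(a$p_empirical, 0.5)
  expect_gt(b$p_empirical, 0.5)
})
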