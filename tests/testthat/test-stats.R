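test_that("t-to-p conversion matches direct density integration", {
  expect_equal(t_two_tailed_p(0, 5), 1)
  for (df in c(1, 3, 9, 25, 80, 200)) {
    tval <- 2.37
    num <- 2 * integrate(function(u) dt(u, df), tval, Inf,
                         rel.tol = 1e-12)$value
    expect_equal(t_two_tailed_p(tval, df), num, tolerance = 1e-8)
  }
  expect_error(t_two_tailed_p(Inf, 4), "non-finite")
  expect_error(t_two_tailed_p(1, 0), "df")
})

test_that("printed figure-legend statistics convert at printed rounding", {
  expect_equal(round(t_two_tailed_p(3.114, 9), 3), 0.012)
  expect_equal(round(t_two_tailed_p(5.977, 5), 4), 0.0019)
  expect_equal(round(t_two_tailed_p(2.868, 25), 4), 0.0083)
  expect_equal(round(t_two_tailed_p(0.1294, 18), 4), 0.8985)
})

test_that("two-sample t test: hand oracle, identity, invariances", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  # pooled variance 1, se = sqrt(2/3), t = -3/se
  tr <- t_test(x, y)
  expect_equal(tr$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tr$df, 4)
  expect_equal(round(tr$statistic, 3), -3.674)

  same <- c(1.2, 3.4, 2.2, 0.9)
  tr2 <- t_test(same, same)
  expect_equal(tr2$statistic, 0)
  expect_equal(tr2$p, 1)

  shift <- t_test(x + 100, y + 100)
  expect_equal(shift$statistic, tr$statistic)
  expect_equal(shift$p, tr$p)

  expect_warning(tr3 <- t_test(c(2, 2, 2), c(2, 2, 2)), "convention")
  expect_equal(tr3$p, 1)
  w <- t_test(c(1, 2, 3, 4), c(10, 30, 50, 90), variant = "welch")
  expect_lt(w$df, 6)  # Satterthwaite df below pooled df
})

test_that("one-way ANOVA: F = t^2 identity, constants, hand SS oracle", {
  x <- c(3.1, 4.5, 2.2, 5.0); y <- c(6.3, 7.1, 5.5, 8.0)
  aw <- anova_one_way(list(a = x, b = y))
  tr <- t_test(x, y)
  expect_equal(aw$statistic, tr$statistic^2, tolerance = 1e-12)
  expect_equal(aw$p, tr$p, tolerance = 1e-12)

  cw <- anova_one_way(list(a = rep(2, 3), b = rep(2, 4)))
  expect_equal(cw$statistic, 0)
  expect_equal(cw$p, 1)

  g <- list(a = c(1, 2, 4), b = c(3, 5), c = c(7, 8, 10, 6))
  y_all <- unlist(g); N <- length(y_all); k <- 3
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - mean(y_all))^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  f_hand <- (ssb / (k - 1)) / (ssw / (N - k))
  aw2 <- anova_one_way(g)
  expect_equal(aw2$statistic, f_hand, tolerance = 1e-10)
  expect_equal(aw2$df, c(k - 1, N - k))
  expect_error(anova_one_way(list(a = 1:3)), ">= 2 groups")
})

test_that("two-way ANOVA: balanced = textbook, empty cells, degeneracy", {
  set.seed(81)
  d <- expand.grid(trt = c("MC903", "EtOH"), day = c("D1", "D5", "D8"),
                   rep = 1:5)
  d$y <- rnorm(nrow(d), 10) + 2 * (d$trt == "MC903") + 0.5 * (d$day == "D8")
  res <- anova_two_way(d, "y", "trt", "day")
  # balanced design: Type III equals sequential Type I
  fit <- lm(y ~ trt * day, d)
  t1 <- anova(fit)
  expect_equal(res$F, t1$`F value`[1:3], tolerance = 1e-10)
  expect_equal(res$p, t1$`Pr(>F)`[1:3], tolerance = 1e-10)
  expect_equal(res$df2, rep(t1$Df[4], 3))

  d_miss <- d[!(d$trt == "MC903" & d$day == "D8"), ]
  expect_error(anova_two_way(d_miss, "y", "trt", "day"), "empty cell")

  d1 <- d[d$day == "D1", ]
  res1 <- anova_two_way(d1, "y", "trt", "day")
  aw <- anova_one_way(split(d1$y, d1$trt))
  expect_equal(res1$F, aw$statistic)
  expect_equal(res1$p, aw$p)
})

test_that("two-way interaction type-I error is calibrated (null simulation)", {
  rej <- vapply(1:150, function(seed) {
    set.seed(9000 + seed)
    d <- expand.grid(trt = c("a", "b"), day = c("x", "y", "z"), rep = 1:4)
    d$y <- rnorm(nrow(d)) + 1 * (d$trt == "a") + 0.5 * (d$day == "y")
    anova_two_way(d, "y", "trt", "day")$p[3] < 0.05
  }, NA)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("post-hoc families: degeneracy, closed forms, dominance", {
  set.seed(83)
  g2 <- list(a = rnorm(6, 0), b = rnorm(6, 1))
  for (fam in c("tukey", "sidak", "holm_sidak")) {
    ph <- posthoc(g2, family = fam)
    expect_equal(ph$p_adjusted, ph$p_raw, tolerance = 1e-6,
                 label = paste("single comparison,", fam))
  }
  expect_equal(sidak_adjust(0.05, m = 2), 1 - 0.95^2)
  expect_equal(sidak_adjust(0.05, m = 2), 0.0975)

  g4 <- list(a = rnorm(5, 0), b = rnorm(5, 0.5), c = rnorm(5, 1),
             d = rnorm(5, 3))
  ps <- posthoc(g4, family = "sidak")
  ph <- posthoc(g4, family = "holm_sidak")
  expect_true(all(ph$p_adjusted <= ps$p_adjusted + 1e-12))
  expect_true(all(ps$p_adjusted >= ps$p_raw - 1e-12))
  tk <- posthoc(g4, family = "tukey")
  expect_equal(nrow(tk), choose(4, 2))
  expect_true(all(tk$p_adjusted >= tk$p_raw - 1e-12))
  expect_error(posthoc(g4, family = "tukey", unequal_variance = TRUE),
               "unequal")
})

test_that("Tukey matches TukeyHSD on the same design", {
  set.seed(84)
  g <- list(a = rnorm(7, 0), b = rnorm(7, 1), c = rnorm(7, 2))
  tk <- posthoc(g, family = "tukey")
  y <- unlist(g); f <- factor(rep(names(g), each = 7))
  ref <- TukeyHSD(aov(y ~ f))$f
  # match comparisons by unordered pair
  ours <- setNames(tk$p_adjusted,
                   vapply(strsplit(tk$comparison, " vs "),
                          function(z) paste(sort(z), collapse = "-"), ""))
  theirs <- setNames(ref[, "p adj"],
                     vapply(strsplit(rownames(ref), "-"),
                            function(z) paste(sort(z), collapse = "-"), ""))
  expect_equal(ours[names(theirs)], theirs, tolerance = 1e-6)
})

test_that("control pooling rule: identical, far apart, symmetric", {
  a <- c(10, 11, 12, 10.5); b <- a
  expect_equal(pooling_check(a, b)$decision, "pooled")
  far <- a + 100  # ~10+ SDs away
  expect_equal(pooling_check(a, far)$decision, "separate")
  set.seed(85)
  u <- rnorm(6); v <- rnorm(6, 0.3)
  expect_equal(pooling_check(u, v)$decision, pooling_check(v, u)$decision)
  expect_equal(pooling_check(u, v)$p, pooling_check(v, u)$p)
  pl <- pooling_check(u, v)
  if (pl$decision == "pooled") expect_length(pl$pooled, 12)
})
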