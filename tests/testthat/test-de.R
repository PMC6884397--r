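test_that("size factors: identity, hand example, equivariance, reorder", {
  cm <- tiny_cm(cbind(c(5, 10, 20), c(5, 10, 20)))
  expect_equal(unname(size_factors(cm)), c(1, 1))

  # per-gene geometric means sqrt(8), sqrt(32), sqrt(72); every column-1
  # ratio is 1/sqrt(2), every column-2 ratio sqrt(2)
  cm2 <- tiny_cm(cbind(c(2, 4, 6), c(4, 8, 12)))
  expect_equal(unname(size_factors(cm2)), c(1 / sqrt(2), sqrt(2)))

  # size factors are defined up to a common scale: multiplying one sample's
  # counts by k multiplies its size factor relative to the others by k
  base <- cbind(a = c(3, 7, 11, 20), b = c(6, 2, 9, 30))
  sf0 <- size_factors(tiny_cm(base))
  scaled <- base; scaled[, 2] <- scaled[, 2] * 5
  sf1 <- size_factors(tiny_cm(scaled))
  expect_equal((sf1[2] / sf1[1]) / (sf0[2] / sf0[1]), 5,
               ignore_attr = TRUE, tolerance = 1e-12)

  perm <- base[c(3, 1, 4, 2), ]
  expect_equal(unname(size_factors(tiny_cm(perm))), unname(sf0))
})

test_that("size factors refuse silent pseudo-reference fallback", {
  cm <- tiny_cm(cbind(c(0, 5), c(4, 0)))
  expect_error(size_factors(cm), "pseudo-reference")
})

test_that("dispersion estimation: floor, Poisson, parameter recovery", {
  set.seed(101)
  # constant gene: identical normalized counts -> floor
  k <- rbind(rep(7, 6), matrix(rpois(60 * 6, 50), ncol = 6))
  cm <- tiny_cm(k, condition = rep(c("MC903", "EtOH"), each = 3))
  d <- estimate_dispersions(cm, setNames(rep(1, 6), cm$sample_meta$sample))
  expect_equal(unname(d[1]), 1e-8)

  s <- simulate_counts(sim_design(n_genes = 2000, de_fraction = 0, seed = 5,
    dispersion_function = function(mu) rep(0, length(mu))))
  dp <- estimate_dispersions(s$counts, size_factors(s$counts))
  expect_lt(median(dp), 0.05)

  s2 <- simulate_counts(sim_design(n_genes = 2000, de_fraction = 0, seed = 5,
    dispersion_function = function(mu) rep(0.2, length(mu))))
  d2 <- estimate_dispersions(s2$counts, size_factors(s2$counts))
  expect_gt(median(d2), 0.1)
  expect_lt(median(d2), 0.4)
})

test_that("Wald test: exact recovery on expectation-valued input", {
  lfc <- c(0, 2, -1.5, 0.75, 0)
  cm <- noiseless_cm(baseline = c(100, 50, 200, 400, 10), lfc = lfc)
  nf <- setNames(rep(1, 6), cm$sample_meta$sample)
  r <- nb_wald_test(cm, nf, rep(0.1, 5))
  expect_equal(r$log2fc, lfc, tolerance = 1e-8)
})

test_that("Wald test: contrast antisymmetry and error on absent label", {
  s <- simulate_counts(sim_design(n_genes = 300, de_fraction = 0.2, seed = 8))
  nf <- size_factors(s$counts)
  dp <- estimate_dispersions(s$counts, nf)
  r1 <- nb_wald_test(s$counts, nf, dp, contrast = c("MC903", "EtOH"))
  r2 <- nb_wald_test(s$counts, nf, dp, contrast = c("EtOH", "MC903"))
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-6)
  expect_equal(r1$p_raw, r2$p_raw, tolerance = 1e-6)
  expect_error(nb_wald_test(s$counts, nf, dp, contrast = c("MC903", "DNFB")),
               "DNFB")
})

test_that("all-zero genes report log2fc 0 and p 1", {
  set.seed(103)
  k <- rbind(rep(0, 8), matrix(rpois(50 * 8, 40), ncol = 8))
  cm <- tiny_cm(k, condition = rep(c("MC903", "EtOH"), each = 4))
  nf <- size_factors(cm)
  r <- nb_wald_test(cm, nf, estimate_dispersions(cm, nf))
  expect_equal(r$log2fc[1], 0)
  expect_equal(r$p_raw[1], 1)
})

test_that("BH adjustment: m = 1, hand example, dominance, NaN", {
  set.seed(102)
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
})

test_that("significant_genes applies the joint adjusted-p/fold rule", {
  r <- structure(data.frame(
    gene = c("A", "B", "C"),
    log2fc = c(1.5, 2.0, 1.001),
    p_raw = c(0.01, 0.02, 0.001),
    p_adjusted = c(0.04, 0.06, 0.04),
    mean_expression = c(10, 10, 10)), class = c("de_result", "data.frame"))
  expect_equal(significant_genes(r, alpha = 0.05, fold_threshold = 2),
               c("A", "C"))
  # boundary of >2 fold: |log2fc| = 1.001 admitted, 0.999 rejected
  r$log2fc <- c(0.999, 2, 1.001)
  expect_equal(significant_genes(r, alpha = 0.05, fold_threshold = 2), "C")
  # degenerate thresholds admit every tested gene
  expect_equal(significant_genes(r, alpha = 1, fold_threshold = 1),
               c("A", "B", "C"))
  # candidate-list intersection and empty-results warning
  expect_equal(significant_genes(r, 0.05, 2, candidate_list = "Z"),
               character(0))
  expect_warning(significant_genes(list(), 0.05), "empty")
})

test_that("DE engine agrees with an independent NB pipeline on shared input", {
  skip_if_not_installed("DESeq2")
  s <- simulate_counts(sim_design(n_genes = 600, de_fraction = 0.2, seed = 13))
  cm <- s$counts
  nf <- size_factors(cm)
  r <- nb_wald_test(cm, nf, estimate_dispersions(cm, nf))

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cm$counts, data.frame(condition = factor(cm$sample_meta$condition,
                                               levels = c("EtOH", "MC903"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    rd <- DESeq2::results(dds, contrast = c("condition", "MC903", "EtOH"))
  })
  expect_equal(unname(size_factors(cm)),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-6)
  keep <- !is.na(rd$log2FoldChange) & !is.na(rd$pvalue) & rowSums(cm$counts) > 0
  expect_gt(cor(r$log2fc[keep], rd$log2FoldChange[keep]), 0.97)
  expect_gt(cor(-log10(r$p_raw[keep] + 1e-12),
                -log10(rd$pvalue[keep] + 1e-12), method = "spearman"), 0.9)
})

test_that("BH discoveries control the false discovery proportion", {
  fdps <- vapply(1:10, function(sd) {
    s <- simulate_counts(sim_design(
      n_genes = 1000, de_fraction = 0.3, seed = sd,
      effect_size_function = function(n) sample(c(-2, 2), n, replace = TRUE)))
    nf <- size_factors(s$counts)
    r <- nb_wald_test(s$counts, nf, estimate_dispersions(s$counts, nf))
    disc <- r$gene[r$p_adjusted < 0.05]
    if (length(disc) == 0) return(0)
    sum(!s$truth$is_de[disc]) / length(disc)
  }, 0)
  expect_lte(mean(fdps), 0.07)
})
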