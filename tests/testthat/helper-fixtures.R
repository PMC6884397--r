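# Small builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

# minimal count matrix with explicit values
tiny_cm <- function(counts, condition = c("MC903", "EtOH"), day = "D8") {
  k <- as.matrix(counts)
  n <- ncol(k)
  cond <- rep(condition, length.out = n)
  meta <- data.frame(sample = paste0("s", seq_len(n)), condition = cond,
                     tissue = "skin", day = day)
  rownames(k) <- sprintf("g%03d", seq_len(nrow(k)))
  count_matrix(k, meta)
}

# expectation-valued (noiseless) count matrix for exact log2fc recovery:
# counts equal their NB means under unit size factors
noiseless_cm <- function(baseline, lfc, n_per_group = 3) {
  x <- rep(c(1, 0), each = n_per_group)
  mu <- outer(baseline * 1, rep(1, length(x))) * 2^outer(lfc, x)
  tiny_cm(mu, condition = rep(c("MC903", "EtOH"), each = n_per_group))
}

# named fold-change universe
fc_universe <- function(values, prefix = "g") {
  setNames(values, paste0(prefix, seq_along(values)))
}

# reference 4PL response used to build fixtures independently of the package
fourpl_ref <- function(x, a, b, cc, d) d + (a - d) / (1 + (x / cc)^b)

expect_paths_exist <- function(paths) {
  for (p in paths) testthat::expect_true(file.exists(p), label = p)
}
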