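#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed as the median, over genes with
#' positive counts in every sample, of the ratio of the sample's count to the
#' gene's geometric mean across samples.
#'
#' @param cm a [count_matrix()] (or a plain genes x samples matrix).
#' @return named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(cm) {
  k <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos))
    stop("no gene has positive counts in all samples; ",
         "a pseudo-reference fallback is not applied silently - filter or ",
         "subset samples first")
  lk <- log(k[pos, , drop = FALSE])
  geo <- rowMeans(lk)
  sf <- apply(lk, 2, function(col) exp(median(col - geo)))
  gm <- exp(mean(log(sf)))
  if (gm < 0.5 || gm > 2)
    warning("geometric mean of size factors (", signif(gm, 3),
            ") outside [0.5, 2]; check library sizes")
  sf
}

#' Per-gene NB dispersion with trend shrinkage
#'
#' Method-of-moments gene-wise dispersions from normalized counts, computed
#' within replicate groups (condition x day) and pooled, then shrunk on the
#' log scale toward a fitted mean-dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}. The trend is fitted by least squares
#' over all moment estimates, including negative ones, so it is not biased
#' upward by selection; the shrinkage weight (`shrink_weight`, default 0.75
#' toward the trend) reflects how noisy gene-wise moment estimates are at
#' typical replicate numbers. Genes whose moment estimate is non-positive
#' (at or below the floor) stay at the floor of 1e-8.
#'
#' @param cm a [count_matrix()].
#' @param nf size factors from [size_factors()].
#' @param shrink_weight weight on the trend in the log-scale combination,
#'   in \[0, 1\].
#' @return named per-gene dispersion vector with attribute `trend`
#'   (the fitted `c(a0, a1)`).
#' @export
estimate_dispersions <- function(cm, nf, shrink_weight = 0.75) {
  stopifnot(inherits(cm, "count_matrix"))
  k <- cm$counts
  meta <- cm$sample_meta
  grp <- interaction(meta$condition, meta$day %||% "all", drop = TRUE)
  if (max(table(grp)) < 2)
    stop("estimate_dispersions: needs >= 2 replicates in at least one group")
  z <- sweep(k, 2, nf, "/")
  floor_a <- 1e-8

  num <- 0; den <- 0
  for (g in levels(grp)) {
    j <- which(grp == g)
    if (length(j) < 2) next
    zj <- z[, j, drop = FALSE]
    m <- rowMeans(zj)
    v <- apply(zj, 1, var)
    shot <- m * mean(1 / nf[j])          # Poisson part of Var(K/s)
    w <- length(j) - 1
    num <- num + w * (v - shot)
    den <- den + w * m^2
  }
  mu <- rowMeans(z)
  raw <- ifelse(den > 0, num / den, 0)

  ok <- is.finite(raw) & mu > 0
  trend <- c(a0 = 0.01, a1 = 0)
  if (sum(ok) >= 10) {
    fit <- stats::lm(raw[ok] ~ I(1 / mu[ok]))
    trend <- c(a0 = max(unname(coef(fit)[1]), 1e-4),
               a1 = max(unname(coef(fit)[2]), 0))
  }
  a_tr <- trend[["a0"]] + trend[["a1"]] / pmax(mu, 1e-8)
  w <- shrink_weight
  alpha <- rep(floor_a, length(raw))
  up <- which(is.finite(raw) & raw > floor_a)
  alpha[up] <- pmax(exp((1 - w) * log(raw[up]) + w * log(a_tr[up])), floor_a)
  names(alpha) <- rownames(k)
  attr(alpha, "trend") <- trend
  alpha
}

# Vectorized per-gene IRLS for an NB log-linear model with two coefficients
# (intercept + treated indicator), offsets log(size factor), dispersion fixed.
nb_irls <- function(k, sf, x, alpha, maxit = 50, tol = 1e-10) {
  G <- nrow(k); S <- ncol(k)
  off <- matrix(log(sf), G, S, byrow = TRUE)
  i1 <- x == 1; i0 <- x == 0
  m1 <- rowSums(sweep(k[, i1, drop = FALSE], 2, sf[i1], "/")) / sum(i1)
  m0 <- rowSums(sweep(k[, i0, drop = FALSE], 2, sf[i0], "/")) / sum(i0)
  b0 <- log(pmax(m0, 1e-8))
  b1 <- log(pmax(m1, 1e-8)) - b0
  xm <- matrix(x, G, S, byrow = TRUE)
  for (it in seq_len(maxit)) {
    eta <- b0 + b1 * xm + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    zres <- (eta - off) + (k - mu) / pmax(mu, 1e-12)
    a11 <- rowSums(w); a12 <- rowSums(w * xm); a22 <- rowSums(w * xm * xm)
    c1 <- rowSums(w * zres); c2 <- rowSums(w * xm * zres)
    det <- a11 * a22 - a12^2
    det[det < 1e-300] <- NA
    nb0 <- (a22 * c1 - a12 * c2) / det
    nb1 <- (a11 * c2 - a12 * c1) / det
    nb0[!is.finite(nb0)] <- b0[!is.finite(nb0)]
    nb1[!is.finite(nb1)] <- b1[!is.finite(nb1)]
    nb0 <- pmin(pmax(nb0, -30), 30)
    nb1 <- pmin(pmax(nb1, -60), 60)
    delta <- max(abs(nb0 - b0), abs(nb1 - b1), na.rm = TRUE)
    b0 <- nb0; b1 <- nb1
    if (is.finite(delta) && delta < tol) break
  }
  eta <- b0 + b1 * xm + off
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  a11 <- rowSums(w); a12 <- rowSums(w * xm); a22 <- rowSums(w * xm * xm)
  det <- a11 * a22 - a12^2
  se1 <- sqrt(ifelse(det > 0, a11 / det, Inf))
  list(beta1 = b1, se1 = se1)
}

#' Negative-binomial Wald test, treated vs. control
#'
#' Per-gene NB log-linear fit (log link, size-factor offsets, plugged-in
#' dispersion); the treated-vs-control coefficient on the log2 scale is the
#' reported fold change, with a Wald p-value from the coefficient and its
#' standard error (normal reference, the standard Wald convention with
#' trend-stabilized plug-in dispersions). Genes with all-zero counts get
#' `log2fc = 0, p = 1`. Adjusted p-values are Benjamini-Hochberg within the
#' contrast.
#'
#' @param cm a [count_matrix()].
#' @param nf size factors.
#' @param dispersions per-gene dispersion vector.
#' @param contrast character(2): treated label, control label.
#' @return data.frame of class `de_result`: gene, log2fc, p_raw, p_adjusted,
#'   mean_expression; attributes `contrast`, `tissue`, `day`.
#' @export
nb_wald_test <- function(cm, nf, dispersions,
                         contrast = c("MC903", "EtOH")) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  cond <- cm$sample_meta$condition
  missing_lv <- setdiff(contrast, unique(cond))
  if (length(missing_lv))
    stop("contrast condition(s) absent from metadata: ",
         paste(missing_lv, collapse = ", "))
  j <- cond %in% contrast
  k <- cm$counts[, j, drop = FALSE]
  sf <- nf[j]
  x <- as.numeric(cond[j] == contrast[1])
  alpha <- pmax(as.numeric(dispersions), 1e-8)

  nz <- rowSums(k) > 0
  fit <- nb_irls(k[nz, , drop = FALSE], sf, x, alpha[nz])
  log2fc <- numeric(nrow(k)); p <- rep(1, nrow(k))
  zstat <- fit$beta1 / fit$se1
  p_nz <- 2 * pnorm(abs(zstat), lower.tail = FALSE)
  p_nz[!is.finite(p_nz)] <- 1
  log2fc[nz] <- fit$beta1 / log(2)
  p[nz] <- p_nz
  res <- data.frame(gene = rownames(k),
                    log2fc = log2fc,
                    p_raw = p,
                    p_adjusted = bh_adjust(p),
                    mean_expression = rowMeans(sweep(k, 2, sf, "/")),
                    row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  attr(res, "contrast") <- contrast
  attr(res, "tissue") <- cm$sample_meta$tissue[j][1]
  attr(res, "day") <- (cm$sample_meta$day %||% NA)[j][1]
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, capped at 1 (wraps [stats::p.adjust()]).
#'
#' @param p_raw numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_raw) {
  if (any(is.na(p_raw))) stop("bh_adjust: NaN/NA p-values are not allowed")
  if (any(p_raw < 0 | p_raw > 1)) stop("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(p_raw, method = "BH")
}

#' Select significant genes across time points
#'
#' A gene is selected when, at one or more time points, its adjusted p-value
#' falls below `alpha` and its absolute log2 fold change exceeds
#' `log2(fold_threshold)`. Degenerate thresholds (`alpha >= 1`,
#' `fold_threshold <= 1`) disable the corresponding filter, so
#' `alpha = 1, fold_threshold = 1` returns every tested gene. Set
#' `fold_threshold = NULL` for adjusted-p-only selection (the trigeminal
#' ganglia convention at alpha = 0.1).
#'
#' @param results a `de_result` or list of them (one per time point).
#' @param alpha adjusted-p threshold (0.05 skin/spinal cord, 0.1 ganglia).
#' @param fold_threshold linear fold-change display threshold (default 2),
#'   or NULL for none.
#' @param candidate_list optional character vector (curated gene list) to
#'   intersect with.
#' @return character vector of selected gene ids.
#' @export
significant_genes <- function(results, alpha = 0.05, fold_threshold = 2,
                              candidate_list = NULL) {
  if (inherits(results, "de_result")) results <- list(results)
  if (length(results) == 0 || all(vapply(results, nrow, 0L) == 0)) {
    warning("significant_genes: empty results")
    return(character(0))
  }
  hit <- lapply(results, function(r) {
    ok_p <- if (alpha >= 1) rep(TRUE, nrow(r)) else r$p_adjusted < alpha
    ok_fc <- if (is.null(fold_threshold) || fold_threshold <= 1)
      rep(TRUE, nrow(r)) else abs(r$log2fc) > log2(fold_threshold)
    r$gene[ok_p & ok_fc]
  })
  out <- unique(unlist(hit))
  out <- out[order(match(out, results[[1]]$gene))]
  if (!is.null(candidate_list)) out <- intersect(out, candidate_list)
  out
}

#' Fold-change matrix across time points
#'
#' Assembles the genes x time-points log2 fold-change matrix used for heatmap
#' clustering, restricted to `genes`, with columns in the given chronological
#' order.
#'
#' @param results named list of `de_result`s, names = time-point labels in
#'   chronological order.
#' @param genes gene ids (rows).
#' @return numeric matrix genes x time points.
#' @export
foldchange_matrix <- function(results, genes) {
  stopifnot(is.list(results), length(results) >= 1)
  cols <- names(results) %||% paste0("T", seq_along(results))
  m <- sapply(results, function(r) r$log2fc[match(genes, r$gene)])
  m <- matrix(m, nrow = length(genes), dimnames = list(genes, cols))
  if (any(!is.finite(m))) stop("foldchange_matrix: missing/non-finite entries")
  m
}
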