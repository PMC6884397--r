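#' Two-tailed Student-t p-value from (t, df)
#'
#' Converts a printed t statistic and degrees of freedom back to its
#' two-tailed p-value: `2 * P(T_df >= |t|)`.
#'
#' @param t t statistic (finite).
#' @param df degrees of freedom (> 0).
#' @return two-tailed p-value.
#' @export
t_two_tailed_p <- function(t, df) {
  if (any(!is.finite(t))) stop("t_two_tailed_p: non-finite t")
  if (any(df <= 0)) stop("t_two_tailed_p: df must be > 0")
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' Two-sample t test report
#'
#' Pooled-variance Student (default) or Welch-Satterthwaite t test, two
#' tailed. Zero variance in both groups with equal means returns `t = 0,
#' p = 1` by convention with a warning.
#'
#' @param x,y numeric vectors, each length >= 2.
#' @param variant "student" (pooled) or "welch".
#' @return list of class `test_report`: statistic, df, p, estimate
#'   (mean difference x - y), variant.
#' @export
t_test <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("t_test: each group needs >= 2 values")
  res <- tryCatch(
    stats::t.test(x, y, var.equal = variant == "student"),
    error = function(e) {
      if (grepl("constant", conditionMessage(e)) && isTRUE(all.equal(mean(x), mean(y)))) {
        warning("zero variance in both groups with equal means; p = 1 by convention")
        return(NULL)
      }
      stop(e)
    })
  if (is.null(res))
    return(structure(list(statistic = 0, df = length(x) + length(y) - 2,
                          p = 1, estimate = 0, variant = variant),
                     class = "test_report"))
  structure(list(statistic = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, estimate = unname(diff(rev(res$estimate))),
                 variant = variant),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("test_report: statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(signif(x$df, 5), collapse = ", "), x$p))
  invisible(x)
}

#' One-way ANOVA
#'
#' Between/within mean-square F with `(k - 1, N - k)` degrees of freedom.
#' For two balanced groups, F equals the square of the pooled t statistic.
#' When every observation is identical (zero total sum of squares), `F = 0,
#' p = 1` by convention.
#'
#' @param groups named list of numeric vectors (one per group).
#' @return list of class `test_report`: statistic (F), df = c(df1, df2), p,
#'   plus `mse` and `group_means` for post-hoc use.
#' @export
anova_one_way <- function(groups) {
  if (length(groups) < 2) stop("anova_one_way: needs >= 2 groups")
  if (any(vapply(groups, length, 0L) < 1)) stop("anova_one_way: empty group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  if (sum((y - mean(y))^2) == 0) {
    return(structure(list(statistic = 0,
                          df = c(length(groups) - 1, length(y) - length(groups)),
                          p = 1, mse = 0,
                          group_means = vapply(groups, mean, 0),
                          group_n = vapply(groups, length, 0L)),
                     class = "test_report"))
  }
  fit <- aov(y ~ f)
  tab <- anova(fit)
  structure(list(statistic = tab$`F value`[1],
                 df = c(tab$Df[1], tab$Df[2]),
                 p = tab$`Pr(>F)`[1],
                 mse = tab$`Mean Sq`[2],
                 group_means = vapply(groups, mean, 0),
                 group_n = vapply(groups, length, 0L)),
            class = "test_report")
}

#' Two-way ANOVA with Type-III sums of squares
#'
#' Main effects and interaction for two crossed factors (e.g. treatment x
#' time) on possibly unbalanced data, using Type-III sums of squares with sum
#' contrasts (the convention of the point-and-click statistics software used
#' in this field). Balanced designs reduce to the textbook decomposition.
#'
#' @param data data.frame in long format.
#' @param response,factor_a,factor_b column names.
#' @return data.frame with one row per effect (A, B, interaction): effect,
#'   F, df1, df2, p.
#' @export
anova_two_way <- function(data, response, factor_a, factor_b) {
  fa <- factor(data[[factor_a]]); fb <- factor(data[[factor_b]])
  if (nlevels(fa) < 2) stop("anova_two_way: factor '", factor_a, "' needs >= 2 levels")
  if (nlevels(fb) < 2) {
    # degenerate design: a single level of B reduces to the one-way ANOVA on A
    aw <- anova_one_way(split(data[[response]], fa))
    return(data.frame(effect = factor_a, F = aw$statistic,
                      df1 = aw$df[1], df2 = aw$df[2], p = aw$p))
  }
  tab <- table(fa, fb)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("anova_two_way: empty cell (", levels(fa)[bad[1]], ", ",
         levels(fb)[bad[2]], ")")
  }
  d <- data.frame(y = data[[response]], A = fa, B = fb)
  fit <- lm(y ~ A * B, data = d,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  rows <- c(A = "A", B = "B", interaction = "A:B")
  res_df <- a3["Residuals", "Df"]
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    data.frame(effect = c(A = factor_a, B = factor_b,
                          interaction = paste0(factor_a, ":", factor_b))[[nm]],
               F = a3[r, "F value"], df1 = a3[r, "Df"], df2 = res_df,
               p = a3[r, "Pr(>F)"])
  }))
  rownames(out) <- NULL
  out
}

#' Post-hoc multiple-comparison families
#'
#' Tukey-Kramer over all pairs via the studentized-range distribution (using
#' the one-way ANOVA mean square error), or Sidak / Holm-Sidak over an
#' explicit set of comparisons (raw p from pooled-MSE t tests). With a single
#' comparison all three families return the raw p.
#'
#' @param groups named list of numeric vectors.
#' @param family "tukey", "sidak", or "holm_sidak".
#' @param comparisons for sidak/holm_sidak: list of character pairs (group
#'   names); default all pairs.
#' @param unequal_variance Tukey with unequal variances is refused.
#' @return data.frame: comparison, estimate, p_raw, p_adjusted.
#' @export
posthoc <- function(groups, family = c("tukey", "sidak", "holm_sidak"),
                    comparisons = NULL, unequal_variance = FALSE) {
  family <- match.arg(family)
  if (family == "tukey" && unequal_variance)
    stop("posthoc: Tukey with unequal variances is not supported")
  aw <- anova_one_way(groups)
  mse <- aw$mse; df2 <- aw$df[2]
  mns <- aw$group_means; ns <- aw$group_n
  k <- length(groups)
  if (is.null(comparisons))
    comparisons <- combn(names(groups), 2, simplify = FALSE)
  est <- vapply(comparisons, function(cp) mns[[cp[1]]] - mns[[cp[2]]], 0)
  sed <- vapply(comparisons, function(cp)
    sqrt(mse * (1 / ns[[cp[1]]] + 1 / ns[[cp[2]]])), 0)
  tstat <- est / sed
  lab <- vapply(comparisons, paste, "", collapse = " vs ")
  if (family == "tukey") {
    q <- abs(tstat) * sqrt(2)
    padj <- ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    praw <- 2 * pt(abs(tstat), df2, lower.tail = FALSE)
  } else {
    praw <- 2 * pt(abs(tstat), df2, lower.tail = FALSE)
    m <- length(praw)
    if (family == "sidak") {
      padj <- 1 - (1 - praw)^m
    } else {
      o <- order(praw)
      adj <- 1 - (1 - praw[o])^(m - seq_len(m) + 1)
      adj <- cummax(adj)
      padj <- numeric(m); padj[o] <- adj
    }
  }
  data.frame(comparison = lab, estimate = est,
             p_raw = praw, p_adjusted = pmin(padj, 1))
}

#' Sidak adjustment of a p-value vector
#'
#' `1 - (1 - p)^m` with `m = length(p)` by default.
#'
#' @param p raw p-values.
#' @param m family size.
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) pmin(1 - (1 - p)^m, 1)

#' Holm-Sidak step-down adjustment
#'
#' @param p raw p-values.
#' @return adjusted p-values (monotone, capped at 1).
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- cummax(1 - (1 - p[o])^(m - seq_len(m) + 1))
  out <- numeric(m); out[o] <- pmin(adj, 1)
  out
}

#' Control-pooling decision
#'
#' Different control conditions (e.g. uninjected vs. vehicle-injected) are
#' pooled when the comparison test does not find them significantly
#' different at `alpha`; otherwise they stay separate. The decision is
#' symmetric in argument order.
#'
#' @param control_a,control_b numeric vectors, each length >= 2.
#' @param alpha significance level for the pooling test.
#' @param variant t-test variant passed to [t_test()].
#' @return list: `decision` ("pooled"/"separate"), `p`, `pooled` (the merged
#'   vector when pooled, else NULL).
#' @export
pooling_check <- function(control_a, control_b, alpha = 0.05,
                          variant = "student") {
  tr <- t_test(control_a, control_b, variant = variant)
  if (tr$p >= alpha)
    list(decision = "pooled", p = tr$p, pooled = c(control_a, control_b))
  else
    list(decision = "separate", p = tr$p, pooled = NULL)
}
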