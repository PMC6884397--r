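#' Bead-calibrated absolute cell count
#'
#' A known number of counting beads is added to each sample before
#' acquisition; the fraction of beads actually acquired calibrates the cell
#' events to absolute numbers: `cells = cell_events * beads_total /
#' bead_events`.
#'
#' @param cell_events gated cell events (vectorized).
#' @param bead_events acquired bead events (> 0).
#' @param beads_total beads added to the sample.
#' @return absolute cell count(s).
#' @export
absolute_count <- function(cell_events, bead_events, beads_total) {
  if (any(bead_events <= 0))
    stop("absolute_count: bead_events must be > 0 (acquisition failure)")
  if (any(cell_events < 0) || any(beads_total <= 0))
    stop("absolute_count: negative events or non-positive beads_total")
  if (any(bead_events > beads_total))
    warning("bead_events exceed beads_total for some samples")
  cell_events * beads_total / bead_events
}

#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of `OD = d + (a - d) / (1 + (x/c)^b)` to standards
#' (blank wells enter at `x = 0`, where the curve equals the zero-dose
#' asymptote `a`). Levenberg-Marquardt with multi-start initialization over a
#' grid of midpoints and slopes; the best converged start by residual sum of
#' squares is kept.
#'
#' @param concs standard concentrations (>= 5 distinct values; may include 0
#'   for blanks).
#' @param ods optical densities, same length.
#' @return object of class `curve_4pl`: list with `a`, `b`, `c`, `d`, `rss`,
#'   `converged`, `conc_range` (positive standards), and `data`.
#' @export
fit_4pl <- function(concs, ods) {
  if (length(concs) != length(ods)) stop("fit_4pl: length mismatch")
  if (any(!is.finite(ods))) stop("fit_4pl: ODs must be finite")
  if (length(unique(concs)) < 5) stop("fit_4pl: >= 5 distinct concentrations required")
  df <- data.frame(x = concs, od = ods)
  pos <- sort(unique(concs[concs > 0]))
  # monotonicity check on mean OD per standard (beyond small noise)
  mu <- tapply(df$od, df$x, mean)[as.character(c(0, pos))]
  mu <- mu[!is.na(mu)]
  tolr <- 0.02 * diff(range(ods))
  dirs <- diff(mu)
  if (any(dirs > tolr) && any(dirs < -tolr))
    warning("fit_4pl: standards are non-monotone beyond noise tolerance")

  a0 <- mean(df$od[df$x == min(concs)])
  d0 <- mean(df$od[df$x == max(concs)])
  best <- NULL
  for (c0 in quantile(pos, c(0.25, 0.5, 0.75), names = FALSE))
    for (b0 in c(0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(od ~ d + (a - d) / (1 + (x / cc)^b), data = df,
                          start = list(a = a0, b = b0, cc = c0, d = d0),
                          lower = c(a = -Inf, b = 1e-6, cc = min(pos) / 100, d = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  if (is.null(best)) stop("fit_4pl: singular fit; no start converged")
  cf <- coef(best$fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["cc"]), d = unname(cf["d"]),
                 rss = best$rss, converged = TRUE,
                 conc_range = range(pos), data = df),
            class = "curve_4pl")
}

#' Evaluate a fitted 4PL curve
#'
#' @param object a `curve_4pl`.
#' @param x concentrations.
#' @param ... unused.
#' @return predicted OD(s).
#' @export
predict.curve_4pl <- function(object, x, ...) {
  fourpl(x, object$a, object$b, object$c, object$d)
}

#' @export
print.curve_4pl <- function(x, ...) {
  cat(sprintf("4PL curve: a = %.4g, b = %.4g, c = %.4g, d = %.4g (rss = %.3g)\n",
              x$a, x$b, x$c, x$d, x$rss))
  invisible(x)
}

#' Invert a 4PL curve: OD to concentration
#'
#' Closed-form inverse `x = c * ((a - d)/(od - d) - 1)^(1/b)`, multiplied by
#' the combined dilution factor. ODs outside the open interval between the
#' asymptotes are errors; concentrations outside the standard range are
#' flagged via the `extrapolated` attribute.
#'
#' @param curve a `curve_4pl`.
#' @param od optical density (vectorized).
#' @param dilution_factor combined sample dilution (default 2, the 1:2
#'   dilution into reagent diluent).
#' @return concentration(s) with logical attribute `extrapolated`.
#' @export
invert_4pl <- function(curve, od, dilution_factor = 2) {
  lo <- min(curve$a, curve$d); hi <- max(curve$a, curve$d)
  if (any(od <= lo))
    stop("invert_4pl: OD at or below the zero-dose asymptote (", signif(lo, 4), ")")
  if (any(od >= hi))
    stop("invert_4pl: OD at or above the saturation asymptote (", signif(hi, 4), ")")
  x <- curve$c * ((curve$a - curve$d) / (od - curve$d) - 1)^(1 / curve$b)
  out <- x * dilution_factor
  attr(out, "extrapolated") <- x < curve$conc_range[1] | x > curve$conc_range[2]
  out
}

#' Quantify an ELISA plate
#'
#' Fits the 4PL standard curve on standard + blank wells, inverts sample-well
#' ODs, and reports per-well and per-sample (averaged) concentrations with
#' extrapolation flags. Wells are inverted individually and then averaged;
#' the mean OD inversion is also reported for comparison.
#'
#' @param plate data.frame with columns well, role (standard/blank/sample),
#'   sample, conc (standards), od.
#' @param dilution_factor combined dilution correction (default 2).
#' @return list: `curve`, `wells` (per-well concentrations), `samples`
#'   (per-sample means of per-well inversions plus `conc_from_mean_od`).
#' @export
quantify_plate <- function(plate, dilution_factor = 2) {
  std <- plate[plate$role %in% c("standard", "blank"), ]
  curve <- fit_4pl(std$conc, std$od)
  sm <- plate[plate$role == "sample", ]
  conc <- invert_4pl(curve, sm$od, dilution_factor)
  wells <- data.frame(well = sm$well, sample = sm$sample, od = sm$od,
                      conc_pg_per_mL = as.numeric(conc),
                      extrapolated = attr(conc, "extrapolated"))
  agg <- do.call(rbind, lapply(split(wells, wells$sample), function(w) {
    mean_od <- mean(w$od)
    data.frame(sample = w$sample[1],
               conc_pg_per_mL = mean(w$conc_pg_per_mL),
               conc_from_mean_od = as.numeric(
                 invert_4pl(curve, mean_od, dilution_factor)),
               n_wells = nrow(w),
               extrapolated = any(w$extrapolated))
  }))
  rownames(agg) <- NULL
  list(curve = curve, wells = wells, samples = agg)
}
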