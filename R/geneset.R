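#' Gene group
#'
#' A named set of gene identifiers to be tested against a fold-change
#' universe.
#'
#' @param name group label.
#' @param members character vector of gene ids (deduplicated; must be
#'   non-empty).
#' @param description optional free text.
#' @return object of class `gene_group`.
#' @export
gene_group <- function(name, members, description = "") {
  members <- unique(as.character(members))
  if (length(members) < 1) stop("gene_group: needs >= 1 member")
  structure(list(name = name, members = members, n = length(members),
                 description = description), class = "gene_group")
}

#' Group statistic: central absolute log2 fold change
#'
#' The observed statistic `z` of a gene group: the median (default) or mean
#' of the absolute log2 fold changes of its members in the universe of all
#' detected genes. The median of an even-sized set is the midpoint of the two
#' central values.
#'
#' @param universe named numeric vector, gene -> log2 fold change, covering
#'   all genes detected in the samples.
#' @param members gene ids, all present in the universe.
#' @param center "median" (default) or "mean".
#' @return the non-negative statistic.
#' @export
group_statistic <- function(universe, members, center = c("median", "mean")) {
  center <- match.arg(center)
  miss <- setdiff(members, names(universe))
  if (length(miss))
    stop("group members missing from universe: ", paste(miss, collapse = ", "))
  v <- abs(universe[members])
  if (center == "median") median(v) else mean(v)
}

# B draws of n indices from m, uniform without replacement within a draw.
# Vectorized rejection sampling: draw all columns with replacement, redo the
# few columns containing duplicates (exact, since rejection preserves
# uniformity over duplicate-free draws).
sample_null_indices <- function(m, n, B) {
  if (n == 1) return(matrix(sample.int(m, B, replace = TRUE), 1, B))
  idx <- matrix(sample.int(m, n * B, replace = TRUE), nrow = n)
  bad <- which(apply(idx, 2, anyDuplicated) > 0)
  for (j in bad) idx[, j] <- sample.int(m, n)
  idx
}

#' Permutation test for a gene group's expression change
#'
#' Tests whether a group of `n` genes changes expression more than random
#' gene sets: the observed statistic `z_true` (central absolute log2 fold
#' change of the members, [group_statistic()]) is compared with a null
#' distribution built by drawing `n` genes uniformly without replacement from
#' the universe of all detected genes, `B` times. The empirical p-value uses
#' the plus-one correction `(1 + #\{z_null >= z_true\}) / (B + 1)`, so large
#' group effects give small p. `literal = TRUE` instead reports the
#' proportion with `z_true >= z_null` (the complementary direction), kept
#' for comparison.
#'
#' @param universe named gene -> log2fc vector (all detected genes).
#' @param group a [gene_group()] (or character vector of members).
#' @param B number of null draws (default 10000).
#' @param center "median" or "mean".
#' @param seed integer seed.
#' @param literal report the complementary-direction proportion instead.
#' @return object of class `permutation_result`: list with `name`, `n`,
#'   `z_true`, `z_null`, `B`, `p_empirical`, `center`, `seed`.
#' @export
permutation_test <- function(universe, group, B = 10000,
                             center = c("median", "mean"), seed = 1L,
                             literal = FALSE) {
  center <- match.arg(center)
  if (is.character(group)) group <- gene_group("group", group)
  stopifnot(inherits(group, "gene_group"), B >= 1)
  if (group$n > length(universe))
    stop("group larger than universe (", group$n, " > ", length(universe), ")")
  z_true <- group_statistic(universe, group$members, center)
  absfc <- abs(unname(universe))
  m <- length(absfc); n <- group$n
  z_null <- with_seed(seed, {
    idx <- sample_null_indices(m, n, B)
    vals <- matrix(absfc[idx], nrow = n)
    if (center == "median") {
      if (n == 1) as.numeric(vals)
      else if (n == 2) colMeans(vals)
      else apply(vals, 2, median)
    } else colMeans(vals)
  })
  hits <- if (literal) sum(z_true >= z_null) else sum(z_null >= z_true)
  structure(list(name = group$name, n = n, z_true = z_true, z_null = z_null,
                 B = B, p_empirical = (1 + hits) / (B + 1),
                 center = center, seed = seed, literal = literal),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result '%s': n = %d, z_true = %.4g, p = %.4g (B = %d, center = %s, seed = %s)\n",
              x$name, x$n, x$z_true, x$p_empirical, x$B, x$center, x$seed))
  invisible(x)
}

#' Exhaustive-enumeration test (oracle for small universes)
#'
#' Enumerates every size-`n` subset of the universe and reports the exact
#' null proportion `#\{z_subset >= z_true\} / C(m, n)`. Only feasible when
#' `choose(m, n) <= 1e6`; validates the Monte Carlo path.
#'
#' @inheritParams permutation_test
#' @return list with `p_exact`, `z_true`, `n_subsets`.
#' @export
exact_permutation_test <- function(universe, group, center = c("median", "mean")) {
  center <- match.arg(center)
  if (is.character(group)) group <- gene_group("group", group)
  m <- length(universe); n <- group$n
  if (choose(m, n) > 1e6)
    stop("choose(", m, ", ", n, ") exceeds 1e6 subsets; use permutation_test()")
  z_true <- group_statistic(universe, group$members, center)
  absfc <- abs(unname(universe))
  subs <- combn(m, n)
  stat <- if (center == "median")
    apply(matrix(absfc[subs], nrow = n), 2, median)
  else colMeans(matrix(absfc[subs], nrow = n))
  list(p_exact = sum(stat >= z_true) / ncol(subs),
       z_true = z_true, n_subsets = ncol(subs))
}

#' Run the permutation test over a panel of groups and conditions
#'
#' One [permutation_test()] per group x condition, with independent
#' deterministic seed substreams, returned as a tidy table. Groups with no
#' members in a universe yield an NA row and the run continues; members
#' absent from a universe are counted in `n_missing` (reported, not silently
#' dropped).
#'
#' @param universes named list of fold-change universes (e.g. one per
#'   tissue/day), each a named gene -> log2fc vector.
#' @param groups list of [gene_group()]s (e.g. from [read_gmt()]).
#' @param B null draws per test.
#' @param center "median" or "mean".
#' @param seed global seed; each group x condition gets its own substream.
#' @return data.frame (class `group_panel`): group, condition, n, n_missing,
#'   z_true, p_empirical, B, seed; attribute `results` holds the full
#'   `permutation_result` objects.
#' @export
run_group_panel <- function(universes, groups, B = 10000,
                            center = c("median", "mean"), seed = 1L) {
  center <- match.arg(center)
  if (inherits(groups, "gene_group")) groups <- list(groups)
  if (!is.list(universes)) universes <- list(all = universes)
  if (is.null(names(universes)))
    names(universes) <- paste0("u", seq_along(universes))
  rows <- list(); full <- list()
  for (cond in names(universes)) {
    uni <- universes[[cond]]
    for (g in groups) {
      present <- intersect(g$members, names(uni))
      n_missing <- g$n - length(present)
      task_seed <- substream_seed(seed, c(cond, g$name))
      if (length(present) == 0) {
        warning("group '", g$name, "' empty after intersection with universe '",
                cond, "'; reported as NA")
        rows[[length(rows) + 1L]] <- data.frame(
          group = g$name, condition = cond, n = 0L, n_missing = n_missing,
          z_true = NA_real_, p_empirical = NA_real_, B = B, seed = task_seed)
        next
      }
      pr <- permutation_test(uni, gene_group(g$name, present), B = B,
                             center = center, seed = task_seed)
      full[[paste(cond, g$name, sep = "|")]] <- pr
      rows[[length(rows) + 1L]] <- data.frame(
        group = g$name, condition = cond, n = pr$n, n_missing = n_missing,
        z_true = pr$z_true, p_empirical = pr$p_empirical, B = B,
        seed = task_seed)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_panel", "data.frame")
  attr(out, "results") <- full
  out
}

#' Bar plot of a group panel
#'
#' Observed group statistics with significance annotation (stars at the
#' conventional p cutoffs), one bar per group x condition.
#'
#' @param panel a `group_panel` from [run_group_panel()].
#' @param file optional PNG path; when NULL, draws on the current device.
#' @return invisibly, the file path (or NULL).
#' @export
plot_group_panel <- function(panel, file = NULL) {
  stopifnot(inherits(panel, "group_panel"))
  panel <- panel[is.finite(panel$z_true), , drop = FALSE]
  if (nrow(panel) == 0) stop("plot_group_panel: no finite group statistics")
  if (!is.null(file)) { png(file, width = 900, height = 500); on.exit(dev.off()) }
  lab <- paste(panel$group, panel$condition, sep = "\n")
  stars <- cut(panel$p_empirical, c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
               labels = c("****", "***", "**", "*", ""))
  op <- par(mar = c(6, 4, 2, 1)); on.exit(par(op), add = TRUE)
  bp <- barplot(panel$z_true, names.arg = lab, las = 2,
                ylab = "median |log2 fold change|",
                ylim = c(0, max(panel$z_true, na.rm = TRUE) * 1.2))
  text(bp, panel$z_true, labels = as.character(stars), pos = 3)
  invisible(file)
}
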