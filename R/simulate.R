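#' Simulation design for gene-level count data
#'
#' Describes a bulk RNA-seq style experiment: treated vs. vehicle-control
#' samples across time points, negative-binomial gene counts with per-gene
#' baseline means, a mean-dispersion trend, library-size factors and a
#' configurable fraction of truly differential genes.
#'
#' Defaults emulate a moderately deep bulk time-course: lognormal baseline
#' means centred at 100 counts, library-size factors in \[0.7, 1.4\],
#' dispersion trend \eqn{\alpha(\mu) = 0.05 + 5/\mu}, 10% of genes
#' differential with sign-symmetric log2 effects of magnitude 0.5 + Exp(1).
#'
#' @param n_genes number of genes.
#' @param groups data.frame with columns `condition`, `time`, `n` (replicates
#'   per condition/time cell). Any group entering a two-group contrast needs
#'   `n >= 2`.
#' @param library_size_range length-2 positive interval for the true
#'   per-sample size factors (sampled uniformly).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline means.
#' @param dispersion_function function mapping a mean to an NB dispersion
#'   (`var = mu + alpha * mu^2`).
#' @param de_fraction proportion of genes in \[0,1\] with a true effect.
#' @param effect_size_function function of `n` returning `n` true log2 fold
#'   changes for the differential genes.
#' @param treated,control condition labels forming the contrast.
#' @param tissue tissue label recorded in sample metadata.
#' @param seed integer seed.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_genes = 2000,
                       groups = data.frame(
                         condition = rep(c("MC903", "EtOH"), each = 1),
                         time = "D8",
                         n = 4L),
                       library_size_range = c(0.7, 1.4),
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1.2,
                       dispersion_function = function(mu) 0.05 + 5 / mu,
                       de_fraction = 0.1,
                       effect_size_function = function(n)
                         sample(c(-1, 1), n, replace = TRUE) * (0.5 + stats::rexp(n)),
                       treated = "MC903", control = "EtOH",
                       tissue = "skin",
                       seed = 1L) {
  d <- structure(list(
    n_genes = n_genes, groups = groups,
    library_size_range = library_size_range,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion_function = dispersion_function,
    de_fraction = de_fraction,
    effect_size_function = effect_size_function,
    treated = treated, control = control, tissue = tissue,
    seed = seed), class = "sim_design")
  validate_sim_design(d)
  d
}

validate_sim_design <- function(d) {
  if (!is.numeric(d$n_genes) || d$n_genes < 1)
    stop("sim_design: n_genes must be a positive count")
  g <- d$groups
  if (!all(c("condition", "time", "n") %in% names(g)))
    stop("sim_design: groups must have columns condition, time, n")
  if (any(g$n < 2))
    stop("sim_design: groups: every group entering a contrast needs n >= 2 replicates")
  r <- d$library_size_range
  if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2])
    stop("sim_design: library_size_range must be a positive interval")
  if (!is.finite(d$baseline_meanlog) || !is.finite(d$baseline_sdlog) || d$baseline_sdlog < 0)
    stop("sim_design: baseline_meanlog/baseline_sdlog invalid")
  if (d$de_fraction < 0 || d$de_fraction > 1)
    stop("sim_design: de_fraction must lie in [0, 1]")
  if (!is.function(d$dispersion_function))
    stop("sim_design: dispersion_function must be a function")
  mu_test <- exp(d$baseline_meanlog)
  if (any(!is.finite(d$dispersion_function(mu_test))) || any(d$dispersion_function(mu_test) < 0))
    stop("sim_design: dispersion_function must return non-negative finite values")
  invisible(d)
}

#' Count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, genes x samples, with rownames.
#' @param sample_meta data.frame with one row per column of `counts` and at
#'   least columns `sample`, `condition`; `tissue` and `day` optional.
#' @return object of class `count_matrix` (list with `counts`, `gene_ids`,
#'   `sample_meta`).
#' @export
count_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("count_matrix: counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) stop("count_matrix: gene_ids must be unique")
  if (nrow(sample_meta) != ncol(counts))
    stop("count_matrix: sample_meta rows must match count columns")
  if (!all(c("sample", "condition") %in% names(sample_meta)))
    stop("count_matrix: sample_meta needs columns sample, condition")
  colnames(counts) <- sample_meta$sample
  structure(list(counts = counts, gene_ids = rownames(counts),
                 sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(unique(x$sample_meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate negative-binomial gene counts with known truth
#'
#' Counts are drawn `NB(mean = size_factor * baseline * 2^(log2fc * treated),
#' dispersion = alpha(baseline))`. The true per-gene log2 fold change, the
#' differential flags, and the true size factors are returned alongside.
#'
#' @param design a [sim_design()].
#' @return list with elements `counts` (a [count_matrix()]) and `truth`
#'   (list: `true_log2fc`, `is_de`, `size_factor_true`, `baseline_mean`,
#'   `dispersion`).
#' @export
simulate_counts <- function(design) {
  validate_sim_design(design)
  with_seed(substream_seed(design$seed, "counts"), {
    g <- design$groups
    meta <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      data.frame(condition = g$condition[i], tissue = design$tissue,
                 day = g$time[i], rep = seq_len(g$n[i]))
    }))
    meta$sample <- sprintf("%s_%s_r%d", meta$condition, meta$day, meta$rep)
    meta <- meta[, c("sample", "condition", "tissue", "day")]
    S <- nrow(meta); G <- as.integer(design$n_genes)

    sf <- runif(S, design$library_size_range[1], design$library_size_range[2])
    if (any(sf <= 0)) stop("library_size_range produced non-positive size factors")
    q <- rlnorm(G, design$baseline_meanlog, design$baseline_sdlog)
    if (any(q <= 0)) stop("baseline_mean_distribution produced non-positive means")

    n_de <- as.integer(round(design$de_fraction * G))
    lfc <- numeric(G)
    is_de <- logical(G)
    if (n_de > 0) {
      idx <- sample.int(G, n_de)
      lfc[idx] <- design$effect_size_function(n_de)
      is_de[idx] <- TRUE
    }
    treated_ind <- as.numeric(meta$condition == design$treated)
    alpha <- design$dispersion_function(q)

    # mean matrix: genes x samples
    mu <- (q * 2^(outer(lfc, treated_ind))) * rep(sf, each = G)
    counts <- matrix(rnbinom(G * S, mu = mu, size = 1 / pmax(alpha, 1e-12)),
                     nrow = G, ncol = S,
                     dimnames = list(sprintf("g%05d", seq_len(G)), meta$sample))
    list(counts = count_matrix(counts, meta),
         truth = list(true_log2fc = setNames(lfc, rownames(counts)),
                      is_de = setNames(is_de, rownames(counts)),
                      size_factor_true = setNames(sf, meta$sample),
                      baseline_mean = setNames(q, rownames(counts)),
                      dispersion = setNames(alpha, rownames(counts))))
  })
}

# stamp a filled disk of radius r at (x, y) into matrix m (by reference value)
stamp_disk <- function(mask, x, y, offs) {
  xs <- pmin(pmax(round(x) + offs$dx, 1L), nrow(mask))
  ys <- pmin(pmax(round(y) + offs$dy, 1L), ncol(mask))
  mask[cbind(xs, ys)] <- TRUE
  mask
}

disk_offsets <- function(r) {
  d <- seq(-ceiling(r), ceiling(r))
  gr <- expand.grid(dx = d, dy = d)
  gr <- gr[gr$dx^2 + gr$dy^2 <= r^2 + 1e-9, , drop = FALSE]
  list(dx = as.integer(gr$dx), dy = as.integer(gr$dy))
}

#' Simulate a whole-mount innervation image stack
#'
#' Generates a >= 3 plane fluorescence stack whose maximum-intensity
#' projection shows `n_fibers` curvilinear bright structures (smoothed random
#' walks with a disk cross-section) on a dark background, plus dimmer
#' hair-follicle autofluorescence blobs and Gaussian noise. The ground-truth
#' foreground mask covers fiber pixels only; follicles are excluded by
#' intensity (fibers at 0.90 of the dynamic range, follicles at 0.30), so the
#' suggested binarization window separates them.
#'
#' @param width,height image dimensions in px (>= 64).
#' @param n_fibers number of nerve fibers.
#' @param fiber_width_px fiber diameter in px (>= 1).
#' @param follicle_count number of autofluorescent follicle blobs.
#' @param noise_sd Gaussian noise sd on the \[0, 1\] intensity scale.
#' @param n_planes number of z planes (>= 3).
#' @param seed integer seed.
#' @return list: `stack` (class `image_stack`: list of plane matrices plus
#'   `channel`), `truth` (list: `mask` logical matrix, `fiber_fraction`,
#'   `follicle_centers`, `suggested_thresholds` = c(min, max) for
#'   [binarize()]).
#' @export
simulate_innervation_image <- function(width = 256, height = 256,
                                       n_fibers = 10, fiber_width_px = 3,
                                       follicle_count = 5, noise_sd = 0,
                                       n_planes = 3, seed = 1L) {
  if (width < 64 || height < 64) stop("image dimensions must be >= 64 px")
  if (fiber_width_px < 1) stop("fiber_width_px must be >= 1")
  if (n_planes < 3) stop("n_planes must be >= 3")
  with_seed(substream_seed(seed, "innervation"), {
    mask <- matrix(FALSE, width, height)
    offs <- disk_offsets(fiber_width_px / 2)
    fiber_plane <- sample.int(n_planes, max(n_fibers, 1), replace = TRUE)
    plane_masks <- replicate(n_planes, matrix(FALSE, width, height), simplify = FALSE)
    if (n_fibers > 0) {
      for (f in seq_len(n_fibers)) {
        x <- runif(1, 1, width); y <- runif(1, 1, height)
        ang <- runif(1, 0, 2 * pi)
        n_steps <- round(runif(1, 0.4, 0.8) * min(width, height))
        for (s in seq_len(n_steps)) {
          ang <- ang + rnorm(1, 0, 0.25)
          x <- x + cos(ang); y <- y + sin(ang)
          if (x < 1 || x > width) { ang <- pi - ang; x <- pmin(pmax(x, 1), width) }
          if (y < 1 || y > height) { ang <- -ang; y <- pmin(pmax(y, 1), height) }
          mask <- stamp_disk(mask, x, y, offs)
          plane_masks[[fiber_plane[f]]] <- stamp_disk(plane_masks[[fiber_plane[f]]], x, y, offs)
        }
        if (mean(mask) > 0.95)
          stop("cannot place ", n_fibers, " fibers without exceeding 95% coverage")
      }
    }
    # follicle blobs: dim autofluorescence present on every plane
    foll <- matrix(0, width, height)
    centers <- NULL
    if (follicle_count > 0) {
      foffs <- disk_offsets(6)
      centers <- cbind(x = runif(follicle_count, 8, width - 8),
                       y = runif(follicle_count, 8, height - 8))
      fm <- matrix(FALSE, width, height)
      for (i in seq_len(follicle_count))
        fm <- stamp_disk(fm, centers[i, 1], centers[i, 2], foffs)
      foll[fm] <- 0.30
    }
    planes <- lapply(seq_len(n_planes), function(p) {
      img <- matrix(0, width, height)
      img[plane_masks[[p]]] <- 0.90
      img <- pmax(img, foll)
      if (noise_sd > 0) img <- pmin(pmax(img + rnorm(length(img), 0, noise_sd), 0), 1)
      img
    })
    stack <- structure(list(planes = planes, channel = "BTIII",
                            pixel_size_um = 1), class = "image_stack")
    list(stack = stack,
         truth = list(mask = mask,
                      fiber_fraction = mean(mask),
                      follicle_centers = centers,
                      suggested_thresholds = c(0.45, 1)))
  })
}

#' Simulate a stained ganglia section image
#'
#' Places `n_cells` disk-shaped stained cells (non-overlapping, with a
#' separation margin) on a dark background with Gaussian noise; used to test
#' size-filtered cell counting against known truth.
#'
#' @param width,height dimensions in px (>= 64).
#' @param n_cells number of cells.
#' @param cell_radius_px disk radius in px.
#' @param noise_sd Gaussian noise sd on the \[0, 1\] scale.
#' @param seed integer seed.
#' @return list: `image` (matrix), `truth` (list: `mask`, `centroids`,
#'   `cell_area_px`, `suggested_thresholds`, `suggested_size_criteria`).
#' @export
simulate_section_image <- function(width = 192, height = 192, n_cells = 12,
                                   cell_radius_px = 4, noise_sd = 0, seed = 1L) {
  if (width < 64 || height < 64) stop("image dimensions must be >= 64 px")
  with_seed(substream_seed(seed, "section"), {
    offs <- disk_offsets(cell_radius_px)
    area <- length(offs$dx)
    mask <- matrix(FALSE, width, height)
    centers <- matrix(NA_real_, n_cells, 2)
    margin <- cell_radius_px + 2
    min_sep <- 2 * cell_radius_px + 3
    placed <- 0; tries <- 0
    while (placed < n_cells) {
      tries <- tries + 1
      if (tries > 20000) stop("cannot place ", n_cells, " non-overlapping cells")
      x <- runif(1, margin + 1, width - margin)
      y <- runif(1, margin + 1, height - margin)
      if (placed > 0 &&
          any((centers[seq_len(placed), 1] - x)^2 +
              (centers[seq_len(placed), 2] - y)^2 < min_sep^2)) next
      placed <- placed + 1
      centers[placed, ] <- c(x, y)
      mask <- stamp_disk(mask, x, y, offs)
    }
    img <- matrix(0, width, height)
    img[mask] <- 0.90
    if (noise_sd > 0) img <- pmin(pmax(img + rnorm(length(img), 0, noise_sd), 0), 1)
    list(image = img,
         truth = list(mask = mask, centroids = centers, cell_area_px = area,
                      suggested_thresholds = c(0.45, 1),
                      suggested_size_criteria = c(ceiling(area / 2), 4 * area)))
  })
}

#' Simulate a flow-cytometry event table with counting beads
#'
#' A known number of counting beads is spiked into each sample; acquisition
#' recovers a binomial fraction of both beads and cells, so the bead ratio
#' calibrates absolute counts.
#'
#' @param true_cells_per_sample named or unnamed vector of true cell numbers.
#' @param beads_total number of beads added per sample (> 0).
#' @param bead_recovery_fraction acquisition recovery in (0, 1].
#' @param seed integer seed.
#' @return list: `events` (data.frame: sample, cell_events, bead_events,
#'   beads_total_added), `truth` (list: `true_cells`, `recovery`).
#' @export
simulate_flow_events <- function(true_cells_per_sample, beads_total = 10000,
                                 bead_recovery_fraction = 0.3, seed = 1L) {
  if (beads_total <= 0) stop("beads_total must be > 0")
  if (bead_recovery_fraction <= 0 || bead_recovery_fraction > 1)
    stop("bead_recovery_fraction must lie in (0, 1]")
  with_seed(substream_seed(seed, "flow"), {
    n <- length(true_cells_per_sample)
    nm <- names(true_cells_per_sample) %||% sprintf("s%02d", seq_len(n))
    bead_events <- rbinom(n, beads_total, bead_recovery_fraction)
    bad <- which(bead_events == 0)
    while (length(bad) > 0) {
      warning("resampling ", length(bad), " sample(s) with zero bead events (degenerate acquisition)")
      bead_events[bad] <- rbinom(length(bad), beads_total, bead_recovery_fraction)
      bad <- which(bead_events == 0)
    }
    cell_events <- rbinom(n, round(true_cells_per_sample), bead_recovery_fraction)
    list(events = data.frame(sample = nm, cell_events = cell_events,
                             bead_events = bead_events,
                             beads_total_added = beads_total),
         truth = list(true_cells = setNames(round(true_cells_per_sample), nm),
                      recovery = bead_recovery_fraction))
  })
}

# 4PL response: OD = d + (a - d) / (1 + (x / c)^b), b > 0; OD(0) = a.
fourpl <- function(x, a, b, cc, d) d + (a - d) / (1 + (x / cc)^b)

#' Simulate an ELISA plate read from a 4PL standard curve
#'
#' Seven standards plus blank (in duplicate by default) and sample wells, with
#' optical densities generated from the four-parameter logistic curve plus
#' Gaussian noise. Sample true concentrations outside
#' \[min standard / 10, max standard x 10\] are flagged as extrapolation in
#' the truth.
#'
#' @param curve_params list with elements `a` (OD at zero concentration),
#'   `b` (slope, > 0), `c` (midpoint concentration, pg/mL), `d` (OD at
#'   saturation).
#' @param standard_concs exactly 7 positive standard concentrations.
#' @param sample_true_concs named or unnamed vector of true in-well sample
#'   concentrations (pg/mL).
#' @param od_noise_sd Gaussian OD noise sd.
#' @param replicates wells per standard/blank/sample.
#' @param seed integer seed.
#' @return list: `plate` (data.frame: well, role, sample, conc, od), `truth`
#'   (list: `curve_params`, `true_concs`, `extrapolated`).
#' @export
simulate_elisa_plate <- function(curve_params = list(a = 0.04, b = 1.1, c = 250, d = 2.6),
                                 standard_concs = 2000 / 2^(0:6),
                                 sample_true_concs = c(s1 = 80, s2 = 400),
                                 od_noise_sd = 0.01, replicates = 2, seed = 1L) {
  if (length(standard_concs) != 7 || any(standard_concs < 0))
    stop("exactly 7 non-negative standard concentrations are required (plus blank)")
  p <- curve_params
  if (p$a == p$d) stop("curve_params: a and d must differ")
  if (p$b <= 0 || p$c <= 0) stop("curve_params: b and c must be positive")
  with_seed(substream_seed(seed, "elisa"), {
    nm <- names(sample_true_concs) %||%
      sprintf("s%02d", seq_along(sample_true_concs))
    rows <- list()
    add <- function(role, sample, conc) {
      od0 <- fourpl(conc, p$a, p$b, p$c, p$d)
      for (r in seq_len(replicates))
        rows[[length(rows) + 1L]] <<- data.frame(
          role = role, sample = sample, conc = conc,
          od = od0 + if (od_noise_sd > 0) rnorm(1, 0, od_noise_sd) else 0)
    }
    for (cs in sort(standard_concs, decreasing = TRUE)) add("standard", NA, cs)
    add("blank", NA, 0)
    for (i in seq_along(sample_true_concs)) add("sample", nm[i], sample_true_concs[i])
    plate <- do.call(rbind, rows)
    plate$well <- sprintf("w%02d", seq_len(nrow(plate)))
    plate <- plate[, c("well", "role", "sample", "conc", "od")]
    extrap <- sample_true_concs < min(standard_concs) / 10 |
      sample_true_concs > max(standard_concs) * 10
    list(plate = plate,
         truth = list(curve_params = p,
                      true_concs = setNames(sample_true_concs, nm),
                      extrapolated = setNames(extrap, nm)))
  })
}
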