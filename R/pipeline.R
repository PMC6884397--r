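#' Default pipeline configuration
#'
#' Stage selection, generator parameters, DE thresholds per tissue,
#' permutation settings, image thresholds and size criteria, and assay
#' dilution factors, overridable per run (deep-merged over these defaults).
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "de", "permtest", "heatmap", "images", "assays", "stats"),
    seed = 1L,
    output_dir = "dermquant_run",
    simulate = list(n_genes = 2000, n_replicates = 4,
                    days = c("D1", "D2", "D5", "D8"),
                    de_fraction = 0.1, tissue = "skin"),
    de = list(alpha = c(skin = 0.05, spinal_cord = 0.05, tg = 0.1),
              fold_threshold = 2,
              contrast = c("MC903", "EtOH")),
    permtest = list(B = 10000, center = "median", gmt = NULL, day = "D8"),
    images = list(n_images = 3, noise_sd = 0.02,
                  thresholds = c(0.45, 1), size_criteria = NULL),
    assays = list(beads_total = 10000, bead_recovery = 0.3,
                  dilution_factor = 2, od_noise_sd = 0.01),
    stats = list(alpha = 0.05)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

# Polynomial rolling hash over the deparsed config: deterministic
# provenance hash without an extra dependency (stays within 31-bit ints).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

validate_config <- function(cfg) {
  if (any(cfg$de$alpha <= 0 | cfg$de$alpha >= 1))
    stop("config: de$alpha must lie in (0, 1)")
  if (cfg$permtest$B < 1) stop("config: permtest$B must be >= 1")
  if (!is.null(cfg$permtest$gmt) && !file.exists(cfg$permtest$gmt))
    stop("config: permtest$gmt path does not exist: ", cfg$permtest$gmt)
  known <- c("simulate", "de", "permtest", "heatmap", "images", "assays", "stats")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("config: unknown stage(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Run the end-to-end pipeline
#'
#' Executes the selected stages in dependency order (simulate -> de ->
#' permtest -> heatmap; images; assays; stats) and writes a versioned run
#' manifest (config hash, seed, per-stage outputs). Re-running with an
#' identical config and seed reproduces identical CSV outputs. A stage whose
#' prerequisite was neither selected nor previously run fails fast naming
#' the missing dependency.
#'
#' @param config nested list (or path to a YAML file) overriding
#'   [default_config()].
#' @return the manifest (list), invisibly written as JSON to the output
#'   directory.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  validate_config(cfg)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list())
  seed <- cfg$seed
  state <- new.env()

  run_stage <- function(name, deps, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    for (d in deps)
      if (is.null(state[[d]]))
        stop("stage '", name, "' requires stage '", d,
             "' which was not run (dependency error)")
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                           digits = NA)
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    state[[name]] <- res
    manifest$stages[[name]] <<- c(list(status = "ok"), res$meta)
    invisible(res)
  }

  run_stage("simulate", character(0), function() {
    sc <- cfg$simulate
    days <- sc$days
    sims <- lapply(days, function(d) {
      des <- sim_design(
        n_genes = sc$n_genes,
        groups = data.frame(condition = c("MC903", "EtOH"), time = d,
                            n = sc$n_replicates),
        de_fraction = sc$de_fraction, tissue = sc$tissue,
        seed = substream_seed(seed, c("sim", d)))
      simulate_counts(des)
    })
    names(sims) <- days
    files <- character(0)
    for (d in days) {
      ct <- file.path(out, paste0("counts_", d, ".tsv"))
      mt <- file.path(out, paste0("meta_", d, ".csv"))
      tr <- file.path(out, paste0("truth_", d, ".csv"))
      write_count_matrix(sims[[d]]$counts, ct, mt)
      write.csv(data.frame(gene = names(sims[[d]]$truth$true_log2fc),
                           true_log2fc = sims[[d]]$truth$true_log2fc,
                           is_de = sims[[d]]$truth$is_de),
                tr, row.names = FALSE)
      files <- c(files, ct, mt, tr)
    }
    list(sims = sims, meta = list(outputs = files, days = days,
                                  n_genes = sc$n_genes))
  })

  run_stage("de", "simulate", function() {
    sims <- state$simulate$sims
    results <- lapply(names(sims), function(d) {
      cm <- sims[[d]]$counts
      nf <- size_factors(cm)
      disp <- estimate_dispersions(cm, nf)
      nb_wald_test(cm, nf, disp, contrast = cfg$de$contrast)
    })
    names(results) <- names(sims)
    files <- vapply(names(results), function(d) {
      f <- file.path(out, paste0("de_", d, ".csv"))
      write_de_result(results[[d]], f)
      f
    }, "")
    alpha <- unname(cfg$de$alpha[cfg$simulate$tissue] %||% 0.05)
    if (is.na(alpha)) alpha <- 0.05
    n_sig <- vapply(results, function(r)
      length(significant_genes(r, alpha, cfg$de$fold_threshold)), 0L)
    list(results = results,
         meta = list(outputs = unname(files), alpha = alpha,
                     n_significant = as.list(n_sig)))
  })

  run_stage("permtest", "de", function() {
    day <- cfg$permtest$day
    res <- state$de$results[[day]]
    if (is.null(res)) stop("permtest: no DE result for day ", day)
    universe <- setNames(res$log2fc, res$gene)
    groups <- if (!is.null(cfg$permtest$gmt)) read_gmt(cfg$permtest$gmt)
    else {
      # default demo panel: the top-|fc| genes and a random group
      ord <- order(-abs(universe))
      list(gene_group("top_changed", names(universe)[ord[1:20]]),
           gene_group("random_set",
                      names(universe)[substream_seed(seed, "panelpick") %%
                                        (length(universe) - 20) + 1:20]))
    }
    panel <- run_group_panel(
      setNames(list(universe), paste0(cfg$simulate$tissue, ":", day)),
      groups, B = cfg$permtest$B, center = cfg$permtest$center, seed = seed)
    f <- file.path(out, "permutation_panel.csv")
    write.csv(as.data.frame(panel), f, row.names = FALSE)
    fp <- file.path(out, "permutation_panel.png")
    plot_group_panel(panel, fp)
    list(panel = panel, meta = list(outputs = c(f, fp), B = cfg$permtest$B,
                                    groups = vapply(groups, `[[`, "", "name")))
  })

  run_stage("heatmap", "de", function() {
    results <- state$de$results
    alpha <- state$de$meta$alpha %||% 0.05
    genes <- significant_genes(results, alpha = 0.05,
                               fold_threshold = cfg$de$fold_threshold)
    if (length(genes) < 2) {
      warning("heatmap: fewer than 2 selected genes; skipping export")
      return(list(meta = list(outputs = character(0), n_genes = length(genes))))
    }
    fc <- foldchange_matrix(results, genes)
    cl <- hierarchical_cluster(fc)
    fpng <- file.path(out, "heatmap.png")
    fcsv <- file.path(out, "heatmap_ordered.csv")
    heatmap_export(fc, cl$order, fpng, fcsv)
    list(fc = fc, meta = list(outputs = c(fpng, fcsv), n_genes = length(genes)))
  })

  run_stage("images", character(0), function() {
    ic <- cfg$images
    rows <- lapply(seq_len(ic$n_images), function(i) {
      sim <- simulate_innervation_image(noise_sd = ic$noise_sd,
                                        seed = substream_seed(seed, c("img", i)))
      mask <- binarize(max_z_projection(sim$stack),
                       ic$thresholds[1], ic$thresholds[2])
      sec <- simulate_section_image(noise_sd = ic$noise_sd,
                                    seed = substream_seed(seed, c("sec", i)))
      crit <- ic$size_criteria %||% sec$truth$suggested_size_criteria
      cells <- count_cells(binarize(sec$image, ic$thresholds[1],
                                    ic$thresholds[2]), crit,
                           image_id = paste0("sec", i))
      data.frame(image = i,
                 percent_innervation = percent_innervation(mask, min_region_px = 4),
                 truth_percent = 100 * sim$truth$fiber_fraction,
                 cell_count = nrow(cells),
                 truth_cells = nrow(sec$truth$centroids))
    })
    tab <- do.call(rbind, rows)
    f <- file.path(out, "image_quant.csv")
    write.csv(tab, f, row.names = FALSE)
    list(table = tab, meta = list(outputs = f, n_images = ic$n_images))
  })

  run_stage("assays", character(0), function() {
    ac <- cfg$assays
    flow <- simulate_flow_events(c(a = 5000, b = 12000, c = 800),
                                 beads_total = ac$beads_total,
                                 bead_recovery_fraction = ac$bead_recovery,
                                 seed = substream_seed(seed, "flow"))
    flow$events$absolute_count <- absolute_count(
      flow$events$cell_events, flow$events$bead_events,
      flow$events$beads_total_added)
    plate <- simulate_elisa_plate(od_noise_sd = ac$od_noise_sd,
                                  seed = substream_seed(seed, "elisa"))
    q <- quantify_plate(plate$plate, dilution_factor = ac$dilution_factor)
    f1 <- file.path(out, "flow_counts.csv")
    f2 <- file.path(out, "elisa_results.csv")
    write.csv(flow$events, f1, row.names = FALSE)
    write.csv(q$samples, f2, row.names = FALSE)
    list(flow = flow$events, elisa = q,
         meta = list(outputs = c(f1, f2),
                     curve = q$curve[c("a", "b", "c", "d", "rss")]))
  })

  run_stage("stats", character(0), function() {
    # worked statistics on simulated behavior-style data: two controls that
    # should pool, a treatment effect, and the post hoc family
    s <- substream_seed(seed, "stats")
    dat <- with_seed(s, list(
      ctrl_a = rnorm(8, 50, 15), ctrl_b = rnorm(8, 52, 15),
      treat = rnorm(8, 110, 20)))
    pool <- pooling_check(dat$ctrl_a, dat$ctrl_b, alpha = cfg$stats$alpha)
    grp <- if (pool$decision == "pooled")
      list(control = pool$pooled, MC903 = dat$treat)
    else list(ctrl_a = dat$ctrl_a, ctrl_b = dat$ctrl_b, MC903 = dat$treat)
    aw <- anova_one_way(grp)
    ph <- posthoc(grp, family = "tukey")
    f <- file.path(out, "stats_report.json")
    jsonlite::write_json(list(pooling = pool[c("decision", "p")],
                              anova = aw[c("statistic", "df", "p")],
                              posthoc = ph),
                         f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(meta = list(outputs = f, pooling = pool$decision))
  })

  manifest$config <- cfg
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Render a markdown report from a run manifest
#'
#' Summarizes each pipeline stage from the manifest alone (no recomputation):
#' DE counts per threshold, the permutation panel with its B and seed per
#' group, image quantification and assay outputs. Stages that were not run
#' are marked unavailable.
#'
#' @param manifest a manifest list from [run_pipeline()], or a path to a
#'   manifest.json.
#' @param file optional output path for the markdown text.
#' @return the markdown lines, invisibly if `file` is given.
#' @export
make_report <- function(manifest, file = NULL) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  st <- manifest$stages %||% list()
  sec <- function(name, body) {
    c(paste0("## ", name),
      if (is.null(st[[name]])) "_not run_"
      else if (identical(st[[name]]$status, "failed"))
        paste0("**failed**: ", st[[name]]$error)
      else body, "")
  }
  lines <- c(
    "# dermquant pipeline report",
    paste0("config hash: `", manifest$config_hash %||% "?", "`; seed: ",
           manifest$seed %||% "?"), "",
    sec("simulate", paste0("days: ",
                           paste(unlist(st$simulate$days), collapse = ", "),
                           "; genes: ", st$simulate$n_genes)),
    sec("de", c(paste0("alpha: ", st$de$alpha),
                paste0("significant genes per day: ",
                       paste(names(st$de$n_significant), "=",
                             unlist(st$de$n_significant), collapse = ", ")))),
    sec("permtest", c(paste0("B = ", st$permtest$B, "; seed = ",
                             manifest$seed),
                      paste0("groups: ",
                             paste(unlist(st$permtest$groups), collapse = ", ")))),
    sec("heatmap", paste0("genes plotted: ", st$heatmap$n_genes)),
    sec("images", paste0("images quantified: ", st$images$n_images)),
    sec("assays", paste0("4PL curve: a=", signif(as.numeric(st$assays$curve$a), 4),
                         " b=", signif(as.numeric(st$assays$curve$b), 4),
                         " c=", signif(as.numeric(st$assays$curve$c), 4),
                         " d=", signif(as.numeric(st$assays$curve$d), 4))),
    sec("stats", paste0("control pooling: ", st$stats$pooling)))
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}
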