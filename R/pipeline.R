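# End-to-end orchestration: simulate (or read) a tetrad dataset, call events,
# and compute the interference, CO-control and hotspot statistics, writing a
# machine-readable summary.

#' Run the full recombination analysis pipeline
#'
#' Stages: simulate (or load) segregation data, call events, interference
#' statistics, CO-control statistics, hotspot/coldspot detection, and
#' optionally molecular-evolution statistics. All randomness flows from a
#' single seed set at the start of the run; the hotspot permutation stage
#' draws from the same stream.
#'
#' @param config a named list or path to a YAML file. Recognized blocks:
#'   `simulate` (arguments of [sim_config()] except layout, plus `n_meioses`),
#'   `input` (alternatively: `segregation` TSV path + `layout` TSV path),
#'   `merge_dist`, `interference` (list: `bin`), `hotspots` (list: `window`,
#'   `coldspot_window`, `n_perm`, `rank`; omit the block to skip the stage),
#'   `molevol` (list: `fasta` = named character vector/list of codon-alignment
#'   FASTA paths, `focal_set`).
#' @param out_dir output directory (created if missing); set NULL to skip all
#'   file output.
#' @param seed integer seed for the run.
#' @param quiet suppress progress messages.
#' @return An object of class `meiorec_report` (a list with the stage
#'   results and a flat `summary` list), invisibly writes `events.tsv`,
#'   `summary.json`, `coc_curve.tsv`, `interference.tsv`, window BEDs.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  say <- function(...) if (!quiet) message("[meiorec] ", ...)
  set.seed(seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # ---- data ----
  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    n_meioses <- sc$n_meioses %||% 100L
    sc$n_meioses <- NULL
    layout_args <- sc$layout %||% list()
    sc$layout <- NULL
    layout <- stage("simulate", do.call(kl_layout, layout_args))
    cfg <- stage("simulate", do.call(sim_config, c(list(layout = layout), sc)))
    say("simulating ", n_meioses, " meioses")
    pop <- stage("simulate", simulate_population(cfg, n_meioses))
    tetrads <- pop$tetrads
    truth <- pop$truth
  } else if (!is.null(config$segregation)) {
    say("reading ", config$segregation)
    tetrads <- stage("read", read_segregation(config$segregation))
    layout <- stage("read", read_layout(config$layout,
      markers = lapply(tetrads[[1]]$chroms, `[[`, "pos")))
    n_meioses <- length(tetrads)
    cfg <- NULL
  } else {
    stop("config must contain a 'simulate' block or a 'segregation' path")
  }

  # ---- event calling ----
  merge_dist <- config$merge_dist %||% 5000
  say("calling events (merge_dist = ", merge_dist, ")")
  events <- stage("call-events",
                  call_events(tetrads, merge_dist = merge_dist,
                              layout = layout))
  summ <- stage("call-events", summarize_events(events, layout, n_meioses))

  # ---- interference ----
  G <- genome_size(layout)
  bin <- (config$interference %||% list())$bin %||% 25000
  d_bp <- inter_co_distances(events)
  fit <- if (length(d_bp) >= 30) {
    stage("interference", fit_gamma(
      inter_co_distances(events, scale = "cM", genome_size = G,
                         mean_co = summ$mean_co)))
  } else NULL
  coc <- stage("interference",
               coc_curve(events, layout, n_meioses, bin = bin))
  chromint <- suppressWarnings(chromatid_interference(events))

  # ---- CO control ----
  say("crossover control statistics")
  nco_med <- config$nco_tract_median %||%
    (if (!is.null(cfg)) cfg$nco_tract_median else 1200)
  ctrl <- stage("control",
                control_report(events, layout, n_meioses,
                               nco_tract_median = nco_med))

  # ---- hotspots ----
  hots <- colds <- NULL
  if (!identical(config$hotspots, FALSE)) {
    hp <- config$hotspots %||% list()
    say("hotspot permutation test")
    hots <- stage("hotspots", call_hotspots(
      events, layout, window = hp$window %||% 5000,
      n_perm = hp$n_perm %||% 1e5, rank = hp$rank %||% 2000))
    colds <- stage("hotspots", call_coldspots(
      events, layout, window = hp$coldspot_window %||% 20000,
      n_perm = hp$n_perm %||% 1e5, rank = hp$rank %||% 2000))
  }

  # ---- molevol (optional) ----
  mol <- NULL
  if (!is.null(config$molevol)) {
    say("molecular evolution statistics")
    mol <- stage("molevol", {
      fa <- config$molevol$fasta
      per_gene <- lapply(names(fa), function(g) {
        a <- read_codon_alignment(fa[[g]], gene = g)
        dd <- mean_pairwise_dnds(a)
        data.frame(gene = g, dnds = dd$mean_ratio,
                   pi = nucleotide_diversity(a),
                   theta_w = watterson_theta(a))
      })
      tab <- do.call(rbind, per_gene)
      enr <- if (!is.null(config$molevol$focal_set)) {
        median_rank_enrichment(stats::setNames(tab$dnds, tab$gene),
                               config$molevol$focal_set)
      } else NULL
      list(table = tab, enrichment = enr)
    })
  }

  summary <- list(
    seed = seed, n_meioses = n_meioses,
    genome_size_bp = G, n_chromosomes = nrow(layout$chrom),
    median_co = summ$median_co, median_nco = summ$median_nco,
    mean_co = summ$mean_co, mean_nco = summ$mean_nco,
    co_per_chromosome = summ$co_per_chromosome,
    nco_per_chromosome = summ$nco_per_chromosome,
    co_per_mb_total = summ$co_per_mb_total,
    mean_co_nco_ratio = summ$mean_co_nco_ratio,
    frac_co_with_gc = summ$frac_co_with_gc,
    median_co_tract = summ$median_co_tract,
    median_nco_tract = summ$median_nco_tract,
    frac_complex_co = summ$frac_complex_co,
    gamma_shape = if (!is.null(fit)) fit$shape else NA,
    gamma_scale_cm = if (!is.null(fit)) fit$scale else NA,
    median_inter_co_cm = if (!is.null(fit)) fit$median else NA,
    ks_p_vs_shape1 = if (!is.null(fit)) fit$ks_p else NA,
    homeostasis_r = ctrl$homeostasis$r,
    homeostasis_p = ctrl$homeostasis$p,
    homeostasis_r_corrected = ctrl$homeostasis_corrected$r,
    dispersion_fisher_p = ctrl$dispersion$fisher_p,
    n_underdispersed = sum(ctrl$dispersion$table$underdispersed),
    pct_meioses_e0 = ctrl$e0$pct_ge1,
    pct_meioses_e0_gt1 = ctrl$e0$pct_gt1,
    expected_e0_pct = ctrl$expected_e0_pct,
    expected_e0_pct_uniform = ctrl$expected_e0_pct_uniform,
    chromatid_interference_p = chromint$p,
    hotspot_threshold = if (!is.null(hots)) hots$threshold else NA,
    n_hotspot_windows = if (!is.null(hots)) nrow(hots$windows) else NA,
    coldspot_threshold = if (!is.null(colds)) colds$threshold else NA,
    n_coldspot_windows = if (!is.null(colds)) nrow(colds$windows) else NA
  )

  report <- structure(list(
    summary = summary, events = events, event_summary = summ,
    interference = fit, coc = coc, chromatid_interference = chromint,
    control = ctrl, hotspots = hots, coldspots = colds, molevol = mol,
    truth = truth, layout = layout), class = "meiorec_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(events, file.path(out_dir, "events.tsv"))
    utils::write.table(coc, file.path(out_dir, "coc_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(hots)) {
      write_windows(hots$windows, file.path(out_dir, "hotspots.bed"))
      write_windows(colds$windows, file.path(out_dir, "coldspots.bed"))
    }
    if (!is.null(mol)) {
      utils::write.table(mol$table, file.path(out_dir, "molevol.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    say("outputs written to ", out_dir)
  }
  invisible(report)
}

#' @export
print.meiorec_report <- function(x, ...) {
  cat("<meiorec_report> seed", x$summary$seed, "-", x$summary$n_meioses,
      "meioses\n")
  print(x$event_summary)
  if (!is.null(x$interference)) print(x$interference)
  print(x$control)
  if (!is.null(x$hotspots)) {
    cat(sprintf("  hotspots: threshold %d, %d windows; coldspots: threshold %d, %d windows\n",
                x$hotspots$threshold, nrow(x$hotspots$windows),
                x$coldspots$threshold, nrow(x$coldspots$windows)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
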