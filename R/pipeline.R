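#' Run configuration for the end-to-end pipeline
#'
#' Bundles the experiment design, population and blot-panel settings, seeds
#' and per-stage toggles for a reproducible run. The default configuration is
#' a demonstration dataset: the five shipped KRAS lines, two replicate
#' experiments of 50 cells each per line (500 cells total), plus a four-
#' replicate synthetic blot panel.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; all stage seeds derive from it.
#' @param design An [experiment_design()].
#' @param n_cells_per_experiment,n_experiments Cells per replicate experiment
#'   and replicate experiments per line.
#' @param lines Character vector of line names (must exist in the isoform
#'   parameter set).
#' @param responder_fraction,noise_cv Population settings per
#'   [default_population_spec()].
#' @param blot_reps,blot_cv Blot panel replicates and measurement CV.
#' @param n_perm Permutations for the PLSR null bounds stage.
#' @param stages Named logical vector enabling stages `simulate`, `quantify`,
#'   `metrics`, `model`, `phosphatase`, `stats`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, design = experiment_design(),
                       n_cells_per_experiment = 50, n_experiments = 2,
                       lines = names(default_isoform_params()),
                       responder_fraction = 0.6, noise_cv = 0.02,
                       blot_reps = 4, blot_cv = 0.1, n_perm = 200,
                       stages = c(simulate = TRUE, quantify = TRUE,
                                  metrics = TRUE, model = TRUE,
                                  phosphatase = TRUE, stats = TRUE)) {
  validate_design(design)
  all_stages <- c("simulate", "quantify", "metrics", "model",
                  "phosphatase", "stats")
  st <- setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  structure(list(out_dir = out_dir, seed = as.integer(seed), design = design,
                 n_cells_per_experiment = n_cells_per_experiment,
                 n_experiments = n_experiments, lines = lines,
                 responder_fraction = responder_fraction, noise_cv = noise_cv,
                 blot_reps = blot_reps, blot_cv = blot_cv, n_perm = n_perm,
                 stages = st),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- config[setdiff(names(config), "out_dir")]
  flat$design <- unclass(flat$design)
  yaml::write_yaml(flat, tmp)
  unname(tools::md5sum(tmp))
}

#' Write or read a pipeline CSV with a provenance header
#'
#' Stage outputs carry a comment header recording the producing stage, the
#' package version, the seed and the configuration hash, so every table is
#' traceable to its run.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @param stage Stage name.
#' @param seed Seed used by the stage.
#' @param hash Configuration hash.
#' @return `write_stage_csv()` returns `path` invisibly; `read_stage_csv()`
#'   the data frame (header lines skipped).
#' @export
write_stage_csv <- function(df, path, stage = "manual", seed = NA,
                            hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s", stage), con)
  writeLines(sprintf("# package: erkrescale %s",
                     as.character(utils::packageVersion("erkrescale"))), con)
  writeLines(sprintf("# seed: %s", seed), con)
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_csv
#' @export
read_stage_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full simulate-quantify-analyze pipeline
#'
#' Executes the enabled stages in order: `simulate` (single-cell populations
#' per line and experiment, raw intensities, and a synthetic blot panel),
#' `quantify` (ratiometric correction and calibration to activity ratios),
#' `metrics` (QC and per-cell descriptors), `model` (internal-factors panel
#' prediction and model-measurement discrepancy), `phosphatase` (per-cell
#' decay fits and group summaries), and `stats` (per-line baseline
#' comparisons against the reference line with BH FDR, and PLSR of the blot
#' panel with permutation-null bounds). Every output CSV carries a
#' provenance header; a manifest lists seeds, stage status and output
#' hashes. A stage whose inputs are missing (because an upstream stage was
#' disabled and its outputs absent) halts the run with the failing stage
#' named; partial outputs are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  check_that(inherits(config, "run_config"), "run_config", "not a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  pth <- function(f) file.path(config$out_dir, f)
  manifest <- list(package = as.character(utils::packageVersion("erkrescale")),
                   seed = config$seed, config_hash = hash, stages = list())
  curve <- default_calibration_curve()
  spectral <- default_spectral_config()
  seeds <- derive_seeds(config$seed,
                        length(config$lines) * config$n_experiments + 1L)
  log_counts <- list()

  require_input <- function(file, stage, producer) {
    if (!file.exists(pth(file)))
      stop(sprintf("stage '%s' failed: missing input %s (enable stage '%s')",
                   stage, file, producer), call. = FALSE)
  }

  if (config$stages[["simulate"]]) {
    iso <- default_isoform_params()
    missing_lines <- setdiff(config$lines, names(iso))
    check_that(length(missing_lines) == 0, "run_config",
               paste("unknown lines:", paste(missing_lines, collapse = ", ")))
    traces <- list(); truths <- list()
    idx <- 0L
    for (line in config$lines) {
      for (e in seq_len(config$n_experiments)) {
        idx <- idx + 1L
        spec <- default_population_spec(
          n_cells = config$n_cells_per_experiment,
          responder_fraction = config$responder_fraction,
          noise_cv = config$noise_cv, seed = seeds[idx])
        sim <- simulate_population(spec, config$design, raw = TRUE,
                                   curve = curve, spectral = spectral,
                                   experiment_id = sprintf("%s_rep%d", line, e))
        sim$traces$cell_id <- paste(line, e, sim$traces$cell_id, sep = "_")
        sim$truth$cell_id <- paste(line, e, sim$truth$cell_id, sep = "_")
        sim$traces$cell_line <- line
        sim$truth$cell_line <- line
        traces[[idx]] <- sim$traces
        truths[[idx]] <- sim$truth
      }
    }
    traces <- do.call(rbind, traces)
    truths <- do.call(rbind, truths)
    write_stage_csv(traces[c("cell_id", "experiment_id", "cell_line",
                             "time_min", "cfp", "yfp")],
                    pth("traces_raw.csv"), "simulate", config$seed, hash)
    write_stage_csv(truths, pth("ground_truth.csv"), "simulate",
                    config$seed, hash)
    blot_seed <- seeds[length(seeds)]
    bspec <- default_blot_panel_spec(n_reps = config$blot_reps,
                                     cv = config$blot_cv, seed = blot_seed)
    bspec$lines <- bspec$lines[intersect(names(bspec$lines), config$lines)]
    panel <- simulate_blot_panel(bspec)
    write_stage_csv(panel, pth("blot_panel.csv"), "simulate",
                    blot_seed, hash)
    log_counts$cells_simulated <- length(unique(traces$cell_id))
    manifest$stages$simulate <- "ok"
  }

  if (config$stages[["quantify"]]) {
    require_input("traces_raw.csv", "quantify", "simulate")
    raw <- read_stage_csv(pth("traces_raw.csv"))
    rho <- quantify_traces(raw, curve, spectral)
    write_stage_csv(rho, pth("rho.csv"), "quantify", config$seed, hash)
    log_counts$clip_report <- attr(rho, "clip_report")
    manifest$stages$quantify <- "ok"
  }

  if (config$stages[["metrics"]]) {
    require_input("rho.csv", "metrics", "quantify")
    rho <- read_stage_csv(pth("rho.csv"))
    qc <- qc_filter(rho)
    cell_lines <- vapply(split(rho$cell_line, rho$cell_id),
                         function(x) x[1], character(1))
    metrics <- compute_trace_metrics(qc$traces, config$design)
    metrics$cell_line <- cell_lines[metrics$cell_id]
    write_stage_csv(metrics, pth("metrics.csv"), "metrics", config$seed, hash)
    jsonlite::write_json(
      list(qc = qc$report, outliers = attr(metrics, "outlier_report")),
      pth("qc_report.json"), auto_unbox = TRUE, pretty = TRUE)
    log_counts$cells_after_qc <- qc$report$n_kept
    manifest$stages$metrics <- "ok"
  }

  if (config$stages[["model"]]) {
    require_input("blot_panel.csv", "model", "simulate")
    iso <- default_isoform_params()[config$lines]
    predicted <- predict_panel(iso, abundances(),
                               rates = default_cascade_rates(),
                               reference_line = config$lines[1])
    write_stage_csv(predicted, pth("model_panel.csv"), "model",
                    config$seed, hash)
    blot <- read_stage_csv(pth("blot_panel.csv"))
    measured <- data.frame(
      line = blot$line,
      condition = ifelse(blot$treatment == "baseline", "baseline", "stimulated"),
      pperk_rel = blot$pperk_rel, stringsAsFactors = FALSE)
    disc <- model_measurement_discrepancy(predicted, measured,
                                          reference_line = config$lines[1])
    write_stage_csv(disc, pth("discrepancy.csv"), "model", config$seed, hash)
    manifest$stages$model <- "ok"
  }

  if (config$stages[["phosphatase"]]) {
    require_input("rho.csv", "phosphatase", "quantify")
    rho <- read_stage_csv(pth("rho.csv"))
    fits <- fit_population_decays(rho, config$design)
    write_stage_csv(fits, pth("decays.csv"), "phosphatase", config$seed, hash)
    summ <- group_decay_summary(fits, group_cols = "cell_line")
    write_stage_csv(summ, pth("decay_summary.csv"), "phosphatase",
                    config$seed, hash)
    log_counts$decay_unconverged <- sum(!fits$converged)
    manifest$stages$phosphatase <- "ok"
  }

  if (config$stages[["stats"]]) {
    require_input("metrics.csv", "stats", "metrics")
    require_input("blot_panel.csv", "stats", "simulate")
    metrics <- read_stage_csv(pth("metrics.csv"))
    ref <- config$lines[1]
    others <- setdiff(unique(metrics$cell_line), ref)
    tests <- lapply(others, function(line) {
      a <- metrics[metrics$cell_line == line, c("baseline", "experiment_id")]
      b <- metrics[metrics$cell_line == ref, c("baseline", "experiment_id")]
      names(a)[1] <- names(b)[1] <- "value"
      ht <- hierarchical_ttest(a, b)
      data.frame(line = line, reference = ref, t = ht$t, df = ht$df,
                 p = ht$p, stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, tests)
    fdr <- bh_fdr(tests$p)
    tests$p_adjusted <- fdr$adjusted
    tests$significant <- fdr$significant
    write_stage_csv(tests, pth("stats_baseline.csv"), "stats",
                    config$seed, hash)
    blot <- read_stage_csv(pth("blot_panel.csv"))
    X <- data.frame(EGF = as.numeric(blot$stimulated),
                    RAS = blot$RAS_t, BRAF = blot$BRAF_t, CRAF = blot$CRAF_t,
                    MEK = blot$MEK_t, ERK = blot$ERK_t)
    pf <- plsr_fit(X, blot$pperk_rel)
    nb <- plsr_null_bounds(X, blot$pperk_rel, n_perm = config$n_perm,
                           seed = config$seed)
    plsr_out <- data.frame(predictor = names(pf$weights),
                           weight = unname(pf$weights),
                           lower = nb$bounds$lower, upper = nb$bounds$upper,
                           significant = unname(nb$significant),
                           stringsAsFactors = FALSE)
    attr(plsr_out, "variance_explained") <- pf$variance_explained
    write_stage_csv(plsr_out, pth("plsr_weights.csv"), "stats",
                    config$seed, hash)
    jsonlite::write_json(
      list(variance_explained_pct = pf$variance_explained),
      pth("plsr_variance.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$stats <- "ok"
  }

  manifest$counts <- log_counts
  outs <- list.files(config$out_dir, pattern = "\\.(csv|json)$")
  outs <- setdiff(outs, "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(config$out_dir, outs)))
  names(manifest$outputs) <- outs
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
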