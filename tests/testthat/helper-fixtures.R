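# Shared fixtures: a default design and small constructed traces.

fix_design <- experiment_design()

# A constant trace over the full design grid (value v), as time/value vectors.
const_trace <- function(design = fix_design, v = 1) {
  tt <- seq(design$t_start, design$t_end, by = design$sampling_interval)
  list(time = tt, value = rep(v, length(tt)))
}

# Long-format traces data frame from a list of value vectors keyed by cell id.
as_long_traces <- function(values_by_cell, design = fix_design,
                           experiment_id = "exp1") {
  tt <- seq(design$t_start, design$t_end, by = design$sampling_interval)
  do.call(rbind, lapply(names(values_by_cell), function(id) {
    data.frame(cell_id = id, experiment_id = experiment_id, time_min = tt,
               rho = values_by_cell[[id]], stringsAsFactors = FALSE)
  }))
}

# Acceptance-condition population: responder fraction 0.6, noise CV 2%, and
# stimulated amplitudes of at least 10% of the population full scale (the
# maximum noiseless peak activity under the default distributions).
acceptance_population_spec <- function(n_cells, seed,
                                       responder_fraction = 0.6,
                                       noise_cv = 0.02) {
  spec0 <- default_population_spec(n_cells, responder_fraction,
                                   noise_cv = noise_cv, seed = seed)
  fs <- max(draw_ground_truths(spec0)$peak_rho)
  amp <- spec0$dists$amplitude
  amp$min <- max(amp$min, 0.1 * fs)
  population_spec(n_cells, responder_fraction,
                  dists = list(amplitude = amp,
                               noise_cv = list(dist = "fixed", value = noise_cv)),
                  seed = seed)
}

# Simulate -> forward optical model -> quantify, returning truth and rho traces.
simulate_and_quantify <- function(spec, design = fix_design) {
  sim <- simulate_population(spec, design, raw = TRUE)
  rho <- quantify_traces(
    sim$traces[c("cell_id", "experiment_id", "time_min", "cfp", "yfp")],
    default_calibration_curve(), default_spectral_config())
  list(truth = sim$truth, rho = rho, rho_true = sim$traces)
}
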