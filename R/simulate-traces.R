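#' Ground-truth kinetic parameters for one simulated cell
#'
#' The simulator's per-cell truth: baseline ERK:phosphatase ratio, a
#' responder flag, the stimulated response shape (peak level, rise and
#' adaptation time constants, steady-state level), spontaneous baseline pulse
#' statistics, the post-MEKi exponential decay constant, and the measurement
#' noise CV applied at the raw-intensity stage.
#'
#' @param baseline_rho Baseline activity ratio (dimensionless, `>= 0`).
#' @param responder Logical: does the cell respond to the stimulus?
#' @param peak_rho Peak activity for responders (`>= baseline_rho`).
#' @param rise_tau,adapt_tau Rise and adaptation time constants (min); the
#'   response is a difference of exponentials peaking about
#'   `log(adapt_tau/rise_tau) * adapt_tau * rise_tau / (adapt_tau - rise_tau)`
#'   minutes after the stimulus.
#' @param steady_rho Post-attenuation steady-state activity.
#' @param pulse_rate Baseline pulse rate (events/hour).
#' @param pulse_amp,pulse_duration Rectangular pulse amplitude (activity
#'   units) and duration (min).
#' @param meki_decay_b Post-MEKi exponential decay constant (1/min, `> 0`).
#' @param noise_cv Multiplicative lognormal CV applied to raw intensities.
#' @return An object of class `cell_ground_truth`.
#' @export
cell_ground_truth <- function(baseline_rho = 0.35, responder = TRUE,
                              peak_rho = 1.05, rise_tau = 6, adapt_tau = 45,
                              steady_rho = 0.55, pulse_rate = 1,
                              pulse_amp = 0.1, pulse_duration = 9,
                              meki_decay_b = 0.1, noise_cv = 0.02) {
  tr <- structure(
    list(baseline_rho = baseline_rho, responder = isTRUE(responder),
         peak_rho = peak_rho, rise_tau = rise_tau, adapt_tau = adapt_tau,
         steady_rho = steady_rho, pulse_rate = pulse_rate,
         pulse_amp = pulse_amp, pulse_duration = pulse_duration,
         meki_decay_b = meki_decay_b, noise_cv = noise_cv),
    class = "cell_ground_truth")
  validate_truth(tr)
  tr
}

validate_truth <- function(tr) {
  check_that(inherits(tr, "cell_ground_truth"), "cell_ground_truth",
             "not a cell_ground_truth")
  num <- setdiff(names(tr), "responder")
  for (f in num)
    check_that(is_number(tr[[f]]), "cell_ground_truth",
               paste(f, "must be a finite number"))
  for (f in num)
    check_that(tr[[f]] >= 0, "cell_ground_truth", paste(f, "must be >= 0"))
  check_that(tr$meki_decay_b > 0, "cell_ground_truth", "meki_decay_b must be > 0")
  check_that(tr$rise_tau > 0 && tr$adapt_tau > 0, "cell_ground_truth",
             "rise_tau and adapt_tau must be > 0")
  if (tr$responder) {
    check_that(tr$peak_rho >= tr$baseline_rho, "cell_ground_truth",
               "peak_rho must be >= baseline_rho for a responder")
    check_that(tr$peak_rho >= tr$steady_rho, "cell_ground_truth",
               "peak_rho must be >= steady_rho for a responder")
  }
  invisible(tr)
}

# Difference-of-exponentials response shape, s = minutes after stimulus.
# Handles the rise_tau == adapt_tau limit (gamma-like shape).
resp_shape <- function(s, rise_tau, adapt_tau) {
  if (abs(adapt_tau - rise_tau) < 1e-9) {
    (s / rise_tau) * exp(1 - s / rise_tau)  # normalized to max 1 at s = tau
  } else {
    exp(-s / adapt_tau) - exp(-s / rise_tau)
  }
}

resp_shape_argmax <- function(rise_tau, adapt_tau) {
  if (abs(adapt_tau - rise_tau) < 1e-9) return(rise_tau)
  log(adapt_tau / rise_tau) * adapt_tau * rise_tau / (adapt_tau - rise_tau)
}

#' Time constants placing the response peak at a given delay
#'
#' Given a rise time constant, finds the adaptation time constant such that
#' the difference-of-exponentials response peaks `peak_time` minutes after the
#' stimulus. Used to encode the default kinetics (peak about 15 min after
#' stimulation, attenuation over 1.5 to 2 h).
#'
#' @param peak_time Target peak delay (min).
#' @param rise_tau Rise time constant (min), `< peak_time`.
#' @return The adaptation time constant (min).
#' @export
adapt_tau_for_peak <- function(peak_time, rise_tau = 6) {
  check_that(peak_time > rise_tau, "kinetics",
             "peak_time must exceed rise_tau")
  f <- function(a) resp_shape_argmax(rise_tau, a) - peak_time
  stats::uniroot(f, c(rise_tau * 1.0001, 1e5))$root
}

#' Simulate one cell's activity-ratio time series
#'
#' Piecewise kinetic trace on the design's time grid: before the stimulus the
#' cell sits at its baseline activity plus Poisson-timed rectangular pulses;
#' at the stimulus a responder rises toward its peak with time constant
#' `rise_tau` and relaxes toward its steady state with `adapt_tau`
#' (difference-of-exponentials, scaled so the maximum equals `peak_rho`);
#' after MEK inhibition the activity decays exponentially with the cell's
#' decay constant from its value at the moment of inhibition. Non-responders
#' skip the stimulated transient but still decay after MEKi (their baseline
#' activity is MEK dependent). Deterministic given `seed` (only the pulse
#' process is random).
#'
#' @param design An [experiment_design()].
#' @param truth A [cell_ground_truth()].
#' @param seed Integer seed for the pulse process (optional).
#' @return Data frame with columns `time_min` and `rho`.
#' @export
simulate_rho_trace <- function(design, truth, seed = NULL) {
  validate_design(design)
  validate_truth(truth)
  times <- design_times(design)
  rho <- rep(truth$baseline_rho, length(times))

  pre <- times < design$t_stim
  if (truth$pulse_rate > 0 && truth$pulse_amp > 0 && truth$pulse_duration > 0) {
    pulse_add <- with_opt_seed(seed, function() {
      span <- design$t_stim - design$t_start
      n_pulse <- rpois(1, truth$pulse_rate * span / 60)
      add <- numeric(length(times))
      if (n_pulse > 0) {
        starts <- runif(n_pulse, design$t_start, design$t_stim)
        for (s0 in starts) {
          on <- pre & times >= s0 & times < s0 + truth$pulse_duration
          add[on] <- add[on] + truth$pulse_amp
        }
      }
      add
    })
    rho <- rho + pulse_add
  }

  resp_at <- function(t) {
    # deterministic stimulated-response envelope at absolute time t
    s <- t - design$t_stim
    if (!truth$responder) return(rep(truth$baseline_rho, length(s)))
    g <- resp_shape(s, truth$rise_tau, truth$adapt_tau)
    s_star <- resp_shape_argmax(truth$rise_tau, truth$adapt_tau)
    g_star <- resp_shape(s_star, truth$rise_tau, truth$adapt_tau)
    drift <- (truth$steady_rho - truth$baseline_rho) * (1 - exp(-s / truth$adapt_tau))
    amp <- (truth$peak_rho - truth$baseline_rho -
              (truth$steady_rho - truth$baseline_rho) * (1 - exp(-s_star / truth$adapt_tau))) / g_star
    truth$baseline_rho + amp * g + drift
  }

  mid <- times >= design$t_stim & times < design$t_meki
  if (any(mid)) rho[mid] <- resp_at(times[mid])

  post <- times >= design$t_meki
  if (any(post)) {
    rho_meki <- resp_at(design$t_meki)
    rho[post] <- rho_meki * exp(-truth$meki_decay_b * (times[post] - design$t_meki))
  }
  data.frame(time_min = times, rho = rho)
}

#' Forward model: raw channel intensities from an activity trace
#'
#' Composes the reporter model forward: `p = rho / (1 + rho)`,
#' `E = intercept + slope * p`, `CFP/YFP = R_P * (1 - E)`. The yellow channel
#' is a per-cell constant brightness times multiplicative lognormal noise; the
#' cyan channel is the ratio times the (noiseless) yellow level times an
#' independent lognormal factor, so the CFP/YFP ratio carries a single
#' lognormal error with the stated CV. Quantifying the output with the same
#' curve and spectral configuration recovers rho up to that noise.
#'
#' @param rho_trace Data frame with `time_min` and `rho` (from
#'   [simulate_rho_trace()]).
#' @param curve A [calibration_curve()].
#' @param spectral A [spectral_config()] (or give `R_P`).
#' @param noise_cv Lognormal CV of each channel's multiplicative noise.
#' @param seed Integer seed (optional).
#' @param brightness Per-cell yellow-channel brightness (arbitrary units).
#' @param R_P Optional precomputed power ratio.
#' @return Data frame with columns `time_min`, `cfp`, `yfp`.
#' @export
rho_to_raw_intensities <- function(rho_trace, curve, spectral = NULL,
                                   noise_cv = 0, seed = NULL,
                                   brightness = 1000, R_P = NULL) {
  validate_curve(curve)
  check_that(all(is.finite(rho_trace$rho) & rho_trace$rho >= 0),
             "rho trace", "rho must be finite and >= 0")
  check_that(noise_cv >= 0, "rho_to_raw_intensities", "noise_cv must be >= 0")
  if (is.null(R_P)) R_P <- power_ratio(spectral)
  p <- activity_to_phospho(rho_trace$rho)
  E <- curve$intercept + curve$slope * p
  if (any(E <= 0 | E >= 1))
    fail_invariant("forward model", "corrected signal outside (0, 1): calibration range exceeded")
  ratio <- R_P * (1 - E)
  n <- nrow(rho_trace)
  noise <- with_opt_seed(seed, function()
    list(y = lognormal_noise(n, noise_cv), c = lognormal_noise(n, noise_cv)))
  yfp <- brightness * noise$y
  cfp <- ratio * brightness * noise$c
  data.frame(time_min = rho_trace$time_min, cfp = cfp, yfp = yfp)
}

#' Specification of a simulated single-cell population
#'
#' Describes how per-cell ground truths are drawn: number of cells, responder
#' probability, and a distribution for each kinetic field. Distributions are
#' given as lists: `list(dist = "lognormal", meanlog=, sdlog=)`,
#' `list(dist = "normal", mean=, sd=)` (truncated at 0),
#' `list(dist = "uniform", min=, max=)`, or `list(dist = "fixed", value=)`;
#' any distribution may carry `min`/`max` truncation bounds.
#'
#' Responder peaks are parameterized through an `amplitude` distribution
#' (`peak_rho = baseline_rho + amplitude`) and a `steady_frac` distribution
#' (`steady_rho = baseline_rho + steady_frac * amplitude`), which keeps the
#' per-cell invariants satisfied by construction.
#'
#' @param n_cells Number of cells (`>= 1`).
#' @param responder_fraction Probability a cell responds, in `[0, 1]`.
#' @param dists Named list of distribution specs for `baseline_rho`,
#'   `amplitude`, `rise_tau`, `adapt_tau`, `steady_frac`, `pulse_rate`,
#'   `pulse_amp`, `pulse_duration`, `meki_decay_b`, `noise_cv`; missing
#'   entries take the defaults of [default_population_spec()].
#' @param seed Integer master seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells, responder_fraction = 0.6,
                            dists = list(), seed = 1L) {
  check_that(is_number(n_cells) && n_cells >= 1, "population_spec",
             "n_cells must be >= 1")
  check_that(is_number(responder_fraction) &&
               responder_fraction >= 0 && responder_fraction <= 1,
             "population_spec", "responder_fraction must be in [0, 1]")
  defaults <- default_truth_dists()
  unknown <- setdiff(names(dists), names(defaults))
  check_that(length(unknown) == 0, "population_spec",
             paste("unknown distribution fields:", paste(unknown, collapse = ", ")))
  dists <- utils::modifyList(defaults, dists)
  structure(list(n_cells = as.integer(n_cells),
                 responder_fraction = responder_fraction,
                 dists = dists, seed = as.integer(seed)),
            class = "population_spec")
}

default_truth_dists <- function() {
  list(
    baseline_rho = list(dist = "lognormal", meanlog = log(0.35), sdlog = 0.25),
    amplitude    = list(dist = "lognormal", meanlog = log(0.7), sdlog = 0.35,
                        min = 0.2),
    rise_tau     = list(dist = "fixed", value = 6),
    adapt_tau    = list(dist = "fixed", value = 45),
    steady_frac  = list(dist = "uniform", min = 0.15, max = 0.35),
    pulse_rate   = list(dist = "fixed", value = 1),
    pulse_amp    = list(dist = "fixed", value = 0.1),
    pulse_duration = list(dist = "fixed", value = 9),
    meki_decay_b = list(dist = "lognormal", meanlog = log(0.1), sdlog = 0.4,
                        min = 0.02, max = 0.3),
    noise_cv     = list(dist = "fixed", value = 0.02))
}

#' Default population specification
#'
#' The study-condition defaults used throughout the tests and examples: a
#' responder/non-responder mixture with moderately heterogeneous baseline
#' activity, stimulated amplitudes well above the 10%-of-full-scale floor,
#' response kinetics peaking about 15 min post-stimulus with attenuation over
#' roughly 2 h, sporadic baseline pulses, and 2% multiplicative measurement
#' noise.
#'
#' @inheritParams population_spec
#' @param noise_cv Measurement noise CV applied at the intensity stage.
#' @return A [population_spec()].
#' @export
default_population_spec <- function(n_cells = 500, responder_fraction = 0.6,
                                    noise_cv = 0.02, seed = 1L) {
  population_spec(n_cells, responder_fraction,
                  dists = list(noise_cv = list(dist = "fixed", value = noise_cv)),
                  seed = seed)
}

draw_dist <- function(spec, n) {
  x <- switch(spec$dist,
    fixed = rep(spec$value, n),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    normal = rnorm(n, spec$mean, spec$sd),
    uniform = runif(n, spec$min, spec$max),
    fail_invariant("distribution", paste("unknown family:", spec$dist)))
  if (identical(spec$dist, "normal")) x <- pmax(x, 0)
  if (!identical(spec$dist, "uniform")) {
    if (!is.null(spec$min)) x <- pmax(x, spec$min)
    if (!is.null(spec$max)) x <- pmin(x, spec$max)
  }
  x
}

#' Draw per-cell ground truths from a population specification
#'
#' @param spec A [population_spec()].
#' @return Data frame, one row per cell, with `cell_id`, `responder`, and all
#'   [cell_ground_truth()] fields.
#' @export
draw_ground_truths <- function(spec) {
  check_that(inherits(spec, "population_spec"), "population_spec",
             "not a population_spec")
  n <- spec$n_cells
  withr::with_seed(spec$seed, {
    responder <- runif(n) < spec$responder_fraction
    d <- lapply(spec$dists, draw_dist, n = n)
    amplitude <- ifelse(responder, d$amplitude, 0)
    data.frame(
      cell_id = sprintf("cell%04d", seq_len(n)),
      responder = responder,
      baseline_rho = d$baseline_rho,
      peak_rho = d$baseline_rho + amplitude,
      rise_tau = d$rise_tau,
      adapt_tau = d$adapt_tau,
      steady_rho = d$baseline_rho + d$steady_frac * amplitude,
      pulse_rate = d$pulse_rate,
      pulse_amp = d$pulse_amp,
      pulse_duration = d$pulse_duration,
      meki_decay_b = d$meki_decay_b,
      noise_cv = d$noise_cv,
      stringsAsFactors = FALSE)
  })
}

truth_from_row <- function(row) {
  cell_ground_truth(
    baseline_rho = row$baseline_rho, responder = row$responder,
    peak_rho = row$peak_rho, rise_tau = row$rise_tau,
    adapt_tau = row$adapt_tau, steady_rho = row$steady_rho,
    pulse_rate = row$pulse_rate, pulse_amp = row$pulse_amp,
    pulse_duration = row$pulse_duration, meki_decay_b = row$meki_decay_b,
    noise_cv = row$noise_cv)
}

#' Simulate a population of single-cell traces with known ground truth
#'
#' Draws per-cell truths from the population specification and simulates each
#' cell's activity trace; optionally pushes every trace through the forward
#' optical model to raw two-channel intensities. Fully reproducible from the
#' spec's master seed.
#'
#' @param spec A [population_spec()].
#' @param design An [experiment_design()].
#' @param raw If `TRUE`, also emit raw `cfp`/`yfp` intensities via
#'   [rho_to_raw_intensities()] using `curve`/`spectral`.
#' @param curve,spectral Calibration curve and spectral configuration for the
#'   forward model (defaults: the package defaults).
#' @param experiment_id Label recorded on every row.
#' @return List with `traces` (long data frame: `cell_id`, `experiment_id`,
#'   `time_min`, `rho` and, when `raw`, `cfp`, `yfp`) and `truth` (one row per
#'   cell).
#' @export
simulate_population <- function(spec, design, raw = FALSE,
                                curve = default_calibration_curve(),
                                spectral = default_spectral_config(),
                                experiment_id = "sim") {
  validate_design(design)
  truth <- draw_ground_truths(spec)
  seeds <- derive_seeds(spec$seed, 2L * nrow(truth))
  R_P <- if (raw) power_ratio(spectral) else NULL
  traces <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- simulate_rho_trace(design, truth_from_row(truth[i, ]), seed = seeds[2 * i - 1])
    out <- data.frame(cell_id = truth$cell_id[i], experiment_id = experiment_id,
                      time_min = tr$time_min, rho = tr$rho,
                      stringsAsFactors = FALSE)
    if (raw) {
      rawtr <- rho_to_raw_intensities(tr, curve, noise_cv = truth$noise_cv[i],
                                      seed = seeds[2 * i], R_P = R_P)
      out$cfp <- rawtr$cfp
      out$yfp <- rawtr$yfp
    }
    traces[[i]] <- out
  }
  traces <- do.call(rbind, traces)
  truth$experiment_id <- experiment_id
  list(traces = traces, truth = truth)
}
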