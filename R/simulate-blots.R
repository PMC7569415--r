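#' Specification of a synthetic condition-level immunoblot panel
#'
#' Describes a panel of cell lines measured at baseline, peak (15 min) and
#' steady state (2 h) after stimulation, with replicate immunoblot
#' measurements carrying multiplicative lognormal noise. The noiseless mean
#' of fractional ppERK for each line and condition is the internal-factors
#' model prediction ([internal_model_state()]); an optional per-treatment
#' `external_scaling` multiplies the predicted fraction before noise, which
#' plants a known condition-dependent external factor for recovery tests.
#'
#' @param lines Named list: per line a list with `params`
#'   ([isoform_params()]) and `abund` ([abundances()]).
#' @param rates A [cascade_rates()].
#' @param treatments Character vector of treatments; `"baseline"` uses the
#'   unstimulated model state, anything else the stimulated state.
#' @param external_scaling Named numeric: multiplicative factor on the
#'   predicted ppERK fraction per treatment (default all 1).
#' @param n_reps Replicates per line and treatment, `>= 1`.
#' @param cv Lognormal measurement CV, `>= 0`.
#' @param seed Integer seed.
#' @return An object of class `blot_panel_spec`.
#' @export
blot_panel_spec <- function(lines, rates = cascade_rates(),
                            treatments = c("baseline", "peak_15min", "steady_2h"),
                            external_scaling = NULL,
                            n_reps = 4, cv = 0.1, seed = 1L) {
  check_that(length(lines) >= 1 && !is.null(names(lines)), "blot_panel_spec",
             "lines must be a named list")
  for (nm in names(lines)) {
    validate_isoform(lines[[nm]]$params)
    check_that(inherits(lines[[nm]]$abund, "abundances"), "blot_panel_spec",
               paste("line", nm, "needs an abundances object"))
  }
  if (is.null(external_scaling))
    external_scaling <- setNames(rep(1, length(treatments)), treatments)
  check_that(all(treatments %in% names(external_scaling)), "blot_panel_spec",
             "external_scaling must cover every treatment")
  check_that(all(external_scaling > 0), "blot_panel_spec",
             "external_scaling must be > 0")
  check_that(is_number(n_reps) && n_reps >= 1, "blot_panel_spec",
             "n_reps must be >= 1")
  check_that(is_number(cv) && cv >= 0, "blot_panel_spec", "cv must be >= 0")
  structure(list(lines = lines, rates = rates, treatments = treatments,
                 external_scaling = external_scaling,
                 n_reps = as.integer(n_reps), cv = cv, seed = as.integer(seed)),
            class = "blot_panel_spec")
}

#' Default blot panel specification over the shipped isoform set
#'
#' One entry per shipped KRAS line, equal unit abundances, four replicates
#' and 10% measurement CV.
#'
#' @inheritParams blot_panel_spec
#' @return A [blot_panel_spec()].
#' @export
default_blot_panel_spec <- function(n_reps = 4, cv = 0.1, seed = 1L,
                                    external_scaling = NULL) {
  iso <- default_isoform_params()
  ab <- abundances()
  lines <- lapply(iso, function(p) list(params = p, abund = ab))
  blot_panel_spec(lines, rates = default_cascade_rates(),
                  external_scaling = external_scaling,
                  n_reps = n_reps, cv = cv, seed = seed)
}

#' Simulate a condition-level immunoblot panel
#'
#' For each line, treatment and replicate, emits measured component
#' abundances (truth times lognormal noise) and fractional ppERK (internal
#' model prediction, times any planted external scaling, times lognormal
#' noise, clipped to (0, 1)). With `cv = 0` measurements equal the noiseless
#' model values exactly.
#'
#' @param spec A [blot_panel_spec()].
#' @return Data frame with one row per line x treatment x replicate:
#'   `line`, `treatment`, `replicate`, `stimulated`, measured `RAS_t`,
#'   `BRAF_t`, `CRAF_t`, `MEK_t`, `ERK_t`, `f_pperk`, `pperk_rel`.
#' @export
simulate_blot_panel <- function(spec) {
  check_that(inherits(spec, "blot_panel_spec"), "blot_panel_spec",
             "not a blot_panel_spec")
  eps <- 1e-9
  comp <- c("RAS_t", "BRAF_t", "CRAF_t", "MEK_t", "ERK_t")
  withr::with_seed(spec$seed, {
    rows <- list()
    for (line in names(spec$lines)) {
      entry <- spec$lines[[line]]
      for (tt in spec$treatments) {
        stim <- !identical(tt, "baseline")
        st <- internal_model_state(entry$params, entry$abund, spec$rates,
                                   stimulated = stim)
        f_mean <- st$f_pperk * spec$external_scaling[[tt]]
        if (f_mean <= 0 || f_mean >= 1)
          fail_invariant("blot panel", sprintf(
            "predicted ppERK fraction %.3g outside (0,1) for %s/%s (model configuration)",
            f_mean, line, tt))
        for (r in seq_len(spec$n_reps)) {
          ab_meas <- vapply(comp, function(f)
            entry$abund[[f]] * lognormal_noise(1, spec$cv), numeric(1))
          f_meas <- min(max(f_mean * lognormal_noise(1, spec$cv), eps), 1 - eps)
          rows[[length(rows) + 1L]] <- data.frame(
            line = line, treatment = tt, replicate = r, stimulated = stim,
            t(ab_meas), f_pperk = f_meas,
            pperk_rel = f_meas * ab_meas[["ERK_t"]],
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
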