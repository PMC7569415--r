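#' Experiment timeline for a live-cell imaging run
#'
#' Describes the common clock of a reporter imaging experiment: a growth-factor
#' free baseline period, a stimulus addition, and a terminal MEK-inhibitor
#' (MEKi) treatment that provides the per-cell zero-activity reference. All
#' times are minutes from the start of imaging.
#'
#' The baseline window must span at least 2 h before the stimulus (the window
#' averaged for the baseline measurement) and the MEKi period at least 1 h
#' (the window searched for the per-cell minimum used in normalization).
#'
#' @param sampling_interval Frame spacing in minutes (default 3).
#' @param t_start,t_stim,t_meki,t_end Times (min) of imaging start, stimulus,
#'   MEKi addition and imaging end; must be strictly increasing.
#' @param stimulus_label Name of the stimulus (e.g. `"EGF"`).
#' @param stimulus_dose Stimulus dose in ng/ml.
#' @param meki_dose MEK inhibitor dose in nM.
#' @return An object of class `experiment_design`.
#' @examples
#' design <- experiment_design()
#' design$t_stim
#' @export
experiment_design <- function(sampling_interval = 3,
                              t_start = 0, t_stim = 240,
                              t_meki = 390, t_end = 450,
                              stimulus_label = "EGF",
                              stimulus_dose = 10,
                              meki_dose = 100) {
  d <- structure(
    list(sampling_interval = sampling_interval,
         t_start = t_start, t_stim = t_stim, t_meki = t_meki, t_end = t_end,
         stimulus_label = stimulus_label, stimulus_dose = stimulus_dose,
         meki_dose = meki_dose),
    class = "experiment_design")
  validate_design(d)
  d
}

validate_design <- function(d) {
  check_that(inherits(d, "experiment_design"), "experiment_design", "not an experiment_design")
  for (f in c("sampling_interval", "t_start", "t_stim", "t_meki", "t_end"))
    check_that(is_number(d[[f]]), "experiment_design", paste(f, "must be a finite number"))
  check_that(d$sampling_interval > 0, "experiment_design", "sampling_interval must be > 0")
  check_that(d$t_start < d$t_stim && d$t_stim < d$t_meki && d$t_meki < d$t_end,
             "experiment_design", "times must satisfy t_start < t_stim < t_meki < t_end")
  check_that(d$t_stim - d$t_start >= 120, "experiment_design",
             "baseline period (t_stim - t_start) must be at least 120 min")
  check_that(d$t_end - d$t_meki >= 60, "experiment_design",
             "MEKi period (t_end - t_meki) must be at least 60 min")
  invisible(d)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "experiment_design: %g min frames; baseline [%g, %g), %s %g ng/ml at %g, MEKi %g nM at %g, end %g\n",
    x$sampling_interval, x$t_start, x$t_stim, x$stimulus_label,
    x$stimulus_dose, x$t_stim, x$meki_dose, x$t_meki, x$t_end))
  invisible(x)
}

design_times <- function(design) {
  seq(design$t_start, design$t_end, by = design$sampling_interval)
}

#' Read or write an experiment design as YAML
#'
#' @param path File path.
#' @param design An [experiment_design()] object.
#' @return `read_design()` returns an `experiment_design`;
#'   `write_design()` returns `path` invisibly.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(experiment_design, y)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  validate_design(design)
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}
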