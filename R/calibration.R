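#' Calibration curve linking corrected signal to phosphorylated fraction
#'
#' The corrected reporter signal E is affine in the fraction p of reporter
#' molecules phosphorylated by ERK: `E = intercept + slope * p`. The intercept
#' is the spontaneous fluorophore-association background at p = 0; intercept +
#' slope is the signal of a fully phosphorylated reporter and cannot exceed 1.
#'
#' @param intercept Corrected-signal value at p = 0 (background), `>= 0`.
#' @param slope Corrected-signal change per unit phosphorylated fraction,
#'   `> 0`; `intercept + slope <= 1`.
#' @param residual_sd,n_points,provenance Optional fit diagnostics.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(intercept, slope, residual_sd = NA_real_,
                              n_points = NA_integer_, provenance = "manual") {
  cc <- structure(list(intercept = intercept, slope = slope,
                       residual_sd = residual_sd, n_points = n_points,
                       provenance = provenance, warning = NULL),
                  class = "calibration_curve")
  validate_curve(cc)
  cc
}

validate_curve <- function(cc, require_positive_slope = TRUE) {
  check_that(inherits(cc, "calibration_curve"), "calibration_curve",
             "not a calibration_curve")
  check_that(is_number(cc$intercept) && cc$intercept >= 0,
             "calibration_curve", "intercept must be >= 0")
  check_that(is_number(cc$slope), "calibration_curve", "slope must be finite")
  if (require_positive_slope)
    check_that(cc$slope > 0, "calibration_curve", "slope must be > 0")
  check_that(cc$intercept + cc$slope <= 1 + 1e-12, "calibration_curve",
             "intercept + slope must be <= 1")
  invisible(cc)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: E = %.4f + %.4f * p", x$intercept, x$slope))
  if (!is.na(x$residual_sd))
    cat(sprintf("  (residual SD %.4g, n = %d)", x$residual_sd, x$n_points))
  cat("\n")
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' Fit the reporter calibration curve
#'
#' Ordinary least squares of mean corrected signal E on the reporter
#' phosphorylated fraction p measured by Phos-Tag immunoblot under matched
#' conditions. The design mirrors a calibration panel of cell lines with and
#' without growth-factor stimulation spanning the full activity range.
#'
#' @param points Data frame with columns `p` (phosphorylated fraction) and
#'   `E` (mean corrected signal); extra columns (condition labels, replicate
#'   counts) are kept as provenance.
#' @return A [calibration_curve()] with fit diagnostics. A non-positive fitted
#'   slope does not error but sets a warning flag on the curve (non-physical
#'   calibration).
#' @export
fit_calibration <- function(points) {
  check_that(is.data.frame(points) && all(c("p", "E") %in% names(points)),
             "calibration points", "need columns p and E")
  pts <- points[is.finite(points$p) & is.finite(points$E), , drop = FALSE]
  check_that(nrow(pts) >= 2, "calibration points", "need at least 2 points")
  if (length(unique(pts$p)) < 2)
    fail_invariant("calibration points", "all p identical (rank-deficient fit)")
  fit <- lm(E ~ p, data = pts)
  co <- coef(fit)
  rsd <- if (nrow(pts) > 2) sqrt(sum(fit$residuals^2) / (nrow(pts) - 2)) else 0
  cc <- structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                       residual_sd = rsd, n_points = nrow(pts),
                       provenance = "fit_calibration", warning = NULL),
                  class = "calibration_curve")
  if (cc$slope <= 0) {
    cc$warning <- "fitted slope <= 0: non-physical calibration"
    warning(cc$warning)
  }
  validate_curve(cc, require_positive_slope = FALSE)
  cc
}

#' Mass-action map between phosphorylated fraction and activity ratio
#'
#' At steady state of the reporter phosphorylation cycle (phosphorylation by
#' active ERK at rate `k_f * ERK`, dephosphorylation at rate `k_r * Ptase`),
#' `k_f * ERK * (1 - p) = k_r * Ptase * p`, so the ERK:phosphatase activity
#' ratio is `rho = p / (1 - p)` (the unidentifiable constant k_f/k_r is fixed
#' to 1, making rho a relative measure). `activity_to_phospho()` is the exact
#' inverse, `p = rho / (1 + rho)`.
#'
#' @param p Phosphorylated fraction(s) in `[0, 1)`.
#' @param rho Nonnegative activity ratio(s).
#' @return Numeric vector.
#' @examples
#' phospho_to_activity_ratio(0.5)  # balanced cycle: rho = 1
#' @export
phospho_to_activity_ratio <- function(p) {
  check_that(all(is.finite(p)), "phosphorylated fraction", "p must be finite")
  check_that(all(p >= 0), "phosphorylated fraction", "p must be >= 0")
  if (any(p >= 1))
    fail_invariant("phosphorylated fraction",
                   "p >= 1: saturated reporter outside linear range")
  p / (1 - p)
}

#' @rdname phospho_to_activity_ratio
#' @export
activity_to_phospho <- function(rho) {
  check_that(all(is.finite(rho) & rho >= 0), "activity ratio",
             "rho must be finite and >= 0")
  rho / (1 + rho)
}

#' ERK:phosphatase activity ratio from corrected signal
#'
#' Inverts the calibration: `p = (E - intercept) / slope`, clipped to
#' `[0, 1 - 1e-6]` (measurement noise can push E outside the calibrated band;
#' clipped points are counted), then `rho = p / (1 - p)`.
#'
#' @param E Corrected signal vector (NA passed through).
#' @param curve A [calibration_curve()]; its slope must be positive.
#' @param eps Upper clip margin on p (default 1e-6).
#' @return Numeric vector of rho with attributes `clipped_low` and
#'   `clipped_high` giving the clip counts.
#' @export
activity_from_signal <- function(E, curve, eps = 1e-6) {
  validate_curve(curve)
  p <- (E - curve$intercept) / curve$slope
  lo <- sum(p < 0, na.rm = TRUE)
  hi <- sum(p > 1 - eps, na.rm = TRUE)
  p <- pmin(pmax(p, 0), 1 - eps)
  rho <- p / (1 - p)
  attr(rho, "clipped_low") <- lo
  attr(rho, "clipped_high") <- hi
  rho
}

#' Default synthetic calibration curve
#'
#' Synthetic stand-in for an instrument calibration: background 0.10 and span
#' 0.50, so the corrected signal runs from 0.10 (unphosphorylated) to 0.60
#' (fully phosphorylated), matching the order of magnitude of reporter
#' calibrations over the full activity range.
#'
#' @return A [calibration_curve()].
#' @export
default_calibration_curve <- function() {
  calibration_curve(intercept = 0.10, slope = 0.50,
                    provenance = "synthetic default")
}

#' Read or write a calibration curve as YAML
#' @param path File path.
#' @param curve A [calibration_curve()].
#' @return `read_calibration_curve()` returns a `calibration_curve`;
#'   `write_calibration_curve()` returns `path` invisibly.
#' @export
read_calibration_curve <- function(path) {
  y <- yaml::read_yaml(path)
  calibration_curve(intercept = y$intercept, slope = y$slope,
                    residual_sd = y$residual_sd %||% NA_real_,
                    n_points = y$n_points %||% NA_integer_,
                    provenance = y$provenance %||% "yaml")
}

#' @rdname read_calibration_curve
#' @export
write_calibration_curve <- function(curve, path) {
  validate_curve(curve)
  yaml::write_yaml(curve[c("intercept", "slope", "residual_sd",
                           "n_points", "provenance")], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify raw two-channel traces into activity ratios
#'
#' Applies the ratiometric correction and the calibrated mass-action inverse
#' to a long-format table of raw intensities, yielding one activity value
#' (rho) per cell per time point.
#'
#' @param raw Data frame with columns `cell_id`, `time_min`, `cfp`, `yfp`
#'   (other columns are carried through).
#' @param curve A [calibration_curve()].
#' @param spectral A [spectral_config()] (used for the power ratio), or
#'   directly a numeric `R_P` via the `R_P` argument.
#' @param R_P Optional precomputed power ratio overriding `spectral`.
#' @return Data frame with column `rho` replacing `cfp`/`yfp`, and an
#'   attribute `clip_report` with per-trace clip counts.
#' @export
quantify_traces <- function(raw, curve, spectral = NULL, R_P = NULL) {
  check_that(is.data.frame(raw) &&
               all(c("cell_id", "time_min", "cfp", "yfp") %in% names(raw)),
             "raw traces", "need columns cell_id, time_min, cfp, yfp")
  if (is.null(R_P)) {
    check_that(!is.null(spectral), "quantify_traces",
               "provide spectral config or R_P")
    R_P <- power_ratio(spectral)
  }
  E <- ekar_signal(raw$cfp, raw$yfp, R_P)
  rho <- activity_from_signal(E, curve)
  out <- raw[setdiff(names(raw), c("cfp", "yfp"))]
  out$rho <- as.numeric(rho)
  attr(out, "clip_report") <- list(
    clipped_low = attr(rho, "clipped_low"),
    clipped_high = attr(rho, "clipped_high"),
    n_points = nrow(out))
  out
}
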