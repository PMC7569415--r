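#' Optical configuration of the two reporter channels
#'
#' Holds, for the cyan and yellow channels, the scalar factors that determine
#' the total optical power collected in each channel: relative excitation
#' intensity, exposure time, molar extinction coefficient, quantum yield, and
#' the excitation- and emission-side spectral overlap integrals (source or
#' filter transmissivity times fluorophore spectrum, integrated over a
#' wavelength grid in nm). The ratio of the cyan product to the yellow product
#' is the power ratio R_P used in the ratiometric reporter correction.
#'
#' @param cyan,yellow Lists with elements `excitation_intensity`,
#'   `exposure_time` (ms), `extinction_coefficient` (1/M/cm), `quantum_yield`,
#'   and either precomputed `excitation_overlap` / `emission_overlap` scalars
#'   in (0, 1] or `excitation_spectra` / `emission_spectra` (each a list with
#'   numeric `wavelength` and two transmissivity/spectrum vectors `source` and
#'   `fluorophore` on that grid) from which the overlaps are integrated.
#' @return An object of class `spectral_config`.
#' @seealso [power_ratio()]
#' @export
spectral_config <- function(cyan, yellow) {
  s <- structure(list(cyan = prep_channel(cyan, "cyan"),
                      yellow = prep_channel(yellow, "yellow")),
                 class = "spectral_config")
  validate_spectral(s)
  s
}

prep_channel <- function(ch, name) {
  for (side in c("excitation", "emission")) {
    ov <- paste0(side, "_overlap")
    sp <- paste0(side, "_spectra")
    if (is.null(ch[[ov]])) {
      check_that(!is.null(ch[[sp]]), "spectral_config",
                 sprintf("channel %s needs %s or %s", name, ov, sp))
      ch[[ov]] <- overlap_integral(ch[[sp]])
    }
  }
  ch
}

# Trapezoidal integral of the product of normalized transmissivity curves on a
# shared wavelength grid, normalized by the grid span so a perfect overlap of
# unit-height spectra gives 1.
overlap_integral <- function(spectra, normalize = TRUE) {
  wl <- spectra$wavelength
  check_that(is.numeric(wl) && length(wl) >= 2 && all(diff(wl) > 0),
             "spectral_config", "wavelength grid must be increasing, length >= 2")
  curves <- spectra[setdiff(names(spectra), "wavelength")]
  check_that(length(curves) >= 1, "spectral_config", "no spectra provided")
  lens <- vapply(curves, length, integer(1))
  check_that(all(lens == length(wl)), "spectral_config",
             "spectra and wavelength grid lengths differ (mismatched grids)")
  prod_curve <- Reduce(`*`, curves)
  val <- trapz(wl, prod_curve)
  if (normalize) val <- val / (max(wl) - min(wl))
  val
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

channel_factors <- function(ch) {
  c(ch$excitation_intensity, ch$exposure_time, ch$extinction_coefficient,
    ch$quantum_yield, ch$excitation_overlap, ch$emission_overlap)
}

validate_spectral <- function(s) {
  for (name in c("cyan", "yellow")) {
    f <- channel_factors(s[[name]])
    check_that(length(f) == 6 && all(is.finite(f)), "spectral_config",
               sprintf("channel %s must provide six finite factors", name))
    check_that(all(f > 0), "spectral_config",
               sprintf("channel %s has a nonpositive factor", name))
    for (ov in c("excitation_overlap", "emission_overlap"))
      check_that(s[[name]][[ov]] <= 1, "spectral_config",
                 sprintf("%s of channel %s must be in (0, 1]", ov, name))
  }
  invisible(s)
}

#' Spectral power ratio of the cyan and yellow channels
#'
#' R_P is the ratio of total optical power collected in the cyan channel over
#' that collected in the yellow channel, each computed as the product of the
#' channel's six factors (excitation intensity, exposure time, extinction
#' coefficient, quantum yield, and the excitation/emission spectral overlap
#' integrals). It rescales the raw CFP/YFP intensity ratio so that the
#' corrected reporter signal is instrument independent.
#'
#' @param spectral A [spectral_config()].
#' @return The dimensionless power ratio R_P.
#' @examples
#' ch <- list(excitation_intensity = 1, exposure_time = 100,
#'            extinction_coefficient = 3e4, quantum_yield = 0.4,
#'            excitation_overlap = 0.5, emission_overlap = 0.5)
#' power_ratio(spectral_config(ch, ch))  # identical channels: exactly 1
#' @export
power_ratio <- function(spectral) {
  validate_spectral(spectral)
  prod(channel_factors(spectral$cyan)) / prod(channel_factors(spectral$yellow))
}

#' Corrected reporter signal from raw channel intensities
#'
#' The corrected reporter level is `E = 1 - (CFP/YFP) / R_P`. It is linear in
#' the fraction of reporter molecules in the FRET (associated) conformation.
#' Negative values are allowed (they indicate signal below the spontaneous
#' association background) and are not clipped here.
#'
#' @param cfp,yfp Numeric vectors of cyan and yellow channel intensities.
#' @param R_P Spectral power ratio from [power_ratio()].
#' @return Numeric vector of corrected signal values, `NA` where `yfp <= 0`
#'   (the count of such points is reported via a warning).
#' @export
ekar_signal <- function(cfp, yfp, R_P) {
  check_that(is_number(R_P) && R_P > 0, "ekar_signal", "R_P must be > 0")
  check_that(length(cfp) == length(yfp), "ekar_signal",
             "cfp and yfp must have equal length")
  bad <- !is.na(yfp) & yfp <= 0
  out <- 1 - (cfp / yfp) / R_P
  if (any(bad)) {
    out[bad] <- NA_real_
    warning(sprintf("ekar_signal: %d points with yfp <= 0 set to NA", sum(bad)))
  }
  out
}

#' Default synthetic optical configuration
#'
#' A plausible synthetic two-channel configuration (not measured instrument
#' values) used by the simulator and examples. Its factors give a power ratio
#' near 1.2.
#'
#' @return A [spectral_config()].
#' @export
default_spectral_config <- function() {
  spectral_config(
    cyan = list(excitation_intensity = 1.0, exposure_time = 90,
                extinction_coefficient = 32500, quantum_yield = 0.40,
                excitation_overlap = 0.62, emission_overlap = 0.45),
    yellow = list(excitation_intensity = 1.0, exposure_time = 90,
                  extinction_coefficient = 83400, quantum_yield = 0.61,
                  excitation_overlap = 0.24, emission_overlap = 0.44))
}

#' Read or write a spectral configuration as YAML
#' @param path File path.
#' @param spectral A [spectral_config()].
#' @return `read_spectral_config()` returns a `spectral_config`;
#'   `write_spectral_config()` returns `path` invisibly.
#' @export
read_spectral_config <- function(path) {
  y <- yaml::read_yaml(path)
  spectral_config(cyan = y$cyan, yellow = y$yellow)
}

#' @rdname read_spectral_config
#' @export
write_spectral_config <- function(spectral, path) {
  validate_spectral(spectral)
  yaml::write_yaml(list(cyan = spectral$cyan, yellow = spectral$yellow), path)
  invisible(path)
}
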