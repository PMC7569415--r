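#' Per-isoform RAS GTPase-cycle and effector-binding constants
#'
#' Kinetic constants of the nucleotide cycle for one RAS isoform: intrinsic
#' GTP hydrolysis (`k_int`), GAP-stimulated hydrolysis (`k_gap`, about zero
#' for GAP-insensitive oncogenic mutants), nucleotide exchange without and
#' with growth-factor stimulation (`k_ex_basal`, `k_ex_stim`; stimulation is
#' modeled solely as GEF recruitment raising the exchange rate), and the
#' RAS-GTP/RAF dissociation constant `Kd_raf` in relative concentration
#' units. Oncogenic mutants reduce total hydrolysis (`k_int + k_gap`) tens to
#' hundreds of fold versus wild type and can weaken RAF binding up to
#' several-fold.
#'
#' @param k_int,k_gap Hydrolysis rates (1/min), `>= 0`.
#' @param k_ex_basal,k_ex_stim Exchange rates (1/min); `k_ex_stim >=
#'   k_ex_basal`.
#' @param Kd_raf Dissociation constant (relative units), `> 0`.
#' @param provenance Citation tag or free-text provenance.
#' @return An object of class `isoform_params`.
#' @export
isoform_params <- function(k_int, k_gap, k_ex_basal, k_ex_stim, Kd_raf,
                           provenance = "") {
  p <- structure(list(k_int = k_int, k_gap = k_gap,
                      k_ex_basal = k_ex_basal, k_ex_stim = k_ex_stim,
                      Kd_raf = Kd_raf, provenance = provenance),
                 class = "isoform_params")
  validate_isoform(p)
  p
}

validate_isoform <- function(p) {
  for (f in c("k_int", "k_gap", "k_ex_basal", "k_ex_stim", "Kd_raf"))
    check_that(is_number(p[[f]]) && p[[f]] >= 0, "isoform_params",
               paste(f, "must be a finite number >= 0"))
  check_that(p$k_ex_stim >= p$k_ex_basal, "isoform_params",
             "k_ex_stim must be >= k_ex_basal")
  check_that(p$Kd_raf > 0, "isoform_params", "Kd_raf must be > 0")
  invisible(p)
}

#' Relative abundances of cascade components
#'
#' Total (phosphorylated plus unphosphorylated) relative concentrations on the
#' immunoblot scale. BRAF and CRAF are pooled into one RAF species for the
#' cascade (`RAF_t = BRAF_t + CRAF_t`).
#'
#' @param RAS_t,BRAF_t,CRAF_t,MEK_t,ERK_t Positive relative concentrations.
#' @return An object of class `abundances`.
#' @export
abundances <- function(RAS_t = 1, BRAF_t = 0.5, CRAF_t = 0.5,
                       MEK_t = 1, ERK_t = 1) {
  a <- structure(list(RAS_t = RAS_t, BRAF_t = BRAF_t, CRAF_t = CRAF_t,
                      MEK_t = MEK_t, ERK_t = ERK_t),
                 class = "abundances")
  for (f in names(a))
    check_that(is_number(a[[f]]) && a[[f]] > 0, "abundances",
               paste(f, "must be > 0"))
  a
}

#' Composite activation/deactivation constants of the kinase tiers
#'
#' First-order push-pull constants: active RAF phosphorylates MEK with
#' composite rate `a_mek` (per unit active RAF) against dephosphorylation
#' `d_mek`; active MEK phosphorylates ERK with `a_erk` against `d_erk`. The
#' tiers are kept far from saturation (fractional ppERK stays well below 1),
#' so linear kinase/phosphatase cycles apply.
#'
#' @param a_mek,d_mek,a_erk,d_erk Positive rate constants (1/min scale).
#' @return An object of class `cascade_rates`.
#' @export
cascade_rates <- function(a_mek = 50, d_mek = 0.5, a_erk = 0.5, d_erk = 1) {
  r <- structure(list(a_mek = a_mek, d_mek = d_mek,
                      a_erk = a_erk, d_erk = d_erk),
                 class = "cascade_rates")
  for (f in names(r))
    check_that(is_number(r[[f]]) && r[[f]] > 0, "cascade_rates",
               paste(f, "must be > 0"))
  r
}

#' Steady-state GTP-bound fraction of RAS
#'
#' Two-state nucleotide cycle at steady state: exchange (GDP to GTP) at rate
#' `k_ex` against hydrolysis at `k_int + k_gap` gives
#' `f_gtp = k_ex / (k_ex + k_int + k_gap)`. The GAP/GEF balance thereby sets
#' the fraction of RAS molecules in the active state; no feedback or other
#' regulation enters this internal-factors model.
#'
#' @param params An [isoform_params()].
#' @param stimulated Logical: use `k_ex_stim` instead of `k_ex_basal`.
#' @return GTP-bound fraction in `[0, 1]`.
#' @export
ras_gtp_fraction <- function(params, stimulated = FALSE) {
  validate_isoform(params)
  k_ex <- if (stimulated) params$k_ex_stim else params$k_ex_basal
  denom <- k_ex + params$k_int + params$k_gap
  if (denom <= 0)
    fail_invariant("ras_gtp_fraction", "all rates zero: fraction undefined")
  k_ex / denom
}

#' Active RAS-GTP/RAF complex from equilibrium binding
#'
#' Solves the one-site binding equilibrium for the complex C between GTP-bound
#' RAS (`G = f_gtp * RAS_t`) and pooled RAF:
#' `C^2 - C (G + RAF_t + Kd) + G * RAF_t = 0`, taking the physical root
#' `C <= min(G, RAF_t)`. Written in the numerically stable form
#' `C = 2 G RAF_t / (b + sqrt(b^2 - 4 G RAF_t))` with `b = G + RAF_t + Kd`,
#' which is continuous in all parameters including `Kd = 0`.
#'
#' @param f_gtp GTP-bound fraction from [ras_gtp_fraction()].
#' @param RAS_t,RAF_t Total RAS and (pooled) RAF, `> 0`.
#' @param Kd_raf Dissociation constant, `>= 0`.
#' @return Active complex concentration (relative units).
#' @export
raf_recruitment <- function(f_gtp, RAS_t, RAF_t, Kd_raf) {
  check_that(f_gtp >= 0 && f_gtp <= 1, "raf_recruitment", "f_gtp must be in [0, 1]")
  check_that(RAS_t > 0 && RAF_t > 0 && Kd_raf >= 0, "raf_recruitment",
             "RAS_t, RAF_t must be > 0 and Kd_raf >= 0")
  G <- f_gtp * RAS_t
  if (G == 0) return(0)
  b <- G + RAF_t + Kd_raf
  disc <- b^2 - 4 * G * RAF_t
  if (disc < 0) {
    if (disc > -1e-9 * b^2) disc <- 0
    else fail_invariant("raf_recruitment", "negative discriminant")
  }
  2 * G * RAF_t / (b + sqrt(disc))
}

#' Steady state of the MEK/ERK push-pull tiers
#'
#' Each tier is a linear kinase/phosphatase cycle far from saturation: the
#' phosphorylated fraction of MEK is `a_mek * raf_active / (a_mek *
#' raf_active + d_mek)`; active MEK (`f_ppmek * MEK_t`) then drives ERK the
#' same way. Returns all intermediate fractions and the relative ppERK
#' concentration `f_pperk * ERK_t`.
#'
#' @param raf_active Active RAF complex from [raf_recruitment()].
#' @param abund An [abundances()].
#' @param rates A [cascade_rates()].
#' @return List with `f_ppmek`, `f_pperk`, `ppmek_rel`, `pperk_rel`.
#' @export
cascade_steady_state <- function(raf_active, abund, rates) {
  check_that(raf_active >= 0, "cascade_steady_state", "raf_active must be >= 0")
  v1 <- rates$a_mek * raf_active
  f_ppmek <- v1 / (v1 + rates$d_mek)
  active_mek <- f_ppmek * abund$MEK_t
  v2 <- rates$a_erk * active_mek
  f_pperk <- v2 / (v2 + rates$d_erk)
  list(f_ppmek = f_ppmek, f_pperk = f_pperk,
       ppmek_rel = f_ppmek * abund$MEK_t,
       pperk_rel = f_pperk * abund$ERK_t)
}

#' Full internal-model steady state for one line and condition
#'
#' Composes [ras_gtp_fraction()], [raf_recruitment()] and
#' [cascade_steady_state()].
#'
#' @param params An [isoform_params()].
#' @param abund An [abundances()].
#' @param rates A [cascade_rates()].
#' @param stimulated Logical.
#' @return List with `f_gtp`, `raf_active`, `f_ppmek`, `f_pperk`,
#'   `pperk_rel`.
#' @export
internal_model_state <- function(params, abund, rates, stimulated = FALSE) {
  f_gtp <- ras_gtp_fraction(params, stimulated)
  raf_active <- raf_recruitment(f_gtp, abund$RAS_t,
                                abund$BRAF_t + abund$CRAF_t, params$Kd_raf)
  ss <- cascade_steady_state(raf_active, abund, rates)
  c(list(f_gtp = f_gtp, raf_active = raf_active), ss)
}

#' Predict the ppERK panel across cell lines and conditions
#'
#' Runs the internal-factors model for every line at baseline and under
#' stimulation, and normalizes relative ppERK to the reference (wild-type)
#' line's baseline value, matching how measured panels are reported.
#'
#' @param isoforms Named list of [isoform_params()], one per line.
#' @param abund Named list of [abundances()] (same names), or a single
#'   `abundances` object shared by all lines.
#' @param rates A [cascade_rates()] shared across lines.
#' @param reference_line Line whose baseline prediction is the unit;
#'   default the first line.
#' @param normalize If `FALSE`, return unnormalized `pperk_rel`.
#' @return Data frame with columns `line`, `condition` (`"baseline"` /
#'   `"stimulated"`), `f_gtp`, `f_pperk`, `pperk_rel`.
#' @export
predict_panel <- function(isoforms, abund, rates = cascade_rates(),
                          reference_line = names(isoforms)[1],
                          normalize = TRUE) {
  check_that(length(isoforms) >= 1 && !is.null(names(isoforms)),
             "predict_panel", "isoforms must be a named list")
  if (inherits(abund, "abundances"))
    abund <- setNames(rep(list(abund), length(isoforms)), names(isoforms))
  missing_ab <- setdiff(names(isoforms), names(abund))
  check_that(length(missing_ab) == 0, "predict_panel",
             paste("missing abundances for line:", paste(missing_ab, collapse = ", ")))
  check_that(reference_line %in% names(isoforms), "predict_panel",
             paste("missing line:", reference_line))
  rows <- list()
  for (line in names(isoforms)) {
    for (cond in c("baseline", "stimulated")) {
      st <- internal_model_state(isoforms[[line]], abund[[line]], rates,
                                 stimulated = cond == "stimulated")
      rows[[length(rows) + 1L]] <- data.frame(
        line = line, condition = cond, f_gtp = st$f_gtp,
        f_pperk = st$f_pperk, pperk_rel = st$pperk_rel,
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  if (normalize) {
    ref <- panel$pperk_rel[panel$line == reference_line &
                             panel$condition == "baseline"]
    panel$pperk_rel <- panel$pperk_rel / ref
  }
  panel
}

#' Fold change of ppERK upon stimulation
#'
#' @param panel Output of [predict_panel()] (or a measured panel with the
#'   same columns).
#' @return Data frame with `line` and `fold_change` (stimulated / baseline);
#'   `NA` with a warning where the baseline is zero.
#' @export
stimulation_amplitude <- function(panel) {
  check_that(all(c("line", "condition", "pperk_rel") %in% names(panel)),
             "panel", "need columns line, condition, pperk_rel")
  lines <- unique(panel$line)
  out <- data.frame(line = lines, fold_change = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    b <- panel$pperk_rel[panel$line == lines[i] & panel$condition == "baseline"]
    s <- panel$pperk_rel[panel$line == lines[i] & panel$condition == "stimulated"]
    check_that(length(b) == 1 && length(s) == 1, "panel",
               paste("line", lines[i], "must have both conditions"))
    if (b == 0) warning("zero baseline for line ", lines[i])
    else out$fold_change[i] <- s / b
  }
  out
}

#' Model-measurement discrepancy: the external-factor rescaling
#'
#' Both panels are normalized to their own reference-line baseline (so the
#' arbitrary units of each cancel) and compared elementwise. The ratio
#' measured/predicted per line and condition summarizes the rescaling
#' attributable to external factors (feedbacks, scaffolds, phosphatase
#' regulation) that the internal model deliberately omits.
#'
#' @param predicted,measured Data frames with columns `line`, `condition`,
#'   `pperk_rel`. Replicate rows in `measured` are summarized by their median
#'   before normalization.
#' @param reference_line Reference line for normalization (default: first
#'   line of `predicted`).
#' @return Data frame with `line`, `condition`, `predicted_norm`,
#'   `measured_norm`, `ratio` (= measured/predicted, both normalized).
#' @export
model_measurement_discrepancy <- function(predicted, measured,
                                          reference_line = predicted$line[1]) {
  for (nm in list(predicted, measured))
    check_that(all(c("line", "condition", "pperk_rel") %in% names(nm)),
               "panel", "need columns line, condition, pperk_rel")
  agg <- function(df) {
    a <- stats::aggregate(pperk_rel ~ line + condition, data = df, FUN = median)
    ref <- a$pperk_rel[a$line == reference_line & a$condition == "baseline"]
    check_that(length(ref) == 1 && ref > 0, "panel",
               paste("reference baseline missing or zero for", reference_line))
    a$pperk_rel <- a$pperk_rel / ref
    a
  }
  p <- agg(predicted)
  m <- agg(measured)
  key_p <- paste(p$line, p$condition)
  key_m <- paste(m$line, m$condition)
  if (!setequal(key_p, key_m))
    fail_invariant("panel", paste(
      "mismatched line/condition keys:",
      paste(setdiff(union(key_p, key_m), intersect(key_p, key_m)), collapse = ", ")))
  m <- m[match(key_p, key_m), ]
  data.frame(line = p$line, condition = p$condition,
             predicted_norm = p$pperk_rel, measured_norm = m$pperk_rel,
             ratio = m$pperk_rel / p$pperk_rel,
             stringsAsFactors = FALSE)
}

#' Literature-informed synthetic isoform parameter set
#'
#' Default kinetic constants for the wild-type and mutant KRAS lines shipped
#' with the package (`inst/extdata/isoform_params.yaml`). Values are
#' synthetic but respect the published relative bounds: GAP-insensitive
#' mutants have `k_gap = 0` and total hydrolysis 50- to 800-fold below wild
#' type, and mutant RAF affinity is weakened by at most 7-fold.
#'
#' @return Named list of [isoform_params()].
#' @export
default_isoform_params <- function() {
  path <- system.file("extdata", "isoform_params.yaml", package = "erkrescale")
  read_isoform_params(path)
}

#' Read isoform parameters from YAML
#' @param path YAML file: a map of line name to parameter fields.
#' @return Named list of [isoform_params()].
#' @export
read_isoform_params <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(e) do.call(isoform_params, e))
}

#' Default cascade rates shipped with the package
#' @return A [cascade_rates()].
#' @export
default_cascade_rates <- function() {
  path <- system.file("extdata", "cascade_rates.yaml", package = "erkrescale")
  do.call(cascade_rates, yaml::read_yaml(path))
}
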