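#' Quality-control parameters for single-cell traces
#'
#' @param min_length Minimum number of non-missing samples per trace.
#' @param max_contiguous_gap Longest tolerated run of missing samples.
#' @param outlier_sd Outlier threshold on per-cell metric values, in SDs of
#'   the dataset mean (default 6).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_length = 10, max_contiguous_gap = 3, outlier_sd = 6) {
  check_that(min_length >= 2, "qc_params", "min_length must be >= 2")
  check_that(outlier_sd > 0, "qc_params", "outlier_sd must be > 0")
  check_that(max_contiguous_gap >= 0, "qc_params",
             "max_contiguous_gap must be >= 0")
  structure(list(min_length = min_length,
                 max_contiguous_gap = max_contiguous_gap,
                 outlier_sd = outlier_sd),
            class = "qc_params")
}

longest_na_run <- function(x) {
  if (!any(is.na(x))) return(0L)
  r <- rle(is.na(x))
  max(r$lengths[r$values])
}

#' Filter traces for quality
#'
#' Drops whole traces that are too short or contain too long a run of missing
#' samples. The companion single-pass outlier rule on per-cell metric values
#' (exclusion beyond `outlier_sd` standard deviations of the dataset mean) is
#' applied by [mask_metric_outliers()] after metrics are computed. The filter
#' is idempotent: re-applying it to its own output changes nothing.
#'
#' @param traces Long data frame with `cell_id`, `time_min` and a value
#'   column.
#' @param params A [qc_params()].
#' @param value_col Name of the value column (default `"rho"`).
#' @return List with `traces` (kept rows) and `report` (counts per rule).
#' @export
qc_filter <- function(traces, params = qc_params(), value_col = "rho") {
  check_that(all(c("cell_id", "time_min", value_col) %in% names(traces)),
             "traces", paste("need columns cell_id, time_min,", value_col))
  if (nrow(traces) == 0) {
    return(list(traces = traces,
                report = list(n_in = 0L, n_kept = 0L,
                              dropped_short = 0L, dropped_gap = 0L)))
  }
  by_cell <- split(traces, traces$cell_id, drop = TRUE)
  short <- vapply(by_cell, function(df)
    sum(!is.na(df[[value_col]])) < params$min_length, logical(1))
  gap <- vapply(by_cell, function(df)
    longest_na_run(df[[value_col]][order(df$time_min)]) > params$max_contiguous_gap,
    logical(1))
  drop <- short | gap
  kept <- do.call(rbind, by_cell[!drop])
  if (is.null(kept)) kept <- traces[0, ]
  rownames(kept) <- NULL
  list(traces = kept,
       report = list(n_in = length(by_cell), n_kept = sum(!drop),
                     dropped_short = sum(short),
                     dropped_gap = sum(gap & !short)))
}

#' Mask outlying per-cell metric values
#'
#' Single-pass rule: values farther than `outlier_sd` standard deviations
#' from the dataset mean (both computed once, on the full dataset) are set to
#' `NA`.
#'
#' @param x Numeric vector of one metric across cells.
#' @param outlier_sd Threshold in SDs (default 6).
#' @return `x` with outliers replaced by `NA`; attribute `n_masked` gives the
#'   count.
#' @export
mask_metric_outliers <- function(x, outlier_sd = 6) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  out <- x
  n_masked <- 0L
  if (is.finite(s) && s > 0) {
    bad <- !is.na(x) & abs(x - m) > outlier_sd * s
    out[bad] <- NA_real_
    n_masked <- sum(bad)
  }
  attr(out, "n_masked") <- n_masked
  out
}

window_values <- function(time, value, lo, hi, include_hi = TRUE,
                          include_lo = TRUE) {
  sel <- (if (include_lo) time >= lo else time > lo) &
    (if (include_hi) time <= hi else time < hi)
  list(time = time[sel], value = value[sel])
}

#' Normalize a trace to its MEK-inhibitor reference
#'
#' The MEKi treatment at the end of the experiment provides the cell-specific
#' residual reporter signal. Default mode `"min"` subtracts the minimum over
#' the first hour of MEKi treatment; mode `"median"` subtracts the median of
#' the whole MEKi-treated period. Idempotent in mode `"min"`.
#'
#' @param time,value Numeric vectors of one cell's trace.
#' @param design An [experiment_design()].
#' @param mode `"min"` or `"median"`.
#' @return Numeric vector of normalized values, with attributes `offset` and
#'   `mode`.
#' @export
normalize_trace <- function(time, value, design, mode = c("min", "median")) {
  mode <- match.arg(mode)
  validate_design(design)
  hi <- if (mode == "min") design$t_meki + 60 else design$t_end
  w <- window_values(time, value, design$t_meki, hi)
  if (length(w$value) == 0 || all(is.na(w$value)))
    fail_invariant("normalize_trace",
                   "trace does not cover the MEKi window; skip normalization explicitly")
  offset <- if (mode == "min") min(w$value, na.rm = TRUE)
            else median(w$value, na.rm = TRUE)
  out <- value - offset
  attr(out, "offset") <- offset
  attr(out, "mode") <- mode
  out
}

#' Baseline activity: mean of the 2 h window before stimulation
#'
#' @param time,value One cell's trace.
#' @param design An [experiment_design()].
#' @return Mean over samples with `t` in `[t_stim - 120, t_stim)`, missing
#'   values excluded.
#' @export
baseline_mean <- function(time, value, design) {
  w <- window_values(time, value, design$t_stim - 120, design$t_stim,
                     include_hi = FALSE)
  if (length(w$value) == 0) fail_invariant("baseline_mean", "window empty")
  mean(w$value, na.rm = TRUE)
}

#' Peak stimulated activity and time to peak
#'
#' @param time,value One cell's trace.
#' @param design An [experiment_design()].
#' @param search_horizon Minutes after the stimulus searched for the peak
#'   (default 60; later maxima belong to attenuation, not the stimulus peak).
#' @return List with `peak` (maximum over `(t_stim, t_stim + horizon]`) and
#'   `time_to_peak` (minutes from stimulus to the first maximum; ties break
#'   to the earlier time).
#' @export
peak_response <- function(time, value, design, search_horizon = 60) {
  w <- window_values(time, value, design$t_stim,
                     design$t_stim + search_horizon, include_lo = FALSE)
  ok <- !is.na(w$value)
  if (!any(ok)) fail_invariant("peak_response", "window empty")
  i <- which.max(w$value)  # first maximum on ties
  list(peak = w$value[i], time_to_peak = w$time[i] - design$t_stim)
}

#' Post-stimulus mean and steady-state activity
#'
#' `post_stim_mean()` averages the 2 h window following the stimulus;
#' `steady_state()` averages a 30 min window centered 2 h after the stimulus
#' (`[t_stim + 105, t_stim + 135]`). Windows truncated by the MEKi treatment
#' are computed on the intersection and flagged via the `truncated`
#' attribute.
#'
#' @param time,value One cell's trace.
#' @param design An [experiment_design()].
#' @param window Half-open override of the default window (length-2 numeric,
#'   minutes after stimulus).
#' @return Mean activity (numeric scalar, attribute `truncated`).
#' @export
post_stim_mean <- function(time, value, design, window = c(0, 120)) {
  lo <- design$t_stim + window[1]
  hi <- design$t_stim + window[2]
  truncated <- hi > design$t_meki
  hi_eff <- min(hi, design$t_meki)
  w <- window_values(time, value, lo, hi_eff, include_hi = !truncated)
  if (length(w$value) == 0) fail_invariant("post_stim_mean", "window empty")
  out <- mean(w$value, na.rm = TRUE)
  attr(out, "truncated") <- truncated
  out
}

#' @rdname post_stim_mean
#' @export
steady_state <- function(time, value, design, window = c(105, 135)) {
  post_stim_mean(time, value, design, window = window)
}

#' Volatility: mean-scaled mean absolute derivative
#'
#' The time-resolved analogue of the coefficient of variation: the mean of
#' `|x(t[i+1]) - x(t[i])| / (t[i+1] - t[i])` over a window, divided by the
#' window mean of `x`. Zero for constant traces, scale-free (multiplying the
#' trace by any positive constant leaves it unchanged), and larger for
#' pulsatile or drifting activity. The default window is the 2 h following
#' stimulation; pre-stimulus volatility uses `window = "baseline"`.
#'
#' @param time,value One cell's trace.
#' @param design An [experiment_design()].
#' @param window `"post_stim"` (default, `[t_stim, t_stim + 120)`),
#'   `"baseline"` (`[t_stim - 120, t_stim)`), or a length-2 numeric of
#'   absolute times; windows are half-open on the right so a 2 h window holds
#'   a whole number of sampling intervals.
#' @return Volatility (1/min), `NA` (flagged via attribute `undefined`) when
#'   the window mean is not positive.
#' @export
volatility <- function(time, value, design, window = "post_stim") {
  if (is.character(window)) {
    window <- switch(window,
      post_stim = c(design$t_stim, min(design$t_stim + 120, design$t_meki)),
      baseline = c(design$t_stim - 120, design$t_stim),
      fail_invariant("volatility", paste("unknown window:", window)))
  }
  w <- window_values(time, value, window[1], window[2], include_hi = FALSE)
  ok <- !is.na(w$value)
  tt <- w$time[ok]; vv <- w$value[ok]
  check_that(length(vv) >= 3, "volatility", "window must have >= 3 samples")
  m <- mean(vv)
  if (!is.finite(m) || m <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mean(abs(diff(vv)) / diff(tt)) / m
}

#' Classify a cell as a responder to the stimulus
#'
#' A cell responds if both hold: (i) its mean activity in the 30 min after
#' the stimulus exceeds its baseline mean by at least `magnitude_frac` of the
#' full scale (default 5%), and a one-sided unequal-variance comparison of
#' the two windows' samples is significant at `alpha`; and (ii) its maximum
#' forward-difference derivative in the 15 min after the stimulus exceeds the
#' maximum absolute derivative anywhere in the baseline window, so slow
#' drifts that accumulate a large increase without a stimulus-locked rise are
#' not called responders.
#'
#' @param time,value One cell's trace.
#' @param design An [experiment_design()].
#' @param full_scale Reference scale for the magnitude floor. Default: the
#'   trace's own maximum; population-level classification
#'   ([compute_trace_metrics()]) passes the dataset maximum.
#' @param magnitude_frac Magnitude floor as a fraction of `full_scale` (or of
#'   the baseline mean when `threshold_mode = "baseline"`).
#' @param alpha Significance level of the window comparison.
#' @param threshold_mode `"full_scale"` (default) or `"baseline"`.
#' @param smooth_frames Width (frames) of the running mean applied within
#'   each segment before the derivative comparison of criterion (ii); 1
#'   disables smoothing. Smoothing is confined to each window, so the
#'   stimulus step can never leak into the baseline derivatives.
#' @return Logical.
#' @export
classify_responder <- function(time, value, design, full_scale = NULL,
                               magnitude_frac = 0.05, alpha = 0.05,
                               threshold_mode = c("full_scale", "baseline"),
                               smooth_frames = 5) {
  threshold_mode <- match.arg(threshold_mode)
  base <- window_values(time, value, design$t_stim - 120, design$t_stim,
                        include_hi = FALSE)
  post <- window_values(time, value, design$t_stim, design$t_stim + 30)
  if (length(base$value) < 3 || length(post$value) < 3)
    fail_invariant("classify_responder", "baseline or post-stimulus window missing")
  if (is.null(full_scale)) full_scale <- max(value, na.rm = TRUE)
  m_base <- mean(base$value, na.rm = TRUE)
  m_post <- mean(post$value, na.rm = TRUE)
  floor_val <- if (threshold_mode == "full_scale")
    magnitude_frac * full_scale else magnitude_frac * m_base
  crit1 <- (m_post - m_base) >= floor_val
  if (crit1) {
    pval <- tryCatch(
      t.test(post$value, base$value, alternative = "greater")$p.value,
      error = function(e) 1)
    crit1 <- is.finite(pval) && pval < alpha
  }
  if (!crit1) return(FALSE)
  # derivative criterion: smooth each segment over its full extent (the
  # stimulus step can never leak into the baseline segment), differentiate,
  # then compare the stated windows
  stimw <- window_values(time, value, design$t_stim, design$t_stim + 30)
  vb <- running_mean(base$value, smooth_frames)
  vs <- running_mean(stimw$value, smooth_frames)
  dbase <- diff(vb) / diff(base$time)
  dstim <- (diff(vs) / diff(stimw$time))[head(stimw$time, -1) <
                                           design$t_stim + 15]
  if (length(dstim) == 0 || length(dbase) == 0)
    fail_invariant("classify_responder", "derivative windows missing")
  max(dstim, na.rm = TRUE) > max(abs(dbase), na.rm = TRUE)
}

# Centered running mean with partial windows at the edges.
running_mean <- function(v, w) {
  if (w <= 1 || length(v) < 3) return(v)
  half <- (w - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(v[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Per-cell metric set for a population of traces
#'
#' Normalizes each trace to its MEKi reference (unless `normalize = "none"`),
#' then computes the per-cell descriptors: baseline, peak and time to peak,
#' amplitude (peak minus baseline), post-stimulus mean, steady state,
#' volatility, responder flag, and the MEKi reference offset. After all cells
#' are measured, the single-pass outlier rule masks metric values beyond
#' `outlier_sd` SDs of the dataset mean (responder flags and times to peak of
#' non-responders are unaffected; time to peak is reported only for
#' responders).
#'
#' @param traces Long data frame (`cell_id`, `time_min`, value column,
#'   optionally `experiment_id`).
#' @param design An [experiment_design()].
#' @param value_col Name of the value column (default `"rho"`).
#' @param normalize `"min"`, `"median"`, or `"none"`.
#' @param outlier_sd Outlier threshold (SDs) applied to metric columns.
#' @param full_scale Scale for the responder magnitude floor; default the
#'   dataset maximum of the normalized traces.
#' @param ... Passed to [classify_responder()].
#' @return Data frame with one row per cell and the metric columns; the
#'   outlier-mask counts are in the `outlier_report` attribute.
#' @export
compute_trace_metrics <- function(traces, design, value_col = "rho",
                                  normalize = c("min", "median", "none"),
                                  outlier_sd = 6, full_scale = NULL, ...) {
  normalize <- match.arg(normalize)
  validate_design(design)
  check_that(all(c("cell_id", "time_min", value_col) %in% names(traces)),
             "traces", paste("need columns cell_id, time_min,", value_col))
  if (!"experiment_id" %in% names(traces)) traces$experiment_id <- "exp1"
  by_cell <- split(traces, traces$cell_id, drop = TRUE)
  prepped <- lapply(by_cell, function(df) {
    df <- df[order(df$time_min), ]
    v <- df[[value_col]]
    offset <- 0
    if (normalize != "none") {
      v <- normalize_trace(df$time_min, v, design, mode = normalize)
      offset <- attr(v, "offset")
    }
    list(time = df$time_min, value = as.numeric(v), offset = offset,
         experiment_id = df$experiment_id[1])
  })
  if (is.null(full_scale))
    full_scale <- max(vapply(prepped, function(p)
      max(p$value, na.rm = TRUE), numeric(1)))
  rows <- lapply(names(prepped), function(id) {
    p <- prepped[[id]]
    pk <- peak_response(p$time, p$value, design)
    resp <- classify_responder(p$time, p$value, design,
                               full_scale = full_scale, ...)
    base <- baseline_mean(p$time, p$value, design)
    data.frame(
      cell_id = id, experiment_id = p$experiment_id,
      baseline = base, peak = pk$peak, amplitude = pk$peak - base,
      post_stim_mean = as.numeric(post_stim_mean(p$time, p$value, design)),
      steady_state = as.numeric(steady_state(p$time, p$value, design)),
      volatility = as.numeric(volatility(p$time, p$value, design)),
      responder = resp,
      time_to_peak = if (resp) pk$time_to_peak else NA_real_,
      meki_min = p$offset,
      stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  masked <- list()
  for (col in c("baseline", "peak", "amplitude", "post_stim_mean",
                "steady_state", "volatility")) {
    mm <- mask_metric_outliers(metrics[[col]], outlier_sd)
    masked[[col]] <- attr(mm, "n_masked")
    metrics[[col]] <- as.numeric(mm)
  }
  metrics$amplitude <- metrics$peak - metrics$baseline  # exact identity
  attr(metrics, "outlier_report") <- masked
  attr(metrics, "full_scale") <- full_scale
  metrics
}

#' Fraction of responding cells, per experiment and overall
#'
#' @param metrics Metric table from [compute_trace_metrics()] (needs
#'   `experiment_id` and `responder`).
#' @return List with `per_experiment` (data frame: `experiment_id`, `n`,
#'   `fraction`), `mean` and `sd` across experiments. With zero cells the
#'   fraction is `NA` and `undefined` is `TRUE`.
#' @export
response_frequency <- function(metrics) {
  if (nrow(metrics) == 0) {
    return(list(per_experiment = data.frame(experiment_id = character(),
                                            n = integer(), fraction = numeric()),
                mean = NA_real_, sd = NA_real_, undefined = TRUE))
  }
  sp <- split(metrics$responder, metrics$experiment_id)
  per <- data.frame(
    experiment_id = names(sp),
    n = vapply(sp, length, integer(1)),
    fraction = vapply(sp, function(x) mean(x, na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_experiment = per, mean = mean(per$fraction),
       sd = if (nrow(per) > 1) sd(per$fraction) else NA_real_,
       undefined = FALSE)
}
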