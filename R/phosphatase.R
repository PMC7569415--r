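#' Fit the post-MEKi exponential signal decay of one cell
#'
#' After MEK inhibition, reporter dephosphorylation is unopposed, so the
#' signal relaxes as `y(t) = a * exp(-b * (t - t_meki)) + c`; the rate
#' constant `b` is in principle proportional to the phosphatase activity
#' acting on the reporter. Nonlinear least squares with `b >= 0` and
#' `c >= 0`, initialized from the window endpoints
#' (`a = y(t_meki) - y_end`, `c = y_end`, `b = log(2) / (window / 3)`).
#' Nearly constant windows return a degenerate flat fit (`a = 0`, `b = 0`)
#' rather than an error; non-convergence is reported via the `converged`
#' flag, never silently.
#'
#' @param time,value One cell's trace (absolute minutes).
#' @param design An [experiment_design()].
#' @param window Fit window length in minutes after MEKi (default 45, inside
#'   the 1 h MEKi period to avoid edge effects).
#' @param offset If `FALSE`, fix `c = 0` (pure exponential).
#' @return An object of class `decay_fit`: list with `a`, `b`, `c`, `rss`,
#'   `n_points`, `converged`, `degenerate`.
#' @export
fit_meki_decay <- function(time, value, design, window = 45, offset = TRUE) {
  validate_design(design)
  w <- window_values(time, value, design$t_meki, design$t_meki + window)
  ok <- is.finite(w$value)
  tt <- w$time[ok] - design$t_meki
  yy <- w$value[ok]
  check_that(length(yy) >= 4, "fit_meki_decay",
             "need >= 4 samples in the MEKi window")
  out <- list(a = NA_real_, b = NA_real_, c = NA_real_, rss = NA_real_,
              n_points = length(yy), converged = FALSE, degenerate = FALSE)
  class(out) <- "decay_fit"

  scale <- mean(abs(yy))
  if (sd(yy) < 1e-8 * max(scale, 1e-300) || scale == 0) {
    # flat trace: b unidentifiable, report the degenerate flat fit
    out$a <- 0; out$b <- 0; out$c <- mean(yy)
    out$rss <- sum((yy - mean(yy))^2)
    out$converged <- TRUE; out$degenerate <- TRUE
    return(out)
  }

  y_end <- mean(tail(yy, 2))
  a0 <- max(yy[1] - y_end, 1e-6 * scale)
  c0 <- max(y_end, 0)
  b0 <- log(2) / (window / 3)
  df <- data.frame(t = tt, y = yy)
  fit <- tryCatch({
    if (offset)
      minpack.lm::nlsLM(y ~ a * exp(-b * t) + cc, data = df,
                        start = list(a = a0, b = b0, cc = c0),
                        lower = c(-Inf, 0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ a * exp(-b * t), data = df,
                        start = list(a = a0, b = b0),
                        lower = c(-Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  co <- coef(fit)
  out$a <- unname(co["a"])
  out$b <- unname(co["b"])
  out$c <- if (offset) unname(co["cc"]) else 0
  out$rss <- sum(stats::residuals(fit)^2)
  out$converged <- TRUE
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit: y = %.4g * exp(-%.4g t) + %.4g  (rss %.3g, n = %d, %s%s)\n",
    x$a, x$b, x$c, x$rss, x$n_points,
    if (x$converged) "converged" else "NOT converged",
    if (isTRUE(x$degenerate)) ", degenerate flat fit" else ""))
  invisible(x)
}

#' Fit post-MEKi decays for every cell of a population
#'
#' @param traces Long data frame (`cell_id`, `time_min`, value column;
#'   `experiment_id`, `cell_line`, `treatment` carried through if present).
#' @param design An [experiment_design()].
#' @param value_col Value column name (default `"rho"`).
#' @param ... Passed to [fit_meki_decay()].
#' @return Data frame, one row per cell: grouping columns plus `a`, `b`,
#'   `c`, `rss`, `n_points`, `converged`.
#' @export
fit_population_decays <- function(traces, design, value_col = "rho", ...) {
  by_cell <- split(traces, traces$cell_id, drop = TRUE)
  keep <- intersect(c("experiment_id", "cell_line", "treatment"), names(traces))
  rows <- lapply(names(by_cell), function(id) {
    df <- by_cell[[id]][order(by_cell[[id]]$time_min), ]
    f <- fit_meki_decay(df$time_min, df[[value_col]], design, ...)
    r <- data.frame(cell_id = id, a = f$a, b = f$b, c = f$c, rss = f$rss,
                    n_points = f$n_points, converged = f$converged,
                    stringsAsFactors = FALSE)
    for (col in keep) r[[col]] <- df[[col]][1]
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize decay-rate constants per group
#'
#' Median and quartiles of the fitted decay rate over converged fits within
#' each group (typically cell line by treatment); unconverged fits are
#' excluded and counted.
#'
#' @param fits Data frame from [fit_population_decays()].
#' @param group_cols Character vector of grouping columns present in `fits`.
#' @return Data frame with group columns, `n`, `n_unconverged`, `b_median`,
#'   `b_q25`, `b_q75`. Groups with no converged fit are omitted with a
#'   warning.
#' @export
group_decay_summary <- function(fits, group_cols = "experiment_id") {
  check_that(all(group_cols %in% names(fits)), "group_decay_summary",
             "grouping columns missing from fits")
  key <- interaction(fits[group_cols], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    sub <- fits[key == k, ]
    conv <- sub[sub$converged & is.finite(sub$b), ]
    if (nrow(conv) == 0) {
      warning("group with no converged fits omitted: ",
              gsub("\r", "/", k))
      return(NULL)
    }
    q <- quantile(conv$b, c(0.25, 0.5, 0.75), names = FALSE)
    cbind(sub[1, group_cols, drop = FALSE],
          data.frame(n = nrow(conv), n_unconverged = nrow(sub) - nrow(conv),
                     b_median = q[2], b_q25 = q[1], b_q75 = q[3]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Substrate-level phosphatase activity as the ppERK/activity ratio
#'
#' The reporter activity measurement is the ratio of active-ERK to
#' phosphatase concentrations, while ppERK measures active ERK alone; their
#' ratio `ppERK / activity` therefore estimates the relative phosphatase
#' activity per line and condition. Inputs are matched on `(line,
#' condition)`; replicate rows are summarized by their median, with an
#' optional bootstrap percentile interval over replicates.
#'
#' @param pperk Data frame with `line`, `condition`, `value` (relative
#'   ppERK; replicate rows allowed).
#' @param activity Data frame with `line`, `condition`, `value` (ERK
#'   activity; replicate rows allowed).
#' @param n_boot Bootstrap resamples for the interval (0 to skip).
#' @param conf Interval coverage (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return Data frame with `line`, `condition`, `ratio`, and (when
#'   bootstrapped) `lower`, `upper`. Entries with nonpositive activity are
#'   `NA` and flagged in the `flagged` column.
#' @export
phosphatase_ratio <- function(pperk, activity, n_boot = 500, conf = 0.95,
                              seed = 1L) {
  for (nm in list(pperk, activity))
    check_that(all(c("line", "condition", "value") %in% names(nm)),
               "phosphatase_ratio", "need columns line, condition, value")
  key_p <- unique(paste(pperk$line, pperk$condition, sep = "\r"))
  key_a <- unique(paste(activity$line, activity$condition, sep = "\r"))
  if (!setequal(key_p, key_a))
    fail_invariant("phosphatase_ratio", "mismatched (line, condition) keys")
  boot_ratio <- function(pv, av) {
    median(sample(pv, replace = TRUE)) / median(sample(av, replace = TRUE))
  }
  withr::with_seed(seed, {
    rows <- lapply(key_p, function(k) {
      parts <- strsplit(k, "\r")[[1]]
      pv <- pperk$value[pperk$line == parts[1] & pperk$condition == parts[2]]
      av <- activity$value[activity$line == parts[1] &
                             activity$condition == parts[2]]
      med_a <- median(av)
      flagged <- !is.finite(med_a) || med_a <= 0
      ratio <- if (flagged) NA_real_ else median(pv) / med_a
      r <- data.frame(line = parts[1], condition = parts[2], ratio = ratio,
                      flagged = flagged, stringsAsFactors = FALSE)
      if (n_boot > 0 && !flagged) {
        bs <- replicate(n_boot, boot_ratio(pv, av))
        qq <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
        r$lower <- qq[1]; r$upper <- qq[2]
      }
      r
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
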