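test_that("qc filter drops short and gappy traces and is idempotent", {
  good <- rep(1, 151)
  gappy <- good; gappy[20:25] <- NA          # 6-frame gap > default 3
  short <- c(rep(1, 5), rep(NA, 146))        # 5 finite points < default 10
  traces <- as_long_traces(list(a = good, b = gappy, c = short, d = good))
  out <- qc_filter(traces)
  expect_setequal(unique(out$traces$cell_id), c("a", "d"))
  expect_equal(out$report$dropped_short, 1)
  expect_equal(out$report$dropped_gap, 1)

  again <- qc_filter(out$traces)
  expect_identical(again$traces, out$traces)
  expect_equal(again$report$n_in, again$report$n_kept)

  empty <- qc_filter(traces[0, ])
  expect_equal(nrow(empty$traces), 0)
  expect_equal(empty$report$n_in, 0)
})

test_that("six-SD rule masks an extreme metric value, single pass", {
  withr::with_seed(1, x <- rnorm(500, 10, 1))
  x[1] <- 10 + 10 * sd(x)
  masked <- mask_metric_outliers(x, outlier_sd = 6)
  expect_true(is.na(masked[1]))
  expect_equal(attr(masked, "n_masked"), 1L)
  expect_equal(sum(is.na(masked)), 1)
  # single pass: re-application with the same rule leaves the rest intact
  again <- mask_metric_outliers(as.numeric(masked), outlier_sd = 6)
  expect_equal(attr(again, "n_masked"), 0L)
})

test_that("MEKi normalization zeroes the reference window and is idempotent", {
  ct <- const_trace(v = 2)
  ct$value <- ct$value + 0.5 * (ct$time >= fix_design$t_meki)  # offset anywhere
  v1 <- normalize_trace(ct$time, ct$value, fix_design)
  w <- ct$time >= fix_design$t_meki & ct$time <= fix_design$t_meki + 60
  expect_equal(min(v1[w]), 0)
  expect_equal(as.numeric(v1), ct$value - attr(v1, "offset"))
  v2 <- normalize_trace(ct$time, as.numeric(v1), fix_design)
  expect_equal(as.numeric(v2), as.numeric(v1))

  # median mode subtracts the MEKi-period median
  vm <- normalize_trace(ct$time, ct$value, fix_design, mode = "median")
  expect_equal(attr(vm, "offset"),
               median(ct$value[ct$time >= fix_design$t_meki]))

  expect_error(normalize_trace(0:10, rnorm(11), fix_design), "MEKi window")
})

test_that("baseline mean matches constants and ramp midpoints", {
  ct <- const_trace(v = 0.7)
  expect_equal(baseline_mean(ct$time, ct$value, fix_design), 0.7)
  ramp <- const_trace()
  ramp$value <- 0.01 * ramp$time
  w <- ramp$time >= fix_design$t_stim - 120 & ramp$time < fix_design$t_stim
  expect_equal(baseline_mean(ramp$time, ramp$value, fix_design),
               0.01 * mean(ramp$time[w]))
  expect_error(baseline_mean(c(0, 3), c(1, 1), fix_design), "window empty")
})

test_that("peak response returns the first maximum within the horizon", {
  ct <- const_trace(v = 0.2)
  ct$value[ct$time == fix_design$t_stim + 15] <- 0.8
  pk <- peak_response(ct$time, ct$value, fix_design)
  expect_equal(pk$peak, 0.8)
  expect_equal(pk$time_to_peak, 15)

  # tie at two times: earlier returned
  ct$value[ct$time == fix_design$t_stim + 30] <- 0.8
  expect_equal(peak_response(ct$time, ct$value, fix_design)$time_to_peak, 15)
})

test_that("post-stimulus windows average as specified", {
  ct <- const_trace(v = 0.9)
  expect_equal(as.numeric(post_stim_mean(ct$time, ct$value, fix_design)), 0.9)
  expect_equal(as.numeric(steady_state(ct$time, ct$value, fix_design)), 0.9)

  step <- const_trace(v = 0)
  step$value[step$time >= fix_design$t_stim] <- 1
  expect_equal(as.numeric(post_stim_mean(step$time, step$value, fix_design)), 1)

  # window truncated by MEKi is flagged
  tight <- experiment_design(t_stim = 240, t_meki = 330, t_end = 420)
  ps <- post_stim_mean(step$time, step$value, tight)
  expect_true(attr(ps, "truncated"))
})

test_that("steady-state window recovers the generator steady level", {
  tr <- cell_ground_truth(adapt_tau = 20, pulse_rate = 0, steady_rho = 0.5)
  x <- simulate_rho_trace(fix_design, tr)
  expect_equal(as.numeric(steady_state(x$time_min, x$rho, fix_design)),
               0.5, tolerance = 0.01)
})

test_that("volatility is zero on constants, scale-free, and matches its closed form", {
  ct <- const_trace(v = 3)
  expect_equal(volatility(ct$time, ct$value, fix_design), 0)

  # alternating a, a + d at interval dt: V = (d / dt) / (a + d / 2)
  alt <- const_trace()
  a <- 0.4; d <- 0.3; dt <- fix_design$sampling_interval
  alt$value <- a + d * (seq_along(alt$time) %% 2)
  w <- alt$time >= fix_design$t_stim & alt$time < fix_design$t_stim + 120
  expect_equal(sum(w) %% 2, 0)  # even count: window mean is exactly a + d/2
  expect_equal(volatility(alt$time, alt$value, fix_design),
               (d / dt) / (a + d / 2), tolerance = 1e-12)

  # scale invariance over random traces
  withr::with_seed(8, {
    for (i in 1:20) {
      v <- abs(rnorm(length(ct$time), 1, 0.3)) + 0.1
      c_scale <- runif(1, 0.1, 10)
      expect_equal(volatility(ct$time, c_scale * v, fix_design),
                   volatility(ct$time, v, fix_design), tolerance = 1e-12)
    }
  })

  # undefined when the window mean is not positive
  neg <- const_trace(v = -1)
  expect_true(is.na(suppressWarnings(volatility(neg$time, neg$value, fix_design))))

  # baseline-window variant sees pre-stimulus variation only
  pre <- const_trace(v = 1)
  pre$value[pre$time < fix_design$t_stim] <-
    1 + 0.5 * (seq_len(sum(pre$time < fix_design$t_stim)) %% 2)
  expect_gt(volatility(pre$time, pre$value, fix_design, window = "baseline"),
            volatility(pre$time, pre$value, fix_design))
})

test_that("responder classification accepts steps and rejects flat or drifting traces", {
  # instantaneous +50% step at the stimulus
  step <- const_trace(v = 1)
  step$value[step$time > fix_design$t_stim] <- 1.5
  expect_true(classify_responder(step$time, step$value, fix_design))

  # flat trace with 1% noise: non-responder in >= 95% of cells
  withr::with_seed(33, {
    calls <- vapply(1:200, function(i) {
      v <- 1 * (1 + rnorm(151, 0, 0.01))
      classify_responder(const_trace()$time, v, fix_design)
    }, logical(1))
  })
  expect_gte(mean(!calls), 0.95)

  # slow linear drift reaching +20% of baseline by 2 h: derivative criterion
  # rejects it even though the magnitude criterion passes
  drift <- const_trace(v = 1)
  slope <- 0.2 / 120
  drift$value <- 1 + slope * (drift$time - fix_design$t_start)
  expect_false(classify_responder(drift$time, drift$value, fix_design,
                                  full_scale = 1.5))
})

test_that("per-cell metrics satisfy their identities and order invariance", {
  spec <- default_population_spec(40, seed = 13)
  sq <- simulate_and_quantify(spec)
  m <- compute_trace_metrics(sq$rho, fix_design)
  expect_equal(nrow(m), 40)
  expect_equal(m$amplitude, m$peak - m$baseline, tolerance = 1e-12)
  expect_true(all(m$volatility >= 0, na.rm = TRUE))
  expect_true(all(is.na(m$time_to_peak[!m$responder])))

  # invariant to the order of cells in the input
  shuf <- sq$rho[withr::with_seed(2, sample(nrow(sq$rho))), ]
  m2 <- compute_trace_metrics(shuf, fix_design)
  m2 <- m2[match(m$cell_id, m2$cell_id), ]
  rownames(m2) <- NULL
  expect_equal(m2, m, tolerance = 1e-12)
})

test_that("MEKi normalization improves baseline recovery under per-cell offsets", {
  # plant a per-cell additive offset (non-specific fluorescence analogue)
  spec <- default_population_spec(30, seed = 41)
  sim <- simulate_population(spec, fix_design, raw = FALSE)
  withr::with_seed(42, offs <- runif(30, 0.05, 0.3))
  names(offs) <- sim$truth$cell_id
  sim$traces$rho <- sim$traces$rho + offs[sim$traces$cell_id]
  err <- function(normalize) {
    m <- compute_trace_metrics(sim$traces, fix_design, normalize = normalize)
    mean(abs(m$baseline - sim$truth$baseline_rho[match(m$cell_id,
                                                       sim$truth$cell_id)]))
  }
  expect_lt(err("min"), err("none"))
})

test_that("response frequency aggregates per experiment", {
  m <- data.frame(cell_id = sprintf("c%02d", 1:40),
                  experiment_id = rep(c("e1", "e2"), each = 20),
                  responder = rep(c(TRUE, FALSE), times = c(30, 10)))
  rf <- response_frequency(m)
  expect_equal(rf$per_experiment$fraction, c(1, 0.5))
  expect_equal(rf$mean, 0.75)

  all_resp <- data.frame(cell_id = "c", experiment_id = "e1", responder = TRUE)
  expect_equal(response_frequency(all_resp)$mean, 1)

  none <- response_frequency(m[0, ])
  expect_true(none$undefined)
})
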