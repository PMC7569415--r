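# Independent ODE oracle: integrates the explicit kinetic system (nucleotide
# cycle, RAS-GTP/RAF binding with finite on/off rates, and both push-pull
# tiers) to steady state with deSolve and reports the fractional ppERK.
ode_pperk <- function(params, abund, rates, stimulated, t_end = 1e4) {
  k_ex <- if (stimulated) params$k_ex_stim else params$k_ex_basal
  raf_t <- abund$BRAF_t + abund$CRAF_t
  kon <- 100  # fast binding; koff = kon * Kd keeps the stated equilibrium
  rhs <- function(t, y, p) {
    G <- y[1]; C <- y[2]; Mp <- y[3]; Ep <- y[4]
    dG <- k_ex * (abund$RAS_t - G) - (params$k_int + params$k_gap) * G
    dC <- kon * (G - C) * (raf_t - C) - kon * params$Kd_raf * C
    dMp <- rates$a_mek * C * (abund$MEK_t - Mp) - rates$d_mek * Mp
    dEp <- rates$a_erk * Mp * (abund$ERK_t - Ep) - rates$d_erk * Ep
    list(c(dG, dC, dMp, dEp))
  }
  out <- deSolve::ode(c(0, 0, 0, 0), c(0, t_end), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), 5] / abund$ERK_t)
}

test_that("GTP-loading fraction follows the exchange/hydrolysis balance", {
  p <- isoform_params(k_int = 0.05, k_gap = 0.15, k_ex_basal = 0.2,
                      k_ex_stim = 0.5, Kd_raf = 1)
  expect_equal(ras_gtp_fraction(p), 0.5)  # k_ex == k_int + k_gap
  expect_equal(ras_gtp_fraction(p, stimulated = TRUE), 0.5 / (0.5 + 0.2))

  # monotone: increasing in k_ex, decreasing in k_int and k_gap
  f <- function(ki, kg, ke) ras_gtp_fraction(
    isoform_params(ki, kg, ke, ke, 1))
  ke_grid <- seq(0.01, 2, length.out = 10)
  expect_true(all(diff(vapply(ke_grid, function(ke) f(0.1, 0.1, ke),
                              numeric(1))) > 0))
  kg_grid <- seq(0, 5, length.out = 10)
  expect_true(all(diff(vapply(kg_grid, function(kg) f(0.1, kg, 0.3),
                              numeric(1))) < 0))
  # GAP-insensitive mutant with shared exchange loads more GTP
  expect_gt(f(0.1, 0, 0.3), f(0.1, 5, 0.3))

  expect_error(ras_gtp_fraction(isoform_params(0, 0, 0, 0, 1)), "undefined")
})

test_that("RAF recruitment solves the binding quadratic at its known points", {
  # G = RAF = Kd = 1: C = (3 - sqrt(5)) / 2
  expect_equal(raf_recruitment(1, 1, 1, 1), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  # tight-binding limit: C -> min(G, RAF)
  expect_equal(raf_recruitment(0.4, 1, 2, 0), 0.4, tolerance = 1e-12)
  expect_equal(raf_recruitment(1, 3, 2, 0), 2, tolerance = 1e-12)
  # weak-binding limit: C ~ G * RAF / Kd -> 0
  expect_equal(raf_recruitment(0.5, 1, 1, 1e8), 0.5 * 1 / 1e8,
               tolerance = 1e-3)
  expect_equal(raf_recruitment(0, 1, 1, 1), 0)
  # continuity across Kd = 0 (no branch discontinuity at the root)
  kd <- c(1e-10, 1e-8, 1e-6, 1e-4)
  cc <- vapply(kd, function(k) raf_recruitment(0.5, 1, 1, k), numeric(1))
  expect_true(all(abs(cc - 0.5) < 1e-3))
})

test_that("push-pull tiers hit their balance points and saturation limits", {
  ab <- abundances()
  r <- cascade_rates(a_mek = 1, d_mek = 0.5, a_erk = 1, d_erk = 0.4)
  ss <- cascade_steady_state(0.5, ab, r)  # a_mek * raf = d_mek
  expect_equal(ss$f_ppmek, 0.5)
  near_on <- cascade_steady_state(10, ab, cascade_rates(1, 1e-9, 1, 1e-9))
  expect_equal(near_on$f_ppmek, 1, tolerance = 1e-6)
  expect_equal(near_on$f_pperk, 1, tolerance = 1e-6)
})

test_that("closed-form steady states agree with the ODE oracle on random parameters", {
  withr::with_seed(101, {
    for (i in 1:100) {
      p <- isoform_params(k_int = runif(1, 0.001, 0.1),
                          k_gap = runif(1, 0, 5),
                          k_ex_basal = runif(1, 0.005, 0.3),
                          k_ex_stim = runif(1, 0.3, 1),
                          Kd_raf = runif(1, 0.2, 7))
      ab <- abundances(RAS_t = runif(1, 0.3, 3), BRAF_t = runif(1, 0.2, 2),
                       CRAF_t = runif(1, 0.2, 2), MEK_t = runif(1, 0.3, 3),
                       ERK_t = runif(1, 0.3, 3))
      r <- cascade_rates(a_mek = runif(1, 1, 60), d_mek = runif(1, 0.1, 2),
                         a_erk = runif(1, 0.1, 2), d_erk = runif(1, 0.1, 2))
      stim <- runif(1) < 0.5
      closed <- internal_model_state(p, ab, r, stimulated = stim)$f_pperk
      expect_equal(closed, ode_pperk(p, ab, r, stim), tolerance = 1e-6)
    }
  })
})

test_that("panel predictions have the stated symmetries and monotonicities", {
  iso <- default_isoform_params()
  ab <- abundances()
  rates <- default_cascade_rates()

  # identical parameters across lines: identical predictions
  same <- setNames(rep(list(iso$KRAS_WT), 3), c("l1", "l2", "l3"))
  pan_same <- predict_panel(same, ab, rates)
  expect_equal(unique(pan_same$pperk_rel[pan_same$condition == "baseline"]),
               1)
  expect_equal(length(unique(pan_same$pperk_rel[pan_same$condition ==
                                                  "stimulated"])), 1)

  # reducing total hydrolysis 100-fold raises baseline ppERK above wild type
  wt <- iso$KRAS_WT
  mut <- isoform_params(k_int = (wt$k_int + wt$k_gap) / 100, k_gap = 0,
                        k_ex_basal = wt$k_ex_basal, k_ex_stim = wt$k_ex_stim,
                        Kd_raf = wt$Kd_raf)
  pan <- predict_panel(list(KRAS_WT = wt, MUT = mut), ab, rates,
                       reference_line = "KRAS_WT")
  base <- pan[pan$condition == "baseline", ]
  expect_gt(base$pperk_rel[base$line == "MUT"],
            base$pperk_rel[base$line == "KRAS_WT"])
  # cross-check the same ordering with the ODE oracle
  expect_gt(ode_pperk(mut, ab, rates, FALSE), ode_pperk(wt, ab, rates, FALSE))

  # predictions invariant to rescaling the concentration unit: abundances and
  # Kd (both concentrations) scale by c, bimolecular rates a1, a2 by 1/c
  c_fac <- 3.7
  ab2 <- abundances(RAS_t = c_fac, BRAF_t = 0.5 * c_fac, CRAF_t = 0.5 * c_fac,
                    MEK_t = c_fac, ERK_t = c_fac)
  rates2 <- cascade_rates(a_mek = rates$a_mek / c_fac, d_mek = rates$d_mek,
                          a_erk = rates$a_erk / c_fac, d_erk = rates$d_erk)
  iso2 <- lapply(iso, function(p) {
    p$Kd_raf <- p$Kd_raf * c_fac
    p
  })
  pan1 <- predict_panel(iso, ab, rates)
  pan2 <- predict_panel(iso2, ab2, rates2)
  expect_equal(pan2$pperk_rel, pan1$pperk_rel, tolerance = 1e-9)

  expect_error(predict_panel(iso, ab, rates, reference_line = "NOPE"),
               "missing line")
})

test_that("stimulation amplitude behaves as the composed model dictates", {
  iso <- default_isoform_params()
  pan <- predict_panel(iso, abundances(), default_cascade_rates())
  fc <- stimulation_amplitude(pan)
  # fold change >= 1 whenever stimulation raises exchange
  expect_true(all(fc$fold_change >= 1))
  # wild type has a strictly larger fold change than GAP-insensitive mutants
  wt_fc <- fc$fold_change[fc$line == "KRAS_WT"]
  for (line in setdiff(fc$line, "KRAS_WT"))
    expect_gt(wt_fc, fc$fold_change[fc$line == line])

  flat <- data.frame(line = "x", condition = c("baseline", "stimulated"),
                     pperk_rel = c(2, 2))
  expect_equal(stimulation_amplitude(flat)$fold_change, 1)
  zero <- data.frame(line = "x", condition = c("baseline", "stimulated"),
                     pperk_rel = c(0, 1))
  expect_warning(out <- stimulation_amplitude(zero), "zero baseline")
  expect_true(is.na(out$fold_change))
})

test_that("model-measurement discrepancy recovers a planted suppression factor", {
  iso <- default_isoform_params()
  predicted <- predict_panel(iso, abundances(), default_cascade_rates(),
                             normalize = FALSE)
  s_base <- 0.6; s_stim <- 0.25
  measured <- predicted
  measured$pperk_rel <- measured$pperk_rel *
    ifelse(measured$condition == "baseline", s_base, s_stim) * 13.7  # units
  disc <- model_measurement_discrepancy(predicted, measured,
                                        reference_line = "KRAS_WT")
  # after reference normalization the recoverable quantity is s / s_baseline
  expect_equal(disc$ratio[disc$condition == "baseline"],
               rep(1, 5), tolerance = 1e-9)
  expect_equal(disc$ratio[disc$condition == "stimulated"],
               rep(s_stim / s_base, 5), tolerance = 1e-9)

  ident <- model_measurement_discrepancy(predicted, predicted,
                                         reference_line = "KRAS_WT")
  expect_equal(ident$ratio, rep(1, nrow(ident)), tolerance = 1e-12)

  bad <- measured[measured$line != "KRAS_Q61R", ]
  expect_error(model_measurement_discrepancy(predicted, bad, "KRAS_WT"),
               "mismatched")
})

test_that("shipped mutant parameters respect the literature bounds", {
  iso <- default_isoform_params()
  wt_total <- iso$KRAS_WT$k_int + iso$KRAS_WT$k_gap
  for (line in setdiff(names(iso), "KRAS_WT")) {
    fold <- wt_total / (iso[[line]]$k_int + iso[[line]]$k_gap)
    expect_gte(fold, 50)
    expect_lte(fold, 800)
    expect_lte(iso[[line]]$Kd_raf / iso$KRAS_WT$Kd_raf, 7)
    expect_equal(iso[[line]]$k_gap, 0)
  }
})
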