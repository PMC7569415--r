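test_that("two-level t-test collapses to Welch on experiment means", {
  # zero within-experiment variance: cells within an experiment identical
  mA <- c(1.0, 1.4, 0.9, 1.2)
  mB <- c(0.7, 0.8, 0.9)
  gA <- lapply(mA, function(m) rep(m, 50))
  gB <- lapply(mB, function(m) rep(m, 50))
  ht <- hierarchical_ttest(gA, gB)
  wt <- t.test(mA, mB)  # Welch on the experiment means
  expect_equal(ht$t, unname(wt$statistic), tolerance = 1e-12)
  expect_equal(ht$df, unname(wt$parameter), tolerance = 1e-12)
  expect_equal(ht$p, wt$p.value, tolerance = 1e-12)
})

test_that("two-level t-test is symmetric and zero for identical groups", {
  withr::with_seed(3, g <- lapply(1:4, function(j) rnorm(30, j / 10)))
  same <- hierarchical_ttest(g, g)
  expect_equal(same$t, 0)
  withr::with_seed(4, h <- lapply(1:3, function(j) rnorm(30, 0.5)))
  ab <- hierarchical_ttest(g, h)
  ba <- hierarchical_ttest(h, g)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  expect_error(hierarchical_ttest(g[1], h), ">= 2 experiments")
  expect_error(hierarchical_ttest(list(1, 1:5), h), ">= 2 cells")
})

test_that("two-level t-test accepts long data frames", {
  withr::with_seed(5, {
    df <- data.frame(value = rnorm(60),
                     experiment_id = rep(c("e1", "e2", "e3"), each = 20))
  })
  ht1 <- hierarchical_ttest(df, df)
  expect_equal(ht1$t, 0)
})

# Brute-force step-up oracle: largest k with p_(k) <= k * alpha / m.
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  flags <- rep(FALSE, m)
  if (length(k) > 0) flags[o[seq_len(max(k))]] <- TRUE
  flags
}

test_that("BH flags match the exhaustive step-up oracle on random vectors", {
  expect_true(all(bh_fdr(rep(0.001, 10))$significant))
  expect_true(bh_fdr(0.04)$significant)   # m = 1 reduces to the raw threshold
  expect_false(bh_fdr(0.06)$significant)
  withr::with_seed(11, {
    for (i in 1:1000) {
      m <- sample(1:8, 1)
      p <- round(runif(m), 3)
      res <- bh_fdr(p)
      expect_identical(res$significant, bh_oracle(p))
      expect_true(all(diff(sort(res$adjusted)) >= 0))
    }
  })
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("BH flags are monotone when any p-value decreases", {
  withr::with_seed(12, {
    for (i in 1:200) {
      p <- runif(6)
      f1 <- bh_fdr(p)$significant
      j <- sample(6, 1)
      p2 <- p
      p2[j] <- p[j] * runif(1)
      f2 <- bh_fdr(p2)$significant
      # lowering one p-value never unflags another test
      expect_true(all(f2[setdiff(which(f1), j)]))
    }
  })
})

test_that("PLSR captures a perfect single-factor response", {
  withr::with_seed(21, {
    n <- 64
    X <- data.frame(EGF = rbinom(n, 1, 0.5), RAS = rnorm(n), BRAF = rnorm(n),
                    CRAF = rnorm(n), MEK = rnorm(n), ERK = rnorm(n))
    # make the noise predictors exactly orthogonal to the active one in
    # sample, so a single latent component carries all the signal
    for (col in c("EGF", "BRAF", "CRAF", "MEK", "ERK"))
      X[[col]] <- residuals(lm(X[[col]] ~ X$RAS))
    y <- 3 * X$RAS + 1
  })
  f <- plsr_fit(X, y, max_components = 4)
  expect_gte(f$variance_explained[1], 99.9)
  expect_equal(names(which.max(abs(f$weights))), "RAS")
  # variance explained never decreases with components
  expect_true(all(diff(f$variance_explained) >= -1e-9))

  Xc <- X; Xc$BRAF <- 5
  expect_error(plsr_fit(Xc, y), "constant column.*BRAF")
})

test_that("PLSR is invariant to affine rescaling of predictors", {
  withr::with_seed(22, {
    X <- matrix(rnorm(40 * 4), 40)
    colnames(X) <- letters[1:4]
    y <- X[, 1] - 0.5 * X[, 3] + rnorm(40, 0, 0.2)
  })
  f1 <- plsr_fit(X, y)
  X2 <- X
  X2[, 2] <- 100 * X2[, 2] - 7
  f2 <- plsr_fit(X2, y)
  expect_equal(f2$weights, f1$weights, tolerance = 1e-9)
  expect_equal(f2$variance_explained, f1$variance_explained, tolerance = 1e-9)
})

test_that("PLSR agrees with an independent implementation", {
  withr::with_seed(23, {
    n <- 30
    X <- matrix(rnorm(n * 5), n)
    colnames(X) <- paste0("x", 1:5)
    y <- X[, 1] + 0.7 * X[, 2] + rnorm(n, 0, 0.5)
  })
  mix <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  r2_mix <- vapply(1:3, function(k) {
    yhat <- predict(mix, X)$predict[, 1, k]
    100 * (1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  }, numeric(1))
  f <- plsr_fit(X, y, max_components = 3)
  expect_equal(f$variance_explained, r2_mix, tolerance = 1e-6)
})

test_that("permuted responses fall below their own null calibration", {
  withr::with_seed(24, {
    X <- matrix(rnorm(40 * 5), 40)
    colnames(X) <- paste0("x", 1:5)
    y_null <- rnorm(40)
    v_obs <- plsr_fit(X, y_null, max_components = 1)$variance_explained[1]
    v_perm <- vapply(1:200, function(i)
      plsr_fit(X, sample(y_null), max_components = 1)$variance_explained[1],
      numeric(1))
  })
  expect_lt(v_obs, quantile(v_perm, 0.95))
})

test_that("null bounds are seed-deterministic and detect a planted predictor", {
  withr::with_seed(25, {
    X <- matrix(rnorm(32 * 6), 32)
    colnames(X) <- paste0("x", 1:6)
    y <- 1.0 * X[, 3] + rnorm(32)
  })
  b1 <- plsr_null_bounds(X, y, n_perm = 200, seed = 5)
  b2 <- plsr_null_bounds(X, y, n_perm = 200, seed = 5)
  expect_identical(b1, b2)
  expect_true(b1$significant[["x3"]])
  expect_lte(sum(b1$significant[-3]), 2)
  expect_warning(plsr_null_bounds(X, y, n_perm = 50, seed = 1), "unstable")
})

test_that("Tjur's D separates, nulls, and matches a grid-search oracle", {
  # perfectly separated classes: D -> 1
  withr::with_seed(30, x_sep <- c(rnorm(30, 0), rnorm(30, 200)))
  y_sep <- rep(c(FALSE, TRUE), each = 30)
  fit_sep <- tjur_discrimination(x_sep, y_sep)
  expect_gte(fit_sep$D, 0.99)
  # a short separated sample triggers the penalized fallback explicitly
  fit_pen <- tjur_discrimination(c(1, 2, 3, 10, 11, 12),
                                 rep(c(FALSE, TRUE), each = 3))
  expect_true(fit_pen$penalized)
  expect_true(is.finite(fit_pen$slope))
  # the Jeffreys penalty keeps estimates finite, at the cost of shrinkage on
  # such a short sample; D still clearly separates the classes
  expect_gte(fit_pen$D, 0.7)

  # flags independent of the covariate: |D| small
  withr::with_seed(31, {
    x0 <- rnorm(1000)
    y0 <- runif(1000) < 0.5
  })
  expect_lte(abs(tjur_discrimination(x0, y0)$D), 0.05)

  # 4-point dataset: compare with brute-force ML over a parameter grid
  x4 <- c(0, 0.2, 0.8, 1)
  y4 <- c(FALSE, TRUE, FALSE, TRUE)
  loglik <- function(b0, b1) {
    pr <- 1 / (1 + exp(-(b0 + b1 * x4)))
    sum(ifelse(y4, log(pr), log(1 - pr)))
  }
  grid <- expand.grid(b0 = seq(-5, 5, by = 0.01), b1 = seq(-5, 5, by = 0.01))
  ll <- mapply(loglik, grid$b0, grid$b1)
  best <- grid[which.max(ll), ]
  pr_best <- 1 / (1 + exp(-(best$b0 + best$b1 * x4)))
  d_oracle <- mean(pr_best[y4]) - mean(pr_best[!y4])
  expect_lt(abs(tjur_discrimination(x4, y4)$D - d_oracle), 1e-3)

  # D is invariant under linear rescaling of the covariate
  withr::with_seed(32, {
    xl <- rnorm(200)
    yl <- runif(200) < 1 / (1 + exp(-xl))
  })
  expect_equal(tjur_discrimination(3 * xl + 2, yl)$D,
               tjur_discrimination(xl, yl)$D, tolerance = 1e-6)

  expect_error(tjur_discrimination(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("Pearson summaries match their closed forms", {
  x <- 1:20
  expect_equal(pearson_summary(x, 2 * x)$R, 1)
  expect_equal(pearson_summary(x, -x + 5)$R, -1)
  withr::with_seed(41, {
    a <- rnorm(1000)
    b <- rnorm(1000)
  })
  expect_lt(abs(pearson_summary(a, b)$R), 0.1)
  expect_error(pearson_summary(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_summary(1:2, 2:3), "n >= 3")
})
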