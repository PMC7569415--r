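#' Two-level-error t-test for single-cell data with experiment replicates
#'
#' Implements the additive error model `e_cell + e_exp`: the error of an
#' individual cell is the sum of cell-to-cell and experiment-to-experiment
#' components. For each group, the variance of each experiment's mean is
#' estimated from its single-cell sample (`s_j^2 / n_j`) and added to the
#' variance across experiment means; the comparison is a Welch-style unequal
#' variance t-test on the group means with Satterthwaite degrees of freedom.
#'
#' @param groupA,groupB Either a list of numeric vectors (one per
#'   experiment), or a data frame with columns `value` and `experiment_id`.
#'   Each group needs at least 2 experiments with at least 2 cells each.
#' @return List with `t`, `p` (two-sided), `df`, and per-group summaries
#'   (`mean`, `var_of_mean`, `n_experiments`).
#' @export
hierarchical_ttest <- function(groupA, groupB) {
  sA <- hier_summary(groupA)
  sB <- hier_summary(groupB)
  VA <- sA$var_of_mean
  VB <- sB$var_of_mean
  tstat <- (sA$mean - sB$mean) / sqrt(VA + VB)
  df <- (VA + VB)^2 /
    (VA^2 / (sA$n_experiments - 1) + VB^2 / (sB$n_experiments - 1))
  list(t = tstat, p = 2 * pt(-abs(tstat), df), df = df,
       groupA = sA, groupB = sB)
}

hier_summary <- function(g) {
  if (is.data.frame(g)) {
    check_that(all(c("value", "experiment_id") %in% names(g)),
               "hierarchical sample", "need columns value and experiment_id")
    g <- split(g$value, g$experiment_id)
  }
  check_that(is.list(g), "hierarchical sample",
             "group must be a list of per-experiment vectors or a data frame")
  g <- lapply(g, function(x) x[is.finite(x)])
  J <- length(g)
  check_that(J >= 2, "hierarchical sample", "need >= 2 experiments per group")
  n_j <- vapply(g, length, integer(1))
  check_that(all(n_j >= 2), "hierarchical sample",
             "need >= 2 cells per experiment")
  m_j <- vapply(g, mean, numeric(1))
  v_j <- vapply(g, var, numeric(1)) / n_j  # variance of each experiment mean
  list(mean = mean(m_j),
       var_of_mean = var(m_j) / J + mean(v_j) / J,
       n_experiments = J, experiment_means = m_j)
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `significant` (logical flags from the step-up rule) and
#'   `adjusted` (monotone BH-adjusted p-values).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  check_that(is.numeric(pvalues) && all(is.finite(pvalues)), "bh_fdr",
             "p-values must be finite numbers")
  if (any(pvalues < 0 | pvalues > 1))
    fail_invariant("bh_fdr", "p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(significant = adjusted <= alpha, adjusted = adjusted)
}

standardize_columns <- function(X) {
  X <- as.matrix(X)
  check_that(is.numeric(X), "plsr", "predictors must be numeric")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  bad <- which(!is.finite(sdv) | sdv == 0)
  if (length(bad) > 0)
    fail_invariant("plsr", paste("constant column cannot be standardized:",
                                 paste(colnames(X)[bad], collapse = ", ")))
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

# Core PLS1 (NIPALS) on pre-standardized matrices; returns per-component
# weights, regression coefficients and cumulative variance explained.
pls1_core <- function(Xs, ys, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  ncomp <- min(ncomp, p, n - 1)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  Xr <- Xs; yr <- ys
  ss_tot <- sum(ys^2)
  varexp <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {  # residual orthogonal to X: stop early
      W <- W[, seq_len(k - 1), drop = FALSE]
      P <- P[, seq_len(k - 1), drop = FALSE]
      qv <- qv[seq_len(k - 1)]
      varexp <- c(varexp[seq_len(k - 1)],
                  rep(varexp[max(k - 1, 1)], ncomp - k + 1))[seq_len(ncomp)]
      ncomp <- k - 1
      break
    }
    w <- w / nw
    tt <- Xr %*% w
    tt2 <- sum(tt^2)
    pv <- crossprod(Xr, tt) / tt2
    qk <- sum(yr * tt) / tt2
    Xr <- Xr - tt %*% t(pv)
    yr <- yr - qk * tt
    W[, k] <- w; P[, k] <- pv; qv[k] <- qk
    varexp[k] <- 1 - sum(yr^2) / ss_tot
  }
  # regression coefficients (standardized scale) at each component count
  coefs <- matrix(0, p, length(qv))
  if (length(qv) > 0) {
    for (k in seq_along(qv)) {
      Wk <- W[, seq_len(k), drop = FALSE]
      Pk <- P[, seq_len(k), drop = FALSE]
      coefs[, k] <- Wk %*% solve(crossprod(Pk, Wk), qv[seq_len(k)])
    }
  }
  list(W = W, P = P, q = qv, coefficients = coefs,
       variance_explained = 100 * varexp, ncomp = ncomp)
}

#' Partial least squares regression of ppERK on pathway predictors
#'
#' NIPALS PLS regression with a univariate response. Predictors and response
#' are standardized internally (zero mean, unit SD), so results are invariant
#' to affine rescaling of any predictor column. Reports the percentage of
#' response variance explained at each component count and the predictor
#' weights; `weights` are the standardized regression coefficients at the
#' chosen component count (default 2), the quantity compared against
#' permutation-null bounds.
#'
#' @param X Data frame or matrix of predictors (e.g. EGF indicator and
#'   RAS/BRAF/CRAF/MEK/ERK abundances), `>= 2` rows, no constant column.
#' @param y Numeric response (e.g. relative ppERK).
#' @param max_components Maximum number of latent components.
#' @param report_components Component count at which `weights` are reported.
#' @return An object of class `plsr_result`: list with `variance_explained`
#'   (% per component count, non-decreasing), `weights` (named numeric),
#'   `coefficients` (matrix: predictors by component count), `W`
#'   (projection weights), `predictors`, `ncomp`, `report_components`.
#' @export
plsr_fit <- function(X, y, max_components = 4, report_components = 2) {
  X <- as.data.frame(X)
  check_that(nrow(X) >= 2, "plsr", "need >= 2 rows")
  check_that(length(y) == nrow(X), "plsr", "y length must match rows of X")
  Xs <- standardize_columns(X)
  ys <- as.numeric(scale(y))
  check_that(all(is.finite(ys)), "plsr", "response is constant or non-finite")
  core <- pls1_core(Xs, ys, max_components)
  k <- min(report_components, core$ncomp)
  weights <- setNames(core$coefficients[, k], colnames(Xs))
  structure(list(variance_explained = core$variance_explained,
                 weights = weights, coefficients = core$coefficients,
                 W = core$W, predictors = colnames(Xs),
                 ncomp = core$ncomp, report_components = k),
            class = "plsr_result")
}

#' @export
print.plsr_result <- function(x, ...) {
  cat("plsr_result:", x$ncomp, "components; % variance explained:",
      paste(sprintf("%.1f", x$variance_explained), collapse = ", "), "\n")
  cat("weights at", x$report_components, "components:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Permutation-null significance bounds for PLSR weights
#'
#' The association between predictors and response is broken by permuting the
#' response rows; the PLSR weights are refit for each permutation and the
#' 2.5th/97.5th percentiles of each predictor's null weight distribution form
#' its significance band. A fitted weight is significant when it falls
#' outside its band.
#'
#' @param X,y As in [plsr_fit()].
#' @param n_perm Number of permutations (warning below 100: unstable
#'   percentiles).
#' @param report_components Component count at which weights are compared.
#' @param level Two-sided significance level (default 0.05).
#' @param seed Integer seed.
#' @return List with `bounds` (data frame: `predictor`, `lower`, `upper`),
#'   `weights` (observed), `significant` (logical per predictor), `n_perm`.
#' @export
plsr_null_bounds <- function(X, y, n_perm = 1000, report_components = 2,
                             level = 0.05, seed = 1L) {
  if (n_perm < 100)
    warning("n_perm < 100: percentile bounds will be unstable")
  X <- as.data.frame(X)
  Xs <- standardize_columns(X)
  ys <- as.numeric(scale(y))
  k <- report_components
  obs <- pls1_core(Xs, ys, k)
  kk <- min(k, obs$ncomp)
  w_obs <- setNames(obs$coefficients[, kk], colnames(Xs))
  null_w <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- ys[sample.int(length(ys))]
      core <- pls1_core(Xs, yp, k)
      core$coefficients[, min(k, core$ncomp)]
    }, numeric(ncol(Xs)))
  })
  # order-statistic bounds with the (m + 1) permutation convention, so a
  # null weight falls outside its band with probability ~level exactly
  k_lo <- max(1L, floor((level / 2) * (n_perm + 1)))
  k_hi <- min(n_perm, ceiling((1 - level / 2) * (n_perm + 1)))
  lo <- apply(null_w, 1, function(v) sort(v)[k_lo])
  hi <- apply(null_w, 1, function(v) sort(v)[k_hi])
  bounds <- data.frame(predictor = colnames(Xs), lower = lo, upper = hi,
                       stringsAsFactors = FALSE)
  list(bounds = bounds, weights = w_obs,
       significant = w_obs < lo | w_obs > hi, n_perm = n_perm)
}

#' Tjur's coefficient of discrimination for a binary response
#'
#' Fits a logistic regression of the binary flag on a single covariate and
#' reports D, the difference between the mean fitted probability among
#' positive and among negative cases — a correlation-coefficient analogue
#' for binary outcomes. Under complete separation the maximum-likelihood fit
#' diverges, so a Jeffreys-prior (Firth-type) penalized fit is used instead
#' and flagged.
#'
#' @param baseline_values Numeric covariate (e.g. per-cell baseline
#'   activity).
#' @param responder_flags Logical (or 0/1) outcome; both classes must be
#'   present.
#' @return List with `D`, `intercept`, `slope`, `penalized` (logical).
#' @export
tjur_discrimination <- function(baseline_values, responder_flags) {
  x <- as.numeric(baseline_values)
  yb <- as.logical(responder_flags)
  keep <- is.finite(x) & !is.na(yb)
  x <- x[keep]; yb <- yb[keep]
  if (length(unique(yb)) < 2)
    fail_invariant("tjur_discrimination", "both outcome classes must be present")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(yb ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || any(abs(coef(fit)) > 1e3)) {
    co <- firth_logistic(x, yb)
    penalized <- TRUE
  } else {
    co <- coef(fit)
    penalized <- FALSE
  }
  eta <- co[1] + co[2] * x
  pr <- 1 / (1 + exp(-eta))
  list(D = mean(pr[yb]) - mean(pr[!yb]),
       intercept = unname(co[1]), slope = unname(co[2]),
       penalized = penalized)
}

# Jeffreys-prior penalized logistic regression (single covariate):
# maximizes loglik + 0.5 * log det X'WX, which keeps estimates finite under
# complete separation.
firth_logistic <- function(x, yb) {
  X <- cbind(1, x)
  nll <- function(beta) {
    eta <- X %*% beta
    pr <- 1 / (1 + exp(-eta))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    ll <- sum(ifelse(yb, log(pr), log(1 - pr)))
    W <- as.numeric(pr * (1 - pr))
    info <- crossprod(X * sqrt(W))
    det_info <- det(info)
    if (!is.finite(det_info) || det_info <= 0) return(1e10)
    -(ll + 0.5 * log(det_info))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  setNames(opt$par, c("(Intercept)", "x"))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors, `n >= 3`, non-constant.
#' @return List with `R` and `p`.
#' @export
pearson_summary <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  check_that(length(x) >= 3, "pearson_summary", "need n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    fail_invariant("pearson_summary", "zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value)
}
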