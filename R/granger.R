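#' Fit a lagged linear autoregression by ordinary least squares
#'
#' Regresses the one-step-ahead value of `target` on `lag_order` lags of the
#' target itself and of every variable in `predictors` (plus an intercept).
#' By default only strictly historical terms enter (lags 1..n); setting
#' `include_contemporaneous = TRUE` also admits lag-0 terms of the
#' non-target predictors, a convention choice documented in the package
#' vignette.
#'
#' @param data A [trial_set()], data frame, or named-column matrix.
#' @param target Name of the response variable.
#' @param predictors Character vector of additional predictor variables
#'   (the target's own lags are always included).
#' @param lag_order Number of lags n (>= 1).
#' @param include_contemporaneous Include lag-0 terms of non-target
#'   predictors? Default `FALSE`.
#' @return A `var_model_fit` list: `target`, `lag_order`, `intercept`,
#'   `coefficients`, `residuals`, `rss`, `n_used`, `n_coef`.
#' @export
fit_autoregression <- function(data, target, predictors = character(),
                               lag_order = 2, include_contemporaneous = FALSE) {
  if (lag_order < 1) stop_param("lag_order must be >= 1")
  yfull <- trial_var(data, target)
  T_ <- length(yfull)
  n <- lag_order
  use <- (n + 1):T_                      # response times
  design <- list()
  for (k in seq_len(n)) design[[paste0(target, "_lag", k)]] <- yfull[use - k]
  for (v in predictors) {
    vfull <- trial_var(data, v)
    ks <- if (include_contemporaneous) 0:n else seq_len(n)
    for (k in ks) design[[paste0(v, "_lag", k)]] <- vfull[use - k]
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, design))
  y <- yfull[use]
  n_coef <- ncol(X)
  if (length(y) < 5 * n_coef) {
    stop_param("usable length ", length(y), " is below 5 x ", n_coef,
               " coefficients")
  }
  if (stats::sd(y) == 0) {
    stop(structure(class = c("causalts_degenerate_data", "error", "condition"),
                   list(message = "constant target series", call = NULL)))
  }
  qrX <- qr(X)
  if (qrX$rank < n_coef) {
    stop(structure(class = c("causalts_degenerate_data", "error", "condition"),
                   list(message = "rank-deficient design matrix", call = NULL)))
  }
  coef <- qr.coef(qrX, y)
  res <- as.numeric(y - X %*% coef)
  structure(list(target = target, lag_order = n, intercept = coef[1],
                 coefficients = coef[-1], residuals = res,
                 rss = sum(res^2), n_used = length(y), n_coef = n_coef),
            class = "var_model_fit")
}

#' Linear Granger causality test (nested-autoregression F-test)
#'
#' Tests whether the history of `x` improves one-step-ahead prediction of `y`
#' beyond `y`'s own history (and any conditioning variables): the full model
#' includes lags of `x`, the restricted model sets all of `x`'s coefficients
#' to zero, and the two are compared with the standard nested-regression
#' F-statistic.
#'
#' The test declines to answer (`rejected_data = TRUE`, no p-value) when the
#' data cannot support it: a rank-deficient design (e.g. deterministic copy
#' dynamics) or a full-model residual variance below `1e-12` times the
#' target's variance (effectively deterministic dynamics, where prediction
#' improvements are meaningless).
#'
#' @param data A [trial_set()], data frame, or named-column matrix.
#' @param x Putative causer variable name.
#' @param y Target variable name.
#' @param conditioning Character vector of additional conditioning variables.
#' @param lag_order Number of lags, or `"bic"` to pick the order in 1..5 by
#'   BIC on the full model (the chosen order is fixed for both fits).
#' @param alpha Significance level.
#' @param include_contemporaneous Passed to [fit_autoregression()].
#' @return A `granger_result` list: `direction`, `f_statistic`, `dof`,
#'   `p_value`, `reject`, `rejected_data`, `reason`.
#' @export
linear_granger_test <- function(data, x, y, conditioning = character(),
                                lag_order = 2, alpha = 0.05,
                                include_contemporaneous = FALSE) {
  if (identical(lag_order, "bic")) {
    lag_order <- select_lag_bic(data, y, c(x, conditioning),
                                include_contemporaneous)
  }
  declined <- function(reason) {
    structure(list(direction = c(x, y), f_statistic = NA_real_,
                   dof = c(NA_integer_, NA_integer_), p_value = NA_real_,
                   reject = FALSE, rejected_data = TRUE, reason = reason,
                   alpha = alpha),
              class = "granger_result")
  }
  full <- tryCatch(
    fit_autoregression(data, y, predictors = c(x, conditioning), lag_order,
                       include_contemporaneous),
    causalts_degenerate_data = function(e) e)
  if (inherits(full, "condition")) return(declined(conditionMessage(full)))
  restricted <- tryCatch(
    fit_autoregression(data, y, predictors = conditioning, lag_order,
                       include_contemporaneous),
    causalts_degenerate_data = function(e) e)
  if (inherits(restricted, "condition")) {
    return(declined(conditionMessage(restricted)))
  }
  yv <- trial_var(data, y)
  if (full$rss / full$n_used < 1e-12 * stats::var(yv)) {
    return(declined("full-model residual variance below determinism floor"))
  }
  q <- full$n_coef - restricted$n_coef  # number of restricted x-lag terms
  df2 <- full$n_used - full$n_coef
  f <- ((restricted$rss - full$rss) / q) / (full$rss / df2)
  p <- stats::pf(f, q, df2, lower.tail = FALSE)
  structure(list(direction = c(x, y), f_statistic = f, dof = c(q, df2),
                 p_value = p, reject = p <= alpha, rejected_data = FALSE,
                 reason = NULL, alpha = alpha,
                 rss_full = full$rss, rss_restricted = restricted$rss),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  if (x$rejected_data) {
    cat(sprintf("<granger_result> %s -> %s: data rejected (%s)\n",
                x$direction[1], x$direction[2], x$reason))
  } else {
    cat(sprintf("<granger_result> %s -> %s: F(%d, %d) = %.3f, p = %.4g, %s\n",
                x$direction[1], x$direction[2], x$dof[1], x$dof[2],
                x$f_statistic, x$p_value,
                if (x$reject) "Granger-causal" else "no signal"))
  }
  invisible(x)
}

## BIC scan over lag orders 1..5 for the full model; falls back to the
## smallest feasible order when higher ones degenerate.
select_lag_bic <- function(data, target, predictors,
                           include_contemporaneous = FALSE, max_lag = 5) {
  bic <- rep(Inf, max_lag)
  for (n in seq_len(max_lag)) {
    fit <- tryCatch(
      fit_autoregression(data, target, predictors, n,
                         include_contemporaneous),
      error = function(e) NULL)
    if (!is.null(fit) && fit$rss > 0) {
      bic[n] <- fit$n_used * log(fit$rss / fit$n_used) +
        fit$n_coef * log(fit$n_used)
    }
  }
  if (all(!is.finite(bic))) 1L else which.min(bic)
}

#' Covariance-stationarity screen
#'
#' Two cheap checks for the stationarity assumption behind Granger and
#' surrogate tests: an augmented Dickey-Fuller style unit-root regression
#' (constant, no trend; lag order `floor((T-1)^(1/3))`; asymptotic 5%
#' critical value -2.86) and a split-half variance-ratio F-test. The screen
#' fails if the unit root cannot be rejected or the two halves have unequal
#' variance at the 5% level.
#'
#' @param series Numeric series of length >= 30.
#' @param alpha Level for the variance-ratio check (default 0.05).
#' @return `"pass"`, `"fail"`, or `"inconclusive"` (degenerate input).
#' @export
stationarity_check <- function(series, alpha = 0.05) {
  T_ <- length(series)
  if (T_ < 30) stop_param("stationarity check needs length >= 30")
  if (stats::sd(series) == 0) return("inconclusive")
  # ADF-style regression: diff(y)_t ~ 1 + y_{t-1} + lagged diffs
  k <- max(1L, floor((T_ - 1)^(1 / 3)))
  d <- diff(series)
  n <- length(d)
  use <- (k + 1):n
  X <- cbind(1, series[use], vapply(seq_len(k), function(j) d[use - j],
                                    numeric(length(use))))
  yr <- d[use]
  qrX <- qr(X)
  unit_root <- TRUE
  if (qrX$rank == ncol(X)) {
    coef <- qr.coef(qrX, yr)
    res <- yr - as.numeric(X %*% coef)
    dfree <- length(yr) - ncol(X)
    sigma2 <- sum(res^2) / dfree
    # a perfectly deterministic difference equation cannot certify
    # stationarity either; only a finite, well-posed t-statistic can
    if (sigma2 > 1e-20 * stats::var(series)) {
      XtXinv <- chol2inv(chol(crossprod(X)))
      tstat <- coef[2] / sqrt(sigma2 * XtXinv[2, 2])
      unit_root <- !is.finite(tstat) || tstat > -2.86
    }
  }
  half <- floor(T_ / 2)
  vr <- stats::var.test(series[seq_len(half)],
                        series[(T_ - half + 1):T_])
  if (unit_root || vr$p.value <= alpha) "fail" else "pass"
}

## Marginal equal-width binning into `bins` categories over the data range.
bin_series <- function(v, bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  b <- pmin(bins, 1L + floor((v - r[1]) / (r[2] - r[1]) * bins))
  as.integer(b)
}

#' Binned plug-in transfer entropy
#'
#' Estimates the transfer entropy from `x` to `y` in bits: the conditional
#' mutual information `I(Y_{t+1}; X-history | Y-history)` with histories of
#' length `l` (own past of y) and `k` (past of x), computed from counts on a
#' marginal equal-width binning of each series. Empty joint bins contribute
#' nothing (`0 log 0 := 0`). The plug-in estimator is biased upward on finite
#' samples; the recommended sample size is `10 * bins^(k + l + 1)`.
#'
#' @param data A [trial_set()], data frame, matrix, or `NULL` if `x`/`y` are
#'   numeric vectors.
#' @param x Source variable (name, or numeric vector when `data` is `NULL`).
#' @param y Target variable (name or numeric vector).
#' @param bins Number of bins per variable (>= 2).
#' @param history `c(k, l)`: lags of x and of y conditioned on.
#' @return Estimated transfer entropy in bits (>= 0 up to roundoff).
#' @export
transfer_entropy_binned <- function(data, x, y, bins = 4, history = c(1, 1)) {
  if (bins < 2) stop_param("bins must be >= 2")
  k <- history[1]; l <- history[2]
  if (k < 1 || l < 1) stop_param("history lengths must be >= 1")
  xv <- if (is.numeric(x)) x else trial_var(data, x)
  yv <- if (is.numeric(y)) y else trial_var(data, y)
  if (length(xv) != length(yv)) stop_param("series must have equal length")
  xb <- bin_series(xv, bins)
  yb <- bin_series(yv, bins)
  T_ <- length(xv)
  m <- max(k, l)
  use <- (m + 1):T_                      # times of Y_{t+1}
  if (length(use) < 4) stop_param("series too short for requested history")
  ## composite symbols for the histories (mixed-radix encoding)
  enc <- function(b, lags, t) {
    s <- rep(0L, length(t))
    for (j in seq_len(lags)) s <- s * bins + (b[t - j] - 1L)
    s
  }
  yh <- enc(yb, l, use)
  xh <- enc(xb, k, use)
  yf <- yb[use] - 1L
  H <- function(sym) {
    p <- tabulate(sym, nbins = max(sym)) / length(sym)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  ## joint symbols; +1 shifts to 1-based for tabulate
  s_yh <- yh + 1L
  s_yf_yh <- yf + bins * yh + 1L
  s_yh_xh <- yh + bins^l * xh + 1L
  s_yf_yh_xh <- yf + bins * yh + bins^(l + 1) * xh + 1L
  ## TE = H(Y',Yh) - H(Yh) - H(Y',Yh,Xh) + H(Yh,Xh)
  te <- H(s_yf_yh) - H(s_yh) - H(s_yf_yh_xh) + H(s_yh_xh)
  max(0, te)
}

#' Surrogate significance test for transfer entropy
#'
#' Compares the observed transfer entropy against surrogates in which the
#' source series `x` is circularly time-shifted (minimum shift 10 samples),
#' preserving both marginals and `y`'s own dynamics while breaking the
#' temporal alignment. One-sided counting p-value. Note this tests the
#' independence-style null, not the sharp Granger-non-causality null; see the
#' package vignette for the distinction.
#'
#' @inheritParams transfer_entropy_binned
#' @param n_surrogates Number of circular-shift surrogates.
#' @param seed Integer RNG seed.
#' @param alpha Significance level.
#' @param min_shift Minimum circular shift (samples).
#' @return A `te_result` list: `te_bits`, `bins`, `history_lengths`,
#'   `p_value`, `reject`, `surrogate_te`.
#' @export
te_test <- function(data, x, y, bins = 4, history = c(1, 1),
                    n_surrogates = 99, seed = 1, alpha = 0.05,
                    min_shift = 10) {
  xv <- if (is.numeric(x)) x else trial_var(data, x)
  yv <- if (is.numeric(y)) y else trial_var(data, y)
  te <- transfer_entropy_binned(NULL, xv, yv, bins, history)
  n <- length(xv)
  if (n <= 2 * min_shift) stop_param("series too short for shift surrogates")
  surr_te <- with_substream(seed, "te_shift", {
    offs <- sample(seq(min_shift, n - min_shift), n_surrogates, replace = TRUE)
    vapply(offs, function(o) {
      xs <- xv[((seq_len(n) - 1L + o) %% n) + 1L]
      transfer_entropy_binned(NULL, xs, yv, bins, history)
    }, numeric(1))
  })
  p <- (1 + sum(surr_te >= te)) / (1 + n_surrogates)
  structure(list(te_bits = te, bins = bins, history_lengths = history,
                 p_value = p, reject = p <= alpha, surrogate_te = surr_te,
                 alpha = alpha),
            class = "te_result")
}
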