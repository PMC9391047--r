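#' Pearson correlation coefficient
#'
#' Sample Pearson correlation, computed from the definition. Constant input
#' raises an error rather than silently returning 0: an undefined statistic
#' must not masquerade as "no correlation".
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_param("series must have equal length")
  if (length(x) < 3) stop_param("series must have length >= 3")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    stop_param("Pearson correlation undefined for a constant series")
  }
  sum(dx * dy) / (sx * sy)
}

#' Surrogate-generation specification
#'
#' @param method `"permutation"` (shuffle the values; assumes exchangeability),
#'   `"phase_randomization"` (preserve the Fourier amplitude spectrum, draw
#'   new phases; assumes a linear, Gaussian, stationary process), or
#'   `"time_shift"` (circular shift by a random offset).
#' @param n_surrogates Number of surrogates (>= 1; >= 19 resolves alpha 0.05).
#' @param seed Integer RNG seed.
#' @return A `surrogate_spec` list.
#' @export
surrogate_spec <- function(method = c("permutation", "phase_randomization",
                                      "time_shift"),
                           n_surrogates = 99, seed = 1) {
  method <- match.arg(method)
  if (n_surrogates < 1) stop_param("n_surrogates must be >= 1")
  structure(list(method = method, n_surrogates = as.integer(n_surrogates),
                 seed = seed),
            class = "surrogate_spec")
}

## One phase-randomized surrogate column from precomputed FFT pieces is
## cheaper done in bulk; this generates the whole ensemble at once.
phase_randomize <- function(y, n_surrogates) {
  n <- length(y)
  f <- stats::fft(y)
  half <- floor((n - 1) / 2)          # freely randomizable bins 2..half+1
  even <- n %% 2 == 0
  surr <- matrix(0i, nrow = n, ncol = n_surrogates)
  surr[1, ] <- f[1]                    # DC kept
  if (half >= 1) {
    idx <- 2:(half + 1)
    amp <- Mod(f[idx])
    ph <- matrix(stats::runif(half * n_surrogates, 0, 2 * pi), nrow = half)
    pos <- amp * exp(1i * ph)
    surr[idx, ] <- pos
    surr[n + 2 - idx, ] <- Conj(pos)   # conjugate symmetry => real output
  }
  if (even) surr[n / 2 + 1, ] <- f[n / 2 + 1] # Nyquist bin kept real
  Re(stats::mvfft(surr, inverse = TRUE)) / n
}

#' Generate a surrogate ensemble
#'
#' Produces `n_surrogates` resampled versions of `y` under the null model
#' named by the spec. Permutation surrogates are uniformly random reorderings;
#' phase-randomization surrogates preserve the discrete-Fourier amplitudes
#' exactly (DC and, for even lengths, Nyquist bins are kept unrandomized so
#' the output is real); time-shift surrogates are circular shifts by uniform
#' random offsets.
#'
#' @param y Numeric series (length >= 8 for phase randomization).
#' @param spec A [surrogate_spec()].
#' @return Numeric matrix, one surrogate per column, with attributes `method`
#'   and `seed`.
#' @export
make_surrogates <- function(y, spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  n <- length(y)
  m <- spec$n_surrogates
  out <- with_substream(spec$seed, paste0("surr_", spec$method), {
    switch(spec$method,
      permutation = vapply(seq_len(m), function(i) y[sample.int(n)],
                           numeric(n)),
      phase_randomization = {
        if (n < 8) stop_param("phase randomization needs length >= 8")
        phase_randomize(y, m)
      },
      time_shift = {
        offs <- sample.int(n, m, replace = TRUE) - 1L
        vapply(offs, function(o) y[((seq_len(n) - 1L + o) %% n) + 1L],
               numeric(n))
      })
  })
  attr(out, "method") <- spec$method
  attr(out, "seed") <- spec$seed
  out
}

#' Counting p-value from surrogate statistics
#'
#' The add-one counting rule: `p = (1 + #\{|s| >= |observed|\}) / (1 + n)`.
#' Strength is compared by magnitude ("at least as strong"), ties count
#' toward the numerator, and the +1 convention keeps p in `(0, 1]` so a
#' p-value of exactly 0 can never be reported.
#'
#' @param observed Observed statistic.
#' @param surrogate_stats Numeric vector of surrogate statistics (length >= 1).
#' @return p-value in `(0, 1]`.
#' @export
surrogate_pvalue <- function(observed, surrogate_stats) {
  if (length(surrogate_stats) < 1) stop_param("surrogate statistics are empty")
  (1 + sum(abs(surrogate_stats) >= abs(observed))) /
    (1 + length(surrogate_stats))
}

#' Surrogate-data dependence test between two time series
#'
#' Computes the Pearson correlation between `x` and `y`, then rebuilds the
#' null by holding `x` fixed and correlating it with surrogates of `y` only.
#' The p-value uses the add-one counting rule on absolute correlations
#' (two-sided).
#'
#' @param x,y Numeric series of equal length.
#' @param spec A [surrogate_spec()].
#' @param alpha Significance level (default 0.05).
#' @return A `dependence_result` list: `statistic`, `surrogate_statistics`,
#'   `p_value`, `alpha`, `reject`.
#' @export
dependence_test <- function(x, y, spec = surrogate_spec(), alpha = 0.05) {
  r <- pearson_r(x, y)
  surr <- make_surrogates(y, spec)
  # correlation of fixed x with every surrogate column at once
  stats_ <- as.numeric(stats::cor(x, surr))
  p <- surrogate_pvalue(r, stats_)
  structure(list(statistic = r, surrogate_statistics = stats_,
                 p_value = p, alpha = alpha, reject = p <= alpha,
                 method = spec$method, n_surrogates = spec$n_surrogates),
            class = "dependence_result")
}

#' @export
print.dependence_result <- function(x, ...) {
  cat(sprintf("<dependence_result> r = %.4f, p = %.4f (%s, %d surrogates), %s at alpha = %g\n",
              x$statistic, x$p_value, x$method, x$n_surrogates,
              if (x$reject) "reject independence" else "no rejection", x$alpha))
  invisible(x)
}

#' Cross-trial dependence test
#'
#' When several independent trials are available, dependence between two
#' variables can be tested without any surrogate model: the observed statistic
#' is the mean within-trial correlation, and the null distribution is built by
#' randomly re-pairing the `x` series of one trial with the `y` series of a
#' *different* trial (a random derangement of trial labels). Under
#' independence the labels are exchangeable, so the test is exact.
#'
#' @param trials List of >= 5 [trial_set()] objects, each containing both
#'   variables.
#' @param var_x,var_y Variable names.
#' @param n_null Number of null re-pairings (default 999).
#' @param seed Integer RNG seed.
#' @param alpha Significance level.
#' @return A `dependence_result`.
#' @export
cross_trial_test <- function(trials, var_x, var_y, n_null = 999, seed = 1,
                             alpha = 0.05) {
  if (length(trials) < 5) {
    stop_param("cross-trial test needs >= 5 independent trials")
  }
  xs <- lapply(trials, trial_var, var_x)
  ys <- lapply(trials, trial_var, var_y)
  k <- length(trials)
  within_r <- mapply(pearson_r, xs, ys)
  stat <- mean(within_r)
  null_stats <- with_substream(seed, "cross_trial", {
    vapply(seq_len(n_null), function(b) {
      repeat {                        # random derangement of trial labels
        perm <- sample.int(k)
        if (!any(perm == seq_len(k))) break
      }
      mean(mapply(pearson_r, xs, ys[perm]))
    }, numeric(1))
  })
  p <- surrogate_pvalue(stat, null_stats)
  structure(list(statistic = stat, surrogate_statistics = null_stats,
                 within_trial_r = within_r, p_value = p, alpha = alpha,
                 reject = p <= alpha, method = "cross_trial",
                 n_surrogates = n_null),
            class = "dependence_result")
}
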