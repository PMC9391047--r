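#' Simulate an island population
#'
#' Two single-variable null models for island biomass/abundance used in the
#' false-positive-rate experiments. `random_walk` accumulates IID Gaussian net
#' changes (mean 0, sd `increment_sd`), a nonstationary null. `migration_death`
#' is a stationary immigration-death birth-death process: each step the island
#' gains `Poisson(immigration)` individuals and each resident dies with
#' probability `death`; the series is recorded only after `burn_in` steps so
#' the population has reached its stationary regime (mean `immigration/death`).
#'
#' @param model `"random_walk"` or `"migration_death"`.
#' @param length Number of recorded time points.
#' @param seed Integer RNG seed.
#' @param increment_sd Standard deviation of random-walk increments.
#' @param immigration Immigration rate (individuals/step), `migration_death`.
#' @param death Per-capita death probability per step, `migration_death`.
#' @param burn_in Steps discarded before recording, `migration_death`.
#' @return A [trial_set()] with one variable `N`.
#' @export
simulate_island <- function(model = c("random_walk", "migration_death"),
                            length = 100, seed = 1, increment_sd = 1,
                            immigration = 10, death = 0.1, burn_in = 1000) {
  model <- match.arg(model)
  if (length <= 0) stop_param("length must be positive")
  if (model == "random_walk") {
    vals <- with_substream(seed, "rw", cumsum(stats::rnorm(length, 0, increment_sd)))
  } else {
    if (immigration <= 0 || death <= 0 || death > 1) {
      stop_param("migration_death needs immigration > 0 and death in (0, 1]")
    }
    if (burn_in < 1000) stop_param("migration_death burn_in must be >= 1000")
    vals <- with_substream(seed, "md", {
      n <- round(immigration / death)
      total <- burn_in + length
      out <- numeric(length)
      for (t in seq_len(total)) {
        n <- n - stats::rbinom(1L, n, death) + stats::rpois(1L, immigration)
        if (t > burn_in) out[t - burn_in] <- n
      }
      out
    })
  }
  trial_set(matrix(vals, ncol = 1, dimnames = list(NULL, "N")),
            seed = seed, model = paste0("island_", model),
            params = list(increment_sd = increment_sd,
                          immigration = immigration, death = death,
                          burn_in = burn_in))
}

#' Simulate two independent exponential growth curves
#'
#' Two causally unrelated cultures growing (or declining) exponentially,
#' `x0 * exp(rate * t)`. Deterministic: monotone trends make the pair
#' strongly correlated despite independence.
#'
#' @param rate1,rate2 Per-step growth rates.
#' @param length Number of time points.
#' @param x0 Initial density of both cultures.
#' @return A [trial_set()] with variables `A` and `B`.
#' @export
simulate_growth_pair <- function(rate1 = 0.1, rate2 = 0.15, length = 50, x0 = 1) {
  if (length <= 0) stop_param("length must be positive")
  t <- seq_len(length) - 1
  trial_set(cbind(A = x0 * exp(rate1 * t), B = x0 * exp(rate2 * t)),
            model = "growth_pair",
            params = list(rate1 = rate1, rate2 = rate2, x0 = x0))
}

#' Simulate Granger-causality pathology systems
#'
#' Three toy systems on which Granger causality is known to misbehave:
#' \describe{
#'   \item{`copy`}{Deterministic mutual copy: `X(t) = Y(t-1)` and
#'     `Y(t) = X(t-1)`, so `X(t) = X(t-2)` exactly. Each variable's own
#'     history already predicts it perfectly, so no Granger signal exists
#'     (and regression-based tests face degenerate, collinear data).}
#'   \item{`hidden_common_cause`}{A latent IID N(0,1) driver `U` feeds `Y`
#'     at lag 1 and `Z` at lag 2 (`Y(t) = U(t-1) + e`, `Z(t) = U(t-2) + e`,
#'     `e ~ N(0, noise_sd^2)`); only `Y` and `Z` are returned. Because `Y`
#'     receives the shared information one step before `Z`, `Y` spuriously
#'     Granger-causes `Z`.}
#'   \item{`noisy_chain`}{Linear stochastic chain `X -> Y -> Z` with
#'     unit-variance IID process noise on every variable (coefficients from
#'     [system_coefficients()], overridable via `coeffs`).}
#' }
#'
#' @param kind One of `"copy"`, `"hidden_common_cause"`, `"noisy_chain"`.
#' @param length Number of recorded time points (>= 20).
#' @param seed Integer RNG seed.
#' @param noise_sd Noise sd on `Y`,`Z` for `hidden_common_cause` (default 1).
#' @param coeffs Optional named list overriding `noisy_chain` coefficients
#'   (`self_x`, `self_y`, `self_z`, `x_to_y`, `y_to_z`).
#' @return A [trial_set()].
#' @export
simulate_granger_pathology <- function(kind, length = 200, seed = 1,
                                       noise_sd = 1, coeffs = NULL) {
  if (!kind %in% c("copy", "hidden_common_cause", "noisy_chain")) {
    stop_param("unknown pathology kind: ", kind)
  }
  if (length < 20) stop_param("length must be >= 20")
  if (kind == "copy") {
    init <- with_substream(seed, "copy_init", stats::rnorm(2))
    x <- y <- numeric(length)
    x[1] <- init[1]; y[1] <- init[2]
    for (t in 2:length) {
      x[t] <- y[t - 1]
      y[t] <- x[t - 1]
    }
    vals <- cbind(X = x, Y = y)
  } else if (kind == "hidden_common_cause") {
    u <- with_substream(seed, "hcc_latent", stats::rnorm(length + 1))
    ey <- with_substream(seed, "hcc_ey", stats::rnorm(length, 0, noise_sd))
    ez <- with_substream(seed, "hcc_ez", stats::rnorm(length, 0, noise_sd))
    # Y(t) sees the latent driver one step before Z does.
    vals <- cbind(Y = u[2:(length + 1)] + ey, Z = u[1:length] + ez)
  } else {
    cf <- utils::modifyList(system_coefficients()$noisy_chain,
                            if (is.null(coeffs)) list() else coeffs)
    burn <- 50L
    total <- length + burn
    ex <- with_substream(seed, "chain_ex", stats::rnorm(total))
    ey <- with_substream(seed, "chain_ey", stats::rnorm(total))
    ez <- with_substream(seed, "chain_ez", stats::rnorm(total))
    x <- y <- z <- numeric(total)
    for (t in 2:total) {
      x[t] <- cf$self_x * x[t - 1] + ex[t]
      y[t] <- cf$self_y * y[t - 1] + cf$x_to_y * x[t - 1] + ey[t]
      z[t] <- cf$self_z * z[t - 1] + cf$y_to_z * y[t - 1] + ez[t]
    }
    keep <- (burn + 1):total
    vals <- cbind(X = x[keep], Y = y[keep], Z = z[keep])
  }
  trial_set(vals, seed = seed, model = paste0("granger_", kind),
            params = list(kind = kind, noise_sd = noise_sd, coeffs = coeffs))
}

#' Simulate the five-variable linear network
#'
#' A linear deterministic system (plus optional process noise) in which `Z` is
#' causally driven by `X` and `Y` while `W` and `V` are causally unrelated
#' bystanders. `X`, `Y`, `W`, `V` are linear oscillators
#' `x(t+1) = 2 cos(2 pi / p) x(t) - x(t-1)` (exact unit sinusoids with random
#' phase); `Z(t+1) = a Z(t) + b X(t) + c Y(t)`. With the default periods,
#' `Z`'s fundamental period is three times `X`'s. Coefficients come from
#' [system_coefficients()].
#'
#' @param length Number of recorded time points.
#' @param seed Integer RNG seed (drives phases and, if any, noise).
#' @param noise_sd Process-noise sd added inside every recursion (default 0).
#' @param coeffs Optional overrides for the `linear_network` coefficient block.
#' @param var_seeds Optional named list giving a per-variable seed override
#'   (e.g. `list(W = 99)`); unlisted variables keep substreams of `seed`.
#' @return A [trial_set()] with variables `X`, `Y`, `Z`, `W`, `V`.
#' @export
simulate_linear_network <- function(length = 200, seed = 1, noise_sd = 0,
                                    coeffs = NULL, var_seeds = NULL) {
  cf <- utils::modifyList(system_coefficients()$linear_network,
                          if (is.null(coeffs)) list() else coeffs)
  if (length < 3) stop_param("length must be >= 3")
  burn <- cf$burn_in
  total <- length + burn
  var_seed <- function(v) {
    if (!is.null(var_seeds[[v]])) var_seeds[[v]] else substream_seed(seed, v)
  }
  osc <- function(v, period) {
    phi <- with_substream(var_seed(v), "phase", stats::runif(1, 0, 2 * pi))
    eps <- if (noise_sd > 0) {
      with_substream(var_seed(v), "noise", stats::rnorm(total, 0, noise_sd))
    } else {
      numeric(total)
    }
    w <- 2 * pi / period
    x <- numeric(total)
    x[1] <- cos(w + phi); x[2] <- cos(2 * w + phi)
    for (t in 2:(total - 1)) x[t + 1] <- 2 * cos(w) * x[t] - x[t - 1] + eps[t + 1]
    x
  }
  x <- osc("X", cf$period_x)
  y <- osc("Y", cf$period_y)
  w <- osc("W", cf$period_w)
  v <- osc("V", cf$period_v)
  ez <- if (noise_sd > 0) {
    with_substream(var_seed("Z"), "noise", stats::rnorm(total, 0, noise_sd))
  } else {
    numeric(total)
  }
  z <- numeric(total)
  for (t in 1:(total - 1)) {
    z[t + 1] <- cf$z_self * z[t] + cf$z_from_x * x[t] + cf$z_from_y * y[t] + ez[t + 1]
  }
  keep <- (burn + 1):total
  trial_set(cbind(X = x[keep], Y = y[keep], Z = z[keep],
                  W = w[keep], V = v[keep]),
            seed = seed, model = "linear_network",
            params = list(noise_sd = noise_sd, coeffs = cf))
}

#' Parameters for the two-species community simulator
#'
#' @param process_sd Sd of the IID normal process noise added inside each
#'   species' update (propagates to later times).
#' @param measurement_sd Sd of the IID normal measurement noise added to the
#'   recorded output only (does not propagate).
#' @param driver1_on,driver2_on Toggle the unobserved periodic external driver
#'   of species 1 / species 2.
#' @param driver1_period,driver2_period Driver periods (time steps, > 0).
#' @param driver1_amplitude,driver2_amplitude Driver amplitudes (> 0).
#' @param length Recorded series length (> 0).
#' @param burn_in Steps discarded before recording.
#' @return A `two_species_params` list.
#' @export
two_species_params <- function(process_sd = 0, measurement_sd = 0,
                               driver1_on = TRUE, driver2_on = TRUE,
                               driver1_period = NULL, driver2_period = NULL,
                               driver1_amplitude = NULL, driver2_amplitude = NULL,
                               length = 400, burn_in = NULL) {
  cf <- system_coefficients()$two_species
  p <- list(
    process_sd = process_sd, measurement_sd = measurement_sd,
    driver1_on = isTRUE(driver1_on), driver2_on = isTRUE(driver2_on),
    driver1_period = driver1_period %||% cf$driver1_period,
    driver2_period = driver2_period %||% cf$driver2_period,
    driver1_amplitude = driver1_amplitude %||% cf$driver1_amplitude,
    driver2_amplitude = driver2_amplitude %||% cf$driver2_amplitude,
    length = as.integer(length), burn_in = (burn_in %||% cf$burn_in))
  if (p$process_sd < 0 || p$measurement_sd < 0) {
    stop_param("noise standard deviations must be >= 0")
  }
  if (any(c(p$driver1_period, p$driver2_period,
            p$driver1_amplitude, p$driver2_amplitude) <= 0)) {
    stop_param("driver periods and amplitudes must be > 0")
  }
  if (p$length <= 0) stop_param("length must be > 0")
  structure(p, class = "two_species_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the two-species community
#'
#' A discrete-time two-species system with known ground truth: `S1` causally
#' influences `S2` but not vice versa. `S1` is forced by an unobserved
#' periodic driver (random phase per trial); `S2` optionally has its own
#' driver. Process noise enters the recursions and propagates; measurement
#' noise corrupts the recorded output only; abundances are floored at 0.
#' With `driver2_on = FALSE` and no noise the two species synchronize (both
#' become purely periodic at the `S1` driver period), the regime in which
#' state-space methods are expected to fail.
#'
#' The noise-free latent trajectory is stored in `meta$latent` so tests can
#' verify that measurement noise never feeds back into the dynamics.
#'
#' @param params A [two_species_params()] object.
#' @param seed Integer RNG seed.
#' @return A [trial_set()] with variables `S1`, `S2`.
#' @export
simulate_two_species <- function(params = two_species_params(), seed = 1) {
  stopifnot(inherits(params, "two_species_params"))
  cf <- system_coefficients()$two_species
  total <- params$length + params$burn_in
  phi <- with_substream(seed, "ts_phases", stats::runif(2, 0, 2 * pi))
  ep1 <- if (params$process_sd > 0) {
    with_substream(seed, "ts_proc1", stats::rnorm(total, 0, params$process_sd))
  } else numeric(total)
  ep2 <- if (params$process_sd > 0) {
    with_substream(seed, "ts_proc2", stats::rnorm(total, 0, params$process_sd))
  } else numeric(total)
  d1 <- if (params$driver1_on) {
    params$driver1_amplitude * sin(2 * pi * seq_len(total) / params$driver1_period + phi[1])
  } else numeric(total)
  d2 <- if (params$driver2_on) {
    params$driver2_amplitude * sin(2 * pi * seq_len(total) / params$driver2_period + phi[2])
  } else numeric(total)
  s1 <- s2 <- numeric(total)
  s1[1] <- cf$s1_base / (1 - cf$s1_self)
  s2[1] <- (cf$s2_base + cf$coupling * s1[1]) / (1 - cf$s2_self)
  for (t in 1:(total - 1)) {
    s1[t + 1] <- max(0, cf$s1_self * s1[t] + cf$s1_base + d1[t] + ep1[t + 1])
    s2[t + 1] <- max(0, cf$s2_self * s2[t] + cf$s2_base +
                        cf$coupling * s1[t] + d2[t] + ep2[t + 1])
  }
  keep <- (params$burn_in + 1):total
  latent <- cbind(S1 = s1[keep], S2 = s2[keep])
  obs <- latent
  if (params$measurement_sd > 0) {
    em <- with_substream(seed, "ts_meas",
                         matrix(stats::rnorm(2 * params$length, 0,
                                             params$measurement_sd),
                                ncol = 2))
    obs <- latent + em
  }
  out <- trial_set(obs, seed = seed, model = "two_species",
                   params = unclass(params))
  out$meta$latent <- latent
  out
}

#' Simulate state-space-reconstruction pathology systems
#'
#' Four systems on which delay-embedding causality detection is known to
#' misbehave:
#' \describe{
#'   \item{`nonreverting`}{Causally unrelated pair: `X` a strictly monotone
#'     "wavy" linear increase, `Z` a parabola in time. Both delay spaces map
#'     continuously to time, hence spuriously to each other.}
#'   \item{`synchrony`}{Chaotic logistic driver `X` strongly coupled into `Z`
#'     (`Z(t+1) = 0.3 Z(t) + 0.7 X(t)`): `Z` synchronizes to `X`, so
#'     continuous delay maps exist in both directions despite unidirectional
#'     causation.}
#'   \item{`period_multiple`}{Two causally unrelated sinusoids with period
#'     ratio exactly 5 (periods 50.5 and 10.1 samples): the slow variable's
#'     phase determines the fast one, so `Z` is falsely inferred to cause `X`.}
#'   \item{`lorenz`}{The classic chaotic Lorenz system (sigma = 10, rho = 28,
#'     beta = 8/3), 4th-order fixed-step integration at dt = 0.01 with a
#'     1000-step transient discarded; returns the `X` and `Z` coordinates.}
#' }
#'
#' @param kind One of `"nonreverting"`, `"synchrony"`, `"period_multiple"`,
#'   `"lorenz"`.
#' @param length Number of recorded time points (>= 100).
#' @param seed Integer RNG seed (phases / initial conditions).
#' @return A [trial_set()] with variables `X`, `Z`.
#' @export
simulate_ssr_pathology <- function(kind, length = 500, seed = 1) {
  if (!kind %in% c("nonreverting", "synchrony", "period_multiple", "lorenz")) {
    stop_param("unknown pathology kind: ", kind)
  }
  if (length < 100) stop_param("length must be >= 100")
  tt <- seq_len(length)
  if (kind == "nonreverting") {
    phi <- with_substream(seed, "nr_phase", stats::runif(1, 0, 2 * pi))
    # slope exceeds the wave's derivative amplitude, so X is strictly monotone
    x <- 0.05 * tt + 0.1 * sin(2 * pi * tt / 20 + phi)
    # one arm of a parabola: continuous in t and curved, but nonreverting
    z <- 4 * (tt / length)^2
    vals <- cbind(X = x, Z = z)
  } else if (kind == "synchrony") {
    burn <- 100L
    total <- length + burn
    x0 <- with_substream(seed, "sync_init", stats::runif(1, 0.2, 0.8))
    x <- z <- numeric(total)
    x[1] <- x0; z[1] <- x0
    for (t in 1:(total - 1)) {
      x[t + 1] <- 3.8 * x[t] * (1 - x[t])
      z[t + 1] <- 0.3 * z[t] + 0.7 * x[t]
    }
    keep <- (burn + 1):total
    vals <- cbind(X = x[keep], Z = z[keep])
  } else if (kind == "period_multiple") {
    phi <- with_substream(seed, "pm_phase", stats::runif(2, 0, 2 * pi))
    # periods in an exact 5:1 ratio but incommensurate with the sampling
    # grid, so no spurious exact recurrences arise from integer periods
    pz <- 3 * pi
    vals <- cbind(X = sin(2 * pi * tt / (5 * pz) + phi[1]),
                  Z = sin(2 * pi * tt / pz + phi[2]))
  } else {
    jit <- with_substream(seed, "lorenz_init", stats::runif(3, -0.5, 0.5))
    vals <- integrate_lorenz(length, state = c(1, 1, 20) + jit)
  }
  trial_set(vals, seed = seed, model = paste0("ssr_", kind),
            params = list(kind = kind))
}

## Classic Lorenz system, 4th-order Runge-Kutta at fixed dt = 0.01,
## 1000-step transient discarded; returns X and Z coordinates.
integrate_lorenz <- function(length, state, sigma = 10, rho = 28,
                             beta = 8 / 3, dt = 0.01, transient = 1000L) {
  deriv <- function(s) {
    c(sigma * (s[2] - s[1]),
      s[1] * (rho - s[3]) - s[2],
      s[1] * s[2] - beta * s[3])
  }
  step <- function(s) {
    k1 <- deriv(s)
    k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2)
    k4 <- deriv(s + dt * k3)
    s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  for (i in seq_len(transient)) state <- step(state)
  out <- matrix(0, nrow = length, ncol = 2, dimnames = list(NULL, c("X", "Z")))
  for (i in seq_len(length)) {
    state <- step(state)
    out[i, ] <- state[c(1, 3)]
  }
  out
}

#' Observation operator: measurement noise, subsampling, aggregation
#'
#' @param measurement_sd Sd of IID Gaussian measurement noise (>= 0).
#' @param subsample_step Keep every k-th point (integer >= 1).
#' @param aggregate If `TRUE`, average within consecutive windows of
#'   `subsample_step` points instead of decimating.
#' @return An `observation_spec` list.
#' @export
observation_spec <- function(measurement_sd = 0, subsample_step = 1L,
                             aggregate = FALSE) {
  if (measurement_sd < 0) stop_param("measurement_sd must be >= 0")
  if (subsample_step < 1) stop_param("subsample_step must be >= 1")
  structure(list(measurement_sd = measurement_sd,
                 subsample_step = as.integer(subsample_step),
                 aggregate = isTRUE(aggregate)),
            class = "observation_spec")
}

#' Apply an observation operator to a trial
#'
#' Adds IID Gaussian measurement noise to every variable (after the dynamics
#' are complete, so it never feeds back), then either decimates (keeps every
#' k-th row) or window-averages. The input trial is untouched.
#'
#' @param trial A [trial_set()].
#' @param spec An [observation_spec()].
#' @param seed Integer RNG seed for the measurement noise.
#' @return A new [trial_set()].
#' @export
observe <- function(trial, spec = observation_spec(), seed = 1) {
  stopifnot(inherits(trial, "trial_set"), inherits(spec, "observation_spec"))
  v <- trial$values
  n <- nrow(v)
  if (spec$subsample_step > n) {
    stop_param("subsample_step exceeds series length")
  }
  if (spec$measurement_sd > 0) {
    noise <- with_substream(seed, "observe_meas",
                            matrix(stats::rnorm(base::length(v), 0, spec$measurement_sd),
                                   nrow = n))
    v <- v + noise
  }
  k <- spec$subsample_step
  if (k > 1L) {
    if (spec$aggregate) {
      nwin <- n %/% k
      idx <- rep(seq_len(nwin), each = k)
      v <- apply(v[seq_len(nwin * k), , drop = FALSE], 2,
                 function(col) tapply(col, idx, mean))
      v <- matrix(v, nrow = nwin, dimnames = list(NULL, trial$names))
    } else {
      v <- v[seq(k, n, by = k), , drop = FALSE]
    }
  }
  out <- trial_set(v, dt = trial$dt * k, trial_id = trial$trial_id,
                   seed = seed, model = trial$meta$model,
                   params = trial$meta$params)
  out$meta$observation <- unclass(spec)
  out
}
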