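test_that("every simulator is bit-identical under a repeated seed", {
  gens <- list(
    function(s) simulate_island("random_walk", 50, seed = s),
    function(s) simulate_island("migration_death", 30, seed = s),
    function(s) simulate_granger_pathology("copy", 40, seed = s),
    function(s) simulate_granger_pathology("hidden_common_cause", 40, seed = s),
    function(s) simulate_granger_pathology("noisy_chain", 40, seed = s),
    function(s) simulate_linear_network(60, seed = s, noise_sd = 0.1),
    function(s) simulate_two_species(two_species_params(process_sd = 1,
                                                        measurement_sd = 0.5,
                                                        length = 60), seed = s),
    function(s) simulate_ssr_pathology("synchrony", 120, seed = s))
  for (gen in gens) {
    a <- gen(42)
    b <- gen(42)
    c <- gen(43)
    expect_identical(a$values, b$values)
    expect_false(identical(a$values, c$values))
  }
})

test_that("random-walk islands have standard-normal increments and a degenerate zero-noise limit", {
  tr <- simulate_island("random_walk", 1000, seed = 7)
  inc <- diff(c(0, tr$values[, 1]))
  expect_lt(abs(mean(inc)), 0.1)       # 3 MC standard errors ~ 0.095
  expect_lt(abs(sd(inc) - 1), 0.1)
  flat <- simulate_island("random_walk", 50, seed = 1, increment_sd = 0)
  expect_true(all(flat$values == 0))
})

test_that("migration-death equilibrium matches the immigration-death stationary mean", {
  m <- 10; d <- 0.1
  oracle_mean <- m / d                  # closed-form stationary mean
  tr <- simulate_island("migration_death", 1000, seed = 11,
                        immigration = m, death = d)
  # stationary var ~ m/d (Poisson), lag-1 autocorr (1-d): se of the mean
  # ~ sqrt(m/d / n * (2-d)/d); 3 se ~ 4.1
  expect_lt(abs(mean(tr$values) - oracle_mean), 5)
  expect_error(simulate_island("migration_death", 10, seed = 1, death = 0),
               class = "causalts_parameter_error")
  expect_error(simulate_island("random_walk", 0), class = "causalts_parameter_error")
})

test_that("independent exponential growth curves correlate by trend alone", {
  flat <- simulate_growth_pair(0, 0, 50)
  expect_true(all(flat$values[, "A"] == 1) && all(flat$values[, "B"] == 1))
  up <- simulate_growth_pair(0.1, 0.15, 50)
  expect_gt(cor(up$values[, "A"], up$values[, "B"]), 0.9)
  opp <- simulate_growth_pair(0.1, -0.1, 50)
  expect_lt(cor(opp$values[, "A"], opp$values[, "B"]), 0)
})

test_that("the copy system repeats itself with period two", {
  tr <- simulate_granger_pathology("copy", 60, seed = 5)
  x <- tr$values[, "X"]
  y <- tr$values[, "Y"]
  expect_equal(x[3:60], x[1:58])
  expect_equal(y[3:60], y[1:58])
  expect_equal(x[2:60], y[1:59])        # X copies Y's previous value
})

test_that("the hidden common cause reaches Y one step before Z", {
  tr <- simulate_granger_pathology("hidden_common_cause", 500, seed = 9)
  y <- tr$values[, "Y"]
  z <- tr$values[, "Z"]
  n <- length(y)
  lagged <- sapply(-3:3, function(l) {
    idx <- seq_len(n - abs(l))
    if (l >= 0) cor(y[idx], z[idx + l]) else cor(y[idx + abs(l)], z[idx])
  })
  expect_equal((-3:3)[which.max(abs(lagged))], 1)  # Z(t+1) tracks Y(t)
  expect_gt(max(abs(lagged)), 0.4)
})

test_that("the decoupled noisy chain collapses to IID standard normals", {
  tr <- simulate_granger_pathology(
    "noisy_chain", 2000, seed = 3,
    coeffs = list(self_x = 0, self_y = 0, self_z = 0, x_to_y = 0, y_to_z = 0))
  for (v in c("X", "Y", "Z")) {
    s <- tr$values[, v]
    expect_lt(abs(sd(s) - 1), 0.08)
    expect_lt(abs(cor(s[-1], s[-length(s)])), 0.08)  # no serial structure
  }
  expect_error(simulate_granger_pathology("nope", 100),
               class = "causalts_parameter_error")
})

test_that("the linear network is deterministic and Z ignores W and V", {
  a <- simulate_linear_network(100, seed = 2)
  b <- simulate_linear_network(100, seed = 2)
  expect_identical(a$values, b$values)
  # replacing W's seed must leave every other variable untouched
  c <- simulate_linear_network(100, seed = 2, var_seeds = list(W = 999))
  expect_identical(a$values[, c("X", "Y", "Z", "V")],
                   c$values[, c("X", "Y", "Z", "V")])
  expect_false(identical(a$values[, "W"], c$values[, "W"]))
  # zeroing the X->Z and Y->Z couplings decouples Z from X, Y entirely
  d1 <- simulate_linear_network(100, seed = 2,
                                coeffs = list(z_from_x = 0, z_from_y = 0))
  d2 <- simulate_linear_network(100, seed = 2,
                                coeffs = list(z_from_x = 0, z_from_y = 0),
                                var_seeds = list(X = 77, Y = 88))
  expect_identical(d1$values[, "Z"], d2$values[, "Z"])
})

test_that("two-species measurement noise is additive, non-propagating, and separable", {
  p0 <- two_species_params(length = 300)
  base <- simulate_two_species(p0, seed = 4)
  expect_identical(base$values, simulate_two_species(p0, seed = 4)$values)
  p1 <- two_species_params(measurement_sd = 1, length = 300)
  noisy <- simulate_two_species(p1, seed = 4)
  # the latent trajectory is invariant to measurement noise (separation)
  expect_identical(noisy$meta$latent, base$meta$latent)
  resid <- noisy$values - noisy$meta$latent
  expect_lt(abs(sd(resid) - 1), 0.1)
  # the strongest process noise stays finite under the abundance floor
  loud <- simulate_two_species(two_species_params(process_sd = 8,
                                                  length = 300), seed = 4)
  expect_true(all(is.finite(loud$values)))
  expect_true(all(loud$meta$latent >= 0))
  expect_error(two_species_params(process_sd = -1),
               class = "causalts_parameter_error")
})

test_that("SSR pathology systems have their stated signatures", {
  pm <- simulate_ssr_pathology("period_multiple", 1000, seed = 6)
  peak_freq <- function(v) {
    sp <- stats::spec.pgram(v, plot = FALSE, taper = 0, detrend = TRUE)
    sp$freq[which.max(sp$spec)]
  }
  ratio <- peak_freq(pm$values[, "Z"]) / peak_freq(pm$values[, "X"])
  expect_lt(abs(ratio - 5), 0.5)
  nr <- simulate_ssr_pathology("nonreverting", 500, seed = 6)
  expect_true(all(diff(nr$values[, "X"]) > 0))      # strictly monotone
  expect_lt(max(abs(diff(nr$values[, "Z"]))), 0.05) # continuous in t
  lz <- simulate_ssr_pathology("lorenz", 10000, seed = 1)
  expect_lt(max(abs(lz$values)), 100)               # attractor stays bounded
  expect_error(simulate_ssr_pathology("x", 200), class = "causalts_parameter_error")
})

test_that("the observation operator decimates, aggregates, and leaves identity intact", {
  tr <- trial_set(cbind(A = as.numeric(1:100)))
  same <- observe(tr, observation_spec(), seed = 1)
  expect_equal(same$values, tr$values)
  dec <- observe(tr, observation_spec(subsample_step = 2), seed = 1)
  expect_equal(nrow(dec$values), 50)
  expect_equal(as.numeric(dec$values), seq(2, 100, by = 2))
  agg <- observe(trial_set(cbind(A = c(1, 3, 5, 7))),
                 observation_spec(subsample_step = 2, aggregate = TRUE))
  expect_equal(as.numeric(agg$values), c(2, 6))
  expect_error(observe(agg, observation_spec(subsample_step = 10)),
               class = "causalts_parameter_error")
  # input trial untouched by the noisy observation
  before <- tr$values
  invisible(observe(tr, observation_spec(measurement_sd = 2), seed = 1))
  expect_identical(tr$values, before)
})

test_that("trial sets round-trip through CSV plus YAML sidecar", {
  tr <- simulate_two_species(two_species_params(length = 40), seed = 8)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  back <- read_trial_csv(path)
  expect_equal(back$values, tr$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$meta$model, "two_species")
  expect_equal(back$dt, tr$dt)
  unlink(c(path, paste0(path, ".yaml")))
})
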