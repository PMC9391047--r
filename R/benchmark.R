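#' False-positive-rate experiment for surrogate dependence tests
#'
#' Simulates `n_sims` pairs of *independent* island populations, runs the
#' surrogate dependence test on each pair, and returns the fraction of pairs
#' declared significant at `alpha` -- the empirical false-positive rate of
#' the test under that null. The full per-simulation record is attached so
#' any rejection can be drilled into.
#'
#' @param model Island model: `"random_walk"` (nonstationary null) or
#'   `"migration_death"` (stationary null).
#' @param surrogate_method Passed to [surrogate_spec()].
#' @param n_sims Number of simulated independent pairs (>= 100).
#' @param n_surrogates Surrogates per test.
#' @param alpha Significance level.
#' @param seed Integer base seed; per-simulation seeds are derived from it.
#' @param length Recorded series length per island.
#' @return The rejection fraction, with attribute `records` (data frame of
#'   per-simulation statistic and p-value).
#' @export
run_fpr_experiment <- function(model = c("random_walk", "migration_death"),
                               surrogate_method = "phase_randomization",
                               n_sims = 1000, n_surrogates = 99,
                               alpha = 0.05, seed = 1, length = 100) {
  model <- match.arg(model)
  if (n_sims < 100) stop_param("n_sims must be >= 100")
  stat <- pval <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    s1 <- substream_seed(seed, paste0("fpr_a", i))
    s2 <- substream_seed(seed, paste0("fpr_b", i))
    x <- simulate_island(model, length = length, seed = s1)$values[, 1]
    y <- simulate_island(model, length = length, seed = s2)$values[, 1]
    res <- dependence_test(x, y,
                           surrogate_spec(surrogate_method, n_surrogates,
                                          substream_seed(seed, paste0("fpr_s", i))),
                           alpha = alpha)
    stat[i] <- res$statistic
    pval[i] <- res$p_value
  }
  rate <- mean(pval <= alpha)
  attr(rate, "records") <- data.frame(sim = seq_len(n_sims),
                                      statistic = stat, p_value = pval,
                                      reject = pval <= alpha)
  rate
}

#' Classify a replicate's causal-analysis outcome
#'
#' Maps the pair of directional verdicts for a system whose ground truth is
#' "S1 causes S2 only" onto the five benchmark outcome categories. The
#' classification never inspects the data, only the verdicts.
#'
#' @param forward Verdict for the true direction (S1 -> S2).
#' @param backward Verdict for the reverse direction (S2 -> S1).
#' @param rejected Did the method decline the data?
#' @return One of `"correct_unidirectional"`, `"reversed"`,
#'   `"bidirectional"`, `"none_detected"`, `"data_rejected"`.
#' @export
classify_outcome <- function(forward, backward, rejected) {
  if (isTRUE(rejected)) return("data_rejected")
  if (forward && backward) return("bidirectional")
  if (forward) return("correct_unidirectional")
  if (backward) return("reversed")
  "none_detected"
}

outcome_categories <- c("correct_unidirectional", "reversed", "bidirectional",
                        "none_detected", "data_rejected")

#' Noise-grid benchmark specification
#'
#' @param process_sd_levels,measurement_sd_levels Noise grids (sds >= 0).
#' @param n_replicates Replicates per grid cell and method.
#' @param methods Subset of `"granger"`, `"ccm_main"`, `"ccm_alternative"`.
#' @param regime `"both_drivers"` (each species has its own unobserved
#'   periodic driver) or `"s1_driver_only"` (the downstream species does not;
#'   the synchrony-prone regime).
#' @param base_seed Integer; replicate seeds are derived deterministically.
#' @param length Recorded series length per replicate.
#' @param granger_lag Lag order for the Granger tests.
#' @param ccm Optional [ccm_config()] template for the CCM methods.
#' @return A `noise_grid_spec` list.
#' @export
noise_grid_spec <- function(process_sd_levels = c(0, 2, 8),
                            measurement_sd_levels = c(0, 0.5, 1),
                            n_replicates = 200,
                            methods = c("granger", "ccm_main",
                                        "ccm_alternative"),
                            regime = c("both_drivers", "s1_driver_only"),
                            base_seed = 1, length = 400, granger_lag = 5,
                            ccm = NULL) {
  regime <- match.arg(regime)
  bad <- setdiff(methods, c("granger", "ccm_main", "ccm_alternative"))
  if (base::length(bad) > 0) {
    stop_param("unknown methods: ", paste(bad, collapse = ", "))
  }
  if (any(process_sd_levels < 0) || any(measurement_sd_levels < 0)) {
    stop_param("noise levels must be >= 0")
  }
  structure(list(process_sd_levels = process_sd_levels,
                 measurement_sd_levels = measurement_sd_levels,
                 n_replicates = as.integer(n_replicates), methods = methods,
                 regime = regime, base_seed = base_seed,
                 length = as.integer(length), granger_lag = granger_lag,
                 ccm = ccm %||% ccm_config()),
            class = "noise_grid_spec")
}

## Re-derive a direction verdict under a specific convergence-test variant
## (a CCM run evaluates both variants, so the two CCM methods share one run).
ccm_verdict_variant <- function(dir_res, variant) {
  crit <- dir_res$criteria
  if (!is.null(crit$c3_convergent) && !is.null(dir_res$c3_variants)) {
    crit$c3_convergent <- dir_res$c3_variants[[variant]]
  }
  run <- !vapply(crit, is.null, logical(1))
  if (is.na(dir_res$skill_rho)) FALSE else all(unlist(crit[run]))
}

## Run the methods on one replicate trial; returns named outcome categories.
## Any unexpected failure is recorded as data_rejected with its reason.
run_methods_once <- function(trial, methods, spec, rep_seed) {
  out <- character(0)
  if ("granger" %in% methods) {
    out["granger"] <- tryCatch({
      fwd <- linear_granger_test(trial, "S1", "S2",
                                 lag_order = spec$granger_lag)
      bwd <- linear_granger_test(trial, "S2", "S1",
                                 lag_order = spec$granger_lag)
      classify_outcome(isTRUE(fwd$reject), isTRUE(bwd$reject),
                       fwd$rejected_data || bwd$rejected_data)
    }, error = function(e) "data_rejected")
  }
  ccm_methods <- intersect(methods, c("ccm_main", "ccm_alternative"))
  if (base::length(ccm_methods) > 0) {
    res <- tryCatch({
      cfg <- spec$ccm
      cfg$seed <- rep_seed
      ccm_infer(trial, "S1", "S2", cfg)
    }, error = function(e) e)
    for (method in ccm_methods) {
      variant <- if (method == "ccm_main") "bootstrap" else "kendall"
      out[method] <- if (inherits(res, "error")) {
        "data_rejected"
      } else {
        classify_outcome(ccm_verdict_variant(res$x_causes_y, variant),
                         ccm_verdict_variant(res$y_causes_x, variant),
                         FALSE)
      }
    }
  }
  out
}

#' Run the noise-grid benchmark
#'
#' For every (process sd, measurement sd) grid cell and every method,
#' simulates `n_replicates` independent two-species trials (ground truth:
#' S1 causes S2 only), runs the method in both directions, classifies each
#' replicate into the five outcome categories, and tallies. Deterministic
#' given `base_seed`; per-replicate verdict records are attached as
#' attribute `records`.
#'
#' @param spec A [noise_grid_spec()].
#' @param verbose Print per-cell progress?
#' @return A data frame of class `outcome_tally`: one row per condition with
#'   counts over the five categories.
#' @export
run_noise_grid <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "noise_grid_spec"))
  grid <- expand.grid(process_sd = spec$process_sd_levels,
                      measurement_sd = spec$measurement_sd_levels)
  rows <- list()
  records <- list()
  for (g in seq_len(nrow(grid))) {
    psd <- grid$process_sd[g]
    msd <- grid$measurement_sd[g]
    params <- two_species_params(
      process_sd = psd, measurement_sd = msd,
      driver1_on = TRUE, driver2_on = spec$regime == "both_drivers",
      length = spec$length)
    outcomes <- matrix("", nrow = spec$n_replicates,
                       ncol = length(spec$methods),
                       dimnames = list(NULL, spec$methods))
    for (r in seq_len(spec$n_replicates)) {
      rep_seed <- substream_seed(spec$base_seed,
                                 sprintf("grid_p%g_m%g_r%d", psd, msd, r))
      trial <- simulate_two_species(params, seed = rep_seed)
      res <- run_methods_once(trial, spec$methods, spec, rep_seed)
      outcomes[r, names(res)] <- res
    }
    for (method in spec$methods) {
      counts <- table(factor(outcomes[, method], levels = outcome_categories))
      rows[[length(rows) + 1]] <- data.frame(
        method = method, regime = spec$regime, process_sd = psd,
        measurement_sd = msd, n_replicates = spec$n_replicates,
        as.list(counts), check.names = FALSE)
    }
    records[[g]] <- data.frame(process_sd = psd, measurement_sd = msd,
                               replicate = seq_len(spec$n_replicates),
                               outcomes, check.names = FALSE)
    if (verbose) {
      message(sprintf("cell process_sd=%g measurement_sd=%g done", psd, msd))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_tally", "data.frame")
  attr(out, "records") <- do.call(rbind, records)
  out
}

#' Write tallies as long-format CSV and JSON proportions
#'
#' @param tallies An `outcome_tally` data frame from [run_noise_grid()].
#' @param csv_path,json_path Output paths (`NULL` to skip writing).
#' @return Invisibly, a list with the long-format data frame (`long`) and the
#'   proportions list (`proportions`).
#' @export
tally_report <- function(tallies, csv_path = NULL, json_path = NULL) {
  if (nrow(tallies) == 0) stop_param("empty tallies")
  long <- do.call(rbind, lapply(seq_len(nrow(tallies)), function(i) {
    row <- tallies[i, ]
    data.frame(method = row$method, regime = row$regime,
               process_sd = row$process_sd,
               measurement_sd = row$measurement_sd,
               category = outcome_categories,
               count = as.numeric(row[outcome_categories]),
               proportion = as.numeric(row[outcome_categories]) /
                 row$n_replicates,
               n_replicates = row$n_replicates)
  }))
  props <- lapply(seq_len(nrow(tallies)), function(i) {
    row <- tallies[i, ]
    list(method = row$method, regime = row$regime,
         process_sd = row$process_sd, measurement_sd = row$measurement_sd,
         n_replicates = row$n_replicates,
         proportions = as.list(stats::setNames(
           as.numeric(row[outcome_categories]) / row$n_replicates,
           outcome_categories)))
  })
  out <- list(schema_version = 1, long = long, proportions = props)
  if (!is.null(csv_path)) utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(schema_version = 1, conditions = props),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Rebuild an outcome tally from a long-format CSV
#'
#' @param csv_path Path written by [tally_report()].
#' @return An `outcome_tally` data frame.
#' @export
read_tally_csv <- function(csv_path) {
  long <- utils::read.csv(csv_path)
  conds <- unique(long[c("method", "regime", "process_sd", "measurement_sd",
                         "n_replicates")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- merge(conds[i, ], long)
    counts <- stats::setNames(sel$count, sel$category)[outcome_categories]
    data.frame(conds[i, c("method", "regime", "process_sd", "measurement_sd",
                          "n_replicates")],
               as.list(counts), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("outcome_tally", "data.frame")
  out
}
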