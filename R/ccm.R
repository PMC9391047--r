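#' Delay embedding of a scalar series
#'
#' Builds the delay vectors `[x(t), x(t - tau), ..., x(t - (E-1) tau)]` for
#' every usable time `t`. The first coordinate is the current value; usable
#' times run from `(E-1) tau + 1` to `T` (1-based), giving
#' `T - (E-1) tau` vectors.
#'
#' @param x Numeric series.
#' @param E Embedding dimension (number of delays, >= 1).
#' @param tau Delay in samples (>= 1).
#' @param source Optional variable name carried along for labelling.
#' @return A `delay_embedding` list: `source`, `E`, `tau`, `vectors`
#'   (matrix usable-times x E), `times`.
#' @export
delay_embed <- function(x, E, tau = 1, source = "x") {
  if (E < 1 || tau < 1) stop_param("E and tau must be >= 1")
  T_ <- length(x)
  if (T_ <= (E - 1) * tau) {
    stop_param("series length ", T_, " too short for E = ", E,
               ", tau = ", tau)
  }
  times <- ((E - 1) * tau + 1):T_
  vectors <- vapply(0:(E - 1), function(j) x[times - j * tau],
                    numeric(length(times)))
  vectors <- matrix(vectors, ncol = E)
  structure(list(source = source, E = E, tau = tau,
                 vectors = vectors, times = times),
            class = "delay_embedding")
}

## Simplex-style prediction machinery. Given an embedding of the causee and
## library/prediction row indices, returns for each prediction row the
## exponential-distance weights over library rows. Weights are returned as a
## dense (n_pred x series length) matrix so that predictions for any target
## series (including surrogates and lag-shifted causers) are a single
## matrix product.
cross_map_weight_matrix <- function(emb, lib_rows, pred_rows,
                                    n_neighbors, exclusion_radius,
                                    series_length) {
  L <- emb$vectors[lib_rows, , drop = FALSE]
  P <- emb$vectors[pred_rows, , drop = FALSE]
  lib_t <- emb$times[lib_rows]
  pred_t <- emb$times[pred_rows]
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  d2[d2 < 0] <- 0
  W <- matrix(0, nrow = length(pred_rows), ncol = series_length)
  ok <- rep(TRUE, length(pred_rows))
  for (i in seq_along(pred_rows)) {
    valid <- abs(lib_t - pred_t[i]) >= exclusion_radius
    if (exclusion_radius == 0) valid <- rep(TRUE, length(lib_t))
    if (sum(valid) < n_neighbors) { ok[i] <- FALSE; next }
    dv <- sqrt(d2[i, ])
    dv[!valid] <- Inf
    nn <- order(dv)[seq_len(n_neighbors)]
    dn <- dv[nn]
    if (dn[1] == 0) {
      # exact matches: limit of the exponential weight puts all mass on them
      zero <- nn[dn == 0]
      w <- rep(1 / length(zero), length(zero))
      tsel <- lib_t[zero]
    } else {
      w <- exp(-dn / dn[1])
      w <- w / sum(w)
      tsel <- lib_t[nn]
    }
    for (j in seq_along(tsel)) W[i, tsel[j]] <- W[i, tsel[j]] + w[j]
  }
  list(W = W, ok = ok, pred_times = pred_t)
}

#' Cross-map prediction of a single target value
#'
#' Predicts the causer value at `query_time` from the causee's delay
#' embedding: the `n_neighbors` library vectors nearest (Euclidean) to the
#' query's contemporaneous delay vector are found, weighted by
#' `w_i = exp(-d_i / d_1)` (normalized; exact matches take all the weight,
#' the limit of the exponential form), and their contemporaneous target
#' values averaged.
#'
#' @param library A [delay_embed()] of the causee.
#' @param target_values Causer series, indexed on the same time grid as the
#'   series the library was built from.
#' @param query_time Time index (1-based) at which to predict.
#' @param n_neighbors Number of neighbours (default `E + 1`).
#' @param exclusion_radius Library vectors within this many samples of the
#'   query are excluded (default `tau * E`); `0` disables all exclusion,
#'   including of the query itself.
#' @param lib_rows Optional integer rows of the embedding to use as library
#'   (default: all).
#' @return Predicted target value (scalar).
#' @export
cross_map_estimate <- function(library, target_values, query_time,
                               n_neighbors = NULL, exclusion_radius = NULL,
                               lib_rows = NULL) {
  stopifnot(inherits(library, "delay_embedding"))
  n_neighbors <- n_neighbors %||% (library$E + 1)
  exclusion_radius <- exclusion_radius %||% (library$tau * library$E)
  lib_rows <- lib_rows %||% seq_along(library$times)
  if (length(lib_rows) < n_neighbors) stop_param("library too small")
  q <- match(query_time, library$times)
  if (is.na(q)) stop_param("no delay vector available at query time")
  res <- cross_map_weight_matrix(library, lib_rows, q, n_neighbors,
                                 exclusion_radius, length(target_values))
  if (!res$ok) stop_param("too few library points outside exclusion radius")
  as.numeric(res$W %*% target_values)
}

## Shared core: skill of cross-mapping `causer` from the embedding of
## `causee` with a given library row set. Returns skill plus the weight
## matrix so callers can reuse it for surrogates / lag profiles.
cross_map_core <- function(causee, causer, E, tau, n_neighbors,
                           exclusion_radius, lib_rows = NULL,
                           pred_rows = NULL) {
  emb <- delay_embed(causee, E, tau)
  lib_rows <- lib_rows %||% seq_along(emb$times)
  pred_rows <- pred_rows %||% seq_along(emb$times)
  res <- cross_map_weight_matrix(emb, lib_rows, pred_rows, n_neighbors,
                                 exclusion_radius, length(causer))
  use <- res$ok
  pred <- as.numeric(res$W %*% causer)
  actual <- causer[res$pred_times]
  skill <- if (sum(use) < 3 || stats::sd(pred[use]) == 0 ||
               stats::sd(actual[use]) == 0) {
    NA_real_
  } else {
    stats::cor(actual[use], pred[use])
  }
  list(skill = skill, W = res$W, ok = use, pred_times = res$pred_times,
       emb = emb)
}

#' Cross-map skill
#'
#' The Pearson correlation between actual causer values and their cross-map
#' predictions from the causee's delay embedding, over all usable prediction
#' times. When `library_size` is smaller than the number of available delay
#' vectors, the library is a contiguous random segment of that size.
#' Returns `NA` when the correlation is undefined (constant predictions).
#'
#' @param data A [trial_set()], data frame, or named-column matrix.
#' @param causee Variable whose delay embedding is used (the putative effect).
#' @param causer Variable being predicted (the putative cause).
#' @param E,tau Embedding dimension and delay.
#' @param library_size Library size (default: all available vectors).
#' @param seed Integer RNG seed for library placement.
#' @param n_neighbors Number of neighbours (default `E + 1`).
#' @param exclusion_radius Temporal exclusion radius (default `tau * E`).
#' @return Cross-map skill rho in `[-1, 1]`, or `NA`.
#' @export
cross_map_skill <- function(data, causee, causer, E = 3, tau = 1,
                            library_size = NULL, seed = 1,
                            n_neighbors = NULL, exclusion_radius = NULL) {
  ce <- trial_var(data, causee)
  cr <- trial_var(data, causer)
  n_neighbors <- n_neighbors %||% (E + 1)
  exclusion_radius <- exclusion_radius %||% (tau * E)
  n_avail <- length(ce) - (E - 1) * tau
  lib_rows <- NULL
  if (!is.null(library_size) && library_size < n_avail) {
    if (library_size < n_neighbors) stop_param("library too small")
    start <- with_substream(seed, "ccm_lib",
                            sample.int(n_avail - library_size + 1, 1))
    lib_rows <- start:(start + library_size - 1)
  }
  cross_map_core(ce, cr, E, tau, n_neighbors, exclusion_radius, lib_rows)$skill
}

#' Convergence verdicts from skill profiles
#'
#' `convergence_bootstrap_verdict` implements the main test: with paired
#' bootstrap skills at the smallest and largest library sizes, convergence
#' holds if at least `level` of the (large - small) differences are positive.
#' `convergence_kendall_verdict` implements the alternative: Kendall's tau of
#' (median) skill against library size must be positive with one-sided
#' p <= `alpha`.
#'
#' @param skill_small,skill_large Bootstrap skill samples at the smallest and
#'   largest library sizes.
#' @param level Required fraction of positive differences (default 0.95).
#' @return Logical verdict.
#' @export
convergence_bootstrap_verdict <- function(skill_small, skill_large,
                                          level = 0.95) {
  d <- skill_large - skill_small
  d <- d[is.finite(d)]
  if (length(d) == 0) return(FALSE)
  mean(d > 0) >= level
}

#' @rdname convergence_bootstrap_verdict
#' @param sizes Library sizes.
#' @param skills Skill (e.g. median over resamples) at each size.
#' @param alpha One-sided significance level (default 0.05).
#' @export
convergence_kendall_verdict <- function(sizes, skills, alpha = 0.05) {
  keep <- is.finite(skills)
  if (sum(keep) < 3 || stats::sd(skills[keep]) == 0) return(FALSE)
  ct <- suppressWarnings(stats::cor.test(sizes[keep], skills[keep],
                                         method = "kendall",
                                         alternative = "greater"))
  isTRUE(unname(ct$estimate) > 0) && ct$p.value <= alpha
}

#' Cross-map convergence profile
#'
#' Computes cross-map skill across a grid of library sizes (contiguous random
#' segments, `n_profile` resamples per size) and evaluates the convergence
#' criterion with both test variants: the main bootstrap comparison of the
#' smallest versus largest size (libraries resampled with replacement) and
#' the alternative Kendall trend test on median skill versus size.
#'
#' @inheritParams cross_map_skill
#' @param library_sizes Integer vector (>= 3 sizes, small to maximal).
#' @param n_boot Bootstrap resamples for the main variant.
#' @param n_profile Contiguous-segment resamples per size for the profile.
#' @return A list: `library_sizes`, `skill_by_library` (median per size),
#'   `skills` (matrix resample x size), `c3_bootstrap`, `c3_kendall`.
#' @export
ccm_convergence_profile <- function(data, causee, causer, E = 3, tau = 1,
                                    library_sizes, n_boot = 100,
                                    n_profile = 20, seed = 1,
                                    n_neighbors = NULL,
                                    exclusion_radius = NULL) {
  if (length(library_sizes) < 3) stop_param("need >= 3 library sizes")
  ce <- trial_var(data, causee)
  cr <- trial_var(data, causer)
  n_neighbors <- n_neighbors %||% (E + 1)
  exclusion_radius <- exclusion_radius %||% (tau * E)
  n_avail <- length(ce) - (E - 1) * tau
  library_sizes <- sort(pmin(as.integer(library_sizes), n_avail))
  ## skills for the profile are evaluated on a fixed random subset of
  ## prediction times: the profile compares library sizes, so a common,
  ## smaller prediction set keeps the comparison fair and fast
  pred_rows <- if (n_avail > 100) {
    sort(with_substream(seed, "ccm_pred", sample.int(n_avail, 100)))
  } else {
    seq_len(n_avail)
  }
  skill_for_rows <- function(rows) {
    cross_map_core(ce, cr, E, tau, n_neighbors, exclusion_radius, rows,
                   pred_rows)$skill
  }
  contiguous <- function(size, s) {
    start <- with_substream(s, "ccm_seg",
                            sample.int(max(1, n_avail - size + 1), 1))
    start:(min(n_avail, start + size - 1))
  }
  skills <- matrix(NA_real_, nrow = n_profile, ncol = length(library_sizes))
  for (j in seq_along(library_sizes)) {
    for (b in seq_len(n_profile)) {
      skills[b, j] <- skill_for_rows(
        contiguous(library_sizes[j], substream_seed(seed, paste0("p", j, "_", b))))
    }
  }
  med <- apply(skills, 2, stats::median, na.rm = TRUE)
  boot_rows <- function(size, s) {
    with_substream(s, "ccm_boot", sample.int(n_avail, size, replace = TRUE))
  }
  smin <- library_sizes[1]
  smax <- library_sizes[length(library_sizes)]
  boot_small <- vapply(seq_len(n_boot), function(b) {
    skill_for_rows(boot_rows(smin, substream_seed(seed, paste0("bs", b))))
  }, numeric(1))
  boot_large <- vapply(seq_len(n_boot), function(b) {
    skill_for_rows(boot_rows(smax, substream_seed(seed, paste0("bl", b))))
  }, numeric(1))
  list(library_sizes = library_sizes, skill_by_library = med, skills = skills,
       c3_bootstrap = convergence_bootstrap_verdict(boot_small, boot_large),
       c3_kendall = convergence_kendall_verdict(library_sizes, med))
}

#' Prediction-lag profile
#'
#' Cross-map skill as a function of the prediction lag: at lag `l` the
#' embedding of the causee at time `t` predicts the causer at `t + l`.
#' For a genuine causal link with transmission delay, skill should peak at a
#' strictly negative lag (the causee's delay vectors record the causer's
#' *past*); a peak at lag >= 0 fails the criterion.
#'
#' @inheritParams cross_map_skill
#' @param lags Integer lags to profile (e.g. `-8:8`).
#' @return A list: `lags`, `skill` (per lag), `best_lag`, `c4` verdict.
#' @export
prediction_lag_profile <- function(data, causee, causer, E = 3, tau = 1,
                                   lags = -8:8, n_neighbors = NULL,
                                   exclusion_radius = NULL) {
  ce <- trial_var(data, causee)
  cr <- trial_var(data, causer)
  n_neighbors <- n_neighbors %||% (E + 1)
  exclusion_radius <- exclusion_radius %||% (tau * E)
  core <- cross_map_core(ce, cr, E, tau, n_neighbors, exclusion_radius)
  T_ <- length(cr)
  skill <- vapply(lags, function(l) {
    shifted <- rep(NA_real_, T_)
    src <- seq_len(T_) + l
    okt <- src >= 1 & src <= T_
    shifted[okt] <- cr[src[okt]]
    pred <- as.numeric(core$W %*% ifelse(is.na(shifted), 0, shifted))
    touched <- as.numeric(core$W %*% as.numeric(is.na(shifted))) == 0
    actual <- shifted[core$pred_times]
    use <- core$ok & touched & !is.na(actual)
    if (sum(use) < 3 || stats::sd(pred[use]) == 0 ||
        stats::sd(actual[use]) == 0) return(NA_real_)
    stats::cor(actual[use], pred[use])
  }, numeric(1))
  ## ties (e.g. perfect prediction at every lag) break toward the smallest
  ## |lag|: parsimony, and the self-map then correctly peaks at 0
  ord <- order(-skill, abs(lags), na.last = TRUE)
  best <- lags[ord[1]]
  list(lags = lags, skill = skill, best_lag = best,
       c4 = isTRUE(best < 0))
}

#' Configuration for a CCM causal inference
#'
#' @param E,tau Embedding dimension and delay (defaults 3, 1).
#' @param n_neighbors Neighbours per prediction (default `E + 1`).
#' @param exclusion_radius Temporal exclusion radius (default `tau * E`).
#' @param criteria Integer subset of `1:4`; criteria to run. Default
#'   `c(1, 2, 3)` (the prediction-lag test is hard to interpret for periodic
#'   dynamics, where skill oscillates with lag, so it is off by default).
#' @param variant Convergence-test variant: `"bootstrap"` (main) or
#'   `"kendall"` (alternative).
#' @param library_sizes Library-size grid for the convergence profile
#'   (default: 4 sizes from small to maximal, chosen from the data).
#' @param n_boot,n_profile,n_surrogates Resampling effort.
#' @param alpha Significance level for criteria 2 and 3.
#' @param lags Lag grid for criterion 4.
#' @param seed Integer RNG seed.
#' @return A `ccm_config` list.
#' @export
ccm_config <- function(E = 3, tau = 1, n_neighbors = NULL,
                       exclusion_radius = NULL, criteria = c(1, 2, 3),
                       variant = c("bootstrap", "kendall"),
                       library_sizes = NULL, n_boot = 100, n_profile = 20,
                       n_surrogates = 99, alpha = 0.05, lags = -8:8,
                       seed = 1) {
  structure(list(E = E, tau = tau, n_neighbors = n_neighbors %||% (E + 1),
                 exclusion_radius = exclusion_radius %||% (tau * E),
                 criteria = criteria, variant = match.arg(variant),
                 library_sizes = library_sizes, n_boot = n_boot,
                 n_profile = n_profile, n_surrogates = n_surrogates,
                 alpha = alpha, lags = lags, seed = seed),
            class = "ccm_config")
}

ccm_one_direction <- function(ce, cr, label, cfg) {
  n_avail <- length(ce) - (cfg$E - 1) * cfg$tau
  core <- cross_map_core(ce, cr, cfg$E, cfg$tau, cfg$n_neighbors,
                         cfg$exclusion_radius)
  rho <- core$skill
  crit <- list(c1_positive = NULL, c2_significant = NULL,
               c3_convergent = NULL, c4_lag = NULL)
  p2 <- NA_real_
  profile <- NULL
  c3_both <- NULL
  if (!is.na(rho)) {
    if (1 %in% cfg$criteria) crit$c1_positive <- rho > 0
    if (2 %in% cfg$criteria) {
      surr <- make_surrogates(cr, surrogate_spec("phase_randomization",
                                                 cfg$n_surrogates,
                                                 substream_seed(cfg$seed, paste0("c2", label))))
      pred <- core$W %*% surr
      act <- surr[core$pred_times, , drop = FALSE]
      rho_surr <- vapply(seq_len(ncol(surr)), function(j) {
        a <- act[core$ok, j]; p <- pred[core$ok, j]
        if (stats::sd(a) == 0 || stats::sd(p) == 0) return(-Inf)
        stats::cor(a, p)
      }, numeric(1))
      p2 <- (1 + sum(rho_surr >= rho)) / (1 + cfg$n_surrogates)
      crit$c2_significant <- p2 <= cfg$alpha
    }
    if (3 %in% cfg$criteria) {
      sizes <- cfg$library_sizes %||%
        unique(round(seq(max(cfg$n_neighbors + 2, 10), n_avail,
                         length.out = 4)))
      profile <- ccm_convergence_profile(
        matrix(c(ce, cr), ncol = 2, dimnames = list(NULL, c("ce", "cr"))),
        "ce", "cr", cfg$E, cfg$tau, sizes, cfg$n_boot, cfg$n_profile,
        substream_seed(cfg$seed, paste0("c3", label)),
        cfg$n_neighbors, cfg$exclusion_radius)
      crit$c3_convergent <- if (cfg$variant == "bootstrap") {
        profile$c3_bootstrap
      } else {
        profile$c3_kendall
      }
      c3_both <- list(bootstrap = profile$c3_bootstrap,
                      kendall = profile$c3_kendall)
    }
    if (4 %in% cfg$criteria) {
      lagp <- prediction_lag_profile(
        matrix(c(ce, cr), ncol = 2, dimnames = list(NULL, c("ce", "cr"))),
        "ce", "cr", cfg$E, cfg$tau, cfg$lags, cfg$n_neighbors,
        cfg$exclusion_radius)
      crit$c4_lag <- lagp$c4
    }
  }
  run <- !vapply(crit, is.null, logical(1))
  verdict <- if (is.na(rho)) FALSE else all(unlist(crit[run]))
  structure(list(direction = label, skill_rho = rho, p_value = p2,
                 library_sizes = profile$library_sizes,
                 skill_by_library = profile$skill_by_library,
                 criteria = crit, c3_variants = c3_both,
                 verdict = isTRUE(verdict)),
            class = "cross_map_result")
}

#' @export
print.cross_map_result <- function(x, ...) {
  cr <- vapply(x$criteria, function(v) {
    if (is.null(v)) "-" else if (v) "T" else "F"
  }, character(1))
  cat(sprintf("<cross_map_result> %s: rho = %s, c1..c4 = [%s], verdict = %s\n",
              x$direction,
              if (is.na(x$skill_rho)) "NA" else sprintf("%.3f", x$skill_rho),
              paste(cr, collapse = " "), x$verdict))
  invisible(x)
}

#' Delay-map shading table
#'
#' Returns the causee's delay vectors together with the contemporaneous
#' causer value and the time index, the table behind continuity ("shading")
#' plots of the delay space: shade by the causer to eyeball whether nearby
#' delay vectors carry similar causer values, or shade by `time` to check
#' for the nonreverting-trend pathology.
#'
#' @inheritParams cross_map_skill
#' @param path Optional CSV path to write the table to.
#' @return A data frame: `time`, embedding coordinates `d0..d(E-1)`, `causer`.
#' @export
delay_map_shading <- function(data, causee, causer, E = 3, tau = 1,
                              path = NULL) {
  ce <- trial_var(data, causee)
  cr <- trial_var(data, causer)
  emb <- delay_embed(ce, E, tau, source = causee)
  out <- data.frame(time = emb$times, emb$vectors, causer = cr[emb$times])
  names(out) <- c("time", paste0("d", 0:(E - 1)), "causer")
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' CCM causal inference in both directions
#'
#' Runs the full convergent-cross-mapping procedure for "`x` causes `y`?"
#' (cross-mapping `x` from `y`'s delay embedding) and "`y` causes `x`?".
#' The criteria run are configurable; criterion 2 uses phase-randomization
#' surrogates of the causer with a one-sided counting p-value on skill, and
#' criterion 3 uses the convergence-test variant named in the config. The
#' verdict for a direction is the conjunction of all criteria run.
#'
#' @param data A [trial_set()], data frame, or named-column matrix.
#' @param x,y Variable names.
#' @param config A [ccm_config()].
#' @return A list with elements `x_causes_y` and `y_causes_x`, each a
#'   `cross_map_result`.
#' @export
ccm_infer <- function(data, x, y, config = ccm_config()) {
  xv <- trial_var(data, x)
  yv <- trial_var(data, y)
  list(
    x_causes_y = ccm_one_direction(yv, xv, paste0(x, "->", y), config),
    y_causes_x = ccm_one_direction(xv, yv, paste0(y, "->", x), config))
}
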