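#' Construct a trial set
#'
#' A `trial_set` holds one simulated (or observed) multivariate trial on a
#' shared uniform time grid: a numeric matrix with one row per time point and
#' one named column per variable, plus the sampling interval and the
#' generating-model metadata needed to regenerate it bit-identically.
#'
#' @param values Numeric matrix, rows = time points, named columns = variables.
#' @param dt Sampling interval (time units per row).
#' @param trial_id Integer trial identifier.
#' @param seed Integer RNG seed the trial was generated from (`NA` if none).
#' @param model Name of the generating model.
#' @param params Named list of generating-model parameters.
#'
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(values, dt = 1, trial_id = 1L, seed = NA_integer_,
                      model = "unknown", params = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_param("trial values must be numeric")
  if (anyNA(values)) stop_param("trial values must not contain missing values")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  structure(
    list(values = values, names = colnames(values), dt = dt,
         trial_id = as.integer(trial_id), seed = seed,
         meta = list(model = model, params = params)),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> model '%s': %d time points x %d variables (%s), dt = %g\n",
              x$meta$model, nrow(x$values), ncol(x$values),
              paste(x$names, collapse = ", "), x$dt))
  invisible(x)
}

#' @export
as.data.frame.trial_set <- function(x, ...) {
  data.frame(time = seq_len(nrow(x$values)) * x$dt, x$values,
             check.names = FALSE)
}

#' Extract one variable from a trial set
#'
#' @param data A `trial_set`, data frame, or numeric matrix with named columns;
#'   a plain numeric vector is returned as-is.
#' @param name Variable (column) name.
#' @return Numeric vector.
#' @export
trial_var <- function(data, name) {
  if (is.numeric(data) && is.null(dim(data))) return(as.numeric(data))
  m <- if (inherits(data, "trial_set")) data$values else as.matrix(data)
  if (!name %in% colnames(m)) {
    stop_param("variable '", name, "' not found in data")
  }
  as.numeric(m[, name])
}

#' Write / read a trial set as CSV with a YAML sidecar
#'
#' The CSV has a leading `time` column and one named column per variable; the
#' sidecar (`<path>.yaml`) records model, parameters, seed and sampling
#' interval so the trial can be reconstructed or regenerated.
#'
#' @param trial A `trial_set`.
#' @param path CSV file path.
#' @param sidecar Write the YAML sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, sidecar = TRUE) {
  stopifnot(inherits(trial, "trial_set"))
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  if (sidecar) {
    meta <- list(model = trial$meta$model, params = trial$meta$params,
                 seed = trial$seed, dt = trial$dt, trial_id = trial$trial_id)
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  has_time <- identical(names(df)[1], "time")
  vals <- as.matrix(df[if (has_time) -1 else TRUE])
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  dt <- meta$dt
  if (is.null(dt)) dt <- if (has_time && nrow(df) > 1) diff(df$time[1:2]) else 1
  trial_set(vals, dt = dt,
            trial_id = if (is.null(meta$trial_id)) 1L else meta$trial_id,
            seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
            model = if (is.null(meta$model)) "unknown" else meta$model,
            params = if (is.null(meta$params)) list() else meta$params)
}
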