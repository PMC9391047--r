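#' @keywords internal
"_PACKAGE"

## Deterministic per-stream seed derivation. Every simulator draws each noise
## source from its own substream so that toggling one source (e.g. measurement
## noise) never shifts the draws of another. Keeps results < 2^31 so set.seed()
## accepts them on 32-bit integer platforms.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(stream)) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

## Run expr with the RNG seeded from (seed, stream), restoring the caller's
## RNG state afterwards. All package randomness funnels through here.
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}

## Cached package configuration (coefficients of the toy dynamical systems).
.causalts_env <- new.env(parent = emptyenv())

#' System coefficient configuration
#'
#' Returns the versioned coefficient set used by the toy-system simulators
#' ([simulate_linear_network()], [simulate_two_species()]). Shipped as a YAML
#' file under `inst/extdata` so that the exact update equations live in one
#' auditable place.
#'
#' @return A named list of coefficient blocks.
#' @export
system_coefficients <- function() {
  if (is.null(.causalts_env$coefs)) {
    path <- system.file("extdata", "system_coefficients.yaml",
                        package = "causalts", mustWork = TRUE)
    .causalts_env$coefs <- yaml::read_yaml(path)
  }
  .causalts_env$coefs
}

stop_param <- function(...) {
  stop(structure(class = c("causalts_parameter_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
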