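#' @keywords internal
"_PACKAGE"

# Smallest p-value ever reported; avoids log(0) downstream.
P_FLOOR <- 1e-300

clip_p <- function(p) pmin(pmax(p, P_FLOOR), 1)

#' @noRd
stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Seed a private RNG stream derived from a base seed
#'
#' Each stochastic stage of the simulator draws from its own stream so that
#' stages can be re-run or reordered without perturbing one another.
#' @noRd
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
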