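# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pm <- function(..., call. = FALSE) stop(..., call. = call.)

assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop_pm(...)
}

#' Derive a reproducible sub-seed from a master seed and integer keys
#'
#' All randomness in the package flows from one user-supplied seed; per-potter
#' and per-trial substreams are derived deterministically so that subsets of a
#' synthetic study are reproducible in isolation. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param ... integer keys (e.g. potter index, trial number).
#' @return an integer seed.
#' @keywords internal
sub_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed) %% 2147483629
  for (k in keys) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(h) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
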