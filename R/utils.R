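#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classed error helper so callers can condition on failure modes.
#' @noRd
stop_echovol <- function(msg, class) {
  stop(structure(
    class = c(class, "echovol_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate `code` under a temporary RNG seed, restoring global RNG state.
#' @noRd
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream of independent sub-seeds from one master seed.
#' Values stay below 2^31 so they remain valid R integers.
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
}

#' Structured log line used by the pipeline stages.
#' @noRd
log_stage <- function(stage, seed, t0, ...) {
  extra <- paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                 collapse = " ")
  message(sprintf("[echovol] stage=%s seed=%s elapsed=%.2fs %s",
                  stage, seed, as.numeric(Sys.time()) - t0, extra))
}
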