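#' @keywords internal
"_PACKAGE"

CONDITIONS <- c("A", "V", "AV")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All stochastic stages draw their randomness from one root seed via named
#' substreams, so toggling one stage never perturbs another stage's draws.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer root seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147482951
  as.integer((as.numeric(seed) %% 2147482951 * 48271 + h) %% 2147482951 + 1)
}

## AUC over the unit quantile interval: rectangle rule on equally spaced
## quantiles, i.e. the arithmetic mean of the per-quantile values.
quantile_auc <- function(x) mean(x)

## Assert two quantile CDFs share an evaluation grid.
check_shared_times <- function(a, b) {
  if (length(a$eval_times_ms) != length(b$eval_times_ms) ||
      max(abs(a$eval_times_ms - b$eval_times_ms)) > 1e-9) {
    stop_invalid("quantile CDFs do not share evaluation times")
  }
  invisible(TRUE)
}
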