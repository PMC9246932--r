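## Quantile-indexed empirical CDFs and conditioned trial subsets -------------

#' Construct a quantile CDF object
#'
#' @param probs Cumulative probabilities at the evaluation times.
#' @param eval_times_ms Linearly spaced latencies (ms).
#' @param n_rts Number of RTs the CDF is based on.
#' @return An object of class `quantile_cdf`.
#' @export
quantile_cdf <- function(probs, eval_times_ms, n_rts = NA_integer_) {
  stopifnot(length(probs) == length(eval_times_ms))
  structure(list(probs = as.numeric(probs),
                 eval_times_ms = as.numeric(eval_times_ms),
                 lo_ms = eval_times_ms[1],
                 hi_ms = eval_times_ms[length(eval_times_ms)],
                 n_rts = n_rts),
            class = "quantile_cdf")
}

#' @export
print.quantile_cdf <- function(x, ...) {
  cat(sprintf("quantile CDF: %d points on [%.0f, %.0f] ms (n = %s)\n",
              length(x$probs), x$lo_ms, x$hi_ms, x$n_rts))
  invisible(x)
}

#' Pooled latency cutoffs across conditions
#'
#' The lowest 2.5th and highest 97.5th percentile over the three conditions
#' define one shared evaluation range, preserving the relationship between
#' conditions whose outliers were trimmed separately.
#'
#' @param rts_by_condition Named list of RT vectors (ms), one per condition.
#' @param pct_limits Percentile pair, default `c(0.025, 0.975)`.
#' @return `c(lo_ms, hi_ms)`.
#' @export
pooled_percentile_limits <- function(rts_by_condition,
                                     pct_limits = c(0.025, 0.975)) {
  if (any(lengths(rts_by_condition) < 2)) {
    stop_invalid("need at least 2 RTs per condition")
  }
  lo <- min(vapply(rts_by_condition, function(x) {
    stats::quantile(x, pct_limits[1], names = FALSE, type = 7)
  }, numeric(1)))
  hi <- max(vapply(rts_by_condition, function(x) {
    stats::quantile(x, pct_limits[2], names = FALSE, type = 7)
  }, numeric(1)))
  if (lo >= hi) stop_invalid("degenerate pooled limits (lo >= hi)")
  c(lo_ms = lo, hi_ms = hi)
}

#' Empirical CDF on linearly spaced latencies
#'
#' The cumulative probability `P(RT <= t)` is evaluated at `n_q` linearly
#' spaced times between the pooled cutoffs ("vertical" quantisation; no
#' interpolation to the RT axis, so unequal trial counts across conditions
#' are fine). Ties at an evaluation time count as below-or-equal.
#'
#' @param rts RT vector (ms), non-empty.
#' @param limits `c(lo_ms, hi_ms)` from [pooled_percentile_limits()].
#' @param n_q Number of quantiles (default 20).
#' @return A [quantile_cdf()].
#' @export
empirical_cdf <- function(rts, limits, n_q = 20L) {
  if (length(rts) == 0) stop_invalid("empty RT sample")
  if (limits[1] >= limits[2]) stop_invalid("invalid limits")
  t_k <- seq(limits[1], limits[2], length.out = n_q)
  probs <- vapply(t_k, function(t) mean(rts <= t), numeric(1))
  quantile_cdf(probs, t_k, n_rts = length(rts))
}

#' Annotate trials with preceding modality and switch/repeat class
#'
#' The preceding modality is the condition of the immediately preceding
#' trial within the same block (never carried across blocks). Trials whose
#' preceding trial received no response (a miss) get no stratum: their
#' context is considered unusable for conditioned estimates. Switch/repeat
#' classes: repeats are A->A, V->V, AV->AV; switches are V->A, A->V and the
#' pooled V/A->AV; unisensory trials preceded by AV (AV->A, AV->V) are
#' neither.
#'
#' @param trials One subject's trial records (raw order, all rows).
#' @return The table with added `prev_modality` and `transition`
#'   (`"repeat"`, `"switch"` or NA) columns.
#' @export
annotate_sequence <- function(trials) {
  o <- order(trials$block, trials$trial_idx)
  tr <- trials[o, , drop = FALSE]
  n <- nrow(tr)
  prev <- c(NA_character_, tr$condition[-n])
  prev_responded <- c(NA, !is.na(tr$rt_ms[-n]))
  first <- c(TRUE, tr$block[-1] != tr$block[-n])
  prev[first] <- NA_character_
  prev[!first & !prev_responded] <- NA_character_
  tr$prev_modality <- prev
  tr$transition <- ifelse(is.na(prev), NA_character_,
    ifelse(prev == tr$condition, "repeat",
      ifelse(tr$condition == "AV" | prev != "AV", "switch", NA_character_)))
  tr
}

## Build one stratum CDF or NULL when below the minimum count.
cdf_or_null <- function(rts, limits, n_q, min_n) {
  if (length(rts) < min_n) return(NULL)
  empirical_cdf(rts, limits, n_q)
}

#' Build the full set of conditioned quantile CDFs for one subject
#'
#' Produces, on one shared evaluation grid: per-condition CDFs, CDFs
#' stratified by preceding modality, and switch/repeat CDFs (with the two
#' multisensory switch directions A->AV and V->AV both pooled and kept
#' separate). Strata below `min_n` RTs are flagged degenerate (NULL);
#' downstream consumers decide the fallback.
#'
#' @param trials One subject's trial records; cleaned flags are computed if
#'   absent and only valid RTs are used.
#' @param n_q Number of quantiles.
#' @param min_n Minimum RTs per stratum (default 5).
#' @param limits Optional fixed evaluation limits; by default the pooled
#'   2.5/97.5 cutoffs of the window-valid per-condition samples, i.e. the
#'   same cutoffs used by the percentile trim, so the limits exactly bound
#'   the retained data.
#' @return A list of class `cdf_set`: `cdf` (per condition), `by_prev`
#'   (condition x preceding modality), `switch`, `repeat_` (per condition),
#'   `av_switch_from` (A and V separately), `limits`, `eval_times_ms`, `n`.
#' @export
condition_subsets <- function(trials, n_q = 20L, min_n = 5L, limits = NULL) {
  if (is.null(trials$rt_valid)) trials <- clean_rts(trials)
  ## keep caller-provided sequence annotation (e.g. for partition re-analysis)
  tr <- if (is.null(trials$prev_modality)) annotate_sequence(trials) else trials
  cl <- tr[tr$rt_valid, , drop = FALSE]
  rts_by_cond <- split(cl$rt_ms, factor(cl$condition, levels = CONDITIONS))
  if (is.null(limits)) {
    ## pooled range of the retained data = min/max of the trim cutoffs
    pre <- tr[is.na(tr$rm_reason) | tr$rm_reason %in% c("", "pct-fast", "pct-slow"), ]
    pre <- pre[!is.na(pre$rt_ms), ]
    limits <- pooled_percentile_limits(
      split(pre$rt_ms, factor(pre$condition, levels = CONDITIONS)))
  }
  mk <- function(x) cdf_or_null(x, limits, n_q, min_n)

  by_prev <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cc) {
    lapply(stats::setNames(CONDITIONS, CONDITIONS), function(m) {
      mk(cl$rt_ms[cl$condition == cc & !is.na(cl$prev_modality) &
                    cl$prev_modality == m])
    })
  })
  sw <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cc) {
    mk(cl$rt_ms[cl$condition == cc & !is.na(cl$transition) &
                  cl$transition == "switch"])
  })
  rp <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cc) {
    mk(cl$rt_ms[cl$condition == cc & !is.na(cl$transition) &
                  cl$transition == "repeat"])
  })
  av_from <- lapply(c(A = "A", V = "V"), function(m) {
    mk(cl$rt_ms[cl$condition == "AV" & !is.na(cl$prev_modality) &
                  cl$prev_modality == m])
  })
  structure(list(
    cdf = lapply(rts_by_cond, function(x) mk(x)),
    by_prev = by_prev, switch = sw, repeat_ = rp,
    av_switch_from = av_from,
    limits = limits,
    eval_times_ms = seq(limits[1], limits[2], length.out = n_q),
    n_q = n_q, min_n = min_n,
    n = vapply(rts_by_cond, length, integer(1)),
    trials = cl
  ), class = "cdf_set")
}
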