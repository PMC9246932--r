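## Modality switch effects ----------------------------------------------------

#' Modality switch effect as an area between CDFs
#'
#' `MSE = AUC(F_repeat - F_switch)` over the unit quantile interval;
#' positive when switching slows responses (the repeat CDF dominates).
#'
#' @param f_repeat,f_switch [quantile_cdf()]s on a shared grid.
#' @return Scalar MSE (unitless AUC in `[-1, 1]`).
#' @export
mse_auc <- function(f_repeat, f_switch) {
  check_shared_times(f_repeat, f_switch)
  quantile_auc(f_repeat$probs - f_switch$probs)
}

#' Switch effects for every condition of one subject
#'
#' Computes the CDF-based MSE for V->A, A->V, the pooled multisensory
#' switch condition V/A->AV, and the separated A->AV and V->AV directions
#' (both against the AV repeat CDF). The separated multisensory MSEs can
#' later be normalised by the pooled AV MSE at group level (see
#' [normalise_av_mse()]).
#'
#' @param cdfset A `cdf_set` from [condition_subsets()].
#' @return A data frame: `condition`, `mse_auc`, `degenerate`.
#' @export
mse_by_condition <- function(cdfset) {
  pairs <- list(
    "V->A" = list(r = cdfset$repeat_$A, s = cdfset$switch$A),
    "A->V" = list(r = cdfset$repeat_$V, s = cdfset$switch$V),
    "V/A->AV" = list(r = cdfset$repeat_$AV, s = cdfset$switch$AV),
    "A->AV" = list(r = cdfset$repeat_$AV, s = cdfset$av_switch_from$A),
    "V->AV" = list(r = cdfset$repeat_$AV, s = cdfset$av_switch_from$V)
  )
  data.frame(
    condition = names(pairs),
    mse_auc = vapply(pairs, function(p) {
      if (is.null(p$r) || is.null(p$s)) NA_real_ else mse_auc(p$r, p$s)
    }, numeric(1)),
    degenerate = vapply(pairs, function(p) is.null(p$r) || is.null(p$s),
                        logical(1)),
    row.names = NULL
  )
}

#' Normalise the separated multisensory MSEs by the pooled AV MSE
#'
#' Group-level normalisation: the mean A->AV and V->AV MSEs are divided by
#' the mean pooled V/A->AV MSE, allowing comparison across age groups.
#' Undefined (and flagged) when the pooled reference is zero.
#'
#' @param mse_table Stacked per-subject output of [mse_by_condition()].
#' @return A list: `a_to_av`, `v_to_av` (normalised), `reference`, `ok`.
#' @export
normalise_av_mse <- function(mse_table) {
  m <- function(cc) mean(mse_table$mse_auc[mse_table$condition == cc],
                         na.rm = TRUE)
  ref <- m("V/A->AV")
  ok <- is.finite(ref) && abs(ref) > .Machine$double.eps
  list(a_to_av = if (ok) m("A->AV") / ref else NA_real_,
       v_to_av = if (ok) m("V->AV") / ref else NA_real_,
       reference = ref, ok = ok)
}

#' Mean-RT modality switch effect
#'
#' `mean(switch RTs) - mean(repeat RTs)` in ms over the unisensory
#' conditions, optionally restricted to trials whose preceding ISI falls in
#' a window (e.g. 2500-3000 ms to approximate designs with longer ISIs).
#'
#' @param trials One subject's trial records.
#' @param isi_window Optional `c(lo, hi)` ms restriction on preceding ISI.
#' @param conditions Conditions included (default both unisensory).
#' @return Scalar MSE in ms.
#' @export
mse_mean_rt <- function(trials, isi_window = NULL, conditions = c("A", "V")) {
  if (is.null(trials$rt_valid)) trials <- clean_rts(trials)
  tr <- annotate_sequence(trials)
  cl <- tr[tr$rt_valid & tr$condition %in% conditions &
             !is.na(tr$transition), , drop = FALSE]
  if (!is.null(isi_window)) {
    cl <- cl[cl$isi_ms >= isi_window[1] & cl$isi_ms <= isi_window[2], ,
             drop = FALSE]
  }
  sw <- cl$rt_ms[cl$transition == "switch"]
  rp <- cl$rt_ms[cl$transition == "repeat"]
  if (length(sw) == 0 || length(rp) == 0) {
    stop_invalid("empty switch or repeat subset")
  }
  mean(sw) - mean(rp)
}

#' Race-model gain within switch and repeat partitions
#'
#' Runs the full race pipeline separately on a subject's switch trials and
#' repeat trials. Within a partition the conditioned race is used where the
#' strata permit, otherwise the unconditioned Raab model (logged via the
#' returned `conditioned` flags). Subjects without enough trials in both
#' partitions are not analysable.
#'
#' @param trials One subject's trial records.
#' @param min_n Minimum RTs per condition within a partition.
#' @return A list: `gain_switch`, `gain_repeat`, `conditioned` (logical
#'   per partition), or NULL when a partition is unusable.
#' @export
race_by_switch <- function(trials, min_n = 10L) {
  if (is.null(trials$rt_valid)) trials <- clean_rts(trials)
  tr <- annotate_sequence(trials)
  cl <- tr[tr$rt_valid, , drop = FALSE]
  part_gain <- function(which) {
    sub <- cl[!is.na(cl$transition) & cl$transition == which, , drop = FALSE]
    counts <- table(factor(sub$condition, levels = CONDITIONS))
    if (any(counts < min_n)) return(NULL)
    cs <- suppressWarnings(condition_subsets(sub, min_n = min_n))
    ## conditioned race only if every unisensory-by-prev stratum is present
    strata_ok <- all(vapply(CONDITIONS, function(m) {
      !is.null(cs$by_prev$A[[m]]) && !is.null(cs$by_prev$V[[m]])
    }, logical(1)))
    ro <- suppressWarnings(race_outcome(cs, conditioned = strata_ok))
    list(gain = ro$gain, conditioned = strata_ok)
  }
  s <- part_gain("switch")
  r <- part_gain("repeat")
  if (is.null(s) || is.null(r)) return(NULL)
  list(gain_switch = s$gain, gain_repeat = r$gain,
       conditioned = c(switch = s$conditioned, repeat_ = r$conditioned))
}
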