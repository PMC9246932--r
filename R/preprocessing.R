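## Preprocessing: detection accuracy, participant exclusion, RT cleaning -----

#' Score detection accuracy from trials and a false-alarm count
#'
#' Detection accuracy is the F1 score, the harmonic mean of precision and
#' recall, which accounts for both misses and excessive button pressing.
#' Recall = hits / (hits + misses); precision = hits / (hits + FAs). Miss
#' and FA rates are reported as proportions of the total stimulus trials.
#'
#' @param trials Trial records for one subject (`rt_ms` NA = miss).
#' @param fa_count Number of false alarms (responses with no stimulus).
#' @return A list: `f1`, `precision`, `recall`, `fa_rate`, `miss_rate`,
#'   `hits`, `misses`, `fas`, `n_trials`.
#' @export
score_accuracy <- function(trials, fa_count = 0) {
  n <- nrow(trials)
  if (is.null(n) || n == 0) stop_invalid("no stimulus trials to score")
  hits <- sum(!is.na(trials$rt_ms))
  misses <- n - hits
  recall <- if (hits + misses > 0) hits / (hits + misses) else 0
  precision <- if (hits + fa_count > 0) hits / (hits + fa_count) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(f1 = f1, precision = precision, recall = recall,
       fa_rate = fa_count / n, miss_rate = misses / n,
       hits = hits, misses = misses, fas = fa_count, n_trials = n)
}

## Per-condition hit counts, used for the modality-imbalance criterion.
hits_by_condition <- function(trials) {
  vapply(c("A", "V"), function(cc) {
    sum(trials$condition == cc & !is.na(trials$rt_ms))
  }, numeric(1))
}

#' Apply participant exclusion criteria
#'
#' Flags each subject against seven criteria: age outside 6-40 years,
#' performance IQ below 80 or missing, detection accuracy more than 3 SDs
#' below the cohort mean, false alarms on more than 65% of trials, hits in
#' one unisensory modality fewer than 50% of the other (eye closure / not
#' listening), ISIs outside 1-3 s, and fewer than 20 valid RTs in any
#' condition. The accuracy cutoff is evaluated on the candidate pool's F1
#' scores before any RT-based exclusion.
#'
#' @param subjects Subject table (`subject_id`, `age_years`, `piq`).
#' @param trials Trial table for all subjects.
#' @param summaries Optional named list of [score_accuracy()] results; if
#'   missing they are computed from `trials` and `subjects$fa_count`.
#' @param age_limits Inclusive age range, default `c(6, 40)`.
#' @param min_piq Minimum performance IQ (inclusive), default 80.
#' @return A data frame with `subject_id`, `excluded` and a comma-separated
#'   `reasons` column (empty when retained).
#' @export
apply_exclusions <- function(subjects, trials, summaries = NULL,
                             age_limits = c(6, 40), min_piq = 80) {
  ids <- subjects$subject_id
  if (is.null(summaries)) {
    summaries <- lapply(seq_along(ids), function(i) {
      tr <- trials[trials$subject_id == ids[i], ]
      fa <- if ("fa_count" %in% names(subjects)) subjects$fa_count[i] else 0
      score_accuracy(tr, fa)
    })
    names(summaries) <- ids
  }
  f1 <- vapply(summaries, `[[`, numeric(1), "f1")
  f1_cut <- mean(f1) - 3 * stats::sd(f1)

  reasons <- lapply(seq_along(ids), function(i) {
    r <- character(0)
    tr <- trials[trials$subject_id == ids[i], ]
    age <- subjects$age_years[i]
    if (is.na(age) || age < age_limits[1] || age > age_limits[2]) {
      r <- c(r, "age-range")
    }
    piq <- subjects$piq[i]
    if (is.na(piq) || piq < min_piq) r <- c(r, "piq")
    if (f1[i] < f1_cut) r <- c(r, "accuracy-3sd")
    if (summaries[[i]]$fa_rate > 0.65) r <- c(r, "fa-excess")
    h <- hits_by_condition(tr)
    if (min(h) < 0.5 * max(h)) r <- c(r, "modality-imbalance")
    if (any(tr$isi_ms < 1000 | tr$isi_ms > 3000)) r <- c(r, "isi-range")
    cl <- cleaned_rts(clean_rts(tr))
    n_cond <- table(factor(cl$condition, levels = CONDITIONS))
    if (any(n_cond < 20)) r <- c(r, "min-rts")
    r
  })
  data.frame(
    subject_id = ids,
    excluded = lengths(reasons) > 0,
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Flag invalid response times for analysis
#'
#' Cleaning is a pure flagging pass over the raw trial table: no rows are
#' dropped, so applying it twice yields byte-identical output. A trial's RT
#' is flagged invalid when (in order) it has more than one response
#' (double-press), it is one of the first 3 trials of a block (training),
#' its preceding ISI falls outside 1000-3000 ms, there is no response
#' (miss), the RT falls outside the 100-2000 ms window (anticipatory /
#' late), or the RT falls outside the middle 95th percentile (2.5-97.5,
#' linear interpolation; boundary values retained) of its condition. The
#' percentile step is skipped with a warning for conditions with fewer than
#' 2 window-valid RTs.
#'
#' @param trials Trial records for one subject.
#' @param rt_window RT validity window in ms, default `c(100, 2000)`.
#' @param pct_limits Per-condition percentile trim, default `c(0.025, 0.975)`.
#' @return The input table with added columns `rt_valid` (logical) and
#'   `rm_reason`, plus attributes `outlier_fractions` (fast/slow, as
#'   fractions of responded in-window-eligible trials) and `pct_cutoffs`
#'   (per-condition trim cutoffs in ms).
#' @export
clean_rts <- function(trials, rt_window = c(100, 2000),
                      pct_limits = c(0.025, 0.975)) {
  tr <- trials
  tr$rt_valid <- NULL
  tr$rm_reason <- NULL
  n <- nrow(tr)
  reason <- rep(NA_character_, n)
  mark <- function(idx, why) {
    new <- idx & is.na(reason)
    reason[new] <<- why
  }
  mark(tr$n_presses > 1, "double-press")
  mark(tr$trial_idx <= 3, "training")
  mark(tr$isi_ms < 1000 | tr$isi_ms > 3000, "isi")
  mark(is.na(tr$rt_ms), "miss")
  eligible <- is.na(reason)
  mark(eligible & tr$rt_ms < rt_window[1], "fast-outlier")
  mark(eligible & tr$rt_ms > rt_window[2], "slow-outlier")

  n_fast <- sum(reason == "fast-outlier", na.rm = TRUE)
  n_slow <- sum(reason == "slow-outlier", na.rm = TRUE)
  denom <- sum(eligible)

  cutoffs <- matrix(NA_real_, nrow = 2, ncol = 3,
                    dimnames = list(c("lo", "hi"), CONDITIONS))
  for (cc in CONDITIONS) {
    in_cond <- is.na(reason) & tr$condition == cc
    rts <- tr$rt_ms[in_cond]
    if (length(rts) < 2) {
      if (length(rts) > 0) {
        warning(sprintf("condition %s: fewer than 2 RTs, percentile trim skipped", cc))
      }
      next
    }
    q <- stats::quantile(rts, pct_limits, names = FALSE, type = 7)
    cutoffs[, cc] <- q
    mark(in_cond & tr$rt_ms < q[1], "pct-fast")
    mark(in_cond & tr$rt_ms > q[2], "pct-slow")
  }

  tr$rt_valid <- is.na(reason)
  tr$rm_reason <- ifelse(is.na(reason), "", reason)
  attr(tr, "outlier_fractions") <- c(
    fast = if (denom > 0) n_fast / denom else 0,
    slow = if (denom > 0) n_slow / denom else 0
  )
  attr(tr, "pct_cutoffs") <- cutoffs
  tr
}

#' Extract the rows retained by [clean_rts()]
#'
#' @param trials Output of [clean_rts()] (cleaning is applied first if the
#'   flags are absent).
#' @return The subset of rows with valid RTs.
#' @export
cleaned_rts <- function(trials) {
  if (is.null(trials$rt_valid)) trials <- clean_rts(trials)
  trials[trials$rt_valid, , drop = FALSE]
}
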