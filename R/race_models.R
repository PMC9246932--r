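## Race models, bounds, benefits and gain ------------------------------------

#' Raab's independent race model
#'
#' Probability summation under context invariance and channel independence:
#' `F_AuV(t) = F_A(t) + F_V(t) - F_A(t) * F_V(t)`.
#'
#' @param f_a,f_v Unisensory [quantile_cdf()]s on a shared grid.
#' @return A [quantile_cdf()] of the race model.
#' @export
raab_race <- function(f_a, f_v) {
  check_shared_times(f_a, f_v)
  quantile_cdf(f_a$probs + f_v$probs - f_a$probs * f_v$probs,
               f_a$eval_times_ms)
}

#' Preceding-modality-conditioned race model
#'
#' Computes an individual race model within each preceding-modality stratum
#' (A, V, AV) and averages them with equal 1/3 weights, capturing part of
#' the trial-to-trial dependency between channels. A degenerate stratum
#' (too few RTs) falls back to the unconditioned CDF for the affected
#' term(s), with a warning.
#'
#' @param cdfset A `cdf_set` from [condition_subsets()].
#' @return A [quantile_cdf()].
#' @export
conditioned_race <- function(cdfset) {
  terms <- lapply(CONDITIONS, function(m) {
    fa <- cdfset$by_prev$A[[m]]
    fv <- cdfset$by_prev$V[[m]]
    used_fallback <- FALSE
    if (is.null(fa)) { fa <- cdfset$cdf$A; used_fallback <- TRUE }
    if (is.null(fv)) { fv <- cdfset$cdf$V; used_fallback <- TRUE }
    if (is.null(fa) || is.null(fv)) return(NULL)
    if (used_fallback) {
      warning(sprintf("degenerate stratum (prev = %s): using unconditioned CDF", m))
    }
    raab_race(fa, fv)$probs
  })
  ok <- !vapply(terms, is.null, logical(1))
  if (!any(ok)) stop_invalid("all preceding-modality strata are degenerate")
  quantile_cdf(Reduce(`+`, terms[ok]) / sum(ok), cdfset$eval_times_ms)
}

#' Grice and Miller bounds on statistical facilitation
#'
#' Grice's (lower) bound is the faster unisensory CDF at each latency,
#' `max(F_A, F_V)`; Miller's (upper) bound drops the joint-probability term
#' of the race model, `min(F_A + F_V, 1)`. Violation of Miller's bound
#' implies integration beyond any race.
#'
#' @param f_a,f_v Unisensory [quantile_cdf()]s on a shared grid.
#' @return A list with `grice` and `miller` [quantile_cdf()]s.
#' @export
race_bounds <- function(f_a, f_v) {
  check_shared_times(f_a, f_v)
  list(grice = quantile_cdf(pmax(f_a$probs, f_v$probs), f_a$eval_times_ms),
       miller = quantile_cdf(pmin(f_a$probs + f_v$probs, 1), f_a$eval_times_ms))
}

#' Predicted and empirical multisensory benefits
#'
#' Benefits are areas between CDFs over the unit quantile interval (the
#' arithmetic mean of the per-quantile differences): the predicted benefit
#' is the area between the race model and Grice's bound, the empirical
#' benefit the area between the multisensory CDF and Grice's bound.
#'
#' @param f_av Multisensory [quantile_cdf()].
#' @param race Race-model [quantile_cdf()].
#' @param grice Grice's bound [quantile_cdf()].
#' @return A list: `benefit_pred`, `benefit_emp`.
#' @export
race_benefits <- function(f_av, race, grice) {
  check_shared_times(f_av, race)
  check_shared_times(f_av, grice)
  list(benefit_pred = quantile_auc(race$probs - grice$probs),
       benefit_emp = quantile_auc(f_av$probs - grice$probs))
}

#' Multisensory gain and the race-model difference function
#'
#' The difference function is `F_AV - F_race` per quantile; the gain is its
#' area over the unit quantile interval, equal to the sum of the positive
#' and negative areas, and mathematically equivalent to the difference
#' between empirical and predicted benefits.
#'
#' @param f_av Multisensory [quantile_cdf()].
#' @param race Race-model [quantile_cdf()].
#' @return A list: `gain`, `diff_fn`, `auc_pos`, `auc_neg`.
#' @export
multisensory_gain <- function(f_av, race) {
  check_shared_times(f_av, race)
  d <- f_av$probs - race$probs
  list(gain = quantile_auc(d), diff_fn = d,
       auc_pos = mean(pmax(d, 0)), auc_neg = mean(pmin(d, 0)))
}

#' Full race-model outcome for one subject
#'
#' Runs the race pipeline on a conditioned CDF set: conditioned (or plain
#' Raab) race model, Grice/Miller bounds, predicted and empirical benefits,
#' gain and difference function.
#'
#' @param cdfset A `cdf_set` from [condition_subsets()].
#' @param conditioned Use the preceding-modality-conditioned race (default)
#'   or the unconditioned Raab model.
#' @return A list of class `race_outcome` with `race_cdf`, `grice_cdf`,
#'   `miller_cdf`, `diff_fn`, `benefit_pred`, `benefit_emp`, `gain`,
#'   `auc_pos`, `auc_neg`.
#' @export
race_outcome <- function(cdfset, conditioned = TRUE) {
  f_a <- cdfset$cdf$A; f_v <- cdfset$cdf$V; f_av <- cdfset$cdf$AV
  if (is.null(f_a) || is.null(f_v) || is.null(f_av)) {
    stop_invalid("missing condition CDF")
  }
  race <- if (conditioned) conditioned_race(cdfset) else raab_race(f_a, f_v)
  b <- race_bounds(f_a, f_v)
  ben <- race_benefits(f_av, race, b$grice)
  g <- multisensory_gain(f_av, race)
  structure(c(list(race_cdf = race, grice_cdf = b$grice,
                   miller_cdf = b$miller), ben, g),
            class = "race_outcome")
}

#' Test race-model violation across subjects at every quantile
#'
#' One-sample permutation test (sign flipping) of the per-subject
#' difference functions at each quantile, with max-statistic correction
#' across quantiles for family-wise error control. Right-tailed by default:
#' positive deviations indicate multisensory facilitation.
#'
#' @param diff_fns Matrix of difference functions (subjects x quantiles).
#' @param tail `"right"`, `"left"` or `"both"`.
#' @param n_perm Number of permutations.
#' @param alpha Significance level for flagging quantiles.
#' @param seed Optional seed.
#' @return A data frame per quantile: `statistic`, `p_perm`, `significant`.
#' @export
race_violation_test <- function(diff_fns, tail = "right", n_perm = 10000L,
                                alpha = 0.05, seed = NULL) {
  diff_fns <- as.matrix(diff_fns)
  if (nrow(diff_fns) < 2) stop_invalid("need at least 2 subjects")
  res <- permutation_test(diff_fns, tail = tail, n_perm = n_perm,
                          correction = "tmax", seed = seed)
  data.frame(quantile = seq_len(ncol(diff_fns)),
             statistic = res$statistic, p_perm = res$p,
             significant = res$p < alpha)
}
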