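## Competition (bias) models and the facilitation-competition mixture -------

#' Age-group assignment
#'
#' Cross-sectional bins: children 6-9, pre-adolescents 10-12, adolescents
#' 13-17, adults 18-40 (inclusive integer ages at test).
#'
#' @param age Numeric ages in years.
#' @return A factor with levels `6-9`, `10-12`, `13-17`, `18-40`.
#' @export
age_group <- function(age) {
  cut(floor(age), breaks = c(6, 10, 13, 18, 41), right = FALSE,
      labels = c("6-9", "10-12", "13-17", "18-40"))
}

#' Bias-model CDF for competitive multisensory processing
#'
#' Family "model1" is biased towards one fixed modality `b`: the average
#' over preceding-modality strata of that modality's conditioned CDF,
#' `F_1b = (1/3) sum_m F_b(m, .)`. Family "model2" is biased towards the
#' preceding modality, falling back to `b` when the previous trial was
#' multisensory: `F_2b = (1/3) (F_A(A,.) + F_V(V,.) + F_b(AV,.))`.
#' Degenerate strata fall back to the relevant unconditioned CDF with a
#' warning.
#'
#' @param cdfset A `cdf_set` from [condition_subsets()].
#' @param family `"model1"` or `"model2"`.
#' @param bias Biased modality, `"A"` or `"V"`.
#' @return A [quantile_cdf()].
#' @export
bias_model_cdf <- function(cdfset, family = c("model1", "model2"),
                           bias = c("A", "V")) {
  family <- match.arg(family)
  bias <- match.arg(bias)
  get_stratum <- function(cc, m) {
    f <- cdfset$by_prev[[cc]][[m]]
    if (is.null(f)) {
      f <- cdfset$cdf[[cc]]
      if (is.null(f)) stop_invalid("missing stratum %s | prev %s and no fallback", cc, m)
      warning(sprintf("degenerate stratum (%s | prev %s): using unconditioned CDF",
                      cc, m))
    }
    f$probs
  }
  probs <- if (family == "model1") {
    (get_stratum(bias, "A") + get_stratum(bias, "V") +
       get_stratum(bias, "AV")) / 3
  } else {
    (get_stratum("A", "A") + get_stratum("V", "V") +
       get_stratum(bias, "AV")) / 3
  }
  quantile_cdf(probs, cdfset$eval_times_ms)
}

#' Mixture benefit of facilitative and competitive processing
#'
#' With probability `p` the response is triggered competitively (bias
#' model) and with probability `1 - p` facilitatively (race model); the
#' predicted benefit is the area between the mixture CDF and Grice's
#' bound: `AUC[(1-p) race + p bias - grice]`. `p = 0` recovers the race
#' model's predicted benefit; the value is affine in `p`.
#'
#' @param race,bias,grice [quantile_cdf()]s on a shared grid.
#' @param p Mixture probability in `[0, 1]`.
#' @return The mixture benefit (scalar AUC).
#' @export
mixture_benefit <- function(race, bias, grice, p) {
  if (p < 0 || p > 1) stop_invalid("p must lie in [0, 1]")
  check_shared_times(race, bias)
  check_shared_times(race, grice)
  quantile_auc((1 - p) * race$probs + p * bias$probs - grice$probs)
}

#' Evaluate facilitation/competition models against empirical benefits
#'
#' For each model specification (race `p = 0`, and each bias family/modality
#' at each mixture probability), computes the Pearson correlation across
#' subjects, within each age group, between the model's predicted benefit
#' and the empirical benefit; significance by a two-tailed permutation test
#' of subject pairings.
#'
#' @param results Per-subject data frame with `benefit_emp`, an `age_grp`
#'   column, and one `benefit_<model>` column per evaluated model (as built
#'   by [cohort_model_benefits()]).
#' @param p_grid Mixture probabilities for the bias models.
#' @param n_perm Permutations for the correlation test (0 skips testing).
#' @param min_group Minimum subjects per group (smaller groups are omitted).
#' @param seed Optional seed.
#' @return A long data frame: `group`, `model`, `p_mix`, `r`, `p_perm`, `n`.
#' @export
evaluate_models <- function(results, p_grid = c(0, 0.25, 0.5, 0.75, 1),
                            n_perm = 2000L, min_group = 3L, seed = NULL) {
  specs <- model_spec_grid(p_grid)
  out <- list()
  for (g in levels(results$age_grp)) {
    sub <- results[results$age_grp == g, , drop = FALSE]
    if (nrow(sub) < min_group) next
    for (i in seq_len(nrow(specs))) {
      col <- specs$column[i]
      if (!col %in% names(sub)) next
      x <- sub[[col]]; y <- sub$benefit_emp
      if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
        warning(sprintf("constant benefits in group %s for %s: r omitted", g, col))
        next
      }
      r <- stats::cor(x, y)
      p <- if (n_perm > 0) {
        cor_permutation_p(x, y, n_perm = n_perm,
                          seed = if (is.null(seed)) NULL
                                 else stage_seed(seed, paste(g, col)))
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        group = g, model = specs$model[i], p_mix = specs$p_mix[i],
        r = r, p_perm = p, n = nrow(sub))
    }
  }
  do.call(rbind, out)
}

## The evaluated model grid: the race model plus each bias model at each
## nonzero mixture probability.
model_spec_grid <- function(p_grid) {
  grid <- expand.grid(model = c("model1A", "model1V", "model2A", "model2V"),
                      p_mix = setdiff(p_grid, 0), stringsAsFactors = FALSE)
  grid <- rbind(data.frame(model = "race", p_mix = 0), grid)
  grid$column <- ifelse(grid$model == "race", "benefit_race",
                        sprintf("benefit_%s_p%03d", grid$model,
                                round(grid$p_mix * 100)))
  grid
}

#' Per-subject model benefits for a cohort
#'
#' Runs the subject-level CDF pipeline and computes, for every subject:
#' empirical benefit, race-model (mixture `p = 0`) benefit, and mixture
#' benefits for each bias model at each requested probability.
#'
#' @param trials Cohort trial table.
#' @param subjects Subject table (`subject_id`, `age_years`).
#' @param p_grid Mixture probabilities.
#' @param min_n Minimum RTs per stratum.
#' @return A data frame, one row per analysable subject.
#' @export
cohort_model_benefits <- function(trials, subjects,
                                  p_grid = c(0, 0.25, 0.5, 0.75, 1),
                                  min_n = 5L) {
  specs <- expand.grid(family = c("model1", "model2"), bias = c("A", "V"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    id <- subjects$subject_id[i]
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    cs <- try(suppressWarnings(condition_subsets(tr, min_n = min_n)),
              silent = TRUE)
    if (inherits(cs, "try-error")) return(NULL)
    ro <- try(suppressWarnings(race_outcome(cs)), silent = TRUE)
    if (inherits(ro, "try-error")) return(NULL)
    row <- data.frame(subject_id = id, age_years = subjects$age_years[i],
                      benefit_emp = ro$benefit_emp,
                      benefit_race = ro$benefit_pred, gain = ro$gain)
    for (j in seq_len(nrow(specs))) {
      bm <- suppressWarnings(
        bias_model_cdf(cs, specs$family[j], specs$bias[j]))
      for (p in setdiff(p_grid, 0)) {
        col <- sprintf("benefit_%s%s_p%03d", specs$family[j], specs$bias[j],
                       round(p * 100))
        row[[col]] <- mixture_benefit(ro$race_cdf, bm, ro$grice_cdf, p)
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out$age_grp <- age_group(out$age_years)
  out
}

#' Sensory dominance profiles
#'
#' Correlation between empirical benefits and the two fixed-bias models
#' (auditory vs visual) at pure competition (`p = 1`), per age group; a
#' higher auditory-model correlation indicates auditory dominance.
#'
#' @inheritParams evaluate_models
#' @return A data frame restricted to model1A/model1V at `p = 1`.
#' @export
sensory_dominance <- function(results, n_perm = 2000L, min_group = 3L,
                              seed = NULL) {
  ev <- evaluate_models(results, p_grid = c(0, 1), n_perm = n_perm,
                        min_group = min_group, seed = seed)
  ev[ev$model %in% c("model1A", "model1V") & ev$p_mix == 1, , drop = FALSE]
}
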