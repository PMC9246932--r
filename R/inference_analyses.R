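## Cohort-level analyses: similarity matrices, participant matching,
## moving-window comparisons, mixed-effects RT model, ANCOVA, mediation ------

#' Age-binned similarity matrices between race-model difference functions
#'
#' Computes the pairwise root-mean-square error and, after a rank-based
#' inverse normal transform of the pooled values, the Pearson correlation
#' between every pair of subjects' quantile difference functions, then
#' averages within age-bin pairs. When `groups` is given, rows are the
#' first group and columns the second (e.g. ASD rows vs NT columns);
#' otherwise all subjects appear on both axes. The extremal trace is the
#' per-row argmin (RMSE) / argmax (correlation) bin: rows whose best match
#' sits below their own age bin indicate a developmental lag.
#'
#' @param diff_fns Matrix (subjects x quantiles) of difference functions.
#' @param ages Ages in years, one per subject.
#' @param groups Optional 2-level factor/character; the first level in
#'   `row_group`/`col_group` order defines the rows.
#' @param bin_edges Age bin edges (default 6 to 21 by 2.5 years).
#' @param row_group,col_group Group labels for rows/columns when `groups`
#'   is given.
#' @return A list: `rmse`, `corr` (bin x bin matrices), `trace_rmse`,
#'   `trace_corr` (best column bin per row, NA for empty rows),
#'   `bin_centers`, `row_n`, `col_n`.
#' @export
similarity_matrices <- function(diff_fns, ages, groups = NULL,
                                bin_edges = seq(6, 21, by = 2.5),
                                row_group = NULL, col_group = NULL) {
  diff_fns <- as.matrix(diff_fns)
  stopifnot(nrow(diff_fns) == length(ages))
  keep <- ages >= bin_edges[1] & ages <= bin_edges[length(bin_edges)]
  diff_fns <- diff_fns[keep, , drop = FALSE]
  ages <- ages[keep]
  if (!is.null(groups)) groups <- groups[keep]
  nb <- length(bin_edges) - 1
  bin <- findInterval(ages, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  if (is.null(groups)) {
    rows <- cols <- seq_along(ages)
  } else {
    lev <- unique(as.character(groups))
    rg <- row_group %||% lev[1]
    cg <- col_group %||% setdiff(lev, rg)[1]
    rows <- which(groups == rg)
    cols <- which(groups == cg)
  }
  ## pooled RIN transform so ranks are comparable across subjects
  rin <- matrix(rin_transform(as.vector(diff_fns)), nrow = nrow(diff_fns))

  q <- ncol(diff_fns)
  pr_rmse <- matrix(NA_real_, length(rows), length(cols))
  pr_corr <- matrix(NA_real_, length(rows), length(cols))
  for (i in seq_along(rows)) {
    di <- diff_fns[rows[i], ]
    ri <- rin[rows[i], ]
    pr_rmse[i, ] <- sqrt(rowMeans(sweep(diff_fns[cols, , drop = FALSE], 2, di)^2))
    rc <- rin[cols, , drop = FALSE]
    pr_corr[i, ] <- suppressWarnings(
      as.vector(stats::cor(ri, t(rc))))
  }

  rmse <- matrix(NA_real_, nb, nb)
  corr <- matrix(NA_real_, nb, nb)
  rb <- bin[rows]; cb <- bin[cols]
  for (b1 in seq_len(nb)) {
    for (b2 in seq_len(nb)) {
      sel_r <- rb == b1; sel_c <- cb == b2
      if (any(sel_r) && any(sel_c)) {
        rmse[b1, b2] <- mean(pr_rmse[sel_r, sel_c, drop = FALSE], na.rm = TRUE)
        corr[b1, b2] <- mean(pr_corr[sel_r, sel_c, drop = FALSE], na.rm = TRUE)
      }
    }
  }
  trace_of <- function(m, pick) {
    vapply(seq_len(nb), function(b) {
      row <- m[b, ]
      if (all(is.na(row))) return(NA_integer_)
      as.integer(pick(row))
    }, integer(1))
  }
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  list(rmse = rmse, corr = corr,
       trace_rmse = trace_of(rmse, which.min),
       trace_corr = trace_of(corr, which.max),
       bin_centers = centers,
       row_n = tabulate(rb, nb), col_n = tabulate(cb, nb))
}

#' Match control participants to cases
#'
#' Sex is matched exactly; within sex, the nearest available control on the
#' standardised (age, performance IQ) Euclidean distance is selected,
#' sampling without replacement, processing cases in input order. Ties are
#' broken by the lexicographically lower control subject id, so matching is
#' deterministic.
#'
#' @param cases,control_pool Data frames with `subject_id`, `sex`,
#'   `age_years`, `piq`.
#' @return A data frame, one row per case: `case_id`, `control_id` (NA when
#'   no same-sex control remains), `distance`, `matched`.
#' @export
match_participants <- function(cases, control_pool) {
  sd_age <- stats::sd(c(cases$age_years, control_pool$age_years))
  sd_piq <- stats::sd(c(cases$piq, control_pool$piq))
  if (!is.finite(sd_age) || sd_age == 0) sd_age <- 1
  if (!is.finite(sd_piq) || sd_piq == 0) sd_piq <- 1
  avail <- rep(TRUE, nrow(control_pool))
  out <- lapply(seq_len(nrow(cases)), function(i) {
    cand <- which(avail & control_pool$sex == cases$sex[i])
    if (length(cand) == 0) {
      return(data.frame(case_id = cases$subject_id[i],
                        control_id = NA_character_,
                        distance = NA_real_, matched = FALSE))
    }
    d <- sqrt(((control_pool$age_years[cand] - cases$age_years[i]) / sd_age)^2 +
                ((control_pool$piq[cand] - cases$piq[i]) / sd_piq)^2)
    ord <- order(d, control_pool$subject_id[cand])
    pick <- cand[ord[1]]
    avail[pick] <<- FALSE
    data.frame(case_id = cases$subject_id[i],
               control_id = control_pool$subject_id[pick],
               distance = d[ord[1]], matched = TRUE)
  })
  do.call(rbind, out)
}

#' Moving-window group comparison of a per-subject metric
#'
#' Slides an age window across the cohort; within each window, controls are
#' re-matched to cases (when demographics are supplied), group means and
#' BCa confidence intervals are computed, groups are compared with a
#' two-tailed permutation test (FDR-corrected across windows) and a JZS
#' Bayes factor quantifies evidence for the absence of a difference.
#' Windows with fewer than `min_n` subjects per group are omitted.
#'
#' @param metric Per-subject metric values.
#' @param ages Ages in years.
#' @param groups 2-level grouping (first level = cases for matching).
#' @param demographics Optional data frame (`subject_id`, `sex`, `piq`,
#'   aligned with `metric`) enabling within-window matching.
#' @param window Window width in years (default 7).
#' @param step Window increment in years (default 1).
#' @param centers Window centres; default spans the age range.
#' @param n_perm,n_boot Permutations / bootstrap resamples.
#' @param min_n Minimum per-group subjects per window.
#' @param seed Optional seed.
#' @return A data frame per retained window: centre, group means, CI
#'   bounds, `p_perm`, `p_fdr`, `significant`, `bf01`, group sizes.
#' @export
moving_window_compare <- function(metric, ages, groups, demographics = NULL,
                                  window = 7, step = 1, centers = NULL,
                                  n_perm = 2000L, n_boot = 1000L,
                                  min_n = 3L, seed = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  if (is.null(centers)) {
    centers <- seq(floor(min(ages)), ceiling(max(ages)), by = step)
  }
  rows <- list()
  for (ct in centers) {
    inw <- which(ages >= ct - window / 2 & ages <= ct + window / 2)
    i1 <- inw[groups[inw] == lev[1]]
    i2 <- inw[groups[inw] == lev[2]]
    if (!is.null(demographics) && length(i1) >= min_n && length(i2) >= min_n) {
      demo_of <- function(idx) data.frame(
        subject_id = demographics$subject_id[idx],
        sex = demographics$sex[idx], piq = demographics$piq[idx],
        age_years = ages[idx], stringsAsFactors = FALSE)
      m <- match_participants(demo_of(i1), demo_of(i2))
      keep <- m$matched
      i1 <- i1[keep]
      i2 <- i2[match(m$control_id[keep], demographics$subject_id[i2])]
    }
    if (length(i1) < min_n || length(i2) < min_n) next
    x1 <- metric[i1]; x2 <- metric[i2]
    sseed <- if (is.null(seed)) NULL else stage_seed(seed, paste0("win_", ct))
    pt <- permutation_test(x1, x2, tail = "both", n_perm = n_perm,
                           correction = "none", seed = sseed)
    ci1 <- bootstrap_ci(x1, mean, n_boot = n_boot,
                        seed = if (is.null(sseed)) NULL else sseed + 1L)
    ci2 <- bootstrap_ci(x2, mean, n_boot = n_boot,
                        seed = if (is.null(sseed)) NULL else sseed + 2L)
    rows[[length(rows) + 1]] <- data.frame(
      center = ct, n1 = length(x1), n2 = length(x2),
      mean1 = mean(x1), mean2 = mean(x2),
      ci1_lo = ci1$ci[1], ci1_hi = ci1$ci[2],
      ci2_lo = ci2$ci[1], ci2_hi = ci2$ci[2],
      statistic = pt$statistic, p_perm = pt$p,
      bf01 = bayes_factor_t(pt$statistic, length(x1), length(x2)))
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_perm, "BH")
  out$significant <- out$p_fdr < 0.05
  out
}

#' Mixed-effects model of single-trial response times
#'
#' Fixed effects: contrast-coded group (NT = -0.5, ASD = +0.5), continuous
#' age, and condition with the multisensory condition as reference. Random
#' effects: by-subject intercepts with condition slopes, ISI (discretised
#' into deciles, since a continuous variable cannot index a grouping
#' factor) intercepts, and preceding-modality intercepts with condition
#' slopes. Fitted by maximum likelihood; p-values via Satterthwaite
#' approximation.
#'
#' @param trials Cleaned, annotated trial table (only valid RTs are used).
#' @param subjects Subject table with `group` and `age_years`.
#' @param isi_bins Number of ISI bins for the random factor (default 10).
#' @return A list: `coefficients` (data frame), `model`, `singular`.
#' @export
fit_rt_lmm <- function(trials, subjects, isi_bins = 10L) {
  if (is.null(trials$rt_valid)) {
    trials <- do.call(rbind, lapply(split(trials, trials$subject_id),
                                    clean_rts))
  }
  if (is.null(trials$prev_modality)) {
    trials <- do.call(rbind, lapply(split(trials, trials$subject_id),
                                    annotate_sequence))
  }
  d <- trials[trials$rt_valid & !is.na(trials$prev_modality), , drop = FALSE]
  d <- merge(d, subjects[, c("subject_id", "group", "age_years")],
             by = "subject_id")
  d$condition <- factor(d$condition, levels = c("AV", "A", "V"))
  d$group_c <- ifelse(d$group == "ASD", 0.5, -0.5)
  d$isi_bin <- cut(d$isi_ms, stats::quantile(d$isi_ms, seq(0, 1, length.out = isi_bins + 1)),
                   include.lowest = TRUE)
  d$prev_modality <- factor(d$prev_modality, levels = CONDITIONS)
  fit <- lmerTest::lmer(
    rt_ms ~ group_c + age_years + condition +
      (1 + condition | subject_id) + (1 | isi_bin) +
      (1 + condition | prev_modality),
    data = d, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  co$term <- rownames(co)
  rownames(co) <- NULL
  list(coefficients = co[, c("term", "estimate", "se", "df", "t", "p")],
       model = fit, singular = lme4::isSingular(fit))
}

#' ANCOVA of empirical on predicted benefits with age group partialled out
#'
#' Regresses empirical benefits on predicted benefits with age group as a
#' partialled-out categorical factor; the interaction term tests whether
#' the predicted-empirical slope depends on age group. Per-group Pearson
#' correlations are returned alongside.
#'
#' @param benefit_pred,benefit_emp Per-subject benefit AUCs.
#' @param age_grp Age-group factor.
#' @return A list: `f_pred`, `p_pred`, `partial_r2_pred`, `f_interaction`,
#'   `p_interaction`, `partial_r2_interaction`, `group_r` (named vector),
#'   `rank_deficient`.
#' @export
ancova_benefit_correlation <- function(benefit_pred, benefit_emp, age_grp) {
  age_grp <- droplevels(factor(age_grp))
  d <- data.frame(pred = benefit_pred, emp = benefit_emp, grp = age_grp)
  if (nlevels(age_grp) < 2) {
    fit <- stats::lm(emp ~ pred, data = d)
    an <- stats::anova(fit)
    gr <- stats::setNames(stats::cor(d$pred, d$emp), levels(age_grp))
    return(list(f_pred = an["pred", "F value"], p_pred = an["pred", "Pr(>F)"],
                partial_r2_pred = summary(fit)$r.squared,
                f_interaction = NA_real_, p_interaction = NA_real_,
                partial_r2_interaction = NA_real_,
                group_r = gr, rank_deficient = FALSE))
  }
  m0 <- stats::lm(emp ~ grp, data = d)
  m1 <- stats::lm(emp ~ grp + pred, data = d)
  m2 <- stats::lm(emp ~ grp * pred, data = d)
  rank_deficient <- any(is.na(stats::coef(m2)))
  a01 <- stats::anova(m0, m1)
  a12 <- stats::anova(m1, m2)
  rss <- function(m) sum(stats::resid(m)^2)
  group_r <- vapply(split(d, d$grp), function(s) {
    if (nrow(s) < 3 || stats::sd(s$pred) == 0 || stats::sd(s$emp) == 0) {
      return(NA_real_)
    }
    stats::cor(s$pred, s$emp)
  }, numeric(1))
  list(f_pred = a01$F[2], p_pred = a01$`Pr(>F)`[2],
       partial_r2_pred = (rss(m0) - rss(m1)) / rss(m0),
       f_interaction = a12$F[2], p_interaction = a12$`Pr(>F)`[2],
       partial_r2_interaction = (rss(m1) - rss(m2)) / rss(m1),
       group_r = group_r, rank_deficient = rank_deficient)
}

#' Three-variable mediation analysis
#'
#' Tests whether the modality switch effect mediates the relationship
#' between age and multisensory gain. All three variables are z-scored.
#' Three regressions define the paths: total effect `c` (gain ~ age), path
#' `a` (mse ~ age), and paths `b` and `c'` (gain ~ age + mse). The mediated
#' (indirect) effect is `a * b`; its SE and p come from a BCa-adjusted
#' bootstrap over subjects. OLS algebra guarantees `a * b + c' = c`.
#'
#' @param age Causal variable (years).
#' @param mse Mediating variable (switch effect, averaged over the two
#'   unisensory directions).
#' @param gain Outcome variable (multisensory gain).
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed.
#' @return A list of class `mediation_result`: paths `a`, `b`, `c`,
#'   `c_prime`, `ab` each with `estimate`, `se`, `ci`, `p`; plus
#'   `mediation` (`"none"`, `"partial"` or `"full"`).
#' @export
mediation_analysis <- function(age, mse, gain, n_boot = 10000L, seed = NULL) {
  n <- length(age)
  if (n < 10) stop_invalid("need at least 10 complete triples")
  if (stats::sd(age) == 0 || stats::sd(mse) == 0 || stats::sd(gain) == 0) {
    stop_invalid("degenerate variance in a mediation variable")
  }
  z <- function(x) (x - mean(x)) / stats::sd(x)
  one <- rep(1, n)
  paths_of <- function(age, mse, gain) {
    a <- stats::.lm.fit(cbind(one[seq_along(age)], age), mse)$coefficients[2]
    cc <- stats::.lm.fit(cbind(one[seq_along(age)], age), gain)$coefficients[2]
    m2 <- stats::.lm.fit(cbind(one[seq_along(age)], age, mse), gain)$coefficients
    c(a = a, b = m2[3], c = cc, c_prime = m2[2], ab = a * m2[3])
  }
  az <- z(age); mz <- z(mse); gz <- z(gain)
  est <- paths_of(az, mz, gz)
  with_seed(seed, {
    boot <- t(vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      paths_of(az[i], mz[i], gz[i])
    }, numeric(5)))
    jack <- t(vapply(seq_len(n), function(i) {
      paths_of(az[-i], mz[-i], gz[-i])
    }, numeric(5)))
    res <- lapply(names(est), function(k) {
      ci <- bca_interval(est[[k]], boot[, k], jack[, k])
      p <- 2 * min(mean(boot[, k] <= 0), mean(boot[, k] >= 0))
      list(estimate = est[[k]], se = stats::sd(boot[, k]),
           ci = ci, p = max(p, 1 / n_boot))
    })
    names(res) <- names(est)
    med <- if (res$ab$p >= 0.05) "none"
           else if (res$c_prime$p < 0.05) "partial" else "full"
    structure(c(res, list(mediation = med)), class = "mediation_result")
  })
}
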