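#!/usr/bin/env Rscript
# Group and age inference: mixed-effects model of single-trial RTs,
# ANCOVA of empirical on predicted benefits with age group partialled out,
# similarity matrices between difference functions, moving-window group
# comparison of multisensory gain (with matching, FDR and Bayes factors),
# partial correlations between switch effects and gain, and the mediation
# analysis (age -> switch effect -> gain).

suppressPackageStartupMessages(library(multirace))
seed <- 20260926

subjects <- read_subject_table("results/data/subjects.csv")
trials <- read_trial_table("results/data/trials.csv")
excl <- read.csv("results/exclusions.csv")
keep <- excl$subject_id[!excl$excluded]
subjects <- subjects[subjects$subject_id %in% keep, ]
trials <- trials[trials$subject_id %in% keep, ]
race <- read.csv("results/race_results.csv")
mse <- read.csv("results/mse_results.csv")

d <- merge(race, subjects, by = "subject_id")
d <- merge(d, unique(mse[, c("subject_id", "mse_uni")]), by = "subject_id")
d$age_grp <- age_group(d$age_years)

lmm <- fit_rt_lmm(trials, subjects)
write_table_csv(lmm$coefficients, "results/rt_lmm.csv")
cat("single-trial RT mixed model (ms):\n")
print(lmm$coefficients[, c("term", "estimate", "se", "p")], row.names = FALSE)

anc <- ancova_benefit_correlation(d$benefit_pred, d$benefit_emp, d$age_grp)
cat(sprintf("benefit ANCOVA: F_pred = %.2f (p = %.2g), interaction F = %.2f (p = %.2g)\n",
            anc$f_pred, anc$p_pred, anc$f_interaction, anc$p_interaction))

dmat <- as.matrix(d[, grep("^diff_", names(d))])
sm <- similarity_matrices(dmat, d$age_years, groups = d$group,
                          row_group = "ASD", col_group = "NT")
write_table_csv(as.data.frame(sm$rmse), "results/similarity_rmse.csv")
cat(sprintf("similarity trace (best NT bin per ASD bin): %s\n",
            paste(sm$trace_rmse, collapse = " ")))

mw <- moving_window_compare(d$gain, d$age_years, d$group,
                            demographics = d, centers = 6:26,
                            n_perm = 2000, n_boot = 1000,
                            seed = stage_seed(seed, "window"))
write_table_csv(mw, "results/gain_moving_window.csv")
cat(sprintf("moving-window gain comparison: %d/%d windows significant (FDR)\n",
            sum(mw$significant), nrow(mw)))

pc <- partial_correlation(d$mse_uni, d$gain, d$age_years, n_perm = 2000,
                          seed = stage_seed(seed, "partial"))
cat(sprintf("partial r(switch effect, gain | age) = %.3f (p = %.3g)\n",
            pc$r, pc$p_perm))

med <- mediation_analysis(d$age_years, d$mse_uni, d$gain, n_boot = 5000,
                          seed = stage_seed(seed, "mediation"))
write_table_csv(data.frame(
  path = c("a", "b", "c", "c_prime", "ab"),
  estimate = c(med$a$estimate, med$b$estimate, med$c$estimate,
               med$c_prime$estimate, med$ab$estimate),
  se = c(med$a$se, med$b$se, med$c$se, med$c_prime$se, med$ab$se),
  p = c(med$a$p, med$b$p, med$c$p, med$c_prime$p, med$ab$p)),
  "results/mediation.csv")
cat(sprintf("mediation of the age->gain path by the switch effect: %s (ab = %.3f, p = %.3g)\n",
            med$mediation, med$ab$estimate, med$ab$p))
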