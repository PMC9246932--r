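#!/usr/bin/env Rscript
# Race-model analysis: per subject, the preceding-modality-conditioned race
# CDF, Grice/Miller bounds, predicted and empirical benefits, multisensory
# gain and the 20-quantile difference function; then right-tailed
# permutation tests (t_max corrected) of race-model violation per age group.

suppressPackageStartupMessages(library(multirace))
seed <- 20260926

subjects <- read_subject_table("results/data/subjects.csv")
trials <- read_trial_table("results/data/trials.csv")
excl <- read.csv("results/exclusions.csv")
keep <- excl$subject_id[!excl$excluded]
subjects <- subjects[subjects$subject_id %in% keep, ]
trials <- trials[trials$subject_id %in% keep, ]

race <- cohort_race_table(trials, subjects)
write_table_csv(race, "results/race_results.csv")

d <- merge(race, subjects, by = "subject_id")
d$age_grp <- age_group(d$age_years)
cat(sprintf("analysed %d subjects\n", nrow(d)))
cat(sprintf("mean benefit: predicted %.4f, empirical %.4f, gain %.4f\n",
            mean(d$benefit_pred), mean(d$benefit_emp), mean(d$gain)))

viol <- do.call(rbind, lapply(split(d, list(d$group, d$age_grp)), function(s) {
  if (nrow(s) < 3) return(NULL)
  dm <- as.matrix(s[, grep("^diff_", names(s))])
  v <- race_violation_test(dm, n_perm = 2000,
                           seed = stage_seed(seed, paste(s$group[1], s$age_grp[1])))
  data.frame(group = s$group[1], age_grp = as.character(s$age_grp[1]),
             n = nrow(s), quantile = v$quantile, statistic = v$statistic,
             p = v$p_perm, significant = v$significant)
}))
write_table_csv(viol, "results/race_violation.csv")

sig <- aggregate(significant ~ group + age_grp, viol, sum)
cat("quantiles with significant facilitation (t_max corrected):\n")
print(sig, row.names = FALSE)
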