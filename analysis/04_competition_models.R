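#!/usr/bin/env Rscript
# Competition-model analysis: mixture benefits for the four bias models
# (fixed auditory/visual bias; preceding-modality bias with an A or V
# fallback) across the facilitation-competition probability grid, evaluated
# within age groups by their correlation with empirical benefits; plus the
# pure-bias (p = 1) sensory-dominance profiles.

suppressPackageStartupMessages(library(multirace))
seed <- 20260926

subjects <- read_subject_table("results/data/subjects.csv")
trials <- read_trial_table("results/data/trials.csv")
excl <- read.csv("results/exclusions.csv")
keep <- excl$subject_id[!excl$excluded]
subjects <- subjects[subjects$subject_id %in% keep, ]
trials <- trials[trials$subject_id %in% keep, ]

ben <- cohort_model_benefits(trials, subjects)
write_table_csv(ben, "results/model_benefits.csv")

grid <- evaluate_models(ben, n_perm = 2000, seed = stage_seed(seed, "grid"))
write_table_csv(grid, "results/model_grid.csv")

for (g in unique(grid$group)) {
  s <- grid[grid$group == g, ]
  best <- s[which.max(s$r), ]
  cat(sprintf("age group %s (n = %d): best model %s at p = %.2f (r = %.3f)\n",
              g, best$n, best$model, best$p_mix, best$r))
}

dom <- sensory_dominance(ben, n_perm = 2000, seed = stage_seed(seed, "dom"))
write_table_csv(dom, "results/sensory_dominance.csv")
cat("pure-bias dominance profile (r by age group):\n")
print(dom[, c("group", "model", "r", "p_perm")], row.names = FALSE)
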