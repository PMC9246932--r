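#!/usr/bin/env Rscript
# Channel-dependency modelling: LATER (reciprocal-normal) fits to the
# unisensory RTs, then maximum-likelihood estimation of the channel
# correlation rho and noise inflation eta of the context-variant race
# model from the multisensory RTs; age trends of both parameters and the
# switch/repeat frequency profile across RT quantiles.

suppressPackageStartupMessages(library(multirace))

subjects <- read_subject_table("results/data/subjects.csv")
trials <- read_trial_table("results/data/trials.csv")
excl <- read.csv("results/exclusions.csv")
keep <- excl$subject_id[!excl$excluded]
subjects <- subjects[subjects$subject_id %in% keep, ]
trials <- trials[trials$subject_id %in% keep, ]

fits <- cohort_context_fits(trials, subjects)
write_table_csv(fits, "results/context_fits.csv")
d <- merge(fits, subjects, by = "subject_id")

cat(sprintf("fitted %d subjects (%.0f%% converged)\n", nrow(d),
            100 * mean(d$converged)))
cat(sprintf("median rho = %.3f, median eta = %.3f\n",
            median(d$rho), median(d$eta)))
for (p in c("rho", "eta")) {
  m <- lm(reformulate("age_years", p), d)
  cat(sprintf("%s ~ age: beta = %.4f (p = %.2g)\n", p, coef(m)[2],
              summary(m)$coefficients[2, 4]))
}

# switch trials crowd the slow quantiles (negative channel dependency)
prof <- Reduce(`+`, lapply(subjects$subject_id, function(id) {
  p <- switch_repeat_frequency_profile(trials[trials$subject_id == id, ])
  cbind(p$n_switch, p$n_repeat)
}))
frac <- prof[, 1] / rowSums(prof)
write_table_csv(data.frame(quantile = seq_along(frac),
                           switch_fraction = frac),
                "results/switch_frequency_profile.csv")
cat(sprintf("switch fraction: fastest half %.3f, slowest half %.3f\n",
            mean(frac[1:10]), mean(frac[11:20])))
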