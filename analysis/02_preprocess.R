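#!/usr/bin/env Rscript
# Score detection accuracy (F1), apply the participant exclusion criteria,
# and summarise the RT cleaning (training trials, window and percentile
# outliers). Writes the exclusion audit and the per-subject accuracy table.

suppressPackageStartupMessages(library(multirace))

subjects <- read_subject_table("results/data/subjects.csv")
trials <- read_trial_table("results/data/trials.csv")

acc <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
  tr <- trials[trials$subject_id == subjects$subject_id[i], ]
  s <- score_accuracy(tr, subjects$fa_count[i])
  data.frame(subject_id = subjects$subject_id[i], f1 = s$f1,
             precision = s$precision, recall = s$recall,
             miss_rate = s$miss_rate, fa_rate = s$fa_rate)
}))
write_table_csv(acc, "results/accuracy.csv")

excl <- apply_exclusions(subjects, trials)
write_table_csv(excl, "results/exclusions.csv")

frac <- vapply(subjects$subject_id, function(id) {
  cl <- clean_rts(trials[trials$subject_id == id, ])
  mean(cl$rt_valid)
}, numeric(1))

cat(sprintf("mean F1 = %.3f (range %.3f-%.3f)\n",
            mean(acc$f1), min(acc$f1), max(acc$f1)))
cat(sprintf("excluded %d of %d subjects: %s\n", sum(excl$excluded),
            nrow(excl),
            paste(unique(unlist(strsplit(excl$reasons[excl$excluded], ","))),
                  collapse = ", ")))
cat(sprintf("mean fraction of trials retained after cleaning: %.3f\n",
            mean(frac)))
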