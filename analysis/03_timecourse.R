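#!/usr/bin/env Rscript
# Fixation-proportion and log-ratio time courses: expand fixations to 1-ms
# samples, aggregate into 100-ms bins over (-2000, +1000) ms around the
# critical noun, compute condition means with within-subject adjusted 95%
# CIs, and the per-trial female-vs-male log-ratio preference series.

suppressMessages({library(gazecluster); library(data.table)})

fixations <- read_fixation_report("results/fixations.tsv")
trials <- fread("results/trials.tsv", sep = "\t")
bins <- bin_experiment(fixations, trials)
lr <- log_ratio_series(bins)

tc <- condition_timecourse(bins)
lrtc <- logratio_timecourse(lr)
fwrite(bins, "results/bins.tsv", sep = "\t")
fwrite(lr, "results/logratio.tsv", sep = "\t")
fwrite(tc, "results/timecourse.tsv", sep = "\t")
fwrite(lrtc, "results/logratio_timecourse.tsv", sep = "\t")

cat("bins per trial:", uniqueN(bins$bin), "\n")
cat("\nmean log-ratio in the last pre-noun second (positive = female",
    "character preference):\n")
print(lrtc[bin_start >= -1000 & bin_start < 0,
           .(mean_logratio = round(mean(mean), 3)),
           by = .(action_stereotype, occupation_stereotype)])
cat("wrote results/bins.tsv, logratio.tsv, timecourse.tsv,",
    "logratio_timecourse.tsv\n")
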