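#!/usr/bin/env Rscript
# Attitude stage: score the NGRO and ASI questionnaires, estimate
# Cronbach's alpha, z-standardize the scores, aggregate the log-ratio per
# participant over each pre-noun significant cluster of interest (male-
# preference clusters multiplied by -1), and fit the cluster-level OLS
# regression with the cluster factor rotated through each reference level.

suppressMessages({library(gazecluster); library(data.table)})

ngro <- as.matrix(fread("results/ngro_responses.tsv"))
asi_bs <- as.matrix(fread("results/asi_bs_responses.tsv"))
asi_hs <- as.matrix(fread("results/asi_hs_responses.tsv"))
scores <- score_attitudes(ngro, asi_bs, asi_hs)
al <- attr(scores, "alpha")
cat(sprintf("Cronbach's alpha: NGRO %.2f, ASI-BS %.2f, ASI-HS %.2f\n",
            al["ngro"], al["asi_bs"], al["asi_hs"]))
fwrite(scores, "results/attitude_scores.tsv", sep = "\t")

lr <- fread("results/logratio.tsv", sep = "\t")
# clusters of interest: significant zero-reference clusters that begin
# before the critical noun, truncated at noun onset so the aggregate
# reflects the anticipatory portion only
sig <- fread("results/clusters.tsv", sep = "\t")[
  significant == TRUE & start_ms < 0 & contrast != "condition"]
last_pre_bin <- 20L                       # bins 1..20 cover (-2000, 0) ms
coi <- sig[, .(cluster = paste0(action, "_act_",
                                ifelse(contrast == "female-vs-zero",
                                       "fem", "male"), "_occ"),
               action,
               occupation = ifelse(contrast == "female-vs-zero",
                                   "female", "male"),
               start_bin, end_bin = pmin(end_bin, last_pre_bin),
               flip = sum_t < 0)]
cat("\nclusters of interest (pre-noun, zero-reference):\n")
print(coi)

agg <- aggregate_cluster_logratio(lr, coi)
scl <- scores[, .(participant, ngro = ngro_z, asi_bs = asi_bs_z,
                  asi_hs = asi_hs_z)]
models <- fit_attitude_models(agg, scl)
coefs <- rbindlist(lapply(names(models), function(r) {
  co <- copy(models[[r]]$coefficients)
  co[, reference := r]
}))
fwrite(agg, "results/cluster_aggregates.tsv", sep = "\t")
fwrite(coefs, "results/attitude_coefficients.tsv", sep = "\t")

cat("\nper-reference intercepts and scale effects (Table-1 style):\n")
print(coefs[term %in% c("(Intercept)", "ngro", "asi_bs", "asi_hs"),
            .(reference, term, estimate = round(estimate, 3),
              se = round(se, 3), t = round(t, 2), p = round(p, 3))])
cat("wrote results/attitude_scores.tsv, cluster_aggregates.tsv,",
    "attitude_coefficients.tsv\n")
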