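#!/usr/bin/env Rscript
# Stage 5 -- validation statistics.
#
# (a) recovery of true subset fractions by NNLS; (b) recovery of the true
# total by the calibration model; (c) the internal consistency check --
# summed HSC+LMPP+CMP deconvolution fractions against the calibration
# model's independent total estimate; (d) blast-count correlation on a
# simulated 39-sample leukemia cohort at noise sd 0.03.

suppressPackageStartupMessages(library(methylHSPC))
seed <- 1L

cohort <- read.table("results/cohort_deconvolution.tsv", header = TRUE,
                     sep = "\t")

cat("== subset-fraction recovery (NNLS, % scale) ==\n")
for (s in c("HSC", "LMPP", "CMP")) {
  rr <- recovery_report(cohort[[paste0("true_", s)]],
                        cohort[[paste0("est_", s)]])
  cat(sprintf("%-5s rmse %5.2f%%  bias %+5.2f%%  r %.3f\n",
              s, rr$rmse, rr$bias, rr$pearson_r))
}

cat("\n== total-HSPC recovery (calibration model) ==\n")
rr_tot <- recovery_report(cohort$true_total, cohort$predicted_total)
cat(sprintf("rmse %5.2f%%  bias %+5.2f%%  r %.3f  (n = %d)\n",
            rr_tot$rmse, rr_tot$bias, rr_tot$pearson_r, rr_tot$n))

cat("\n== consistency: summed subsets vs calibrated total ==\n")
summed <- cohort$est_HSC + cohort$est_LMPP + cohort$est_CMP
totals <- stats::setNames(cohort$predicted_total, cohort$sample_id)
res <- lapply(seq_len(nrow(cohort)), function(i)
  structure(list(sample_id = cohort$sample_id[i],
                 fractions = c(HSC = cohort$est_HSC[i] / 100,
                               LMPP = cohort$est_LMPP[i] / 100,
                               CMP = cohort$est_CMP[i] / 100),
                 raw_fractions = NULL, residual_norm = NA, normalized = FALSE,
                 degenerate = FALSE), class = "deconvolution_result"))
cc <- consistency_check(totals, res)
write.table(cc$table, "results/consistency_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("r = %.3f, max |difference| = %.2f%% over %d samples\n",
            cc$pearson_r, cc$max_abs_difference, nrow(cc$table)))

cat("\n== leukemia cohort: marker methylation vs blast count ==\n")
atlas <- read_atlas("results/reference_atlas.tsv")
cand <- read.table("results/hspc_candidates.tsv", header = TRUE, sep = "\t")
beta <- read_beta_matrix("results/reference_beta.tsv")
ann <- read_annotations("results/reference_annotation.tsv")
panel3 <- marker_panel("hspc3-synthetic",
                       data.frame(cpg_id = cand$cpg_id, gene = NA_character_,
                                  direction = cand$direction))
atlas3 <- build_reference(beta, ann, c("HSC", "LMPP", "CMP", "leukocytes"),
                          panel3)
atlasL <- cbind(HSPC = rowMeans(atlas3[, c("HSC", "LMPP", "CMP")]),
                leukocytes = atlas3[, "leukocytes"])
coh <- make_leukemia_cohort(atlasL, n_samples = 39, noise_sd = 0.03,
                            seed = derive_seed(seed, "leuk"))
write_measurements(coh, "results/leukemia_measurements.tsv")
for (cg in cand$cpg_id) {
  r <- correlate_with_covariate(coh, cg, "blast_count_percent", loo = TRUE)
  cat(sprintf("%s: r = %.3f (n = %d, leave-one-out %.3f..%.3f)\n",
              cg, r$r, r$n, r$loo_range[1], r$loo_range[2]))
}

summary <- data.frame(
  metric = c("total_rmse_percent", "total_r", "consistency_r",
             "consistency_max_abs_diff"),
  value = c(rr_tot$rmse, rr_tot$pearson_r, cc$pearson_r,
            cc$max_abs_difference))
write.table(summary, "results/evaluation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
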