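#!/usr/bin/env Rscript
# Stage 2 -- cell-type-specific CpG selection.
#
# Scores every CpG of the simulated reference by the two selection axes
# (difference of group mean beta, worst-case within-group sd), ranks
# total-HSPC candidates against all leukocyte groups, picks three hypo-
# and three hypermethylated candidates per progenitor subset (the 18-CpG
# design), and emits a Pareto-front report of the unscalarized axes.

suppressPackageStartupMessages(library(methylHSPC))

beta <- read_beta_matrix("results/reference_beta.tsv")
ann <- read_annotations("results/reference_annotation.tsv")
truth <- read.table("results/planted_markers.tsv", header = TRUE, sep = "\t")
subsets <- c("HSC", "LMPP", "CMP")

# total-HSPC markers: progenitor subsets together vs mature leukocytes
st <- group_stats(beta, ann, target_group = subsets)
top <- rank_candidates(st, direction = "hyper", n_top = 3)
write.table(top, "results/hspc_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("top hypermethylated pan-HSPC candidates:\n")
print(top[, c("cpg_id", "score", "delta", "sd_target", "sd_rest")],
      row.names = FALSE, digits = 3)
pan_planted <- truth$cpg_id[grepl("^cgP", truth$cpg_id)]
cat(sprintf("planted pan markers recovered: %d of %d\n",
            sum(top$cpg_id %in% pan_planted), length(pan_planted)))

pf <- pareto_front(st)
write.table(pf, "results/hspc_pareto_front.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Pareto front: %d CpGs of %d\n", nrow(pf), nrow(st)))

# subset-specific markers (one row per selected CpG, 18 in total)
sel <- select_subset_markers(beta, ann, subsets, n_hypo = 3, n_hyper = 3)
sel_tab <- do.call(rbind, lapply(names(sel), function(s)
  cbind(subset = s, sel[[s]])))
write.table(sel_tab, "results/subset_markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (s in subsets) {
  planted <- truth$cpg_id[truth$cell_type == s]
  cat(sprintf("%s: %d/6 selected CpGs are the planted markers\n",
              s, sum(sel[[s]]$cpg_id %in% planted)))
}
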