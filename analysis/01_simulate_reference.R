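#!/usr/bin/env Rscript
# Stage 1 -- simulate the reference compendium.
#
# Builds a synthetic stand-in for a sorted-cell-type 450k reference set:
# three HSPC subsets (HSC, LMPP, CMP) and three mature leukocyte groups,
# four replicates each, with per-subset marker CpGs (3 hyper + 3 hypo,
# delta-beta 0.6), three pan-HSPC hypermethylated markers, and 1,000
# bimodal background CpGs. Writes the beta matrix, sample annotation and
# planted-marker truth table under results/.

suppressPackageStartupMessages(library(methylHSPC))
seed <- 1L

spec <- synthetic_spec(seed = derive_seed(seed, "ref"))
ref <- make_reference_profiles(spec)

dir.create("results", showWarnings = FALSE)
write_beta_matrix(ref$beta, "results/reference_beta.tsv")
write.table(ref$annotation, "results/reference_annotation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ref$truth, "results/planted_markers.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("reference compendium: %d CpGs x %d samples (%d planted markers)\n",
            nrow(ref$beta), ncol(ref$beta), nrow(ref$truth)))
cat("groups:", paste(unique(ref$annotation$group), collapse = ", "), "\n")
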