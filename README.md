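# methylHSPC

Quantification of hematopoietic stem and progenitor cells (HSPCs) from
targeted DNA methylation measurements.

Monitoring HSPCs — conventionally done by flow cytometry of the CD34
surface marker — matters for stem cell mobilization, apheresis quality
control and transplant assessment, but flow cytometry needs fresh cells.
DNA methylation is stable in frozen blood and dried blood spots, so a
handful of cell-type-specific CpG sites measured by targeted bisulfite
assays (pyrosequencing, ddPCR) can substitute. This package implements
that pipeline end to end:

1. **Marker selection.** Candidate CpGs discriminate a target cell
   population from a comparison population by two criteria: a high
   difference in mean methylation (Δβ = β̄_target − β̄_rest) and low
   within-group variation. The package scalarizes the two axes as
   `score = |Δβ| − w·max(sd_target, sd_rest)` (default w = 1) and also
   reports the unscalarized Pareto front.
2. **Dilution-series calibration.** Graded mixtures of sorted CD34⁺ and
   CD34⁻ cells with flow-verified fractions train an ordinary
   least-squares model `fraction% = b₀ + Σⱼ bⱼ βⱼ` over a 3-CpG panel;
   predictions are reported clamped to [0, 100] with the raw value
   retained.
3. **NNLS deconvolution.** Subset composition (HSC, LMPP, CMP,
   leukocytes) is estimated from a 6-CpG panel by non-negative least
   squares, `min ‖Ax − b‖₂ s.t. x ≥ 0`, where A is a reference atlas of
   mean β per cell type (Lawson–Hanson active-set solver, authored here,
   KKT-checked in the tests).
4. **Evaluation.** Pearson correlation (with explicit handling of
   zero-variance degeneracy and optional leave-one-out leverage ranges),
   parameter-recovery reports (RMSE, bias, r), and the internal
   consistency check that summed HSC+LMPP+CMP fractions track the
   independently calibrated total HSPC estimate.
5. **Synthetic data.** A seeded generator produces reference methylomes
   with planted markers over a bimodal background, linear cell mixtures,
   dilution series and leukemia-like cohorts with known blast counts, so
   every stage is testable without external downloads.

The two marker panels from the targeted HSPC assay literature are
packaged: `builtin_panel("hspc3")` (STK17A cg17707057, MYO1D cg00164282,
SP140 cg17607231 — hypermethylated in HSPCs, demethylated during
hematopoietic differentiation) and `builtin_panel("subset6")` (HLF,
STK17A, BMF, FTO, TESC, MYO1D — one hypo- and one hypermethylated CpG
per HSPC subtype).

## Worked example

```r
library(methylHSPC)

# a synthetic sorted-cell reference with planted markers
spec <- synthetic_spec(seed = 1)
ref  <- make_reference_profiles(spec)

# select one hypo- and one hypermethylated CpG per progenitor subset
sel <- select_subset_markers(ref$beta, ref$annotation,
                             c("HSC", "LMPP", "CMP"),
                             n_hypo = 1, n_hyper = 1)
panel <- marker_panel("subset6-synthetic", data.frame(
  cpg_id = unlist(lapply(sel, `[[`, "cpg_id")), gene = NA,
  direction = unlist(lapply(sel, `[[`, "direction"))))

# reference atlas and deconvolution of a known 10/20/30/40 mixture
atlas <- build_reference(ref$beta, ref$annotation,
                         c("HSC", "LMPP", "CMP", "leukocytes"), panel)
b <- simulate_mixture(atlas, c(0.1, 0.2, 0.3, 0.4), noise_sd = 0.02, seed = 7)
deconvolve_sample(atlas, b)
#> deconvolution_result
#>        HSC       LMPP        CMP leukocytes
#>     0.1493     0.1882     0.2918     0.3560
#> residual norm: 0.0311725
```

The estimated fractions recover the simulated composition to within a
few percent at a technical noise of sd 0.02 on β; the residual norm is
the remaining ‖Ax − b‖₂ after the fit.

The `analysis/` directory walks the whole study as numbered driver
scripts — `01_simulate_reference.R` through `05_evaluate.R` — each a thin
narrative wrapper over the package functions that prints what it found
and writes its tables under `results/`. Run them in order from the
repository root with `Rscript analysis/01_simulate_reference.R`, etc.

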