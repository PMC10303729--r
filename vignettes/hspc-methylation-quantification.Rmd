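---
title: "Quantifying hematopoietic stem and progenitor cells from targeted DNA methylation"
author: "methylHSPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hematopoietic stem and progenitor cells from targeted DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Hematopoietic stem and progenitor cells (HSPCs) are a small CD34⁺
compartment of blood whose abundance matters clinically: mobilization
efficiency before stem cell apheresis, graft quality, and — because
leukemic blasts derive from HSPC-related cell types — blast burden in
leukemia. Flow cytometry, the standard assay, needs fresh cells and
multi-marker panels. DNA methylation offers an alternative readout: a
CpG site whose methylation level (β ∈ [0, 1], the methylated fraction of
molecules) differs sharply between HSPCs and mature leukocytes reports
the HSPC fraction of bulk DNA, and works on frozen blood or dried blood
spots.

The package implements the three computational stages of such a
targeted-assay pipeline — marker selection, dilution-series calibration,
and reference-based deconvolution — plus the validation statistics and a
synthetic-data generator that makes every stage testable end to end.

## Marker selection

Given a β matrix over sorted reference samples and a two-group contrast
(target cell population vs everything else), each CpG is summarized by
the difference of group means Δβ and the within-group sample standard
deviations (n−1 denominator). A usable marker needs both a large |Δβ|
and low variation in *both* groups; the package therefore scores

    score = |Δβ| − w · max(sd_target, sd_rest),      default w = 1.

Design choices worth stating:

* **Worst-case sd, not the sum.** A marker is unusable if either group
  is noisy; taking the maximum penalizes exactly that. The weight `w` is
  exposed, and `pareto_front()` reports the non-dominated set of the two
  raw axes for inspection without any scalarization, since any scalar
  weighting is ultimately a judgment call.
* **Ties** break by larger |Δβ|, then lexicographic CpG id, making
  rankings fully deterministic.
* **Missing values** are handled complete-case per CpG within the two
  groups; CpGs missing in more than 20% of either group (configurable)
  are dropped outright. No imputation anywhere.
* **Subset markers.** For progenitor subsets (HSC, LMPP, CMP) each
  subset is contrasted against the union of the other subsets and all
  leukocyte groups; three hypo- and three hypermethylated candidates per
  subset (the defaults) give an 18-CpG design. A CpG may serve only one
  subset: claims are resolved greedily by best score, which makes the
  cross-subset uniqueness rule explicit and reproducible.

Hypermethylated markers have Δβ > 0 in the target; direction is defined
by that sign.

## Dilution-series calibration

Artificial mixtures of sorted CD34⁺ and CD34⁻ cells, with the mixing
fraction verified by flow cytometry, provide training pairs (known
fraction %, panel β). The "multivariable model" is ordinary least
squares with intercept,

    fraction% = b₀ + Σⱼ bⱼ βⱼ,

the simplest estimator consistent with a multivariable linear fit;
regularized variants are deliberately out of scope. Fits are per source
(mobilized peripheral blood vs cord blood), because panel methylation
differs between adult and fetal CD34⁺ cells and no cross-source
correction is attempted. All dilution points weigh equally.

Two numerical decisions deserve explanation:

* **Clamping.** Raw predictions can leave [0, 100] (slightly negative
  for non-mobilized blood, say). Reported fractions are clamped, but the
  unclamped value is always retained, because clamping must not hide
  systematic overestimation — a constant offset shows up as
  `bias = rmse` with r = 1 in `recovery_report()`.
* **Collinearity.** An idealized noise-free multi-CpG dilution series is
  *exactly* collinear: every panel β is then the same linear function of
  the mixing fraction, so the design matrix has rank 2 regardless of
  panel size. A constant β column is an error (its slope is genuinely
  unidentifiable), but exact collinearity falls back to the minimum-norm
  least-squares solution with a warning. This preserves fitted values —
  noise-free series predict their known fractions exactly — while real
  (noisy) data always take the ordinary full-rank path, which the test
  suite pins against an explicit normal-equations oracle at 1e−8.

## NNLS deconvolution

Subset composition is estimated from a 6-CpG panel (one hypo- and one
hypermethylated CpG per subset) against a reference atlas A: mean β per
panel CpG (rows) per cell type (columns: HSC, LMPP, CMP, leukocytes).
For a sample's panel vector b the package solves

    min ‖Ax − b‖₂  subject to  x ≥ 0

with a Lawson–Hanson active-set solver (dual tolerance 1e−10). The
solver is authored in the package because it is the pipeline's core
numerical contract; tests verify the Karush–Kuhn–Tucker conditions at
every returned solution, compare against an independent NNLS
implementation, and bound the objective by a brute-force scaled-simplex
grid search at step 0.01 on small instances.

* **No sum-to-one constraint.** The raw coefficients are the natural
  output; normalization to proportions is a reporting option
  (`normalize = TRUE`) with raw values always retained, and an all-zero
  fit sets a `degenerate` flag rather than dividing by zero. No
  equality-constrained quadratic-programming variant is provided.
* **Leukocyte aggregation.** The "leukocytes" atlas column is the
  equal-weight mean of per-group means (granulocytes, CD4 T cells,
  monocytes, …), not the pooled sample mean — reference group sizes are
  arbitrary, and pooling would bias the pseudo-type toward the largest
  group. The grouping is configurable.

The two estimates of the same quantity — calibrated total HSPC fraction
from the 3-CpG panel, summed HSC+LMPP+CMP from the 6-CpG NNLS — come
from different assays and models, so their per-sample agreement
(`consistency_check()`) is a genuine internal validation, not a
tautology.

## Evaluation

Pearson's r is the only correlation measure. Zero-variance input returns
an explicit *undefined* result (`is_undefined_r()`), never a silent
`NaN`, so degenerate cohorts stay visible. Covariate correlations
(CD34 flow counts, manual blast counts) pair complete cases only, and an
optional leave-one-out range of r exposes correlations carried by a
single leverage point — a known failure mode of small-cohort
correlations. Bare r values are reported without p-values or confidence
intervals.

## What the synthetic generator emulates — and what it does not

`make_reference_profiles()` draws background CpGs from a bimodal β
distribution (modes near 0.1 and 0.9, equal weight — the genome-wide β
shape on methylation arrays), adds a small non-specific between-type
wobble (sd 0.01), and plants markers: per-type markers offset one cell
type by ±Δβ from a common level, pan markers offset the whole progenitor
compartment jointly (the regime of the 3-CpG total-HSPC panel, which is
methylated across HSPC subsets and demethylated in mature leukocytes).
Offsets that would leave [0, 1] are shrunk to fit and the realized Δβ
recorded in the truth table. Replicates jitter about type means;
mixtures are b = Ap + ε with i.i.d. Gaussian ε clamped to [0, 1], with
clamping events counted.

Defaults are the study conditions used throughout tests and the
acceptance script: six cell types (three progenitor subsets, three
leukocyte groups), four replicates per type, 1,000 background CpGs,
marker Δβ 0.6, within-type sd 0.02, technical noise sd 0.02 (0.03 for
the leukemia cohort), dilution grid {0, 1, 2.5, 5, 10, 25, 50, 100}%,
leukemia cohort n = 39. The grid and replicate counts are artifact
choices at realistic assay scale; the cohort size mirrors the size at
which blast correlations are typically reported.

What the generator does *not* model: bisulfite-conversion failure,
SNP-under-probe artifacts, array batch effects, pyrosequencing
overdispersion beyond a single Gaussian noise knob, and the biological
reality that hematopoietic differentiation is a continuum — synthetic
subsets are cleanly separated where real HSC/LMPP methylomes partially
overlap. Passing recovery tests on this generator therefore demonstrates
correctness of the algorithms under their stated assumptions, not
field performance on clinical samples; the deconvolution of subsets that
are epigenetically adjacent will be harder on real data than here. A
further general limit of bulk deconvolution applies: cell types present
at very low fractions barely move bulk β, so precision at the low end is
bounded by assay noise, not by the model.

## Problem sizes and numerics

Tests and the acceptance script run at desk scale: 200 random NNLS
instances against the grid oracle (≤3 cell types, ≤8 CpGs), 100
noise-free recovery atlases, 50 planted-marker replicates at 1,000
background CpGs, a 30-sample consistency cohort, and a 39-sample
leukemia cohort — a few seconds in total. NNLS uses a dual tolerance of
1e−10; exact-recovery assertions hold at 1e−8; recovery thresholds
(mixture MAE < 0.05 at noise sd 0.02) were frozen once from oracle runs
and act as regression bounds. One master seed drives every stochastic
stage through deterministic per-stage derivation (`derive_seed()`), so
all results are bit-reproducible.

## Packaged panels

`builtin_panel("hspc3")` and `builtin_panel("subset6")` encode the two
published targeted panels. For `subset6`, the hypermethylated three are
STK17A (cg17707057), FTO (cg01986630) and MYO1D (cg00164282) — the ones
whose methylation tracks blast counts — and HLF (cg08865625), BMF
(cg09749364) and TESC (cg06768361) are packaged as hypomethylated,
following the one-hypo-plus-one-hyper-per-subtype design; per-CpG
directions for the hypomethylated three are the package's reading of
that design rather than an independently published table.
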