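---
title: "Spatial immune scoring and outcome association: models and choices"
author: "spatialTME maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial immune scoring and outcome association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTME)
```

# The problem

Multiplex immunofluorescence (mIF) of tumor tissue yields, after
segmentation, a table of cells with coordinates and binary marker calls.
Two samples with identical immune-cell *counts* can have radically
different biology depending on whether those cells intermix with the
tumor or sit segregated at its margin. This package quantifies that
spatial dimension — colocalization and proximity of phenotype pairs —
alongside conventional abundance and gene-signature features, and relates
all of them to overall survival (OS) and radiological complete response
(rCR) in a uniform per-unit association framework.

# Phenotype gating

Cells are gated on binary marker calls by prioritized rules: each cell
receives the highest-priority gate it satisfies, or `"other"`. The
shipped defaults are tumor = CK+, regulatory T cell (Treg) =
CD3+FoxP3+CD8−, cytotoxic T = CD3+CD8+, helper T = CD3+CD8−, PD1+ T =
CD3+PD1+, B cell = CD20+, macrophage = CD68+, NK = CD56+. Three choices
deserve comment:

* **Binary inputs.** Positivity thresholding happens upstream in the
  image-analysis software; this package consumes 0/1 calls. Gating on
  raw intensities would require per-marker cutoffs that are
  instrument-specific.
* **CK exclusion.** Whether CK+ cells may carry immune labels is
  genuinely open; the default excludes them (immune gates require CK−),
  because a CK+CD3+ object is most often a segmentation doublet. This is
  configurable via `defaultPhenotypeRules(excludeTumor = FALSE)`.
* **Priority, not multi-label.** Gates overlap (a CD3+CD8−FoxP3+ cell
  satisfies both the helper-T and Treg gates). Priorities resolve this
  deterministically — Treg above the generic T gates — and two distinct
  gates matching at *equal* priority raise an error rather than picking
  one silently.

The two staining panels (panel 1: CD3, CD20, FoxP3, CK, Ki-67; panel 2:
CD3, CD8, CD68, PD1, PDL1, CK) come from different sections, so
phenotypes are computed per panel and merged only at the per-sample
feature level, never per cell.

# Quadrat colocalization: Morisita–Horn

The sample is tiled into non-overlapping squares of 100 µm — the scale of
a few cell diameters, small enough to resolve infiltration, large enough
that counts per square are stable. With per-square counts $x_i$, $y_i$
and totals $X$, $Y$:

$$\mathrm{MH} \;=\; \frac{2\sum_i x_i y_i}
  {\left(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2\right) X\, Y}$$

MH is 0 when no square holds both types and 1 when the two types are
identically distributed over squares; it is symmetric and insensitive to
the absolute abundance of either type.

Numerical conventions:

* The grid is anchored at the per-sample bounding-box minimum; partial
  edge squares are **included** (excluding them would silently discard
  cells). Binning is half-open, $[ks, (k+1)s)$, so a cell exactly on a
  boundary belongs to the higher-index square.
* When either type is absent, MH is **missing, not zero** — a zero would
  assert observed segregation that the data cannot support.
* Scores are computed per core; when a sample contributes several cores
  the per-core values are averaged (the `spatialScoreTable()` caller
  controls the grouping).

# Proximity: G(r), SPS and the Ecoscore

The nearest-neighbor distance distribution $G(r)$ is the fraction of
reference-type cells whose nearest target-type cell lies within $r$
(self-pairs excluded when reference and target coincide). The Spatial
Proximity Score summarizes the curve:

$$\mathrm{SPS} = \frac{1}{r_{\max}} \int_0^{r_{\max}} G(r)\,dr,$$

evaluated by the trapezoidal rule on a 1 µm radius grid with
$r_{\max} = 50$ µm by default — roughly the scale of direct cell–cell
interaction; both are configuration keys. SPS is 1 when every reference
cell is essentially touching a target cell and 0 when no target lies
within $r_{\max}$. This normalized-area definition is this package's
explicit construction for the score; sites with a house definition of a
proximity score can substitute their own by operating on the exported
`GFunctionCurve`.

No edge correction is applied by default: tissue cores are small, and
border corrections trade bias for variance in ways that are hard to
standardize. A reduced-sample (minus-sampling) option is available
(`gFunction(..., border = "reduced")`), reported cumulatively so the
curve stays monotone.

The **Ecoscore** classifies a sample by comparing the mean SPS of
anti-tumor classes toward tumor cells (default: cytotoxic T) with that of
pro-tumor classes (default: Tregs and macrophages): `anti-tumor` if the
first mean exceeds the second by more than a relative margin (default 0),
`pro-tumor` in the reverse case, `indeterminate` on ties or when either
side is missing. Class membership and margin are arguments, since the
pro/anti assignment of macrophage subsets in particular is
context-dependent.

# Signature scoring

Expression matrices (log scale assumed) are mean-centered per gene across
all samples before scoring; the score of a sample on a signature is the
unweighted mean of its centered signature-gene values, with optional
±1 direction weights. The mean-of-centered-genes rule is the simplest
member of the metagene family and the convention for the published
signature collections this supports; weights accommodate signatures
defined with down-regulated components. Genes absent from the matrix are
dropped with a warning; an empty intersection yields a missing score, not
an error, so a screen over many signatures degrades gracefully.

Centering is joint over all samples by default. Centering primary tumors
and metastases separately would remove exactly the primary-vs-metastasis
shifts the contrast analyses look for, so the joint default is the right
one whenever both groups are analyzed together; subset first to center
within groups.

# Outcome association

Every feature enters the same machinery: a Cox proportional-hazards model
for OS (Efron approximation for ties — the accepted default, and it
matters at monthly time granularity) and a logistic model for rCR, each
reporting the estimate per unit increase with a likelihood-ratio (LR)
p-value on one degree of freedom from nested fits on the same complete
cases. Odds ratios imply a logistic link, and this package fits rCR by
logistic regression throughout (reported descriptions of such analyses
sometimes say "linear regression" while reporting odds ratios; the
estimates here are from the logistic likelihood).

* **"Per unit" is taken literally** — no internal rescaling — because the
  natural unit differs per feature (percent sTILs, cells/mm², an MH
  index). A `standardize = TRUE` switch gives per-SD estimates when
  features on incommensurate scales must be compared.
* **Subgroups and adjustment.** The screen runs every (variable,
  endpoint, subgroup, covariate-set) cell: subgroups all / ER+ / ER− /
  rCR / no-rCR / primary / metastasis, covariate sets typically
  unadjusted and ER+rCR-adjusted. A covariate is dropped automatically
  when it coincides with the endpoint or the subgroup split (rCR cannot
  adjust an rCR model). Cells that cannot be estimated — zero events,
  single outcome class, constant variable, complete separation — are
  flagged `not estimable` and retained, never dropped, so the multiplicity
  family is visible.
* **Multiplicity.** Benjamini–Hochberg adjustment is applied across the
  whole screen family (all cells), and both raw and adjusted p-values are
  reported. Dot-plot exports carry the three-tier background encoding
  (white p < 0.05, light gray 0.05–0.10, gray otherwise).
* **Follow-up** is estimated by reverse Kaplan–Meier (censoring as the
  event); **tertile splits** use the empirical 1/3 and 2/3 quantiles with
  ties to the lower group; **paired primary-vs-metastasis contrasts** use
  the Wilcoxon signed-rank test, computed by exact sign enumeration
  (average ranks on tied absolute differences) for up to 12 informative
  pairs and the normal approximation beyond — small paired cohorts are
  exactly where the approximation is worst.

# The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. It emulates three things:

* **Point patterns**: a Thomas-style cluster process — Poisson parents,
  Poisson offspring counts, isotropic Gaussian displacements — in a
  600 × 600 µm window (a typical core's scale), with a
  `sharedParentFraction` $f$ controlling colocalization: shared parents
  spawn both types, exclusive parents one, and the per-type parent
  intensity is constant in $f$ so that moving $f$ changes *arrangement*,
  not abundance. Offspring outside the window are discarded, as at a
  physical core boundary. Defaults (10 parents/mm², 30 offspring per
  parent, 20 µm spread, 50 background cells/mm² per type) give a few
  hundred cells per type per core, in the range of infiltrated tissue.
* **Outcomes**: survival from a proportional-hazards model with
  exponential baseline (Weibull shape exposed; exponential keeps the
  inverse-CDF draw and the interpretation of coefficients simple),
  administratively censored at 120 months; rCR Bernoulli through a
  logistic link with intercept −1.5 (a ~18% response rate). Baseline
  hazard 0.02/month gives median survival near 35 months, realistic for
  a metastatic cohort with long follow-up. Scores entering the models
  are z-scored, so generating coefficients are per SD.
* **Expression**: i.i.d. standard-normal background genes plus, per
  signature, a per-sample latent factor added to its genes scaled by an
  effect size; the generating factors are stored in the object metadata
  for recovery tests.

What it does **not** emulate — and hence what passing tests do not show
about real data: irregular core shapes and tissue folds, marker-call
errors and segmentation doublets, spatially varying cell density within
a core, correlations between features beyond the planted ones, informative
censoring, and cohort-level confounding. Tests on this generator
establish the *correctness and calibration* of the estimators, not the
biological validity of any particular finding.

# Verification scale and numerical notes

The test suite verifies Morisita–Horn and G(r) exactly (to 1e−12)
against brute-force oracles on hundreds of random ≤50-cell patterns, the
Cox coefficient against a grid-maximized Efron partial likelihood to
1e−4 on tied toy data, and the closed-form worked values (MH = 0.8 on
counts (2,1)/(1,2); SPS = 0.5 on a linear ramp). Calibration runs use 50
simulation replicates per shared-parent fraction, 100 replicates at
n = 300 for null type-I error (accepted band 0.01–0.10 at α = 0.05) and
100 replicates at n = 500 for hazard-ratio CI coverage (≥ 90%) — sizes
at which these Monte-Carlo checks are stable from run to run.

Degenerate inputs are handled explicitly rather than by convention: empty
patterns raise errors where a statistic is undefined, absent types yield
missing values with reasons, all-tied tertiles warn and collapse to T1,
and a near-zero censoring horizon produces an all-censored cohort rather
than a failure.

# Limitations

Phenotypes are as good as the upstream segmentation and thresholding;
the SPS and Ecoscore constructions are this package's explicit
definitions of those summaries and other sites may define them
differently; the association screen is exploratory machinery — per-unit
estimates with LR p-values and FDR control — not a causal analysis, and
subgroup cells with few events are reported but should be read with the
flagged event counts in hand.
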