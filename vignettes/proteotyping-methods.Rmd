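---
title: "Methods: MRM plasma proteotyping from peak areas to knockout signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRM plasma proteotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteotypeR)
```

## Scope and contract

proteotypeR implements the analysis side of an internal-standard MRM
proteotyping study. Its contract deliberately begins at *integrated peak
areas*: upstream chromatogram processing includes manual inspection and
correction of peak integration, which no reusable pipeline can reproduce.
The transition table is therefore a frozen, simplified dialect — one row
per sample × peptide with light and heavy areas — and each protein is
represented by exactly one surrogate peptide (tables with several peptides
per protein are rejected at read time, since no summarization rule across
peptides is defined for this assay style).

Missing values are encoded explicitly and are distinct from zero: a zero
concentration is a measured blank-level signal; a missing cell is an
absent record.

## Quantification

Calibration regresses the light/heavy ratio on nominal concentration with
`1/x^w` weights, `w = 2` by default. The weighting exponent reflects the
near-constant *relative* (not absolute) error of MRM responses across a
three-decade curve; `w = 0` recovers ordinary least squares and is exposed
for sensitivity checks. The model is linear: with a heavy internal
standard normalizing out matrix and injection effects, a quadratic term
has no mechanistic justification inside the 1–1000× LLOQ range, and a
quadratic fit would mask saturation rather than flag it.

Back-calculation inverts the line. Conventions, fixed once and tested:

* the LLOQ/ULOQ boundaries are inclusive — a value exactly at a limit is
  `in_range` ("above the lower limit of quantification" is read as ≥ for
  the limit itself);
* negative back-calculations (ratio below the fitted intercept) clamp to
  0 fmol/μL with flag `below_lloq`; concentrations are physical
  quantities, and the flag preserves the information that the signal was
  sub-blank;
* curves with non-positive slope are rejected, and back-calculation
  through them refuses to run rather than return signed nonsense;
* calibration uses the *ratio* response, not the absolute light response:
  the heavy standard is explicitly the normalizer, and a ratio-based curve
  cancels injection-to-injection variation of the standards themselves.

Curves are fitted once, from the standards on the first plate, and applied
to all plates. Plate-to-plate differences are a multiplicative effect on
measured intensities and are handled by pooled-reference normalization,
not by per-plate curves (which would confound curve error with plate
bias).

## Plate normalization and filtering

For each (plate, protein) the scale factor is
`grand median / plate median` of the pooled-reference concentrations. The
median, not the mean, is used for robustness against the occasional
censored or aberrant pooled value; below-LLOQ pooled values are excluded
from both medians. The grand median across all plates is the anchor — no
external reference value exists, and any per-protein anchor is a global
constant that cancels in every downstream contrast (the tests assert
idempotence: normalizing already-normalized data yields factors of 1 to
1e−12). When more than half of a plate's pooled values for a protein sit
below the LLOQ, the plate factor would be driven by censored values, so
the original back-calculated values are kept unchanged; the report records
`exception_applied`.

The filtering cascade is computed on post-normalization flags (flags are
recomputed after scaling; the alternative — pre-normalization flags —
would let a plate factor push nominally "quantifiable" values out of
range unrecorded). "Detectable" is operationalized as ≥ 1 in-range
measurement anywhere; it is the weakest defensible definition, and the
per-protein disposition table makes the choice auditable. Proteins that
survive filtering keep their below-LLOQ values as back-calculated numbers:
nothing is imputed or dropped, because the downstream rank-based tests
tolerate noisy sub-LLOQ values far better than any imputation scheme, and
censored fractions remain visible in the flags.

## Contamination screening

Contamination by erythrocyte (and platelet) cell content is a
*sample-level* artifact: one preparation event loads every panel protein
of that sample at once. Correlation clustering therefore operates on raw
concentrations (where a shared heavy-tailed loading dominates the
covariance), with pairwise-complete observations and a minimum of 3
complete pairs. Clusters are connected components of the |r| ≥ 0.8 graph,
not complete subgraphs — the weakest reading of a thresholded correlation
matrix; users wanting cliques can raise the threshold. Panel extension
ranks non-panel proteins by median |r| to the panel, which is how an
unexpected intracellular protein is recognized as co-varying with the
erythrocyte set.

The differential audit is qualitative in origin: "similar trend" is
operationalized as same-sign log2 fold change of magnitude ≥ 0.5 in at
least 50% of the other panel members, both knobs config-exposed
(`co_trend_min_lfc`, `co_trend_fraction`); with fewer than 3 other panel
members measured the verdict is `indeterminate`. Platelet proteins are
clustered and reported but never auto-flagged: platelet-rich plasma makes
them a legitimate part of the sample.

## Differential inference

The Mann–Whitney–Wilcoxon implementation enumerates all
`choose(n_a + n_b, n_a)` labelings when `n_a + n_b ≤ 12` (at most 924
labelings), handling ties by midranks; the permutation null of U is
symmetric about `n_a n_b / 2` even under ties, so the two-sided p is the
two-tailed mass of `|U − n_a n_b / 2|`. Larger groups use the normal
approximation with midrank tie correction and continuity correction. The
exact path is hand-implemented because no stock routine provides exact
p-values under ties; the stock routine serves as an independent
cross-check in the tests on the paths where both are exact.

With 3 mice per strain and sex, the smallest exact two-sided p of a
3-vs-3 rank test is 0.1, so no per-sex knockout contrast can reach
p < 0.05. Knockout contrasts therefore default to both sexes of a strain
(n = 6) against all wild-type controls (n = 38); per-sex contrasts remain
available. Significance defaults: knockout contrasts at BH-adjusted
p < 0.05 and twofold change (`|log2FC| ≥ 1`); sex contrasts at raw
p < 0.01 and twofold change, with BH values reported alongside. The
twofold reading of the knockout threshold is the default; a stricter
`log2FC > 2` reading is one config value away (`ko_fold_threshold = 4`).
BH families are per contrast, not pooled across strains, since each
strain comparison is reported independently.

Ablation is detected from censor flags, not from literal zeros: a protein
whose non-missing values are all `below_lloq` in one group, while at least
half the other group is in range, carries the `ablated` sentinel, an
infinite signed log2 fold change, and is significant by absence. This is
the expected signature of the knocked-out protein itself in a homozygous
strain, where the measured signal is blank-level noise rather than exactly
zero.

LASSO details are unstated in this literature and fixed here for
determinism: features are log10-transformed (zeros shifted by half the
smallest positive value of that protein), standardized, and fitted by
L1-penalized logistic regression with the penalty chosen by leave-one-out
cross-validated binomial deviance over the default descending penalty
grid; the selection is the nonzero-coefficient set at the chosen penalty.
Leave-one-out folds make the choice deterministic at these sample sizes.
Empty selections are legal and expected for strains without a plasma
signature. PCA uses the same log10 transform, mean-imputes missing cells
after the transform, drops constant proteins with a warning, and scales to
unit variance, so that abundance (five decades) does not dominate the
projection. The classifier behind the C-statistic is a ridge-stabilized
(penalty 1e−6) logistic regression in stratified k-fold cross-validation
(default k = 5); standardization parameters are estimated on each training
fold only, and the C-statistic is the rank-based AUC of held-out scores.

Over-representation uses the one-sided hypergeometric upper tail with the
quantified panel as background — the only background under which "is this
set over-represented among my hits" is well-posed for a targeted assay.
Sets are intersected with the background before testing, sets with fewer
than 3 background members are skipped, and BH runs across the sets tested
within one collection. Ortholog mapping is an explicit caller-supplied
table; no identifier database is embedded.

## Phenotype integration

Protein–test correlations are reported with Spearman as the headline
method (robust to the monotone nonlinearities typical between enzyme
levels and derived clinical indices) and Pearson available in the same
table; both appear in this literature and neither is privileged by the
data. Sex adjustment removes the per-sex mean from both variables —
exactly regression on a sex indicator — and correlates the residuals;
this equals the partial correlation given the binary covariate (asserted
in tests to 1e−10) for the Pearson case. Per-sex stratified correlations
are reported alongside, since agreement in sign between stratified and
residual estimates is the signature of a genuine within-sex association
rather than a sex-mean artifact.

## The synthetic-data generator

The generator emulates the study conditions end to end: 30 knockout
strains × 2 sexes × 3 mice + 19 + 19 wild-type controls = 218 study
samples randomized over 3 plates; 11 pooled references per plate (33
total); an 8-point calibration curve at 1, 2, 5, 10, 50, 100, 500, 1000×
LLOQ on plate 1; 3 curve-QC standards per plate; 226 proteins with
baselines log-uniform over 0.3–6 × 10⁴ fmol/μL.

The forward model for sample *s*, protein *p* is

    T = mu_p * 2^(sex effect * [male]) * 2^(KO effect) * plate bias * bio
        + lambda_p * c_s * [p in erythrocyte panel]

with observed ratio `(T / heavy_spike_p) * eps`, `eps` log-normal at CV
κ = 0.09, and `light_area = ratio * heavy_area`. Choices and rationale:

* **multiplicative log-normal noise** (`sdlog = sqrt(log(1 + κ²))`):
  measurement precision is reported as relative CV and the concentrations
  span five decades;
* **inter-individual biological variance** (`biological_cv = 0.2`,
  study samples only): pooled references measure one shared pool and carry
  none, which is exactly why the pooled CV estimates measurement
  precision while study samples spread wider — and why protein–phenotype
  correlations can exist at all;
* **plate bias** is per-protein-per-plate multiplicative with mean
  exactly 1 (`plate_bias_sd = 0.05`), matching the per-protein
  within-plate normalization design;
* **contamination is additive on the concentration scale** (physical
  carry-over of cell content), sparse (25% of samples), with a
  heavy-tailed per-sample level (log-normal, sdlog 1) and panel loadings
  of 3× the protein baseline; one extra non-panel protein carries the
  same loading by default, so panel-extension logic is exercised; an
  independent platelet component clusters without ever being auto-flagged;
* **ablation produces blank-level signal** at 0.1× the LLOQ response
  rather than an exact zero — real blanks have nonzero noise, and this
  keeps the censoring path honest; the blank level is a free parameter
  with no literature value;
* **assay LLOQs** place baselines 20–800× above LLOQ (log-uniform), so
  that default measurements sit inside the 1–1000× assay range, matching
  a panel of validated assays;
* effect sizes default to 20 sex-dimorphic proteins and 3 knockout
  bystander proteins per strain, |log2FC| uniform in [1, 2] with random
  sign, plus each strain's own target protein (ablated when homozygous,
  −1 log2 unit when heterozygous).

What the generator does **not** emulate: transition-level interferences
and peak-shape artifacts, missingness mechanisms other than censoring,
correlated biology between proteins (pathway co-regulation), drift within
a plate, or heteroscedastic calibration residuals beyond the 1/x² model.
Passing the recovery tests therefore demonstrates that the pipeline's
statistics behave correctly under the stated generative assumptions — not
that real plasma data satisfy those assumptions. In particular the PC1+PC2
variance share of real data (where co-regulation concentrates variance) is
substantially higher than in simulations with independent proteins.

## Problem sizes and determinism

The test suite runs the full 218 × 226 study shape where the shape is the
point (filter cascade, sex-signature recovery over 10 seeds, contamination
recovery over 10 seeds) and a reduced 28-sample × 60-protein design
elsewhere; oracle-equivalence checks use 1000 random calibration designs,
exhaustive hypergeometric enumeration to N = 30, and full
Mann–Whitney labeling enumeration to n = 10. Every stochastic stage takes
an explicit seed, and `simulate_dataset` is bit-identical for identical
(design, truth, seed).

## Known limitations

* One peptide per protein is a contract, not a convenience; assays with
  several surrogates need upstream summarization.
* The normalization anchor is internal (grand pooled median), so absolute
  accuracy across *studies* is only as good as the pooled reference;
  within-study contrasts are unaffected.
* `flag_differential_contaminants` is categorical; no quantitative
  per-sample contamination fraction is estimated.
* The Welch t-test is a comparator only and is reported with an epsilon
  guard for zero-variance degeneracy; the rank test is the primary
  inference.
* ORA consumes user-supplied GMT files; no knowledgebase snapshots are
  bundled, so results depend on the collections the caller provides.
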