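---
title: "Rank-based integration and biomarker panel evaluation with dcmScreen"
author: "dcmScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based integration and biomarker panel evaluation with dcmScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmScreen)
```

# The problem

Diabetic cardiomyopathy (DCM) begins as asymptomatic left-ventricular
diastolic dysfunction, detectable only with specialized
echocardiography (a falling mitral E:A ratio). A serum biomarker for
this stage would have to be found indirectly: no "DCM expression
dataset" exists, but DCM sits at the intersection of type-2 diabetes
(T2DM) and cardiovascular disease (CVD), both of which have public
microarray studies. `dcmScreen` operationalizes that idea — find genes
perturbed in *both* diseases using rank-based cross-platform
integration, then evaluate a small serum panel in a longitudinal
two-group mouse design — and validates every stage against synthetic
data with known ground truth.

# The discovery model

## Why rank bins

Microarray studies from different platforms differ by scale, offset
and non-linear (but monotone) intensity response. The package's
integration therefore works only at the rank level: per sample, the
`G` gene values are average-ranked and assigned to `Q` quantile bins,

$$\mathrm{bin}(g) = \min\!\big(\max\!\big(\lceil r_g \, Q / G \rceil,
1\big), Q\big),$$

with ties sharing their mean rank. Two facts carry the design:

* **Monotone invariance.** Any strictly increasing per-sample
  transform leaves ranks, hence bins, unchanged. Platform warps —
  and any rank-preserving normalization — are exactly absorbed.
* **Near-uniformity.** Without ties and with `Q | G`, every bin holds
  exactly `G/Q` genes, so bins are comparable across samples.

Discretization is done **per sample**, not per pooled study
distribution: only the per-sample construction has the invariance
property above, which is what justifies merging samples from different
platforms at all.

Defaults are `Q = 128` for within-disease runs and `Q = 1028` for the
integrated run. Both are configurable; 1028 is kept as the
conventional default for this pipeline even though the power of two
1024 may look more natural.

The per-sample median/MAD standardization offered by
`standardizeStudy()` is a deliberately simple, rank-preserving
pre-processing step: the pipeline does not attempt platform-specific
normalization (RMA and similar are out of scope), and because the
standardization is strictly increasing per sample it provably cannot
change any downstream bin.

## Differential expression and candidate ranking

Per gene, case vs control bins are compared with a two-sided Wilcoxon
rank-sum test. The p-value is exact (full null distribution of the
Mann–Whitney U) when the pooled sample size is at most 12 with no
ties; otherwise a normal approximation with tie-corrected variance and
continuity correction is used. The cutoff 12 keeps the exact path in
the regime where it is cheap and matters most; a deterministic sweep
in the tests shows the two paths agree within 0.01 wherever the exact
p is below 0.2 (the calling region) and within 0.02 everywhere.

Both Bonferroni and Benjamini–Hochberg adjustments are attached to
every table. The primary DEG call is `q_BH < α` (default `α = 0.05`);
raw-p and Bonferroni calls are also emitted because a bare
"p < 0.05 was considered significant" rule admits several readings —
all three are reproducible from one `DEGTable`.

Candidates are the intersection of the two disease DEG sets, ranked by
the integrated-analysis p-value ascending ("Wilcoxon score"), with
ties broken by |standardized W| descending and then lexicographic gene
id — a fully deterministic ordering. The top `k = 2` selection mirrors
a setting where limited serum constrains how many candidates can be
assayed.

# The synthetic-data model

## Expression studies

`simulateStudy()` draws per-gene baselines normal on the log-intensity
scale (`N(6, 1.5)`, mimicking array skew), adds
`d × noiseSd` to case samples of planted DE genes, adds `N(0, noiseSd)`
noise, then applies the platform profile (affine transform followed by
an optional `exp` or cubic warp). Effects are parameterized in
within-group SD units so rank-test power is analytically predictable
(noncentrality ≈ `d √(n₁n₂/(n₁+n₂))`).

A baseline is a property of the *gene*, not of the study:
`simulateDiseaseCollection()` draws the baseline vector once and
shares it across all studies of a collection, so studies differ only
by noise, planted effects and platform profile. (Drawing baselines
independently per study would inject gene-level between-study
heterogeneity that no monotone-invariant method can remove — a
different and harsher data model than the one emulated here.)

What the generator does **not** model: probe-level CEL intensities,
non-monotone batch effects, correlated genes, and study-specific
biological heterogeneity. Passing tests therefore demonstrate
correctness of the machinery under the stated data model, not
robustness to every pathology of real meta-analysis.

The default discovery design (`plantedOverlapDesign()`) uses 2000
genes, two studies per disease at 15 vs 15 samples (a typical
desk-scale microarray design, matched to the spike-in power
calculation), 50 overlap genes plus 30 disease-specific genes per
disease at `d = 1.5`, and two designated strongest overlap genes at
`d = 3`. At these sizes the integrated analysis separates the
strongest pair from the `d = 1.5` background in essentially every
seed.

## Serum panels

`simulateSerumPanel()` emulates a terminal design: `n = 8` animals per
group at each of weeks 6, 9, 11, 14, 16 (each animal measured once).
Default markers:

| marker | baseline | case shift by week (SD units) | emulates |
|---|---|---|---|
| `marker_up` | 10 | +0.5, +1.5, +2, +1.5, +1.5 | LOXL2-like, elevated from week 9 |
| `marker_down` | 8 | 0, −0.5, −2, −2.5, −1.5 | ETFβ-like, reduced from week 11 |
| `marker_null` | 12 | 0 everywhere | NT-proBNP-like comparator |

The E:A ratio is 1.6 in controls at every week and declines in cases
from week 11 (1.25 → 1.10), with residual sd 0.12 and coupling
weights −0.08/+0.08/0 linking each marker's within-cell deviation to
the E:A deviation. The couplings were fixed by a closed-form pooled
covariance calculation (group-by-week mean co-movement plus residual
coupling) so the pooled population correlation is near |r| = 0.65 —
the magnitude regime the panel arm is meant to exercise. Units are
arbitrary concentration units; only signs, SD-scaled effects and
correlation magnitudes are meaningful.

# The panel-evaluation model

* **Weekly tests.** A Gaussian GLM of marker on group indicator per
  week — algebraically the pooled-variance two-sample t-test; the
  t sign is case minus control. The family is the natural default for
  concentration-scale data at `n = 8` per cell.
* **Composites.** Markers are standardized over the used records.
  *Unsupervised*: first principal component of the marker correlation
  matrix; weights unit-norm, sign fixed so the first non-zero weight
  is positive; the PC1 variance share (top eigenvalue fraction) is
  reported. *Supervised*: logistic regression of group on the
  standardized markers, scored as predicted case probability. The two
  modes formalize ROC "groups not specified" vs "groups specified":
  the only reading in which group specification changes the ROC input
  is whether the labels are used to learn the combination weights.
  Both are always computed side by side.
* **ROC.** Thresholds are the unique scores (descending, preceded by
  +∞); AUC is the trapezoidal area and equals the Mann–Whitney
  identity `(concordant + ½ tied)/(n₁n₂)` exactly on every input,
  ties included. If raw AUC < 0.5 the flipped value is reported with
  a flag rather than silently reorienting. The cutoff maximizes
  Youden's J with the lowest threshold on ties, and is reported on
  the score scale (a probability in supervised mode). ROC is
  in-sample by design — the evaluation mirrors a small-animal study,
  not a validated clinical classifier; treat supervised in-sample
  AUCs as optimistic.
* **Week window.** ROC pools records from weeks 9–14 by default, the
  window in which both planted markers separate the groups; the
  window is a parameter. Pooling treats animal-week records as
  independent, correct for a terminal design.
* **Correlations.** Pearson on values and Spearman on ranks, pooled
  over all weeks, pairwise-excluding records with a missing E:A
  value.

# Numerical and degenerate-input choices

* Empty p-vector, single-condition data, empty gene intersection,
  zero-covered probe maps, unknown group labels, and duplicate
  (animal, week) records are errors, never silent coercions.
* All values identical in a rank-sum test → p = 1, direction `none`.
* Constant scores in ROC → degenerate flag, AUC 0.5, cutoff `NA`.
* Zero-variance marker in a composite → error naming the marker.
* Sample MAD of zero in standardization → divide by 1.
* `Q > G` warns (bins sparse) but proceeds, since the binning formula
  remains valid.
* Gene order in merged outputs is lexicographic; all generators are
  deterministic given an integer seed via R's default RNG.

# Problem sizes used in validation

The shipped tests exercise: exactness of the rank-sum p at every
untied size up to pooled `n = 12` against full enumeration; 1000
random vectors against brute-force correction oracles; 500-sample
warp-invariance and uniformity checks of the binning; null calibration
at 2000 genes, 10 vs 10 (raw-p rate and BH discoveries over 50
seeds); spike-in recovery at 2000 genes, 100 planted at `d = 2`,
15 vs 15 over two warped platforms (20 seeds); end-to-end top-2
recovery over 100 seeds; exact AUC pair-counting on 200 tied inputs
plus the binormal closed form `Φ(1/√2)`; the two-marker PC1
eigenvalue closed form `(1+ρ)/2`; and 200-seed sign-recovery and
null-marker calibration of the panel generator. These sizes were
chosen so each property is measured with comfortable Monte-Carlo
margin at desk scale.

# Known limitations

* Genes are simulated independently; correlated expression modules
  would change DEG-count variability (not the validity of per-gene
  p-values).
* The integration assumes strictly monotone platform distortions;
  non-monotone batch effects are out of scope.
* Rank-based integration attenuates effects for genes at the extreme
  top or bottom of the expression distribution (rank saturation) —
  an intrinsic property of quantile binning worth remembering when
  interpreting candidate lists.
* In-sample ROC over-estimates out-of-sample discrimination,
  especially for the supervised composite at these group sizes.
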