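---
title: "Scoring cell-based RNAi screens of cellular cholesterol phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cell-based RNAi screens of cellular cholesterol phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscreen)
```

## The assay and its statistics

`lipidscreen` analyzes high-content siRNA screens in which two cellular
cholesterol phenotypes are read out by automated fluorescence microscopy:
endocytic uptake of labelled LDL (DiI-LDL, endosomal spots) and free
cellular cholesterol (filipin staining, perinuclear structures). Cells are
transfected in 384-position layouts; each position holds one siRNA, and a
fixed complement of control positions anchors all statistics: 16
non-silencing negative controls, mock transfections (reagent without
siRNA), positive controls for each assay (LDLR for LDL uptake, NPC1 for
free cholesterol) and INCENP transfection controls.

From every segmented cell, up to seven parameters are measured inside
detected structure masks: for LDL uptake, `total` (summed signal above
local background), `concentration` (mean signal above local background per
mask pixel) and `structures` (mask count); for free cholesterol the same
three plus `area` (summed mask area). By construction
`total = concentration x mask area`, an identity the test suite asserts
for every cell.

### The deviation value

Cell means are averaged per image, image means per biological replicate.
For siRNA $s$ in replicate $r$ the screen's core statistic is the
*deviation value*

$$ d_{r,s} \;=\; \frac{\bar{x}_{r,s} - \overline{c}_r}{2\,E_r}, $$

where $\overline{c}_r$ is the mean of the negative-control replicate means
and $E_r$ their error. The statistic is a z-score-like quantity in which
*twice the absolute error* of the controls replaces the standard
deviation. We interpret the absolute error as the mean absolute deviation
of the control means about their mean; this is the closest literal reading
of "absolute error" as contrasted with the standard deviation, and the
`error` argument of `deviation_value()` / `score_deviations()` provides
`"sd"` and `"sem"` alternatives behind a flag. Deviation values of a
siRNA's replicates are averaged arithmetically into its functional effect
(`aggregate_deviations()`), and control deviations are checked for
normality per parameter by Shapiro-Wilk test and QQ points
(`control_normality_check()`).

Centring on the same-replicate controls makes the statistic exactly
location-free (control deviations average to zero to numerical precision)
and, because the mean absolute deviation scales linearly, exactly
invariant to multiplicative intensity rescaling - both are asserted as
identities in the tests.

### Region normalization

384-well plates show edge artifacts. Wells are partitioned into region 1
(plate edge), region 2 (neighbours of edge wells) and region 3 (the
rest), and deviation values on plate assays are computed against negative
controls *of the same region* (`score_deviations(region_normalize =
TRUE)`). Cell-array assays use all controls. When a region holds fewer
than two negative controls, scoring falls back to plate-wide controls
with a warning. The layout generator places the 16 negative controls
stratified over the three regions (at least two per region,
proportionally otherwise), as screening plates do in practice, so that
region normalization is always anchored.

### Thresholds, effector siRNAs, hit genes

Effector thresholds derive only from negative-control and mock positions:
a siRNA is an effector on parameter `total` when its mean deviation lies
above or below the mean of *any* control position by more than three
standard errors of the mean, with SEM = sd(all control deviation values) /
sqrt(number of biological replicates). We implement the "any" as the
extreme control envelope (`max` control mean + 3 SEM, `min` − 3 SEM),
which is consistent with the companion requirement that no control passes
its own thresholds; a nearest-bound (`"all"`) mode is available behind a
flag. Boundary equality is deliberately *not* an effect (strict
inequality), giving deterministic tie behaviour. The identical rule is
applied per parameter to flag fingerprint entries. Published threshold
pairs for the original screens are shipped verbatim
(`published_thresholds()`) so reported per-siRNA deviations can be
re-classified without raw data.

A gene is a **hit** when at least two distinct siRNAs targeting it are
effectors in the same assay; genes with fewer than two tested siRNAs are
flagged untestable rather than silently non-hit. Screen-to-screen
reproducibility is summarized by `validation_rate()` (effectors of screen
1 re-meeting criteria in screen 2) and `parameter_correlations()`
(pairwise Pearson correlations across parameters and screens).

Because the original report does not state how its per-siRNA FDR column
was computed, `empirical_fdr()` implements a documented choice: a
two-sided empirical p-value against the pooled control deviation
distribution with the add-one rule, Benjamini-Hochberg adjusted across
siRNAs. This is this package's own procedure, not a reconstruction.

## Image quantification

The imaging stage mirrors a CellProfiler-style pipeline:

* `segment_nuclei()` - Gaussian smoothing, Otsu (or fixed) threshold,
  connected components, minimum-area filter, optional distance-map
  watershed for touching nuclei. Fields whose smoothed intensity range is
  below `min_contrast` (default 0.1) are treated as empty rather than
  letting a global threshold split camera noise.
* `approximate_cell_regions()` - either stepwise dilation of the nuclear
  masks up to a radius with nearest-nucleus ties (free-cholesterol
  plates) or intensity-guided propagation over an auxiliary channel (LDL
  arrays). Cell labels preserve nucleus labels, so cell count equals
  nucleus count by construction. On a flat guidance image propagation
  reduces to the geometric dilation result, which the tests exploit as an
  equivalence oracle.
* `detect_structures()` - local adaptive thresholding: a pixel is a
  candidate when it exceeds the local window median by `offset` robust
  standard deviations (1.4826 x local median absolute deviation, floored
  at `min_robust_sd` so that noise-free flat windows do not threshold at
  zero). Components are filtered by area and eccentricity, clipped to
  their majority cell, and optionally restricted to a perinuclear ring.
  Each structure's local background is the median of its window with all
  structure pixels excluded.
* `extract_cell_features()` computes the seven parameters;
  background-subtracted intensities are floored at zero, and cells
  without structures get zeros, not missing values.

The exact size/shape parameters of the original quantification module are
unpublished; the defaults here (31 px window, offset 3 robust sd, area
4-400 px², eccentricity ≤ 0.95, perinuclear ring nucleus boundary to
+15 px for the FC assay) are configurable via `structure_params()` and are
chosen to make detection essentially exact on the synthetic scenes.
Whether "concentration" averages per pixel or per structure is likewise
unstated; this package fixes the per-pixel mean over all mask pixels,
which yields the `total = concentration x area` identity. Cells touching
the image border are retained. Pixel coordinates are 0-based row-major;
areas are px² (no micrometre calibration); images are single-plane 16-bit.

Automated QC (`qc_images()`) substitutes for visual curation: variance of
the Laplacian as focus score, nucleus-count bounds, and a saturation
fraction bound.

## The synthetic-data generator

Because no raw screen images are deposited, the generator is a
first-class module producing every downstream input with known ground
truth. Cells are discs with disc nuclei and an annular perinuclear ring -
deliberately simple morphology, since the statistics rather than cell
shape are under test. Per-siRNA effects are multiplicative shifts on the
latent drivers of the seven parameters (structure count, structure
amplitude, structure area), applied to a configurable penetrant fraction
of cells; null siRNAs have all shifts at 1.

Defaults emulate the study conditions: 384-position layouts with 16
negative controls, 3 (first screen) or 8 (validation screen) mocks, 4
INCENP, 8 LDLR and 8 NPC1 positive controls; 3-4 biological replicates
with 4 images per position; about 150 cells per image field for plate
assays. Intensity noise is layered multiplicatively - a plate x replicate
factor (log-sd 0.08), a position x replicate factor (log-sd 0.05), and a
per-image factor (log-sd 0.02) - plus per-cell sampling noise; the
position-level replicate factor is what the deviation statistic's
control-anchored SEM has to absorb. Edge effects are multiplicative per
region (defaults 0.85 / 0.95 / 1), the documented magnitude being this
artifact's choice since the original report documents only that region
normalization exists. Rendering adds Gaussian read noise of sd 2% of the
dynamic range by default (optionally Poisson shot noise); the camera model
is not described in the original work. Absolute intensity scales are
arbitrary; only relative effects are meaningful.

What the generator does *not* emulate: realistic cell morphology,
confluent monolayers (fields are sub-confluent by construction),
segmentation-error regimes, z-stacks, or transfection biochemistry.
Passing recovery tests therefore demonstrate the correctness and
calibration of the statistics on data satisfying the model's assumptions,
not robustness to real-world segmentation failure.

## Secondary assays

The decision rules are conjunctive throughout, so removing any
sub-criterion can only increase the number of calls (asserted by ablation
on synthetic tables):

* **Enzymatic cholesterol** (`enzymatic_call()`): replica mean deviating
  > 2 sd from the pooled negative controls AND two t-tests (vs control
  siRNA and vs mock) both p < 0.05.
* **HuH7 validation** (`huh7_fc_call()`): ≥ 50 quantified cells per
  experiment (under-counted replicas are excluded; none left means
  *untestable*, a distinct state from not-significant), deviation outside
  the control mean ± 2 SEM interval, and per-replica t-tests p < 0.05 in
  at least two replicas.
* **LDLR mRNA** (`ddct_fold_change()`, `ldlr_mrna_call()`): technical
  triplicates are averaged on the CT scale, ΔCT = CT(LDLR) − CT
  (housekeeper), ΔΔCT subtracts the calibrator mean, fold = 2^−ΔΔCT,
  computed separately for GAPDH and ACTB. A call requires the > 2-sd
  criterion on both normalizations and four t-tests (vs untreated and
  mock, per housekeeper) all p < 0.01. The original control SDs (0.21
  GAPDH, 0.20 ACTB) are accepted as configuration to reproduce the rule
  verbatim, or recomputed from supplied controls.
* **LDLR protein** (`normalize_densitometry()`, `ldlr_protein_call()`):
  band densities are normalized within each gel to the average of its
  control lanes (making the call invariant to rescaling a gel), then the
  same 2-sd + four-t-test conjunction applies on both the absolute and
  tubulin-normalized scales (original SDs 0.13 / 0.18).
* **Overexpression** (`classify_transfection()`,
  `overexpression_fc_effect()`): the untransfected bound is the 97th
  percentile of the mock GFP distribution - the only reading of "< 97% of
  mock transfected cells" that yields a threshold - and transfected cells
  exceed 4 x that bound; intermediates are excluded. Filipin ratios
  (transfected vs untransfected in-dish, and vs mock) are averaged over
  replicas, with stars from the count of replicas at p < 0.01 and a
  per-cell filipin-vs-log(GFP) regression slope as the
  concentration-dependence trend.

All t-tests default to Welch's unequal-variance form (the original text
says only "two-sided Student's t-test"); a `pooled` flag restores the
pooled-variance form. In the gene x assay summary matrix, two concordant
flagged siRNAs print `+`/`-`, one prints `(+)`/`(-)`, and discordant
flagged siRNAs print `-/+` (the discordance symbol has no stated
quantitative rule; two flagged siRNAs with opposite directions is the
rule here).

## Fingerprints, functional groups, loci

`build_fingerprint()` assembles the 2 x 7 matrix of mean deviations for a
gene's two strongest siRNAs (ranked by |deviation| on `total`, best assay,
ties broken lexicographically by siRNA id) with per-entry significance
flags identical to re-applying the effector rule - an internal-consistency
invariant of the tests. The original clustering into functional groups was
explicitly tentative and its method unstated; this package instead fixes
deterministic sign-pattern rules on the flagged `total` entries
(both assays same sign -> co-correlated; FC only -> FC-only; opposite
signs -> inverse; LDL only -> LDL-only; nothing flagged -> unclassified),
preferring reproducibility over an unstated heuristic. Locus summaries
(`locus_summary()`) treat gene-to-lead-SNP windows as closed ±50 kb
intervals on the annotation's 1-based coordinates and count loci with more
than one effector gene; no liftover is performed.

## Problem sizes, determinism, limitations

Every simulation is a pure function of its inputs and a single integer
seed; screen-level runs split one master seed per stage and record it in
the report provenance. The validation suites run at the sizes chosen for
this package's own test design: full 384-position layouts with 3
replicates for null-calibration (20-50 seeds) and effector-recovery (5-10
seeds; 10 effector genes of 3 siRNAs among 90 null genes, shifts 0.6 /
1.6 on total intensity), 10-20 noise-free rendered scenes for the imaging
oracle, and 20-50 seeded tables per secondary assay.

Known limitations: the deviation error estimator is an interpretation (see
above); hit calling is threshold-based and unadjusted for the number of
parameters (as in the original design); the empirical FDR is this
package's addition; and imaging accuracy claims are established on
synthetic, sub-confluent disc-cell scenes.
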