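---
title: "Methods: from segmentation volumes to phenotype subgroups and hazards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from segmentation volumes to phenotype subgroups and hazards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurophenoclust)
```

## The problem

Patients with manifest arterial disease accumulate heterogeneous brain
abnormalities — atrophy, white matter hyperintensities (WMH), lacunes,
cortical and subcortical infarcts, reduced cerebral blood flow. Analysing
each marker separately discards the pattern in which they co-occur. This
package implements a combined analysis: quantify all markers per patient,
cluster patients into MRI phenotype subgroups, and estimate each
subgroup's hazard of future ischaemic stroke and (vascular) mortality
against a merged low-burden reference.

Because no patient-level data are distributed, a synthetic generator
stands in for the cohort at every stage; each stage is validated against
analytic phantoms or brute-force oracles instead of against the original
scans.

## Morphometry

**Volumes and fractions.** Tissue volumes are voxel counts times the voxel
volume. Total brain volume is white matter + grey matter + WMH + infarcts;
intracranial volume (ICV) adds the lateral ventricles and peripheral CSF.
Fractions are percentages of ICV, so brain parenchymal fraction,
peripheral-CSF fraction and ventricular fraction sum to 100 by
construction (a property the tests enforce on random inputs). Cerebral
blood flow is expressed per 100 ml of brain — the usual convention when
flow is reported "as a fraction of brain volume"; the reference volume is
a parameter.

**WMH classification.** Each connected WMH lesion (26-connectivity) is
periventricular/confluent (CPWMH) when any of its voxels lies within 3 mm
(boundary inclusive) of the lateral-ventricle surface, and deep (DWMH)
otherwise. Distances are Euclidean in millimetres on the anisotropic grid,
measured against the ventricle boundary voxels. The any-voxel rule makes a
confluent lesion that reaches the ventricle margin periventricular, which
is the intended semantics; a majority-vote rule is available
(`rule = "majority"`).

**Shape features.** Lesions are resampled to an isotropic grid (nearest
neighbour, edge = smallest in-plane spacing) before meshing: 4 mm slices
would otherwise distort areas and box counts. The surface mesh is obtained
by marching tetrahedra at iso-level 0.5 over a 3×3×3 box-smoothed copy of
the binary mask. The smoothing matters: on a digital ball of radius 10 mm
the binary-field mesh overestimates the analytic area by ~28%, the
smoothed-field mesh is within ~2%. Lesions so thin that the smoothed field
never reaches 0.5 fall back to the binary mesh and are flagged; isolated
single voxels get voxel-face areas.

From the mesh and the voxel set we compute

* **solidity** = lesion volume / hull volume, where both are voxel
  volumes: the hull volume counts the voxel centres inside the convex hull
  of the lesion's voxel centres, so a convex voxel set scores exactly 1
  (mixing a voxel numerator with a mesh denominator biases the ratio a few
  percent either way);
* **convexity** = hull mesh area / lesion mesh area, both mesh-based for
  the same reason;
* **concavity index** = 2 − convexity − solidity, zero for a convex body
  and increasing with irregularity — the simplest statistic with the
  conventional direction, since no formula is fixed by convention;
* **eccentricity** = √(1 − λ_min/λ_max) of the second-moment matrix of the
  voxel coordinates (0 = sphere, →1 elongated); coplanar lesions use the
  top two moments;
* **fractal dimension** = box-counting slope of log N(ε) against
  log(1/ε) on the boundary voxel set.

The convex hull is an in-package incremental (quickhull-style)
implementation — no 3D computational-geometry package ships with the
analysis stack — validated in the tests against exhaustive
facet-enumeration oracles.

**Box-size ladder.** The default ladder is dyadic (1, 2, 4, 8, 16 voxels)
restricted to sizes at most one eighth of the largest extent. The cap is a
scaling-regime requirement: with fewer than ~8 boxes along the longest
axis the counts saturate towards the embedding dimension, and a filled
cube's boundary then measures ~2.2–2.4 instead of 2. With the cap, a
64³ cube boundary measures 2.11 and a 1-voxel segment measures exactly
1.0. Explicit ladders are honoured as given — the Menger-sponge level-2
set (a 9³ grid, 400 voxels) with sizes {1, 3, 9} reproduces
log 20 / log 3 ≈ 2.727 exactly. Sets that leave fewer than three usable
scales return `NA` with a flag rather than a silent default; on cohorts
this reproduces the realistic pattern that small deep lesions often have
no defined FD.

Patient-level summaries are unweighted means per feature within each WMH
class, plus pooled per-class FDs (all voxels of a class pooled before box
counting); a class with no lesions is flagged missing rather than zeroed,
which is what produces the deep-WMH missingness downstream.

## Feature matrix

The clustering feature set is: the five volume fractions; CPWMH and DWMH
fraction per lobe (ICV denominator, so lobe fractions partition each
class's total); the five shape means with separate pooled FD per class;
lacune/cortical/subcortical infarct counts plus per-lobe indicators and
counts; and normalized CBF — 31 columns. Lobes are the four classical
lobes (frontal, parietal, temporal, occipital), configurable.

Normalization is mixed: columns declared normally distributed are
Z-scored; all others are affinely mapped so the observed minimum is 0 and
the maximum 2 (binary indicators land on {0, 2}). Which columns are
"normal" is declared in configuration (`default_normality()`), not decided
by a data-dependent test, to avoid silent switching; the defaults Z-score
the volume fractions, shape means and CBF. Every scaling is recorded and
invertible. Missing entries are filled with the column's
post-normalization centre (0 for Z-scores, the observed median for 0–2
columns), which is neutral in the Ward distance; complete-case analysis is
a flag.

## Clustering and cut selection

Ward clustering uses the minimum-variance criterion with Euclidean
distances in the `ward.D2` convention (heights √(2·ΔSS)); the tests verify
the merge sequence and heights against an exhaustive greedy oracle.
Cut levels k = 2..20 are scored by the average silhouette width and the
Dunn index (minimum single-linkage separation over maximum cluster
diameter), and the chosen k maximizes the rank-sum of the two — a
composite, because the original procedure blended the quantitative indices
with visual heatmap inspection; `force_k` reproduces a human choice.
Subgroups are renumbered by ascending mean age, youngest first.

## Synthetic cohort

The generator works directly in normalized feature space: published
subgroup tables give group contrasts, not raw generative distributions, so
centroids are specified in normalized units. Defaults are chosen once:

* 1003 patients in 11 subgroups sized 46–188;
* centroid profiles qualitatively mirroring the published phenotypes
  (four low-burden groups, two limited-burden, cortical-infarct, lacunar,
  small-vessel-disease, multi-burden, neurodegenerative), each carrying a
  small subgroup-specific signature bump in one fully observed feature so
  that the low-burden profiles are not near-collinear, then rescaled so
  the minimum pairwise centroid separation is 6 normalized units;
* within-subgroup dispersion 0.5 per feature. This makes the planted
  11-group partition the dominant structure. The profiles form three
  coarse branches (low burden, infarct-dominated, atrophy/WMH-dominated);
  with substantially larger within-group noise, the silhouette genuinely
  prefers the three-branch cut, and the premise of a well-separated
  11-subgroup cohort no longer holds;
* ages Normal(59, 10) truncated to 25–82 years, with subgroup-specific
  shifts so age-based renumbering is well defined; 75% male;
* missingness mirroring the published pattern: 38.5% for deep-WMH FD and
  eccentricity — applied structurally to the patients with the least
  deep-WMH burden, because "no deep lesion" is what makes the features
  undefined (applying it at random splits high-burden subgroups into
  imputed/observed halves, an artefact of uniform missingness, not of the
  data) — plus 6.4% (blood flow) and 0.4% (other shape means) at random.

What the generator does **not** emulate: correlated feature noise,
heavy-tailed marker distributions, measurement drift, and any spatial
structure (the feature-space cohort has no images). Recovery results
(adjusted Rand index ≥ 0.9, k = 11 selected across seeds) therefore show
the procedure is correct and stable under the stated conditions, not that
eleven subgroups would be recovered from arbitrary clinical data.

## Subgroup statistics

Continuous variables: ANCOVA — `value ~ covariates + subgroup`, overall
F-test on the subgroup block, all pairwise contrasts with Bonferroni
correction over the number of pairs. Skewed variables can be natural-log
transformed first; zero-inflated ones are offset by half the smallest
positive observed value. Discrete variables: multinomial logistic
regression with subgroup as the outcome (so each non-reference subgroup
gets an odds ratio with a Wald 95% CI, the published layout) and a
likelihood-ratio test for the overall feature effect; perfect separation
is flagged with an unbounded CI. The default covariate set is age and sex,
with an age-only switch, reflecting that both adjustments appear in the
source material. Both tests hold their nominal type-I error within
[0.03, 0.07] at α = 0.05 in 1000-replicate null simulations.

## Survival

Follow-up records are coded per outcome: overall mortality; vascular
mortality (deaths by myocardial infarction, stroke, sudden death,
congestive heart failure, aneurysm rupture or other vascular cause, with
other deaths censored at the death time); ischaemic stroke (non-fatal
strokes leave the patient at risk for the mortality outcomes — a
decision the source leaves open). Cause-specific Cox models with the
Efron tie correction (Breslow by flag) estimate hazard ratios per
subgroup against the merged reference 1+2+3+7, adjusted for age and sex,
with normal-approximation 95% CIs; subgroups without events are flagged
non-estimable rather than reported. The generator plants one latent
exponential time per outcome with rate h₀·exp(offset + 0.08·(age−59) +
0.3·male), administrative censoring at 15 years plus exponential dropout —
a cause-specific view matching the analysis models. Parameter recovery
(planted HR 4, n = 1000, ≈200 events): mean HR within 10%, CI coverage
0.95 ± 0.04 over 200 replicates; a hand-written partial-likelihood grid
search reproduces small-fixture coefficients to 3 decimals.

## Numerical choices and degenerate inputs

* Tolerances: hull visibility scales with the bounding-box diagonal
  (~1e-7 relative); validity indices and Ward heights are exact to
  floating precision against their oracles.
* Ties: Ward ties resolve to the lowest pair index; rank-sum ties in cut
  selection to the smaller k; renumbering ties by original label.
* Degenerate inputs error early and specifically: empty lesions, constant
  feature columns, ICV = 0, duplicate patient ids, unknown segmentation
  labels, reference subgroups absent, events before the scan date.
* Problem sizes used by the test-suite experiments: 10 seeded cohorts of
  1003 patients for cut-selection recovery; 200 replicates of n = 1000
  for Cox recovery; 1000 replicates for test calibration; phantoms up to
  64³ voxels. These sizes give Monte-Carlo error comfortably inside every
  asserted tolerance.

## Known limitations

* The concavity-index and eccentricity formulas are declared conventions;
  other definitions exist and would shift Table-2-style values without
  changing the pipeline.
* Surface areas inherit a ~2% voxelization bias even after smoothing;
  convexity is accordingly accurate only to a few percent on small
  lesions.
* The frequency maps require a common grid; no registration is performed.
* The synthetic cohort is a calibration instrument, not a reconstruction
  of the study data; its subgroup contrasts are loosely calibrated to the
  published summaries.
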