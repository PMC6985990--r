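# neurophenoclust

Data-driven MRI phenotypes of the brain, and what they mean for outcome.
Patients with manifest arterial disease carry mixtures of brain
abnormalities — atrophy, white matter hyperintensities (WMH), lacunes,
infarcts, reduced cerebral blood flow — that are usually analysed one
marker at a time. This package implements the combined analysis as a
tested pipeline:

1. **Morphometry** — from 3D segmentation label volumes: tissue volumes,
   intracranial-volume fractions (BPF = total brain / ICV, in %),
   normalized cerebral blood flow, classification of WMH into
   periventricular/confluent (≤ 3 mm from the lateral ventricles) versus
   deep lesions via an exact anisotropic distance transform, and per-lesion
   3D shape features from isosurface meshes and convex hulls:

   * solidity `V / V_hull`, convexity `A_hull / A`,
     concavity index `2 − convexity − solidity`,
   * eccentricity `sqrt(1 − λ_min/λ_max)` of the voxel second moments,
   * box-counting fractal dimension (slope of `log N(ε)` vs `log 1/ε`).

2. **Feature matrix** — 31 markers per patient, Z-scored when declared
   normal, otherwise scaled to [0, 2]; invertible scaling records;
   centre imputation.

3. **Clustering** — Ward minimum-variance linkage (`ward.D2` heights
   `sqrt(2·ΔSS)`), dendrogram cut chosen by the average silhouette width
   and the Dunn index, subgroups renumbered youngest-first; dendrogram,
   heatmap and per-subgroup WMH frequency maps.

4. **Subgroup statistics** — age(/sex)-adjusted ANCOVA and multinomial
   logistic regression with Bonferroni correction.

5. **Survival** — cause-specific Cox models (Efron ties) for overall
   mortality, vascular mortality and ischaemic stroke versus the merged
   low-burden reference subgroups {1, 2, 3, 7}: `HR = exp(β)` with
   Wald 95% CIs, rendered as a forest plot.

6. **Synthetic cohort generator** — analytic shape phantoms (ball,
   ellipsoid, dented ball, segment, Menger-sponge level set), whole-head
   segmentation phantoms, feature-space cohorts with planted subgroup
   structure, and survival records with planted proportional hazards — so
   every stage is testable without patient data.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables to `results/`. A condensed session:

```r
library(neurophenoclust)

co   <- simulate_cohort(cohort_spec(seed = 20260))      # 1003 patients, 11 planted subgroups
nm   <- impute_missing(normalize_features(co$features))
tree <- ward_linkage(nm)
sel  <- select_k(tree, nm, k_range = 2:20)
sel$k
#> [1] 11

asg <- renumber_by_age(cut_ward(tree, sel$k), co$meta$age)
table(asg$labels)
#>   1   2   3   4   5   6   7   8   9  10  11
#> 188  95 149  99  85  80  67  65  69  46  60

meta <- co$meta; meta$subgroup <- asg$labels
rec <- simulate_survival(meta, hazard_spec(seed = 2015))
hz  <- fit_cox(rec, reference = c(1, 2, 3, 7))
subset(as.data.frame(hz), outcome == "ischaemic_stroke" & subgroup == "10")
#>             outcome subgroup       hr   ci_low  ci_high        se n_events estimable
#> 20 ischaemic_stroke       10 17.61521 9.055139 34.26734 0.3395052       25      TRUE
```

Reading the output: the cut-selection procedure recovers the 11 planted
subgroups; subgroup sizes span 46–188; and the multi-burden subgroup
(here numbered 10 by mean age) shows a strongly elevated stroke hazard
against the merged low-burden reference — the planted hazard ratio of
10.34 lies inside the estimate's 95% CI (9.1–34.3; only 25 stroke events
fall in this subgroup, hence the wide interval). `analysis/01_phantoms.R` prints
the shape-feature validation: a digital ball scores solidity 1.000,
convexity 1.000, concavity 0.000, eccentricity 0; a 20×5×5 mm ellipsoid
measures eccentricity 0.971 against the analytic 0.968; the Menger-sponge
level-2 set measures fractal dimension 2.727 = log 20 / log 3 exactly.

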