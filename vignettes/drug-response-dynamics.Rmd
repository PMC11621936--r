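---
title: "Methods: dynamic drug-response proteomics with rppadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic drug-response proteomics with rppadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppadyn)
```

## Scope and model

`rppadyn` analyses drug-perturbation experiments on cancer cell-line
panels profiled by reverse-phase protein array (RPPA), and carries the
markers such experiments nominate into survival analysis of patient
cohorts. The pipeline starts from per-spot intensities (image-level spot
detection is out of scope) and ends at forest tables of stratified
hazard ratios. Every stage consumes and emits plain tables, so each is
inspectable and independently testable.

The statistical model underlying each stage:

1. **Spot level.** A sample's replicate spots (tetraplicate by default)
   measure a common true level under multiplicative log-normal noise,
   with occasional gross errors (a bad spot, a print artefact). The
   level estimate is the replicate median after MAD-based outlier
   exclusion: values further than `k * 1.4826 * MAD` from the median
   (default `k = 3.5`, the conventional robust cut) are excluded. The
   rule is skipped when the MAD is zero and all replicates agree;
   when the MAD is zero with unequal values, only values equal to the
   median survive, which is the conservative literal reading of the
   rule.
2. **Normalisation.** Antibody staining efficiencies differ by orders
   of magnitude, and total printed protein varies by sample. Dividing
   by the antibody's median control-MIX level removes the former;
   median-centring each sample in log2 space removes the latter. The
   scheme is deliberately simple and auditable — the published
   amplification-era protocols it stands in for are external — and it
   is isolated behind one function so a different scheme can be
   substituted. It is exactly invariant to rescaling an antibody
   together with its controls, and preserves within-sample rank order
   of antibodies after control division.
3. **Time courses.** Fold changes are taken against the same series' t
   = 0 sample (the design samples t = 0 per condition, so vehicle
   subtraction is not needed): `log2fc(t) = log2(I(t) / I(0))`, with
   `log2fc(0) = 0` by construction. Series lacking a t = 0 sample are
   skipped and reported rather than imputed.
4. **Kinetic classification.** Classes are defined by peak timing, not
   direction: *early* peaked by 6 h, *intermediate* by 12 h, *late* by
   24 h, *none* flat. Because up- and down-regulation are both
   responses, clustering uses |log2fc| vectors; direction remains
   available in the underlying tables. Following the two-step
   convention, K-means (default k = 7, 10 restarts, best
   within-cluster sum of squares) groups the courses and each centroid
   is mapped to a class, which propagates to members. A direct
   per-course mode exists for testing and for noiseless data.
5. **Dose response.** Viability profiles are summarised by GI50 (first
   downward crossing of 50% viability, interpolated linearly in log10
   dose — the pharmacological convention, since curves are
   approximately logistic in log dose) and by AUC (trapezoid of the
   viability fraction over log10 dose, divided by the log-dose span so
   AUC is in [0, 1] and scale-free across drugs). Full four-parameter
   logistic fitting is intentionally not performed: interpolation
   suffices for GI50 and avoids fit instabilities on 3-dose designs.
6. **Sensitivity segregation.** Lines are sorted by log10 GI50 and
   split at the largest adjacent gap; the lower block is sensitive.
   Right-censored GI50s (never reaching 50% inhibition) are resistant
   by definition, left-censored ones sensitive, and the gap search runs
   over finite values only. A fixed threshold can override the rule.
7. **Contrasts.** Responsive-versus-flat contrasts between groups use
   the two-sided Fisher exact test (sum of hypergeometric probabilities
   not exceeding the observed table's); copy-number loss burdens are
   compared with an exact Mann–Whitney U (full enumeration up to
   combined n = 12, tie-corrected normal approximation beyond).
   Correlation rankings report Pearson r with the t-distribution p on
   n − 2 degrees of freedom; ranked outputs carry a Benjamini–Hochberg
   q column as auxiliary information but are ordered by r, not q.
8. **Survival.** Kaplan–Meier product-limit curves with Greenwood
   errors; log-rank tests; unadjusted univariable Cox models with Efron
   tie handling (tabulated months produce heavy ties). "5-year" rates
   read the step function at 60 months. Markers are dichotomised at the
   median with ties assigned to the negative group.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `time_grid_h` | 0, 3, 6, 12, 24 | hours | five points over 24 h; 6/12/24 must be on the grid to express the class windows, 3 h is the early interior point |
| `replicates` | 4 | spots | tetraplicate printing |
| `amplitude_log2` | 2 | log2 units | a 4-fold peak change, typical of strong phosphoprotein responses |
| `noise_sd_log2` | 0.25 | log2 units | replicate-level scatter of well-behaved RPPA data |
| `outlier_rate` | 0.01 | fraction | occasional gross spot failures, modelled as ×10 spikes |
| `flat_threshold` | 0.25 | log2 units | changes below ~19% are not treated as responses |
| `k`, `restarts` | 7, 10 | — | seven clusters grouped into four classes; restarts stabilise the optimum |
| loss/gain cutoffs | ≤ 1 / ≥ 3 | copies | one copy lost/gained on a diploid baseline |
| `censor_rate` | log(2)/240 | per month | mild independent censoring on top of a 120-month administrative horizon |
| `median_surv_months` | 60 | months | control-arm median survival of an advanced-cancer cohort |

## The synthetic world

The generator emulates, with ground truth recorded for every entity:
the printed-slide geometry (12 conditions × 5 time points × 8 cell
lines × 4 replicates plus 80 control spots = 2000 spots per slide, one
slide per antibody); time courses drawn from the four kinetic
archetypes — unit-height Gaussian bumps in log2-time centred at 6, 12
and 24 h, scaled by the amplitude, signed at random, with additive
Gaussian noise after t = 0; sigmoidal viability curves (4-parameter
logistic, top 100, bottom 0) with known midpoints; diploid genomes with
a planted shared-loss region confined to one group plus sporadic
background events; and cohorts with exponential event times,
stratum-specific treatment hazard ratios, and independent exponential
censoring. All randomness derives from a single root seed through named
substreams, so adding a generator never perturbs another's draws, and
identical configurations reproduce byte-identical outputs.

What it does **not** emulate: slide-to-slide batch effects, antibody
cross-reactivity, spatial artefacts within slides, dose–time
interactions beyond the archetype scaling, correlated censoring, or
covariate-dependent marker distributions. A green test on this world
therefore establishes that the estimators recover planted structure
under idealised noise — not that they are robust to the systematic
artefacts of real arrays.

## Numerical and design choices

- **Flat detection by peak prominence.** A centroid of absolute fold
  changes carries a uniform positive offset from folded noise
  (E|ε| = σ√(2/π) ≈ 0.4 log2 units at σ = 0.5), so thresholding the raw
  maximum would misclassify every flat cluster. Flatness is therefore
  judged on peak prominence — the maximum minus the post-baseline
  minimum — which cancels any uniform offset while leaving genuinely
  peaked profiles untouched.
- **Known limitation of the two-step mapping.** When flat courses
  dominate (≳ 90%) and k exceeds the number of distinct kinetic
  shapes, K-means splits the flat cloud along noise directions and the
  selected sub-centroids acquire spurious peaks of about 1.6 σ, near
  the flat threshold; and at amplitude-to-noise ratios near 4 the
  within-cluster optimum can place a "bridging" centroid between
  adjacent archetypes that absorbs members of both. Group contrasts at
  moderate sample sizes are then attenuated. The direct per-course mode
  and lower-noise regimes do not exhibit the artefact; with the default
  noise the mapping recovers all four classes essentially perfectly.
- **Exact Fisher p values are super-uniform.** Being discrete and
  conservative, the two-sided exact p has a null distribution
  stochastically larger than uniform (mean ≈ 0.53 at 200-per-arm
  margins); goodness-of-fit tests against exact uniformity will often
  reject even for a correct implementation. Near-uniformity is the
  property that holds and is what calibration checks should target.
- **Ties and degenerate inputs.** Peak-time ties classify to the
  earliest time ("peaked by"); median-split ties go to the negative
  group; all-equal GI50s label everything sensitive with a warning;
  zero-margin 2×2 tables return p = 1; constant vectors are errors for
  correlations and skipped with a warning in screens; complete
  separation in Cox fits is flagged and the interval reported
  unbounded. Efron tie handling means exact replication of a data set
  shifts the hazard ratio slightly (it would be exactly invariant under
  Breslow); this is accepted as the cost of better tie behaviour on
  month-resolution data.
- **Loss "loci" count events, not segments:** adjacent qualifying
  segments merge before counting, so re-segmentation does not inflate
  counts. Coordinates are 1-based inclusive; regions absent from a
  profile are imputed diploid with a warning.
- **Responsive-vs-none dichotomy** is used for the 2×2 kinetic
  contrasts; pooling courses across antibodies and cell lines treats
  courses as units, which overstates independence when cell lines are
  few — a per-line stratified variant is a natural extension and the
  pooled p values should be read as screening statistics.

## What the tests establish

The suite validates: the slide-count and course-count identities (2000
spots; 96 series × 202 antibodies → 19,392 courses); agreement of the
exact-test engines with brute-force enumeration oracles over all small
tables and rank splits; exact recovery of noiseless planted structure
(archetypes, GI50 round trips, region-confined losses); detection power
and calibration on planted effects (kinetic-class recall, depletion
contrasts, planted hazard ratios with interval coverage and log-rank
type-I error); and byte-level reproducibility of the pipeline under a
fixed seed.
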