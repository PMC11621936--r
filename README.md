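# rppadyn

Dynamic phospho-proteomic drug-response analysis for cancer cell-line
panels, with survival stratification of patient cohorts.

## What this package is for

Panels of gastric-cancer cell lines are routinely profiled by
reverse-phase protein array (RPPA): lysates collected at several time
points after drug exposure are printed in replicate spots on slides, one
slide per antibody, so that hundreds of (phospho)protein time courses
can be read out per cell line and drug condition. Interpreting such
experiments requires a chain of standard but fiddly steps — replicate
aggregation, control-based normalisation, fold-change assembly, kinetic
classification, dose-response summarisation, copy-number association,
and survival analysis of the clinical markers the cell-line work
suggests. `rppadyn` implements that chain as composable, tested
functions, together with a synthetic-data generator that produces every
input with recorded ground truth, so the whole pipeline can be
exercised and validated without access to restricted data.

The core quantities:

- **Replicate aggregation.** A sample's level is the median of its
  replicate spots after excluding outliers with
  |x − median| > 3.5 · 1.4826 · MAD.
- **Normalisation.** Each intensity is divided by the antibody's median
  control-MIX level, then samples are median-centred in log2 space.
- **Kinetic classes.** Each time course's log2 fold change from t = 0 is
  classified as *early* (peaked by 6 h), *intermediate* (by 12 h),
  *late* (by 24 h) or *none* (flat), via K-means (k = 7) on
  |log2FC| vectors with cluster centroids mapped to classes.
- **GI50.** The 50% growth-inhibitory concentration, estimated as the
  first downward crossing of 50% viability by log-linear interpolation;
  profiles never reaching 50% are right-censored. AUC is the normalised
  trapezoidal integral of viability over log10 dose. Cell lines are
  segregated sensitive/resistant at the largest gap in log10 GI50.
- **Exact tests.** Two-sided Fisher exact p (sum of hypergeometric
  probabilities ≤ that of the observed table) for responsive-vs-flat
  and loss-vs-group 2×2 contrasts; exact (enumerated) Mann–Whitney U
  for small count comparisons.
- **Survival.** Kaplan–Meier product-limit curves, log-rank tests, and
  unadjusted Cox proportional-hazards ratios (Efron ties) for
  marker-stratified treatment contrasts, subgroup tables and per-gene
  hazard screens with median-split dichotomisation.

## Worked example

```r
library(rppadyn)

# synthetic slide set: 8 cell lines, 4 drugs x 3 doses, 30 antibodies
cfg <- sim_config(seed = 42, n_antibodies = 30)
st  <- gen_spot_table(cfg)                       # 30 slides x 2000 spots
q   <- quantify_spots(st$spots)                  # tetraplicate -> levels
mat <- normalize_intensities(q$matrix, q$controls)
courses <- assemble_timecourses(mat)             # 96 series x 30 antibodies
length(unique(courses$course_id))
#> [1] 2880

cl <- classify_courses(courses, k = 7, seed = 42)
table(cl$class)
#>        early intermediate         late         none
#>          436          439          272         1733

# dose-response calls for one drug across the panel
doses <- 10^seq(-2, 2, 0.5)
gi50s <- c(0.4, 0.6, 0.5, 0.3, 0.7, 45, 60, 80)  # planted truth
calls <- do.call(rbind, lapply(1:8, function(i) {
  pr  <- gen_dose_response(gi50s[i], doses, noise_sd = 2, seed = i)
  est <- compute_gi50(pr$dose, pr$viability_pct)
  data.frame(cell_line = sprintf("line%02d", i), gi50 = est$gi50,
             censored = est$censored,
             auc = compute_auc(pr$dose, pr$viability_pct))
}))
segregate_by_gi50(calls)[, c("cell_line", "gi50", "label")]
#>   cell_line   gi50     label
#> 1    line01  0.386 sensitive
#> ...
#> 6    line06 45.149 resistant
```

The five lines with planted GI50 near 0.5 are called sensitive and the
three near 50 resistant: the largest-gap rule recovers the planted
bimodal structure. A cohort with a treatment effect confined to the
marker-positive stratum is analysed the same way:

```r
co <- gen_cohort(658, hr_by_stratum = c(`TLC-` = 1, `TLC+` = 0.46),
                 seed = 42)$cohort
subgroup_analysis(co, "stratum", "arm", arm_levels = c("surgery", "S-1"))
#>   stratum   n n_events    hr    lo   hi        p
#> 1    TLC- 330      222 1.094 0.840 1.42 0.505104
#> 2    TLC+ 328      193 0.601 0.452 0.80 0.000486
```

The planted hazard ratio of 0.46 in the marker-positive stratum is
recovered (point estimate 0.60, CI 0.45–0.80 here at n ≈ 330 per
stratum), while the null stratum stays at HR ≈ 1.

`run_pipeline(demo_config(seed = 1), "out/")` chains all stages
(simulate → quantify → gi50 → dynamics → correlate → cnv → survive),
writes every intermediate as TSV plus a ground-truth JSON sidecar, and
returns a manifest; reruns with the same seed are byte-identical.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: a full demo
pipeline run, the slide-layout spot count, the 96 × 202 time-course
assembly, kinetic-class recovery on ~4000 labelled courses, GI50
recovery under 5% viability noise, and a planted hazard-ratio scenario,
logging each quantity and writing the JSON result file.
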