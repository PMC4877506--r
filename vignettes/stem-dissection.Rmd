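---
title: "Stem-based virtual dissection: model, phantom and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem-based virtual dissection: model, phantom and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemdissect)
library(dplyr)
```

## 1. The stem-based dissection model

A whole-brain tractogram represents white-matter pathways as polylines
("streamlines") in world (scanner) millimeter coordinates. The package
isolates the inferior fronto-occipital fasciculus (IFOF) and the
uncinate fasciculus (UF) through their *anatomical stems* — the compact
bottlenecks lateral to the external capsule through which every fiber
of the tract passes. A stem ROI is a binary mask confined to a single
slice: coronal for the IFOF (its stem runs anteroposteriorly) and axial
for the UF (its stem hooks vertically).

The workflow has three phases, each an explicit function with an
auditable tally:

1. `prepare_tractogram()` removes artifactual or out-of-scope
   streamlines from the whole-brain set, in a fixed order: (1) shorter
   than `min_length_mm` (default 10 mm), (2) confined to cortical gray
   matter (CGM), (3) superficial U-fibers that traverse only CGM and
   superficial white matter (SWM) and never enter deep white matter
   (DWM), (4) entering cerebellum or brainstem, (5) crossing the
   mid-sagittal plane x = 0. A streamline removed by several rules is
   attributed to the first, so the rule tally partitions the removed
   set exactly.
2. `expose_stem()` + `suggest_stem_slice()` support drawing the stem
   ROI: exposure hides streamlines whose endpoints obscure the stem
   (insula and temporal pole for the IFOF; insula and superior temporal
   gyrus for the UF), and the slice suggester scans a slice range for
   the narrowest occupied cross-section of the remaining bundle.
   Externally drawn masks enter via `read_stem_roi()`. Extraction never
   uses the exposed set — it always runs on the original tractogram.
3. `extract_tract()` keeps every original streamline intersecting the
   stem mask, then applies *least-constraint* rules
   (`extraction_rules()`): drop streamlines traversing an exclusion
   label set, drop streamlines reaching beyond an exclusion half-space
   (e.g. a coronal plane posterior to the external capsule for the UF).
   Endpoints are then labeled on a modally dilated atlas. Endpoints in
   the insula or subcortical nuclei are flagged *excluded from
   analysis* (recorded, not counted as cortical terminations);
   endpoints still in white matter or background are flagged *broken*.

### Termination statistics

For each subject and cortical region, the normalized termination
density score is

NTDS(region) = terminations in the region / all streamlines of the
tract across *both* hemispheres,

so scores are comparable across subjects with different streamline
yields, and hemispheric scores for one tract share a denominator.
Broken streamlines stay in the denominator by default — they passed the
stem, so they are evidence of the tract's size even though their
cortical target is unknown (`discard_broken = TRUE` reverses this).

A *false-positive region* — one known to contain no true terminations
of the tract — calibrates the noise floor: the presence threshold is
mean + 2 × sample SD of that region's NTDS over the cohort
(hemispheres pooled by default). Threshold-adjusted scores
(`adjust_ntds()`) retain negative values so location tests see a
complete paired sample; *presence* means adjusted score > 0.

`territory_test()` asks, per region × hemisphere, whether the adjusted
scores are located above zero (one-sided Wilcoxon signed rank).
`asymmetry_index()` is AI = (R − L)/(R + L) on NTDS, undefined (NA) at
0/0; `asymmetry_test()` runs one-sample location tests on per-subject
AIs.

### Stem morphometry

`stem_summary()` reduces a stem ROI to volume and center of mass
(optionally mapped through an affine to a standard space);
`com_distance()` gives per-axis and Euclidean COM separations;
`interoperator_report()` computes paired volume statistics and mean COM
distance between two operators' masks; `stem_volume_anova()` fits the
sex × tract × hemisphere mixed ANOVA (subject as the random factor,
tract and hemisphere within-subject) with `tidy()`/`glance()` methods.
`stem_reference_coordinates()` ships a small built-in reference table
of stem volumes and standard-space COMs from two operators, used in the
examples to illustrate the between-tract contrasts (the IFOF stem sits
dorsal and slightly lateral to the UF stem).

## 2. The phantom

`build_phantom_atlas()` rasterizes a deterministic labeled volume
(60 × 72 × 60 voxels at 2 mm, RAS+ with the grid centered on the
origin) containing, per hemisphere: a deep-white-matter core; anterior
and posterior SWM ribbons; anterior gyral bands (temporal pole, orbital,
inferior/middle/superior frontal, precentral) and posterior bands
(superior temporal, lingual, middle occipital, superior parietal);
insula; subcortical nuclei; cerebellum/brainstem. Two voxels of
background separate the hemispheres across x = 0, and every label
carries hemisphere, lobe, tissue class (CGM/SWM/DWM/other) and terminal
side (anterior/posterior set) in its label table.

`simulate_subject()` generates a seeded cohort member containing:

- **Designed tracts.** For each tract and hemisphere,
  `n_per_hemisphere` streamlines are drawn: an anterior and a posterior
  termination region sampled from the tract's designed probability
  vectors, a path threaded through the tract's designed stem voxel, and
  sub-voxel jitter. Ground truth records each streamline's tract,
  hemisphere and sampled regions.
- **Broken streamlines.** A `broken_fraction` of each tract's
  streamlines is truncated at one end (chosen at random), which then
  stops inside SWM/DWM. The expected NTDS of a region with designed
  probability *p* on one side is therefore
  0.5 × (1 − broken_fraction/2) × p: the hemisphere share, times the
  probability that the relevant end survived truncation, times *p*.
- **Decoy classes**, each engineered to be removed by exactly one
  preparation rule (short fragments, CGM-confined, U-fibers,
  cerebellar, inter-hemispheric) plus **stem-bypass** decoys that
  funnel through a waist *near* the stems without touching either stem
  mask — they survive preparation and test the specificity of the stem
  intersection itself.

Determinism: each subject's generator seed is a fixed arithmetic
function of the cohort seed and the subject index, so any subject can be
regenerated in isolation.

### Three simulator levels

Validation uses the cheapest level that exercises the code under test:

1. **Geometric** (`simulate_subject()`): full streamlines; exercises
   IO, preparation, exposure, stem suggestion and extraction.
2. **Count-level** (`simulate_termination_tables()`): multinomial
   termination tallies drawn directly from the designed probabilities;
   exercises NTDS, thresholds, territory and asymmetry machinery at
   cohort scale cheaply.
3. **Summary-level** (`simulate_stem_summaries()`): per-subject stem
   volumes and COMs for two operators with designed hemisphere/tract
   effects; exercises morphometry, inter-operator agreement and the
   ANOVA.

## 3. Numerical conventions

These choices are load-bearing; tests pin each one.

- **Voxel ownership.** World points map through the inverse affine to
  0-based continuous voxel coordinates; voxel *i* owns
  `[i − 0.5, i + 0.5)` per axis (`floor(v + 0.5)`). Boundary points
  belong to the upper voxel.
- **Exact traversal.** `classify_streamlines()` does not sample the
  polyline at a fixed step. Each segment is swept analytically: the
  parameters at which it crosses any half-integer boundary plane are
  enumerated, and the label is read at the midpoint of every
  inter-crossing interval. Fixed-step sampling — even at half a voxel —
  can miss a voxel whose traversal interval is shorter than the step
  (corner clips); the analytic sweep cannot. Stem-*hit* detection in
  `extract_tract()` and `suggest_stem_slice()` intentionally keeps the
  conventional half-voxel sampling of the drawing/selection workflow.
- **Mid-sagittal crossing** is decided on vertices: a piecewise-linear
  path attains its x extremes at vertices, so it reaches both sides of
  x = 0 iff some vertex is strictly negative and some strictly
  positive. (A sign-product test on consecutive samples fails when a
  sample lands exactly on 0.)
- **Modal dilation.** One pass assigns to each background voxel with a
  nonzero 26-neighbor the most frequent neighboring label; ties break
  to the lowest label id, making the operation deterministic. Endpoint
  lookups use the dilated atlas; traversal uses the undilated one.
- **Slice suggestion ties** go to the lower slice index; slices crossed
  by no streamline are ignored rather than treated as zero-width
  minima.
- **TRK geometry.** TRK stores corner-origin voxel-mm coordinates:
  `world = vox_to_ras %*% (p / voxel_size − 0.5)` on read, inverted on
  write. TCK stores world mm directly (Float32, NaN-separated).
- **Wilcoxon conventions.** The territory test drops exact zeros and
  uses the exact signed-rank null up to n = 25 when |values| are
  untied; otherwise the normal approximation with continuity and tie
  correction. Ten all-positive distinct values give exactly
  p = 1/1024.
- **Bonferroni divisor.** Both the territory and asymmetry tests divide
  α by the number of *non-degenerate* tests (regions whose values are
  not identically zero, and with at least `min_n` subjects for the
  asymmetry test); degenerate regions are reported with p = 1 and never
  significant.
- **Degenerate-data guards.** `fp_threshold()` with a single value uses
  SD = 0; paired t statistics on constant differences return t = 0,
  p = 1; ANOVA strata with zero effect (error) sums of squares return
  F = 0 (F = ∞) rather than NaN.

### Small-sample conservatism

NTDS values are ratios of small counts, so ties are common and the
signed-rank test usually runs in normal-approximation mode. An
all-positive sample of n subjects then has a floor on its p-value
(≈ 0.0029 at n = 10, ≈ 0.0013 at n = 12); with ~20 non-degenerate
regions, the Bonferroni cutoff of α/20 = 0.0025 is unreachable below a
dozen subjects. This is expected statistical behavior, not a defect:
territory detection is designed for cohorts of ~15 or more subjects, at
which point all designed territories are recovered (see the cohort
example in the README, n = 30).

## 4. Worked cohort run

```{r pipeline, eval = FALSE}
out <- run_pipeline(list(n_subjects = 12, seed = 7,
                         n_per_hemisphere = 150),
                    out_dir = "run7")
names(out$tracts)
# "IFOF" "UF"
```

The run directory contains the resolved YAML config, the per-subject
preparation and extraction tallies, and per-tract NTDS, adjusted-score,
presence, territory and asymmetry tables, plus `summary.json` and a
log. `scripts/acceptance.R` (in the source repository) replays the full
validation against the installed package and writes every computed
quantity to JSON.

## 5. Limitations

- The phantom is rectilinear and axis-aligned: it validates logic and
  conventions, not registration, curvature-dependent tractography
  biases, or partial-volume effects.
- The preparation filters assume an accurate tissue-labeled atlas in
  the tractogram's space; no registration is performed.
- The false-positive threshold trusts the choice of FP region; a region
  with true terminations inflates the threshold and deflates presence
  everywhere.
- Asymmetry indexes on near-floor regions are noisy (counts of 0–3):
  with small cohorts, occasional spurious significant asymmetries in
  floor regions are possible and should be judged against the designed
  effect sizes.
- TRK support covers version-2 files without per-point scalars or
  per-track properties beyond reading them as padding; TCK support
  covers Float32LE data.
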