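---
title: "Decoding binocular and monocular cues to surface gloss: models and methods"
author: "glossMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding binocular and monocular cues to surface gloss: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glossMVPA)
```

# The scientific problem

When a glossy object is viewed with two eyes, the specular reflections
do not stick to the surface: because a mirror image lies optically
behind (or in front of) the surface, the two eyes receive reflections
with a disparity that differs from the surface's own disparity.  This
binocular signature of gloss can be manipulated in rendering while
leaving each monocular image almost unchanged, which makes it a clean
probe for asking where visual cortex represents surface material as
opposed to 3-D shape.  glossMVPA implements the full experimental
chain for studying this question in simulation: the stereoscopic
stimulus manipulations, a block-design BOLD simulator with
controllable representational structure, and the multivoxel pattern
analysis (MVPA) used to read out gloss and shape information —
leave-one-run-out linear support-vector decoding, cross-decoding
transfer, signal-detection indices, permutation-null thresholds, and
searchlight mapping.

# Stimulus rendering

## Geometry and the four disparity conditions

The object is a "potato": a sphere whose radius field is modulated by
a seeded sum of smooth low-order angular cosine modes
(`makePotato()`).  The modulation is normalized so the relative
distortion never exceeds the `amplitude` argument; amplitudes are
restricted to [0, 0.5) so the radius stays positive and the surface
remains star-shaped about its centre.  The renderer evaluates this
radial field exactly (ray marching plus bisection along each primary
ray) rather than intersecting the triangulated export, so surface
points and normals are accurate to well below a micrometre at the
default 650-mm viewing distance.  Eyes sit 65 mm apart; the imaged
object subtends roughly 7 degrees; the environment map is treated as
at optical infinity, so its lookup depends only on direction.

All four conditions cast primary rays from the true eye positions
through a shared image plane — the stereo frustum of the surface is
identical across conditions.  Only the direction used to sample the
environment differs (`renderCondition()`):

* **mirror** — each eye's own reflected ray, `omega = 2 (n.V) n - V`
  with `V` pointing from the surface to that eye: physically correct
  specular reflection.  (Printed forms of this equation sometimes
  carry the opposite sign convention for `V`; the implementation
  follows the physical law, which the test suite checks as an
  angle-equality property to 1e-12.)
* **painted** — both eyes sample along the reflection of the
  *cyclopean* (mid-point) view vector, so the reflection pattern gets
  exactly the surface's own disparity, like a texture painted on.
* **anti-mirror** — the two eyes' reflected rays are exchanged at
  each surface point, producing physically wrong disparities that
  nevertheless preserve the monocular images.
* **flat** — one eye's mirror image (seeded coin flip, recorded in
  the pair's metadata) is shown to both eyes; reflection and surface
  disparity are both abolished.

Each rendered pair carries per-pixel metadata (surface points,
normals, lookup directions) so these defining identities are testable
exactly rather than by visual inspection.

## The monocular glossy/matte pair

The non-stereoscopic session's stimuli are produced by highlight
rotation (`makeMonocularPair()`): the object is rendered once from
the cyclopean viewpoint as two separable layers — a Lambertian
diffuse base and a specular layer (the environment reflection raised
to a power so it concentrates into highlights).  Compositing the
specular layer in place yields the glossy image; rotating it by 45
degrees about the image centre (masked to the object silhouette)
yields the matte image.  Rotating the highlights breaks their
congruence with shading and silhouette, which is what abolishes the
gloss impression.  Rendering the layers separately replaces the
interactive colour-range extraction used historically for this
manipulation; it is exactly reproducible, but it is a stand-in — no
claim is made that it reproduces any particular image-editing tool's
pixels.  Angles are reduced modulo 360 degrees, so a full turn is an
exact identity.

# The synthetic BOLD model

## Design arithmetic

`makeDesign()` builds the session timing: 16 experimental blocks of
16 s per run (four conditions, four repeats, seeded pseudo-random
order), seven 16-s fixation blocks (first, last, and after
experimental blocks 3, 5, 8, 11, 13), TR 2 s.  The binocular session
appends a 2-s response window to each experimental block, giving a
scheduled run length of 400 s (200 volumes); the non-stereoscopic
session has none and schedules to 368 s.  Binocular run counts are
drawn uniformly from 7–10 per subject, non-stereoscopic from 8–10.

## Voxel populations

`simulateSubject()` places ellipsoidal ROIs of exactly `nVoxels`
voxels in a toy rectangular brain on the acquisition grid
(2.5 × 2.5 × 3 mm).  Each ROI's voxels are partitioned by the
`EffectModel` fractions into populations implementing the
shared-subpopulation hypothesis for gloss:

* *shared* voxels respond to gloss from either cue (mirror,
  anti-mirror, glossy);
* *mono-only* voxels respond only to monocularly cued gloss;
* *bino-only* voxels respond only to binocularly cued gloss;
* *structure* voxels carry one fixed random multivoxel pattern for
  the disparity-3-D conditions (mirror, painted, anti-mirror) and an
  independent one for flat, so painted-vs-flat is decodable as a
  pattern without any univariate gloss confound.

Hemodynamics are a boxcar delayed by 4 s with a 1-TR linear rise —
deliberately matched to the analysis, which shifts windows by exactly
4 s and averages 8 volumes; a canonical double-gamma response would
only blur block edges that the averaging ignores anyway.  The 2-s
response windows are modelled as rest.  Noise is i.i.d. Gaussian in
percent-signal units (an AR(1) toggle exists; the MVPA stages do not
model autocorrelation, so white noise is the default).  A subject's
geometry and population assignment depend only on the subject seed,
not the session, so binocular and non-stereoscopic datasets of one
subject share voxels — the prerequisite for cross-session transfer.

What the generator does *not* emulate: spatial noise correlations,
motion, physiological drift beyond the injectable global sinusoid,
anatomical variability, and any nonlinearity between neural
population overlap and voxel responses.  Passing tests therefore
certify the analysis chain's arithmetic and statistical calibration
on data whose ground truth is known — not that real cortex behaves
like the model.

# The analysis chain

## Preprocessing contract

`qcRuns()` excludes a run when the variance of its whole-brain-mean
percent-signal time course exceeds 0.23.  `selectVoxels()` ranks ROI
voxels by the all-vs-fixation two-sample t statistic over shifted
windows and keeps the top 250 (or all voxels with t > 0 if fewer);
using only the all-vs-fixation contrast keeps selection independent
of every decoded contrast, preserving cross-validation validity.  The
t contrast is computed directly on shifted block windows rather than
through a GLM with nuisance regressors; no nuisance model is part of
the contract, and the direct form is deterministic.
`extractPatterns()` z-scores each voxel's time course per run,
shifts block windows by 4 s, averages the 8 in-block volumes, and
subtracts each block pattern's across-voxel mean.

Two readings of "subtracting the mean for each time point" exist:
per-pattern across voxels (the cocktail-blank, the default here — it
is the reading that removes run and condition baseline offsets at the
pattern level) and per-voxel across patterns within a run (available
as `normalization = "timepoint_mean"`).  z-scoring is per run, which
removes run offsets before patterns are compared across runs; a
per-session alternative would leave run baselines in the patterns
that the later mean subtraction only partially removes.

## Decoding

`trainClassifier()` fits a maximum-margin linear separator (hinge
loss, soft-margin cost fixed at 1 — the conventional default; the
analysis contract does not specify a value) by dual coordinate
descent with liblinear-style shrinking, implemented in compiled code.
The solver re-permutes its visiting order each epoch with an internal
fixed-seed generator, so results are bit-reproducible; the permutation
machinery performs hundreds of thousands of fits, which is why the
solver is compiled rather than delegated.  The test suite
cross-checks its boundaries and predictions against an independent
SVM implementation on random data.  With `balance = TRUE` (the
default) per-class penalties scale as `n/(2 n_class)`, the class-
weight adjustment used for two-vs-one contrasts.  Decision-value
ties classify as the positive class — deterministic and measure-zero.

Accuracy is reported *class-balanced*: the mean of the two per-class
correct rates from fold-pooled confusion counts.  For every
one-vs-one contrast this equals the plain fraction correct.  For the
two-vs-one contrast it is the definition that actually removes class-
size bias: empirically (and for an independent SVM implementation as
well), a weighted soft-margin SVM trained on 2:1 data still predicts
the majority class about 55–60% of the time on pure noise, so the
plain-accuracy null is centred near 51.7–52.2% rather than 50%.
Balanced accuracy restores an exactly centred null for any prediction
bias, which is what the permutation analysis requires.

`crossValidate()` runs leave-one-run-out folds (a fold whose training
set lacks a class is skipped with a warning); `transferDecode()`
trains once on one contrast and tests once on another, mapping the
test contrast's positive class onto the training one's, and refuses
mismatched voxel lists.  For cross-session transfer, voxels are
selected once from the training session's all-vs-fixation contrast
and applied to both sessions; a per-session-selection alternative
would break feature alignment.

## d-prime and the two indices

`dprime()` converts pooled confusion counts to `z(H) - z(F)` with
rates clipped to `[1/(2N), 1 - 1/(2N)]`; perfect decoding of 28
patterns per class thus maps to `2 qnorm(55/56) = 4.20`.  The
convention (fold-pooled counts, 1/(2N) clipping) is one of several in
use; the permutation baselines it produces are validated against
printed reference values below, and the alternative `2 z(accuracy)`
can be obtained by symmetrising the confusion counts.  The **gloss
index** is `d'(MA_vs_P) - d'(M_vs_A)` and the **3-D structure index**
is `d'(P_vs_F) - d'(M_vs_A)`: mirror-vs-anti-mirror serves as the
baseline because its two conditions share both appearance and
approximate 3-D structure.

## Permutation nulls

`permutationNull()` builds the null of the *across-subject mean*
statistic: per repetition, condition labels are shuffled within each
run (independently per subject and ROI), the statistic is recomputed,
subjects are averaged, and the one-tailed 95th percentile of the
repetition means is the threshold; with several ROIs, per-ROI
thresholds are averaged.  For an accuracy null, only the labels of
the conditions entering the tested contrast are permuted — the
exchangeability null matched to that test.  On null data this is
indistinguishable from shuffling all four conditions jointly
(boundaries agree to about 0.1 percentage points), but on data with
effects in *other* conditions it matters: a joint shuffle would mix
response-carrying patterns into the null's test sets and
miscalibrate the threshold for the contrast under test.  The index
null, whose two terms deliberately share one shuffle, permutes all
four conditions jointly.  The across-subject-mean construction is the
one that yields group thresholds in the 52–53% range for this design
(per-subject thresholds sit near 60%).

The default convention shuffles the labels *per test*: classifiers
are trained once on the true labels and each repetition re-scores
their fixed decision values against re-drawn test labels.  Two
empirical signatures motivated this reading over retraining on
shuffled labels each repetition (also available, `shuffle = "full"`):
retraining couples the folds through shared training data and widens
the group null by roughly a quarter (pushing a 1-vs-1 boundary from
about 53.1% to about 53.9%), and only the fixed-classifier
construction explains why a transfer boundary can sit *below* the CV
boundaries — a fixed, class-biased model shrinks the within-run
label-matching variance.  Repetition seeds are drawn once from the
master seed, so shorter runs are prefixes of longer ones and
everything is bit-reproducible.

The index null re-uses one within-run shuffle for all three contrast
terms of a repetition; coupling the terms through a shared shuffle
keeps the shared `d'(M_vs_A)` baseline correlated between the two
index terms, which narrows the difference null relative to
independent shuffles.  The resulting 95% baselines land near 0.19
(gloss) and 0.20 (structure) for a null cohort of this design —
close to, but a little above, the printed reference values of 0.14
and 0.16, which depend on an unstated d-prime convention and
shuffle coupling; the acceptance suite treats them as approximate
references with a ±0.10 band.

## Group statistics

`groupTest()` is a one-sample, one-tailed t test of per-subject
statistics against a baseline (typically a permutation threshold),
Bonferroni-corrected over ROIs.  `compareIndicesAnova()` runs the
2 (index) × 15 (ROI) within-subject ANOVA — for 12 subjects the
index effect has df (1, 11) and the ROI and interaction effects
(14, 154) — followed by Tukey HSD on the 30 index-by-ROI cell means
using the interaction-stratum mean square.

## Searchlight

`sphereNeighborhoods()` enumerates, for every in-mask voxel, the
in-mask voxels within 8 mm centre-to-centre, respecting the
anisotropic voxel dimensions; on the 2.5 × 2.5 × 3 mm grid an
interior sphere contains 113 voxels (the test suite checks this
against brute-force lattice enumeration).  `searchlightMap()` re-runs
the leave-one-run-out decoder on each sphere's voxels — spheres are
the feature set, so the top-250 selection is skipped — and assigns
the accuracy to the centre.  `groupClusterThreshold()` tests each
voxel's accuracies against chance (0.5, one-tailed t), forms
clusters of significant voxels under 26-connectivity, and removes
clusters smaller than 4 voxels — the grid-native analogue of a
25 mm² cortical-surface criterion (4 × 6.25 mm² in-plane), kept as a
parameter.  Null cross-validated accuracy at sphere-sized feature
counts is slightly pessimistic, so the test against 0.5 is mildly
conservative — a property inherited from testing accuracies against
nominal chance rather than against a per-voxel permutation null.

# Study conditions and problem sizes

The synthetic study conditions follow the experimental design: 12
subjects, 7–10 binocular and 8–10 non-stereoscopic runs drawn
uniformly, 4 conditions per session, 1,000 permutation repetitions
for null thresholds.  Quantities the design does not fix were chosen
once: simulated ROIs of 40–60 voxels (large enough that the top-k
selection with its t > 0 fallback acts, small enough that a
12-subject, 1,000-repetition null finishes in seconds — group-level
null boundaries depend on pattern counts, not voxel counts), three
ROIs for ROI-averaged thresholds, and 1% signal amplitude against 1%
noise for effect simulations unless a test needs a specific
signal-to-noise ratio.  The acceptance script uses exactly these
conditions.

# The transfer-asymmetry emulation

The shared-subpopulation account predicts that cross-session transfer
is carried by voxels responsive to gloss from both cues.  With a
linear readout and session-specific voxel selection, the direction of
any transfer asymmetry is governed by *dilution*: training on the
session whose informative voxels are mostly non-shared spreads the
weights (and calibrates the decision boundary) over voxels that are
silent in the other session, so transfer succeeds from the
concentrated session toward the diluted one.  Reproducing the
observed direction — monocular-to-binocular transfer succeeding, the
reverse weaker — therefore requires the *binocular* session to be the
diluted one (shared = 5%, bino-only = 25%, mono-only = 0 in the
acceptance suite's configuration; with mono-only dominant the
direction reverses, and the mono-trained boundary often degenerates
to a single predicted class).  The package tests the direction of the
asymmetry and the shared-voxel mediation (a shared-only model
transfers essentially perfectly in both directions at moderate SNR),
not its magnitude.

# Numerical choices and degenerate inputs

* Solver: dual optimality tolerance 0.01, iteration cap 2,000;
  deterministic for identical inputs.  Duplicated training sets leave
  a separable boundary unchanged (checked to 1e-8 at tight
  tolerance).
* A voxel constant within a run z-scores to zeros rather than NaN.
* Shuffles preserve the per-run condition multiset (four patterns per
  condition per run), keeping folds balanced under permutation.
* Degenerate group tests (all subjects identical) return t = 0 rather
  than failing.
* `quantile()`'s default (type 7) empirical percentile is used for
  thresholds; at 1,000 repetitions the choice moves a boundary by
  well under 0.05 percentage points.
* Rendering: ray marching uses 48 steps plus 30 bisections per pixel;
  normals are central differences at 1e-3 mm.  One primary ray per
  pixel, no interreflection — consistent with an environment at
  optical infinity.

# Known limitations

The simulator's noise model is white and spatially independent, so
permutation thresholds here are cleaner than on real scanner data;
the searchlight's test against nominal chance is conservative at
small sphere sizes; the printed index-null baselines are reproduced
only approximately (convention-dependent); and the renderer aims for
geometric fidelity of the disparity manipulations, not photorealism.
Real-data properties that depend on the trained classifier's
class-prediction bias (for example, how far a transfer null boundary
sits below the CV boundaries) are reproduced in direction but not
magnitude by null simulations.
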