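---
title: "Co-activation pattern dynamics: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activation pattern dynamics: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Co-activation pattern (CAP) analysis treats every volume of a resting-state
BOLD series as a snapshot of a momentary brain state. Given parcellated time
series (frames x parcels, one matrix per subject per day), frames from many
subjects are pooled and clustered by spatial similarity with k-means; the
cluster centroids are the CAPs, and each frame belongs to exactly one CAP.
From the per-frame state sequence, three temporal measures summarise a
subject-day for every CAP:

* **Fractional occupancy (FO)** — kept frames in the state divided by all
  kept frames; sums to 1 across CAPs within a subject-day.
* **Mean dwell time (mean DT)** — mean length (in TRs) of the maximal
  consecutive segments spent in the state.
* **Var DT** — the standard deviation of those segment lengths (population
  form, so a single segment yields 0 rather than an undefined value; a
  sample-SD switch exists via `var_dt_type`).

Motion scrubbing removes frames whose framewise displacement exceeds 0.5 mm
(strictly greater — a frame exactly at the threshold is kept). Scrubbing is
applied as a mask at clustering and metric time, never by physically
deleting frames, so frame indexing stays valid for diagnostics. Segments on
either side of a scrubbed gap merge when they occupy the same CAP; this
shortens some dwell times ([I,M,I] with M scrubbed gives DT 2, not 3) and
joins some distinct episodes ([I,II,I] with the middle frame scrubbed also
gives DT 2). These identities are asserted verbatim in the test suite.
Segments never span a day boundary; by default they also break at run
boundaries within a day, since concatenated runs are not contiguous in time
(configurable via the `run` argument of `extract_segments()`).

## Split-half permutation engine

A single k-means fit on the full cohort yields one value per subject and no
way to gauge its sampling stability. The engine instead repeats, for each of
`n_perm` permutations: (1) split subjects into two disjoint halves (one
subject randomly dropped when N is odd); (2) pool each half's scrub-masked
frames; (3) scan k-means solutions over a k range (k-means++ seeding, Lloyd
iterations capped at 1000, convergence at a relative inertia change below
1e-4, best of 5 restarts); (4) score each k by the mean silhouette width on
a seeded 1500–2000-frame subsample (the full pairwise distance matrix over
all pooled frames would be quadratic in memory for no detectable gain in the
k decision); (5) pick k-hat by the silhouette-elbow rule. Per-subject
temporal metrics are computed inside every permutation from the k-hat
solution's frame assignments, and a ledger records memberships, k-hat,
centroids and metrics — not per-frame labels, which would dwarf everything
else stored.

The elbow rule range-normalizes the silhouette-versus-k curve and takes the
point of maximum positive distance above the chord joining the endpoints
(ties toward smaller k). A curve with no point above the chord — e.g. a
strictly linear decline — has no knee; the rule then falls back to the
silhouette argmax with a warning. The multi-restart k-means is not optional
polish: with a single initialization the silhouette curve is non-monotonic
enough that the knee wanders even on a clean 4-state cohort.

## Basis CAPs, matching and the delta-occurrence statistic

Centroids from all permutations that produced the same k-hat are stacked and
clustered (Ward linkage, Euclidean) into k groups; each group's parcel-wise
mean, z-scored across parcels, is a basis CAP. The pipeline pools both
splits for its final basis (a group- and permutation-average reference) and
reports per-split bases and their matched correlations separately as a
reproducibility check (`basis_cross_split_similarity()`).

Estimated CAPs are labeled against a basis by a greedy one-to-one
assignment on the Pearson correlation matrix over parcels: repeatedly take
the globally largest unused (estimated, basis) pair. Pearson (not Spearman)
is used because spatial similarity is measured as Pearson correlation
everywhere else in the workflow; a Spearman option exists behind
`method = "spearman"`. On realistic instances — estimated CAPs that are
noisy copies of basis CAPs, including anti-correlated pairs — the greedy
assignment agrees with the exhaustive optimum in well over 95% of trials
(tested); a fully random correlation matrix can defeat any greedy rule, but
that regime does not arise when matching CAPs that share a common origin.

When two solution sizes compete (k and k+1), each subject's preference for
the extra CAP is the **delta occurrence**: per split, the count of
permutations (containing the subject) that yielded k+1 minus those that
yielded k; averaged over splits and z-scored across subjects. Permutations
with other k-hats (rare larger solutions do occur) count toward neither
side but stay in the ledger.

## State-trait statistics

Day-to-day reliability is quantified per CAP and metric by Pearson
correlation across subjects between day-1 and day-2 permutation-averaged
values, and by ICC(2,1) — the two-way random-effects, single-measure,
absolute-agreement intraclass correlation computed from explicit ANOVA mean
squares. Undefined cases (zero total variance) raise a typed condition
(`capdyn_icc_undefined`) rather than returning a sentinel, so distributional
summaries can skip and count them. Subjects whose values are zero on both
days — a CAP structurally absent for them — are excluded from reliability,
but contribute zeros to the feature matrix; both aggregation conventions are
emitted (`absent_as_zero` argument) because mixing them up silently biases
either the reliability or the geometry.

The three-axes table places each CAP in (CV of FO, CV of mean DT, CV of
var DT) space per day, where CV is the across-subject coefficient of
variation (sample SD over mean). The between-day displacement of a CAP in
this space reads out its within-subject (state) variance; the position reads
out the between-subject (trait) variance.

## Feature space and dimension reduction

The per-subject feature matrix has a fixed schema: 3 metrics x k CAPs x 2
days (30 columns for the canonical five-CAP set), absent CAPs as zeros.
Columns are z-scored before clustering and PCA because FO is a fraction
while DT measures are in TRs; the unstandardized variant is available
(`standardize = FALSE`). Subgroups come from Ward/Euclidean hierarchical
clustering cut at 70% of the final merge height. The 70% figure follows the
Methods-level statement of the source procedure; a conflicting 7% appears in
one figure caption of that work, so the fraction is exposed as `cut_frac`
rather than hard-coded. Note a structural consequence of cutting below the
final merge: at least two clusters always result, so a literal "single
cluster" outcome only arises in the degenerate all-identical-subjects case,
which returns one cluster with a warning.

Neural PCA reports loadings, scores, variance explained, and — per
component — the Pearson correlation between the day-1 and day-2 halves of
its loading vector. A component with strongly negative between-day loading
correlation is a "day-flip" component carrying day-to-day state variance;
the sign convention (largest-magnitude loading positive) makes all outputs
deterministic.

## Behavioral analysis and the association model

Reaction-time variables are transformed to 1/RT (so larger is better
everywhere), then all variables are centered and unit-scaled; a provenance
attribute makes double preparation an error. PCA significance uses a
permutation null in which subject order is shuffled independently within
each variable: this breaks inter-variable correlation while preserving
marginals. (Shuffling whole rows would permute subjects jointly and leave
the correlation structure — and hence the eigenvalue spectrum — untouched,
a vacuous null.) p-values use the add-one estimator, so they live in
(0, 1] and are exactly calibrated at the permutation resolution.

The association model is ordinary least squares of one behavioral component
on the neural component scores plus age and sex. Each predictor's partial
R-squared is the proportional reduction in residual sum of squares when it
enters the model, equal to its squared partial correlation (asserted against
that independent formulation in the tests). Cross-validation refits both
PCAs and the regression on a random half and scores held-out R-squared on
the other half projected into the half-specific component spaces; the null
shuffles held-out scores. Subgroup comparisons are Welch two-sided t-tests
with Bonferroni correction over the explicit family (components x subgroup
pairs), with the family size recorded in the output because a correction
whose family is implicit cannot be audited.

## The synthetic cohort generator

The generator emulates exactly the structure the analysis assumes, with full
ground truth for recovery tests:

* **Spatial patterns** — five z-scaled parcel patterns: two anti-correlated
  pairs (`I-` is the sign flip of `I+`, likewise `II`) and one extra
  pattern `III`. Frames are `snr x pattern + N(0, 1)` noise per parcel,
  i.i.d.; spatial noise autocorrelation is out of scope because the
  clustering operates on spatial profiles, for which i.i.d. noise suffices
  to test recovery.
* **Markov switching** — per subject-day transition matrices with baseline
  self-transition 0.8 (expected dwell 5 TRs at TR 0.72 s). Trait variance:
  per-subject, per-state logit effects `~ N(0, trait_sd)` (default 0.8).
  State variance: per-day perturbations `~ N(0, day_sd)` (default 0.25).
  Sequences start from the stationary distribution, so expected FO equals
  the stationary probability and expected dwell is `1/(1 - T_ii)` — the
  closed forms the recovery tests check against.
* **Subgroups** — a fraction (default 0.3) of subjects, subgroup C, carry
  state III in their chains; everyone else never enters it. Subgroups A and
  B differ by a persistence shift (default 0.7 on the self-transition
  logits) so the feature geometry has recoverable structure beyond the
  presence of III.
* **The extra state renders at half the base amplitude**
  (`extra_state_snr = 0.5`). This is the deliberate emulation of a weakly
  expressed, unstable extra CAP: at full amplitude every split detects it
  and the k decision is unimodal at 5; at half amplitude detectability
  depends on how many subgroup-C subjects a split happens to contain, and
  the split-half permutations become bimodal between 4 and 5 — the
  phenomenon the mixed cohort exists to reproduce. The bracketing sweep
  (0.35 rarely detected, 0.55 detected in most splits) is what fixed 0.5.
* **Motion** — FD is a low-motion floor (|N(0.15, 0.05)| mm) plus
  Bernoulli spikes (rate 0.02, magnitude ~0.8 mm), so a realistic few
  percent of frames exceed the 0.5 mm threshold.
* **Behavior** — latent per-subject factors are computed from the
  generating chains (CAP-I-versus-II stationary-occupancy contrast, overall
  persistence, state-III occupancy); behavioral variables are linear
  combinations of these factors plus unit Gaussian noise and per-variable
  sex loadings; a configurable subset is emitted as positive
  reaction-time-like variables to exercise the 1/RT transform.
* Simulated runs contain no dummy frames (the generator emits steady-state
  signal), so synthetic pipelines run with `n_dummy = 0`; dummy-frame
  removal is exercised on constructed fixtures instead.

What passing recovery tests on this generator shows — and what it does not:
the pipeline correctly recovers planted spatial patterns, occupancy
structure, reliability ordering and planted neuro-behavioral links under
Gaussian i.i.d. noise and exact Markov switching. It does not certify
behaviour under hemodynamic smoothing, spatially correlated noise,
non-Markov state dynamics, or real-data artifact structure.

## Problem sizes and numerical choices

Defaults: 20 subjects, 64 parcels, 2 runs x 200 frames per day, TR 0.72 s.
Heavy experiments scan k over 2:8 rather than 2:15 — the planted cohorts
have 4–5 states and the silhouette knee sits well below 8, so the larger
range adds cost without changing a single k decision (verified on planted
cohorts). The recovery study runs 50 permutations; the mixed-cohort study
runs 100 permutations on a 30-subject cohort — at 30% that gives 9
subgroup-C subjects, enough for a two-sample comparison of delta-occurrence
scores, while the per-split C count still varies enough to drive the 4-vs-5
bimodality. The reliability calibration uses 60 subjects, 600-frame runs
and `trait_sd = 1`, sized from a power argument: between-subject
stationary-FO spread (~0.16 SD) must dominate the within-day FO sampling
error over ~1200 frames (~0.04 SE) for the day_sd = 0 condition to pin the
ICC near its theoretical ceiling (~0.94).

Other numerical decisions: k-means converges on relative inertia change
below 1e-4 (capped at 1000 Lloyd iterations); empty clusters trigger
re-seeded retries (5) before erroring; zero-variance frames in
correlation-mode assignment fall back to the Euclidean rule and are
flagged; ties in the greedy matcher break toward the lower basis index;
ties in the knee rule break toward smaller k; all derived seeds stay below
2^31.

## A worked run

```{r example}
library(capdyn)

sim <- generate_cohort(sim_config(seed = 1))
res <- run_cap_pipeline(
  sim$cohort,
  behavior = sim$behavior, behavior_meta = sim$behavior_meta,
  n_perm = 50, k_range = 2:8, seed = 42,
  reference_patterns = sim$ground_truth$patterns
)
res
res$k_occurrence          # occurrence rates of each estimated k
res$reliability           # day-to-day r and ICC(2,1) per CAP x metric
autoplot(res$basis)       # z-scored basis CAP patterns
plot_three_axes(res$three_axes)
tidy(res$behavior$association)
```

## Known limitations

* The silhouette subsample (not the full frame pool) scores each k; the
  subsample size is recorded and configurable, but exact silhouette values
  shift slightly with it.
* The greedy matcher is not a Hungarian solver; it is the documented
  rank-ordered rule, optimal in the realistic matching regime and checked
  against exhaustive enumeration there.
* Behavioral cross-validation projects split-2 subjects onto split-1
  component spaces; refitting PCA on split 2 and aligning spaces is a
  different, unimplemented convention.
* The generator's noise model is spatially and temporally white; estimates
  of absolute silhouette levels or frame-to-CAP correlation magnitudes on
  real data will differ even when the recovery logic carries over.
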