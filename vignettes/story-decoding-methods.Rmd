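---
title: "Decoding attention and agent from story-reading fMRI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attention and agent from story-reading fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Subjects read short stories in which an agent — the reader ("self") or a
named third person ("other") — attends to something either endogenously
(deliberately looking for it) or exogenously (attention captured by it),
plus a nonsocial control in which the agent is an object. The question is
whether multivoxel activity patterns in theory-of-mind regions carry
information about the *attention type* and the *agent* described in the
story, even though the wording differences are minimal and task-irrelevant.
Because any univariate difference is expected to be tiny, the analysis is
multivoxel pattern analysis (MVPA): a linear classifier is trained to
separate conditions from trialwise activity patterns, cross-validated
across scanner runs, and tested at the group level against an empirical
null distribution.

`storymvpa` implements that full chain — trial scheduling, synthetic BOLD
with known ground truth, trialwise GLM, spherical ROI extraction,
leave-one-run-out SVM decoding, group permutation/bootstrap/FDR inference,
searchlight mapping, and the eye-movement control — as a tested R package
with numbered analysis drivers under `analysis/`.

## Trial design

Each run presents 10 trials (2 per condition, 5 conditions) with the order
randomized under the constraint that consecutive trials never share a
condition (rejection sampling; any constraint-satisfying sampler would do).
A run is 130 volumes at TR 2 s: 18 s lead-in baseline, then per trial a
10 s story and a 4 s probe statement, with 9–11 s inter-trial intervals,
and a 12 s closing baseline. These numbers force the ITIs of a run to sum
exactly to the residual run time (90 s for 10 trials), so the generator
draws ITIs uniformly on [9, 11] s and recentres the draw to the required
mean, redrawing until all values stay inside the range. This keeps every
stated invariant — the range, the 18 s first onset, the 130-volume run, and
the 12 s closing baseline — simultaneously; onsets are then rounded to the
millisecond. Timing that cannot fit a run raises an error rather than
being truncated.

## Synthetic BOLD with known ground truth

The generator exists so that every downstream stage has a testable truth.
For voxel $v$ the run time course is

$$ y_v(t) = \sum_{\text{trials } i} a(c_i, v)\,[B_i * h](t)
          + a_p [P * h](t) + d_v(t) + \varepsilon_v(t), $$

where $B_i$ is the 10 s story boxcar, $P$ the union of 4 s probe boxcars,
$h$ the canonical double-gamma HRF, $d_v$ a slow cosine drift, and
$\varepsilon_v$ Gaussian AR(1) noise with marginal SD `noise_sd` (default
1) and autocorrelation `ar1_rho` (default 0.3). The amplitude map is

$$ a(c, v) = a_0 + \tfrac12 \sum_{k} s_k \, z_k(c) \, w_{k}(v), $$

with one $\pm 1$ code $z_k$ per contrast (attention, agent, social,
attention × agent; the nonsocial condition codes 0 on the first two and the
interaction), pattern vectors $w_k \sim \mathcal N(0, 1)$ over voxels, and
pattern separations $s_k$ (`effect_spec()`). Two properties matter:

* $s_k = 0$ makes the two classes of contrast $k$ identically distributed,
  so decoding must sit at chance — the basis of the null-calibration tests;
* $w_k$ is drawn **once per subject** and reused in every run, so
  leave-one-run-out generalization is exactly what the decoder must do.
  A `signal_mask` can confine $w_k$ to one ROI, making "effect in this
  region only" a controllable truth.

Noise choices (AR(1) with $\rho = 0.3$, cosine drift with periods above
128 s, amplitude 0.5) are conventional for 3 T event-related data; the acquisition protocol fixes
only the timing, so these are package defaults, all exposed in
`effect_spec()`. What the generator does *not*
emulate: hemodynamic nonlinearity, physiological noise, head motion (motion
regressors are smooth random walks generated purely to exercise the GLM
interface), or spatial autocorrelation — so passing tests certify the
*pipeline*, not realism of any particular SNR claim about real brains.

## Trialwise GLM (least-squares-all)

First-level estimation uses a single joint model per subject: one boxcar
regressor per trial (100 under the full design), one probe regressor, one
intercept per run, and six motion regressors — 117 columns. Regressors are
convolved at dt = 0.1 s with the double-gamma HRF (peak 6 s, undershoot
16 s, dispersions 1 s, ratio 1/6, unit peak) and sampled at volume onsets.
The first three volumes of each run are discarded. The solver is plain OLS
by QR; a rank-deficient design falls back to the SVD pseudoinverse with a
warning naming the collinear columns. No autocorrelation prewhitening and
no high-pass filter beyond the run intercepts are applied (the drift the
generator injects is slow and largely absorbed by intercepts; a cosine-
regressor flag could be added, but the default mirrors the minimal nuisance
model). Tests pin the estimator to an explicit normal-equations solve at
1e-8 and to exact recovery (≤ 1e-6) of the generating amplitudes on
noiseless data.

## ROIs and pattern extraction

ROIs are spheres defined by an MNI center and radius (default 10 mm; the
six default centers are the bilateral TPJ and STS, MPFC and precuneus peaks
of a theory-of-mind meta-analysis). Sphere membership is by voxel center
without partial-volume weighting — the simplest defensible reading of
"center + radius" (the 10 mm sphere's true volume, ~4189 mm³, is taken at
face value over the rounder "~4000 mm³" description). Conversions round to
the nearest voxel with half-integers away from zero. Masks store voxels in
ascending column-major linear order, so extraction is deterministic,
insertion-order invariant, and a full-grid mask returns the beta matrix
unchanged. Overlapping ROIs are allowed but reported
(`roi_overlap_report()`). On a 2.5 mm lattice a 10 mm sphere centered on a
voxel contains 257 voxels; the test suite checks masks against a
brute-force distance scan.

## Decoding

The classifier is a linear SVM with C fixed at 1 — no feature selection, no
hyperparameter search. Within each leave-one-run-out fold, every feature is
z-scored with the training runs' mean and SD and the *same* transform is
applied to the held-out run (zero-variance training features are zeroed in
both sets); a test verifies that perturbing test rows cannot change the
training transform. Fold accuracy is the percentage of correctly classified
held-out trials; the subject statistic is the arithmetic mean over folds
("run-average accuracy"), never the pooled trial count. Exact decision
ties are assigned to the first class level — a documented, measure-zero
rule with continuous features.

The solver itself is a compact SMO (sequential minimal optimization) dual
solver in compiled code, solving the identical optimization as libsvm with
the unregularized bias recovered from the KKT conditions. Group permutation
inference needs on the order of $10^6$ classifier fits, so per-call
overhead dominates; the fold preparation (normalization and linear-kernel
Gram matrices) is label-independent and precomputed once, leaving each
permutation iteration only the SMO iterations. `e1071::svm` is the
independent cross-check in the test suite: decision values agree to ~1e-2
and predictions disagree only for points sitting on the margin within both
solvers' tolerances.

Derived statistics:

* **Cross-classification**: train endo-vs-exo on self stories, test on
  other stories, and vice versa; folds hold out one run of the *test*
  agent while training on the other agent's remaining runs (a
  `train_all_runs` flag switches to training on all runs). The two
  directional run-averages are averaged.
* **Interaction difference score**: accuracy(endo-self vs exo-self) minus
  accuracy(endo-other vs exo-other), in percentage points, chance 0;
  exactly antisymmetric under swapping the agents.
* **Searchlight**: for every voxel of an analysis mask, decode on the
  spherical neighborhood (Euclidean in voxel units; partial spheres at the
  edge allowed) and store the run-average accuracy at the center. The
  radius is a parameter recorded in the output (4 voxels = 10 mm on a
  2.5 mm grid when mirroring the ROI size; the desk-scale driver uses 2).
* **Univariate contrast**: mean over ROI voxels of the class-mean beta
  difference — the subtraction analysis the MVPA is meant to outperform.

## Group inference

The group statistic is the mean over subjects of the per-subject decoding
statistic. Its null distribution comes from repeating the identical
analysis with permuted labels: within each subject, class labels are
shuffled independently **within each run** — the most conservative
exchangeable scheme that preserves run balance and the fold structure —
and iteration $i$ pools the $i$-th permuted statistic across subjects into
one null group mean. For a binary contrast the binary labels of that
analysis' own trials are shuffled (the trial subset is fixed, which also
allows fold caching); for the interaction and cross-classification schemes
the four social labels are shuffled and the full statistic recomputed.
Labels are permuted on the beta series, not before the GLM — repeating
10,000 GLMs per subject would be both computationally prohibitive and
statistically equivalent for label-exchangeable trial estimates.

The p-value is $(1 + \#\{\text{null} > \text{true}\}) / (1 + N)$ — strict
inequality, ties count against rejection, minimum $1/(N+1)$ (0.0001 at the
default 10,000 iterations). A percentile bootstrap over subjects (default
10,000 resamples) gives the 95% CI; the method is the percentile interval,
chosen as the simplest standard option. Across ROIs, p-values are adjusted
with Benjamini–Hochberg FDR (`stats::p.adjust` behind the package surface,
pinned in tests to the brute-force step-up definition at 1e-12). An effect
is flagged significant only when the corrected p is below 0.05 **and** the
95% CI excludes chance. Eye-movement decoding and the univariate contrast
use one-sample t-tests instead, matching their simpler inferential role.

## Eye-movement control

Gaze samples (1000 Hz) are cleaned by flagging missing-pupil (blink)
samples plus 50 ms padding on each side (padding is a configurable default;
no interpolation), then smoothed with a centered 20 ms moving average over
valid samples only. The story display area is divided into an 8 × 4 grid of
32 equal cells; per trial the features are the proportion of valid in-grid
time per cell (32) plus the 32 × 32 directional cell-transition proportions
(1024), 1056 in total. "Saccades between regions" is operationalized as
consecutive-sample cell transitions — no velocity-based event detection,
since the features are defined directly on grid regions; same-cell pairs
are not transitions (zero diagonal) and pairs spanning a blink gap or
leaving the grid are not counted. Raw counts and a populated diagonal are
available by argument. Trial vectors are averaged per condition per run (40
vectors per subject under the full design) and decoded with exactly the
fMRI machinery (LORO folds, fold-wise z, SVM C = 1); group inference is a
one-sample t-test against 50%. The synthetic gaze generator draws fixation
target cells from per-condition weight vectors — uniform weights make gaze
independent of condition (the negative-control regime), while
`biased_gaze_weights()` gives each social condition a preferred cell block.

## Numerical and scale choices

* SMO stopping tolerance 1e-3 (libsvm's own default), iteration cap 1e5.
* FFT-based convolution leaves a ~1e-16 floor in "zero" regressor entries;
  tests use a 1e-10 causality tolerance.
* Desk-scale study conditions used by the drivers and heavier tests:
  6–8 subjects, 3–6 runs, grids of ~10³ voxels, ROI radii 5–6 mm,
  500 permutations and 1,000–2,000 bootstrap resamples. These sizes keep a
  full pipeline run in minutes on one CPU while leaving every statistical
  property testable; the full-design constants (10 runs, 130 volumes,
  10,000 iterations) are exercised where they are cheap (design, formula
  and worked-example tests).
* Default effect size for "signal present" demonstrations is a pattern
  separation of 1 at noise SD 1 — with ~30-voxel ROIs this decodes near
  ceiling, which is deliberately far from the marginal effect sizes of
  real data: the demonstrations test recovery and selectivity, not power.

## Known limitations

Accuracies near ceiling in the drivers reflect the chosen synthetic effect
size, not expected real-data performance (real story-decoding effects are
a few points above chance). The permutation scheme treats trials within a
run as exchangeable under the null; temporally structured confounds that
survive the GLM (e.g. strong beta autocorrelation from short ITIs) are
mitigated but not eliminated by within-run shuffling. The searchlight group
summary reports voxelwise uncorrected t-maps only — no cluster-level or
brain-wide familywise correction. Behavioral data get descriptive summaries
only, by scope.
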