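---
title: "Methods: test-retest reliability of emotional-conflict fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability of emotional-conflict fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflicticc)
```

## The scientific problem

Longitudinal task-fMRI studies — for instance biomarker studies that scan
patients before and during treatment — implicitly assume that the BOLD
response to a task is stable within a person over time. Whether that holds
must be measured, and the standard instrument is the intraclass correlation
coefficient computed across repeated scanning sessions. `conflicticc`
implements the full analysis chain for an emotional conflict (face-word
Stroop) paradigm: trial generation and coding, behavioral quality control
and statistics, first- and second-level GLM mapping, and voxel-wise
ICC(3,1) reliability maps summarized per activation cluster or atlas
region. Because multi-site clinical imaging data of this kind are
restricted, the package ships a synthetic cohort generator with known
variance components, so every stage is testable end to end and estimator
behavior can be validated against ground truth.

## The reliability model

Each voxel (or behavioral measure) yields a subjects x sessions matrix
$y_{it}$. The two-way model treats subjects as random and sessions as
fixed:

$$y_{it} = \mu + s_i + d_t + e_{it}, \qquad
s_i \sim N(0, \sigma^2_b), \quad e_{it} \sim N(0, \sigma^2_w).$$

The consistency form of the intraclass correlation — ICC(3,1) — asks how
much of the subject-to-subject variance is stable across sessions while
letting the session means $d_t$ shift freely. From the two-way ANOVA mean
squares (BMS between subjects, EMS residual; k sessions):

$$\widehat{ICC}(3,1) = \frac{BMS - EMS}{BMS + (k-1)\,EMS},$$

which is the Shrout-Fleiss estimator and algebraically equals the plug-in
variance fraction $\hat\sigma^2_b / (\hat\sigma^2_b + \hat\sigma^2_w)$ with
$\hat\sigma^2_b = (BMS - EMS)/k$ and $\hat\sigma^2_w = EMS$. A second form
sometimes written for this statistic, $(\sigma^2_b - \sigma^2_w) /
(\sigma^2_b + \sigma^2_w)$, is a genuinely different quantity (it is
negative whenever the within-subject variance exceeds the between-subject
variance, and smaller everywhere). `icc31()` uses the mean-square form as
the primary estimator — it is what the field's ICC toolboxes compute — and
exposes the two-variance form behind `form = "variance_ratio"` so the two
conventions can be compared explicitly; results reports state which form
was used.

Confidence intervals are the F-based Shrout-Fleiss intervals:
$F = BMS/EMS$ on $(n-1)$ and $(n-1)(k-1)$ degrees of freedom, bounds
transformed through $(F/F_{crit} - 1)/(F/F_{crit} + k - 1)$. Under the
normal two-way model this interval is exact, which the coverage test
(1,000 simulated cohorts at true ICC 0.6) confirms empirically.

Negative estimates are reported raw and classified "poor" (a negative ICC
means a reliability of zero); flooring at zero is available as a
presentation option but is never the default, so that averages over voxels
are not biased upward. Voxels with zero total variance yield NaN and are
excluded from medians rather than treated as zero.

Classification bands: poor below 0.4, moderate-to-good from 0.4 to 0.75
inclusive (both boundary values belong to the middle band, matching the
inclusive phrasing "0.4 to 0.75"), excellent above 0.75. An alternate
four-band scheme (0.4 / 0.6 / 0.8) is selectable.

The region-level statistic of interest is the **median** voxel ICC within
a region, because voxel ICC maps are noisy and skewed; regions are defined
by the second-level activation clusters (primary mode) or an integer atlas
(exploratory mode, 136 parcels by default, mirroring a whole-brain
neuromorphometric parcellation; the shipped parcellation is synthetic and
space-filling — it carries no anatomy and exists to exercise the
summarization at a realistic region count).

## Task design

Runs hold 74 one-second face-word stimuli with jittered inter-stimulus
intervals of 3-5 s, exactly counterbalanced for congruency and for face
emotion within each run (with odd 37-trial congruency cells, one cell gets
the extra happy face and the other the extra fearful face, so the run
totals are exactly 37/37). Choices the task description leaves open:

* **ISI distribution** — continuous uniform on [3, 5] s, rounded to 0.1 s
  (projection software operates on frame-size quanta).
* **Transition counts** — trial order is shuffled uniformly under the
  marginal balance constraints and re-shuffled until every
  conflict-adaptation cell (cC, cI, iC, iI) has at least 10 occurrences
  per run (scaled down proportionally for the miniature runs used in
  tests), keeping the iI-cI contrast estimable on every generated
  sequence.
* **Run length** — 74 trials at a 4 s mean ISI occupy about 370 s, short
  of a 6 min 35 s task block; a configurable 10 s lead-in fixation is
  prepended and the remainder is trailing fixation. Whether the original
  timing implies longer ISIs or instruction screens is not derivable from
  the task description, so the generator makes the conservative choice and
  documents it.

Adaptation labels are recomputed by `code_adaptation()` from the
congruency sequence and never cross run boundaries: the first trial of
every run is `first`.

## Behavioral rules

* **Run-level QC**: commission errors at most 25% per run and total
  (commission + omission) errors at most 30% per run; any failing run
  flags the subject.
* **RT trial filter**, in order: error trials; the trial immediately
  following an error (within the run only — runs are separated by rest,
  so post-error slowing does not carry across); trials outside mean
  +/- 2 SD of their subject x session x trial-type cell. The mean and SD
  are computed over the correct, non-post-error trials of the cell (the
  within-subject convention of the task literature; the scope is
  configurable via `type_cols`). The bounds computed on first application
  travel with the filtered data, so re-filtering is a no-op: the exclusion
  criterion is a property of the recording, not of whatever subset it is
  re-applied to.
* **Accuracy** uses all trials — outliers and post-error trials included —
  since only the response itself matters.
* **Tests**: paired comparisons use the Wilcoxon signed-rank z with the
  Pratt convention for zero differences (zeros participate in ranking,
  then drop) and midranks for ties — deterministic and standard; when more
  than 25% of paired differences are zero the exact sign test is used
  instead, because the rank approximation degrades there. Friedman tests
  compare the three sessions; a Shapiro-Wilk check per comparison records
  the normality gate that motivates the nonparametrics; the
  Bonferroni-adjusted alpha for the four within-session comparisons
  (0.0125) is reported with the table.
* Omission trials carry no RT: they are excluded from RT analyses but
  count as errors for QC and accuracy.

## The synthetic cohort generator

The generator emulates the study conditions of the multi-site test-retest
protocol this package models: 36 subjects scanned at 3 sessions (weeks 0,
2, 8), recruited across 4 sites with a 12/4/6/14 split, 2 runs x 74 trials
per session, TR 2 s, 202 volumes per run, 4 mm voxels.

**Contrast level** (`simulate_contrast_cohort`): per region,
$y = a_r + \text{site}(i) + s_{i,r} + d_t + \varepsilon$, with the subject
effect drawn once per subject x region (regional activation is spatially
coherent) and session noise independent per voxel. True ICC per region is
$\sigma^2_b/(\sigma^2_b+\sigma^2_w)$ by construction. A `"voxel"` mode
draws subject effects independently per voxel — the right mode for
estimator validation, where voxels must be independent replicates. Default
truth: a posterior "visual-like" region with true ICC 0.8 and an anterior
"frontal-like" region with true ICC 0.1 — the qualitative structure task
reliability studies repeatedly find (sensory regions moderate-to-high,
frontal/subcortical poor). Amplitudes (2.0 and 1.5 in units of the session
SD) put second-level peak t values in the 8-15 range typical of robustly
activated group maps, so both regions survive family-wise correction and
enter the cluster table. Session effects default to small nonzero shifts
(+0.05/-0.05) precisely because ICC(3,1) must ignore them; site offsets
default to zero and, when set, act as stable subject traits that inflate
between-subject variance and hence raise ICC — documented so users zero
them for pure recovery experiments.

**BOLD level** (`simulate_bold_run`): condition onset trains convolved
with the canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio
1/6), scaled per region, plus Legendre-style linear/quadratic drift and
white Gaussian noise; motion parameters are smoothed random walks with
optional displacement spikes. White noise is a deliberate simplification:
with it, OLS is the maximum-likelihood fit and first-level t statistics
are exactly t-distributed, which is what makes the nominal
false-positive-rate check meaningful. An AR(1) Cochrane-Orcutt option
exists at the fitting stage for colored-noise experiments.

**Behavior** (`simulate_behavior`): log-normal RT with a stable subject
level (SD 0.12 on the log scale), day-to-day session state (SD 0.08), an
incongruency cost of 60 ms and fear-face slowing of 30 ms — values chosen
so that simulated medians land near the published task's ~660/~725 ms
congruent/incongruent medians — plus per-subject stable variation in the
costs (SD 15 and 20 ms) and in commission log-odds (SD 0.5), because real
cohorts show moderately reliable individual differences in these
quantities; without them, accuracy and contrast ICCs would be structurally
zero, which real data contradict. Commission errors are likelier on
incongruent trials (5% vs 2% at the average subject); omissions are rare
(0.5%) and carry no RT.

What the generator does **not** emulate: spatial autocorrelation of noise,
physiological (cardiac/respiratory) noise, registration and normalization
error, scanner drift differences between sites, susceptibility artifacts,
or anatomical variability. Passing tests on synthetic cohorts therefore
demonstrate the correctness of the estimators and the pipeline plumbing
under the stated model — not that real data meet that model.

## Preprocessing utilities

Only the desk-scale, procedurally defined steps are implemented; rigid-body
registration, slice timing, smoothing-to-target-FWHM and tissue masking are
out of scope (the functions that would consume their outputs accept data
as already co-registered, which synthetic data are by construction).

* `min_displacement_reference`: Gaussian-smooth a temporary copy (FWHM
  6 mm), remove the temporal mean volume, PCA the volumes, scale component
  scores by eigenvalues ("factors"), take the component-wise median factor
  vector as a robust center, and return the volume closest to it. Two
  ambiguities resolved here: the median is per component (coordinate-wise),
  and the distance is Euclidean in the eigenvalue-scaled component space —
  the natural PCA metric.
* `motion_regressors`: rotations are converted to arc displacement at a
  50 mm head radius (the common convention) so all six columns are in mm;
  columns are centered but **not** variance-scaled, because the 85%
  criterion is about where the displacement variance actually is — scaling
  every column to unit variance would make a 5 mm drift and a 5 micron
  wiggle count equally. The smallest leading component set reaching 85%
  cumulative variance is returned.
* `censor_outliers`: robust z (median/MAD) in a 15-volume sliding window,
  threshold 4; both defaults are configurable stand-ins for the
  sliding-window censoring method the modeled pipeline cites, whose exact
  constants live outside the task description. Outliers are repaired by
  natural cubic splines over non-outlier volumes (nearest non-outlier value
  at series ends). A locally constant window with a deviant point has MAD
  zero; the deviant is then flagged unconditionally. If more than half the
  series is flagged the function refuses with a `censor_failure` condition
  rather than rewrite the majority of the data.

## GLM mapping

* Condition regressors: unit boxcars at onsets convolved with the
  double-gamma HRF on a 0.1 s grid, sampled at volume times. The standard
  regressor set is all faces, congruent, incongruent, happy/fear faces,
  happy/fear words, iI and cI; empty conditions are dropped with a warning.
* Nuisance: Legendre polynomial trends (orders 0-2) plus a discrete-cosine
  high-pass basis. A high-pass "cutoff of 100" is physically impossible as
  100 Hz at a 2 s TR; it is read as a 100 s cutoff **period**, the standard
  convention, and the run log records this interpretation.
* Fitting is voxel-wise OLS; aliased columns are dropped with a pivot
  report and NA betas. Residual dof is n minus the design rank.
* Second level is a one-sample t across subjects (random effects), dof
  n - 1. Zero-variance voxels with nonzero mean would give infinite t;
  they are capped at 1e6 and flagged instead of propagating Inf.
* Family-wise error control is Bonferroni across in-mask voxels — a
  conservative, assumption-light stand-in for random-field correction,
  which is out of scope — with a sign-flip permutation max-t alternative
  when a permutation budget is supplied. Clusters are connected components
  (face connectivity 6 by default; 18/26 configurable) of supra-threshold
  voxels with a minimum extent of 10; an empty result logs the
  conventional fallback suggestion (uncorrected p < .001).
* Sessions with two runs are combined by averaging the runs' contrast
  maps (a fixed-effects combination); the second-level activation map that
  defines clusters is taken from session 1, so cluster definition is
  baseline-driven and identical across the sessions whose reliability is
  then summarized.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → behave → map → ICC → report from a
single seeded configuration; reruns with the same configuration are
identical, and the run log records every interpretation flag in effect
(high-pass reading, FWE stand-in, ICC form). The test suite exercises the
pipeline at reduced problem sizes chosen to keep the full suite fast while
leaving every code path intact: grids of 10x10x6 to 24x24x16 voxels,
cohorts of 8-36 subjects, runs of 12-74 trials, 40-202 volumes, 25-100
Monte Carlo replicates per property. These sizes are the package's own
validation design; the defaults of every user-facing function remain the
full study conditions.

## Known limitations

* The FWE stand-in is Bonferroni, which is conservative relative to
  random-field or permutation cluster-level corrections on smooth maps.
* OLS without prewhitening is exactly right only for white noise; real
  fMRI noise is autocorrelated (the AR(1) option mitigates, not solves).
* The synthetic atlas is a space-filling parcellation, not an anatomical
  one; atlas-level results on synthetic data validate bookkeeping, not
  localization.
* Behavioral ICC confidence intervals assume the normal two-way model;
  accuracy near ceiling violates it mildly.
* The RT-outlier filter's SD scope (within subject x session x trial type)
  is one reasonable reading of an underspecified rule; the scope is a
  parameter so analysts can match other conventions.
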