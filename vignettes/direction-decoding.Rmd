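---
title: "Decoding walking direction from virtual-navigation fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding walking direction from virtual-navigation fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navdecode)
```

## The scientific problem

Direction-selective neural populations respond maximally to a preferred
direction and progressively less to directions further away, approximately
following a circular-Gaussian tuning profile at the population level. In
humans this structure can be probed with fMRI multi-voxel pattern analysis
(MVPA): during free navigation in a virtual circular arena, the
instantaneous walking direction is binned into discrete classes, and a
classifier is trained to decode the direction bin from the voxel pattern.
Two quantities summarize the fidelity of the directional code:

* **balanced decoding accuracy** — how often (correcting for class
  imbalance) the direction can be read out of the pattern, against a
  chance level of $1/6$ for six bins; and
* **tuning precision** $\tau$ — how steeply the classifier's probability
  mass falls off with angular distance from the true direction.

Both are sensitive to *neural gain* (a multiplicative scaling of the
stimulus-driven response, the hypothesized locus of dopaminergic
modulation) and to *tuning width* (which broadens under age-related neural
dedifferentiation). `navdecode` implements the complete analysis chain and
a synthetic-data generator that embodies exactly this generative structure,
so every stage of the pipeline can be validated against known ground truth
without any imaging data.

## Task simulation

The simulated task reproduces the structure of the arena paradigm: a
circular grass plane bounded by a wall (radius in virtual meters, vm;
1 vm = 62.5 Unreal engine units), five objects whose locations must be
remembered, and a feedback phase of 5 objects × 6 repetitions = 30 trials
per session in which each object is re-placed from memory.

* **Trajectories** are generated by a wrapped-Gaussian heading random walk:
  heading innovations have standard deviation
  `turn_volatility * sqrt(dt)` per step, position is integrated from
  heading and speed, and the agent steers back toward the center when it
  approaches the wall. The generator is *not* a model of human
  navigation; it only needs to produce realistic dwell times within
  60° direction bins so that event extraction and decoding see
  representative class distributions. With the defaults
  (`turn_volatility = 40` deg/√s, `mean_speed = 2` vm/s, 10 Hz sampling)
  a 17.4-min session yields a few hundred usable direction events of
  1–10 s, matching the order of magnitude expected from joystick
  navigation. The sampling rate (10 Hz) is a package choice; any rate
  well above 1/TR works.
* **Heading convention**: heading is the direction of movement, in degrees
  counterclockwise from the positive x-axis. (Camera yaw and movement
  direction coincide in this simulation; for real logs the distinction
  matters and the trajectory reader accepts either, since only the
  `heading` column is interpreted.)
* **Feedback responses** are true locations plus isotropic Gaussian memory
  noise whose standard deviation decays geometrically across repetitions
  (default 8 vm, decay 0.75 per repetition), clipped to the arena. This
  produces the canonical decreasing error curve; `learning_change()`
  measures it as the natural-log difference between first and last trial
  (natural log is the package convention for all log transforms).
* **Behavioural chance** replaces every response with a draw from an
  area-uniform pool of locations (`r = R * sqrt(u)`; naive radius-uniform
  sampling would bias errors low) and repeats the task simulation
  (default $10^5$ pool locations, 1000 simulated runs), yielding a
  chance distribution of trial-wise group means. Two analytic anchors
  pin the sampler: the mean distance of an area-uniform point from the
  center is $\tfrac{2}{3}R$, and between two independent area-uniform
  points $\tfrac{128R}{45\pi} \approx 0.905R$.

## Synthetic BOLD generation

Voxel $j$ at volume $v$ is

$$ y_{vj} = \text{baseline} + g \cdot \bar f_j(v) + d(v) + \varepsilon_{vj}, $$

where $\bar f_j(v)$ is the mean circular-Gaussian tuning response
$\exp(-\Delta^2 / 2\sigma_{\text{tune}}^2)$ over the trajectory samples in
the lag-shifted acquisition window, $g$ is the gain, $d(v)$ a shared
low-frequency cosine drift, and $\varepsilon$ iid Gaussian noise
(an AR(1) option exists because temporal autocorrelation is what makes
fold construction delicate). Only a `fraction_tuned` subset of voxels
receives the gain term; preferred directions are uniform on $[0, 360)$.

The hemodynamic delay is modelled as a **pure temporal shift of two TRs
(4.72 s at TR = 2.36 s)** rather than an HRF convolution, because the
decoding stage corrects lag by exactly this two-volume shift; generator
and analysis therefore agree by construction, and an optional
double-gamma convolution mode exists for robustness checks. Spatial
structure (and hence spatial smoothing) is deliberately absent: synthetic
voxels have no geometry, so smoothing is a no-op conceptually and is
delegated upstream for real volumetric data.

**Signal cleaning** follows the fixed order detrend → discrete-cosine
high-pass (cutoff period 128 s, i.e. 1/128 Hz) → confound regression (up
to 10 columns, OLS residuals, collinear columns dropped with a warning) →
per-voxel z-scoring. The generated confound table contains the generative
drift components plus white-noise regressors, standing in for
anatomical-CompCor components without any tissue-mask PCA.

## Events and examples

Direction space is divided into six half-open 60° bins with edges at
multiples of 60° and center labels 30°, 90°, …, 330° (any two centers
differ by a multiple of 60°, which is all the offset analysis requires).
A *direction event* is a maximal run of samples sharing a bin at speed ≥
0.05 vm/s ("walking" requires displacement; the threshold is
configurable), kept if it lasts ≥ 1 s. Each event maps to every volume
whose acquisition window overlaps the event interval (overlap rule, not
midpoint), those volume indices are shifted by the two-TR lag anchored at
event onset (midpoint anchoring is available as an option), and the
covered volumes are averaged into one pattern. Events whose shifted
volumes fall past the run end are dropped and counted.

A session enters decoding only if every bin has ≥ 3 examples and every
temporal fold contains every bin. The count threshold is a package
default (exposed in the configuration): the usable-session requirement is
qualitative in origin, and 3 is the smallest count for which per-fold
balanced scoring is defined with three folds.

## Decoding

The classifier is an L2-regularized multinomial logistic regression in the
sklearn-style $C$ parameterisation ($C = 1$, tolerance $10^{-4}$, 1000
maximum iterations), implemented as a single-$\lambda$ ridge fit with
$\lambda = 1/(C\,n_{\text{train}})$ via `glmnet`. A short decreasing
$\lambda$ path ending at the target value is used for warm-start
stability, and class probabilities are computed from the extracted
coefficients by softmax (identical to `predict.glmnet` to machine
precision, but fast enough for permutation testing).

* **Folds** are contiguous temporal thirds (remainder to the earliest
  folds). Contiguity limits leakage through temporal autocorrelation; a
  session is split by onset order, deterministically.
* **Upsampling**: training classes are duplicated (seeded sampling with
  replacement, originals always retained) up to the largest class count.
* **Scoring**: balanced accuracy (mean per-class recall) on the held-out
  predictions concatenated across folds; per-fold scores are secondary.
* **Permutation null**: the full CV procedure is repeated (default 1000
  iterations) with training labels permuted independently per fold and
  iteration; test labels are untouched and define the scoring. The null
  mean sits at the 1/6 chance level. Group-level nulls average the
  per-subject null scores iteration-wise, mirroring the averaging of the
  observed scores.

## Tuning precision

For every test example the six class probabilities are re-indexed by the
signed circular offset between class center and true center
(−120°, −60°, 0°, 60°, 120°, 180°; −180 and +180 are identified, so the
diametric class contributes at +180), then averaged over examples into the
*confusion function*. The one-parameter model

$$ g(x) = \frac{1}{Z} e^{-\frac{1}{2}\tau x^2} $$

is fitted by least squares over the six offsets, with $Z$ constrained to
normalize the curve over those offsets — the confusion function itself
sums to 1, so a free $Z$ adds nothing under the model; a free-$Z$
two-parameter variant is available for sensitivity analysis. $x$ is in
degrees and $\tau$ in deg⁻² (a conversion helper to rad⁻² is provided).
The SSE profile is scanned on a log grid over $\tau \in [0, 1]$ deg⁻² and
refined by Brent's method (tolerance $10^{-12}$); noiseless
model-generated curves are recovered to better than $10^{-8}$. Degenerate
inputs are handled explicitly: a uniform confusion function yields exactly
$\tau = 0$, and a near-delta curve (whose SSE is flat up to the bound) is
reported at the bound and flagged non-converged.

## Group statistics

The pipeline reports per-subject statistics in tidy long-format tables
plus simple group tests: one-sided one-sample t-tests of balanced accuracy
against the 1/6 chance baseline, one-sided permutation p-values with the
add-one estimator $p = (1 + \#\{null \ge obs\})/(1 + n)$ (never exactly
zero), Bonferroni–Holm correction across simultaneous tests, and a paired
t contrast between conditions. Full factorial linear mixed models
(intervention × age × ROI × order with per-subject random intercept and
intervention slope) are deliberately *not* estimated here: the tidy table
is designed as the direct input for `lme4`/`emmeans` or equivalent
downstream software.

## What the synthetic validation shows — and what it does not

The generator realizes the very assumptions the analysis makes: circular-
Gaussian tuning, multiplicative gain, additive Gaussian noise, a pure
temporal lag matching the analysis correction. Passing tests therefore
demonstrate the *internal correctness* of the pipeline — lag arithmetic,
chance calibration, estimator consistency, monotone sensitivity to gain
and tuning width — not that real BOLD data satisfy these assumptions.
Real data add HRF shape variability, spatially correlated and non-Gaussian
noise, motion artifacts, and mixed selectivity, none of which are
simulated.

Validation problem sizes are package choices balancing Monte-Carlo
stability against desk-scale runtimes, and are stated here once: chance
calibration uses 20 simulated null subjects × 1000 permutation iterations
(short 3-min sessions, 8 voxels); tuning-width ordering uses 8 subjects
per width in a high-SNR regime (gain 4, unit noise, all of 60 voxels
tuned, 5-min sessions) so that width rather than classifier noise drives
the confusion function; the gain contrast uses 50 paired subjects, and
its false-positive calibration resamples sign-flipped equal-gain session
differences (the two equal-gain sessions are exchangeable, so sign flips
generate exact null draws) rather than re-running thousands of full
pipelines.

## Known limitations

* Tuning precision $\tau$ confounds width with signal-to-noise: at low
  SNR the confusion function flattens regardless of the generative width,
  so $\tau$ comparisons are only meaningful at comparable decoding
  accuracy. This mirrors the interpretive caveat attached to
  tuning-function estimates from classifier confusions generally.
* The 6-point confusion function cannot distinguish tuning shapes
  (Gaussian vs. von Mises); no alternative profile is fitted.
* The trajectory generator produces no goal-directed structure, so
  direction occupancy is more uniform than human navigation; the
  class-distribution check is correspondingly less often triggered than
  in real cohorts.
* Searchlight decoding, cross-session transfer, feature selection and
  alternative classifiers are out of scope.

## Reproducing a study

```{r, eval = FALSE}
cfg <- study_config(
  study = list(n_subjects = 20,
               conditions = list(high_gain = list(gain = 0.6),
                                 low_gain = list(gain = 0.3))))
study <- run_study(cfg, out_dir = "results")
study$tests      # per-condition tests against chance, Holm-corrected
study$contrast   # paired high-vs-low-gain contrast
```

Every randomized stage derives its seed from the configuration's master
seed via a mixing scheme over (condition, subject, stage), so re-running a
configuration reproduces byte-identical tables.
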