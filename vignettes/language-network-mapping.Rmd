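---
title: "Mapping the language network on phantom resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the language network on phantom resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(langmap)
```

This vignette is the package's account of its science: the generative model
behind the phantoms, the denoising chain and its parameters, the classifier
and the choices made where the design was genuinely open, and what the
passing test suite does and does not establish about real data.

## Why phantoms

The pipeline's target application — localizing the language network in
presurgical patients from resting-state fMRI (RS-fMRI) — depends on data
that cannot ship with a package: patient scans, a multi-thousand-subject
normal training corpus, and a meta-analytic activation map. `langmap`
therefore treats the synthetic-data generator as a first-class module. Every
downstream stage is exercised end to end on phantoms whose ground truth is
known by construction, so failures are attributable and recoveries
quantifiable.

## The phantom model

`make_phantom_atlas()` places `K * R` disjoint spherical parcels (radius 1.5
voxels, 19 voxels each) on a lattice inside an ellipsoidal brain mask
(radii 42 % of the grid). Network 1 is the language analog; its first two
parcels are forced to the left hemisphere (low x), one anterior (low y,
"Broca-like") and one posterior ("Wernicke-like"). Two extra blobs act as
white-matter and CSF compartments. The lattice spacing (4 voxels) keeps
parcels at least 1 voxel apart so that 6 mm spatial smoothing cannot merge
neighboring networks outright; some edge bleed remains, which is realistic.

`simulate_rest_run()` builds each voxel's series as

* a latent network signal: white Gaussian noise band-limited below 0.08 Hz
  by an FFT brick wall and standardized. Keeping the latent band strictly
  inside the 0.1 Hz analysis passband means the denoising filter passes the
  planted structure essentially unchanged; a latent shaped by the same
  Butterworth filter as the pipeline would lose ~4 % correlation purely to
  double filtering.
* white noise with variance `1/snr` (so `snr` is the per-voxel signal/noise
  variance ratio). Default `snr = 5`, a moderate value: single voxels are
  clearly but not trivially informative, and 6 mm smoothing raises the
  effective SNR the way it does in practice.
* a per-voxel linear drift (slope uniform on ±1 latent-sd over the run,
  default amplitude 1) and a whole-brain baseline of 1000 intensity units,
  so that the percent-of-mean censoring criterion is meaningful.
* motion spikes: whole-volume intensity offsets of 5x the censoring
  threshold at chosen frames. Geometric displacement and realignment are out
  of scope, so a spike is the censorable signature that survives in
  intensity space; the spike indicator and its temporal derivative stand in
  for realignment parameters among the nuisance regressors.

Background brain voxels are noise-only: unlike cortex in a real scan, they
belong to no network. This makes the phantom *harder* than real data in one
specific way — the classifier never sees "none of the above" patterns at
training time (examples are parcel seeds), yet at inference most voxels are
exactly that.

Defaults the generators commit to: TR 2.2 s; two 160-frame rest runs
(320 frames pooled); 100-frame task runs with five task/rest blocks of 10
frames; 24-cubed grid of 3 mm voxels with K = 6 networks of 4 parcels; 4
spike frames per rest run. Where the underlying study design fixes a value
(run lengths, TR, block structure, censoring threshold, filter band,
smoothing widths, Z threshold, ROC grid and bootstrap counts) the default is
that value; noise, drift and response amplitudes are free parameters of the
generator, chosen once at the values above, and are claims about nothing
beyond this package's phantoms.

## Preprocessing

`preprocess_run()` applies, in order: voxelwise linear detrending; zero-phase
low-pass filtering below 0.1 Hz (order-2 Butterworth run forward and
backward, so the effective squared-magnitude response is
$1/(1+(f/f_c)^4)$ — 94 % amplitude at half the cutoff, 6 % at twice);
separable Gaussian smoothing (FWHM 6 mm, $\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$
per axis converted by voxel size, half-sample symmetric reflection at the
boundaries, which conserves total intensity); and nuisance regression
(intercept, white-matter mean, CSF mean, global mean, spike indicator and
derivative; the indicator columns are passed through the same low-pass
filter as the data so the regression stays matched).

Frame censoring computes, per frame, the RMS over brain voxels of the
intensity change from the previous frame, as a percentage of the whole-brain
mean, and excludes frames above 0.5 %. Two deliberate choices:

* The censor mask is computed on the **raw** run, before filtering can smear
  a spike across neighbors and before the spike regressors can absorb it —
  mirroring the fact that motion is measured on raw data in practice.
  Censored frames are then dropped from every downstream correlation and
  GLM computation.
* An isolated spike exceeds the threshold on both of its transitions, so the
  spike frame *and* its successor are flagged; a +5 % offset at frame 7
  censors {7, 8}.

Frames kept from all runs of a subject are pooled; the 100-frame condition
takes the first 100 kept frames of the pooled series (the study design says
only "contiguous"; first-n is the simplest deterministic reading).

Two quantitative notes that the tests encode explicitly. First, nuisance
regression removes variance from *noiseless* data too: a parcel latent has
chance correlation with the smooth wm/csf regressors at the ~30 effective
temporal degrees of freedom of a band-limited 160-frame run, costing a few
percent of correlation. Second, global-signal regression of a K-network
phantom removes roughly the $(1/K)\sum_k L_k$ component, leaving residual
correlation $\approx (1-1/K)/\sqrt{(1-1/K)^2 + (K-1)/K^2}$ with the original
latent (0.71 at K = 2, 0.91 at K = 6). Both effects are real fMRI behavior,
not bugs; the preprocessing tests assert the no-nuisance chain at 0.99 and
the regressed chains at these derived levels.

## Features

One training example is the whole-brain Fisher-z correlation volume of a
parcel-mean seed over the kept frames, labeled with the seed parcel's
network; one inference example is the same volume for a single voxel's
series. The study this mirrors never states what an "example set" is; this
representation is the natural 3D input for cubic convolutions and reduces
voxelwise classification at test time to the training task. Fisher's z
(atanh, with |r| clamped to 1−1e−7) stabilizes variance. The correlation
*target* grid may be block-averaged by an integer factor; the feature
functions default to factor 1, while the desk-scale pipeline configuration
uses factor 2 (12-cubed classifier input), which cuts the per-voxel
inference cost eightfold and, at 3 mm voxels and 6 mm smoothing, discards
little information the smoothed data still carried. Correlations with fewer
than 30 kept frames are refused (subject excluded with a warning).

## The classifier

`rsn_densenet()` fits a densely connected 3D CNN. Within a dense block,
layer $l$ receives the channel-concatenation of the block input and all
previous layer outputs and emits `growth_rate` channels through
BN→ReLU→conv; blocks alternate 3-cubic and 5-cubic kernels; transitions
compress channels with a 1-cubic convolution (factor 0.5) and average-pool
(stride 2); a final BN→ReLU→global-average-pool feeds the K-way softmax.
All pooling is average pooling.

**Layer accounting.** "Total layers" counts learnable convolution and
fully connected layers: 1 stem + block layers + (blocks − 1) transition
convolutions + 1 head. The reference configuration (3 blocks, 49 layers)
yields 15 layers per block; the layer manifest ships with the model so any
configuration is auditable (`summary(fit)`). When the budget does not divide
evenly, earlier blocks take the extra layers (2 blocks / 14 layers → 6 + 5).

**Training.** Cross-entropy, minibatch SGD with momentum (defaults lr 0.05,
momentum 0.9, batch 32 — unstated in the underlying design and exposed in
the configuration), validation every epoch, early stop after 3 validations
without accuracy improvement, best-validation parameters restored. All
randomness (initialization, shuffling) is seeded; single-threaded C++
kernels make runs bit-reproducible. Gradients of every layer are checked
against finite differences in the test suite.

**Inference.** Each in-mask voxel's correlation volume is streamed through
the network in chunks; zero-variance voxels get uniform probabilities 1/K
and are flagged. Probability maps are then smoothed in two stages: a
stride-1 cubic **mode filter** on the winner-take-all label volume (ties to
the lowest class index; each voxel's probability vector becomes the mean
over neighbors sharing the modal label), followed by a separable length-3
**box filter** per class with per-voxel renormalization. Whether the
original smoothing operated on labels or probabilities is not stated
anywhere; the two stages are independently toggleable so the ambiguity stays
contained, and both preserve the per-voxel probability sum to 1e−5.

## Task comparator and ground truth

The task GLM regresses each voxel on an intercept and the block boxcar
convolved with a gamma-variate hemodynamic kernel (shape 6, scale 1 s —
peak ~5 s; the kernel family is a standard choice, normalized to unit
integral so the regressor plateau is the response amplitude). The t-map
(beta/SE at kept-frames − 2 dof) is smoothed at 10 mm and masked; no
thresholding, no clustering. The comparator score fed to the ROC is the
t-statistic; the ROC is rank-based, so any monotone alternative (z, percent
signal change) would give identical curves.

The ground-truth ROIs come from the five-step meta-analytic recipe
(`build_language_rois()`): 1 mm smooth; tanh transform of positive Z with
threshold at Z > 3.7 — thresholding is done in Z units since 3.7 is a
Z-score, and the tests assert the tanh path selects identical voxels; keep
the two largest left-hemisphere clusters (26-connectivity by default;
size ties broken toward the larger peak Z); 3 mm smooth of each indicator,
re-binarized at 0.5; voxels claimed by both go to the nearer center of mass.
The anterior ROI is named Broca-like, the posterior Wernicke-like.

## Evaluation

Per-subject maps are produced first, then averaged arithmetically, then a
single group-level ROC is computed — not per-subject ROCs averaged. The ROC
machinery is rank-based AUC (concordance with ties at 1/2; verified against
an exhaustive O(n²) oracle and an independent ROC library) plus a voxel
bootstrap: each of 10,000 replicates resamples voxels with replacement, its
ROC polyline is linearly interpolated onto the fixed 101-point FPR grid,
true-positive rates are averaged vertically, and pointwise and AUC
percentile intervals at alpha = 0.05 are reported. The default negative set
for a language ROI is the left-hemisphere brain mask minus the other ROI
(the evaluation hemisphere convention); whole-mask negatives are a
configuration switch. The bootstrap unit is the voxel because group maps
collapse subjects before the ROC.

Calibration is tested in a closed-form scenario: binormal scores with
separation d have true AUC $\Phi(d/\sqrt2)$, and the 95 % bootstrap interval
(1,000 replicates for speed) must cover it in at least 90 % of 200
replicates.

## The desk-scale experiment

`run_experiment(list(seed = 1))` runs the whole pipeline at the default
scale chosen so a complete study fits in minutes on one CPU: an 8-subject
training cohort, a 12-subject test cohort, 24-cubed grid, K = 6, a 2-block
8-layer classifier (growth 6, stem 8 channels) on 12-cubed inputs. Training
and test cohorts are disjoint, mirroring the normal-training /
patient-testing asymmetry of the application. The task run drives the
Broca-like parcel at amplitude 1, the Wernicke-like parcel at 0.4, and one
parcel of a non-language network at 1 — an expressive task that also
recruits task-general control regions — which is why the task comparator
trails the classifier on the Wernicke analog in the shipped example while
matching it on the Broca analog.

At seed 1 this produces group language-probability maps whose AUC against
the planted language parcels is 0.994 (all frames) and 0.995 (100 frames),
a difference well under the 0.03 equivalence band, with overlapping AUC CIs
against the meta-analytic ROIs — the desk-scale analog of tolerance to
limited data.

## Numerical choices and degenerate inputs

* Filtering: order-2 Butterworth coefficients from `signal::butter`; the
  forward-backward pass is a compiled loop with odd-reflection padding of
  length 3×(filter order), steady-state initial conditions scaled by the
  first padded sample. Edge behavior is tested against the analytic
  response; interior samples agree with `signal::filtfilt` to 1e−8.
* Smoothing boundaries: half-sample symmetric reflection (mass-conserving);
  kernel radius 3.5 sigma.
* Zero-variance series: correlation seeds error out at training, are
  flagged and assigned uniform probabilities at inference, and contribute
  r = 0 as correlation targets.
* Ties: ROC ties at 1/2 via midranks; mode-filter ties to the lowest class
  index; cluster-size ties to the larger peak Z.
* Bootstrap replicates that draw a single class are redrawn (vanishingly
  rare at realistic sizes, deterministic under the seed).
* All seeds are explicit; derived per-run seeds stay below 2^31.

## What the tests do and do not show

The suite demonstrates that every stage implements its stated contract and
that, under the generative model above, the full pipeline recovers planted
structure with high fidelity. It does not show robustness to anything the
generator does not emulate: EPI physics and susceptibility distortion,
head-motion geometry, registration error across modalities, tumor mass
effect, neurovascular uncoupling, or inter-subject anatomical variability.
Real-data performance claims require real data; the package's claim is that
the machinery is correct, deterministic, and calibrated where closed forms
exist.
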