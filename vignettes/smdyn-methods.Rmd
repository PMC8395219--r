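---
title: "Models and methods behind smdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdyn)
```

`smdyn` analyses single-molecule TIRF time-lapse recordings of membrane
proteins — the motivating system is HaloTag-labeled TRPV ion channels in the
basal membrane of HEK293 cells — and ships a synthetic-data generator that
emulates the statistical structure of such recordings so that every analysis
stage can be validated against known ground truth. This vignette documents
the models, the parameters that matter, the numerical choices, and the
limits of what passing tests demonstrate.

## The switching-diffusion model

A membrane protein particle is modelled as a 2-D random walk whose diffusion
coefficient switches among K discrete states (immobile, medium, fast for
K = 3) according to a continuous-time Markov chain with rate matrix Q
(1/s). Observed at frame interval dt, the state sequence is a discrete
Markov chain with transition matrix `expm(Q * dt)`. The matrix exponential
is used rather than the first-order approximation `I + Q * dt` because the
dwell times in this system are subsecond while dt = 30.5 ms, so `Q * dt`
entries are not uniformly small; the exponential correctly accounts for
multiple switches within one frame.

Within a state, each displacement step per axis is Gaussian with variance
`2 D dt`. States can be confined: the particle then moves inside a square
domain of side L with specular (reflecting) walls. A square is chosen
because it gives closed forms used by the tests — stationary position
variance `L^2/12` per axis and a 2-D MSD plateau of `L^2/3` — and because
the imaging data constrain only the domain scale, not its shape. The domain
is centred where the particle enters the confined state; particles that
start confined are initialized uniformly inside their domain so the
confined position distribution is stationary from frame 1.

Reported positions add isotropic Gaussian localization noise with SD
`loc_sigma` (default 20 nm, typical of bright organic dyes at these frame
rates). Localization noise has two analytic consequences that the package
treats explicitly: it adds `4 sigma^2` to every MSD lag (absorbed by fit
offsets) and inflates apparent diffusion coefficients by `sigma^2/dt`
(removable with `subtract_loc_noise()`). At dt = 30.5 ms and sigma = 20 nm
that inflation is 0.013 um^2/s — larger than the immobile-state D itself,
which is why the correction matters for slow states.

Track lifetimes are exponential (default mean 30 frames), truncated at the
movie length; this stands in for photobleaching and out-of-focus loss. No
blinking, no EM-CCD excess-noise factor, and no axial effects are modelled.

### Default study conditions

The `sim_params()` defaults encode the imaging conditions of the motivating
experiments: dt = 0.0305 s (the camera exposure; the nominal 33 fps frame
rate differs by under 1% and a single configurable dt is used), 100-frame
movies, 67 nm pixels, D = 0.008/0.05/0.25 um^2/s (midpoints of the ranges
reported for TRPV channels), immobile-state confinement of 0.15 um, and a
cell footprint of 400 um^2 (a typical HEK293 basal surface). The rate
matrix default gives dwell times of 0.5-0.67 s — subsecond, as estimated
for these channels — with a roughly balanced stationary mix; the published
work reports per-channel-type fractions but not a full rate matrix, so this
is a representative choice made once, not a fitted quantity.

Oligomer sizes 1..8 are drawn per particle conditional on its initial
state, with slower states enriched for higher orders (fast peaks at dimers,
medium at trimers, immobile at tetramers and above, echoing per-state
intensity peaks at 2-4x the monomer intensity). Composition is fixed for a
particle's lifetime; association/dissociation within a movie is not
simulated. Labeling is per-subunit multinomial over (dye1, dye2, none) with
default (0.4, 0.4, 0.2): about 50% of subunits carry each dye among labeled
ones and 80% of subunits are labeled in total, consistent with a
saturation-binding estimate of ~50% occupancy per dye and ">80%" overall.
The generator exposes these probabilities directly rather than deriving
them from ligand concentrations, since the competition arithmetic between
the two ligands is not observable in the data.

### Time-lapse endocytosis

`simulate_timelapse()` generates independent movies at 0/5/10/15/20 min
from a particle pool whose per-state counts are thinned binomially by the
removal schedule between time points (`timelapse_preset("TRPV4")` removes
immobile+medium from 5 min; `"TRPV1"` from 10 min; `"vehicle"` removes
nothing). Within a movie each particle keeps one state. This is a
deliberate simplification: state switching equilibrates within seconds, so
if particles resampled states inside each movie, any state-selective
removal would relax back to the stationary mix and per-state densities
could not show the selective loss that motivates the analysis. The frozen
state is best read as a persistent membrane-domain association sampled at
5-minute intervals; fast switching remains the business of
`simulate_trajectories()`.

## VB-HMM over displacement steps

`fit_vbhmm()` clusters steps into K diffusive states. The emission model
for a step vector is zero-mean isotropic Gaussian with per-axis precision
`lambda_k = 1/(2 D_k dt)`; sufficient statistic per step is the squared
length r^2. Inference is conjugate variational Bayes: Dirichlet(1) priors
on the initial distribution and each transition-matrix row, Gamma priors on
the precisions with shape 2 and rate `2 dt D_prior`, where `D_prior` is the
overall mean squared step over `4 dt` — weakly informative and scale-aware,
so the same defaults work in um^2 or nm^2. The E-step is a scaled
forward-backward pass run with expected log-parameters (digamma terms), the
M-step updates the hyperparameters in closed form, and the evidence lower
bound (log-normalizers from the forward pass minus the Dirichlet and Gamma
KL terms) is non-decreasing at every iteration — asserted per iteration in
the test suite, with the E-step additionally checked against brute-force
enumeration of all state sequences on short tracks.

Numerical choices: initialization by quantile split of step lengths into K
groups (restarts use random responsibilities from the run's seed; default
5 restarts, best bound wins); convergence at relative ELBO change 1e-6;
cap 500 iterations; tracks shorter than `min_steps = 5` steps are excluded
from fitting but still Viterbi-labeled afterwards. States are reported in
ascending order of D, so "state 1" is always the immobile state regardless
of the optimizer's internal labels. Reported `D_est` is the
responsibility-weighted mean squared step over `4 dt` (the M-step point
estimate); it therefore reduces exactly to the closed-form MLE when K = 1.
Localization noise is absorbed into apparent D by default, matching how
such coefficients are usually reported; `subtract_loc_noise()` applies the
analytic correction when sigma is known.

`select_model()` fits K = 1..5 and picks the highest lower bound, mirroring
per-cell model comparison; `transition_rates()` converts the per-frame
transition matrix to first-order rate constants `k_ij = A_ij/dt` and dwell
times. Both dye channels of a cell are pooled into one fit by default —
whether the original analysis pooled channels is not stated, and pooling
uses all steps; fitting channels separately is available by subsetting the
trajectory table.

## MSD analysis

`compute_msd()` is the time-and-ensemble average over all overlapping
origins; uncertainty is the SEM across cells when several cells are present
(the unit of replication in live-cell work), otherwise across tracks. The
linear fit uses the first 4 lags (weighted by 1/SEM^2) with the intercept
estimating `4 sigma^2`; the confined fit uses up to 15 lags of the model
`MSD(t) = (L^2/3)(1 - exp(-t/tau)) + offset`. That saturating form is a
single-exponential surrogate for the exact (infinite-series) square-domain
MSD; its leading relaxation time differs from the series' by a few percent,
well inside the quoted recovery tolerances, and its plateau is exact. The
short-time coefficient is reported through `tau = L^2/(12 D_micro)` (the
model's initial slope is then `4 D_micro`). A fitted tau beyond the last
lag means the data never bend over — the fit is flagged `censored` and L
should not be trusted. The fitted L and the raw plateau are both available,
since a "domain size" can be quoted either way.

## Oligomer decomposition

`calibrate_monomer()` fits a lognormal (default; CV around 0.35 is typical
for single organic fluorophores on EM-CCDs) to a monomeric-control
intensity sample by maximum likelihood. `nmer_model()` builds k-mer
intensity distributions by numerical self-convolution. Convolutions are
computed on an 8x oversampled grid and aggregated back to the 256-bin
analysis grid (0 to 8x the monomer mean): repeated convolution directly on
the coarse grid accumulates half-bin smearing that measurably biases the
mixture split, which is why the refinement exists.

`decompose_histogram()` solves a non-negative least-squares problem against
the k-mer bases, k = 1..8. With per-subunit labeling probability p < 1,
each basis is the binomial mixture over the number of labeled subunits
conditioned on at least one label, because a fully unlabeled particle is
never detected. The NNLS weights then describe the mix of *visible*
particles; since a k-mer is visible with probability `1 - (1-p)^k`, the
composition weights divide out that detection probability and renormalize.
Both vectors are returned. NNLS is convex, so the decomposition is
deterministic — no EM restarts, no local optima.

A practical limit, established with the generator: at p = 0.5 the visible
bases for neighbouring sizes overlap so strongly that recovering an
8-component mixture to mean absolute error 0.05 needs pooled-across-cells
particle numbers (tens of thousands of detections, as when ~20 cells
contribute); per-cell counts of a few thousand leave the dimer/tetramer
split under-determined at that labeling level. At p >= 0.75 a few thousand
particles suffice. The recovery tests assert the pooled regime.

## Colocalization kinetics

Two detections from different channels colocalize when they are closer
than 200 nm in the same frame *and* carry the same diffusion-state label.
Candidate pairs are resolved one-to-one greedily by ascending separation
with ties broken by particle id (the resolution rule is not dictated by the
data; greedy-by-distance is the simplest deterministic choice). Pairs of
the same two particles in consecutive frames merge into events; by default
a single missed frame splits an event (configurable). An event whose last
frame coincides with the end of either member's track (or the movie) is
right-censored — its dissociation was not observed — and the on-time
analysis uses Kaplan-Meier survival plus the censoring-aware exponential
MLE (total observed time over observed dissociations).

The on-rate constant follows its operational definition: cumulative
association events per unit area against time, initial slope V0 over the
first third of the movie (the window is a package choice; no window is
prescribed by the definition), and `k_on = V0/([Ch1][Ch2])`. Pairs already
colocalized in the movie's first frame are left-censored associations and
are excluded from the cumulative count — with co-labeled oligomers most
colocalized pairs exist from frame 1, and counting them as associations
would make V0 an artefact of the movie start.

Colocalized fractions are reported per movie: a particle counts if it
participates in at least one event. No correction for chance colocalization
by density is applied.

## Pharmacology

`hill_fit()` fits `f(x) = bottom + (top - bottom)/(1 + (EC50/x)^n)` by
Levenberg-Marquardt least squares, parameterized in log-EC50 (so the
estimate stays positive and the optimizer moves in decades), with the span
`top - bottom` bounded at zero and n constrained to (0, 10]. Starting
values come from the response extremes and the concentration nearest the
half response. Replicates enter unweighted by default. `peak_response()`
is the plate-reader readout (post-stimulation maximum over baseline mean),
and `specific_binding()` subtracts nonspecific from total binding
(floored at zero with a warning) before refitting.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` chains simulate -> HMM -> labeling -> MSD -> densities ->
oligomers -> colocalization and emits a JSON-serializable summary; with an
output directory it also writes labeled trajectory CSVs and the fully
resolved YAML configuration next to the results. All randomness flows from
one root seed through `derive_seeds()`, and a fixed seed gives
byte-identical summaries — asserted in the tests.

The test suite and the acceptance script run at deliberately chosen scales:
recovery checks use 500-2,000 tracks of 20-100 frames (about 4 x 10^4
displacement steps for the three-state fit), 5,000-sample calibrations, and
50,000-particle pooled decompositions. These sizes were picked so that each
statistical tolerance (e.g. 25% on D, 15% on L and EC50, 5% on the monomer
mean) sits several standard errors away from the pass boundary under the
generator's known sampling variability.

## What the synthetic tests do and do not show

The generator reproduces the *statistical skeleton* the analysis relies on:
Markov switching with known rates, Gaussian steps, square-domain
confinement, lognormal fluorophore intensities with binomial labeling,
exponential track lifetimes, state-selective removal between time points,
and Hill-shaped dose-response tables. Passing recovery tests therefore
demonstrates correctness of the estimators under the model's own
assumptions. Real recordings violate those assumptions in known ways —
non-square domains, anomalous subdiffusion, dye blinking and photophysics,
detection/linking errors at high density, spatial heterogeneity across the
cell, and drift — none of which the generator emulates. Agreement on
synthetic data bounds implementation error, not model error.
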