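# smdyn — single-molecule dynamics of membrane channels

`smdyn` is an R package for analysing single-molecule TIRF time-lapse
imaging of plasma-membrane proteins — the kind of data produced by
HaloTag/organic-dye labeling of TRPV ion channels in living HEK293 cells.
It is written for microscopists and quantitative biologists who need to go
from particle trajectories (or raw movies) to diffusion states, membrane
domain sizes, oligomeric composition, subunit association kinetics, and
agonist pharmacology, with every stage testable against a built-in
synthetic-data generator with known ground truth.

## What it computes

* **Switching-diffusion simulation** — 2-D tracks from a K-state
  continuous-time Markov chain (per-frame transitions `expm(Q dt)`), with
  Gaussian steps of per-axis variance `2 D_k dt`, square reflecting
  confinement domains, localization noise, exponential track lifetimes,
  state-dependent oligomer sizes with two-dye stochastic labeling,
  time-lapse series with state-selective removal (endocytosis), rendered
  TIRF movies (integrated Gaussian PSF + Poisson noise), and Hill
  dose-response tables.
* **Tracking** — rolling-ball-style background subtraction and two-frame
  averaging, Gaussian-fit spot detection, greedy nearest-neighbour linking
  with gap closing.
* **VB-HMM diffusion-state clustering** — variational-Bayes HMM over
  displacement steps (Dirichlet/Gamma conjugate priors, forward-backward
  E-step with expected log-parameters, monotone evidence lower bound),
  model selection over K by the lower bound, per-frame transition matrix
  converted to rate constants `k_ij = A_ij / dt` and dwell times, Viterbi
  step labels.
* **MSD analysis** — time-and-ensemble MSD with overlapping origins,
  linear fits (`MSD = 4 D t + 4 sigma^2`), and confined fits
  `MSD(t) = (L^2/3)(1 - e^{-t/tau}) + offset` whose plateau `L^2/3` gives
  the membrane-domain side L; per-state MSD computed within state dwells.
* **Oligomer decomposition** — single-fluorophore calibration from a
  monomeric control (CD86-style), n-mer intensity models by numerical
  convolution, and non-negative least-squares decomposition of per-state
  intensity histograms with partial-labeling (binomial, visibility-
  conditioned) bases; density-normalized difference histograms.
* **Two-colour colocalization** — events defined by separation < 200 nm in
  the same frame *and* the same diffusion state, colocalized fractions,
  association on-rate constants `k_on = V0 / ([Ch1][Ch2])`, and
  Kaplan-Meier on-time survival with right-censoring.
* **Pharmacology** — Hill-equation fits
  `f(x) = bottom + (top - bottom)/(1 + (EC50/x)^n)` for FLIPR-style
  dose-response and saturation binding, peak-response normalization, and
  specific-binding computation.
* **Pipeline** — `run_pipeline()` chains all stages on synthetic data from
  one seed and writes a machine-readable summary plus the resolved
  configuration.

## Worked example

Simulate a three-state TRPV-like cell (500 particles, 60 frames, dt =
30.5 ms), cluster the diffusion states, and measure the immobile-state
confinement and an agonist EC50:

```r
library(smdyn)

p   <- sim_params(n_particles = 500, n_frames = 60, seed = 17)
sim <- simulate_oligomer_intensities(simulate_trajectories(p), p)

fit <- fit_vbhmm(sim$traj, K = 3, seed = 1)
summary(fit)
#> VB-HMM with 3 diffusion states (ascending D)
#> D (um^2/s): 0.01925, 0.06219, 0.2635
#> stationary fractions: 0.323, 0.349, 0.328
#> per-frame transition matrix A:
#>         [,1]    [,2]    [,3]
#> [1,] 0.94340 0.04203 0.01456
#> [2,] 0.03512 0.93510 0.02978
#> [3,] 0.01831 0.02777 0.95390
#> rates (1/s):
#>         [,1]    [,2]    [,3]
#> [1,] -1.8550  1.3780  0.4774
#> [2,]  1.1510 -2.1280  0.9765
#> [3,]  0.6002  0.9105 -1.5110
#> dwell times (s): 0.539, 0.47, 0.662
#> ELBO: 32506.986 (converged, 59 iterations)
```

The generating coefficients were 0.008 / 0.05 / 0.25 um^2/s; the fitted
values include the localization-noise inflation `sigma^2/dt` (~0.013
um^2/s here — remove it with `subtract_loc_noise()` when sigma is known).
Dwell times are subsecond, matching the generating rate matrix.

```r
labeled <- assign_states(sim$traj, fit)
msd_imm <- compute_msd(labeled, max_lag = 10, state = 1)
fit_msd_confined(msd_imm, n_lags = 10)
#> <confined_fit> L = 0.1752 um (175.2 nm), tau = 0.2599 s, D_micro = 0.009842 um^2/s
#>   plateau = 0.01135 um^2, offset = 0.001122 um^2
```

The immobile state was simulated in 150 nm domains; the fitted side length
(175 nm) is read off the plateau of the within-dwell MSD, biased slightly
upward by imperfect step labeling. The offset estimates `4 sigma^2`
(truth: 0.0016 um^2).

```r
conc <- 10^seq(-1, 3, length.out = 10)
dr   <- simulate_dose_response(26, 1.5, 1, 6, conc,
                               noise_sd = 0.12, n_reps = 3, seed = 4)
hill_fit(dr$concentration, dr$response)
#> <hill_fit> EC50 = 26.17, n = 1.53, bottom = 1.063, top = 6.06
```

The dose-response table was generated with EC50 = 26 nM (a TRPV4-agonist
potency) and 2% noise; the fit recovers it within sampling error.

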