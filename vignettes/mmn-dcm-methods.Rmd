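---
title: "Dynamic causal modeling of the auditory mismatch negativity: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic causal modeling of the auditory mismatch negativity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmndcm)
```

## What this package models

The mismatch negativity (MMN) is the negative deflection of the auditory
evoked-potential difference wave (deviant minus standard tones), peaking
roughly 100-250 ms after stimulus onset. `mmndcm` implements a complete
desk-scale analogue of a dynamic-causal-modeling (DCM) study of the MMN in
three groups — controls, unaffected first-degree relatives of psychosis
patients, and patients — in which the scientific question is *where in the
auditory hierarchy the gain (self-inhibition) of superficial pyramidal
cells is modulated* by stimulus condition, genetic risk and diagnosis.

Because no EEG recordings are distributed with the package, every analysis
runs on synthetic cohorts with known ground truth: the package simulates
the oddball experiment (1,200 tones, 85% standards of 25 ms, 15% deviants
of 50 ms, 300 ms inter-stimulus interval, three blocks of 400 tones,
acquisition at 500 Hz on a 17-channel 10/20 montage), preprocesses the raw
recordings exactly as an EEG lab would, and inverts the same generative
model that produced the data. Passing tests therefore demonstrate
*internal* consistency — that the inversion machinery recovers what the
simulator planted under realistic noise — not performance on real EEG,
where unmodeled physiology (non-Gaussian background EEG, subject
variability, head-model error) would add sources of error the generator
does not emulate.

## The neural mass model

Each of five sources — bilateral primary auditory cortex (A1), bilateral
superior temporal gyrus (STG), right inferior frontal gyrus (rIFG), with
MNI prior locations from the MMN source-localization literature — is a
canonical microcircuit of four populations: spiny stellate cells (ss),
superficial pyramidal cells (sp), inhibitory interneurons (ii) and deep
pyramidal cells (dp). Each population obeys second-order synaptic
dynamics,

$$\dot v = i, \qquad
  \dot i = \frac{u - 2 i}{T_p} - \frac{v}{T_p^2},$$

where $v$ is the mean postsynaptic depolarization (mV), $T_p$ the
population time constant, and $u$ the gain-weighted presynaptic firing
afferent to the population. Firing is a centred sigmoid
$S(v) = 1/(1+e^{-Rv}) - 1/2$ with slope $R = 2/3$, so the resting state is
a fixed point. The ten intrinsic connections follow the canonical
microcircuit wiring (`cmc_constants()` documents signs and strengths);
extrinsic forward connections run from sp to (ss, dp) of the target,
backward connections from dp to (sp, ii), lateral connections link the
homologous A1 and STG pairs. Auditory input — a Gaussian bump of onset
64 ms and dispersion 16 ms — drives bilateral A1; deviants receive a second
bump delayed by 25 ms, the duration difference between deviant (50 ms) and
standard (25 ms) tones, because duration deviance is physically detectable
only at the standard's offset.

The quantity of scientific interest is the log-scaling of sp
self-inhibition per source (`G_sp`): the *gain* of the prediction-error
units. Larger values mean more self-inhibition, i.e. reduced excitability.
Condition and group effects act additively on this log-scaling through the
factorial design.

### Fixed constants and their calibration

The microcircuit literature fixes the wiring but not
usable numerical values at our integration step, so the defaults in
`cmc_constants()` were frozen once with four requirements: (i) the resting
state is locally stable (all linearization eigenvalues have negative real
part; the default set gives max Re ≈ −0.07/ms); (ii) responses propagate
up the hierarchy so that the frontal source operates at depolarizations
comparable to A1 (strong feedforward gain, `F_ss = 20`); (iii) single-tone
responses decay essentially within the 325 ms stimulus spacing, as real
auditory evoked potentials to brief tones do — this required weak backward
coupling (`B_sp = 0.1`) and slightly faster ii/dp time constants
(8/12 ms) than the canonical 16/28 ms; and (iv) sensor-level amplitudes of
a few microvolts at a baseline dipole moment of 15 nA·m/mV. Requirement
(iii) matters doubly: with 300 ms inter-stimulus intervals, epochs overlap
their predecessors, and a long-ringing generator would make grand averages
systematically different from the isolated-trial predictions the inversion
uses. With the frozen defaults that superposition error is under 2% of
signal RMS.

Integration uses fixed-step RK4 at `dt = 0.5` ms (halving the step changes
the output by well under 0.5%), with 1 ms intrinsic and 16 ms extrinsic
conduction delays realized by linear interpolation of a firing-rate
history buffer; since all couplings are delayed by at least one step, the
afferent drive within a step is an exogenous function of time and the RK4
stages remain explicit.

## Forward model

Each source is an equivalent current dipole; homologous left/right pairs
are mirror-symmetrized and share moment scalings. Scalp potentials come
from the analytic series solution for a three-shell concentric spherical
conductor (brain/skull/scalp conductivities 0.33/0.0042/0.33 S/m, radii
85/88/92 mm, dipoles capped at 80 mm eccentricity), average-referenced;
a user-supplied lead field can replace the spherical model. The series is
evaluated per spherical harmonic by solving the radial transfer system in
radii normalized to the scalp, which keeps terms well-conditioned to
n = 60; the single-shell special case is verified in the test suite
against direct evaluation of the infinite-medium dipole potential plus the
insulating-boundary correction series.

Sensor predictions are `y(t) = M' G diag(m) (0.8 v_sp + 0.2 v_dp)`:
superficial pyramidal cells dominate the observation (the standard reading
of evoked responses), with a small deep-pyramidal contribution; the
weights are configurable. `M` holds the eight leading eigenvectors of the
prior predictive sensor covariance `G G'` (isotropic unit moment priors);
eight modes retain ≥ 99% of simulated sensor variance.

## Synthetic cohorts

`plant_group_effects()` expands per-effect, per-source log-gain deltas
into the six cells of the 2 × 3 design. The default pattern
(`default_effect_config()`) plants: a condition effect of −0.2 at both A1
sources (all groups more excitable to deviants); and at rIFG a risk main
effect of −0.3, a diagnosis main effect of −0.15, a small condition effect
of +0.05, and interactions (+0.2 risk × condition, +0.05
diagnosis × condition) that *reverse* the condition effect in the risk
groups: controls become more excitable to deviants while relatives and
patients become less excitable, with patients most disinhibited overall.
These magnitudes are not printed in any source; they were chosen once as
plausible log-scalings (10–50% gain changes) that express the qualitative
pattern.

`simulate_cohort()` inserts the appropriate simulated ERP at every tone
onset of a continuous 500 Hz recording (450 ms per trial with a raised-
cosine fade over the last 100 ms; contributions superpose when trials
overlap, as in real EEG), then adds IID Gaussian sensor noise (default SD
5 μV per sample) and stereotyped blinks: 300 ms raised-cosine transients,
~120 μV at FP1/FP2, Poisson-arriving at 12/min, with an EOG-like
topography decaying with distance from the eyes (length constant 25 mm).
IID noise matches the observation model of the inversion; real EEG
background is colored and spatially correlated, which is one reason
passing recovery tests here do not guarantee field performance.

## Preprocessing

The chain reproduces a standard sensor-space pipeline, in this order:
common-average re-reference; zero-phase forward-backward Butterworth
filters (0.5 Hz high-pass and 70 Hz low-pass, order 4; 49–50 Hz band-stop,
order 2); polyphase resampling to 200 Hz (Kaiser-windowed sinc); epoching
−100 to +300 ms (inclusive grid, 81 samples at 200 Hz) with baseline
correction over −100 to 0 ms; ICA ocular correction; ±70 μV any-channel
trial rejection; Tukey-bisquare robust averaging (tuning constant 4.685,
residuals standardized per channel/time-point by a MAD computed from the
plain-mean residuals, iterated to a 1e−4 weight tolerance or 20
iterations) followed by the customary post-averaging 70 Hz low-pass; and
unweighted grand averages per group × condition.

Two places needed choices the description of the pipeline leaves open:

* **Epoch grid.** A half-open window would give 80 samples; we adopt the
  inclusive convention (first sample at −100 ms, last at +300 ms, 81
  samples) and document it — the modeled window 0–250 ms always lands on
  grid points either way.
* **Ocular correction.** The data are decomposed into 17 components by
  symmetric FastICA (tanh contrast, deterministic seeded initialization,
  ridge-stabilized whitening because common-average-referenced data are
  rank deficient). Components whose time courses correlate above |r| = 0.7
  with a frontal blink template (FP1/FP2 average, band-limited to the
  0.5–4 Hz blink band) are flagged — at most two, the largest |r| first,
  mirroring manual selection practice. Rather than zeroing a flagged
  component outright, its time course is suppressed only where the
  component is active (|s| > 6 robust SDs, mask dilated by 200 ms — blink
bursts exceed this threshold by an order of magnitude, evoked leakage
does not): blinks
  are temporally sparse, so this removes ≥ 80% of frontal blink-band power
  while sparing evoked variance that leaks into the component estimate —
  full zeroing was measured (on synthetic ground truth, against blink-free
  simulations of the same seed) to distort central-channel evoked
  responses about 2.5× more than gated suppression. Full zeroing remains
  available (`gate = FALSE`).

On noiseless, blink-free synthetic data the whole chain reproduces the
generating ERP to within 5% RMS (edge effects of the filters only).

## Inversion

`variational_laplace()` maximizes the Laplace free energy

$$F = \underbrace{-\tfrac{\tau}{2}\lVert y - g(\theta)\rVert^2 +
  \tfrac{N}{2}(\log\tau - \log 2\pi)}_{\text{accuracy}}
  - \underbrace{\left[\tfrac12 (\theta-\theta_0)^\top \Sigma_0^{-1}
  (\theta-\theta_0) - \tfrac12 \log\lvert \Sigma_0^{-1}\Sigma_q\rvert
  + c_\lambda\right]}_{\text{complexity}}$$

over parameters $\theta$ (Gauss–Newton with Levenberg-style step control:
steps that do not increase $F$ are rejected and the regularization
increased) and the IID noise log-precision $\lambda = \log\tau$
(interleaved one-dimensional maximization; $c_\lambda$ is the
hyperparameter penalty when $\lambda$ is estimated). Gradients of the
forward map are central finite differences (step 1e−3 in log-parameter
space) — robust for a delayed ODE system. Parameters with zero prior
variance are fixed. Convergence is declared after four consecutive
accepted iterations with $\Delta F < 0.01$, capped at 128 iterations. On a
linear-Gaussian conjugate model the converged $F$ equals the analytic log
marginal likelihood (the Laplace approximation is exact there), which the
test suite asserts to 1e−3. Posterior correlations above 0.95 are reported
as identifiability warnings. No random restarts are used by default.

`fit_multicondition()` fits one shared parameter set plus effect-specific
modulation parameters `B` jointly to the six grand averages, windowed to
0–250 ms and projected onto the eight spatial modes; per-cell predictions
apply the cell's design row to the modulations. Priors
(`cmc_priors()`): modulations `B` have variance 1/16, extrinsic couplings,
input gain and moments 1/8 (`full` preset); the `reduced` preset frees
only the modulations, pinning shared dynamics at their prior means — this
is the configuration of the recovery studies, where the generating shared
parameters are the prior means and the scientific question concerns the
modulations.

## Model comparison

The intrinsic model space toggles sp-gain modulation at the three
hierarchical levels (A1, STG, IFG; hemispheric pairs toggle together):
2³ = 8 models, null first. The connection-type space (forward, backward,
intrinsic modulation of the deviant effect) also has 8 members.
`compare_models()` implements fixed-effects selection on grand-average
fits: evidences relative to the designated null, winner by maximal F, ties
broken toward fewer modulated elements, the runner-up margin converted to
an odds ratio $e^{\text{margin}}$, and margins ≥ 3 (odds ≈ 20:1) flagged
as strong evidence.

## Recovery studies and problem sizes

Three seeded studies exercise the whole method; their sizes are the
package's desk-scale choices:

* **Model recovery** (`model_recovery_study()`): ten runs cycling the
  generating model through the 8-member intrinsic space; data are
  simulated at grand-average level in mode space with noise corresponding
  to robust grand averages of the default cohort (SD 0.025 μV standards /
  0.06 μV deviants — band-limited 5 μV trial noise averaged over the
  trials of 12 subjects per group), and all 8 models are fitted with the
  `reduced` preset. Success: the generating model wins or trails the
  winner by less than 3.
* **Null calibration** (`null_calibration_study()`): the same design with
  zero planted effects; success when the null wins or the winner's margin
  over it is below 3.
* **End-to-end pattern recovery** (`pattern_recovery_study()`): the full
  pipeline — cohort simulation (4 subjects/group, the complete 1,200-tone
  paradigm, blinks at 12/min, 5 μV noise), preprocessing, grand averages,
  inversion of the A1+IFG model — checking the recovered gain table for
  the planted signs: negative rIFG risk effect, condition-effect reversal
  at rIFG but not at A1, and a planted-vs-recovered cell-gain correlation
  of at least 0.8. Four subjects per group keeps ten seeded runs tractable
  on one CPU while the full-length paradigm preserves trial counts per
  subject.

## Known limitations

* Fixed-effects comparison on grand averages follows the grand-average
  design it emulates; no subject-level (random-effects) selection is
  provided, so between-subject variance never enters the evidence.
* The spherical head model is a deliberate simplification; supply a
  realistic lead field via `forward_setup(gain = ...)` if you have one.
* The IID noise model (single precision across cells) mismatches the
  4:1 precision ratio between standard and deviant grand averages; this
  costs some efficiency but keeps the hyperparameterization standard.
* Backward couplings are weak in the default dynamics and essentially
  unidentifiable from these data; they are fixed in the `reduced` preset.
* Attention, habituation across blocks and frequency deviants are out of
  scope of the generator.
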