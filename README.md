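# mmndcm

Dynamic causal modeling (DCM) of the auditory mismatch negativity (MMN)
for evoked EEG responses, on fully synthetic cohorts with known ground
truth.

The MMN — the negative deflection of the deviant-minus-standard
difference wave ~100–250 ms after a rule-violating tone — is one of the
most robust electrophysiological findings in psychosis research. Modern
accounts attribute it to changes in the *gain* of superficial pyramidal
cell populations, parameterized in DCM as the inhibitory self-connection
of that population within each cortical source. This package is for
researchers who want a self-contained, inspectable implementation of that
analysis chain: a generative model they can simulate from, invert, and
stress-test with planted effects, without needing access to clinical EEG.

It implements, in R with a small C++ core:

* a **canonical microcircuit neural-mass model** (four populations per
  source: spiny stellate, superficial pyramidal, inhibitory interneurons,
  deep pyramidal; second-order synaptic kernels, centred sigmoid firing,
  conduction delays) over the standard five-source MMN network — bilateral
  A1 and STG plus right IFG, with forward/backward/lateral wiring and
  auditory input to bilateral A1;
* an **analytic three-shell spherical head model** mapping equivalent
  current dipoles to a 17-channel 10/20 montage, with reduction to eight
  spatial modes (a user lead field can be substituted);
* a **synthetic oddball experiment**: 1,200 tones (85% standards/25 ms,
  15% deviants/50 ms), 300 ms ISI, three blocks of 400, digitized at
  500 Hz, with planted group effects on superficial-pyramidal gain,
  Gaussian sensor noise and frontal blink artifacts; EDF export/import;
* the **sensor-space preprocessing chain**: common-average reference,
  0.5/70 Hz Butterworth filters plus 49–50 Hz notch (zero-phase),
  downsampling to 200 Hz, −100..300 ms epochs with baseline correction,
  ICA ocular correction (17 components, at most 2 removed), ±70 μV trial
  rejection, bisquare robust averaging, and grand averages for the six
  group × condition cells;
* **variational Laplace inversion** maximizing the free-energy
  approximation to log model evidence $F = \text{accuracy} -
  \text{complexity}$, fitting one shared parameter set plus
  effect-specific gain modulations jointly to all six cells of the
  2 × 3 (condition × group) factorial design;
* **fixed-effects Bayesian model selection** over the 8-model intrinsic
  space (gain modulation at A1, STG, IFG and all combinations) and the
  8-model connection-type space, with the log-evidence margin ≥ 3
  (odds ≈ 20:1) rule for strong evidence.

## A worked example

Simulate a small cohort with the default planted pattern (all groups more
excitable to deviants in A1; in rIFG the risk groups more excitable
overall but with a *reversed* condition effect), run the full analysis
over the two strongest models, and inspect the result:

```r
library(mmndcm)

report <- run_full_analysis(list(
  seed = 42,
  n_subjects_per_group = 4,
  space = c("A1", "A1+IFG"),   # subset of the intrinsic space
  max_iter = 24))
report
#> Fixed-effects Bayesian model selection
#>   model        F    rel_F n_modulated
#>  A1+IFG 2556.506 11.71733           3
#>      A1 2544.789  0.00000           2
#> winner: A1+IFG (margin 11.72 over A1, odds ratio 122679.6:1, strong evidence)
#>
#> Posterior gain modulations (negative = more excitable):
#>                cell source   gain    sd
#>   controls.standard    lA1  0.160 0.014
#>    controls.deviant    lA1 -0.185 0.013
#>   ...
#>   controls.standard   rIFG  0.562 0.132
#>    controls.deviant   rIFG  0.376 0.117
#>  relatives.standard   rIFG -0.716 0.259
#>   relatives.deviant   rIFG -0.086 0.161
#>   patients.standard   rIFG -0.770 0.264
#>    patients.deviant   rIFG -0.304 0.181
#>
#> rIFG risk effect: -0.938; rIFG reversal: TRUE; A1 reversal: FALSE
```

Reading the numbers: gains are log-scalings of superficial-pyramidal
self-inhibition per cell, so *negative means disinhibited (more
excitable)*. Here controls decrease self-inhibition for deviants
(0.56 → 0.38) while relatives and patients move the other way — the
reversal flag; and the risk groups sit well below controls overall (the
negative risk effect), patients lowest. That is the planted pattern, and
`planted_gain_table(report$truth)` gives the ground truth to compare
against. `plot_bms(report$bms)` and
`plot_gain_modulations(report$gain_table)` draw the corresponding figures.

Lower-level entry points: `generate_stimulus_sequence()`,
`plant_group_effects()`, `simulate_cohort()`, `preprocess_subject()`,
`grand_average()`, `integrate_erp()`, `observe()`,
`fit_multicondition()`, `compare_models()`, `write_edf()`.

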