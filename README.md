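# balancefb

Identification of the sensorimotor transformation behind the **ankle balance
strategy**: does delayed linear feedback of whole-body center-of-mass (COM)
kinematics — rather than local ankle-joint feedback — explain the reactive
ankle moments and muscle activity seen when standing or walking is perturbed?

The package is aimed at motor-control and biomechanics researchers working
with perturbed standing/walking recordings (platform translations, pelvis
pushes, discrete or continuous treadmill belt-speed perturbations). It
implements the full analysis chain and a ground-truth simulator so every
stage is verifiable by parameter recovery.

## The model

Reactive ankle moment and muscle activity are modelled as delayed
proportional-derivative feedback of COM deviations from the unperturbed
reference:

    ΔT_a(t)  = Kp(s) ΔCOM(t − τ_T) + Kv(s) ΔCOṀ(t − τ_T)      (τ_T = 100 ms)
    ΔEMG(t)  = Kp(s) ΔCOM(t − τ_m) + Kv(s) ΔCOṀ(t − τ_m)      (τ_m = 60 ms)

against the local alternative that replaces COM deviations with ankle
angle/velocity deviations (τ = 80/40 ms). Gains may depend on the gait phase
`s`. Fits are two-parameter no-intercept least squares on
non-dimensionalized deviations; fit quality is the uncentered
R² = 1 − Σ(y−ŷ)²/Σy² (possibly negative, never clamped). Model variants:
discrete-onset scalar gains, 16-bin stance profiles, constant gains, and
constant gains multiplied by a delayed sensory modulator (vertical ground
reaction force or COP-to-foot-bound distance). Models are compared across
subjects with Fisher-z paired t-tests and a within-subject repeated-measures
ANOVA with Bonferroni post-hocs.

## Worked example

```r
library(balancefb)

# synthetic platform-translation protocol with known gains Kp = 2.0, Kv = 0.6
sim <- simulate_standing(sim_params("standing_translation", seed = 1))

fit_discrete_onset(sim$dataset, model = "com", output = "moment",
                   scope = "pooled")
#> <fit_result> model=com output=moment scope=pooled
#>   Kp=2.035 Kv=0.6083  R2=0.9988 RMSE=0.00345 (n=16)

fit_discrete_onset(sim$dataset, model = "joint", output = "moment",
                   scope = "pooled")$r2
#> [1] 0.8490594
```

The COM model recovers the generative gains (2.035 vs 2.0 and 0.608 vs 0.6
under default measurement noise; exactly, with noise off) and explains ~99%
of the reactive moment, while the joint-kinematics model — whose ankle angle
is COM-consistent but carries independent sensor noise — explains markedly
less. That asymmetry, and its statistics across simulated subjects, is the
package's core finding-reproduction machinery.

Walking analyses follow the same pattern: `simulate_walking()` +
`fit_phase_binned()` recover a mid-stance-peaked, swing-silent gain profile
from hundreds of strides of continuous belt perturbation;
`fit_constant_gain()` and `fit_modulated_gain()` provide the nested
comparison models; `delay_sensitivity()` sweeps the response delay and peaks
at the true 100 ms.

## Command line

```sh
Rscript inst/cli/balancefb simulate --protocol belt_continuous --seed 7 \
        --n_strides 100 --output data_dir
Rscript inst/cli/balancefb fit --input data_dir --model com,constant \
        --bins 16 --output fits_dir
Rscript inst/cli/balancefb report --input fits_dir
```

Every run writes a `manifest.json` (config, input hashes, package version).
Results go to files; logs to stderr.

## Layout

- `R/` — trial data model and canonical CSV format, preprocessing (gait
  events, phase normalization, references, deviations,
  non-dimensionalization, delays), gain identification, comparison
  statistics, simulator, CLI.
- `src/` — 1 kHz delayed-feedback inverted-pendulum integrator (Rcpp).
- `vignettes/feedback-identification.Rmd` — methods: model, assumptions,
  stated-world choices, numerical decisions, limitations.
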