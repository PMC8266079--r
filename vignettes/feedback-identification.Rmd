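---
title: "Identifying delayed COM feedback behind the ankle balance strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying delayed COM feedback behind the ankle balance strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balancefb)
```

## The model

Upright humans are an inverted pendulum balanced by ankle moments. When
standing or walking is perturbed, the reactive change in the ankle moment
(and in the activity of the muscles that produce it) can be described as
*delayed linear feedback of task-level variables* — the anterior-posterior
position and velocity of the whole-body center of mass (COM) relative to the
base of support:

$$\Delta T_a(t) = K_p(s)\,\Delta COM(t-\tau_T) + K_v(s)\,\Delta \dot{COM}(t-\tau_T)$$
$$\Delta EMG(t) = K_p(s)\,\Delta COM(t-\tau_m) + K_v(s)\,\Delta \dot{COM}(t-\tau_m)$$

where the $\Delta$ quantities are deviations from an unperturbed reference,
$\tau_T$ and $\tau_m$ are neural (plus, for moments, electromechanical)
delays, and the gains $K_p, K_v$ may depend on the gait phase $s$. The
competing local hypothesis replaces the COM deviations with ankle-joint
angle and angular-velocity deviations, with shorter delays appropriate for
spinal reflex pathways. This package estimates these gains from data and
compares the two hypotheses, plus phase-binned, constant and
sensory-modulated gain variants.

All regressions are two-parameter ordinary least squares **without an
intercept**: the inputs and outputs are deviations from a reference, so a
non-zero intercept would absorb reference error rather than describe
control. Consistently, goodness of fit is the *uncentered* coefficient of
determination

$$R^2 = 1 - \frac{\sum (y_{meas} - y_{mod})^2}{\sum y_{meas}^2},$$

which can be negative; negative values are reported as-is (they are
diagnostic: the model does worse than predicting zero).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| $\tau_m$, $\tau_T$ (COM model) | 60 ms, 100 ms | deviation-to-EMG and deviation-to-moment latency of the task-level pathway |
| $\tau_m$, $\tau_T$ (joint model) | 40 ms, 80 ms | shorter local-reflex latency |
| input latency | 150 ms | when after perturbation onset the kinematic deviation is sampled (responses are large and well formed there) |
| phase bins | 16 over stance | resolution of the phase-dependent gain profile |
| $\alpha$ | 0.05 | two-sided test level |

The "230–250 ms" output window for discrete fits is resolved as
*onset + 150 ms + model delay* (COM: 250 ms, joint: 230 ms; EMG: 210/190 ms),
one rule consistent with the per-model delays.

Quantities are pooled across subjects non-dimensionally: positions by the
standing COM height $l_{max}$, velocities by $\sqrt{g\,l_{max}}$, torques by
$m\,g\,l_{max}$, EMG by maximal voluntary contraction (standing) or by the
peak of the gait-cycle-average unperturbed activity (walking, where MVC is
typically unavailable — which is also why EMG fits are per-subject only).
Moment fits pool both perturbation directions into one regression; EMG fits
are direction-split, because muscle activity is half-wave gated (calf
muscles respond to forward falls, tibialis anterior to backward falls).

## The synthetic stated world

The simulator deliberately uses the feedback law itself as the generative
mechanism, embedded in a linearized inverted pendulum integrated at 1 kHz
with a ring-buffer delay (delays exact to 1 ms) and downsampled to the
canonical 100 Hz. That makes *generative-inverse exactness* a testable
property: with every noise source off, the identification pipeline must
return the true gains with $R^2 = 1$ to machine precision — and it does,
through the full pipeline including reference construction, phase locking
and non-dimensionalization, not through any shortcut.

Choices a user should know about, with the reasoning:

* **Spontaneous sway as process noise.** Each trial's deviation dynamics are
  driven by low-pass-filtered random accelerations (RMS 0.05 m/s², cutoff
  0.7 Hz) emulating internal postural noise. This is not cosmetic: without
  it, all trials of a deterministic protocol are scalar multiples of one
  response, the regression design is rank-deficient and the response delay
  is unidentifiable (any delay fits, because the closed loop's
  low-dimensional flow maps the state at one time linearly to the moment at
  any later time). Sway breaks that degeneracy — and scatters unperturbed
  trials around zero, as real unperturbed data scatter. Because sway enters
  the *loop* rather than the measurements, the delayed feedback relation
  between the emitted signals stays exact at any sway level.
* **Measurement noise** is additive on the emitted channels only (defaults:
  2 mm COM position, 0.01 m/s velocity, 1 N·m moment, 0.01 normalized EMG
  units, 5 N force, 2 mm COP — motion-capture-scale magnitudes).
* **Ankle angle** is the pendulum-consistent angle plus independent noise
  (default 0.02 rad). It is therefore *correlated with but not linearly
  predictive of* the COM: exactly the property that lets the COM model beat
  the joint model, mirroring the experimental finding.
* **Perturbations.** Standing: forward/backward platform-acceleration
  pulses, fast/medium/slow profiles (3.5/2.5/1.5 m/s² with 0.1/0.2/0.3 s
  half-widths). Walking: pelvis-push or belt pulses (~15% body weight) at
  the contralateral toe-off phase (10% of the stride), with pulse widths
  varied across magnitudes so trial responses are not collinear; or
  continuous low-pass pseudo-random belt acceleration (RMS 0.1 m/s²) over
  hundreds of strides.
* **Gait templates.** Stride time 1.0 s, stance fraction 0.6, double-humped
  vertical GRF vanishing in swing, heel-to-toe COP progression, smooth
  periodic COM/ankle curves; gait events are emitted exactly from the
  template. The 1.0 s stride puts every 100 Hz sample exactly on the
  200-point reference phase grid, so phase-locked deviations are exact for
  noiseless data.
* **Gain profile.** A raised-cosine window in stride phase (default peak
  0.30, width 0.50, peaks $K_p$ = 1.2, $K_v$ = 0.4), inside stance and zero
  in swing — the mid-stance-peaked, swing-silent modulation the walking
  analyses are designed to detect.
* **Heel-strike base-of-support switch.** COM position is stored relative
  to the stance foot, so the frame switches at each heel strike; the
  simulator implements this as retaining 10% of the deviation and 20% of
  the deviation velocity across the switch. Physically this is a crude
  stand-in for the stepping strategy (out of scope as a model), and
  numerically it is what keeps the loop bounded through the zero-gain swing
  phase; with no reset the pendulum diverges over hundreds of strides.

What a green test does **not** establish: the simulator has no
musculoskeletal dynamics, no muscle contraction model, no foot-placement
control, no 3D motion, and its "EMG" is the rectified feedback drive plus
noise. Green tests certify the *identification machinery* (estimators,
preprocessing, statistics), not the physiology.

## Numerical choices

* Delays that are integer multiples of the sample period are exact shifts;
  fractional delays interpolate linearly. Leading pre-delay samples are
  masked (`NA`), never imputed.
* Rank-deficient two-column designs abort with the condition number
  (threshold $10^8$); per-bin regressions need at least 4 rows, otherwise
  the bin is flagged absent rather than zero-filled.
* An all-zero response (e.g. a noiseless swing bin) has undefined
  uncentered $R^2$; `uncentered_r2()` errors, and per-bin tables carry `NA`.
* Fisher's $z$ is applied to $r = +\sqrt{R^2}$; negative uncentered $R^2$
  has no correlation interpretation, so such entries are dropped with a
  warning before paired tests.
* The paired test returns $t = 0, p = 1$ for literally identical inputs and
  raises a degeneracy error for constant non-zero differences. The
  repeated-measures ANOVA uses the plain within-subject decomposition with
  no sphericity correction (condition counts are small), Bonferroni-capped
  post-hoc p-values.
* Per-bin estimates are within-bin weighted averages of the true profile;
  where the profile curves strongly inside a bin they can differ from the
  bin-center value by tens of percent while remaining inside the within-bin
  envelope. Tests assert the envelope and the profile correlation, not
  bin-center equality.

## Open design points resolved here

* Pooled fits stack non-dimensional rows from all subjects with equal row
  weight (subjects with more trials weigh more).
* Unperturbed trials contribute near-zero rows to discrete-onset
  regressions (at matching time offsets or stride phases).
* The sensory-modulated models use the moment delay (100 ms) for the
  modulator; modulators are non-dimensionalized (vertical force by body
  weight, COP-to-bound distance by foot length) so gains stay
  non-dimensional. With a unit modulator the fit reduces bit-for-bit to the
  constant-gain fit.
* The supplementary-archive importer is an optional extra behind an
  explicit command; its variable mapping is a versioned table authored
  against a documented synthetic layout, because the real archives' internal
  structure is not described anywhere accessible to this build.

## Worked example

```{r example, eval = FALSE}
library(balancefb)

# a synthetic standing protocol with known gains (Kp = 2.0, Kv = 0.6)
sim <- simulate_standing(sim_params("standing_translation", seed = 1))
fit_discrete_onset(sim$dataset, model = "com", output = "moment",
                   scope = "pooled")
#> <fit_result> model=com output=moment scope=pooled
#>   Kp=2.035 Kv=0.6083  R2=0.9988 RMSE=0.00345 (n=16)

# the local-feedback alternative fits worse on the same data
fit_discrete_onset(sim$dataset, model = "joint", output = "moment",
                   scope = "pooled")$r2
#> [1] 0.8490594
```

## Known limitations

* Phase-binned fits support the ankle-moment output only; EMG phase
  profiles would need the direction split crossed with bins and many more
  strides than the emulated protocols provide.
* The importer's variable mapping must be revised against the real
  supplementary archives before it can ingest them.
* Continuous-protocol references come from separate unperturbed trials; if
  only perturbed data existed, the reference would need to be built from
  the perturbed strides themselves, which this package does not do.
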