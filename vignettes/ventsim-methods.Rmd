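---
title: "ventsim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ventsim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventsim)
```

`ventsim` packages two things: an in-silico surrogate of an anaesthetized
pig with graded respiratory insufficiency, assisted by an implanted
pneumatic-artificial-muscle (PAM) diaphragm-assist system; and the
waveform-analysis pipeline used to quantify how well such a system augments
ventilation. This vignette explains the models, the parameters that matter,
the design choices that were genuinely open, and what the packaged
scenarios can and cannot say about real animals.

## The respiratory mechanics surrogate

The subject is a single-compartment linear respiratory system. With airway
flow $Q$ (l/s), lung volume above the end-expiratory reference $V$ (ml),
airway resistance $R_{aw}$ (cmH2O·s/l) and total respiratory compliance
$C_{rs}$ ($1/C_{rs} = 1/C_L + 1/C_{cw}$, ml/cmH2O), the equation of motion
is

$$R_{aw}\,Q + V/C_{rs} = P_{vent} + P_{mus,di} + P_{mus,rc} + P_{act},$$

driven by up to three pressure sources: a positive-pressure ventilator
$P_{vent}$, respiratory muscles split into a diaphragmatic fraction
$f_{di}$ (default 0.7 — the diaphragm contributes up to ~70% of inspiration
in a healthy subject) and a ribcage remainder, and the actuator's
equivalent muscle pressure $P_{act} = k_{act}\,p_{act}$ with $p_{act}$ the
PAM pressure in psi. Severing the phrenic nerves zeroes only the
diaphragmatic term; the ribcage term persists as the residual effort of a
paralyzed-diaphragm subject. Exactly one of {muscle drive, ventilator} may
be active in a record, mirroring how respiratory challenges were run.

Each inspiratory effort follows an occupational profile: a smooth
$\sin^2$ rise over the inspiratory time $T_i$ to the breath amplitude, then
exponential relaxation with time constant $\tau_{rel}$. Breath amplitude
carries multiplicative Gaussian jitter; all sensor channels carry additive
Gaussian noise. Both are seeded: identical seeds give bit-identical
records.

Derived sensor channels:

* pleural surrogate: $P_{pl} = V/C_{cw} - (P_{mus} + (1-\beta)\,P_{act})$.
  Under passive positive-pressure inflation this reduces to $V/C_{cw}$
  (pleural pressure rises with inspiration); under spontaneous or assisted
  breathing the muscle/actuator term dominates and the excursion is
  negative. $\beta$ (`beta_eso`) is the fraction of the actuator's
  equivalent pressure read directly by the oesophageal balloon: the PAMs
  lie against the mediastinum, so part of their push registers on the
  sensor mechanically rather than through the pleural space. With
  $\beta = 0$ the pure superposition form is recovered; the calibrated
  subject uses $\beta = 0.72$, without which a linear single-compartment
  model cannot reproduce the observed pairing of a ~3x tidal-volume
  augmentation with only a ~1.7x rise in work of breathing per litre.
* abdominal surrogate: $P_{ab} = \gamma_{ab}(P_{mus,di} + P_{act})$ — the
  diaphragm descending against abdominal contents raises gastric pressure;
  a passive diaphragm under mechanical ventilation leaves it flat.
* diaphragm displacement: $d_{dia} = k_{disp}(P_{mus,di} +
  \lambda\,P_{act})$. M-mode ultrasound reads displacement along the
  actuator line, where the local push of the PAM exceeds its
  volume-averaged effect (the actuators act along two discrete lines on the
  diaphragm), hence the local weighting $\lambda \ge 1$ (calibrated 1.6).

Integration is fixed-step at the 1 kHz output rate (Heun's method for the
volume state; the electropneumatic lag is advanced by its exact exponential
update). Stiffness is absent at physiological parameters
($\tau = R_{aw} C_{rs} \approx 0.1$ s $\gg$ 1 ms); a 10x-finer-step
Runge-Kutta oracle in the test suite bounds the relative error in tidal
volume and peak pleural excursion below $10^{-3}$. The volume channel is
emitted as the cumulative trapezoidal integral of the emitted (noisy) flow
channel, so flow-volume conservation holds exactly on every record, as it
does for spirometry-integrated volume.

## Gas exchange and chemoreflex

Arterial CO2 follows a one-pool balance,
$\dot{P}_aCO_2 = (0.863\,\dot{V}CO_2 - P_aCO_2\,\dot{V}_A)/V_{store}$
(per minute), whose fixed point is the classic alveolar CO2 relation
$P_aCO_2^* = 0.863\,\dot{V}CO_2/\dot{V}_A$. Alveolar ventilation is
computed per breath as $RR \cdot \max(TV - V_D, 0)/1000$; under apnoea
PaCO2 rises strictly. pH is derived by Henderson–Hasselbalch,
$pH = 6.1 + \log_{10}(HCO_3/(0.03\,P_aCO_2))$, with bicarbonate held
constant (no metabolic compensation on the minutes scale simulated).
Defaults ($\dot{V}CO_2$ = 150 ml/min, $V_{store}$ = 15 l) give an apnoeic
rise of ~8.6 mmHg/min and a normocapnic fixed point near 40 mmHg at
3.2 l/min — a hypercarbia time course consistent with CO2 accumulating
substantially within two minutes of unsupported breathing.

The chemoreflex raises drive amplitude and respiratory rate linearly with
PaCO2 above a set point, smoothed with a ~20 s first-order lag to mimic the
slow drive evolution visible over the first minutes of a respiratory
challenge. The calibrated best-responder scenario freezes the drive
(`G_drive = G_rr = 0`): its published endpoints are steady-state vignette
values, and a stationary baseline is what makes a +/-5% calibration
meaningful. The `weak-responder` scenario keeps the feedback active.

## Actuator model

The PAM follows idealized McKibben braid statics (Chou–Hannaford),
$F = \tfrac{\pi D_0^2 P}{4}\left(\tfrac{3(1-\varepsilon)^2}{\tan^2\theta_0}
- \tfrac{1}{\sin^2\theta_0}\right)$, clamped at zero past braid lock.
Friction and end effects are ignored. The default geometry fixes a typical
25-degree braid angle and solves the resting diameter so that 20 psi at
zero contraction yields 40 N, matching the bench characterization of the
implanted actuators; the implied ~6.7 mm diameter is consistent with the
1/4-inch braid they were built from. A virtual-work computation (numeric
$-P\,dV/dL$ on the cylindrical braid kinematics) serves as an independent
oracle in the tests. The electropneumatic regulator and line are a
first-order lag; commanded cycles are trapezoids or raised-cosine humps
with the nominal 20 psi peak.

Coupling into the lung model is a single gain `k_act` (cmH2O/psi) rather
than a force-to-pressure continuum model — the lumped simulator has no
spatial diaphragm, so a continuum coupling would add parameters the
calibration endpoints cannot identify.

## Triggering

The synchronized controller is the causal, single-pass state machine of the
hardware: a trigger fires at the first sample with flow at or above the
threshold while armed; the detector disarms on firing and re-arms only
after flow falls below threshold x (1 - hysteresis) AND the refractory
interval has elapsed. Hysteresis is read as a fraction of the threshold
(the cleanest dimensionless reading of a "2-5%" hysteresis on a threshold
titrated between 0.01 and 0.07 l/s). The refractory interval defaults to
the commanded cycle length, because the regulator plays one full cycle per
pulse. Thresholds inside the flow-noise floor reproduce the documented
failure mode: pre-emptive (false) triggers and negative P0-V0 intervals.
The independent mode is a fixed-rate schedule, blind to the flow channel.

## The analysis pipeline

Breath bounds are local minima of the volume channel, filtered by
topographic prominence (default 5 ml) and minimum separation (default
0.5 s); the defaults reject 1 kHz sensor noise while keeping every
physiological breath, and both are exposed as parameters. Within a breath,
the start of expiration $V_{pk}$ is the volume argmax and $F_{pk}$ the
flow argmax over the inspiratory window $[V_0, V_{pk}]$ (expiratory-phase
flow spikes are excluded by construction). Tidal volume is
$V(V_{pk}) - V(V_0)$; minute ventilation sums tidal volumes of breaths
starting inside a window (partial breaths at window edges count if their
$V_0$ lies inside — the windowed comparisons use 30 s steady-state
windows). Actuation onsets $P_0$ are rising excursions of the actuator
pressure above 1 psi, debounced with a release level at half the
threshold. Each breath is matched to the unique actuation with $P_0 \in
[t_{V0} - T_{tot}/2,\; t_{Vpk} + T_{tot}/2)$; breaths with zero or several
candidates are flagged and excluded from regressions. Pressure channels are
normalized by zeroing the mean of the samples at the breath bounds, and
per-breath deltas are read against each breath's own bound baseline: the
signed largest-magnitude excursion for $P_{pl}$, peak rises for $P_{ab}$
and for $P_{di} = P_{ab} - P_{pl}$ computed sample-wise (not as a
difference of deltas). Timing regressions are ordinary least squares with
the two-sided slope test.

## Campbell-diagram work of breathing

The passive chest-wall line is fit by pooled least squares of volume on
pleural pressure over the *inspiratory* limbs of mechanical-ventilation
loops (expiratory limbs are excluded to avoid hysteresis bias). Work for a
breath is the area between the inspiratory limb of its pleural PV loop and
the compliance line over the same volume span: the line is evaluated at the
limb's volume samples, the region is integrated in volume with splits at
limb-line crossings, and absolute sub-areas are summed (the shaded-region
reading of a Campbell diagram), converted at 1 cmH2O·l = 0.0980665 J. Work
per litre divides by the breath's tidal volume; the summary reports the
per-breath mean as the headline and the pooled total-work-over-total-volume
alternative alongside, since the averaging convention behind a single
published "total average WOB" figure is ambiguous. Normalization
independence (adding a constant to the pressure channel changes nothing)
and linearity in pressure excursions are property-tested.

## Packaged scenarios and calibration

Four scenario files ship with the package (`list_scenarios()`), each a flat
YAML with frozen parameters and seed:

* **subject-A** — the best responder. Passive mechanics $R_{aw}$ = 2.5
  cmH2O·s/l, $C_L$ = 63.5, $C_{cw}$ = 120 ml/cmH2O, 35 kg; drive amplitude
  1.51 cmH2O at 19.3 breaths/min. The drive amplitude, inspiratory
  fraction, actuator coupling, oesophageal transmission fraction and
  displacement gains were calibrated once against the published
  best-responder endpoints — unassisted/assisted tidal volume 55/161 ml,
  peak inspiratory flow 0.18/0.59 l/s, assisted minute ventilation
  3.1 l/min, displacement 0.37/1.92 cm, WOB 0.10/0.17 J/l — and then
  frozen; the acceptance script re-derives all of them from fresh
  simulations.
* **mech-vent** — the same passive subject under pressure-control
  ventilation (9 cmH2O, 18/min): the source of the chest-wall compliance
  line and of the positive-$\Delta P_{pl}$ / flat-$P_{ab}$ sign contract.
* **severed-phrenic** — bilateral phrenicotomy: the diaphragmatic term is
  zeroed, leaving a weak, slow, irregular ribcage effort
  ($f_{di}$ = 0.8, so the residual carries 20% of the muscle pressure;
  amplitude jitter 35% reflects the unstable residual drive of a severe
  insufficiency model). Independent actuation at 18/min against the
  ~15.5/min residual rhythm sweeps all alignments, reproducing the
  timing-alignment experiment.
* **weak-responder** — a low-coupling subject with the CO2 chemoreflex
  active, for drive-dynamics and gas-exchange behaviour.

## What the generator does and does not emulate

The surrogate reproduces the statistical structure the pipeline assumes:
uniformly sampled multichannel records, breath-to-breath amplitude jitter,
sensor noise, mode-dependent pressure signatures, CO2 dynamics, and
trigger-actuation timing interplay. It does not emulate cardiogenic
oscillations on the balloon channels, oesophageal peristalsis artefacts,
nonlinear or volume-dependent compliances, airway secretions or leaks,
anaesthetic pharmacokinetics, O2 transport, or any spatial diaphragm
mechanics. Passing calibration contracts therefore shows that the analysis
code measures what it claims on signals with this structure — not that the
mechanical model generalizes to real animals.

## Numerical and design notes

* Indices are half-open and 1-based internally; reported times are seconds
  from record start.
* Bound candidates tie-break by volume value, then index; `which.max`
  takes the first of tied maxima. Constant series yield zero breaths, not
  an error.
* The breath-actuation matching window is this package's rule; records
  flag it in metadata (`analyze_record` reports matched counts alongside).
* The fixed-rate schedule treats the duration end-exclusively (a cycle
  beginning exactly at the record end is not emitted), keeping event counts
  consistent with the emitted record length.
* Scenario simulations run 60-720 s at 1 kHz; the sizes were chosen so
  every packaged experiment (including the 200-breath severed-phrenic
  regression) completes in minutes on a single core while holding
  Monte-Carlo error well inside the calibration tolerances.
* Degenerate inputs: zero-variance regressors, empty windows, loops with
  zero tidal volume and missing segments raise structured errors or
  warnings rather than propagating NaNs.

## Known limitations

The calibration identifies one parameter set consistent with the published
endpoints; it is not unique, and the per-subject spread of real mechanics
is far wider than the four packaged scenarios. The oesophageal-transmission
fraction $\beta$ and displacement weighting $\lambda$ are effective,
measurement-level parameters — physically motivated, but not separately
identifiable from the endpoint data used to calibrate them. The CO2 pool
model collapses tissue and blood stores into one compartment, so transient
time constants are only order-of-magnitude. The trigger model has no
sensor latency beyond the one-sample causal delay.
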