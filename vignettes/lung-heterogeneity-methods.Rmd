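---
title: "Measuring lung heterogeneity: inspired sinewave tracer tests and quantitative CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lung heterogeneity: inspired sinewave tracer tests and quantitative CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lunghet)
```

## The problem

In the injured (ARDS) lung, ventilation and perfusion are distributed
unevenly across lung units, and this *heterogeneity* — rather than any
single global volume or flow — is what positive end-expiratory pressure
(PEEP) titration tries to reduce. Quantitative CT is the reference way to
see it, but it is not a bedside tool. The inspired sinewave technique
(IST) modulates a low-dose soluble tracer gas (N₂O) in the inspired air as
a slow sinusoid and reads the attenuated, phase-lagged sinusoid in the
expired gas; because differently ventilated units filter the forcing
differently, the period-dependence of the recovered lung parameters
encodes heterogeneity.

`lunghet` implements both sides of that comparison — the IST forward
model, parameter recovery and two heterogeneity indices; the quantitative
CT aeration and voxel-ring inhomogeneity analysis — plus the statistics
that link them, and a synthetic porcine cohort generator so the whole
chain can be validated end-to-end without animal data.

## The tidal-breathing tracer model

The lung is `n` equal-volume alveolar compartments (default 50). Specific
ventilations and perfusions are log-normally distributed across
compartments with spreads `LogSDv` and `LogSDp`; a homogeneous lung has
spread zero. Distributions are discretized at quantile midpoints
(`discretize_lognormal()`), not sampled, so every simulation is
deterministic and the estimator's objective surface is noise-free. The
two weight vectors are paired in bit-reversal (van der Corput) order,
which leaves ventilation and perfusion effectively rank-uncorrelated
across compartments while staying reproducible; we treat the V/Q
correlation structure as unknown and choose the neutral option.

Each breath applies three steps in fixed order (`simulate_breaths()`):

1. **Inspiration.** The series deadspace gas (at the previous breath's
   mixed end-expiratory composition) is re-inspired first and distributed
   to compartments in proportion to their fresh-gas shares
   $\Delta V_i = s_i V_i (V_T - V_D)$, followed by fresh gas at
   $F_I(t) = F_0 + A \sin(2\pi t / T)$. Both dilute the alveolar content.
2. **Uptake.** Tracer leaves to pulmonary blood at rate
   $\lambda_b\, q_i\, (C_i - C_{\bar v})$, integrated exactly over the
   breath as an exponential relaxation. $\lambda_b = 0.47$ is the N₂O
   blood–gas partition coefficient; mixed-venous content defaults to zero
   (no recirculation over a short test).
3. **Expiration.** The measured output is the flow-weighted mixed
   end-expiratory fraction
   $F_{ET} = \sum_i \Delta V_i C_i / \sum_i \Delta V_i$.

This discrete per-breath recursion conserves tracer mass exactly, which
the test suite asserts to $10^{-9}$ relative. The default forcing uses
$F_0 = 0.04$, $A = 0.02$ (4 ± 2% tracer), periods of 180 s and 60 s, and a
tidal volume of 10 mL/kg at 20–25 breaths/min, matching bedside practice.

## Recovering ELV and Qp, and the ratio indices

For a *single* compartment the recursion is linear with per-breath
transfer function

$$H(\omega) = \frac{g\,\gamma}{1 - g\,\beta\, e^{-i\omega T_b}},\qquad
\beta = \frac{ELV + V_D}{ELV + V_T},\quad
\gamma = \frac{V_T - V_D}{ELV + V_T},$$

where $g$ is the per-breath uptake factor and $T_b$ the breath duration.
`fit_sinusoid()` projects both trace channels onto $\{1, \sin, \cos\}$ at
the known forcing frequency (after a warm-up discard of one forcing
period, floored at 80 breaths so the washin transient is negligible even
at the 60 s period); `invert_single_compartment()` then solves the
measured complex gain for the two unknowns. Requiring $g$ to be real
reduces the problem to one bracketed root-find in ELV (tolerance
$10^{-10}$ relative), after which $Qp = -(ELV + V_T)\ln g /(\lambda_b
T_b)$ is closed-form. Round-trips on simulator data are exact to about
$10^{-5}$. Deadspace is a known input throughout: the synthetic protocol
provides it, and estimating it (Fowler/Bohr staging) is deliberately out
of scope because it would confound the validation of the heterogeneity
indices.

Applied to a *heterogeneous* lung this one-compartment inversion is
deliberately mis-specified: slowly ventilated units contribute little at
short periods, so recovered ELV falls as the period shortens. The
conventional bedside indices exploit exactly that:
`h_ratio_v = ELV₁₈₀/ELV₆₀` and `h_ratio_p = Qp₆₀/Qp₁₈₀`, both 1.0 for a
homogeneous lung and rising with heterogeneity.

## The simulation-fitted LogSD indices

`estimate_logsd()` asks: which spreads, fed through the full forward
pipeline, reproduce the measured results at both periods? The objective
is the scale-free L1 loss

$$L(\mathrm{LogSD}) = \lvert y_{180s} - \hat y(\mathrm{LogSD})\rvert
 + \lvert y_{60s} - \hat y(\mathrm{LogSD})\rvert,$$

with $y = (ELV, Qp)$ per period and residuals divided by the reference
totals so volume and flow are commensurate. The reference totals are the
180 s recoveries — the longest period is the least heterogeneity-biased.
Optimisation is a 13 × 13 grid over $[0, 3]^2$ followed by Nelder–Mead
refinement from the best node; deterministic by construction, no random
restarts. Infeasible forward points (no inversion solution) get infinite
loss.

One design choice deserves emphasis. On real (or realistically synthetic)
measurements the 180 s recoveries are themselves biased low by
heterogeneity, so taking them at face value as the simulator's *true*
totals creates a contradiction: the forward model can then never
reproduce the measured 180 s values at any positive spread, and the
estimator trades spread against level, compressing LogSD toward zero and
even breaking monotonicity. `estimate_logsd()` therefore calibrates by
default: each candidate prediction is rescaled by one multiplicative
factor per channel so its 180 s recoveries match the measured ones
exactly, making the total volume and flow analytically solved nuisance
quantities while the spreads are fitted to the period-dependence — the
part of the signal that actually carries heterogeneity. In
*self-consistent* recovery (measurements generated with known totals) the
estimator returns the truth essentially exactly; the tests require ±0.15
noiselessly and a median absolute error ≤ 0.25 under 0.5% measurement
noise. In the cohort setting the ventilation spread remains a faithful
monotone encoding of the latent heterogeneity, which the tests assert
across the PEEP ladder; the perfusion spread is only weakly identified at
low ventilation heterogeneity (a near-flat loss ridge), mirroring the
weaker perfusion agreement reported in vivo.

## Quantitative CT

`classify_aeration()` bins masked voxels into the four functional
compartments exactly as conventionally printed — over-distended
[−1000, −901] HU, normally aerated [−900, −501], poorly aerated
[−500, −101], atelectasis [−100, +100] — using half-integer cut points so
integer HU cannot fall in a gap; HU below −1000 clamp to −1000 and masked
voxels above +100 are excluded (reported separately). Volumes follow from
the voxel size and tissue mass from the air/water mixture model
(`gas_tissue_fractions()`, water at 1 g/cm³).

`cressoni_index()` computes per-voxel inhomogeneity as the mean **gas
fraction** of the surrounding ring (voxel-centre distances 2.41–3.675 mm;
purely in-plane at 0.5 × 0.5 × 5 mm spacing) divided by the voxel's own
gas fraction, floored at 0.01 so dense atelectasis cannot divide by ~0.
The inflation-ratio form follows the original stress-raiser metric; the
index is 1 in homogeneous lung and large where a dense voxel abuts
aerated tissue. A voxel's index is valid only if at least half of its
geometric ring lies inside the mask — a conservative edge rule, since the
border behaviour is not specified in the source method. `h_ct()` is then
the count ratio of pathologic (> 1.61, the 95th percentile of a healthy
reference population) to normal voxels. A brute-force triple-loop oracle
in the test suite reproduces the vectorized implementation exactly.

## The synthetic cohort

`protocol_spec()` encodes the study conditions: six animals (≈ 30 kg),
PEEP ladder 5→10→15→20→15→10→5 cmH₂O, two paired IST + CT measurements
per step, V_T = 10 mL/kg, RR 20–25/min. `generate_ground_truth()` draws
deterministic per-animal trajectories: LogSDv falls linearly ~1.0 → 0.4
and LogSDp ~1.5 → 1.2 from PEEP 5 to 20 (with ±0.05 per-animal intercept
jitter), ELV rises with PEEP (recruitment), Qp falls slightly, deadspace
distends, and the decremental limb differs by ~3% (hysteresis well under
the 10% the study reports). A single latent quantity drives both
modalities: the CT heterogeneity parameter is a monotone affine map of
LogSDv.

Synthetic CT volumes (64 × 64 × 16 by default — desk-scale; the physics
does not change with size) superpose on a uniform −800 HU base: a
dependent-region atelectasis layer whose thickness grows with the
heterogeneity parameter, a milder non-dependent over-distension
component, and smoothed speckle — all three scaled by the parameter, so
parameter 0 is perfectly homogeneous (index 1 everywhere, H_CT = 0, no
atelectasis). Measurement noise on the expired tracer is iid Gaussian
with SD `noise_sd · F0` (default 0.5%, giving < 10% test–retest variation
in the ratio indices; repeatability is assessed on those directly
measured indices, since a relative criterion on LogSD is ill-defined as
the spread approaches zero).

What the generator does *not* emulate: anatomical lung shapes,
registration error between PEEP steps, cardiogenic oscillations, tracer
recirculation, ventilator waveform detail, or CT acquisition physics.
Passing tests therefore demonstrate internal consistency and correct
implementation of the methods under the study's statistical structure —
not device-level accuracy on real animals.

## Comparison statistics

Repeated measurements at a PEEP level are averaged before any
correlation or regression (`average_repeats()`). `summary_stats()` uses
the population SD (divide by *n*), the convention that reproduces the
reference cohort's printed baseline table. `pearson_matrix()` reports
two-sided p-values from the t transform without multiplicity correction;
`per_animal_regression()` fits OLS within each animal plus a pooled
"overall" row (a pooled fit, not a random-effects model — the labelling
is explicit because the two can differ). `delta_pairs()` differences
consecutive protocol steps within animal (six deltas per animal on the
seven-step ladder) and `four_quadrant()` computes trend concordance: the
percentage of same-sign change pairs outside an exclusion rectangle at
15% of each axis' maximum absolute change, with on-axis pairs counted as
discordant (conservative) and the maxima taken from the analysed pairs
themselves.

## Numerical choices and limitations

* Warm-up: one forcing period, floored at 80 breaths. The floor is what
  makes the 60 s inversion bias ~10⁻⁵ instead of ~10⁻³.
* Root-finding brackets ELV on a log grid from 10⁻² to 10⁷ mL; amplitude
  ratios outside (0, 1] and unbracketed phase conditions raise immediately
  rather than returning garbage.
* The estimator bounds LogSD to [0, 3] — about twice the physiological
  range — and flags convergence from `optim`.
* Problem sizes in tests: 50 compartments, 32 × 32 × 8 oracle volumes,
  64 × 64 × 16 cohort volumes, 13 × 13 estimation grids; chosen as the
  smallest sizes at which every qualitative property of the full-scale
  problem is already present.
* Known limitations: absolute cohort LogSD estimates are biased low (see
  above); perfusion indices are noisier than ventilation indices (soluble
  uptake contributes less to the expired signal than dilution does), which
  mirrors the weaker perfusion correlations reported in vivo; and the
  one-compartment inversion is a stand-in for the proprietary device
  inversion, which may use additional observables.
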