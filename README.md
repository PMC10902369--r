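# lunghet

Quantifying ventilation and perfusion heterogeneity of the injured lung,
two ways: at the bedside with the **inspired sinewave technique** (IST) and
from imaging with **quantitative CT** — plus the statistics that test
whether the two agree.

`lunghet` is aimed at respiratory physiologists and biomedical engineers
working on PEEP titration and lung-protective ventilation. It provides:

* a **multi-compartment tidal-breathing simulator** of an inert soluble
  tracer gas (N₂O) under sinusoidal inspired forcing
  `F_I(t) = F0 + A·sin(2πt/T)`, with log-normally distributed specific
  ventilations (spread `LogSDv`) and perfusions (`LogSDp`) across
  compartments and exact per-breath tracer mass conservation;
* **IST parameter recovery**: least-squares sinusoid fitting of the
  inspired/expired traces and closed-form-plus-root-find inversion of the
  one-compartment frequency response
  `H(ω) = gγ / (1 − gβ e^{−iωT_b})` for effective lung volume (ELV) and
  pulmonary blood flow (Qp);
* two IST **heterogeneity indices**: the ratio method
  (`ELV₁₈₀/ELV₆₀`, `Qp₆₀/Qp₁₈₀`; both 1.0 in a homogeneous lung) and the
  simulation-fitted `LogSD` indices minimising the L1 loss
  `L = |y₁₈₀ − ŷ(LogSD)| + |y₆₀ − ŷ(LogSD)|`;
* **quantitative CT**: Hounsfield-unit aeration compartments
  (over-distended −1000…−901, normal −900…−501, poor −500…−101,
  atelectasis −100…+100), gas/tissue mass decomposition, the voxel-ring
  inhomogeneity index (ring radii 2.41–3.675 mm, pathologic threshold
  1.61) and the `H_CT` pathologic:normal score;
* **comparison statistics**: population-SD summaries, Pearson matrices,
  per-animal and pooled OLS, and four-quadrant ΔH trend concordance with a
  15%-of-maximum exclusion zone;
* a **synthetic porcine cohort generator** (6 animals, PEEP ladder
  5→10→15→20→15→10→5 cmH₂O, two paired IST+CT measurements per step) so
  the entire chain is testable without animal data.

## Worked example

Simulate a mildly heterogeneous lung, measure it at both forcing periods,
and recover its heterogeneity:

```r
library(lunghet)

lung <- build_lung(elv_true = 800, vd = 150, qp_true = 3400,
                   log_sd_v = 1.0, log_sd_p = 1.5, n = 50)

res <- lapply(c(180, 60), function(T) {
  tr <- simulate_breaths(lung, sine_forcing(T, VT = 300, RR = 25))
  analyze_ist_trace(tr, VT = 300, V_D = 150, RR = 25, period_T = T)
})
heterogeneity_ratios(res[[1]], res[[2]])
#> # A tibble: 1 × 2
#>   h_ratio_v h_ratio_p
#>       <dbl>     <dbl>
#> 1      1.19      1.40

ref <- ist_reference(800, 3400, 150, VT = 300, RR = 25)
estimate_logsd(predict_ist(1.0, 1.5, ref), ref)
#> <logsd_estimate> LogSDv = 1.000 | LogSDp = 1.500 | loss = 0 | 312 evaluations
```

The ratio indices sit well above 1.0 (a homogeneous lung gives 1.00), and
the simulation-fitted estimator recovers the generating spreads exactly on
noiseless self-consistent data.

A full synthetic study — generation, recovery, CT analysis, comparison:

```r
res <- run_pipeline(protocol_spec(noise_sd = 0.002, seed = 1))
res$comparison$quadrants$log_sd_v
#> <quadrant_analysis> 36 pairs (0 excluded) | concordance 100.0% | slope 3.489 | R^2 0.770
autoplot(res$comparison$quadrants$log_sd_v)
plot_peep_trend(res$by_step, "h_ct")
```

Both modalities see the lung homogenise as PEEP rises, and the
four-quadrant concordance of their paired changes is high — the synthetic
analogue of the in-vivo finding.

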