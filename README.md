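# rhythmsim

Humans listening to a nearly—but not perfectly—rhythmic sequence of tones
can still predict when the next tone should arrive. Two classic accounts of
how they do it make different predictions once the sequence is jittered:
**relative (rhythm-based) timing** reconstructs the underlying isochronous
grid by regressing tone times on tone position, while **absolute
(duration-based) timing** averages the heard intervals and adds the mean to
the last tone, inheriting its jitter ("drift"). `rhythmsim` is a simulation
and analysis toolkit for the psychophysics built around this distinction:
listeners hear 8–10 jittered cue tones at 1.2, 2 or 4 Hz and judge whether
a final probe tone is early or late; each responder is scored against both
algorithms by logistic psychometric fits, and the slope difference
`slope_ABS − slope_REL` as a function of overall performance
`slope_ABS + slope_REL` (the *dominance curve*, fitted as a no-intercept
polynomial `y = ax² + bx` selected by AIC) says which algorithm explains
them.

The package implements the full pipeline with tidyverse-style, tibble-first
functions:

* **Stimuli** — trial generator with the exact published statistics
  (`T ~ U(b_l, b_h)`, cue jitter `N(0, σ)`, probe jitter
  `U(±0.3·E[T])`), envelope rendering, session assembly with
  `ITI = 0.75 + U(−0.25, 0.25)` s.
* **Timing algorithms & psychometrics** — relative/absolute predictions,
  SOA-normalized deviations, scalar and circular `(cos θ, sin θ)` logistic
  fits with χ² exclusion of noisy responders, dominance-curve fitting with
  confidence bands, rank tests.
* **Wilson-Cowan oscillator** — compiled forward-Euler core
  (`τĖ = −E + S(ρ_E + cE − aI + k·Stim)`, `τİ = −I + S(ρ_I + bE − gI)`,
  `a=b=c=10`, `g=−2`, `τ=1/17` s, `dt=10⁻⁴` s), natural-period scans of the
  SNIC bifurcation at `ρ_I = −7` (onset at `ρ_E ≈ −3.16`), analytic-signal
  phase, phase concentration, phase response curves.
* **Adaptive-frequency oscillator (AFO)** — slow dynamics
  `ρ̇_E = −0.045(ρ_E − ρ0)` with
  `ρ0 = 0.45⟨t⟩/(⟨t⟩ − 0.21) − 3.6` tracking the running mean inter-tone
  interval, cohort simulation (one coupling gain `k = 0.2 + U(0, 0.1)` per
  simulated participant) scored exactly like humans.
* **Bayesian observer** — Gaussian likelihoods fused with relative- or
  absolute-algorithm priors by precision weighting, closed-form
  `P(late)`, weighted-coin responses, sensory-noise sweeps in absolute or
  Weber (rate-proportional) units.

## Worked example

```r
library(rhythmsim)

# three 2 Hz trials, scored against both timing algorithms
cfg <- experiment_config("2hz")
trials <- score_trials(draw_trials(cfg, n_trials = 3, seed = 1))
trials[, c("base_period", "n_tones", "probe_time",
           "dev_absolute_norm", "dev_relative_norm")]
#>   base_period n_tones probe_time dev_absolute_norm dev_relative_norm
#> 1       0.453      10       4.87           -0.0204         -0.264
#> 2       0.453       8       4.17           -0.104          -0.129
#> 3       0.511       9       5.03           -0.0485         -0.000283

# where the unforced oscillator starts to oscillate, and the period map
scan_bifurcation()
#> <bifurcation_scan> oscillation onset at rho_e = -3.160
#>   rational map fit: rho_e = 0.483 p/(p - 0.216) + -3.698

# a precise and a noisy Bayesian observer with an absolute-timing prior
obs <- run_observer_experiment("2hz", sigma_s_grid = c(0.02, 0.30),
                               prior_type = "absolute", n_trials = 300,
                               seed = 1)
obs[, c("sigma_s", "slope_abs", "slope_rel", "slope_diff")]
#>   sigma_s slope_abs slope_rel slope_diff
#> 1    0.02      7.40      6.09       1.31
#> 2    0.30      1.54      2.54      -1.00
```

The first trial's probe lands 2% of a period before the absolute
prediction but 26% before the relative one — jitter makes the algorithms
disagree. The oscillation onset at `ρ_E = −3.16` is the bifurcation the
AFO exploits, and the refit map constants sit within 15% of the
calibration `(0.45, 0.21, −3.6)` it uses. The observer rows show the
signature result: with precise sensing (σ_s = 20 ms) responses align with
absolute timing (`slope_diff > 0`), with noisy sensing (σ_s = 300 ms) the
prior dominates and responses align with relative timing.

Figure-style drivers chain everything (`reproduce("fig3-style", seed = 1)`
for AFO cohorts, `"fig4-style"` for observer sweeps, `"fig5"` for the
bifurcation scan, …), returning tables plus a JSON run manifest, and
`autoplot()` methods draw the standard figures (`autoplot(fit)` for a
dominance fit, `autoplot(scan)` for a period scan).

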