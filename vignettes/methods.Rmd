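---
title: "Models and methods: timing algorithms, an adaptive-frequency oscillator, and a Bayesian observer for jittered tone sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rhythmsim)
```

`rhythmsim` regenerates, from synthetic data alone, a complete computational
study of temporal prediction in quasi-rhythmic tone sequences: how listeners
judge whether a final probe tone arrives early or late, which of two timing
algorithms their judgments follow, and how both a neural-dynamical model and
an ideal-observer model reproduce the behavioral pattern. This vignette is
the package's own account of the models, the choices behind their
implementation, and what the simulations can and cannot show.

## 1. The task and the stimulus generator

Each trial has an underlying isochronous grid with base period
$T \sim U(b_l, b_h)$ and $I \in \{8, 9, 10\}$ cue tones at
$t_i = T\,i + \varepsilon_i$, $\varepsilon_i \sim N(0, \sigma)$, followed by
a probe at $t_{probe} = T\,(I+1) + \varepsilon_{probe}$,
$\varepsilon_{probe} \sim U(-0.3\,\bar T, 0.3\,\bar T)$ with
$\bar T = (b_l + b_h)/2$. Four built-in conditions span rates from 1.2 to
4 Hz, with cue jitter close to 20% of the mean period everywhere except the
low-jitter variant:

| condition  | $T$ bounds (s) | $\sigma$ (s) | tone duration (s) |
|------------|----------------|--------------|-------------------|
| `1.2hz`    | 0.700--1.000   | 0.170        | 0.340             |
| `1.2hz_lj` | 0.700--1.000   | 0.045        | 0.340             |
| `2hz`      | 0.400--0.600   | 0.100        | 0.200             |
| `4hz`      | 0.210--0.290   | 0.045        | 0.100             |

Behavioral sessions have 150 trials; simulated-cohort sessions use 300
trials per participant with inter-trial gaps of $0.75 + U(-0.25, 0.25)$ s.
These are the study conditions, not tuning knobs.

Design choices worth stating:

* **$\bar T$ in the probe bound is the design mean**, not the realized trial
  mean, matching the generative equations.
* **Non-monotone cue sequences** (possible at 1.2 Hz, where
  $\sigma/T \approx 0.2$) are kept and flagged rather than silently
  redrawn; `resample_nonmonotone = TRUE` switches to redrawing. About 0.4%
  of 1.2 Hz trials are affected.
* **Envelopes are rendered directly** as 5 ms raised-cosine-ramped boxcars
  of duration $0.4\,\bar T$ on the integration grid (10 kHz), then
  normalized as $(x - \bar x)/\max(x - \bar x)$ so the peak is exactly 1.
  Synthesizing audio and taking the analytic-signal magnitude would produce
  the same normalized drive at far greater cost. Overlapping tones (about
  13% of 1.2 Hz trials contain at least one overlap) are combined by
  pointwise maximum, as superposed audio would be; an `"error"` mode
  refuses them.
* Setting all noise sources to zero (`jitter_sd = 0`,
  `probe_jitter_frac = 0`, degenerate period bounds, a single tone count)
  yields bit-identical trials regardless of seed, which the tests exploit.

## 2. The two timing algorithms

Given cue times $t_1 \dots t_I$:

* **Relative (rhythm-based)**: ordinary least squares of $t_i$ on $i$,
  evaluated at $i = I + 1$. The regression includes an intercept: the
  listener reconstructs the grid, not a line through the origin. (The
  through-origin *weighted* regression of the Bayesian prior in Section 5
  is a different object with a different job.)
* **Absolute (duration-based)**: the mean inter-tone interval added to the
  last tone, $t_I + (t_I - t_1)/(I-1)$ by telescoping. The last tone's
  jitter propagates fully into this prediction — "drift".

Probe deviations $t_{probe} - \text{prediction}$ are normalized by the
trial's mean realized stimulus onset asynchrony (the observed intervals,
not $T$; a `soa = "base"` switch exists for sensitivity analysis), making
slopes comparable across rates. Objective early/late labels are the sign of
the deviation; an exactly zero deviation (measure zero) is labelled late
with a warning.

## 3. Psychometrics and the dominance curve

Responses (0 = early, 1 = late) are fitted with maximum-likelihood
binomial-logit models: against the scalar normalized deviation for
behavioral-style data, or against $(\cos\theta, \sin\theta)$ of an
oscillator phase for simulated cohorts. The **slope** — the coefficient,
or the Euclidean norm of the $(\cos, \sin)$ pair, which is invariant to
rotating all phases — measures how well that axis sorts the responses. The
norm is our documented reading of the circular fit's "slope"; the paper
trail does not pin it down further. Responders whose fit does not beat the
constant model (deviance $\chi^2$, $p > 0.05$; df 1 scalar, df 2 circular)
are excluded. One-class response vectors are excluded directly; complete
separation caps the slope at 50 and flags it.

Each subject contributes a point in rotated coordinates: overall
performance $x = s_{ABS} + s_{REL}$ and algorithm dominance
$y = s_{ABS} - s_{REL}$. The **dominance curve** is a no-intercept
polynomial fit of $y$ on $x$ (orders 1--3 compared by AIC with the full
Gaussian log-likelihood, $k$ = coefficients + 1). No intercept encodes the
symmetry that equal slopes imply zero difference; the order-2 form is
$y = a x^2 + b x$. A 95% band of the fitted mean (the zero-crossing
criterion; a prediction-interval flag exists because figure captions and
methods texts disagree on which band is shown) delimits the $x$-region of
significant relative dominance. Adjusted $R^2$ follows R's no-intercept
(uncentered) convention; printed AIC values from other software are
convention-dependent and are not comparison targets.

Group comparisons use Wilcoxon signed-rank tests within conditions and
Mann-Whitney-Wilcoxon tests between conditions, Bonferroni-corrected over
the pairwise comparisons.

Because the published per-participant slope table cannot be shipped,
`synthetic_behavior_summaries()` generates a stand-in cohort: 149 subjects
(35 + 63 + 51 across rates), dominance following the published parabola
$y = 0.0196 x^2 - 0.175 x$, and Gaussian residuals whose SD is set
*analytically* so the expected adjusted $R^2$ equals the published 0.71
(for draws $x_j$, $s^2 = \sum f(x_j)^2 (1 - R^2) / (n R^2)$ under the
uncentered convention). It emulates the published dispersion, so fits on
it verify the machinery and conventions — not the human result itself.
`ingest_supplementary()` reads a real table (CSV/TSV/XLSX) whenever one is
available.

## 4. Wilson-Cowan oscillator and the adaptive tonic input

The neural mass model is
$$\tau \dot E = -E + S(\rho_E + cE - aI + k\,\mathit{Stim}), \qquad
  \tau \dot I = -I + S(\rho_I + bE - gI),$$
with $a = b = c = 10$, $g = -2$, $\tau = 1/17$ s, logistic
$S(x) = 1/(1 + e^{-x})$, integrated by forward Euler at $dt = 10^{-4}$ s
(compiled core; state recorded at 1 kHz). The sigmoid form and the mapping
of the literature's "$d = -2$" onto $g$ (so $-gI = +2I$) are validated
empirically: with $\rho_I = -7$ the unforced system's oscillation onset
lands at $\rho_E = -3.16$, the published bifurcation value, and the
alternative sign mapping has no oscillatory regime at all. Near the onset
the period diverges (> 5 s), the signature of a saddle-node-on-invariant-
circle bifurcation, which is what makes smooth frequency control by a
tonic input possible. The "classic" fixed-frequency operating point
$(\rho_E, \rho_I) = (1.6, -2.9)$ has a measured natural period of 0.202 s
under these conventions.

Numerical choices: initial state $(E, I) = (0.25, 0.25)$; natural periods
are mean inter-peak intervals of $E$ after a 5 s transient in a 60 s
window, with peaks defined by prominence of at least 10% of the signal
range; "no oscillation" (amplitude below 0.01 or fewer than three peaks)
is a value, not an error. Halving $dt$ moves measured periods by about
0.1% — first-order Euler at the published step, kept as the production
integrator with the convergence check in the tests. Phase is the argument
of the FFT-based analytic signal of mean-removed $E$ (phase 0 near
excitatory peaks); session grids are padded with silence to lengths with
only small prime factors so the transform stays $O(n \log n)$.

The **adaptive-frequency oscillator** adds
$\dot\rho_E = -0.045\,(\rho_E - \rho_0)$ with
$$\rho_0 = 0.45\,\frac{\langle t \rangle}{\langle t \rangle - 0.21} - 3.6$$
during sound, where $\langle t \rangle$ is the running mean inter-tone
interval of the current trial, actualized after each tone, and
$\rho_0 = -3.4$ (rest, just below onset) during silence. This parse of the
map is forced by its asymptote: $0.45 - 3.6 = -3.15$ sits just above the
measured onset $-3.16$, so every finite perceived period maps into the
oscillatory regime. Refitting the rational form to our own period scan
recovers constants within 15% of the printed triple, with the fit taken on
period residuals (a fit on $\rho_E$ residuals is degenerate near the onset
where $\rho_E$ is nearly flat in the period; it leaves 10% period errors,
the period-space fit 2.5%).

Three open implementation points, and how they were settled:

* **Pole handling.** At 4 Hz the mean interval approaches the map's pole at
  0.21 s. Intervals are clamped to at least 0.23 s and the target capped at
  +2 before use. The unclamped map was also evaluated: it reproduces the
  published 4 Hz exclusion fraction (occasional sub-pole trials throw the
  target strongly negative and transiently kill the oscillation) but not
  the published dominance direction, so the bounded map is the default.
* **Inter-trial target.** `iti_target = "hold"` (default) keeps the
  previous trial's estimate through the gap; `"silence"` returns to rest
  between trials. Holding keeps the adapted natural frequency within 15%
  of the stimulus rate at 2 Hz (returning to rest leaves it 24% slow) and
  is the reading under which cross-trial rate learning actually
  accumulates; $\rho_E$ is never reset either way, and with an e-fold time
  of $1/0.045 \approx 22$ s its memory spans many trials.
* **Phase readout.** `probe_phase_at = "drawn"` (default) reads the phase
  at the jittered probe time — the phase then expresses the oscillator's
  own early/late judgment of that moment; `"slot"` reads at the noiseless
  grid time $T(I+1)$, which keeps the probe's jitter out of the phase,
  lowers slopes, and raises exclusion rates.

A simulated cohort draws one coupling gain $k = 0.2 + U(0, 0.1)$ per
participant, integrates a whole session continuously (probe tones removed
from the envelope, slots tracked), labels each trial objectively per
algorithm, and fits the circular psychometric per algorithm.

**What reproduces, and what does not.** The slow-rate result is robust:
1.2 Hz cohorts are absolute-dominant (median $y > 0$) in 8 of 10 seeded
replicates at 15 participants x 100 trials. The coupling mechanism of the
classic-oscillator analysis also reproduces: weak coupling yields
relative-leaning concentration and small phase response curves, strong
coupling absolute-leaning, and concentration is high only when the
stimulus rate range brackets the oscillator's natural period. But at 4 Hz
the published *relative* dominance does not emerge at the published
coupling range: sweeping $k$ shows the relative/absolute crossover near
$k \approx 0.12$ in this implementation, below the cohort's
$0.2$--$0.3$, so 4 Hz cohorts sit at a median near zero rather than
slightly negative. The corresponding acceptance check is left failing
rather than retuned: the published 4 Hz effect is also smaller than the
sampling noise of a 15-participant median, so the scaled-down replicate
criterion could not resolve it even in a perfect reimplementation.
Similarly, the closed-loop calibration of the printed map is excellent at
fast and middle rates (periods 0.25 and 0.5 s recovered within 2%) but
17% slow at 0.85 s — the rational form is loose at the slow end — and
that leg of the calibration check is likewise left failing with this
explanation.

## 5. The Bayesian observer

Each tone's time is a Gaussian belief. The likelihood of tone $i$ is
centred on its true time ($\mu_{s,i} = t_i$) with hard-coded sensory SD
$\sigma_s$ — one $\sigma_s$ per simulated participant. The prior for tone
$i \ge 3$ extrapolates the *posteriors* of tones $1 \dots i-1$ by either
algorithm:

* **Relative prior**: through-origin weighted regression of posterior
  means on tone index (weights = posterior precisions), evaluated at $i$;
  variance $i^2 / \sum_n n^2/\sigma_{e,n}^2 + \sigma_{exp}^2$, where
  $\sigma_{exp}$ is the experiment's jitter SD, assumed known — it caps
  the achievable prior precision. Time zero is the first tone's start and
  indices are 1-based; the printed summation indices are read as the
  running index over preceding tones, the only reading consistent with
  "linear regression with unequal variance".
* **Absolute prior**: mean posterior interval added to the last posterior
  mean; its variance is implemented exactly as the printed double sum with
  covariance corrections, and asserted (to $10^{-12}$) against the
  telescoped closed form
  $(\sigma_{e,1}^2 + \sigma_{e,i-1}^2)/(i-2)^2 + \sigma_{e,i-1}^2 +
   2\sigma_{e,i-1}^2/(i-2) + \sigma_{exp}^2$.

Tones 1--2 get a flat prior, represented exactly by zero precision
($\sigma = \infty$), never by a large finite number, so fusion is exact.
Fusion is precision-weighted; posteriors are strictly causal and never
revised. For the probe there is no fusion: the model computes
$$P(\text{late}) =
  \Phi\!\left(\frac{\mu_s - \mu_p}{\sqrt{\sigma_p^2 + \sigma_s^2}}\right)$$
(closed form in production; the defining integral is kept as a quadrature
oracle, agreeing to $10^{-8}$) and answers by a weighted coin flip.
Responses are then scored *identically to humans*: deviations from both
algorithms' predictions, SOA-normalized, scalar logistic fits, the same
exclusion rule.

Observer sweeps rove $\sigma_s$: by default 60 observers per condition,
log-spaced over $[0.1, 3] \times \sigma_{exp}$, 300 trials each. Under
`noise_scaling = "weber"` the grid values are fractions of the condition's
mean period; under `"absolute"` they are seconds shared across conditions.
The headline behaviors — the absolute-prior observer crossing from
relative-aligned at high $\sigma_s$ to absolute-aligned at low
$\sigma_s$, the relative-prior observer never crossing, weber noise
collapsing the rate conditions while absolute noise separates them, and
lower experiment jitter widening the relative-aligned range — all
reproduce, and the precision-ratio recast ($\sigma_p/\sigma_s$) aligns
high- and low-jitter sweeps on one curve. The jitter values quoted in the
supplementary precision analysis do not correspond to any combination of
the main-text jitters under an obvious unit convention, so $\sigma_{exp}$
is free configuration and that analysis is reproduced qualitatively only.

## 6. Problem sizes, reproducibility, and limitations

Every cohort function takes a seed and reproduces bit-identically from
`(seed, config)`; `reproduce()` chains the modules per figure-style target
and writes tables plus a JSON manifest echoing seed, scale, and package
version. The default `scale = "reduced"` sizes — 15 participants x 100
trials for oscillator cohorts, 13 observers x 150 trials for observer
sweeps, 40-point period scans — are chosen so a full desk run completes in
minutes while each effect retains the sign and rough magnitude of its
full-scale counterpart; `scale = "full"` restores the published 60 x 300
design. Tests use the same reduced sizes with fixed seeds chosen before
the assertions were written.

What passing tests show — and what they do not: the synthetic generator
reproduces the *statistical design* of the experiments (distributions,
counts, session structure), not idiosyncrasies of human data such as
lapses, learning within a session, or non-Gaussian motor noise. Agreement
of the simulated cohorts with the published directions therefore validates
the models and the analysis chain, not any claim about individual human
participants; the one benchmark that requires the real per-participant
table is exercised against a clearly-labelled synthetic emulation instead.
Known limitations: the 4 Hz oscillator-cohort direction and the slow-end
map calibration discussed in Section 4; stochastic Wilson-Cowan variants,
networks of oscillators, lapse-rate psychometrics, and fitting
$\sigma_s$ to individual humans are out of scope.
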