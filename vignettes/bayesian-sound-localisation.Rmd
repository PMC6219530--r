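---
title: "Decision rules on the auditory spatial posterior: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision rules on the auditory spatial posterior: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesloc)
```

## The observer model

`bayesloc` models a single localisation trial as conjugate Gaussian
inference over one directional coordinate (azimuth or elevation, in plain
degrees — angles are never wrapped and no circular statistics are used,
since all stimuli live well inside the frontal hemifield). A target at
$\varepsilon_T$ produces an internal estimate
$\varepsilon^* = \varepsilon_T + \eta$, $\eta \sim N(0, \sigma_T^2)$: the
sensory noise is additive and stimulus-independent, so the likelihood is a
Gaussian of fixed width $\sigma_T$ centred on $\varepsilon^*$. The spatial
prior is a zero-mean Gaussian of width $\sigma_P$; for elevation it encodes
the expectation that sound sources cluster around the horizon, for azimuth
it is much wider (the flat limit $\sigma_P = \infty$ recovers maximum
likelihood estimation). The posterior is then Gaussian with

$$\mu_{POST} = \frac{\varepsilon^*}{1 + \sigma_T^2/\sigma_P^2},
\qquad
\sigma_{POST}^2 = \frac{\sigma_T^2}{1 + \sigma_T^2/\sigma_P^2}.$$

`posterior_combine()` implements this with exact infinite-SD arithmetic: a
flat component returns the other belief unchanged, rather than approximating
infinity with a large number. Priors with nonzero mean are supported (the
general precision-weighted form), though the model only ever uses zero-mean
priors. Combining two flat beliefs is an error, not a silent fallback.

## Decision rules and their gain-variance signatures

All four rules act on the same posterior, so they share its mean and hence
predict the same stimulus-response **gain**
$G = 1/(1 + \sigma_T^2/\sigma_P^2)$. They differ in what they do with the
posterior's width, which is what the residual variability
$\sigma_{res}$ reveals:

* **MLE** responds at the likelihood peak: $G = 1$,
  $\sigma_{res} = \sigma_T$.
* **MAP** responds at the posterior mode:
  $\sigma_{res}^2 = G(1-G)\,\sigma_P^2$ — a parabola in variance, zero at
  both $G = 0$ and $G = 1$ and maximal ($\sigma_P/2$) at $G = 0.5$. Its
  signature prediction is that with *no* usable sensory evidence the
  response never moves: gain and variability both vanish.
* **PM** (posterior matching) draws the response from the full posterior:
  total variance $G^2\sigma_T^2 + \sigma_{POST}^2 = (1-G^2)\sigma_P^2$,
  exactly. At $G = 0$ the scatter equals the prior width.
* **AS** (adaptive sampling) draws from a window
  $\mu_{POST} \pm w_0\hat\sigma$ whose halfwidth scales with an internal
  estimate of the sensory noise,
  $\hat\sigma^2 = \sigma_{POST}^2/(1 - \sigma_{POST}^2/\sigma_P^2)$.
  Algebraically $\hat\sigma = \sigma_T$, so the window widens exactly as
  the evidence degrades; the implied relation is linear in variance,
  $\sigma_{res}^2 = (1-G)\sigma_P^2$, again intersecting $G = 0$ at the
  prior width.

The parameters that matter, with their defaults:

| parameter | meaning | default | why |
|---|---|---|---|
| $\sigma_P$ (elevation) | prior width, deg | 11.5 | the width at which the PM sweep's zero-gain intercept sits; the canonical elevation prior throughout the package |
| $\sigma_T$ | sensory noise SD, deg | per simulation | the swept quantity |
| $w_0$ | AS window factor | 0.9 | the heuristic sampling-width constant of the AS rule |
| target range | deg | ±35 (blocks), ±90 (sweeps) | oculomotor range vs frontal hemifield |

## The within-window sampling law

The AS rule fixes the *window* but not the *law* by which a sample is drawn
inside it, and the two natural candidates genuinely differ. `decide_as()`
defaults to **the posterior truncated to the window**: it converges to MAP
as the window shrinks and to PM as it grows, and because the truncated
posterior can never be wider than the posterior itself, it degrades
gracefully at extreme noise. Across a full noise sweep
($\sigma_T$ = 1–60 deg) its residual SD stays within 15% of the linear AS
relation. A **uniform-within-window** law is available via
`decision_config(as_law = "uniform")`; with $w_0 = 0.9$ its within-window
variance $w_0^2\sigma_T^2/3$ equals the $G(1-G)\sigma_T^2$ the AS relation
requires exactly at $G = 0.5$ (note $\sqrt{3}/2 \approx 0.87$), so over
moderate noise it tracks the AS curve almost scale-uniformly — but at very
high noise its fixed window $\pm w_0\sigma_T$ far exceeds the posterior's
support and the law overshoots the relation badly.

This is why the synthetic SNR study generator uses the uniform law while
the package default stays truncated: within the study's noise range
(sensory noise up to about 1.5 prior widths) the uniform law realises the
defining AS property $\sigma_{res} \approx \sigma_{POST}$ most faithfully,
and the truncated law's gain-dependent deviation (about $-5\%$ at mid
gains, $+8\%$ near $G = 0.9$) is tilted toward the PM curve strongly enough
to confuse the model comparison that the study exists to exercise. The
choice is a documented property of the generator, not of the AS rule.

Degenerate cases are handled by the limits the model itself implies: with
$\sigma_T = 0$ the posterior is a point mass at the target and every rule
returns the target; when the posterior is no narrower than the prior
(within $10^{-6}\sigma_P$, i.e. no sensory evidence) the AS halfwidth
diverges and the draw falls back to the full posterior.

## Regression and exclusion

`fit_stimulus_response()` fits $R = gT + b$ by ordinary least squares
(`lm()` underneath) and reports the residual SD as the plain
root-mean-square of the residuals — divisor $n$, matching the definition of
response variability as a mean of squared deviations; at $n = 1000$ this
differs from the $n-2$ form by about 0.1%. Biases are estimated and
reported but never propagated into the gain-variance analysis. The 3-SD
gain exclusion (`exclude_outlier_gains()`) computes the mean and SD over
the full set passed in, flags in a single pass, and pools whatever grouping
the caller chooses (the pipeline pools within experiment × component). Note
an arithmetic property of the rule itself: with $n$ points the largest
attainable deviation is $(n-1)/\sqrt{n}$ SDs, so it cannot fire at all for
sets smaller than about 10.

## Fitting the prior width

Every rule's relation is linear in $\sigma_P^2$:
$\sigma^2 = c(G)\,\sigma_P^2$ with $c(G) = G(1-G)$, $1-G$ or $1-G^2$. The
default estimator is therefore closed-form least squares in variance space,
$\hat\sigma_P^2 = \sum_i c_i\sigma_i^2 / \sum_i c_i^2$ — deterministic, no
starting values, no optimiser; an SD-space alternative
(`fit_space = "sigma"`) is provided for sensitivity checks. Goodness of fit
is reported on the SD scale (the scale on which gain-variance data are
plotted): $r^2 = 1 - SS_{res}/SS_{tot}$ of observed versus predicted
$\sigma$, plus their Pearson correlation. $r^2$ can be negative when a
model fits worse than a constant — the MAP parabola on monotone
negative-slope data routinely is. Model correlations are compared with the
independent-samples Fisher r-to-z test by default; since two models fitted
to the same points share data, Steiger's dependent-correlation variant is
available (`method = "steiger"`), at the cost of needing the correlation
between the two predictions. Sample gains can stray marginally outside
$[0, 1]$ by estimation noise; the fitters require clamped gains rather than
silently truncating, so the caller stays aware of the operation.

## What the synthetic studies emulate — and what they do not

`generate_snr_experiment()` mimics the shape of an eye-saccade localisation
experiment in background noise: 5 subjects, SNRs $+30, -6, -12, -18, -21$
dB, targets on a fixed grid of 12 directions × eccentricities 14/20/27 deg
inside ±35 deg, 72 trials per subject and condition (the paradigm specifies
its location counts but not per-condition trial counts; 72 — three cycles
of the grid — is the package's fixture choice). Elevation responses follow
the AS rule against the 11.5-deg prior; azimuth responses are MLE-like with
a fixed 0.9 gain, emulating the robustness of binaural cues and the
characteristic ~10% undershoot. The mapping from SNR to sensory noise is a
four-parameter logistic in dB (floor 4.5, ceiling 18, midpoint −14 dB,
slope 3.5 dB) — pure plumbing chosen so the implied elevation gains span
roughly 0.87 down to 0.33, the informative range for model comparison; it
is not an empirical auditory law. Between-subject heterogeneity is Gaussian
jitter on the prior width (SD 0.6 deg) and the SNR-map midpoint (SD 1.5
dB). `generate_lowpass_experiment()` emulates head-pointing to low-pass
sounds over the frontal hemifield under the double-pole constraint
$|\alpha| + |\varepsilon| \le 90$ deg: no spectral elevation cues, so
elevation responses are draws from the prior itself, while azimuth stays
high-gain.

The generators reproduce the *statistical structure* the analysis assumes —
Gaussian additive noise, a stationary prior, independent azimuth/elevation
channels, trial-independence. Real data violate all of these to some
degree: motor noise, adaptation and sequential effects, attention lapses,
non-Gaussian tails, and cue-dependent (multiplicative) noise components are
absent. Passing the end-to-end recovery tests therefore shows the pipeline
is self-consistent and identifiable under its own assumptions; it does not
show that human data satisfy them.

## Reproducibility and problem sizes

Stochastic entry points take an optional `seed`; when given, the RNG state
is set for the call and restored afterwards (`withr::with_seed`
semantics), so identical configurations reproduce tables bitwise and a
script-level seed propagates through every draw. The test suite sizes its
simulations for tight tolerances at interactive runtimes: 1000-trial
reference blocks, 4000–6000-trial blocks where closed-form laws are checked
to 3 Monte-Carlo standard errors (for the curve checks the error budget
includes the delta-method contribution of the empirical gain), the full
119-condition noise sweep at 1000 trials per condition, and the default
5-subject synthetic study for end-to-end prior recovery.

## Known limitations

* The AS within-window law is a modelling choice, not a measured one; both
  implemented laws are heuristics that bracket the plausible range, and
  conclusions about AS at noise levels beyond ~2 prior widths depend on
  that choice.
* The prior-width fitter weights all points equally; per-point measurement
  error (which varies with trial count) is not propagated.
* The Fisher comparison treats the two correlations as independent, which
  overstates significance for same-data model fits — hence the Steiger
  option.
* Components are simulated and analysed independently; genuinely coupled
  2-D response models (e.g. eccentricity-dependent noise) are out of scope.
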