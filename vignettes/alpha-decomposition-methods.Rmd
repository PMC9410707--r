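---
title: "Methods: periodic/aperiodic decomposition of developmental alpha activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: periodic/aperiodic decomposition of developmental alpha activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadec)
```

## The problem

Conventional measures of EEG alpha power confound three distinct things: the
oscillation itself, the 1/f-like aperiodic background it rides on, and the
position of the individual alpha frequency (IAF) relative to fixed band
limits. During childhood and adolescence all three change at once — the IAF
accelerates, the aperiodic intercept and exponent both decrease — so total
band power, relative band power, and "true" oscillatory power can move in
opposite directions. `alphadec` implements the full measurement pipeline
needed to separate these components, together with a synthetic cohort
generator calibrated so that the pipeline, run end to end, reproduces the
standardized developmental effect sizes reported for a large pediatric
sample. Because the generator is calibrated at the *pipeline output*, every
stage (spectral estimation, decomposition, metric extraction, aggregation,
exclusion rules, regression scaling) is exercised and checkable at desk scale
without any raw EEG.

## The measurement model

A log-spectrum on the 2–40 Hz grid is modeled as

$$\log_{10} P(F) = \underbrace{b - \chi \log_{10} F}_{\text{aperiodic}, L}
  + \sum_n G_n(F) + \varepsilon,$$

with intercept $b$, exponent $\chi$ (no knee: the bend parameter is fixed at
zero), and Gaussian peaks $G_n(F) = h_n \exp(-(F - c_n)^2 / 2 w_n^2)$.
`parameterize_spectrum()` estimates this in the reference algorithm's order:

1. **Robust aperiodic fit.** Since the no-knee model is linear in $(b, \chi)$,
   both passes are exact linear least squares. After an initial fit, residuals
   are floored at zero and only bins at or below the 2.5th percentile of the
   floored residual — in practice, all bins not above the initial curve — are
   kept for the refit, so oscillatory mass cannot pull the background up.
2. **Iterative peak extraction.** The maximum of the flattened spectrum is
   taken as a peak guess if it exceeds `max(min_peak_height, 2 sd)` of the
   current residual; its width is guessed from the half-height crossing of the
   shorter flank (clipped to the width limits), the guess is subtracted, and
   the search repeats. Guesses centered within one guessed sd of a range edge
   are dropped and overlapping guesses keep the taller peak. "Unlimited"
   peaks is implemented as a practical cap of 12 together with the threshold
   rule, since a literal infinity is unimplementable; on smooth spectra the
   threshold always stops the loop first.
3. **Background settling and joint refit.** A single background pass is
   biased when broad peaks overlap much of the fit range, so flattening and
   guess-level peak removal are cycled (up to 5 times, stopping when the
   background parameters move by less than 1e-3). All surviving Gaussians are
   then refit jointly with the background by bounded least squares (analytic
   gradients; equivalent to alternating peak/background refits run to
   convergence), and the model is reassembled. $R^2$ is the squared Pearson
   correlation between model and data; fits with $R^2 \le 0.90$ are flagged,
   and at the cluster level such electrodes are dropped (never the subject —
   if all five electrodes fail the gate the subject is flagged and all are
   averaged, so no subject is excluded on fit quality alone).

All logarithms are base 10. The decomposition is deterministic: identical
input yields identical fits.

Two notes on deliberately simple choices. The Welch estimator computes one
Hamming-tapered, zero-padded (2 s window padded to 4 s, hence 0.25 Hz bins)
modified periodogram per retained 2 s epoch and averages; we do not overlap
windows across epoch boundaries because rejection (below) can remove
arbitrary epochs. And the IAF is the argmax of measured power in 7–14 Hz at
grid resolution, ties toward the lower bin, with border maxima treated as "no
detectable peak" — no parabolic interpolation, since the downstream band
`[IAF - 4, IAF + 2]` Hz is 6 Hz wide and insensitive to sub-bin placement.

## Extracted parameters and exclusion rules

Per electrode, nine parameters: IAF; total (mean log power) alpha in the
canonical 8–13 Hz and individualized bands; relative alpha (mean *linear*
band power divided by mean linear 2–40 Hz power — the ratio is computed on
linear power, the conventional reading, switchable via `band_average()`);
aperiodic-adjusted alpha (mean log periodic power, i.e. after subtracting the
fitted background) for both bands; and the aperiodic intercept and exponent.
Epochs with any sample strictly beyond ±90 μV are rejected; subjects losing
more than 50% of their epochs are excluded. Subjects with no detectable IAF are
excluded. After cluster averaging, a single-pass screen excludes subjects
with any parameter beyond 3 sd of the sample mean (the rule is not iterated;
re-trimming is a different estimator and is not what a single threshold pass
describes).

## The synthetic cohort

`sample_cohort()` draws per-subject latent parameters
(offset, exponent, IAF, alpha height/width, theta height) as

$$\theta_k = \mu_k + \sigma_k\,(E_k^\top x + c_k r_k),$$

with $x$ the standardized covariates (age, gender, FA, task score), $E$ the
effect matrix, $r$ correlated residuals, and $c_k$ chosen so each latent's
total sd equals $\sigma_k$ — effect entries are therefore latent–covariate
correlations. Spectra are the forward model plus iid bin noise (0.03 log10
units); `generate_timeseries()` additionally provides random-phase
inverse-spectrum synthesis for exercising the time-domain path (Welch
convergence, artifact rejection). Ages follow a truncated normal
(mean 10.8, sd 3.44, range 5–22); gender is Bernoulli with P(female) = 0.357;
the two FA covariates share a common age-loaded component and are nearly
collinear (motivating separate left/right models); the task score is
age-standardized by construction.

Default centers describe a pediatric eyes-closed posterior spectrum: offset
0.8 log10 μV²/Hz, exponent 1.5, IAF 9.5 Hz, and a *dominant* alpha peak
(height 1.0 log10 units, about an order of magnitude above background, sd
1.2 Hz) with a smaller theta bump (0.4 at 4.5 Hz). The dominant peak matters:
with a weak peak, linear-power relative alpha is driven almost entirely by
where the individualized band sits on the 1/f curve (IAF- and
exponent-induced variance), the relative–adjusted correlation collapses to
~0.5 where developmental cohorts show ~0.9, and no physically admissible
effect pattern can reproduce the published relative-alpha effect sizes. The
spreads (offset 0.35, exponent 0.20, IAF 0.8 Hz, heights 0.35/0.20, width
0.25) and a high offset–exponent residual correlation (0.90) were likewise
chosen so the *measured* outcome correlation structure is qualitatively the
one observed in such cohorts (strong intercept–slope and total–intercept
coupling); none of these correlations is asserted as a test target.

## Calibration

Because total and relative alpha are emergent, nonlinear functions of the
latents, covariate effects cannot be injected directly. `calibrate_preset()`
runs the full pipeline on a calibration cohort (n = 2000, five electrodes —
the same conditions the packaged preset is used under, since electrode
averaging changes measurement-noise attenuation), regresses each standardized
measured outcome on the standardized latents to obtain an empirical response
map, and applies damped pseudo-inverse updates of the effect matrix until all
targeted coefficients are within 0.03. Directions with tiny gain are
truncated (`rcond = 0.05`): notably, total alpha is an exact function of the
other outcomes (aperiodic band mean plus adjusted power), so its target is
reachable only through the preset's variance design, not through an
independent dial — with the defaults above it emerges within tolerance. The
packaged `hbn_main` preset is the converged result; it ships as plain-text
YAML and is regenerated by `analysis/01_calibrate_preset.R`.

## What the simulations do and do not show

The generator emulates the statistical structure the analysis assumes:
log-linear background, Gaussian peaks, covariate-driven drifts, measurement
noise, epoch artifacts as amplitude excursions. It does not emulate real
artifact morphology (blinks, muscle), eyes-open/closed block structure,
channel covariance beyond a homogeneous five-electrode cluster, non-Gaussian
peak shapes, or knee-type backgrounds. Passing recovery tests therefore
demonstrates that the *pipeline* is correct and unbiased under its own model
class, and that the published effect pattern is self-consistently recoverable
— not that the model class captures every property of real recordings.

## Numerical choices and problem sizes

Tolerances: noiseless decomposition recovery 0.05 (log10 units / exponent
units) and 0.25 Hz on centers; confound-scenario invariance 0.02 log10 units
(decomposition numerical error at zero noise). Degenerate inputs error
early: empty epochs, zero kept epochs (distinct error), grids not covering
the IAF window, zero-variance scaling, rank-deficient designs (naming the
collinear columns). The test suite and the acceptance script use n = 2000
subjects × 5 electrodes (≈10,000 spectral fits, ~90 s) for the end-to-end
coefficient checks; cross-check batteries use 50–200 random spectra. The OLS
backend is the default (deterministic; all coefficient targets are
point-estimate recoveries where OLS and the Bayesian posterior mean agree);
the JAGS backend with Cauchy(0, 2.5) priors exists for interval semantics
and the sequential prior-updating workflow (`posterior_to_prior()`, normal
moment-matched approximation).

## Known limitations

* The 2 sd peak threshold is computed on the evolving flattened residual; on
  iid-noise spectra with `min_peak_height = 0` it admits occasional spurious
  low peaks, as the reference procedure does. These average out at the
  cluster level.
* Robust background fitting still inherits a small upward offset bias when
  very broad peaks overlap most of the fit range; recovery stays within the
  stated tolerances for physiological parameter ranges.
* Relative power's definition (linear-power ratio) is one of two defensible
  readings of a log-ambiguous convention; both are computable via
  `band_average()`.
* The latent model is Gaussian with linear covariate effects; real
  developmental trajectories are nonlinear in age.
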