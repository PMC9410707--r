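# alphadec

Periodic/aperiodic decomposition of resting-state EEG power spectra and the
downstream analysis of alpha-band maturation, as a tested R package plus a
reproducible synthetic-cohort study.

## The problem

The dominant feature of the human EEG, the alpha oscillation (~7–14 Hz),
changes throughout childhood and adolescence — but so does everything around
it: the individual alpha frequency (IAF) accelerates, and the aperiodic
(1/f-like) background drops and flattens. Conventional measures conflate
these components. Total band power mixes oscillation and background; relative
band power is biased by power changes in *other* bands and by the aperiodic
component; fixed 8–13 Hz limits miss the slower alpha peak of young children.
`alphadec` is aimed at researchers who want to study oscillatory parameters
free of these confounds: it separates each log-spectrum into an aperiodic
component

    L(F) = b − χ · log10(F)

(intercept *b*, exponent *χ*, no knee) plus Gaussian oscillatory peaks
G_n(F) = h·exp(−(F−c)²/2w²), and extracts the nine spectral parameters per
electrode (IAF; total / relative / aperiodic-adjusted alpha power, each
canonical 8–13 Hz and individualized [IAF−4, IAF+2] Hz; aperiodic intercept
and exponent).

Because the raw developmental EEG biobanks are not redistributable, the
package includes a calibrated generative model of the cohort: per-subject
latent spectral parameters with age/gender/anatomy/behavior effects, whose
*emergent* pipeline estimates reproduce the published standardized effect
sizes. Everything — spectral estimation, epoch rejection, decomposition,
cluster aggregation, exclusion rules, Gelman-scaled regressions,
effective-number-of-tests correction, sequential Bayesian prior updating —
is exercised end to end on simulated data.

## Worked example

```r
library(alphadec)

# simulate one subject with a 9.8 Hz alpha peak on a 1/f background
preset <- generative_preset()
params <- c(offset = 0.9, exponent = 1.6, iaf = 9.8,
            alpha_level = 1.1, alpha_width = 1.3, theta_level = 0.3)
ts  <- generate_timeseries(params, preset, duration = 190, fs = 500, seed = 1)
rej <- reject_epochs(ts, threshold = 90)
psd <- welch_psd(ts, rej$kept)                  # 0.25 Hz bins, 2-40 Hz
fit <- parameterize_spectrum(psd)
fit
#> <spectral_fit> offset 0.913, exponent 1.602, 3 peak(s), R^2 0.9984
compute_metrics(psd, fit)[, c("iaf", "total_individualized",
                              "adjusted_individualized",
                              "aperiodic_exponent")]
#>    iaf total_individualized adjusted_individualized aperiodic_exponent
#> 1 9.75          -0.03810118               0.5427607           1.601762
```

The decomposition recovers the generative background (offset 0.9, exponent
1.6) from the 93 artifact-free epochs, detects the IAF at the nearest grid
bin (9.75 Hz), and reports alpha power both as measured (`total_*`, log10
μV²/Hz averaged over [IAF−4, IAF+2] Hz) and relative to the fitted
background (`adjusted_*` — the oscillation's own power, here ≈0.54 log10
units above the 1/f curve).

At cohort scale:

```r
pl <- run_cohort_pipeline(hbn_main_preset(), n = 2000, seed = 42)
cf <- maturation_coefficients(pl$metrics)
round(cf$age, 2)
#>                     iaf    total_individualized relative_individualized
#>                    0.42                   -0.31                    0.15
#> adjusted_individualized     aperiodic_intercept      aperiodic_exponent
#>                    0.24                   -0.52                   -0.45
```

i.e. with increasing age, total alpha power *falls* while aperiodic-adjusted
alpha power *rises* — the sign flip that motivates decomposing the spectrum —
alongside the IAF increase and the drop in aperiodic intercept and exponent.

The `analysis/` directory contains the numbered study drivers:
`01_calibrate_preset.R` (regenerates the packaged calibrated preset),
`02_cohort_pipeline.R` (cohort simulation + metric extraction),
`03_maturation_models.R` (regressions, multiplicity correction, sequential
prior updating), `04_confounds.R` (relative- vs adjusted-alpha confound
scenarios). Each writes its tables under `results/`.

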