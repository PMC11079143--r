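# vibeeg

Removal of whole-body-vibration (WBV) movement artifacts from multichannel
EEG using acceleration-referenced adaptive filters, plus the synthetic
benchmark, spectral metrics and vibration-stress statistics needed to
validate and apply the method.

## The problem and who this is for

Passengers exposed to vertical random vibration (cars, trains, aircraft,
simulators) show EEG contamination driven by head motion: the seated body
resonates near 3–4 Hz and the resulting artifact lands inside the delta and
theta bands, where bandpass filtering and ICA-style cleaning cannot touch it
without destroying brain activity. If the vertical head acceleration `x[n]`
is recorded synchronously with the EEG, an adaptive noise canceller can
estimate the artifact per channel and subtract it:

    y[n] = sum_{k=0}^{L-1} w_k x[n-k]        (artifact estimate)
    e[n] = d[n] - y[n]                       (cleaned EEG)

with weights updated online by NLMS or RLS. This package implements both
cancellers (compiled, all channels sharing one reference), the standard
preprocessing pipeline around them, and the evaluation stack: Welch PSD,
magnitude-squared coherence, temporal and spectral RRMSE, relative band
powers, and frontal-alpha-asymmetry stress indices with Friedman and
Conover rank statistics. It is aimed at researchers studying EEG under
vehicle-like vibration and at anyone needing a reproducible semi-synthetic
benchmark for movement-artifact removal:

    d_hat[n] = s[n] + lambda * N[n],  SNR = 10 log10( RMS(s) / RMS(lambda N) )

where `s` is ground-truth EEG, `N` the acceleration-coupled artifact, and
`lambda` is solved exactly for a target SNR (benchmark levels −8 and 4 dB).

## Worked example

```r
library(vibeeg)

# a contaminated benchmark set: 32-channel EEG, 60 s at 250 Hz,
# 2.0 m/s^2 rms drive through a 3.4 Hz body resonance, mixed at -8 dB
cs <- make_benchmark_set(snr_db = -8, seed = 1)
cs$lam
#> [1] 3.781068

fit  <- run_filter(cs$mixture, cs$reference, filter_config("rls"))
truth <- trim_initial(cs$clean, 2)          # discard 2 s adaptation burn-in
clean <- trim_initial(fit$cleaned, 2)
mixed <- trim_initial(cs$mixture, 2)

rrmse_temporal(clean$data, truth$data)      # RLS-cleaned vs ground truth
#> [1] 0.2787149
rrmse_temporal(mixed$data, truth$data)      # unfiltered mixture
#> [1] 6.324967
mean(sapply(1:32, function(ch) corr_coef(clean$data[, ch], truth$data[, ch])))
#> [1] 0.960838
```

RRMSE is the residual RMS relative to the ground-truth RMS: 6.3 means the
raw mixture is dominated by artifact (six times the EEG amplitude); 0.28
means the canceller recovered the EEG to within ~28 % residual. The mean
per-channel correlation of 0.96 says the cleaned traces track the true EEG
closely. Coherence with the head acceleration in the artifact band
collapses accordingly:

```r
max(max_coherence_topography(cs$mixture, cs$reference, band = c(3, 5)))
#> [1] 0.9977446
max(max_coherence_topography(fit$cleaned, cs$reference, band = c(3, 5)))
#> [1] 0.04720234
```

Stress assessment on a synthetic cohort with an imposed frontal-alpha-
asymmetry gradient (FAA decreases under stress):

```r
cohort <- gen_stress_cohort(20, c("static", "v1.0", "v1.5", "v2.0"),
                            faa_offsets = c(0.3, 0.1, -0.1, -0.3),
                            duration = 40, seed = 5)
report <- assess_stress(cohort)
round(colMeans(report$faa), 3)
#> static   v1.0   v1.5   v2.0
#>  0.299  0.059 -0.041 -0.265
report$friedman$faa$p < 0.05
#> [1] TRUE
```

See `vignettes/wbv-artifact-removal.Rmd` for the model details, parameter
choices and the limits of what the synthetic benchmark demonstrates.

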