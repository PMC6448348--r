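# oscillosource

Source-level unmixing of oscillatory EEG activity: simulate multichannel
EEG with planted cortical oscillations, spatially unmix it by solving the
EEG inverse problem with a smoothness prior, temporally unmix the
reconstructed sources with noise-assisted multivariate empirical mode
decomposition (NA-MEMD), and statistically link the instantaneous phase of
the extracted components to a per-trial behavioral response (e.g., the
motor-evoked potential elicited by TMS over the motor cortex).

The package is for researchers who study how the phase of prestimulus
brain rhythms shapes responses to stimulation, and who want a fully
testable pipeline: every stage — forward model, inverse solver,
decomposition, phase statistics — runs on synthetic data with exact ground
truth.

## The model in brief

Sensor data follow the linear forward model

    y(t) = L s(t) + eps(t),

with `L` an N x D leadfield (here: a three-concentric-spheres analytic
model with radial cortical dipoles), and the planted source of interest a
sum of three oscillations at 10.1, 18 and 27.5 Hz (instantaneous frequency
jittered within ±0.5 Hz, amplitudes following the 1/f law). Sensor noise is
scaled so that `SNR = 20 log10(std(L s) / std(eps))` holds exactly per
trial.

Sources are estimated by an evidence-optimized weighted minimum norm with a
Gaussian spatial-coherence prior (a LORETA-style smooth inverse; the
free-energy trace of the hyperparameter optimization is non-decreasing by
construction). Reconstructed region-of-interest sources are decomposed with
NA-MEMD: K = 16 hypersphere projections define multivariate envelopes, 12
white-noise channels enforce the quasi-dyadic filterbank alignment, the
per-band dominant intrinsic mode function (IMF) is selected per noise
realization, and the sample-wise median over realizations is the band
component. Phase, amplitude and frequency come from the analytic signal.

Phase-behavior coupling across trials is measured per time sample by the
circular-linear correlation

    rho = sqrt((r_zc^2 + r_zs^2 - 2 r_zc r_zs r_cs) / (1 - r_cs^2)),

(the multiple correlation of the response on `[cos phi, sin phi]`), with
cluster-based permutation tests (sum-of-t cluster statistic, max-statistic
null over 1000 permutations) controlling multiple comparisons over time or
sensor-time.

## Worked example

Simulate one noisy trial with a 14 Hz distractor 3 cm from the source of
interest, run the source-level pipeline (REST, inverse solution, ROI
extraction, NA-MEMD), and score the alpha-band component against the
planted 10.1 Hz oscillation:

```r
library(oscillosource)

lf <- make_spherical_leadfield(16, 400, seed = 1, roi_radius = 0.015)
#> <leadfield> 16 sensors x 400 vertices, 4 ROI vertices
sv <- default_soi_vertex(lf)
dv <- distractor_placements(lf, sv, 0.03, seed = 1)
cfg <- simulation_config(soi_vertex = sv,
                         distractor_spec = list(list(vertex = dv, center = 14)),
                         snr_db = 0, n_trials = 1, fs = 500, seed = 42)
trials <- assemble_trials(lf, cfg)
#> <trial_set> 1 trials, 16 sensors x 500 samples, SNR 0 dB

res <- run_variant(trials, lf, "1_source",
                   pipeline_config(n_realizations = 4, seed = 1))
gt <- trials$ground_truth[[1]]
m <- evaluate_estimate(res[[1]]$attrs$alpha[[1]],
                       list(phase = gt$phases[1, ], frequency = gt$freqs[1, ]),
                       res[[1]]$series$alpha[1, ], gt$components[1, ])
round(unlist(m), 3)
#>      phase_deviation  frequency_deviation temporal_correlation
#>                0.267                1.273                0.925
```

The extracted alpha component tracks the planted oscillation with 0.93
temporal correlation and a mean phase error of 0.27 rad at 0 dB SNR —
despite the distractor and the ill-posed 16-sensor/400-vertex inversion.
`evaluate_simulation()` runs the same comparison for all eight method
variants (sensor-level, source-level, bandpass comparator,
decompose-then-localize) over many repetitions and reports a variant-by-
metric table with pairwise t-tests; `run_experimental_analysis()` applies
the pipeline to recorded epochs and an MEP response vector and returns
per-band cluster permutation results.

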