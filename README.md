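# pcgst — heart-sound segmentation and S1/S2 classification with the S-transform

`pcgst` locates the first and second heart sounds (S1, S2) in a
single-channel phonocardiogram and labels each sound **without an ECG
reference and without any systolic/diastolic interval rule**.  Interval
rules ("systole is shorter than diastole") fail precisely where automated
auscultation is most needed — stress testing, severe tachycardia,
tachyarrhythmia — because the two intervals converge at high heart rate.
This package classifies every sound from its own time-frequency content
instead, using single scalar features and a plain threshold.

It is aimed at biomedical-signal researchers and engineers building
ECG-free PCG pipelines (wearables, electronic stethoscopes, home
monitoring) who need a reproducible reference implementation plus a
synthetic, annotated stress-test corpus to exercise it.

## Method

All analysis runs on the Stockwell transform with a width-adjustable
Gaussian window, S_x(t, f) = ∫ x(τ) w(τ−t, f) e^(−2πifτ) dτ with
σ(f) = α/f:

* **Segmentation** — a modified Shannon-energy envelope of the S-matrix,
  SSE(τ) = −Σ_f |S(τ,f)|ⁿ log |S(τ,f)|ⁿ Δf with n = 1.5 (the lowered
  exponent boosts faint sounds, typically S2 at high heart rate), smoothed
  and thresholded adaptively against a robust per-recording baseline.
* **Feature α_opt** — the window width maximizing the energy concentration
  CM(α) = 1 / Σ|S̄| ΔtΔf over the inclusive grid α ∈ {0.5, …, 2.0}.
  The multi-component, low-pitched S1 demands frequency resolution
  (α_opt ≈ 0.85); the click-like S2 demands time resolution (≈ 0.6).
* **Feature β** — the time-average of the peak-normalized SSE envelope,
  in (0, 1]: an envelope-occupancy measure, larger for the longer S1.
* **Feature γ** — the non-excess kurtosis of the SSE envelope of the
  normalized ST-spectrogram (treated as a 2-D pseudo-probability
  distribution): larger for the short, peaky S2 (lower bound 1;
  Gaussian = 3).
* **HFS comparator** — the prior-art high-frequency signature (Shannon
  energy of Daubechies-6 detail coefficients), included to quantify how
  its "S2 is always higher-pitched" assumption degrades with heart rate.

A synthetic stress-test generator (Gaussian-windowed sinusoid components,
HR ladder 60–198 bpm, systole/diastole convergence, HR-coupled S2
softening, controllable white-noise SNR, bit-reproducible from a seed)
provides annotated recordings in place of the non-public clinical corpus,
and an evaluation harness reports ROC/AUC, Mann–Whitney tests, a
noise-robustness table and the S2/S1 high-frequency-ratio-vs-HR curve.
The methods vignette (`vignettes/heart-sound-classification.Rmd`) explains
every model assumption, default and limitation.

## Worked example

```r
library(pcgst)

# a 10 s stress recording at 150 bpm with 10 dB of added noise
rec <- generate_recording(duration = 10, config = beat_config(hr = 150),
                          snr_db = 10, seed = 1)
rec
#> <pcg_recording> 10.0 s @ 2000 Hz, 150 bpm, 50 annotated sounds, SNR 10 dB, seed 1

fit <- analyze_pcg(rec$signal)     # segment, featurize, threshold gamma
summary(fit)
#> Heart-sound analysis: 50 sounds over 10.0 s
#>   S1 (n=28): dur 119 ms | alpha_opt 0.81 | beta 0.42 | gamma 1.78
#>   S2 (n=22): dur 65 ms | alpha_opt 0.57 | beta 0.25 | gamma 3.32

head(fit$segments[, c("onset_s", "offset_s", "label", "alpha_opt", "beta", "gamma")], 4)
#>   onset_s offset_s label alpha_opt  beta gamma
#> 1   0.023    0.155    S1       0.8 0.405  1.74
#> 2   0.205    0.268    S2       0.6 0.258  3.43
#> 3   0.424    0.547    S1       0.8 0.400  2.21
#> 4   0.611    0.671    S2       0.7 0.249  3.04
```

All 50 true sounds are recovered (onsets a few ms after the annotated
component onsets, where the envelope crosses threshold).  Each row carries
the four features; the labels come from thresholding γ alone at 2.5 —
S1 sits near 1.8, S2 near 3.3 — and agree with the ground-truth labels for
47 of the 50 sounds (0.94) at a heart rate where systole and diastole are
already nearly equal.  The mean α_opt values (0.81 vs 0.57) show the
transform asking for a wider analysis window on S1 than on S2, and β
confirms S1 occupying more of its analysis window (0.42 vs 0.25).

A command-line front end with `simulate` / `segment` / `features` /
`evaluate` subcommands lives in `inst/cli/pcgst.R`.

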