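# envdecode

Backward decoding of the temporal speech envelope from multichannel EEG,
for studies of **cortical entrainment to running speech** — e.g. asking
whether a listening intervention (such as a hearing aid) changes how
strongly low-frequency cortical activity tracks the speech amplitude
envelope. The intended users are auditory-neuroscience and audiology
researchers working with scalp EEG recorded during continuous speech.

## The model

The speech envelope $y(t_n)$ (magnitude of the analytic signal of the
stimulus) is reconstructed from EEG channels $x_j$ at lags $\tau_k \in
[-100, +400]$ ms with a linear backward temporal response function:

$$\hat y(t_n) = \sum_{j=1}^{N}\sum_{k=1}^{T} \beta_{j,k}\,x_j(t_n+\tau_k),
\qquad \beta = (X^\mathsf{T}X + \lambda I)^{-1} X^\mathsf{T} y$$

Both EEG and envelope are band-passed with zero-phase Hamming-window FIR
filters (delta 1–4 Hz, theta 4–8 Hz, wideband 1–20 Hz), average-referenced
(EEG), and downsampled to 64 Hz. Performance is the Pearson correlation on
10-s test segments under five-fold cross-validation with a 50-point
$\lambda$ sweep ($10^{-15}..10^{15}$); chance level comes from running the
identical pipeline against the **time-reversed** envelope, and per-subject
detection uses a Wilcoxon signed-rank test on segment-paired correlations.
Group inference is nonparametric (signed-rank, exact sign tests, rank
dispersion, bisquare robust regression) with **uncapped**
Benjamini–Yekutieli FDR adjustment. A synthetic forward model
(speech-like envelope → causal cortical kernel → 1/f noise at known SNR)
provides ground truth for every stage.

See `vignettes/envelope-decoding.Rmd` for the methods account.

## Worked example

Simulate one entrained subject (3 minutes, 8 channels, 0 dB SNR), run the
delta-band decoder and its time-reversed null:

```r
library(envdecode)

env  <- gen_envelope(duration = 180, fs = 512, seed = 3)
kern <- gen_kernel(n_channels = 8, fs = 512, seed = 4)
eeg  <- gen_eeg(env, kern, snr_db = 0, seed = 5)

band <- canonical_bands("delta")[[1]]
cfg  <- analysis_config(bands = band,
                        lambda_grid = 10^seq(-15, 15, length.out = 10))
det  <- evaluate_subject(preprocess_band(eeg, band),
                         preprocess_band(env, band), cfg)
print(det)
print(det$forward)
print(det$null)
```

```
<subject_detection> forward r = 0.8697 vs null r = 0.0863, p = 0.000727 (significant)
<evaluation_result> forward: mean r = 0.8697 (sd 0.0180), n = 15 segments, lambda* = 46.4
<evaluation_result> time_reversed: mean r = 0.0863 (sd 0.0773), n = 15 segments, lambda* = 2.15e-12
```

The forward decoder reconstructs the envelope at mean segment correlation
0.87 across the 15 pooled test segments (5 folds × 3 segments of 10 s),
while the time-reversed control sits near chance (0.09); the signed-rank
test on the 15 paired segments detects the response (p ≈ 7e-4, the
smallest value attainable at that segment count). On real data,
correlations are far lower (noise, model mismatch), but the contrast
logic is identical.

Filter designs can be inspected directly:

```r
design_fir(canonical_bands("delta")[[1]], 2048)
#> <filter_kernel> delta band (1-4 Hz), 6759 taps @ 2048 Hz
```

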