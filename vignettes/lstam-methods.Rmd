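---
title: "Methods: spectral attention-augmented LSTM moment regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral attention-augmented LSTM moment regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The package regresses two hip joint moments (flexion/extension and
abduction/adduction, N·m) from six predictor channels: four sEMG signals
(gluteus medius, semitendinosus, biceps femoris, rectus femoris) and two
joint angles (hip adduction, hip flexion). The working sampling rate is
200 Hz; recordings at 1000 Hz are brought down by pure sample dropping
(`decimate()`, 5 ms step). Prediction is windowed and causal: each
overlapping 300 ms window (60 samples, stride 1) is labelled with the
moment at its **last** sample, so a deployed model never looks ahead. A
config switch (`label = "center"`) allows centre labelling instead.

The complete model (variant V) composes five stages per window:

1. **z-scoring** per predictor channel with statistics fitted on the
   training trial only (population standard deviation, divisor N — chosen
   to match the package's variance conventions; targets are never
   normalized, so reported RMSE stays in N·m).
2. **Spectral transform**: the full two-sided FFT magnitude per channel,
   length equal to the window length (60). The one-sided transform of
   length 31 would halve the redundancy, but the feature length is fixed
   at 60 so that the MLP input dimension equals the window length.
   Magnitude only by default; the conjugate-symmetric redundancy is
   accepted. Phase can be concatenated (`fft_mode =
   "magnitude_and_phase"`, doubling the feature length) but is off by
   default: the spectral stage's purpose is the intensity of frequency
   components.
3. **MLP autoencoder**, shared across channels: ReLU-activated affine
   layers 60 → 30 → 15 (encoder) and 15 → 30 → 60 (decoder). The decoder
   is used only for an auxiliary reconstruction loss (weight
   `aux_recon_weight`, default 0.1, settable to 0) added to the
   prediction MSE; whether reconstruction participates in training at all
   is a package choice, and both readings are supported.
4. **1-D convolutional refiner** along the 15-long latent axis, mixing
   the six channels, kernel length 3, zero padding, ReLU. This is the
   smallest module that can blur transient structure in the latent
   trajectory; with an averaging kernel it provably does not increase
   total variation, which is the operational sense of "suppressing local
   features".
5. **Single-layer LSTM + attention + affine head.** In the spectral
   variants the LSTM iterates over the latent-feature axis (15 steps,
   channels as step features), so attention weighs frequency-derived
   steps; variants I–II iterate over the raw time axis (60 steps). This
   sequence-axis choice is an interpretation: the source architecture
   diagram does not state what the recurrence iterates over after
   windowing + FFT, and this reading keeps exactly one prediction per
   window. Attention is a learned scoring vector, softmax (computed with
   max subtraction; mathematically identical), and a convex combination
   of hidden states. Dropout (rate 0.2) acts on the context vector before
   the head. The head predicts both moments jointly.

The gate equations carry no bias terms as printed; biases exist in the
implementation (standard practice, initialized at zero) and the
equation-conformance tests zero them explicitly.

## Training configuration

Adam, learning rate 0.001, MSE loss, batch size 60, 30 epochs, no early
stopping — the published experimental setting, kept as defaults in
`model_config()`. One integer seed controls initialization (uniform
Kaiming-style fan-in scaling), batch shuffling and dropout; two runs with
the same config are bit-identical. Hidden size defaults to 64; the
stochastic acceptance checks use 32 to fit a CPU budget.

A numerical conditioning choice: spectral magnitudes are scaled by a
fixed 2/window_len (amplitude-spectrum normalization) before entering the
encoder, because raw two-sided magnitudes of z-scored windows reach ~30
and would saturate a randomly initialized ReLU stack. The user-facing
`spectral_transform()` output is the raw unnormalized magnitude (Parseval
with factor window_len holds exactly there).

## The ablation ladder

`build_variant()` wires: **I** plain LSTM on raw windows (last hidden
state to the head); **II** + attention; **III** FFT + MLP + LSTM (no
attention, no conv); **IV** + attention; **V** + conv. A Discussion
sentence in the source material attributes the convolution to Model IV;
the enumerated variant list says Model V, and the enumerated list is
followed. Parameter counts are strictly ordered V > IV > III, which the
tests assert component-wise.

## The synthetic world

`generate_gait()` states one fixed world, used unchanged by every test:

* gait phase advancing at 1 Hz with ±3 % per-cycle frequency jitter,
  phase being a deterministic function of absolute time given the jitter
  draws (so 1000 Hz and 200 Hz grids agree exactly);
* four nonnegative EMG channels = Gaussian-in-phase activation envelopes
  (centers 0.05, 0.85, 0.90, 0.35 of the cycle; width 0.08) times a
  rectified seeded Gaussian broadband carrier, ~1 mV scale;
* two angles = two harmonics of the gait phase (adduction 6+2°, flexion
  18+6°);
* moments = a·angle + b·(envelope difference of a muscle pair, delayed
  50 ms — a physiological electromechanical delay) + q·angle², giving a
  ±12 N·m range with a ~5 N·m standard deviation, deliberately sized so a
  bounded-output network can reach it within 1500 Adam steps at the fixed
  learning rate;
* optional corruption: band-limited Gaussian noise at or above 10 Hz
  (half of gait_freq × 20) scaled to noise_sigma × channel SD on the
  predictors, Poisson single-sample spikes of +5 SD, and Gaussian
  observation noise of 0.1 × noise_sigma × SD on the moments. Targets are
  never spike- or noise-band corrupted. Defaults are clean
  (noise_sigma = 0, spike_rate = 0).

What the generator does **not** emulate: real sEMG amplitude statistics,
crosstalk between electrodes, slow drift, gait-speed changes within a
trial, missing data, or OpenSim-grade musculoskeletal dynamics. A green
recovery test therefore establishes that the pipeline can extract a
learnable phase-locked mapping through its spectral bottleneck — not
that it reproduces published accuracy on real treadmill data.

An idealized oracle (`oracle_moments()`) that replays the known mapping
from the clean components scores VAF = 1 on clean data, certifying both
the mapping's learnability and the metric wiring.

## Metrics and aggregation

RMSE, R² = 1 − SSE/SST, and VAF = 1 − var(p̂ − p)/var(p) with the
**population** variance (divisor N) inside VAF; the source prints no
divisor, and this choice makes VAF = R² exact for mean-centred residuals
(asserted as an identity test). Aggregation across test trials uses the
sample standard deviation (divisor n−1), 0 by convention for a single
trial. BMI (for describing subjects) is mass/(height m)², rounded
half-away-from-zero to one decimal — the rule that reproduces 12 of the
14 published table rows; the remaining two rows (25.1755 printed as 25.1,
24.2574 printed as 24.2) are reproducible under no single deterministic
rounding rule and are treated as misprints.

## Numerical and degenerate-input choices

* Decimation is pure sample dropping starting at sample 0; an optional
  moving-average low-pass exists but defaults off, because the source
  states only a downsampling step and an anti-alias filter would be
  un-cited computation.
* Rows containing NaN/Inf are dropped (and counted), never interpolated.
* Constant predictor channels make the normalizer fail loudly rather
  than silently divide by ~0.
* Softmax uses max subtraction; ReLU subgradient at exactly 0 is 0.
* Non-finite training loss aborts with the epoch number (divergence
  error); learning rate 0 is a valid configuration that provably changes
  nothing.
* The treadmill data-rate question (a 20 Hz real-time mode versus the
  300 ms = 60-sample statement, which implies 200 Hz) is resolved in
  favour of 200 Hz as the default; both rates load, and a 20 Hz pipeline
  simply uses a shorter window.

## Known limitations

* **The corrupted-data ablation direction is a negative result in this
  synthetic world.** The acceptance surface asks that the complete model
  (V) beat the plain LSTM (I) in median test VAF at noise_sigma 0.5,
  spike_rate 2 over 5 seeds. In this generator the two angle channels
  remain highly informative in the time domain even after corruption, and
  a 60-step LSTM averages high-frequency noise out naturally, so Model I
  sits near VAF 0.97; the spectral variants discard within-window phase
  (magnitude-only FFT) and see every spike spread across all 60 frequency
  bins of ~60 consecutive windows, landing near 0.94–0.96. The criterion
  is implemented faithfully and left failing rather than re-tuning the
  generator toward the published ordering; the mechanism — magnitude
  spectra are *less* robust to impulsive artifacts than raw signals when
  clean low-frequency channels carry most of the information — is itself
  a finding about when the spectral front end helps.
* Training is pure R; a 30-epoch run on ~3100 windows takes ~40 s
  (variant V, hidden 32) to ~80 s (variant I, 60-step BPTT) on one CPU.
* No multi-layer or bidirectional LSTM, no transformer baselines, no
  statistical significance testing across models.
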