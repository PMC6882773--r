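---
title: "Unit-selection decoding of speech from ECoG high-gamma activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unit-selection decoding of speech from ECoG high-gamma activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(b2s)
```

## The decoding model

`b2s` reconstructs an audible speech waveform directly from multichannel
electrocorticographic (ECoG) recordings over speech-production cortex
(inferior frontal gyrus, ventral premotor and ventral primary motor
cortex).  It is a *concatenative unit-selection* decoder: rather than
fitting a generative acoustic model, it keeps a database of short speech
units — 150 ms Hanning-windowed audio snippets, one per 10 ms neural
frame of the training data — and, for every test frame, retrieves the
unit whose paired neural feature vector is most similar to the current
one.  The retrieved, already-windowed units are summed at their frame
positions (overlap-add); at a 10 ms hop, 15 windows overlap each output
sample, which smooths unit boundaries without any further processing.

The similarity is the cosine

$$\mathrm{sim}(A, B) = \frac{A \cdot B}{\lVert A\rVert\,\lVert B\rVert},$$

maximized over all training vectors \(B\).  Cosine similarity is
invariant to a global gain on the high-gamma power, so only the
*distribution* of power across electrodes and context bins drives the
selection.  Only this target cost is used: a concatenation cost (and
with it Viterbi search) is deliberately omitted, which makes every frame
an independent, exhaustively solvable argmax and keeps the decoder fast
enough for real-time operation at realistic database sizes (about
50,000 units for 500 s of training audio — the exact exhaustive search
is a single matrix product against norm-scaled rows with precomputed
training norms).

## Neural features

Per channel, the raw signal is linearly detrended, resampled to 600 Hz,
and forward–backward filtered with elliptic IIR filters: high-pass at
70 Hz (order 13), low-pass at 170 Hz (order 14), and a band-stop at
118–122 Hz (order 13) that removes the first line-noise harmonic.  Log
band power is `log(x² + ε)` with ε = 1e−10 so silent channels stay
finite.  The filters are designed in zero-pole-gain form and applied as
cascaded second-order sections; a transfer-function representation of a
26-pole band-stop is numerically unusable.  Forward–backward application
makes the cascade zero-phase (power is not smeared in time) and squares
its magnitude response.  Ripple and attenuation are not dictated by the
filter orders alone; the package fixes 0.5 dB passband ripple and 50 dB
stopband attenuation, conventional values for this kind of biosignal
band-limiting.

Each feature vector summarizes a 450 ms context of log band power
around the frame: nine consecutive 50 ms bins, mean-pooled (a 20 Hz
context resolution), flattened channel-major, so 64 channels yield
64 × 9 = 576 features.  Mean-pooling was chosen over decimation for the
"downsampling" of the context window: it is anti-aliased and exactly
deterministic.  Two window conventions exist:

* `centered` — `[t − 225 ms, t + 225 ms)`, the default;
* `causal` — `(t − 450 ms, t]`, using no samples after the frame, the
  configuration relevant for a closed-loop prosthesis.

Frames whose context (or whose 150 ms audio window) would cross a
recording boundary are dropped on both the neural and the audio side,
keeping the feature/unit pairing exact.

Features are z-scored and compressed by PCA to the smallest number of
leading components explaining at least 70% of the training variance.
Both transforms are fitted on training folds only and applied unchanged
to test data: per-fold (rather than global) statistics are the
leakage-free choice when the same normalization is to be reused on held
out data.  Features constant in training (sd = 0) normalize to zero, which
is neutral under cosine similarity.

## Evaluation

Reconstruction quality is measured spectrally.  Both waveforms are
transformed to log-mel spectrograms (50 ms Hann windows, 10 ms hop, 40
triangular filters equally spaced on the mel scale over 0–8 kHz,
`log(x + 1e−10)`); "50 ms windows with 10 ms overlap" is read as a
10 ms *hop*, consistent with the frameshift used everywhere else.  For
every word, the Pearson correlation of each coefficient across the
word's frames is computed; a zero-variance coefficient is undefined and
excluded from that word's mean rather than set to 0 (silent words would
otherwise be biased).  Words enter the grand mean with equal weight
(frame-count weighting would be an alternative; the equal-weight choice
is flagged here deliberately).

The chance level comes from a randomization test: each repetition draws
one uniformly random training unit per test frame, overlap-adds them
exactly as real decoding does, and records the grand-mean correlation;
the *maximum* over repetitions (1,000 by default) is the chance level,
and significance tiers are earned by exceeding 95, 99 or 99.9% of the
randomized controls (strict order-statistic comparison).

Intelligibility is summarized by the short-time objective
intelligibility measure (STOI) and its published logistic link to
transcription accuracy,
\(\mathrm{STOI} = 100 / (1 + e^{a d + b})\) with a = −13.1903,
b = 6.5192.  The STOI entering this formula is on a 0–100 scale: on a
0–1 reading the constants cannot reproduce the mapping's own anchor
values (0.15 ↦ 36%, 0.25 ↦ 41%), which the unit tests pin down.  STOI
itself is an established external measure and is implemented here as a
faithful port of the published algorithm (10 kHz reference rate,
256-sample frames, 15 one-third-octave bands from 150 Hz, 384 ms
segments, −15 dB clipping, 40 dB silent-frame exclusion), verified
against an independently written reference implementation.  Note that
the clipping stage gives even unrelated noise a positive STOI floor
(≈ 0.24 on the package's test signals); STOI differences, not absolute
floors, are the informative quantity.

## Cross-validation

`crossval_run()` performs grouped 5-fold cross-validation: distinct word
labels are shuffled and partitioned, so the word sets of training and
test folds are disjoint and the model is always evaluated on words it
never saw.  Every labeled frame is tested exactly once.  Inter-word
silence frames go to the training side of every fold — they enlarge the
unit inventory — except within 150 ms of a test word, where they are
excluded so that no test-word audio can leak into a training unit (the
150 ms margin equals the unit window, making the exclusion exact).
This silence policy is a design choice of the package: it maximizes the
unit inventory without compromising the held-out words.

For synthetic validation a `split_by_token` option partitions word
*tokens* instead: with a label-disjoint split a decoder can only succeed
through sub-word structure shared across different words, which the
simple synthetic vocabulary does not model, so token splitting (same
label, different tokens, still disjoint audio) is the appropriate
regime there.

## The synthetic session generator

`simulate_session()` produces paired neural/audio sessions with a known
ground-truth coupling, emulating the recording structure of the study
setting: 64 channels at 2 kHz with per-channel region labels, 48 kHz
mono audio, one mostly-CVC word every 2 s.  Each word has a latent
"articulatory" trajectory — four smooth random-Fourier dimensions
interpreted as two formant tracks, voicing amplitude and pitch — that is
a deterministic function of the label, so repeated tokens are
acoustically similar (plus 5% token jitter).  The audio is a small
formant-style synthesis: three frequency-modulated partials under a
raised-cosine envelope.  It is deliberately *not* intelligible speech;
the evaluation is spectral correlation, which only needs word-specific,
repeatable spectrotemporal structure.

Each neural channel is 70–170 Hz band-limited noise whose amplitude is
modulated by `1 + coupling × (w_c · z(t))`, a channel-specific linear
readout of the latent trajectory, plus independent broadband noise
(`noise_sd`, default 0.3) and a slow drift that exercises the
detrending stage.  The readout is linear in amplitude, so log band
power is approximately linear in the latent — the simplest model under
which the feature pipeline can see the trajectory.  Readout strength is
ordered M1v > PMv > IFG > other (gains 1.0 / 0.6 / 0.3 / 0.1),
mirroring the anatomical information ranking reported for real data, so
region-subset decoding has a known expected ordering.  At
`coupling = 0` the neural track carries no speech information at all
and decoding must fall inside the randomization null.

What the generator does *not* model: realistic 1/f spectra beyond the
band-limiting, articulatory dynamics, coarticulation between words,
speaker identity, or any shared phonetic structure between different
labels.  Passing tests on synthetic sessions therefore demonstrate that
the pipeline recovers a known coupling under its stated assumptions —
not that the method achieves any particular performance on patient
data.

The end-to-end test conditions use 60 s sessions (30 tokens over a
10-label inventory) and 16 channels: large enough for ~4,500-unit
training folds and stable correlations, small enough that the full
suite, including a 200-repetition null, runs in minutes on one CPU.

## Numerical choices

* Resampling (2 kHz → 600 Hz, 48 → 16 kHz, 16 → 10 kHz inside STOI) is
  rational-ratio upfirdn with a long linear-phase Hamming FIR,
  group-delay compensated; passband gain error is below 0.4%.
* Unit placement: center sample `round(t · 16000)`, window occupying
  `[center − 1200, center + 1200)`; symmetric (zero-endpoint) Hanning
  window.  The window-sum constant of the 150 ms/10 ms overlap-add is
  7.5 with well under 1% ripple; output is *not* renormalized by it
  (spectral correlation is gain-invariant), though a gain-normalization
  flag exists for listening.
* Ties in the argmax break to the lowest training index; a zero-norm
  feature vector has similarity 0 to everything and selects the first
  unit — both rules exist purely for cross-platform determinism.
* PCA uses the exact covariance eigendecomposition (via `prcomp`);
  the retained dimension is the smallest k with cumulative explained
  variance ≥ 0.70 (a 1e−12 slack absorbs floating-point ties).
* All randomness (simulation, fold shuffling, randomization nulls) is
  driven by explicit seeds through a private RNG stream that does not
  disturb the caller's RNG state.

## Known limitations

* The zero-phase (forward–backward) filtering is an offline operation:
  a truly streaming implementation would need causal filters, and a
  perturbation of *future raw samples* can propagate backward through
  the reversed IIR pass.  The causal guarantee holds exactly from the
  band-power stage onward — causal-mode features at time t are
  bit-identical under any change of later band-power samples — which is
  what the real-time argument is about (using only feature context
  before the current moment).
* EDF import and HDF5 caching are not provided; the native session
  container is a documented raw-float64 + JSON + WAV + TSV layout that
  round-trips exactly (16-bit PCM quantization aside).
* The decoder reconstructs *within-speaker* from simultaneous
  recordings; no cross-session or cross-participant transfer is
  attempted, and no language model or prior information rescoring is
  applied.
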