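---
title: "Detecting sharp-wave ripples with a recurrent network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sharp-wave ripples with a recurrent network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The detection problem

Sharp-wave ripples (SPW-Rs) are brief high-frequency oscillations
(roughly 130–250 Hz, under 100 ms, band-pass amplitudes around 0.1 mV)
in the hippocampal CA1 local field potential (LFP), widely used as a
biomarker of memory consolidation. Conventional detectors band-pass
filter the LFP to the ripple band, take the Hilbert envelope, smooth it,
and threshold it a few standard deviations above a moving mean; a human
then curates the candidates. `swrnet` implements both this conventional
front-end (`detect_baseline()`) and its replacement: a recurrent neural
network trained by supervised sequence labeling, which maps a raw
single-channel LFP trace of any length $N$ to a trace
$\hat y(t) \in (0,1)$ of the same length, interpreted as the
instantaneous probability of a ripple.

## Labels, samples and datasets

Events are labeled by center times $t^{\langle i\rangle}$ and encoded as
a binary boxcar trace: $y(t) = 1$ on
$[t^{\langle i\rangle} - D/2, t^{\langle i\rangle} + D/2)$ with
$D = 50$ ms, overlaps clipped at 1 (`one_hot_encode()`). On the sampling
grid (sample $i$ covers $[i/f_s, (i+1)/f_s)$, 0-based) a sample is set
when it lies fully inside the boxcar, i.e. for
$i \in [\lceil (t-D/2) f_s\rceil, \lfloor (t+D/2) f_s \rfloor)$. At
$f_s = 1250$ Hz this gives 62 or 63 ones depending on the event's phase
relative to the grid; an isolated boxcar decodes back to its center
within one sample. We chose the fully-contained convention over pure
flooring of both endpoints because it is symmetric around the event and
reproduces the 62-sample boxcar that the rest of the pipeline (minimum
peak distance, sparsity accounting) assumes for an event at a half-cycle
offset.

Training samples are 1 s windows centered on each labeled event with a
uniform random offset bounded by $(T_{\mathrm{sample}} - 3D)/2$, which
guarantees the generating boxcar stays inside the window while varying
its position (`extract_samples()`). Event-free negative windows are
deliberately not generated; the label trace is already zero for about
95 % of each sample. Events closer than $T_{\mathrm{sample}}$ to a
session edge are skipped rather than zero-padded, because padding would
fabricate signal. Splitting (`split_dataset()`) removes whole held-out
sessions before a seeded shuffle.

## The network

`swrnet()` fits the stack

> Gaussian noise → conv1d(20, k = 11) → dropout → conv1d(10, k = 11) →
> batch-norm → ReLU → dropout → (bi)LSTM → batch-norm → dropout →
> (bi)LSTM → dropout → batch-norm → dropout →
> time-distributed dense(1) + sigmoid

with Glorot-uniform kernels, orthogonal recurrent matrices, unit
forget-gate biases, and mean binary cross-entropy
$J = -\tfrac1N \sum_n [\,y \log \hat y + (1-y)\log(1-\hat y)\,]$
optimized by Adam (learning rate 0.005, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-7}$, batch size 20); mean squared
error is monitored alongside. The convolutions are length-preserving,
so a trained network accepts sequences of any length. Input noise
(SD 0.1 mV) and dropout (rate 0.2) regularize training only; validation
and prediction run in inference mode. Everything — forward pass, full
backpropagation through time, Adam, and the private RNG driving
shuffling, noise and dropout — is implemented in compiled code inside
this package; a fixed seed reproduces weights bit-for-bit on a fixed
device, and the analytic gradients are tested against finite
differences.

Two variants are provided. The *bidirectional* (non-causal) variant runs
each LSTM layer in both time directions (10 units per direction) and is
the recommended choice for offline analysis; the *unidirectional*
(causal) variant (28 units) sees only past context, the regime a
real-time closed-loop application would face. The unidirectional width
was chosen so its trainable-parameter count is about twice the
bidirectional variant's (13 363 vs 6 731), making the comparison a test
of architecture rather than capacity.

Two training hyperparameters deserve comment:

* **Batch-norm momentum** (`bn_momentum`, default 0.9). The running
  statistics that replace batch statistics at inference converge at a
  rate set by this momentum. With the common 0.99 the statistics lag far
  behind the rapidly drifting activations of a short schedule (a few
  hundred optimizer steps), which degrades inference badly while
  training-mode loss looks healthy. The 0.9 default converges within
  roughly fifty steps and is the convention several mainstream
  frameworks use.
* **Output-bias initialization** (`label_prior`, default 0.05). Kernel
  and recurrent initializers follow the Glorot/orthogonal convention;
  the output bias starts at the logit of the expected labeled fraction
  (the standard rare-event initialization). With a zero bias a short
  schedule spends its first epochs learning the 5 % base rate, which at
  desk scale leaves large seed-to-seed variance in how far each
  instance gets; the prior logit removes that transient for both
  variants.
* **Regularization strengths** (noise SD 0.1 mV, dropout 0.2) are
  exposed in the model interface; they matter most when training data
  are scarce.

## Event extraction and evaluation

Peak detection on $\hat y(t)$ (`find_events()`) selects local maxima
with height at or above a threshold (default 0.5), pairwise separation
of at least 50 ms (the boxcar width; ties keep the higher peak), and
width at half prominence of at least 20 ms — the conventions of the
standard scientific-Python peak finder, including plateau midpoints and
interpolated widths. `grid_search()` re-scores a validation set over
thresholds 0.10–0.95 (step 0.05) and widths 0–50 ms (step 5 ms) and
returns the F1-maximizing pair, resolving ties toward the highest
threshold and smallest width.

Scoring (`classify_detections()`) is per-peak and per-run: a predicted
time is a true positive if the label trace is 1 at its sample, a false
positive otherwise, and each maximal run of ones containing no
prediction is one false negative. True negatives are undefined for
sparse event detection. A prediction just outside a boxcar therefore
counts as both an FP and an FN — the rule's letter, applied
deliberately. Precision, recall and F1 are reported as `NA`, not 0,
when undefined.

Temporal agreement is summarized by a cross-correlogram of the binned
event trains (2 ms bins). The default normalization follows the form
printed in the tradition this detector comes from, where the centering
term uses the total event count $N = N_\upsilon + N_{\hat\upsilon}$;
because that form is not scaled to $[-1, 1]$, a textbook Pearson
normalization over time bins is available via `normalization = "bins"`.
Both are affine in the raw lagged pair counts, so the location of the
correlogram peak — the quantity the package's checks rely on — is
identical under either. Per-event "ripple strength" is the band-pass
signal energy $E_s = \sum |\phi_{BP}|^2$ over ±100 ms around the event
(`signal_energy()`, `energy_probability_table()`).

For time-continuous recordings, `predict_continuous()` splits the
signal into 0.5 s chunks under 5 zero-pad shifts of $k/5$ chunk lengths,
predicts each segmentation, realigns, and takes the elementwise median
(even counts use the standard midpoint), followed by a single final peak
detection. Predicted events within 1 s of a movement interval are
removed by `mask_movement()` (closed boundary: exactly 1 s away is
removed).

## The synthetic corpus

No public labeled recording ships with the package; the generator
(`simulate_lfp()`) defines the study conditions instead. It superposes,
on $1/f$ background noise (realized by spectral shaping of white noise;
the log–log PSD slope over 1–100 Hz is −1 by construction):

* **ripples**: Gaussian-enveloped sinusoids, envelope SD 15 ms (≈70 ms
  visible duration), peak amplitude 0.1 mV, frequency drawn uniformly
  from 150–180 Hz (mouse-like), riding on a negative half-cosine
  sharp-wave deflection (50 ms, 0.15 mV); placed by a Poisson process
  (0.1 events/s) with a 200 ms refractory gap so ground-truth events can
  never be merged by the detectors' 25/50 ms minimum-distance rules;
* **distractors** (unlabeled, 0.02/s): half 30–90 Hz gamma bursts
  (envelope SD 25 ms, 0.1 mV), half 2 ms broadband spikes (0.25 mV),
  there to probe false-positive behaviour;
* optional **movement intervals** (metadata only) covering a requested
  fraction of the session.

Background noise SD defaults to 0.05 mV, which puts the ripple-band
noise floor near 0.01 mV — a clearly detectable but not trivial ~10 dB
band SNR consistent with the qualitative description of awake mouse CA1
recordings this generator emulates. The generator is bit-deterministic
given its seed, and amplitude scaling is linear by construction (band
energy scales quadratically), which the tests exploit.

What the generator does *not* emulate: the temporal correlations of
real LFP beyond a $1/f$ spectrum, state-dependent ripple rates,
electrode drift, and genuinely ambiguous borderline events. Passing the
end-to-end checks therefore demonstrates that the pipeline learns and
recovers events under realistic amplitudes, durations and noise color —
not that its absolute scores transfer to any particular real recording.

## Desk-scale experiment sizes

The shipped experiment driver (`run_variant_comparison()`) trains both
variants × 3 seeds on a common corpus of 10 × 600 s sessions
(~600 labeled events; 120 validation samples) for 10 epochs. Ten epochs
of a few hundred optimizer steps are enough for the directional claims
the package tests (bidirectional at or below the unidirectional error
count; validation F1 ≥ 0.8); the full 50-epoch schedule remains
available through the `epochs` argument. The continuous-session test
uses a fresh 600 s session.

## Numerical choices and edge cases

* Zero-phase filtering throughout (forward–backward application), so no
  detector stage shifts event times; verified by impulse symmetry and
  lag-0 cross-correlation tests.
* The Morlet bank follows $M_f = \lfloor 2 s f_s \omega / f \rfloor$
  points spanning $[-2\pi s, 2\pi s]$ inclusive; 'full'-mode convolution
  is cropped by $(M_f-1)/2$ samples per end to restore input length.
* The 1052-point Gaussian smoothing kernel is normalized to unit sum
  (so constants are preserved); with an even kernel length the output
  carries a half-sample shift, which is negligible at σ = 40 ms.
* Moving mean/SD windows at the signal edges are truncated, not padded.
* Peak width is measured at half prominence relative to the local
  baseline, plateau peaks reduce to their midpoint sample, and the
  minimum-distance rule removes lower peaks first.
* Loss probabilities are clipped to $[10^{-7}, 1-10^{-7}]$.
* Undefined metrics (zero denominators) propagate as `NA` rather than 0.

## Known limitations

* The baseline detector automates the *detection* stage of the manual
  workflow; expert curation is replaced by an export of per-event review
  snippets (`review_snippets()`), not reproduced.
* Training is single-device, CPU-oriented; there is no GPU path. The
  determinism contract is per-device.
* The continuous-mode false-positive rate on real data is known to be
  dominated by unlabeled ripple-like transients; on synthetic data
  distractors stand in for these, which is a much cleaner world.
* Only single-channel input is supported; no multi-class event typing.
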