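---
title: "Methods: from chunked sensor bytes to agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chunked sensor bytes to agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science and the numerical
choices behind it: what each stage computes, which parameters matter and
why they default as they do, what the synthetic generators do and do not
emulate, and where the genuinely open design decisions were settled.

## The recording model

The platform records three modalities on one board: a 3-lead ECG at
2426 Hz, a 9-axis inertial unit at a nominal 70 ± 5 Hz, and audio at
22 050 Hz. Data reach storage in timestamped chunks — every 10 s for
audio, every 30 s for ECG and IMU — and each chunk carries start and end
UTC stamps from a battery-backed real-time clock (RTC). Two facts about
this acquisition drive most of the design:

1. **Sample loss.** Storage writes can stall, dropping samples at chunk
   tails. Under the first firmware generation roughly 8.7% of audio
   samples are lost; the second generation reduces this to about 2.3%
   (and to none for ECG). Lost samples are conventionally replaced by
   zero-padding, so every stage downstream must know which zeros are
   data and which are padding. The codec therefore stores padding both
   as literal zeros *and* in a run-length mask, and `missingFraction()`
   scores loss against the sample count the UTC span implies.
2. **Clock behaviour.** The RTC drifts 1–3 s per 11–12 h. Because all
   three modalities share the same clock, the drift does not affect
   cross-modal alignment and is left uncorrected by `frameStreams()`;
   it is only *simulated* (`degradeRecording()`), so that downstream
   code can be shown to tolerate it. All alignment uses UTC timestamps,
   never sample arithmetic.

Samples are held at codec precision (ECG as uint16 ADC counts, IMU as
int16 fixed point, audio on the signed 24-bit grid), which is what makes
write–read round-trips bit-exact by construction rather than by
tolerance.

## Framing and cross-device alignment

`frameStreams()` cuts each modality on a period grid anchored at the
earliest chunk start and places samples by timestamp; each frame is
forced to exactly `round(period × rate)` samples, with deficits
zero-padded and masked. Sample positions are assigned by rounding the
timestamp offset to the nearest grid slot — flooring, the obvious
alternative, collides adjacent samples under floating-point fuzz.

`alignSeries()` automates what is often done by eye: sliding one IBI
series against another and reading off the lag. Both series are
step-interpolated onto a 0.1 s grid and the mean absolute difference is
minimized over a ±`maxLag` lag grid (default ±30 s), ties breaking
toward zero lag. The estimate is flagged low-confidence when the best
objective improves on the zero-lag objective by less than 5%: a genuine
shift of a structured signal yields a deep, sharp minimum, while
uncorrelated series improve only by chance, an effect that shrinks as
the series grows. Short noisy series can beat 5% by luck; the flag is a
screen, not a test.

## From ECG to interbeat intervals

`detectRPeaks()` is a Pan–Tompkins-style detector: band-limit to
5–20 Hz (3rd-order Butterworth, run forward–backward for zero phase),
differentiate, square, integrate over a 150 ms moving window, then pick
integrator peaks above an adaptive threshold (a running 0.125/0.875
exponential update of the signal-peak estimate, initialized at the 95th
percentile) with a 200 ms refractory period. Each integrator peak is
refined to the maximum of the band-limited signal in the preceding
150 ms, and beat times are quantized to 4 ms — the tick of the 250 Hz
IBI clock that interbeat-interval files conventionally use. On clean
synthetic ECG the detected intervals sit within one tick of the
prescribed rhythm.

When the source ECG contains padded stretches, `extractIbi()` fills
them with the signal median *for detection only*: left at zero, every
gap edge would inject a large filter transient and corrupt the beats
beside it. The padded stretches remain flagged, and editing sees them.

`correctMissingArtifacts()` automates the standard manual editing
rules. An interval is suspect if it overlaps padding, leaves the
physiological bounds (adult 300–2000 ms, infant 250–1000 ms — the
infant range brackets the 375–675 ms intervals typical of the first
year), or deviates more than 25% from the median of its five nearest
neighbours. Suspect intervals are repaired by:

- **divide** — a long interval within 12.5% of an integer multiple
  k ≥ 2 of the local median becomes k equal parts (a missed beat);
- **combine** — an adjacent suspect pair summing to ≈ the local median
  is merged (a false beat);
- **interpolate** — anything else: the suspect run is replaced by
  `round(span / local median)` intervals, linearly blended between the
  flanking medians and rescaled to preserve the run's exact duration.
  Choosing the interval count from the span (rather than keeping the
  run's own count) re-inserts beats lost inside padded gaps; without
  it, recovery error against prescribed rhythms roughly triples.

All edits preserve total duration to the 4 ms tick, so editing is
idempotent and the beat-time/interval invariant survives. The edited
fraction is recorded; above 20% (configurable) the series is marked
unusable, mirroring the practice of excluding heavily edited sessions.

## Respiratory sinus arrhythmia

RSA here is the Porges–Bohrer quantity: the natural log of the variance
of heart period restricted to the respiration band, in ln ms². The
pipeline in `computeRSA()`:

1. step-interpolate heart period onto a uniform grid — 0.5 s for
   adults, 0.25 s for infants, chosen so each band's upper edge stays
   below the Nyquist frequency of its grid;
2. detrend by subtracting a centred 21-point moving cubic fit
   (a Savitzky–Golay smoother — the "moving polynomial" filter — whose
   shrinking-window endpoint handling `signal::sgolayfilt` provides);
3. band-pass with a 127-tap Hamming-window FIR (adult 0.12–0.40 Hz,
   infant 0.3–1.3 Hz), applied forward–backward for zero phase;
4. take ln variance in non-overlapping 30 s epochs anchored at session
   start (trailing partial epoch dropped; a zero-variance epoch is
   undefined and excluded with a warning);
5. average epochs into the task mean.

For a heart period 800 + 100·sin(2π·0.25t) ms the band-limited variance
is A²/2 = 5000 ms², so the task mean should approach ln 5000 ≈ 8.52.
The pipeline lands near 8.62: the residual of the 21-point cubic
smoother slightly *overshoots* unity gain in the passband (about 1.12
at 0.25 Hz on the adult grid), while the step interpolation of ~0.8 s
beats attenuates by ≈ 0.94; the net ≈ +0.10 ln-units is an intrinsic
property of this filter chain, constant across inputs, and irrelevant
to the within-subject *contrasts* the quantity exists for. The
monotonicity that matters — task mean increasing as 2·ln A — holds to
within a few hundredths.

`rsaContrast()` tests task-to-task changes with one-tailed paired
t-tests in the hypothesized direction (challenge sessions suppress RSA;
recovery restores it), reporting per-transition mean change, t, p and
sign agreement.

## Activity recognition

`resampleDynamic()` repairs the IMU's floating sample clock: using the
timestamps, every non-overlapping 30 s interval is mapped to exactly
2100 samples. Both directions use linear interpolation onto the
interval's uniform grid: selecting existing samples by index would keep
their jittered clock and leak several percent RMS phase error into a
1 Hz signal, defeating the purpose of the correction. Intervals holding
under half their expected samples are flagged rather than trusted.

`removeGravity()` subtracts 9.8 m/s² (sign-matched) from the axis whose
0.25 Hz low-pass mean magnitude is largest — adequate while the device
is quasi-static at window scale, which chest wear satisfies for these
tasks.

`classifyActivities()` follows the flattened-window design: 5 s windows
(3 axes × 350 samples = 1050 features) with transition windows
excluded, z-normalization fitted on the training side only (the
leakage-safe reading of "normalize then classify"), and a 100-tree
random forest. The published protocol's "10-fold cross-validation" of
"80/20 splits" cannot be both simultaneously; it is implemented as 10
repeated stratified random 80/20 splits with test predictions pooled
into one confusion matrix, which matches how the pooled tables and the
per-split mean/SD metrics are reported. The installed forest
implementations split on Gini impurity rather than entropy; on a
corpus separable by construction the choice is immaterial. F1 is
reported class-frequency-weighted — the variant that reproduces the
published summary from its own confusion matrix.

A note on chance: with 812 of 1254 windows in one class, a classifier
*trained on shuffled labels* converges to the majority class (accuracy
≈ 0.65, kappa ≈ 0), whereas a classifier *assigning labels uniformly at
random* scores 25% regardless of imbalance. The 25% figure is the
uniform-assignment analysis, and that is what the acceptance checks
reproduce; shuffled-label training is checked through kappa ≈ 0.

`detectRotation()` integrates each gyroscope axis over the window and
fires at ≥ 300° — below the nominal 360° of a full chair rotation to
tolerate integration leakage at window edges; the margin is
configurable.

## Audio preprocessing and emotion recognition

`downsampleAudio()` is rational-ratio polyphase FIR resampling
(320/441 for 22 050 → 16 000 Hz) with the output length pinned to
`round(n × 16000/22050)`.

`declip()` repairs hard-clipped regions at a 70% threshold. Within each
above-threshold run, only *flattened tops* count as clipping: maximal
sub-runs of near-constant value (within 10⁻³ of the maximum magnitude)
of length ≥ 2, or an isolated single sample above threshold. Loud but
wiggly stretches are genuine signal and are never touched — this is
what lets the function be the identity on clean material. Each plateau
is replaced by a quartic least-squares fit through 4 clean flanking
samples per side: a cubic cannot rebuild a symmetric flattened peak
(its odd leading term forces an inflection where the peak should be),
while the quartic restores a 0.7-clipped sine to within 0.2% and is
idempotent. Two guards implement the "without reducing amplitude for
restored peaks" convention: restored samples keep the plateau's sign
and at least its magnitude (except isolated single-sample artifacts,
which are simply interpolated), and no restored value exceeds
`max|x| / threshold` — the full scale the threshold semantics imply.

`serCrossval()` classifies utterance-level functionals (mean, SD,
20th/80th percentiles, slope) of frame-level descriptors — log energy,
an autocorrelation f0 estimate bounded to 50–500 Hz, spectral centroid,
85% rolloff, and 13 real-cepstrum coefficients over 25 ms frames with a
10 ms hop — with linear discriminant analysis under stratified k-fold
cross-validation (default 3). The published pipeline names no feature
set; this one is a declared default chosen to be standard, redundant
and swappable, since the object of interest is the *pipeline shape* and
the paired comparison of devices, not the feature engineering. Folds
are stratified by emotion, not by speaker — a documented limitation
forced by corpus size (141 utterances over 8 speakers). Degenerate
(constant within a class) feature columns are dropped with a warning
before the discriminant fit. Given the utterances and a seed the whole
procedure is deterministic.

## Agreement statistics

`ibiAgreement()` reports mean error (reference − test), mean absolute
error, MAPE (mean of |error|/reference × 100, the conventional
acceptability metric for ECG-derived measures, with ±10% the usual
bar), and Bland–Altman 95% limits of agreement at bias ± 1.96 SD of the
paired differences. `classifierMetrics()` computes accuracy,
class-frequency-weighted F1 and Cohen's kappa from a
rows-are-truth confusion matrix. `mcnemarTest()` defaults to the
*uncorrected* chi-square (b−c)²/(b+c) on the discordant counts: that
form reproduces both published paired-comparison results (χ² = 7.41
from 95/61; p = 0.26 from 16/23), where the continuity-corrected form
gives 6.98; the corrected and exact-binomial variants are options.
`wordErrorRate()` aligns case-folded, punctuation-stripped word tokens
by unit-cost Levenshtein distance with a backtrace splitting errors
into substitutions, deletions and insertions; WER = (S+D+I)/N may
exceed 1. `relativeImprovement()` is (baseline − improved)/baseline ×
100, the arithmetic behind language-model gains on WER tables.

## The synthetic generators

The generators exist so the full chain can be validated against known
truth; they emulate the *structure* of the platform's data, not its
physiology or acoustics.

- `genEcg()` integrates a prescribed instantaneous heart period
  (base + sinusoidal respiratory modulation per session) into beat
  times and stamps each beat with a three-Gaussian QRS-like template
  (Q/R/S amplitudes −0.15/1.0/−0.25 of the R wave, widths 10/12/10 ms)
  on a constant baseline with optional Gaussian noise. No PQRST realism
  is claimed; the template is simply sharp enough to detect to one
  tick.
- `genActivity()` drives one continuous jittered sampling clock
  (spacings within 70 ± 5 Hz) across an activity plan: upright is
  gravity plus low noise; walk, glide and squat are 2 Hz vertical,
  1 Hz lateral and 0.5 Hz high-amplitude vertical oscillations;
  rotation is a sustained ~60°/s single-axis gyroscope rate.
  `genActivityCorpus()` runs the preprocessing chain over per-class
  bouts and trims to exact window counts (the study design is
  812/150/176/116).
- `degradeRecording()` drops a binomial number of samples from each
  chunk's tail — loss lives at chunk tails because it comes from
  storage-write stalls — and applies a linear RTC drift to all stamps,
  returning exact bookkeeping of what was dropped.
- `genSpeechCorpus()` builds 141 utterances (28/37/38/38 across
  neutral/happy/sad/angry) as harmonic sources with emotion-dependent
  f0 level and slope, vibrato, jitter, energy and spectral tilt, under
  a syllable-like 1.5 Hz energy envelope, plus noise and optional hard
  clipping. A `separation` dial scales the inter-class differences;
  at 0 the corpus is chance-level by construction.

What passing tests on these fixtures shows is that the *software chain*
is correct: formats round-trip, padding is accounted, detection and
editing recover prescribed rhythms through realistic loss, and the
statistics match their definitions. What it cannot show is performance
on real infants — real ECG morphology, motion artifacts, real speech
and real room acoustics are all richer than these surrogates, and the
published device-agreement numbers (MAPE tables, absolute WERs) depend
on the original recordings and trained ASR models.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run at deliberately modest
sizes — 5-minute single-session oracles, ten 9-minute synthetic
subjects for the recovery study, the full 1254-window activity corpus,
the full 141-utterance speech corpus, and the complete enumeration of
word-sequence pairs up to length 6 over a 3-word vocabulary — sizes at
which every check is exact or tightly seeded while the whole suite
stays in the minutes range. Seeds are explicit everywhere randomness
enters; quantization grids (4 ms beats, codec fixed point) are part of
the data model, so equality tests are exact rather than approximate;
filters are applied forward–backward wherever phase matters; and
degenerate inputs (flat ECG, constant heart period, empty sessions,
fully clipped audio, single-class corpora) fail loudly rather than
silently.
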