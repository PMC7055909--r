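---
title: "Methods: voice-type discrimination from neck-surface vibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voice-type discrimination from neck-surface vibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Modal, breathy and pressed phonation lie on a continuum of vocal-fold
contact area and open quotient: breathy voice has little fold contact and a
large open quotient, pressed voice the opposite. A neck-surface
accelerometer (NSA) picks up the skin vibration driven by the voice source.
Because neck tissue low-passes the signal (little energy survives above
roughly 3 kHz), NSA recordings carry voice-source information — harmonic
envelope, cycle-to-cycle perturbation, noise floor — while discarding most
formant detail, which also preserves the speaker's privacy. `voicetype`
implements the full discrimination pipeline on such signals: segmentation,
feature extraction, perceptual-panel screening statistics, and a
multi-classifier evaluation harness, together with a synthetic-signal
generator that provides ground truth for every stage.

## The feature model

All features are computed per utterance (one sustained vowel). With $A_i$
($i = 1,\dots,5$) the amplitudes of the first five spectral harmonics, the
harmonic quotients are

$$H_i = \frac{A_i}{A_1 + A_2 + A_3 + A_4 + A_5}, \qquad i = 1,\dots,4 .$$

The five quotients sum to one by construction, so $H_5$ is redundant and
only $H_1,\dots,H_4$ enter the feature vector. Harmonics are searched in
the 50–1500 Hz band; a harmonic predicted above the band contributes
$A_i = 0$.

Spectral entropy over the 0–3000 Hz band, with $p_i$ the normalized
spectral density (squared magnitude),

$$\mathrm{SE} = -\sum_i p_i \log p_i ,$$

is small for tonal spectra and large for noise-like ones. Relative jitter
and shimmer over the $N$ detected vocal cycles, with $T_i$ the cycle
periods and $A_i$ the per-cycle peak magnitudes,

$$J_r = \frac{\tfrac{1}{N-1}\sum_{i=1}^{N-1} |T_i - T_{i+1}|}
             {\tfrac{1}{N}\sum_{i=1}^{N} T_i}, \qquad
  S_r = \frac{\tfrac{1}{N-1}\sum_{i=1}^{N-1} |A_i - A_{i+1}|}
             {\tfrac{1}{N}\sum_{i=1}^{N} A_i} .$$

The classification unit is $[H_1, H_2, H_3, H_4, \mathrm{SE}, J_r, S_r]$.

Interpretation choices the formulas leave open, and how this package fixes
them:

* **$N$ is the number of detected vocal cycles**, not the number of
  sampling points: the sums index per-cycle periods and peak magnitudes,
  so a per-sample reading is not self-consistent. `cycle_series()`
  enforces $N \ge 2$.
* **Entropy base**: natural log (nats) by default; `base` is an argument,
  and the maximum-entropy bound becomes $\log_b(n)$ in the chosen base.
* **Spectral density** means squared magnitude (power).
* **Jitter and shimmer are stored as fractions**; multiply by 100 for the
  percent scale used in reports.
* **Amplitude normalization**: the waveform is scaled to unit peak before
  spectral analysis and spectra are normalized to unit maximum, so
  loudness cannot leak into any feature. Jitter and shimmer are ratios and
  are gain-invariant by construction.

## Numerical choices

* **One whole-utterance spectrum** (Hamming window) rather than a
  frame-averaged one; sustained vowels are quasi-stationary, and a single
  long window gives the sharpest harmonic peaks.
* The FFT is zero-padded to at least $4\times$ the segment length and to a
  bin spacing of at most 1 Hz. The harmonic amplitude is the window-local
  maximum within $\pm f_0/4$ of the predicted harmonic, refined by
  three-point parabolic interpolation; together these reduce scalloping
  loss below ~0.1%, which matters because the quotients compare amplitudes
  across harmonics at different bin offsets.
* **f0 estimation** is autocorrelation-based (FFT autocorrelation,
  normalized at lag zero, search band 100–400 Hz by default) with
  parabolic peak refinement; a normalized peak below 0.3 is declared
  unvoiced.
* **Cycle detection** picks one maximal positive peak per period, advancing
  peak-to-peak with a $[0.5, 1.5]/f_0$ search window; peak positions and
  magnitudes are parabolically refined, giving sub-sample period estimates
  (without refinement, sample quantization alone would inflate jitter by
  ~0.2 percentage points at 44.1 kHz). Cycles with periods outside
  $[0.5, 2]/f_0$ are discarded; fewer than two surviving cycles is an
  error, as is a segment with no positive samples.
* **Conventions**: inside R objects, segments and cycle boundaries use
  R's native 1-based inclusive sample indexing; all JSON/CSV artifacts and
  the CLI report times in seconds and frequencies in Hz, which keeps file
  outputs indexing-free.
* **Degenerate inputs** fail loudly with stage-named errors
  (`[vad]`, `[f0]`, …): all-zero spectra, empty entropy bands, unbalanced
  rating panels, zero total variance in the ICC.

## Voice activity detection

Frames of 25 ms advanced by 10 ms yield per-frame energy (mean squared
sample) and zero-crossing rate (sign changes per second). A frame is
voiced when its energy exceeds `energy_factor` (10) times the noise floor
— the median energy of the lowest-decile frames — and its zcr is below
`zcr_ceiling`. The threshold is capped at a tenth of the peak frame energy
so a recording with no silence at all is returned whole. The voiced mask
is smoothed by a 3-frame majority filter (hangover), and the longest run
becomes the utterance (the protocol records one sustained vowel per
token).

The zcr ceiling defaults to 3000 crossings/s. With the generator's noisier
profiles (pressed voice at 8 dB SNR, noise band-limited to the 3 kHz
sensor band) voiced frames reach ~2000–2600 crossings/s, so a 2000/s gate
— a common textbook value for microphone speech — fragments pressed vowels,
while silence dither is spectrally white (zcr near half the sampling rate,
at least 8000/s at the rates used here). 3000/s separates the two regimes
cleanly and is exposed in the configuration. All framing and threshold
values are conventions of the method class, not measured constants.

## The synthetic-signal generator

`synthesize_waveform()` builds the signal cycle by cycle: cycle $k$ has
period $T_k = (1/f_0)(1 + \varepsilon_k)$ and peak amplitude
$A_k = 1 + \delta_k$ with i.i.d. Gaussian deviates. The drawn deviates are
rescaled so the realized relative jitter/shimmer of the stored truth
cycles equals the requested value *exactly* (solving
$a = J/(\bar{|\Delta e|} - J \bar{e})$ for the scale): the generator's
ground truth is self-consistent with the formulas it will be measured by,
and round-trip tests isolate extraction error alone. Within a cycle the
waveform is a five-harmonic cosine stack weighted by the profile's
`harmonic_weights`; the amplitude envelope between consecutive peaks is a
raised cosine, stationary at each peak, so the waveform is continuous and
the cycle peak sits exactly at the cycle start with exactly amplitude
$A_k$.

Broadband Gaussian noise enters at the profile's SNR, band-limited to
3 kHz because the neck-surface sensor itself passes little beyond that —
this keeps the noise floor inside the spectral-entropy band at any
sampling rate and keeps voiced zero-crossing rates bounded. Leading and
trailing silence carries dither 80 dB below the signal peak so the
zero-crossing rate is defined in "silence". The assembled record is scaled
to 0.9 peak (recorder headroom); every feature is invariant to this gain.

Per-type defaults encode the reported class geometry: breathy
`harmonic_weights = (6, 2, 1, 0.6, 0.4)` (H1 over 60% of the harmonic
sum), pressed a prominent H2 with the lowest SNR (8 dB, hence the largest
spectral entropy), modal a monotone decay with the smallest shimmer (2%)
and the highest SNR. Fundamental frequency defaults to a uniform draw in
180–250 Hz (adult female range; the recording protocol did not constrain
pitch or loudness, and neither value is a measured constant). Harmonic
phases are zero by default (a cosine stack); a flag randomizes them, and
no feature in scope depends on phase.

What the generator does **not** emulate: physiological glottal-flow wave
shapes (no Liljencrants–Fant model), vocal-tract and neck-tissue transfer
functions, room or sensor-mount acoustics, vowel identity, loudness
variation, and within-utterance drift of $f_0$ or voice quality. Passing
tests therefore demonstrate that the *pipeline arithmetic* is correct and
that the *reported class geometry is recoverable when present* — not that
real clinical recordings will separate this well.

## The rater panel and screening

`simulate_panel()` models each rater by a $4\times4$ row-stochastic
confusion matrix over (modal, breathy, pressed, none) and a confidence
distribution; duplicated samples are re-rated independently for the
intra-rater design. Confidence defaults to Beta(9, 1.5) (mean ~0.86) — a
plausible model of confident expert raters; the study itself reports no
confidence distribution, so this is a convention, and point-mass or
per-rater models can be supplied.

Screening statistics: Fleiss' kappa for inter-rater agreement on the
balanced panel (returned as 1 when every item is unanimous, where the
chance-corrected ratio degenerates); per-rater Cohen's kappa on the
duplicated pairs for intra-rater reliability; and the two-way random
ICC from the items-by-raters ANOVA mean squares for numeric scores, in the
single-measure absolute-agreement form ICC(2,1) by default (the
average-measure form is an option; the study names the model and agreement
type but not single-vs-average, and single is the conservative choice).

The pure-sample rule labels a sample when at least `min_agree` (4) of the
raters chose the same target category each with confidence at least
`min_conf` (0.8). The gate is read as "at least four raters chose it *at
or above* the confidence floor": whose confidence the floor applies to is
otherwise ambiguous, and this reading is strict, matches the 4-of-5
worked example, and is monotone in both thresholds. "None"-majority
distractors are never pure.

## Classifiers and evaluation

Five families, with the stated hyperparameters: linear discriminant;
decision tree grown with the Gini index and pruned to at most 20 splits;
linear SVM with one-versus-one voting (ties resolved by summed
decision-function margins, which also provide the per-class scores);
weighted KNN with $k = 10$, Euclidean distance and inverse-squared-distance
weights (the usual reading of "weighted"); and a single-hidden-layer
network with 100 units and softmax output trained under cross-entropy.
The network optimizer is `nnet`'s quasi-Newton method run in chunks with
validation-based early stopping — the optimizer is an implementation
choice, not part of the model contract.

Features are z-scored inside each training fold (KNN, SVM and the network
are scale-sensitive). Evaluation is stratified 5-fold cross-validation for
all classifiers except the network, which uses six repeated stratified
70/15/15 train/validation/test splits, reporting the mean test accuracy
over repeats; a master seed derives every cell's sub-seed. Pooled held-out
predictions give the row-normalized confusion matrix, per-type accuracy,
and one-versus-rest TPR/FPR/AUC, the AUC by the Mann–Whitney rank
statistic (the multiclass reduction is per-class one-vs-rest). Classifier
and subset comparisons use Pearson chi-square tests on
(group × correct/incorrect) contingency tables at $\alpha = 0.05$, flagged
when expected cell counts fall below 1.

The ablation grid covers the full set, the seven leave-one-feature-out
subsets, the spectral set ($H_{1\text{–}4}$ + SE) and the stability set
($J_r$ + $S_r$), with per-set and per-classifier means and standard
deviations.

`simulate_feature_cohort()` is the distribution-level counterpart of the
waveform path: it draws feature vectors directly from per-class Gaussians
calibrated once against the reported class geometry — single features
discriminate weakly (linear-discriminant accuracies roughly 45–65% against
a 33% chance level, with $H_4$ and $J_r$ nearly uninformative), breathy
voice is well separated in every harmonic quotient, pressed voice carries
a spectral entropy about 90% above the other types, and modal voice the
smallest and tightest shimmer. On such cohorts removing shimmer
collapses modal-class accuracy and removing entropy collapses
pressed-class accuracy, while an appended pure-noise column is
inconsequential — the feature-importance structure the ablation harness is
designed to detect.

## Problem sizes

The test-suite and acceptance-script runs use 16 kHz synthesis (all
harmonics sit below 1.5 kHz and the entropy band ends at 3 kHz, so nothing
informative lives above an 8 kHz Nyquist), 2-second utterances for
round-trip accuracy checks, 300 samples per class for the ablation grid,
and a 1395-token, five-rater panel for the screening statistics. These are
the package's chosen verification scales; all functions accept arbitrary
rates and sizes, and 44.1 kHz input is the recorder's native format.

## Known limitations

* The pipeline assumes one sustained vowel per recording; it does not
  segment running speech, and the VAD is not noise-robust beyond its
  energy/zcr design.
* Cycle detection requires a usable $f_0$ estimate and positive peaks; it
  is not a glottal-event detector and will not track strong diplophonia.
* The screening module covers a balanced panel design only; unbalanced
  rater counts per item are rejected rather than approximated.
* Synthetic cohorts demonstrate recoverability, not clinical performance;
  absolute accuracies on real NSA recordings depend on data that is not
  part of this package.
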