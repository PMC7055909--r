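# voicetype

Discrimination of **modal, breathy and pressed phonation** from
neck-surface accelerometer (NSA) vibration signals of sustained vowels.

Clinical voice assessment still leans on auditory-perceptual judgement by
trained listeners, which cannot run continuously outside the clinic. A
neck-surface accelerometer records the skin vibration driven by the voice
source; neck tissue low-passes the signal below ~3 kHz, so the recording
keeps voice-source information (harmonic envelope, cycle perturbation,
noise floor) while discarding most speech content — a privacy-preserving
basis for long-term, automatic voice-type monitoring. `voicetype` is for
researchers in clinical voice and speech signal processing who want a
tested, reproducible implementation of that pipeline.

## What it computes

From each recording, after voice activity detection (short-time energy +
zero-crossing rate), the seven-dimensional feature vector

    [H1, H2, H3, H4, SE, Jr, Sr]

* **Harmonic quotients** `H_i = A_i / (A_1 + … + A_5)`, `i = 1..4`, from
  the amplitudes of the first five spectral harmonics in 50–1500 Hz
  (the five quotients sum to one; H5 is redundant).
* **Spectral entropy** `SE = −Σ p_i log p_i` over the normalized spectral
  density in 0–3000 Hz — small for tonal, large for noise-like spectra.
* **Relative jitter / shimmer** over the `N` detected vocal cycles:
  `Jr = mean|T_i − T_{i+1}| / mean T_i`,
  `Sr = mean|A_i − A_{i+1}| / mean A_i`.

Around the feature core, the package provides:

* a **synthetic-signal generator** (`synthesize_waveform()`) producing
  quasi-periodic vibration signals with exact ground truth: per-type
  harmonic envelopes, exactly-calibrated injected jitter/shimmer,
  band-limited noise and silence padding — plus a **simulated rater
  panel** (`simulate_panel()`) with per-rater confusion and confidence;
* **screening statistics**: Fleiss' kappa, per-rater Cohen's kappa on
  duplicated samples, two-way random ICC(2,1), and the **pure-sample
  rule** (≥ 4 of 5 raters agreeing at ≥ 80% confidence,
  `filter_pure()`);
* a **five-classifier evaluation harness** (`run_lofo()`): linear
  discriminant, decision tree (≤ 20 splits, Gini), linear SVM
  (one-vs-one), weighted KNN (k = 10), and a 100-unit single-hidden-layer
  neural network (70/15/15 splits × 6 repeats, early stopping), evaluated
  over the full feature set, all leave-one-feature-out subsets, and the
  spectral (`H1–H4 + SE`) and stability (`Jr + Sr`) sets, with per-type
  TPR/FPR/AUC and chi-square comparisons.

## Worked example

```r
library(voicetype)

rec <- synthesize_waveform(voice_profile("breathy", f0_hz = 220),
                           duration_s = 2, rate_hz = 16000,
                           silence_s = 0.5, seed = 42)
rec
#> Waveform record: 47992 samples @ 16000 Hz (2.999 s)
#>   truth: breathy, f0 = 220.0 Hz, 440 cycles, silence 0.50 s/side

extract_features(rec)
#>       H1     H2     H3     H4     SE     Jr    Sr    f0_hz   label
#> 1 0.6254 0.2006 0.0933 0.0504 3.0012 0.0213 0.071 220.1112 breathy
```

The breathy template keeps H1 above 0.6 of the harmonic sum (its defining
trait); jitter and shimmer come back near the profile's injected 1% and
6%, and the VAD-located utterance excludes the half second of silence on
each side.

Classifier ablation on a synthetic feature cohort with the reported class
geometry (modal: low shimmer; pressed: high entropy; breathy: dominant
H1):

```r
feats <- simulate_feature_cohort(150, seed = 42)
rep <- run_lofo(feats, classifiers = c("ld", "svm", "knn"),
                plan = feature_subset_plan()[c("full", "-SE", "-Sr",
                                               "stability")],
                seed = 42)
rep
#> Overall accuracy (%) by feature subset and classifier:
#>             ld  svm  knn per-set
#> full      90.7 90.9 88.0    89.9
#> -SE       85.6 88.2 85.6    86.4
#> -Sr       83.6 85.3 81.8    83.6
#> stability 64.0 63.1 56.7    61.3
```

Dropping shimmer (`-Sr`) or entropy (`-SE`) costs several points of
overall accuracy while the two stability features alone reach only ~61%:
spectral and stability information are complementary, and `Sr`/`SE` carry
the modal and pressed classes respectively (see
`per_class_accuracy(rep, "-Sr")`).

A complete simulated pipeline — synthesis, VAD, extraction, optional
panel screening, full evaluation grid — is one call:

```r
res <- run_pipeline(pipeline_config(simulate = 150, rate_hz = 16000,
                                    out_dir = "out", seed = 7))
```

A thin command-line wrapper with `simulate`, `vad`, `extract`, `screen`,
`classify` and `run` subcommands is installed at
`system.file("cli", "voicetype.R", package = "voicetype")`.

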