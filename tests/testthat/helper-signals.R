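# Shared fixtures: small, fast synthetic signals (8-16 kHz keeps FFTs tiny
# while leaving all harmonics and the 3 kHz entropy band below Nyquist).

quiet_profile <- function(name = "modal", f0 = 220, jitter = 0, shimmer = 0,
                          snr = Inf) {
  voice_profile(name, f0_hz = f0, jitter_pct = jitter, shimmer_pct = shimmer,
                noise_snr_db = snr)
}

sine_record <- function(freq = 200, rate = 8000, dur = 2, amp = 1) {
  t <- (seq_len(round(dur * rate)) - 1) / rate
  waveform_record(amp * sin(2 * pi * freq * t), rate)
}

# Direct-formula oracles for the relative perturbation measures, kept
# deliberately separate from the package's implementations.
oracle_jitter <- function(periods)
  mean(abs(diff(periods))) / mean(periods)
oracle_shimmer <- function(amps)
  mean(abs(diff(amps))) / mean(amps)

# Long-hand Fleiss kappa from an item-by-category count matrix.
oracle_fleiss <- function(counts) {
  n <- rowSums(counts)[1]
  P_i <- rowSums(counts * (counts - 1)) / (n * (n - 1))
  q <- colSums(counts) / sum(counts)
  (mean(P_i) - sum(q^2)) / (1 - sum(q^2))
}
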