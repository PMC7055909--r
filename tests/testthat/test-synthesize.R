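test_that("perfectly periodic profile realizes zero jitter and shimmer", {
  rec <- synthesize_waveform(quiet_profile(), duration_s = 1, rate_hz = 16000,
                             silence_s = 0.2, seed = 1)
  tr <- rec$truth
  expect_equal(oracle_jitter(tr$periods_s), 0)
  expect_equal(oracle_shimmer(tr$amplitudes), 0)
  expect_equal(length(tr$periods_s), round(1 * 220))
})

test_that("stored truth cycles realize the requested perturbations exactly", {
  grid <- expand.grid(jit = c(0.5, 1, 2), shim = c(2, 5, 10))
  for (i in seq_len(nrow(grid))) {
    rec <- synthesize_waveform(
      quiet_profile(jitter = grid$jit[i], shimmer = grid$shim[i]),
      duration_s = 2, rate_hz = 16000, silence_s = 0, seed = 100 + i)
    tr <- rec$truth
    expect_equal(100 * oracle_jitter(tr$periods_s), grid$jit[i],
                 tolerance = 1e-9)
    expect_equal(100 * oracle_shimmer(tr$amplitudes), grid$shim[i],
                 tolerance = 1e-9)
  }
})

test_that("truth cycle boundaries are strictly increasing and in bounds", {
  rec <- synthesize_waveform(quiet_profile(jitter = 2, shimmer = 5, snr = 20),
                             duration_s = 1, rate_hz = 16000,
                             silence_s = 0.25, seed = 3)
  ci <- rec$truth$cycle_start_idx
  expect_true(all(diff(ci) > 0))
  expect_true(ci[1] >= 1 && ci[length(ci)] <= length(rec$samples))
  expect_equal(rec$duration_s, length(rec$samples) / rec$rate_hz)
})

test_that("generation is reproducible under a seed and varies without one", {
  a <- synthesize_waveform(quiet_profile(snr = 20), 1, 8000, 0.1, seed = 7)
  b <- synthesize_waveform(quiet_profile(snr = 20), 1, 8000, 0.1, seed = 7)
  c <- synthesize_waveform(quiet_profile(snr = 20), 1, 8000, 0.1, seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("generator rejects aliasing and degenerate requests", {
  expect_error(synthesize_waveform(quiet_profile(f0 = 900), 1, 8000),
               "alias")
  expect_error(synthesize_waveform(quiet_profile(), 0.2, 8000), "duration")
  expect_error(voice_profile("modal", harmonic_weights = rep(0, 5)),
               "not all zero")
  expect_error(voice_profile("modal", jitter_pct = -1), ">= 0")
})

test_that("silence padding is near-silent but dithered", {
  rec <- synthesize_waveform(quiet_profile(), 1, 8000, silence_s = 0.3,
                             seed = 5)
  sil <- rec$samples[1:2000]
  voiced <- rec$samples[rec$truth$voiced_range_idx[1]:rec$truth$voiced_range_idx[2]]
  expect_gt(max(abs(sil)), 0)                       # dither present
  expect_lt(sqrt(mean(sil^2)), 1e-3 * max(abs(voiced)))
})

test_that("spectral entropy increases with broadband noise power", {
  se <- vapply(c(Inf, 25, 15, 8), function(snr) {
    rec <- synthesize_waveform(quiet_profile(snr = snr), 2, 16000,
                               silence_s = 0, seed = 11)
    spectral_entropy(compute_spectrum(rec))
  }, 0)
  expect_true(all(diff(se) > 0))
})

test_that("noiseless harmonic quotients match normalized weights within 0.02", {
  for (cl in c("modal", "breathy", "pressed")) {
    prof <- quiet_profile(cl)
    rec <- synthesize_waveform(prof, 2, 16000, silence_s = 0, seed = 21)
    H <- harmonic_quotients(compute_spectrum(rec), prof$f0_hz)
    target <- prof$harmonic_weights / sum(prof$harmonic_weights)
    expect_lt(max(abs(H - target[1:4])), 0.02)
  }
})
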