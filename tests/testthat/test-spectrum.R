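test_that("spectrum peaks at the tone frequency with <= 1 Hz resolution", {
  sp <- compute_spectrum(sine_record(freq = 200, rate = 8000, dur = 2))
  expect_lte(sp$resolution_hz, 1)
  expect_lt(abs(sp$freqs_hz[which.max(sp$magnitude)] - 200), 1)
  expect_equal(max(sp$magnitude), 1)
})

test_that("two-tone magnitudes scale linearly with component amplitudes", {
  rate <- 8000
  t <- (seq_len(2 * rate) - 1) / rate
  rec <- waveform_record(sin(2 * pi * 200 * t) + 0.5 * sin(2 * pi * 400 * t),
                         rate)
  sp <- compute_spectrum(rec)
  peak_near <- function(f) max(sp$magnitude[abs(sp$freqs_hz - f) < 20])
  expect_equal(peak_near(400) / peak_near(200), 0.5, tolerance = 0.02)
})

test_that("white-noise spectrum is flat after coarse smoothing", {
  set.seed(4)
  rec <- waveform_record(rnorm(16000 * 4), 16000)
  sp <- compute_spectrum(rec)
  sel <- sp$freqs_hz > 0 & sp$freqs_hz <= 3000
  # average the squared magnitudes in 50 Hz blocks: no block should carry
  # more than 3x the median block level
  blocks <- tapply(sp$magnitude[sel]^2, floor(sp$freqs_hz[sel] / 50),
                   mean)
  expect_lt(max(blocks) / median(blocks), 3)
})

test_that("spectrum rejects empty and too-short segments", {
  expect_error(compute_spectrum(waveform_record(numeric(100), 8000)),
               "shorter|zero")
  expect_error(compute_spectrum(sine_record(dur = 0.2)), "shorter")
  expect_error(compute_spectrum(waveform_record(numeric(8000), 8000)),
               "zero")
})

test_that("equal harmonic amplitudes give symmetric quotients of 0.2", {
  rate <- 8000
  t <- (seq_len(2 * rate) - 1) / rate
  x <- rowSums(sapply(1:5, function(i) cos(2 * pi * i * 200 * t)))
  H <- harmonic_quotients(compute_spectrum(waveform_record(x, rate)), 200)
  expect_equal(unname(H), rep(0.2, 4), tolerance = 0.005,
               ignore_attr = TRUE)
})

test_that("quotients follow the harmonic amplitude ratios", {
  # direct arithmetic on A = (6,2,1,0.6,0.4): H = A / sum(A)
  rate <- 16000
  t <- (seq_len(2 * rate) - 1) / rate
  w <- c(6, 2, 1, 0.6, 0.4)
  x <- as.numeric(sapply(1:5, function(i) w[i] * cos(2 * pi * i * 220 * t)) %*%
                    rep(1, 5))
  H <- harmonic_quotients(compute_spectrum(waveform_record(x, rate)), 220)
  expect_equal(unname(H), c(0.6, 0.2, 0.1, 0.06), tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("the five quotients always sum to one", {
  sp <- compute_spectrum(synthesize_waveform(quiet_profile("pressed",
                                                           snr = 15),
                                             1, 16000, 0, seed = 71))
  H <- harmonic_quotients(sp, 220)
  A <- attr(H, "amplitudes")
  expect_equal(sum(A / sum(A)), 1, tolerance = 1e-12)
  H5 <- 1 - sum(H)
  expect_gte(H5, 0)
  expect_lte(H5, 1)
})

test_that("harmonics above the band limit contribute zero amplitude", {
  sp <- compute_spectrum(sine_record(freq = 390, rate = 8000, dur = 1))
  H <- harmonic_quotients(sp, 390)      # harmonics 4 and 5 exceed 1500 Hz
  A <- attr(H, "amplitudes")
  expect_equal(A[4:5], c(0, 0))
})

test_that("entropy identities: point mass, uniform, tone vs noise", {
  sp1 <- structure(list(freqs_hz = 0:99, magnitude = c(1, numeric(99)),
                        resolution_hz = 1), class = "spectrum_view")
  expect_equal(spectral_entropy(sp1, band_hz = c(0, 99)), 0)
  spu <- structure(list(freqs_hz = 0:63, magnitude = rep(0.5, 64),
                        resolution_hz = 1), class = "spectrum_view")
  expect_equal(spectral_entropy(spu, band_hz = c(0, 63)), log(64),
               tolerance = 1e-12)
  expect_equal(spectral_entropy(spu, band_hz = c(0, 63), base = 2), 6,
               tolerance = 1e-12)
  set.seed(9)
  se_tone <- spectral_entropy(compute_spectrum(sine_record(dur = 2)))
  se_noise <- spectral_entropy(compute_spectrum(
    waveform_record(rnorm(16000), 8000)))
  expect_lt(se_tone, se_noise)
})

test_that("entropy is invariant under uniform amplitude scaling", {
  rec <- synthesize_waveform(quiet_profile(snr = 18), 1, 16000, 0, seed = 81)
  rec5 <- waveform_record(5 * rec$samples, rec$rate_hz)
  expect_equal(spectral_entropy(compute_spectrum(rec)),
               spectral_entropy(compute_spectrum(rec5)), tolerance = 1e-10)
})
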