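test_that("digital silence hits the documented feature conventions", {
  f <- spectral_features(numeric(220), 22050)
  expect_equal(unname(f["total_power"]), -120)
  expect_equal(unname(f["relevant_power"]), -120)
  expect_equal(unname(f["power_centroid"]), 0)
  expect_equal(unname(f["spectral_dispersion"]), 0)
  expect_equal(unname(f["spectrum_flatness"]), 1)
  expect_equal(unname(lpc_formants(numeric(220), 22050)), rep(0, 6))
})

test_that("a pure 1 kHz tone centres the spectrum and is far from flat", {
  fs <- frame_signal(tone_clip(1000))
  x <- extract_features(fs)$X
  df_bin <- 22050 / 256                      # spectrum FFT bin width
  expect_lt(abs(median(x[, "power_centroid"]) - 1000), df_bin)
  expect_lt(median(x[, "spectrum_flatness"]), 0.1)
})

test_that("white-noise flatness matches a numerically computed oracle", {
  # oracle: long-run per-frame flatness of a flat spectrum under the same
  # Hamming window, computed by direct DFT on seeded noise
  set.seed(99)
  l <- 220; w <- 0.54 - 0.46 * cos(2 * pi * (0:(l - 1)) / (l - 1))
  oracle <- mean(replicate(100, {
    fr <- rnorm(l); fr <- (fr - mean(fr)) * w
    p <- (Mod(fft(c(fr, numeric(512 - l))))^2)[2:257]
    exp(mean(log(p))) / mean(p)
  }))
  fn <- extract_features(frame_signal(noise_clip(duration = 1, seed = 7)))$X
  expect_lt(abs(mean(fn[, "spectrum_flatness"]) - oracle), 0.05)
  expect_gt(mean(fn[, "spectrum_flatness"]), 0.4)
})

test_that("LPC recovers the pole of a 2-pole resonator within 5%", {
  sr <- 22050; bw <- 100; f0 <- 1500
  r <- exp(-pi * bw / sr)
  set.seed(2)
  y <- as.numeric(stats::filter(rnorm(2 * sr),
                                c(2 * r * cos(2 * pi * f0 / sr), -r^2),
                                method = "recursive"))
  x <- extract_features(frame_signal(audio_clip(y / max(abs(y)), sr)))$X
  f1 <- x[, "formant_freq_1"]
  expect_lt(abs(mean(f1[f1 > 0][1:100]) - f0) / f0, 0.05)
})

test_that("LPC order 2 yields at most one formant", {
  sr <- 22050; r <- exp(-pi * 100 / sr)
  set.seed(3)
  y <- as.numeric(stats::filter(rnorm(sr),
                                c(2 * r * cos(2 * pi * 1500 / sr), -r^2),
                                method = "recursive"))
  f <- lpc_formants(y[1001:1220], sr, lpc_order = 2)
  expect_equal(unname(f[c("formant_freq_2", "formant_freq_3")]), c(0, 0))
  expect_equal(unname(f[c("formant_bw_2", "formant_bw_3")]), c(0, 0))
})

test_that("pitch and harmonicity are accurate on a 440 Hz tone", {
  x <- extract_features(frame_signal(tone_clip(440)))$X
  expect_lt(abs(median(x[, "pitch"]) - 440) / 440, 0.01)
  expect_gt(median(x[, "harmonicity_ratio"]), 0.95)
})

test_that("white noise is mostly unvoiced with low harmonicity", {
  x <- extract_features(frame_signal(noise_clip(duration = 1, seed = 11)))$X
  expect_lt(median(x[, "harmonicity_ratio"]), 0.5)
})

test_that("the first frame reports zero harmonic spectral variation", {
  x <- extract_features(frame_signal(tone_clip(440, duration = 0.1)))$X
  expect_equal(unname(x[1, "harmonic_spectral_variation"]), 0)
  h <- harmonic_features(sin(2 * pi * 440 * (0:219) / 22050), 22050)
  expect_equal(unname(h["harmonic_spectral_variation"]), 0)
})

test_that("the feature matrix has S rows and the canonical 18 columns", {
  ff <- extract_features(frame_signal(tone_clip(duration = 1)))
  expect_equal(dim(ff$X), c(100, 18))
  expect_identical(colnames(ff$X), mpeg7_feature_names())
  expect_false(anyNA(ff$X))
  expect_true(all(is.finite(ff$X)))
})

test_that("doubling the amplitude shifts powers by +6.02 dB and nothing else", {
  clip <- tone_clip(1000, duration = 0.3)
  x1 <- extract_features(frame_signal(clip))$X
  clip2 <- audio_clip(2 * clip$samples, clip$sample_rate)
  x2 <- extract_features(frame_signal(clip2))$X
  expect_equal(x2[, "total_power"] - x1[, "total_power"],
               rep(20 * log10(2), nrow(x1)), tolerance = 1e-6)
  expect_equal(x2[, "relevant_power"] - x1[, "relevant_power"],
               rep(20 * log10(2), nrow(x1)), tolerance = 1e-6)
  invariant <- c("power_centroid", "spectral_dispersion", "spectrum_flatness",
                 "formant_freq_1", "pitch", "harmonicity_ratio")
  for (col in invariant)
    expect_equal(x2[, col], x1[, col], tolerance = 1e-6, label = col)
})

test_that("stationary-tone feature medians survive a half-frame shift", {
  sr <- 22050
  x <- sin(2 * pi * 500 * (0:(sr - 1)) / sr)
  shifted <- c(x[-(1:110)], x[1:110])
  m1 <- apply(extract_features(frame_signal(audio_clip(x, sr)))$X, 2, median)
  m2 <- apply(extract_features(frame_signal(audio_clip(shifted, sr)))$X, 2, median)
  for (col in c("total_power", "power_centroid", "pitch"))
    expect_lt(abs(m2[col] - m1[col]) / max(abs(m1[col]), 1), 0.01)
})

test_that("all Hz-valued features respect the Nyquist bound", {
  for (clip in list(tone_clip(3000, duration = 0.3),
                    noise_clip(duration = 0.3, seed = 5))) {
    x <- extract_features(frame_signal(clip))$X
    hz_cols <- c("power_centroid", "spectral_dispersion", "formant_freq_1",
                 "formant_freq_2", "formant_freq_3", "pitch",
                 "harmonic_centroid", "upper_limit_of_harmonicity")
    for (col in hz_cols) {
      expect_true(all(x[, col] >= 0), label = col)
      expect_true(all(x[, col] <= clip$sample_rate / 2), label = col)
    }
    expect_true(all(x[, "spectrum_flatness"] >= 0 & x[, "spectrum_flatness"] <= 1))
    expect_true(all(x[, "harmonicity_ratio"] >= 0 & x[, "harmonicity_ratio"] <= 1))
  }
})
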