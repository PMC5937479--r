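test_that("identical configuration and seed give bit-identical recordings", {
  spec <- default_call_classes()$croak_low
  sc <- scene_config(seed = 42, recording_duration = 2)
  r1 <- generate_recording(spec, sc)
  r2 <- generate_recording(spec, sc)
  expect_identical(r1$clip$samples, r2$clip$samples)
  expect_identical(r1$roi_spans, r2$roi_spans)
  # byte-identical WAV output
  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(r1$clip$samples, sc$sample_rate, p1)
  write_wav(r2$clip$samples, sc$sample_rate, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  r3 <- generate_recording(spec, scene_config(seed = 43, recording_duration = 2))
  expect_false(identical(r1$clip$samples, r3$clip$samples))
})

test_that("the achieved in-ROI SNR matches the request within 1 dB", {
  spec <- default_call_classes()$whistle_low
  for (snr in c(0, 10, 20)) {
    rec <- generate_recording(spec, scene_config(seed = 5, snr_db = snr,
                                                 recording_duration = 3))
    expect_lt(abs(rec$snr_db - snr), 1)
  }
})

test_that("at high SNR, in-ROI frame power dominates out-of-ROI power", {
  spec <- default_call_classes()$croak_low
  rec <- generate_recording(spec, scene_config(seed = 6, snr_db = 60,
                                               recording_duration = 3))
  ff <- extract_features(frame_signal(rec$clip))
  lab <- frame_labels_from_rois(rec$roi_spans, nrow(ff$X), ff$frame_s,
                                spec$name)
  expect_gt(median(ff$X[lab != "silence", "total_power"]),
            max(ff$X[lab == "silence", "total_power"]))
})

test_that("ROI bookkeeping: spans lie inside the recording and mark all calls", {
  spec <- default_call_classes()$whistle_high
  sc <- scene_config(seed = 7, recording_duration = 4)
  rec <- generate_recording(spec, sc)
  expect_true(all(rec$roi_spans$start_s >= 0))
  expect_true(all(rec$roi_spans$end_s <= sc$recording_duration))
  expect_true(all(rec$roi_spans$end_s > rec$roi_spans$start_s))
  expect_gte(nrow(rec$roi_spans), spec$calls_range[1])
  expect_lte(nrow(rec$roi_spans), spec$calls_range[2])
  # complement contains only noise: rerun with snr +inf-ish and compare
  quiet <- generate_recording(spec, scene_config(seed = 7, snr_db = 80,
                                                 recording_duration = 4))
  n <- length(quiet$clip$samples)
  in_roi <- rep(FALSE, n)
  for (i in seq_len(nrow(quiet$roi_spans))) {
    a <- max(1, floor(quiet$roi_spans$start_s[i] * 22050) + 1)
    b <- min(n, ceiling(quiet$roi_spans$end_s[i] * 22050))
    in_roi[a:b] <- TRUE
  }
  expect_lt(sqrt(mean(quiet$clip$samples[!in_roi]^2)),
            0.01 * sqrt(mean(quiet$clip$samples[in_roi]^2)))
})

test_that("frame labels follow the >= 50% overlap rule", {
  rois <- data.frame(start_s = 0.105, end_s = 0.205)
  lab <- frame_labels_from_rois(rois, 30, 0.01, "callX")
  # frame 11 covers [0.100, 0.110): exactly half inside -> labelled
  expect_equal(lab[11], "callX")
  expect_equal(lab[10], "silence")
  expect_equal(lab[20], "callX")     # [0.19, 0.20) fully inside
  expect_equal(lab[21], "callX")     # [0.20, 0.21): exactly half inside
  expect_equal(lab[22], "silence")
  expect_equal(sum(lab == "callX"), 11)
})

test_that("datasets have the right manifest structure and pattern flags", {
  dir <- withr::local_tempdir()
  specs <- default_call_classes()
  sc <- scene_config(seed = 9, recording_duration = 1.5)
  ds <- generate_dataset(specs, sc, n_per_class = 3, pattern_fraction = 0.1,
                         dir = dir)
  expect_equal(nrow(ds$manifest), 12)
  expect_equal(length(unique(ds$manifest$class)), 4)
  expect_equal(sum(ds$manifest$is_pattern), 4)   # ceiling(0.1 * 3) = 1 per class
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "rois.csv")))
  expect_true(all(file.exists(file.path(dir, ds$manifest$file))))
  # reload round-trip
  back <- load_dataset(dir)
  expect_equal(back$manifest$class, ds$manifest$class)
  expect_equal(length(back$recordings), 12)
  expect_error(generate_dataset(specs[1], sc, 3), ">= 2 classes")
})

test_that("pattern recordings are ~20 dB cleaner than the rest", {
  specs <- default_call_classes()[c("croak_low", "whistle_low")]
  sc <- scene_config(seed = 10, snr_db = 15, recording_duration = 2)
  ds <- generate_dataset(specs, sc, n_per_class = 4, pattern_fraction = 0.25)
  snrs <- vapply(ds$recordings, function(r) r$snr_db, numeric(1))
  pat <- ds$manifest$is_pattern
  expect_lt(abs(mean(snrs[pat]) - mean(snrs[!pat]) - 20), 1)
  expect_lt(abs(mean(snrs[!pat]) - 15), 0.5)
})

test_that("configuration errors are caught early", {
  expect_error(scene_config(sample_rate = 4000), "8000")
  expect_error(scene_config(recording_duration = 0), "duration")
  expect_error(scene_config(snr_db = Inf), "finite")
  expect_error(call_class_spec("x", "pulsatile", pulse_rate = 0), "pulse_rate")
  spec <- call_class_spec("x", "tonal", carrier_freq = 15000)
  expect_error(generate_recording(spec, scene_config(seed = 1)), "Nyquist")
})
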