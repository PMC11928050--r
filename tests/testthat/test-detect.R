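test_that("detection_config enforces its invariants", {
  expect_s3_class(detection_config(), "detection_config")
  expect_error(detection_config(low_threshold = 0.2, high_threshold = 0.1))
  expect_error(detection_config(min_syllable_ms = 60, max_syllable_ms = 5))
  expect_error(detection_config(max_intra_chirp_gap_ms = 100,
                                min_inter_chirp_gap_ms = 40))
})

test_that("envelope of silence is zero and has ceil(n/hop) frames", {
  rec <- audio_recording(numeric(10000), 44100)
  env <- compute_envelope(rec)
  expect_true(all(env$values == 0))
  expect_length(env$values, ceiling(10000 / env$hop_length))
  # frame longer than the recording collapses gracefully
  short <- audio_recording(rep(0.5, 20), 44100)
  env2 <- compute_envelope(short, frame_ms = 10)
  expect_true(all(env2$values > 0))
})

test_that("envelope of a full-scale sine stays near 1 when frames cover a period", {
  fs <- 44100
  # fs/4 puts samples exactly on the carrier peaks, so the frame-max is 1
  x <- sin(2 * pi * (fs / 4) * seq(0, 1, by = 1 / fs))
  env <- compute_envelope(audio_recording(x, fs), frame_ms = 2)
  expect_true(all(env$values >= 0.99 & env$values <= 1))
  # for a sampled 4900 Hz carrier the frame-max is bounded by the phase grid
  x2 <- sin(2 * pi * 4900 * seq(0, 1, by = 1 / fs))
  env2 <- compute_envelope(audio_recording(x2, fs), frame_ms = 2)
  expect_true(all(env2$values >= cos(pi * 4900 / fs) & env2$values <= 1))
})

test_that("envelope is nonzero exactly in frames overlapping a burst", {
  b <- make_burst_recording(total_s = 1, onset_s = 0.4, burst_ms = 20)
  env <- compute_envelope(b$rec)
  frame_start <- (seq_along(env$values) - 1) * env$hop_length
  frame_end <- frame_start + env$frame_length
  nz <- env$values > 0
  expect_true(all(frame_end[nz] > b$onset_sample))
  expect_true(all(frame_start[nz] < b$offset_sample))
  # and every frame fully inside the burst is nonzero
  inside <- frame_start >= b$onset_sample + env$frame_length &
    frame_end <= b$offset_sample - env$frame_length
  expect_true(all(env$values[inside] > 0))
})

test_that("double thresholding finds one candidate per burst and ignores sub-threshold bursts", {
  cfg <- detection_config()
  silent <- compute_envelope(audio_recording(numeric(44100), 44100))
  expect_identical(nrow(detect_events(silent, cfg)), 0L)

  set.seed(21)
  b <- make_burst_recording(amp = 0.5, noise_sd = 0.001)
  cand <- detect_events(compute_envelope(b$rec), cfg)
  expect_identical(nrow(cand), 1L)
  expect_lte(cand$onset_sample, b$onset_sample)
  expect_gte(cand$offset_sample, b$offset_sample - 1L)

  weak <- make_burst_recording(amp = 0.09)
  expect_identical(nrow(detect_events(compute_envelope(weak$rec),
                                      detection_config())), 0L)
})

test_that("boundary refinement recovers a gated-sine onset to within one sample", {
  # carrier chosen incommensurate with the sample grid so the gate edge is
  # the only sample-exact zero near the onset
  b <- make_burst_recording(onset_s = 0.1, burst_ms = 20, carrier_hz = 4897)
  cfg <- detection_config()
  cand <- detect_events(compute_envelope(b$rec), cfg)
  ev <- refine_boundaries(b$rec, cand, cfg)
  expect_identical(nrow(ev), 1L)
  expect_lte(abs(ev$onset_sample - b$onset_sample), 1L)
  # offset lands within the 1 ms fall ramp of the true gate end
  expect_lte(abs(ev$offset_sample - b$offset_sample), 45L)
})

test_that("refinement is idempotent and leaves degenerate candidates unchanged", {
  b <- make_burst_recording()
  cfg <- detection_config()
  cand <- detect_events(compute_envelope(b$rec), cfg)
  ev1 <- refine_boundaries(b$rec, cand, cfg)
  ev2 <- refine_boundaries(b$rec, ev1[, c("onset_sample", "offset_sample")], cfg)
  expect_identical(ev1$onset_sample, ev2$onset_sample)
  expect_identical(ev1$offset_sample, ev2$offset_sample)

  # a candidate over pure silence has no supra-threshold anchor
  silent_cand <- data.frame(onset_sample = 100L, offset_sample = 500L)
  out <- refine_boundaries(audio_recording(numeric(1000), 44100),
                           silent_cand, cfg)
  expect_identical(out$onset_sample, 100L)
  expect_identical(out$offset_sample, 500L)
})

test_that("duration filtering keeps only events inside the syllable window", {
  cfg <- detection_config()   # 5-60 ms
  ev <- make_events(c(0.1, 0.2, 0.4), c(2, 15, 80))
  kept <- filter_syllables(ev, cfg)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$duration_ms, 15)
  expect_identical(attr(kept, "n_discarded"), 2L)

  all_ok <- make_events(c(0.1, 0.2), c(10, 20))
  expect_identical(nrow(filter_syllables(all_ok, cfg)), 2L)
})

test_that("clicks are rejected while true syllables all survive", {
  set.seed(5)
  syn <- synthesize_song(song_spec(n_chirps = 60, noise_rms = 0, seed = 5))
  x <- syn$recording$samples
  fs <- syn$recording$sample_rate
  # inject 1 ms clicks into silent gaps between chirps
  ch <- syn$truth$chirps
  for (k in seq_len(nrow(ch) - 1)) {
    at <- round((ch$offset_s[k] + 0.1) * fs)
    x[at + seq_len(round(0.001 * fs))] <-
      0.9 * sin(2 * pi * 4900 / fs * (seq_len(round(0.001 * fs)) - 1))
  }
  rec <- audio_recording(x, fs)
  syl <- detect_syllables(rec)
  expect_identical(nrow(syl), nrow(syn$truth$syllables))
  expect_gt(attr(syl, "n_discarded"), 0L)
})

test_that("detection output is sorted, non-overlapping, within duration bounds", {
  syn <- synthesize_song(song_spec(n_chirps = 40, noise_rms = 0.01, seed = 9))
  cfg <- detection_config()
  syl <- detect_syllables(syn$recording, cfg)
  expect_false(is.unsorted(syl$onset_s))
  expect_true(all(syl$onset_sample[-1] >= syl$offset_sample[-nrow(syl)]))
  expect_true(all(syl$duration_ms >= cfg$min_syllable_ms &
                    syl$duration_ms <= cfg$max_syllable_ms))
})

test_that("raising the high threshold never increases the number of events", {
  syn <- synthesize_song(song_spec(n_chirps = 30, noise_rms = 0.01,
                                   amplitude_jitter = 0.5, seed = 13))
  rec <- normalize_audio(syn$recording)
  env <- compute_envelope(rec)
  n_prev <- Inf
  for (hi in c(0.08, 0.1, 0.2, 0.4, 0.6, 0.8)) {
    cfg <- detection_config(high_threshold = hi)
    n <- nrow(detect_events(env, cfg))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("detection is invariant to input gain", {
  syn <- synthesize_song(song_spec(n_chirps = 20, noise_rms = 0.005, seed = 3))
  base <- detect_syllables(syn$recording)
  for (g in c(1e-3, 0.25, 1)) {
    scaled <- audio_recording(g * syn$recording$samples,
                              syn$recording$sample_rate)
    out <- detect_syllables(scaled)
    expect_identical(out$onset_sample, base$onset_sample)
    expect_identical(out$offset_sample, base$offset_sample)
  }
})

test_that("clean synthetic songs are recovered exactly with sub-ms boundaries", {
  syn <- synthesize_song(song_spec(n_chirps = 50, noise_rms = 0.001, seed = 17))
  syl <- detect_syllables(syn$recording)
  ev <- evaluate_detection(syn$truth, syl, group_chirps(syl))
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_lte(ev$max_boundary_error_ms, 1)
  expect_true(ev$counts_correct)
})

test_that("the Hilbert envelope variant also detects every syllable", {
  syn <- synthesize_song(song_spec(n_chirps = 20, noise_rms = 0, seed = 23))
  cfg <- detection_config(envelope = "hilbert")
  syl <- detect_syllables(syn$recording, cfg)
  expect_identical(nrow(syl), nrow(syn$truth$syllables))
})
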