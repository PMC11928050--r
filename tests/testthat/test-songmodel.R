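test_that("gap rules partition syllables into chirps with one inter-chirp interval", {
  ev <- events_from_gaps(c(15, 15, 15, 300, 15, 15, 15))
  ch <- group_chirps(ev)
  expect_identical(nrow(ch), 2L)
  expect_identical(ch$n_syllables, c(4L, 4L))
  expect_equal(ch$following_inter_chirp_interval_ms, c(300, NA_real_),
               tolerance = 0.1)
  expect_length(ch$inter_syllable_intervals_ms[[1]], 3)
  expect_equal(ch$inter_syllable_intervals_ms[[1]], rep(15, 3),
               tolerance = 0.1)
})

test_that("a single syllable forms a one-syllable chirp with no intervals", {
  ev <- make_events(0.5, 18)
  ch <- group_chirps(ev)
  expect_identical(nrow(ch), 1L)
  expect_identical(ch$n_syllables, 1L)
  expect_true(is.na(ch$following_inter_chirp_interval_ms))
  expect_length(ch$inter_syllable_intervals_ms[[1]], 0)
  expect_identical(nrow(group_chirps(make_events(numeric(), numeric()))), 0L)
})

test_that("gaps beyond the pause bound terminate the chirp but are not intervals", {
  ev <- events_from_gaps(c(15, 2500, 15))
  ch <- group_chirps(ev)
  expect_identical(nrow(ch), 2L)
  expect_true(is.na(ch$following_inter_chirp_interval_ms[1]))
})

test_that("every syllable belongs to exactly one chirp and durations are additive", {
  syn <- synthesize_song(song_spec(n_chirps = 80, noise_rms = 0.005, seed = 31))
  syl <- detect_syllables(syn$recording)
  ch <- group_chirps(syl)
  expect_identical(sum(ch$n_syllables), nrow(syl))
  recon <- vapply(seq_len(nrow(ch)), function(i) {
    sum(ch$syllable_durations_ms[[i]]) +
      sum(ch$inter_syllable_intervals_ms[[i]])
  }, numeric(1))
  expect_equal(recon, ch$duration_ms, tolerance = 1e-9)
})

test_that("syllable-count tabulation covers all observed classes with proportions summing to 1", {
  ch <- group_chirps(events_from_gaps(
    c(15, 15, 300, 15, 15, 300, 15, 15, 300, 15, 15, 15)))
  # three 3-syllable chirps and one 4-syllable chirp
  d <- syllable_count_distribution(ch)
  expect_identical(d$n[d$n_syllables == 3], 3L)
  expect_identical(d$n[d$n_syllables == 4], 1L)
  expect_equal(d$proportion[d$n_syllables == 3], 0.75)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-9)
  expect_identical(nrow(syllable_count_distribution(ch[0, ])), 0L)
})

test_that("mixture proportions are recovered within binomial sampling error", {
  probs <- c("2" = 0.0139, "3" = 0.2354, "4" = 0.7507)
  spec <- song_spec(syllable_count_probs = probs, n_chirps = 5000, seed = 41)
  syn <- synthesize_song(spec, audio = FALSE)
  d <- syllable_count_distribution(
    data.frame(n_syllables = syn$truth$chirps$n_syllables))
  for (k in names(probs)) {
    p <- probs[[k]]
    se <- sqrt(p * (1 - p) / 5000)
    expect_lt(abs(d$proportion[d$n_syllables == as.integer(k)] - p), 3 * se)
  }
})

test_that("transition intervals pick exactly the from->to adjacencies", {
  ev <- events_from_gaps(c(15, 15, 250, 15, 15, 15, 300, 15, 15, 350, 15, 15, 15))
  ch <- group_chirps(ev)        # counts 3,4,3,4 with intervals 250,300,350
  expect_identical(ch$n_syllables, c(3L, 4L, 3L, 4L))
  got <- transition_intervals(ch, 3, 4)
  expect_equal(got, c(250, 350), tolerance = 0.1)
  expect_length(transition_intervals(ch, 4, 5), 0)
  expect_length(transition_intervals(ch[ch$n_syllables == 3, , drop = FALSE],
                                     3, 4), 0)
})

test_that("dominant frequency finds the spectral peak within one bin", {
  fs <- 44100
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  bin <- fs / 8192
  pure <- audio_recording(sin(2 * pi * 4900 * t), fs)
  expect_lte(abs(dominant_frequency(pure) - 4900), bin)
  mix <- audio_recording(sin(2 * pi * 4900 * t) + 0.2 * sin(2 * pi * 2000 * t), fs)
  expect_lte(abs(dominant_frequency(mix) - 4900), bin)
  expect_true(is.na(dominant_frequency(audio_recording(numeric(1000), fs))))
})

test_that("dominant frequency of a full synthetic song sits at the carrier", {
  syn <- synthesize_song(song_spec(n_chirps = 40, noise_rms = 0.01, seed = 43))
  f <- dominant_frequency(syn$recording)
  expect_lte(abs(f - 4900), 3 * 44100 / 8192)
})

test_that("recording summary aggregates chirp-level features correctly", {
  ev <- events_from_gaps(c(16, 16, 16, 300, 16, 16, 16), dur_ms = 18)
  ch <- group_chirps(ev)
  s <- summarize_recording(NULL, ch, source_id = "toy")
  expect_identical(s$n_chirps, 2L)
  expect_identical(s$n_syllables, 8L)
  # both chirps are 4x18 + 3x16 = 120 ms
  expect_equal(s$mean_chirp_duration_ms, 120, tolerance = 0.1)
  expect_equal(s$mean_inter_chirp_interval_ms, 300, tolerance = 0.1)
  expect_equal(s$prop_4syl, 1)
  expect_equal(s$prop_1syl + s$prop_2syl + s$prop_3syl + s$prop_4syl +
                 s$prop_5syl + s$prop_other, 1, tolerance = 1e-9)
  # two chirps of durations 80 and 100 ms average to 90
  toy <- group_chirps(make_events(c(0, 1), c(80, 100)))
  expect_equal(summarize_recording(NULL, toy)$mean_chirp_duration_ms, 90)
})

test_that("4-syllable generator songs average 120 ms chirps end to end", {
  spec <- song_spec(syllable_ms = c(18, 1), inter_syllable_ms = c(16, 1),
                    syllable_count_probs = c("4" = 1), n_chirps = 100,
                    noise_rms = 0.005, seed = 47)
  syn <- synthesize_song(spec)
  syl <- detect_syllables(syn$recording)
  s <- summarize_recording(syn$recording, group_chirps(syl))
  expect_lte(abs(s$mean_chirp_duration_ms - 120), 2)
  expect_lte(abs(s$mean_syllable_duration_ms - 18), 1)
  expect_lte(abs(s$mean_inter_syllable_interval_ms - 16), 1)
})

test_that("syllable-level means honor the chirp cap", {
  # first chirp 3-syllable with 10 ms ISIs, second 3-syllable with 30 ms ISIs
  ev <- events_from_gaps(c(10, 10, 300, 30, 30))
  ch <- group_chirps(ev)
  capped <- summarize_recording(NULL, ch, chirp_cap = 1)
  expect_equal(capped$mean_inter_syllable_interval_ms, 10, tolerance = 0.1)
  full <- summarize_recording(NULL, ch)
  expect_equal(full$mean_inter_syllable_interval_ms, 20, tolerance = 0.1)
})

test_that("zero chirps produce an empty but well-formed summary", {
  s <- summarize_recording(NULL, group_chirps(make_events(numeric(), numeric())),
                           source_id = "empty")
  expect_identical(s$n_chirps, 0L)
  expect_true(is.na(s$mean_chirp_duration_ms))
  expect_equal(s$prop_3syl, 0)
})

test_that("inclusion filter uses strict inequalities and matches direct evaluation", {
  expect_true(inclusion_filter(5, 25000))
  expect_false(inclusion_filter(4, 25000))
  expect_false(inclusion_filter(5, 20000))
  set.seed(53)
  days <- sample(0:10, 200, replace = TRUE)
  chirps <- sample(c(0, 19999, 20000, 20001, 50000), 200, replace = TRUE)
  expect_identical(inclusion_filter(days, chirps),
                   days > 4 & chirps > 20000)
})
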