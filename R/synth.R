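norm_param <- function(x, what) {
  if (length(x) == 1L) x <- c(x, 0)
  stopifnot(length(x) == 2L, x[2L] >= 0)
  names(x) <- c("mean", "sd")
  if (x[1L] <= 0) stop(what, " mean must be positive")
  x
}

#' Specification of a synthetic calling song
#'
#' Generative parameters of a synthetic stridulation bout: tone-burst
#' syllables (a sine carrier gated by raised-cosine edges) grouped into
#' chirps, with Gaussian-jittered timing, per-syllable amplitude jitter and
#' additive white noise. The seed fully determines the output.
#'
#' Timing parameters are given as `c(mean, sd)` in milliseconds (a scalar
#' means sd = 0). Draws are truncated: syllable durations below
#' `2 * edge_ms + 1` ms and non-positive gaps are re-drawn.
#'
#' @param carrier_hz Carrier frequency in Hz (default 4900, within the
#'   species' typical band).
#' @param syllable_ms Syllable duration, `c(mean, sd)` ms. Default c(18, 1).
#' @param inter_syllable_ms Inter-syllable interval, `c(mean, sd)` ms.
#'   Default c(16, 1).
#' @param inter_chirp_ms Inter-chirp interval, `c(mean, sd)` ms. Default
#'   c(240, 20), giving chirp periods in the 300-400 ms range.
#' @param syllable_count_probs Named numeric vector mapping syllable count to
#'   probability (must sum to 1). Default `c("3" = 0.25, "4" = 0.75)`.
#' @param n_chirps Number of chirps to generate. Default 100.
#' @param amplitude Peak syllable amplitude in (0, 1]. Default 1.
#' @param amplitude_jitter Per-syllable amplitudes are drawn uniformly from
#'   `amplitude * [1 - jitter, 1]`. Default 0.3.
#' @param noise_rms RMS of additive white Gaussian noise, relative to the
#'   pre-normalization syllable amplitude. Default 0.
#' @param sample_rate Sample rate in Hz. Default 44100.
#' @param edge_ms Raised-cosine rise/fall time in ms (default 1), so syllable
#'   onsets and offsets sit at zero amplitude.
#' @param lead_ms Leading/trailing silence in ms. Default 50.
#' @param seed Integer RNG seed.
#' @return A list of class `song_spec`.
#' @export
song_spec <- function(carrier_hz = 4900,
                      syllable_ms = c(18, 1),
                      inter_syllable_ms = c(16, 1),
                      inter_chirp_ms = c(240, 20),
                      syllable_count_probs = c("3" = 0.25, "4" = 0.75),
                      n_chirps = 100,
                      amplitude = 1,
                      amplitude_jitter = 0.3,
                      noise_rms = 0,
                      sample_rate = 44100,
                      edge_ms = 1,
                      lead_ms = 50,
                      seed = 1) {
  stopifnot(carrier_hz > 0, carrier_hz < sample_rate / 2,
            n_chirps >= 1, amplitude > 0, amplitude <= 1,
            amplitude_jitter >= 0, amplitude_jitter < 1,
            noise_rms >= 0, sample_rate >= 8000, edge_ms > 0, lead_ms >= 0)
  if (is.null(names(syllable_count_probs)) ||
      any(is.na(as.integer(names(syllable_count_probs))))) {
    stop("syllable_count_probs must be named by syllable count")
  }
  if (abs(sum(syllable_count_probs) - 1) > 1e-9) {
    stop("syllable_count_probs must sum to 1")
  }
  structure(
    list(carrier_hz = carrier_hz,
         syllable_ms = norm_param(syllable_ms, "syllable duration"),
         inter_syllable_ms = norm_param(inter_syllable_ms,
                                        "inter-syllable interval"),
         inter_chirp_ms = norm_param(inter_chirp_ms, "inter-chirp interval"),
         syllable_count_probs = syllable_count_probs,
         n_chirps = as.integer(n_chirps),
         amplitude = amplitude, amplitude_jitter = amplitude_jitter,
         noise_rms = noise_rms, sample_rate = as.integer(sample_rate),
         edge_ms = edge_ms, lead_ms = lead_ms, seed = as.integer(seed)),
    class = "song_spec"
  )
}

#' @export
print.song_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<song_spec: %d chirps, carrier %g Hz @ %d Hz, syllable %g±%g ms,",
           " ISI %g±%g ms, ICI %g±%g ms, noise_rms %g, seed %d>\n"),
    x$n_chirps, x$carrier_hz, x$sample_rate,
    x$syllable_ms[1], x$syllable_ms[2],
    x$inter_syllable_ms[1], x$inter_syllable_ms[2],
    x$inter_chirp_ms[1], x$inter_chirp_ms[2], x$noise_rms, x$seed))
  cat("  syllable-count probs:",
      paste(names(x$syllable_count_probs), signif(x$syllable_count_probs, 4),
            sep = ":", collapse = " "), "\n")
  invisible(x)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric())
  if (sd == 0) {
    if (mean <= lower) stop("Degenerate timing draw below truncation bound")
    return(rep(mean, n))
  }
  v <- stats::rnorm(n, mean, sd)
  while (any(bad <- v <= lower)) v[bad] <- stats::rnorm(sum(bad), mean, sd)
  v
}

#' Parameter presets anchored to the two illumination treatments
#'
#' `"LD-like"` mimics songs of males reared under a 12 h:12 h light:dark
#' cycle: mean inter-syllable interval 16 ms and syllable-count mixture
#' 1% 2-, 24% 3-, 75% 4-syllable chirps. `"LL-like"` mimics constant-light
#' males: mean inter-syllable interval 11.71 ms and mixture 2% 2-, 47% 3-,
#' 51% 4-syllable chirps. Both share an 18 ms syllable, a 4900 Hz carrier and
#' a 240 +/- 20 ms inter-chirp interval (chirp periods of 300-400 ms); the
#' standard deviations are this package's own choices.
#'
#' @param name `"LD-like"` or `"LL-like"`.
#' @param ... Overrides passed to [song_spec()] (e.g. `n_chirps`, `seed`,
#'   `noise_rms`, `sample_rate`).
#' @return A [song_spec()].
#' @export
song_preset <- function(name, ...) {
  presets <- list(
    "LD-like" = list(
      inter_syllable_ms = c(16, 1),
      syllable_count_probs = c("2" = 0.01, "3" = 0.24, "4" = 0.75)
    ),
    "LL-like" = list(
      inter_syllable_ms = c(11.71, 1),
      syllable_count_probs = c("2" = 0.02, "3" = 0.47, "4" = 0.51)
    )
  )
  if (!name %in% names(presets)) {
    stop("Unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(
    c(presets[[name]], list(syllable_ms = c(18, 1), noise_rms = 0.005)),
    list(...)
  )
  do.call(song_spec, args)
}

draw_song_timing <- function(spec) {
  classes <- as.integer(names(spec$syllable_count_probs))
  counts <- classes[sample.int(length(classes), spec$n_chirps, replace = TRUE,
                               prob = spec$syllable_count_probs)]
  n_syl <- sum(counts)
  min_dur <- 2 * spec$edge_ms + 1
  dur_ms <- rnorm_trunc(n_syl, spec$syllable_ms[1L], spec$syllable_ms[2L],
                        min_dur)
  isi_ms <- rnorm_trunc(n_syl - spec$n_chirps, spec$inter_syllable_ms[1L],
                        spec$inter_syllable_ms[2L], 1)
  ici_ms <- rnorm_trunc(spec$n_chirps - 1L, spec$inter_chirp_ms[1L],
                        spec$inter_chirp_ms[2L], 1)

  chirp_of <- rep(seq_along(counts), counts)
  first_of_chirp <- !duplicated(chirp_of)
  gap_ms <- numeric(n_syl)
  gap_ms[first_of_chirp] <- c(spec$lead_ms, ici_ms)
  gap_ms[!first_of_chirp] <- isi_ms

  onset_ms <- cumsum(gap_ms + c(0, dur_ms[-n_syl]))
  fs <- spec$sample_rate
  onset_smp <- as.integer(round(onset_ms / 1000 * fs))
  dur_smp <- pmax(as.integer(round(dur_ms / 1000 * fs)), 3L)
  offset_smp <- onset_smp + dur_smp

  syllables <- data.frame(
    onset_s = onset_smp / fs, offset_s = offset_smp / fs,
    onset_sample = onset_smp, offset_sample = offset_smp,
    chirp_index = chirp_of
  )
  chirps <- data.frame(
    chirp_index = seq_along(counts),
    onset_s = syllables$onset_s[first_of_chirp],
    offset_s = syllables$offset_s[cumsum(counts)],
    n_syllables = counts
  )
  list(syllables = syllables, chirps = chirps)
}

#' Synthesize a calling song with ground truth
#'
#' Generates the waveform and exact event annotations for a [song_spec()].
#' Each syllable is a sine carrier (phase 0 at onset) gated by a window with
#' raised-cosine rise/fall edges, so the true onset and offset sit at zero
#' amplitude — matching the detector's boundary definition. White noise is
#' added afterwards and the waveform is peak-normalized; ground truth records
#' the pre-noise gate times (normalization is time-invariant). Output is
#' bit-reproducible for a fixed spec.
#'
#' @param spec A [song_spec()].
#' @param audio If `FALSE`, skip waveform rendering and return only ground
#'   truth (identical timing to the `audio = TRUE` call with the same spec).
#' @return A list of class `song_synthesis`: `recording` (an
#'   [audio_recording()], or `NULL` when `audio = FALSE`) and `truth` (list
#'   with data frames `syllables` — onset/offset seconds and samples plus
#'   `chirp_index` — and `chirps`, plus the `spec`).
#' @export
synthesize_song <- function(spec, audio = TRUE) {
  stopifnot(inherits(spec, "song_spec"))
  set.seed(spec$seed)
  timing <- draw_song_timing(spec)
  syl <- timing$syllables
  n_syl <- nrow(syl)
  amps <- spec$amplitude *
    stats::runif(n_syl, 1 - spec$amplitude_jitter, 1)

  truth <- list(syllables = syl, chirps = timing$chirps, spec = spec)
  if (!audio) {
    return(structure(list(recording = NULL, truth = truth),
                     class = "song_synthesis"))
  }

  fs <- spec$sample_rate
  total <- syl$offset_sample[n_syl] +
    as.integer(round(spec$lead_ms / 1000 * fs))
  x <- numeric(total)
  edge <- max(2L, as.integer(round(spec$edge_ms / 1000 * fs)))
  omega <- 2 * pi * spec$carrier_hz / fs
  for (k in seq_len(n_syl)) {
    d <- syl$offset_sample[k] - syl$onset_sample[k]
    i <- seq_len(d) - 1L
    w <- if (d >= 2L * edge) {
      c(0.5 * (1 - cos(pi * (0:(edge - 1L)) / edge)),
        rep(1, d - 2L * edge),
        0.5 * (1 - cos(pi * ((edge - 1L):0) / edge)))
    } else {
      0.5 * (1 - cos(2 * pi * i / (d - 1L)))
    }
    x[syl$onset_sample[k] + seq_len(d)] <- amps[k] * w * sin(omega * i)
  }
  if (spec$noise_rms > 0) {
    x <- x + stats::rnorm(total, 0, spec$noise_rms)
  }
  x <- x / max(abs(x))
  rec <- audio_recording(x, fs, source_id = sprintf("synth-seed%d", spec$seed))
  structure(list(recording = rec, truth = truth), class = "song_synthesis")
}

#' Ground-truth inter-syllable intervals
#'
#' @param truth The `truth` element of a [synthesize_song()] result.
#' @return Numeric vector of within-chirp gaps in milliseconds.
#' @export
ground_truth_isis <- function(truth) {
  s <- truth$syllables
  n <- nrow(s)
  if (n < 2L) return(numeric())
  same <- s$chirp_index[-1L] == s$chirp_index[-n]
  ((s$onset_s[-1L] - s$offset_s[-n]) * 1000)[same]
}

#' Simulate a two-treatment nested recording experiment
#'
#' Mirrors the nested design of the field study: `n_individuals` per
#' treatment, `n_recordings` songs per individual. Each individual receives a
#' persistent offset on its mean inter-syllable interval, drawn from
#' `Normal(0, between_individual_sd)`; recordings are then generated
#' independently with per-recording seeds derived from `seed`, so the whole
#' dataset is seed-deterministic.
#'
#' @param spec1,spec2 Base [song_spec()]s (or preset names understood by
#'   [song_preset()]) for the two treatments.
#' @param n_individuals Individuals per treatment (>= 2). Default 5.
#' @param n_recordings Recordings per individual. Default 5.
#' @param between_individual_sd SD (ms) of the per-individual offset on the
#'   mean inter-syllable interval. Default 1.
#' @param seed Master seed; per-recording seeds are derived from it.
#' @param audio Render waveforms (`TRUE`) or ground truth only.
#' @param process Optional function `(recording, truth, meta) -> value`
#'   applied to each recording as it is synthesized; when supplied, only its
#'   return value is kept (the waveform is discarded), which bounds memory
#'   for large experiments. `meta` is a list with `group`, `individual`,
#'   `recording`.
#' @param labels Character vector of length 2 naming the treatments.
#' @return A list of class `song_experiment` with one element per treatment:
#'   `label`, `base_spec`, `individual_offsets_ms`, and `recordings` — a data
#'   frame with columns `individual`, `recording`, `seed`, `isi_mean_ms` and
#'   a list-column `result` holding either `song_synthesis` objects or the
#'   `process` return values.
#' @export
make_group_dataset <- function(spec1 = "LD-like", spec2 = "LL-like",
                               n_individuals = 5, n_recordings = 5,
                               between_individual_sd = 1,
                               seed = 1, audio = TRUE, process = NULL,
                               labels = c("group1", "group2")) {
  stopifnot(n_individuals >= 2, n_recordings >= 1)
  if (is.character(spec1)) spec1 <- song_preset(spec1)
  if (is.character(spec2)) spec2 <- song_preset(spec2)
  groups <- list(spec1, spec2)
  # draw every design-level random quantity up front, so the per-recording
  # seeding inside synthesize_song cannot perturb the design across modes
  set.seed(seed)
  all_offsets <- lapply(1:2, function(g)
    stats::rnorm(n_individuals, 0, between_individual_sd))
  all_seeds <- lapply(1:2, function(g)
    sample.int(2147483646L, n_individuals * n_recordings))
  out <- vector("list", 2L)
  for (g in 1:2) {
    base <- groups[[g]]
    # keep the shifted ISI mean physical (positive, above truncation floor)
    offsets <- pmax(all_offsets[[g]], 2 - base$inter_syllable_ms[1L])
    rec_seed <- all_seeds[[g]]
    grid <- expand.grid(recording = seq_len(n_recordings),
                        individual = seq_len(n_individuals))
    results <- vector("list", nrow(grid))
    isi_means <- numeric(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      ind <- grid$individual[r]
      sp <- base
      sp$inter_syllable_ms[1L] <- base$inter_syllable_ms[1L] + offsets[ind]
      sp$seed <- rec_seed[r]
      isi_means[r] <- sp$inter_syllable_ms[1L]
      syn <- synthesize_song(sp, audio = audio)
      results[[r]] <- if (is.null(process)) syn else {
        process(syn$recording, syn$truth,
                list(group = labels[g], individual = ind,
                     recording = grid$recording[r]))
      }
    }
    recs <- data.frame(individual = grid$individual,
                       recording = grid$recording,
                       seed = rec_seed, isi_mean_ms = isi_means)
    recs$result <- results
    out[[g]] <- list(label = labels[g], base_spec = base,
                     individual_offsets_ms = offsets, recordings = recs)
  }
  names(out) <- labels
  structure(out, class = "song_experiment")
}
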