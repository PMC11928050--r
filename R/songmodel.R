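#' Group syllables into chirps
#'
#' Consecutive syllables separated by a gap of at most
#' `max_intra_chirp_gap_ms` belong to the same chirp. A gap in
#' `(max_intra_chirp_gap_ms, max_inter_chirp_gap_ms]` is an inter-chirp
#' interval, recorded on the chirp it follows; a longer gap is a pause in the
#' calling song — it still terminates the chirp but is excluded from interval
#' statistics (`following_inter_chirp_interval_ms` is `NA`). Every syllable
#' belongs to exactly one chirp.
#'
#' @param syllables Data frame of syllable events (sorted, non-overlapping),
#'   as returned by [detect_syllables()].
#' @param cfg A [detection_config()].
#' @return A data frame with one row per chirp: `chirp_id`, `n_syllables`,
#'   `onset_s`, `offset_s`, `duration_ms`,
#'   `following_inter_chirp_interval_ms` (NA for the last chirp and before
#'   pauses), and list-columns `syllable_durations_ms` and
#'   `inter_syllable_intervals_ms`.
#' @export
group_chirps <- function(syllables, cfg = detection_config()) {
  n <- nrow(syllables)
  if (n == 0L) {
    return(data.frame(
      chirp_id = integer(), n_syllables = integer(),
      onset_s = numeric(), offset_s = numeric(), duration_ms = numeric(),
      following_inter_chirp_interval_ms = numeric(),
      syllable_durations_ms = I(list()),
      inter_syllable_intervals_ms = I(list())
    ))
  }
  stopifnot(!is.unsorted(syllables$onset_s))
  gaps_ms <- if (n > 1L) {
    (syllables$onset_s[-1L] - syllables$offset_s[-n]) * 1000
  } else numeric()
  chirp_of <- cumsum(c(1L, as.integer(gaps_ms > cfg$max_intra_chirp_gap_ms)))
  idx <- split(seq_len(n), chirp_of)
  k <- length(idx)
  first <- vapply(idx, `[`, integer(1), 1L)
  last <- vapply(idx, function(i) i[length(i)], integer(1))
  following <- rep(NA_real_, k)
  if (k > 1L) {
    g <- gaps_ms[last[-k]]                 # gap after each chirp's last syllable
    inter <- g > cfg$max_intra_chirp_gap_ms & g <= cfg$max_inter_chirp_gap_ms
    following[-k][inter] <- g[inter]
  }
  data.frame(
    chirp_id = seq_len(k),
    n_syllables = lengths(idx),
    onset_s = syllables$onset_s[first],
    offset_s = syllables$offset_s[last],
    duration_ms = (syllables$offset_s[last] - syllables$onset_s[first]) * 1000,
    following_inter_chirp_interval_ms = following,
    syllable_durations_ms = I(lapply(idx, function(i) syllables$duration_ms[i])),
    inter_syllable_intervals_ms = I(lapply(idx, function(i) {
      if (length(i) > 1L) gaps_ms[i[-length(i)]] else numeric()
    })),
    row.names = NULL
  )
}

#' Tabulate syllable counts per chirp
#'
#' @param chirps Data frame from [group_chirps()].
#' @return A data frame with columns `n_syllables`, `n`, `proportion`,
#'   covering every count from 1 to the maximum observed (zeros included).
#'   Empty input yields an empty table.
#' @export
syllable_count_distribution <- function(chirps) {
  if (nrow(chirps) == 0L) {
    return(data.frame(n_syllables = integer(), n = integer(),
                      proportion = numeric()))
  }
  counts <- tabulate(chirps$n_syllables)
  data.frame(
    n_syllables = seq_along(counts),
    n = counts,
    proportion = counts / sum(counts)
  )
}

#' Inter-chirp intervals at a given chirp-class transition
#'
#' Returns the inter-chirp intervals separating a chirp of `from_count`
#' syllables from an immediately following chirp of `to_count` syllables.
#' Gaps classified as pauses do not qualify. The result is honestly empty
#' when no such transition occurs.
#'
#' @param chirps Data frame from [group_chirps()].
#' @param from_count,to_count Syllable counts of the leading and following
#'   chirp (defaults 3 and 4).
#' @return Numeric vector of intervals in milliseconds.
#' @export
transition_intervals <- function(chirps, from_count = 3, to_count = 4) {
  k <- nrow(chirps)
  if (k < 2L) return(numeric())
  i <- which(chirps$n_syllables[-k] == from_count &
               chirps$n_syllables[-1L] == to_count &
               !is.na(chirps$following_inter_chirp_interval_ms[-k]))
  chirps$following_inter_chirp_interval_ms[i]
}

#' Dominant frequency of a recording
#'
#' Frequency of the maximum of a segment-averaged (Welch-style) Hann-windowed
#' periodogram, restricted to the given band. For recordings shorter than the
#' segment length a single full-length periodogram is used.
#'
#' @param rec An [audio_recording()].
#' @param band_hz Length-2 numeric search band in Hz (default 1-10 kHz); it is
#'   intersected with the Nyquist range.
#' @param segment Segment length in samples (default 8192).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return Dominant frequency in Hz, or `NA_real_` for a silent recording.
#' @export
dominant_frequency <- function(rec, band_hz = c(1000, 10000),
                               segment = 8192, overlap = 0.5) {
  stopifnot(inherits(rec, "audio_recording"), length(band_hz) == 2L)
  x <- rec$samples
  if (!length(x) || max(abs(x)) == 0) return(NA_real_)
  fs <- rec$sample_rate
  L <- min(segment, length(x))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
  hop <- max(1L, as.integer(floor(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  seg_mat <- vapply(starts, function(s) x[s:(s + L - 1L)] * w, numeric(L))
  spec <- Mod(stats::mvfft(seg_mat))^2
  n_bins <- L %/% 2L + 1L
  power <- rowMeans(spec[seq_len(n_bins), , drop = FALSE])
  freqs <- (seq_len(n_bins) - 1L) * fs / L
  in_band <- freqs >= max(band_hz[1L], 0) & freqs <= min(band_hz[2L], fs / 2)
  if (!any(in_band)) stop("Search band contains no frequency bins")
  freqs[in_band][which.max(power[in_band])]
}

#' Summarize a recording into its song parameters
#'
#' Computes the per-recording feature vector: chirp-level means over all
#' chirps (chirp duration, inter-chirp interval), syllable-level means over
#' the first `min(n_chirps, chirp_cap)` chirps (syllable duration and
#' inter-syllable interval, overall and separately for 3- and 4-syllable
#' chirps), the syllable-count proportions, the mean 3-to-4-syllable
#' transition interval, and the dominant frequency.
#'
#' @param rec The [audio_recording()] (used for the dominant frequency; pass
#'   `NULL` to skip spectral analysis).
#' @param chirps Data frame from [group_chirps()] for this recording.
#' @param chirp_cap Number of leading chirps used for syllable-level means
#'   (default 3500).
#' @param band_hz Dominant-frequency search band, see [dominant_frequency()].
#' @param source_id Identifier for the summary row; defaults to the
#'   recording's.
#' @return A one-row data frame (class `recording_summary`) with the columns
#'   listed above plus `prop_1syl` .. `prop_5syl` and `prop_other`; the full
#'   count table is attached as attribute `count_distribution`.
#' @export
summarize_recording <- function(rec, chirps, chirp_cap = 3500,
                                band_hz = c(1000, 10000),
                                source_id = NULL) {
  if (is.null(source_id)) {
    source_id <- if (!is.null(rec)) rec$source_id else "unknown"
  }
  n_chirps <- nrow(chirps)
  dist <- syllable_count_distribution(chirps)
  props <- numeric(5)
  if (n_chirps > 0L) {
    props[dist$n_syllables[dist$n_syllables <= 5L]] <-
      dist$proportion[dist$n_syllables <= 5L]
  }
  prop_other <- if (n_chirps > 0L) 1 - sum(props) else 0

  dom <- if (!is.null(rec)) dominant_frequency(rec, band_hz) else NA_real_

  if (n_chirps == 0L) {
    out <- data.frame(
      source_id = source_id, n_chirps = 0L, n_syllables = 0L,
      mean_chirp_duration_ms = NA_real_,
      mean_inter_chirp_interval_ms = NA_real_,
      mean_syllable_duration_ms = NA_real_,
      mean_syllable_duration_3syl_ms = NA_real_,
      mean_syllable_duration_4syl_ms = NA_real_,
      mean_inter_syllable_interval_ms = NA_real_,
      mean_inter_syllable_interval_3syl_ms = NA_real_,
      mean_inter_syllable_interval_4syl_ms = NA_real_,
      mean_3to4_transition_interval_ms = NA_real_,
      dominant_frequency_hz = dom,
      prop_1syl = 0, prop_2syl = 0, prop_3syl = 0, prop_4syl = 0,
      prop_5syl = 0, prop_other = 0,
      stringsAsFactors = FALSE
    )
    class(out) <- c("recording_summary", "data.frame")
    attr(out, "count_distribution") <- dist
    return(out)
  }

  head_chirps <- chirps[seq_len(min(n_chirps, chirp_cap)), , drop = FALSE]
  syl_dur <- unlist(head_chirps$syllable_durations_ms)
  isi <- unlist(head_chirps$inter_syllable_intervals_ms)
  class_mean <- function(col, k) {
    v <- unlist(head_chirps[[col]][head_chirps$n_syllables == k])
    if (length(v)) mean(v) else NA_real_
  }
  trans <- transition_intervals(chirps, 3, 4)

  out <- data.frame(
    source_id = source_id,
    n_chirps = n_chirps,
    n_syllables = sum(chirps$n_syllables),
    mean_chirp_duration_ms = mean(chirps$duration_ms),
    mean_inter_chirp_interval_ms =
      mean(chirps$following_inter_chirp_interval_ms, na.rm = TRUE),
    mean_syllable_duration_ms = mean(syl_dur),
    mean_syllable_duration_3syl_ms = class_mean("syllable_durations_ms", 3L),
    mean_syllable_duration_4syl_ms = class_mean("syllable_durations_ms", 4L),
    mean_inter_syllable_interval_ms =
      if (length(isi)) mean(isi) else NA_real_,
    mean_inter_syllable_interval_3syl_ms =
      class_mean("inter_syllable_intervals_ms", 3L),
    mean_inter_syllable_interval_4syl_ms =
      class_mean("inter_syllable_intervals_ms", 4L),
    mean_3to4_transition_interval_ms =
      if (length(trans)) mean(trans) else NA_real_,
    dominant_frequency_hz = dom,
    prop_1syl = props[1], prop_2syl = props[2], prop_3syl = props[3],
    prop_4syl = props[4], prop_5syl = props[5], prop_other = prop_other,
    stringsAsFactors = FALSE
  )
  class(out) <- c("recording_summary", "data.frame")
  attr(out, "count_distribution") <- dist
  out
}

#' Individual inclusion filter for full-data analysis
#'
#' An individual enters the full-data chirp-duration analysis only if it was
#' recorded for more than 4 days and contributed more than 20,000 chirps —
#' both strict inequalities, so exactly 4 days or exactly 20,000 chirps is
#' excluded.
#'
#' @param n_days Recording span in days (vectorized).
#' @param n_chirps Total chirps recorded (vectorized).
#' @param min_days,min_chirps Exclusive lower bounds (defaults 4 and 20000).
#' @return Logical vector.
#' @export
inclusion_filter <- function(n_days, n_chirps, min_days = 4,
                             min_chirps = 20000) {
  n_days > min_days & n_chirps > min_chirps
}
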