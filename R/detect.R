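#' Detection configuration
#'
#' Parameters of the double-threshold (hysteresis) syllable detector and of
#' the gap rules used to group syllables into chirps. All thresholds apply to
#' the amplitude envelope of a peak-normalized recording, so they are
#' dimensionless fractions of full scale.
#'
#' @param high_threshold Envelope amplitude a frame must exceed for an event
#'   to be opened. Default 0.1.
#' @param low_threshold The second, low, threshold that closes an event and
#'   suppresses noise between chirps and syllables. Default 0.05: above the
#'   frame-maximum of typical post-normalization chamber noise, well below any
#'   real syllable (which must exceed `high_threshold` anyway).
#' @param frame_ms Envelope frame length in milliseconds. Default 2.
#' @param hop_fraction Hop between frames as a fraction of the frame length.
#'   Default 0.5.
#' @param min_syllable_ms,max_syllable_ms Duration window (ms) outside which a
#'   detected event is discarded as a click or artefact. Defaults 5 and 60,
#'   bracketing syllable periods of about 30-40 ms.
#' @param max_intra_chirp_gap_ms Largest silent gap (ms) still counted as an
#'   inter-syllable interval within a chirp. Default 40.
#' @param min_inter_chirp_gap_ms,max_inter_chirp_gap_ms Window (ms) of gaps
#'   counted as inter-chirp intervals; longer gaps are pauses in the calling
#'   song and are excluded from interval statistics. Defaults 40 and 2000.
#' @param zero_eps Absolute amplitude (fraction of full scale) at or below
#'   which a sample counts as "zero amplitude" for boundary refinement.
#'   Default 1e-4; an adaptive floor is added for noisy recordings (see
#'   [refine_boundaries()]).
#' @param envelope Envelope estimator: `"frame_max"` (default) or `"hilbert"`
#'   (frame-maximum of the analytic-signal magnitude).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(high_threshold = 0.1,
                             low_threshold = 0.05,
                             frame_ms = 2,
                             hop_fraction = 0.5,
                             min_syllable_ms = 5,
                             max_syllable_ms = 60,
                             max_intra_chirp_gap_ms = 40,
                             min_inter_chirp_gap_ms = 40,
                             max_inter_chirp_gap_ms = 2000,
                             zero_eps = 1e-4,
                             envelope = c("frame_max", "hilbert")) {
  envelope <- match.arg(envelope)
  cfg <- list(
    high_threshold = high_threshold, low_threshold = low_threshold,
    frame_ms = frame_ms, hop_fraction = hop_fraction,
    min_syllable_ms = min_syllable_ms, max_syllable_ms = max_syllable_ms,
    max_intra_chirp_gap_ms = max_intra_chirp_gap_ms,
    min_inter_chirp_gap_ms = min_inter_chirp_gap_ms,
    max_inter_chirp_gap_ms = max_inter_chirp_gap_ms,
    zero_eps = zero_eps, envelope = envelope
  )
  stopifnot(
    0 < cfg$low_threshold, cfg$low_threshold < cfg$high_threshold,
    cfg$high_threshold < 1,
    0 < cfg$min_syllable_ms, cfg$min_syllable_ms < cfg$max_syllable_ms,
    cfg$frame_ms > 0, cfg$hop_fraction > 0, cfg$hop_fraction <= 1,
    cfg$max_intra_chirp_gap_ms <= cfg$min_inter_chirp_gap_ms,
    cfg$min_inter_chirp_gap_ms <= cfg$max_inter_chirp_gap_ms,
    cfg$zero_eps > 0
  )
  structure(cfg, class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

hilbert_magnitude <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

#' Compute the amplitude envelope
#'
#' The envelope is the per-frame maximum of the absolute waveform, computed
#' over short overlapping frames ("many small fragments" of the recording).
#' On a normalized recording the envelope lies in \[0, 1\], so the detection
#' thresholds retain their full-scale meaning.
#'
#' @param rec A (normalized) [audio_recording()].
#' @param frame_ms Frame length in milliseconds.
#' @param hop_fraction Hop as a fraction of the frame length.
#' @param method `"frame_max"` or `"hilbert"`.
#' @return An object of class `song_envelope`: list with `values` (one per
#'   frame), `frame_length`, `hop_length`, `sample_rate`, `n_samples`.
#' @export
compute_envelope <- function(rec, frame_ms = 2, hop_fraction = 0.5,
                             method = c("frame_max", "hilbert")) {
  stopifnot(inherits(rec, "audio_recording"), frame_ms > 0)
  method <- match.arg(method)
  x <- abs(rec$samples)
  if (method == "hilbert") x <- hilbert_magnitude(rec$samples)
  n <- length(x)
  frame <- max(1L, as.integer(round(frame_ms / 1000 * rec$sample_rate)))
  hop <- max(1L, as.integer(round(frame * hop_fraction)))
  if (frame >= n) {
    vals <- max(x)
    n_frames <- max(1L, as.integer(ceiling(n / hop)))
    vals <- rep(vals, n_frames)
    # frames past the data see only the tail
    if (n_frames > 1L) {
      for (i in 2:n_frames) vals[i] <- max(x[((i - 1L) * hop + 1L):n], 0)
    }
  } else {
    n_frames <- as.integer(ceiling(n / hop))
    if (frame %% hop == 0L) {
      # decompose frames into hop-sized chunks, take running max of chunk maxima
      k <- frame %/% hop
      n_chunks <- n_frames + k - 1L
      xp <- c(x, numeric(n_chunks * hop - n))
      m <- matrix(xp, nrow = hop)
      chunk_max <- do.call(pmax, lapply(seq_len(hop), function(i) m[i, ]))
      vals <- chunk_max[seq_len(n_frames)]
      if (k > 1L) {
        for (j in 1:(k - 1L)) {
          vals <- pmax(vals, chunk_max[seq_len(n_frames) + j])
        }
      }
    } else {
      starts <- (seq_len(n_frames) - 1L) * hop + 1L
      vals <- vapply(starts, function(s) max(x[s:min(s + frame - 1L, n)]),
                     numeric(1))
    }
  }
  structure(
    list(values = as.numeric(vals), frame_length = frame, hop_length = hop,
         sample_rate = rec$sample_rate, n_samples = n),
    class = "song_envelope"
  )
}

#' Detect raw event candidates by double thresholding
#'
#' Hysteresis detection on the envelope: an event is any maximal run of
#' frames whose envelope stays above `low_threshold` and that contains at
#' least one frame exceeding `high_threshold`. Runs above the low threshold
#' that never reach the high threshold are treated as noise and discarded;
#' sub-threshold bursts are not events. Candidates are reported at frame
#' resolution as half-open, 0-based sample intervals.
#'
#' @param env A `song_envelope` from [compute_envelope()].
#' @param cfg A [detection_config()].
#' @return A data frame with columns `onset_sample`, `offset_sample`
#'   (0-based, half-open).
#' @export
detect_events <- function(env, cfg = detection_config()) {
  stopifnot(inherits(env, "song_envelope"), inherits(cfg, "detection_config"))
  v <- env$values
  above_low <- v > cfg$low_threshold
  r <- rle(above_low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) {
    return(data.frame(onset_sample = integer(), offset_sample = integer()))
  }
  hit <- vapply(keep, function(i) any(v[starts[i]:ends[i]] > cfg$high_threshold),
                logical(1))
  keep <- keep[hit]
  if (!length(keep)) {
    return(data.frame(onset_sample = integer(), offset_sample = integer()))
  }
  hop <- env$hop_length
  onset <- (starts[keep] - 1L) * hop
  offset <- pmin((ends[keep] - 1L) * hop + env$frame_length, env$n_samples)
  data.frame(onset_sample = as.integer(onset),
             offset_sample = as.integer(offset))
}

#' Refine candidate boundaries to zero amplitude
#'
#' Each candidate's onset and offset are moved to the nearest "zero
#' amplitude" sample of the raw waveform: the refiner anchors at the first
#' (respectively last) sample inside the candidate whose magnitude reaches
#' the high threshold and walks outward until a sample with
#' `|x| <= eps` is found, where `eps = max(zero_eps, 4 * q10(|x|))` — the
#' adaptive floor keeps the walk from running past the event edge on
#' recordings whose noise floor never touches exact zero. The walk is capped
#' at one frame beyond the candidate edge and never crosses a neighboring
#' event; if no zero is found within the cap the frame edge is kept and a
#' warning is raised. Refinement is deterministic and idempotent. Candidates
#' with no sample reaching the high threshold (degenerate) are returned
#' unchanged.
#'
#' @param rec The normalized [audio_recording()] the candidates came from.
#' @param candidates Data frame from [detect_events()].
#' @param cfg A [detection_config()].
#' @return A data frame of syllable events: `onset_sample`, `offset_sample`
#'   (0-based half-open), `onset_s`, `offset_s`, `duration_ms`,
#'   `peak_amplitude`.
#' @export
refine_boundaries <- function(rec, candidates, cfg = detection_config()) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- rec$samples
  n <- length(x)
  fs <- rec$sample_rate
  frame <- max(1L, as.integer(round(cfg$frame_ms / 1000 * fs)))
  eps <- max(cfg$zero_eps, 4 * stats::quantile(abs(x), 0.1, names = FALSE))
  m <- nrow(candidates)
  onset <- integer(m); offset <- integer(m); peak <- numeric(m)
  n_unrefined <- 0L
  prev_off <- 0L
  for (i in seq_len(m)) {
    s <- candidates$onset_sample[i]
    e <- candidates$offset_sample[i]
    seg <- x[(s + 1L):e]
    hi <- which(abs(seg) >= cfg$high_threshold)
    if (!length(hi)) {                       # degenerate: keep as-is
      onset[i] <- s; offset[i] <- e
      peak[i] <- max(abs(seg))
      prev_off <- e
      next
    }
    a <- s + hi[1L] - 1L                     # 0-based anchor samples
    b <- s + hi[length(hi)] - 1L
    peak[i] <- max(abs(seg))

    lb <- max(prev_off, s - frame, 0L)
    walk <- a:lb
    z <- which(abs(x[walk + 1L]) <= eps)
    if (length(z)) {
      onset[i] <- walk[z[1L]]
    } else {
      onset[i] <- s
      n_unrefined <- n_unrefined + 1L
    }

    nxt <- if (i < m) candidates$onset_sample[i + 1L] else n - 1L
    ub <- min(e + frame, nxt, n - 1L)
    if (b + 1L <= ub) {
      walk <- (b + 1L):ub
      z <- which(abs(x[walk + 1L]) <= eps)
    } else z <- integer()
    if (length(z)) {
      offset[i] <- walk[z[1L]]
    } else {
      offset[i] <- e
      n_unrefined <- n_unrefined + 1L
    }
    prev_off <- offset[i]
  }
  if (n_unrefined > 0L) {
    warning(n_unrefined, " boundar",
            if (n_unrefined == 1L) "y" else "ies",
            " kept at frame edge: no zero-amplitude sample within one frame")
  }
  data.frame(
    onset_sample = onset, offset_sample = offset,
    onset_s = onset / fs, offset_s = offset / fs,
    duration_ms = (offset - onset) / fs * 1000,
    peak_amplitude = peak
  )
}

#' Filter events by syllable duration
#'
#' Keeps events whose duration lies within the configured syllable window,
#' discarding clicks and long artefacts; the number discarded is attached as
#' attribute `n_discarded`.
#'
#' @param events Data frame from [refine_boundaries()].
#' @param cfg A [detection_config()].
#' @return The surviving events, with attribute `n_discarded`.
#' @export
filter_syllables <- function(events, cfg = detection_config()) {
  keep <- events$duration_ms >= cfg$min_syllable_ms &
    events$duration_ms <= cfg$max_syllable_ms
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Detect syllables in a recording
#'
#' Full detection chain: peak normalization, envelope extraction, double
#' thresholding, zero-amplitude boundary refinement, duration filtering.
#'
#' @param rec An [audio_recording()] (normalized internally).
#' @param cfg A [detection_config()].
#' @return A data frame of syllable events (see [refine_boundaries()]), with
#'   attribute `n_discarded`.
#' @export
detect_syllables <- function(rec, cfg = detection_config()) {
  rec <- normalize_audio(rec)
  env <- compute_envelope(rec, cfg$frame_ms, cfg$hop_fraction, cfg$envelope)
  cand <- detect_events(env, cfg)
  ev <- refine_boundaries(rec, cand, cfg)
  filter_syllables(ev, cfg)
}

#' Read / write a detection configuration file
#'
#' Flat `key = value` text format, one parameter per line; unknown keys are
#' rejected. Round-trips exactly through [detection_config()].
#'
#' @param path File path.
#' @return For `read_detection_config`, a [detection_config()].
#' @export
read_detection_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2L)) stop("Malformed config line in ", path)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  args <- as.list(suppressWarnings(as.numeric(vals)))
  names(args) <- keys
  if ("envelope" %in% keys) args$envelope <- vals[keys == "envelope"]
  bad <- setdiff(keys, names(formals(detection_config)))
  if (length(bad)) stop("Unknown config keys: ", paste(bad, collapse = ", "))
  do.call(detection_config, args)
}

#' @rdname read_detection_config
#' @param cfg A [detection_config()].
#' @export
write_detection_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "detection_config"))
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, format, character(1))), path)
  invisible(path)
}
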