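# Hand-built waveform fixtures, independent of the synth module.

# A single tone burst (sine gated by 1 ms raised-cosine edges, phase 0 at
# onset) embedded in silence. onset_sample is 0-based.
make_burst_recording <- function(total_s = 1, onset_s = 0.1, burst_ms = 20,
                                 amp = 1, carrier_hz = 4900, fs = 44100,
                                 noise_sd = 0) {
  n <- round(total_s * fs)
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  onset <- round(onset_s * fs)
  d <- round(burst_ms / 1000 * fs)
  edge <- round(0.001 * fs)
  i <- seq_len(d) - 1
  w <- c(0.5 * (1 - cos(pi * (0:(edge - 1)) / edge)),
         rep(1, d - 2 * edge),
         0.5 * (1 - cos(pi * ((edge - 1):0) / edge)))
  x[onset + seq_len(d)] <- x[onset + seq_len(d)] +
    amp * w * sin(2 * pi * carrier_hz / fs * i)
  list(rec = audio_recording(x, fs, "burst"),
       onset_sample = onset, offset_sample = onset + d)
}

# Synthetic syllable-event table (for grouping/filtering tests that do not
# need audio): onsets in seconds, durations in ms.
make_events <- function(onsets_s, durations_ms, fs = 44100) {
  offs <- onsets_s + durations_ms / 1000
  data.frame(
    onset_sample = round(onsets_s * fs), offset_sample = round(offs * fs),
    onset_s = onsets_s, offset_s = offs,
    duration_ms = durations_ms,
    peak_amplitude = rep(1, length(onsets_s))
  )
}

# Events laid out from a vector of inter-event gaps (ms).
events_from_gaps <- function(gaps_ms, dur_ms = 18, start_s = 0.1) {
  onsets <- start_s + c(0, cumsum(gaps_ms + dur_ms)) / 1000
  make_events(onsets, rep(dur_ms, length(gaps_ms) + 1))
}

# Minimal stereo 16-bit PCM WAV writer (the package's writer is mono-only).
write_stereo_wav <- function(left, right, fs, path) {
  pcm <- as.integer(round(rbind(left, right) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 2L), con, 2L, endian = "little")
  writeBin(as.integer(fs), con, 4L, endian = "little")
  writeBin(as.integer(fs) * 4L, con, 4L, endian = "little")
  writeBin(c(4L, 16L), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(as.vector(pcm), con, 2L, endian = "little")
  invisible(path)
}
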