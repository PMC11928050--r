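#' Construct an audio recording
#'
#' The canonical in-memory representation of a (mono) recording: a numeric
#' sample vector plus its sample rate. All detection functions operate on this
#' object after [normalize_audio()].
#'
#' @param samples Numeric vector of amplitude values.
#' @param sample_rate Sampling rate in Hz (integer, >= 8000 for song analysis,
#'   but any positive rate is accepted here).
#' @param source_id Opaque identifier, usually the file stem.
#' @return An object of class `audio_recording` with fields `samples`,
#'   `sample_rate`, `source_id` and `duration_s`.
#' @export
audio_recording <- function(samples, sample_rate, source_id = "memory") {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate = as.integer(round(sample_rate)),
      source_id = as.character(source_id),
      duration_s = length(samples) / sample_rate
    ),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf(
    "<audio_recording '%s': %d samples @ %d Hz = %.3f s, peak %.4f>\n",
    x$source_id, length(x$samples), x$sample_rate, x$duration_s,
    if (length(x$samples)) max(abs(x$samples)) else 0
  ))
  invisible(x)
}

# -- WAV I/O ------------------------------------------------------------------
# Minimal RIFF/WAVE codec. Reads PCM 16/24/32-bit integer and 32/64-bit float
# (format tags 1, 3 and the WAVE_FORMAT_EXTENSIBLE wrapper); writes 16-bit PCM.

read_u32 <- function(con) readBin(con, "integer", 1L, 4L, signed = TRUE, endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little")

#' Read a PCM WAV file
#'
#' Loads a WAV file into an [audio_recording()]. Integer PCM samples are
#' divided by full scale so the result is floating point in \[-1, 1\]; no
#' peak normalization is applied (see [normalize_audio()]). Stereo files are
#' downmixed by averaging the two channels unless a single channel is
#' requested.
#'
#' @param path Path to a PCM WAV file.
#' @param channel `"mix"` (default, average all channels), or a 1-based
#'   channel index to select a single channel.
#' @return An [audio_recording()].
#' @export
read_song_wav <- function(path, channel = "mix") {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("Not a RIFF/WAV file: ", path)
  read_u32(con)
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("Not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- read_u32(con)
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = read_u16(con),
        n_channels = read_u16(con),
        sample_rate = read_u32(con),
        byte_rate = read_u32(con),
        block_align = read_u16(con),
        bits = read_u16(con)
      )
      extra <- size - 16L
      if (extra > 0L) {
        ext <- readBin(con, "raw", extra)
        # WAVE_FORMAT_EXTENSIBLE: actual format tag leads the 16-byte GUID
        if (fmt$audio_format == 0xFFFE && extra >= 24L) {
          fmt$audio_format <- as.integer(ext[9L]) + 256L * as.integer(ext[10L])
        }
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      break
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(fmt)) stop("Malformed WAV (no fmt chunk): ", path)
  if (is.null(data_raw) || length(data_raw) == 0L) {
    stop("Zero-length or missing data chunk in WAV: ", path)
  }
  if (!fmt$audio_format %in% c(1L, 3L)) {
    stop("Unsupported (compressed?) WAV format tag ", fmt$audio_format,
         " in: ", path)
  }

  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  x <- if (fmt$audio_format == 3L) {
    if (!fmt$bits %in% c(32L, 64L)) stop("Unsupported float bit depth: ", fmt$bits)
    readBin(data_raw, "numeric", n_total, bytes_per, endian = "little")
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", n_total, 2L, signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", n_total, 4L, signed = TRUE, endian = "little") / 2147483648
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
    ifelse(v >= 8388608L, v - 16777216L, v) / 8388608
  } else if (fmt$bits == 8L) {
    (as.integer(readBin(data_raw, "raw", n_total)) - 128L) / 128
  } else {
    stop("Unsupported PCM bit depth: ", fmt$bits)
  }

  nc <- fmt$n_channels
  if (nc > 1L) {
    n_frames <- length(x) %/% nc
    x <- matrix(x[seq_len(n_frames * nc)], nrow = nc)
    x <- if (identical(channel, "mix")) colMeans(x) else x[as.integer(channel), ]
  }
  audio_recording(x, fmt$sample_rate,
                  source_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a 16-bit PCM WAV file
#'
#' @param rec An [audio_recording()] (values outside \[-1, 1\] are clipped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_song_wav <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- pmax(-1, pmin(1, rec$samples))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")              # PCM, mono
  writeBin(rec$sample_rate, con, 4L, endian = "little")
  writeBin(rec$sample_rate * 2L, con, 4L, endian = "little")   # byte rate
  writeBin(c(2L, 16L), con, 2L, endian = "little")             # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Peak-normalize a recording to \[-1, 1\]
#'
#' Divides the waveform by its absolute peak so that `max(abs(samples)) == 1`.
#' A silent (all-zero) recording is returned unchanged: downstream detection
#' then correctly yields zero events.
#'
#' @param rec An [audio_recording()].
#' @return The normalized [audio_recording()].
#' @export
normalize_audio <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  if (length(rec$samples) == 0L) stop("Cannot normalize an empty recording")
  peak <- max(abs(rec$samples))
  if (peak == 0) return(rec)
  rec$samples <- rec$samples / peak
  rec
}

# -- Audacity label tracks ----------------------------------------------------

#' Export events as an Audacity label track
#'
#' Writes the standard Audacity label-track format (TAB-separated
#' `start end label`, seconds with 6 decimals, one line per event,
#' chronologically sorted), so detections can be loaded into the editor for
#' visual validation.
#'
#' @param events A data frame with numeric columns `start_s`, `end_s` and a
#'   `label` column (character).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_audacity_labels <- function(events, path) {
  stopifnot(is.data.frame(events),
            all(c("start_s", "end_s", "label") %in% names(events)))
  if (nrow(events) && any(events$end_s < events$start_s)) {
    stop("Events with end_s < start_s cannot be exported")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(events)) {
    ord <- order(events$start_s, events$end_s)
    lines <- sprintf("%.6f\t%.6f\t%s",
                     events$start_s[ord], events$end_s[ord],
                     as.character(events$label)[ord])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an Audacity label track
#'
#' @param path Path to a TAB-separated label file as written by
#'   [export_audacity_labels()] or exported from Audacity.
#' @return A data frame with columns `start_s`, `end_s`, `label`.
#' @export
read_audacity_labels <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("start_s", "end_s", "label"),
                          colClasses = c("numeric", "numeric", "character"),
                          quote = "", comment.char = "")
  df
}
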