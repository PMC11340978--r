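#' Audio recordings
#'
#' An `audio_recording` is a mono waveform with its sampling rate and an
#' identifier. Samples are dimensionless amplitudes in `[-1, 1]` after
#' decoding 16-bit PCM.
#'
#' @param samples Numeric vector of amplitude values.
#' @param sample_rate_hz Positive integer sampling rate (nominally 4000).
#' @param recording_id Opaque identifier string.
#' @return An object of class `audio_recording` with fields `samples`,
#'   `sample_rate_hz`, `recording_id` and derived `duration_s`.
#' @export
audio_recording <- function(samples, sample_rate_hz, recording_id = "unnamed") {
  stopifnot(is.numeric(samples), length(sample_rate_hz) == 1L)
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a positive number")
  }
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate_hz = as.integer(sample_rate_hz),
      recording_id = as.character(recording_id)
    ),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf(
    "<audio_recording '%s': %d samples @ %d Hz (%.2f s), peak %.3f>\n",
    x$recording_id, length(x$samples), x$sample_rate_hz,
    duration_s(x), if (length(x$samples)) max(abs(x$samples)) else 0
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `audio_recording`.
#' @return Length in seconds (`length(samples) / sample_rate_hz`).
#' @export
duration_s <- function(rec) length(rec$samples) / rec$sample_rate_hz

read_chunk_header <- function(con) {
  id <- rawToChar(readBin(con, "raw", 4L))
  size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Read a mono PCM WAV file
#'
#' Decodes a RIFF/WAVE file containing a single channel of integer PCM.
#' 16-bit samples are scaled by 1/32768 into `[-1, 1]`; 8-bit (unsigned)
#' files are offset and scaled likewise. The sample rate is taken from the
#' format chunk.
#'
#' @param path Path to a `.wav` file.
#' @param recording_id Identifier to attach; defaults to the file stem.
#' @return An [audio_recording()].
#' @export
read_wav <- function(path, recording_id = NULL) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  if (is.null(recording_id)) {
    recording_id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- read_chunk_header(con)
  if (riff$id != "RIFF") stop("not a RIFF file: ", path)
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (wave != "WAVE") stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(body[3:4]) * c(1L, 256L)),
        sample_rate  = sum(as.numeric(body[5:8]) * 256^(0:3)),
        bits         = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$audio_format != 1L) {
        stop("unsupported encoding: only integer PCM (format 1) is supported")
      }
      if (fmt$n_channels != 1L) {
        stop("multi-channel unsupported: file has ", fmt$n_channels, " channels")
      }
      if (fmt$bits == 16L) {
        n <- size %/% 2L
        raw_samples <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                               endian = "little")
        samples <- raw_samples / 32768
      } else if (fmt$bits == 8L) {
        raw_samples <- as.integer(readBin(con, "raw", size))
        samples <- (raw_samples - 128) / 128
      } else {
        stop("unsupported encoding: ", fmt$bits, "-bit PCM")
      }
    } else {
      # skip unknown chunk (word-aligned)
      seek(con, where = size + size %% 2L, origin = "current")
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk in ", path)
  audio_recording(samples, fmt$sample_rate, recording_id)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Amplitudes are clipped to `[-1, 1]` and quantised to 16-bit integers
#' (scaling by 32768, clamped to the representable 32767 maximum), so
#' `read_wav(write_wav(x))` round-trips bit-exactly for signals already on
#' the 16-bit grid.
#'
#' @param rec An [audio_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- pmin(pmax(rec$samples, -1), 1)
  pcm <- as.integer(pmin(round(x * 32768), 32767))
  sr <- as.integer(rec$sample_rate_hz)
  data_size <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(sr * 2L, con, size = 4L, endian = "little")  # byte rate
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Normalise a recording to unit peak amplitude
#'
#' Divides every sample by `max(abs(samples))` so the output peak magnitude
#' is exactly 1. Absolute stethoscope amplitude is unreliable (it varies with
#' application pressure and placement), so all downstream feature extraction
#' assumes unit-peak input.
#'
#' @param rec An [audio_recording()].
#' @return The normalised recording.
#' @export
normalise_peak <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  peak <- max(abs(rec$samples))
  if (peak == 0) {
    stop("degenerate recording: all samples are zero (silent)")
  }
  rec$samples <- rec$samples / peak
  rec
}

#' Crop or zero-pad a recording to a fixed duration
#'
#' Recordings longer than `target_s` are cropped (by default to their first
#' `target_s` seconds, matching capture order); shorter recordings are
#' zero-padded at the end. The output always has exactly
#' `round(target_s * sample_rate_hz)` samples.
#'
#' @param rec An [audio_recording()].
#' @param target_s Target duration in seconds (> 0).
#' @param random_crop If `TRUE`, long recordings are cropped at a uniformly
#'   drawn offset instead of the start (training-time augmentation); uses the
#'   session RNG, so seed upstream for reproducibility. Default `FALSE`.
#' @return The length-standardised recording.
#' @export
standardise_length <- function(rec, target_s, random_crop = FALSE) {
  stopifnot(inherits(rec, "audio_recording"))
  if (!is.numeric(target_s) || length(target_s) != 1L || target_s <= 0) {
    stop("target_s must be a positive number of seconds")
  }
  n_target <- as.integer(round(target_s * rec$sample_rate_hz))
  n <- length(rec$samples)
  if (n >= n_target) {
    start <- 1L
    if (random_crop && n > n_target) {
      start <- sample.int(n - n_target + 1L, 1L)
    }
    rec$samples <- rec$samples[start:(start + n_target - 1L)]
  } else {
    rec$samples <- c(rec$samples, numeric(n_target - n))
  }
  rec
}

#' Resample a recording to a target rate
#'
#' Polyphase resampling (via [signal::resample()]) used to bring recordings
#' captured at other rates onto the 4 kHz grid the feature geometry assumes.
#' Recordings already at the target rate are returned unchanged.
#'
#' @param rec An [audio_recording()].
#' @param target_rate_hz Target sampling rate (default 4000).
#' @return The resampled recording.
#' @export
resample_audio <- function(rec, target_rate_hz = 4000L) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$sample_rate_hz == target_rate_hz) return(rec)
  g <- gcd_int(as.integer(target_rate_hz), rec$sample_rate_hz)
  p <- as.integer(target_rate_hz) %/% g
  q <- rec$sample_rate_hz %/% g
  y <- signal::resample(rec$samples, p = p, q = q)
  audio_recording(y, target_rate_hz, rec$recording_id)
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
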