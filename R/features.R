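#' Spectrogram container
#'
#' Time x frequency power matrix with explicit axes. Frames advance by
#' `window_ms * (1 - overlap_fraction)` milliseconds; bin centres are spaced
#' by `1 / window_s` Hz (no zero padding).
#'
#' @param power Matrix `[n_frames x n_bins]` of nonnegative spectral power.
#' @param bin_centres_hz Ascending bin-centre frequencies.
#' @param frame_times_s Ascending frame-centre times.
#' @param window_ms Analysis window length in milliseconds.
#' @param overlap_fraction Fractional window overlap.
#' @export
spectrogram <- function(power, bin_centres_hz, frame_times_s,
                        window_ms = 100, overlap_fraction = 0.5) {
  stopifnot(is.matrix(power),
            ncol(power) == length(bin_centres_hz),
            nrow(power) == length(frame_times_s))
  structure(
    list(power = power, bin_centres_hz = bin_centres_hz,
         frame_times_s = frame_times_s, window_ms = window_ms,
         overlap_fraction = overlap_fraction),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram: %d frames x %d bins, %g-%g Hz, hop %g ms>\n",
    nrow(x$power), ncol(x$power), min(x$bin_centres_hz), max(x$bin_centres_hz),
    x$window_ms * (1 - x$overlap_fraction)
  ))
  invisible(x)
}

# Periodic Hann window of length n
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)

#' Short-time power spectrogram of a recording
#'
#' Hann window of `window_ms` (default 100 ms = 400 samples at 4 kHz) with
#' 50% overlap (hop 200 samples) and FFT length equal to the window length,
#' giving a one-sided spectrum with exactly 10 Hz bin spacing. Frame count is
#' `floor((N - window) / hop) + 1`.
#'
#' @param rec A peak-normalised [audio_recording()] sampled at 4000 Hz.
#' @param window_ms Window length in milliseconds (default 100).
#' @param overlap_fraction Fractional overlap between windows (default 0.5).
#' @return A [spectrogram()].
#' @export
compute_spectrogram <- function(rec, window_ms = 100, overlap_fraction = 0.5) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$sample_rate_hz != 4000L) {
    stop("compute_spectrogram expects 4000 Hz input; use resample_audio() first")
  }
  fs <- rec$sample_rate_hz
  n_win <- as.integer(round(window_ms / 1000 * fs))
  n_hop <- as.integer(round(n_win * (1 - overlap_fraction)))
  n <- length(rec$samples)
  if (n < n_win) {
    stop("too short for analysis: recording has ", n,
         " samples, window needs ", n_win)
  }
  n_frames <- (n - n_win) %/% n_hop + 1L
  starts <- (seq_len(n_frames) - 1L) * n_hop
  idx <- outer(seq_len(n_win), starts, `+`)   # n_win x n_frames
  frames <- matrix(rec$samples[idx], nrow = n_win)
  w <- hann_window(n_win)
  spec <- stats::mvfft(frames * w)
  n_bins <- n_win %/% 2L + 1L                 # one-sided, DC..Nyquist
  power <- t(Mod(spec[seq_len(n_bins), , drop = FALSE])^2)
  bin_centres <- (seq_len(n_bins) - 1L) * fs / n_win
  frame_times <- (starts + n_win / 2) / fs
  spectrogram(power, bin_centres, frame_times, window_ms, overlap_fraction)
}

#' Clip a spectrogram to a frequency band
#'
#' Retains bins whose centre lies in `[fmin_hz, fmax_hz]` inclusive, without
#' modifying the retained power values. With the default 10 Hz spacing this
#' keeps the 20-400 Hz stethoscope analysis band: exactly 39 bins, which
#' bounds the feature height while still including frequencies above the
#' stertor fundamentals that help separate signal from broadband noise.
#'
#' @param spec A [spectrogram()].
#' @param fmin_hz,fmax_hz Band edges (inclusive), defaults 20 and 400.
#' @return The clipped [spectrogram()].
#' @export
clip_band <- function(spec, fmin_hz = 20, fmax_hz = 400) {
  stopifnot(inherits(spec, "spectrogram"))
  if (fmax_hz > max(spec$bin_centres_hz) || fmin_hz < min(spec$bin_centres_hz)) {
    stop("requested band [", fmin_hz, ", ", fmax_hz,
         "] Hz lies outside available bins [", min(spec$bin_centres_hz),
         ", ", max(spec$bin_centres_hz), "] Hz")
  }
  keep <- spec$bin_centres_hz >= fmin_hz & spec$bin_centres_hz <= fmax_hz
  if (!any(keep)) stop("no spectrogram bins inside requested band")
  spec$power <- spec$power[, keep, drop = FALSE]
  spec$bin_centres_hz <- spec$bin_centres_hz[keep]
  spec
}

#' Convert a clipped spectrogram into network input features
#'
#' Applies a log-power transform `log(power + eps)` followed by
#' per-recording standardisation to zero mean and unit variance across all
#' cells. Log compression is the conventional choice for harmonically
#' structured bioacoustic events; standardisation makes features invariant
#' to any residual overall amplitude scale. A linear-power variant is kept
#' behind `scale = "linear"` (standardisation only).
#'
#' @param spec A band-clipped [spectrogram()].
#' @param scale `"log"` (default) or `"linear"`.
#' @param eps Floor added before the log (default 1e-10).
#' @return A [spectrogram()] whose `power` field holds the standardised
#'   feature matrix (may be negative).
#' @export
to_features <- function(spec, scale = c("log", "linear"), eps = 1e-10) {
  stopifnot(inherits(spec, "spectrogram"))
  scale <- match.arg(scale)
  x <- spec$power
  if (scale == "log") x <- log(x + eps)
  mu <- mean(x)
  sdv <- stats::sd(as.vector(x))
  spec$power <- if (is.na(sdv) || sdv == 0) {
    matrix(0, nrow(x), ncol(x))
  } else {
    (x - mu) / sdv
  }
  spec
}

#' Full waveform-to-features front end
#'
#' Peak normalisation, length standardisation, spectrogram, band clipping
#' and feature scaling in one call; the standard path from a raw recording
#' to the `[n_frames x 39]` matrix the network consumes.
#'
#' @param rec An [audio_recording()].
#' @param input_length_s Standardised recording length in seconds (5 or 10).
#' @param scale Passed to [to_features()].
#' @return Feature matrix `[n_frames x 39]`.
#' @export
extract_features <- function(rec, input_length_s = 10, scale = "log") {
  rec <- resample_audio(rec, 4000L)
  rec <- normalise_peak(rec)
  rec <- standardise_length(rec, input_length_s)
  spec <- compute_spectrogram(rec)
  spec <- clip_band(spec, 20, 400)
  to_features(spec, scale = scale)$power
}
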