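tone <- function(freq, duration_s = 1, fs = 4000L, amp = 1) {
  t <- (0:(duration_s * fs - 1)) / fs
  audio_recording(amp * sin(2 * pi * freq * t), fs)
}

test_that("100 ms Hann window yields 10 Hz bin spacing up to Nyquist", {
  spec <- compute_spectrogram(tone(100))
  expect_equal(unique(diff(spec$bin_centres_hz)), 10)
  expect_equal(range(spec$bin_centres_hz), c(0, 2000))
  expect_true(all(spec$power >= 0))
})

test_that("frame count follows the sliding-window formula", {
  # independent oracle: enumerate window placements directly
  count_windows <- function(n, win = 400L, hop = 200L) {
    starts <- 0L
    k <- 0L
    while (starts + win <= n) {
      k <- k + 1L
      starts <- starts + hop
    }
    k
  }
  for (dur in c(1, 5, 10)) {
    n <- dur * 4000L
    spec <- compute_spectrogram(tone(100, dur))
    expect_equal(nrow(spec$power), count_windows(n))
  }
  expect_equal(nrow(compute_spectrogram(tone(100, 10))$power), 199L)
  expect_equal(nrow(compute_spectrogram(tone(100, 5))$power), 99L)
  ft <- compute_spectrogram(tone(100, 5))$frame_times_s
  expect_equal(diff(ft), rep(0.05, length(ft) - 1L))
})

test_that("a pure tone localises at its frequency bin in every frame", {
  spec <- compute_spectrogram(tone(100))
  argmax <- apply(spec$power, 1L, which.max)
  expect_true(all(spec$bin_centres_hz[argmax] == 100))
})

test_that("too-short recordings and wrong rates are rejected", {
  expect_error(compute_spectrogram(audio_recording(rnorm(399), 4000L)),
               "too short")
  expect_error(compute_spectrogram(audio_recording(rnorm(8000), 8000L)),
               "4000 Hz")
})

test_that("band clipping to 20-400 Hz keeps exactly 39 bins, bit-exact", {
  spec <- compute_spectrogram(tone(100))
  clipped <- clip_band(spec, 20, 400)
  expect_equal(ncol(clipped$power), 39L)
  expect_equal(clipped$bin_centres_hz, seq(20, 400, by = 10))
  keep <- spec$bin_centres_hz >= 20 & spec$bin_centres_hz <= 400
  expect_identical(clipped$power, spec$power[, keep])
})

test_that("degenerate and invalid clip bands behave per contract", {
  spec <- compute_spectrogram(tone(100))
  one <- clip_band(spec, 100, 100)
  expect_equal(ncol(one$power), 1L)
  expect_equal(one$bin_centres_hz, 100)
  expect_error(clip_band(spec, 20, 2500), "outside")
})

test_that("feature scaling is standardised and amplitude-invariant", {
  # constant power -> zero-variance guard returns all zeros
  spec <- compute_spectrogram(audio_recording(rep(c(1, -1), 2000), 4000L))
  spec$power <- matrix(3.7, nrow(spec$power), ncol(spec$power))
  expect_equal(to_features(spec)$power,
               matrix(0, nrow(spec$power), ncol(spec$power)))

  # doubling input amplitude shifts log power by a constant, removed by
  # standardisation
  set.seed(3)
  x <- rnorm(4000)
  f1 <- to_features(clip_band(compute_spectrogram(audio_recording(x, 4000L))))
  f2 <- to_features(clip_band(compute_spectrogram(audio_recording(2 * x, 4000L))))
  expect_equal(f1$power, f2$power, tolerance = 1e-8)

  # standardised output has zero mean, unit variance
  expect_equal(mean(f1$power), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(f1$power)), 1, tolerance = 1e-12)
})

test_that("total spectrogram power grows linearly with input power", {
  set.seed(4)
  x <- rnorm(8000)
  p1 <- sum(compute_spectrogram(audio_recording(x, 4000L))$power)
  p2 <- sum(compute_spectrogram(audio_recording(2 * x, 4000L))$power)
  expect_equal(p2 / p1, 4, tolerance = 1e-10)
})

test_that("feature energy peaks align with synthesised stertor events", {
  ev <- synth_stertor_events(10, 3L, seed = 21L)
  expect_gt(nrow(ev$schedule), 0L)
  rec <- normalise_peak(audio_recording(ev$waveform + rnorm(40000, sd = 1e-3),
                                        4000L))
  spec <- clip_band(compute_spectrogram(rec), 20, 400)
  frame_energy <- rowSums(spec$power)
  in_event <- vapply(spec$frame_times_s, function(tt) {
    any(tt >= ev$schedule$start - 0.05 & tt <= ev$schedule$end + 0.05)
  }, logical(1))
  expect_true(any(in_event) && any(!in_event))
  expect_gt(mean(frame_energy[in_event]), 10 * mean(frame_energy[!in_event]))
  # the strongest frame lies within one hop of a scheduled event
  expect_true(in_event[which.max(frame_energy)])
})

test_that("the full front end yields the documented feature geometry", {
  rec <- audio_recording(rnorm(12 * 4000L), 4000L)
  expect_equal(dim(extract_features(rec, 10)), c(199L, 39L))
  expect_equal(dim(extract_features(rec, 5)), c(99L, 39L))
})
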