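#' Synthetic cohort configuration
#'
#' Settings for the seeded generator of stethoscope-like recordings and
#' their manifest. The defaults emulate the real cohort's published
#' marginal distributions (encounter-level BOAS grades 47/112/157/58,
#' breeds Pug/Bulldog/French Bulldog/Other 87/56/189/42, the corresponding
#' sex and body-condition margins, and a 78/374 post-operative fraction),
#' with acoustics built from three ingredients: broadband breathing noise
#' under a semi-periodic respiratory envelope, harmonic stertor bursts
#' whose salience grows with grade, and low-level sensor noise.
#'
#' Grade-dependent salience acts on event rate, event duration and
#' event-to-noise amplitude together, so mild grades are genuinely sparse
#' and quiet rather than merely attenuated.
#'
#' @param n_dogs Number of dogs.
#' @param encounters_per_dog Encounters per dog (default 1).
#' @param phases Recording phases per encounter (default pre + post).
#' @param duration_s Recording length in seconds (default 10).
#' @param sample_rate_hz Sampling rate (default 4000).
#' @param grade_marginals Probabilities of BOAS grades 0..3.
#' @param breed_marginals,sex_marginals,bcs_marginals Covariate marginals.
#' @param post_op_prob Probability an encounter is post-operative.
#' @param grade_jitter_p Probability the pre-exercise stertor grade sits one
#'   grade below the encounter BOAS grade (post-exercise equals it, so the
#'   post grade is never below the pre grade).
#' @param stertor_params Per-grade event parameters: `rate` (events/s),
#'   `dur_range` (s), `amp` (peak amplitude); plus shared `f0_range` (Hz),
#'   `n_harmonics_range`, `harmonic_decay`.
#' @param breathing_params Respiratory noise parameters: `rate_range`
#'   (breaths/s), `noise_band` (Hz), `amplitude`, `irregular` (mix shallow
#'   and intermittent deeper breaths), `deep_prob`, `deep_gain`.
#' @param sensor_noise_amp White sensor-noise amplitude.
#' @param seed Master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_dogs = 100L, encounters_per_dog = 1L,
                         phases = c("pre", "post"),
                         duration_s = 10, sample_rate_hz = 4000L,
                         grade_marginals = c(47, 112, 157, 58) / 374,
                         breed_marginals = c(Pug = 87, Bulldog = 56,
                                             `French Bulldog` = 189,
                                             Other = 42) / 374,
                         sex_marginals = c(`female intact` = 67,
                                           `female neutered` = 76,
                                           `male intact` = 118,
                                           `male neutered` = 88) / 349,
                         bcs_marginals = c(`1-3` = 8, `4-6` = 276,
                                           `7-9` = 65) / 349,
                         post_op_prob = 78 / 374,
                         grade_jitter_p = 0.25,
                         stertor_params = default_stertor_params(),
                         breathing_params = default_breathing_params(),
                         sensor_noise_amp = 0.01,
                         seed = 1L) {
  stopifnot(abs(sum(grade_marginals) - 1) < 1e-8, n_dogs >= 1,
            all(phases %in% c("pre", "post")))
  structure(as.list(environment()), class = "synth_config")
}

#' @rdname synth_config
#' @export
default_stertor_params <- function() {
  list(
    f0_range = c(30, 150),
    n_harmonics_range = c(3L, 6L),
    harmonic_decay = 0.7,
    grades = list(
      `1` = list(rate = 0.35, dur_range = c(0.20, 0.50), amp = 0.08),
      `2` = list(rate = 0.65, dur_range = c(0.30, 0.80), amp = 0.20),
      `3` = list(rate = 1.00, dur_range = c(0.50, 1.20), amp = 0.45)
    )
  )
}

#' @rdname synth_config
#' @export
default_breathing_params <- function() {
  list(rate_range = c(0.25, 0.6), noise_band = c(50, 800),
       amplitude = 0.05, irregular = TRUE, deep_prob = 0.25,
       deep_gain = 2.5)
}

band_noise <- function(n, fs, band, amplitude) {
  x <- stats::rnorm(n)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / max(stats::sd(y), 1e-12) * amplitude
}

#' Synthesise breathing noise
#'
#' Band-limited Gaussian noise amplitude-modulated by a semi-periodic
#' respiratory envelope: one smooth (Hann-shaped) bump per breath over a
#' small baseline, with per-breath period jitter. In irregular mode the
#' per-breath amplitude mixes shallow breaths with intermittent deeper
#' ones, emulating the obstructive breathing pattern.
#'
#' @param duration_s Duration in seconds.
#' @param params See [default_breathing_params()].
#' @param sample_rate_hz Sampling rate.
#' @param seed Optional seed (uses the session RNG if `NULL`).
#' @return List with `waveform` and the modulating `envelope` (same
#'   length), the latter exposed so tests can count breath cycles.
#' @export
synth_breathing <- function(duration_s, params = default_breathing_params(),
                            sample_rate_hz = 4000L, seed = NULL) {
  gen <- function() {
    fs <- sample_rate_hz
    n <- as.integer(round(duration_s * fs))
    rate <- stats::runif(1, params$rate_range[1], params$rate_range[2])
    env <- rep(0.15, n)
    t0 <- 0
    while (t0 < duration_s) {
      period <- (1 / rate) * stats::runif(1, 0.9, 1.1)
      breath_dur <- 0.7 * period
      gain <- 1
      if (isTRUE(params$irregular)) {
        gain <- if (stats::runif(1) < params$deep_prob) params$deep_gain
                else stats::runif(1, 0.6, 1.0)
      }
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(floor((t0 + breath_dur) * fs), n)
      if (i0 <= n && i1 >= i0) {
        m <- i1 - i0 + 1L
        env[i0:i1] <- env[i0:i1] + gain * hann_window(m)
      }
      t0 <- t0 + period
    }
    if (params$amplitude <= 0) {
      return(list(waveform = numeric(n), envelope = env))
    }
    noise <- band_noise(n, fs, params$noise_band, params$amplitude)
    list(waveform = noise * env, envelope = env)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthesise stertor events
#'
#' Grade 0 yields silence and an empty schedule. Grades 1-3 produce
#' semi-periodic harmonic bursts: each event draws a fundamental from
#' `f0_range`, stacks harmonics with geometrically decaying amplitude
#' under a smooth Hann onset/offset envelope, and is placed with
#' gamma-distributed gaps around the grade's event rate. Higher grades
#' have more frequent, longer and louder events.
#'
#' @param duration_s Duration in seconds.
#' @param grade Stertor grade 0..3.
#' @param params See [default_stertor_params()].
#' @param sample_rate_hz Sampling rate.
#' @param seed Optional seed.
#' @return List with `waveform` and `schedule` (data frame `start`, `end`,
#'   `f0`; zero rows for grade 0).
#' @export
synth_stertor_events <- function(duration_s, grade,
                                 params = default_stertor_params(),
                                 sample_rate_hz = 4000L, seed = NULL) {
  stopifnot(grade %in% 0:3)
  gen <- function() {
    fs <- sample_rate_hz
    n <- as.integer(round(duration_s * fs))
    wave <- numeric(n)
    schedule <- data.frame(start = numeric(0), end = numeric(0),
                           f0 = numeric(0))
    if (grade == 0L) return(list(waveform = wave, schedule = schedule))
    gp <- params$grades[[as.character(grade)]]
    mean_gap <- max(1 / gp$rate - mean(gp$dur_range), 0.05)
    t0 <- stats::rgamma(1, shape = 2, scale = mean_gap / 2)
    while (TRUE) {
      dur <- stats::runif(1, gp$dur_range[1], gp$dur_range[2])
      if (t0 + dur > duration_s) break
      f0 <- stats::runif(1, params$f0_range[1], params$f0_range[2])
      nh <- sample(params$n_harmonics_range[1]:params$n_harmonics_range[2], 1L)
      i0 <- floor(t0 * fs) + 1L
      m <- as.integer(round(dur * fs))
      tt <- (0:(m - 1L)) / fs
      burst <- numeric(m)
      for (k in seq_len(nh)) {
        burst <- burst + params$harmonic_decay^(k - 1) *
          sin(2 * pi * k * f0 * tt + stats::runif(1, 0, 2 * pi))
      }
      burst <- burst / max(abs(burst)) * gp$amp * hann_window(m)
      i1 <- min(i0 + m - 1L, n)
      wave[i0:i1] <- wave[i0:i1] + burst[seq_len(i1 - i0 + 1L)]
      schedule[nrow(schedule) + 1L, ] <- list(t0, t0 + dur, f0)
      t0 <- t0 + dur + stats::rgamma(1, shape = 4, scale = mean_gap / 4)
    }
    list(waveform = wave, schedule = schedule)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# One complete recording for a stertor grade; peak-safe mixture.
synth_recording <- function(duration_s, grade, config, seed) {
  with_seed(seed, {
    br <- synth_breathing(duration_s, config$breathing_params,
                          config$sample_rate_hz)
    ev <- synth_stertor_events(duration_s, grade, config$stertor_params,
                               config$sample_rate_hz)
    n <- length(br$waveform)
    x <- br$waveform + ev$waveform +
      stats::rnorm(n, sd = config$sensor_noise_amp)
    peak <- max(abs(x))
    if (peak > 0.99) x <- x / peak * 0.99
    list(samples = x, schedule = ev$schedule)
  })
}

#' Generate a synthetic cohort of WAV recordings with a manifest
#'
#' Samples per-dog covariates and an encounter BOAS grade from the
#' configured marginals, sets each recording's stertor grade from the BOAS
#' grade (the post-exercise grade equals it; the pre-exercise grade may sit
#' one grade lower with probability `grade_jitter_p`, so the encounter
#' maximum matches the BOAS grade as the grading scheme implies), writes
#' one 16-bit mono WAV per recording and a manifest CSV conforming to the
#' [read_manifest()] schema. Stridor is recorded as grade 0 throughout (it
#' is not modelled). Byte-identical output for identical configuration.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed); WAVs go in
#'   `out_dir/audio`, the manifest in `out_dir/manifest.csv`.
#' @return List with `encounters` (as from [read_manifest()]), `manifest`
#'   (data frame), `manifest_path`, `audio_dir`, and `schedules` (per
#'   recording-id event schedules, for oracle checks).
#' @export
generate_cohort <- function(config = synth_config(), out_dir = tempfile("cohort")) {
  stopifnot(inherits(config, "synth_config"))
  audio_dir <- file.path(out_dir, "audio")
  dir.create(audio_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  schedules <- list()
  rec_counter <- 0L
  meta <- with_seed(config$seed, {
    lapply(seq_len(config$n_dogs), function(d) {
      list(
        breed = sample(names(config$breed_marginals), 1L,
                       prob = config$breed_marginals),
        sex = sample(names(config$sex_marginals), 1L,
                     prob = config$sex_marginals),
        bcs = sample(names(config$bcs_marginals), 1L,
                     prob = config$bcs_marginals),
        boas = lapply(seq_len(config$encounters_per_dog), function(e) {
          list(grade = sample(0:3, 1L, prob = config$grade_marginals),
               post_op = stats::runif(1) < config$post_op_prob,
               jitter = stats::runif(length(config$phases)) < config$grade_jitter_p)
        })
      )
    })
  })
  for (d in seq_len(config$n_dogs)) {
    dog_id <- sprintf("dog%04d", d)
    m <- meta[[d]]
    for (e in seq_len(config$encounters_per_dog)) {
      enc <- m$boas[[e]]
      encounter_id <- sprintf("%s_enc%d", dog_id, e)
      for (pi in seq_along(config$phases)) {
        phase <- config$phases[pi]
        rec_counter <- rec_counter + 1L
        stertor <- enc$grade
        if (phase == "pre" && enc$jitter[pi]) stertor <- max(stertor - 1L, 0L)
        recording_id <- sprintf("%s_%s", encounter_id, phase)
        rec_seed <- (config$seed * 100003L + rec_counter * 977L) %% 2147483647L
        rec <- synth_recording(config$duration_s, stertor, config, rec_seed)
        wav_file <- paste0(recording_id, ".wav")
        write_wav(audio_recording(rec$samples, config$sample_rate_hz,
                                  recording_id),
                  file.path(audio_dir, wav_file))
        schedules[[recording_id]] <- rec$schedule
        rows[[length(rows) + 1L]] <- data.frame(
          recording_id = recording_id, dog_id = dog_id,
          encounter_id = encounter_id, phase = phase,
          stertor_grade = stertor, stridor_grade = 0L,
          breed = m$breed, sex = m$sex, bcs_band = m$bcs,
          boas_grade = enc$grade, post_op = enc$post_op,
          wav_file = wav_file, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  list(encounters = read_manifest(manifest_path), manifest = manifest,
       manifest_path = manifest_path, audio_dir = audio_dir,
       schedules = schedules)
}
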