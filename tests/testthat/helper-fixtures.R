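# Shared fixtures, all generated in code at test time.

# Write a WAV file with explicit PCM integer samples (for decode tests and
# malformed-file cases that write_wav() itself would never produce).
write_raw_wav <- function(path, pcm, sample_rate = 4000L, n_channels = 1L,
                          bits = 16L) {
  bytes_per_sample <- bits %/% 8L
  data_size <- as.integer(bytes_per_sample * length(pcm))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(n_channels), con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * n_channels * bytes_per_sample), con,
           size = 4L, endian = "little")
  writeBin(as.integer(n_channels * bytes_per_sample), con, size = 2L,
           endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(as.integer(pcm), con, size = bytes_per_sample, endian = "little")
  path
}

# Feature matrices for synthetic recordings of given stertor grades,
# bypassing WAV round trips (direct waveform synthesis -> feature pipeline).
make_grade_features <- function(grades, seed = 1L, duration_s = 5,
                                input_length_s = 5) {
  cfg <- synth_config(seed = seed, duration_s = duration_s)
  lapply(seq_along(grades), function(i) {
    rec_seed <- (seed * 1000L + i * 131L) %% 2147483647L
    w <- stertor:::synth_recording(duration_s, grades[i], cfg, rec_seed)
    rec <- audio_recording(w$samples, 4000L, sprintf("fix%03d", i))
    extract_features(rec, input_length_s = input_length_s)
  })
}

# Small in-code encounter list with realistic covariate marginals, no audio.
make_encounters <- function(n_dogs, seed = 1L, encounters_per_dog = 1L) {
  cfg <- synth_config(n_dogs = n_dogs, seed = seed)
  rows <- stertor:::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_dogs), function(d) {
      breed <- sample(names(cfg$breed_marginals), 1L, prob = cfg$breed_marginals)
      sex <- sample(names(cfg$sex_marginals), 1L, prob = cfg$sex_marginals)
      bcs <- sample(names(cfg$bcs_marginals), 1L, prob = cfg$bcs_marginals)
      do.call(rbind, lapply(seq_len(encounters_per_dog), function(e) {
        boas <- sample(0:3, 1L, prob = cfg$grade_marginals)
        data.frame(
          recording_id = sprintf("dog%04d_enc%d_%s", d, e, c("pre", "post")),
          dog_id = sprintf("dog%04d", d),
          encounter_id = sprintf("dog%04d_enc%d", d, e),
          phase = c("pre", "post"),
          stertor_grade = c(max(boas - 1L, 0L), boas),
          stridor_grade = 0L,
          breed = breed, sex = sex, bcs_band = bcs, boas_grade = boas,
          post_op = stats::runif(1) < cfg$post_op_prob,
          wav_file = sprintf("dog%04d_enc%d_%s.wav", d, e, c("pre", "post")),
          stringsAsFactors = FALSE)
      }))
    }))
  })
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  read_manifest(path)
}

# Independent concordant-pair (Mann-Whitney) AUC oracle.
auc_by_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

# Tiny deterministic model for structural tests.
tiny_params <- function(seed = 5L, hidden = 4L, layers = 1L, input_dim = 6L) {
  h <- hyperparameter_set(hidden_size = hidden, n_recurrent_layers = layers,
                          dropout_p = 0, input_length_s = 5,
                          attention_dim = 3L, head_hidden_sizes = 5L)
  init_model(h, seed = seed, input_dim = input_dim)
}
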