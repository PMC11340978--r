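write_manifest_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}

manifest_row <- function(recording_id = "r1", dog_id = "d1",
                         encounter_id = "e1", phase = "pre",
                         stertor = 1L, breed = "Pug",
                         sex = "male intact", bcs = "4-6",
                         boas = 1L, post_op = FALSE) {
  data.frame(recording_id = recording_id, dog_id = dog_id,
             encounter_id = encounter_id, phase = phase,
             stertor_grade = stertor, stridor_grade = 0L,
             breed = breed, sex = sex, bcs_band = bcs, boas_grade = boas,
             post_op = post_op, wav_file = paste0(recording_id, ".wav"),
             stringsAsFactors = FALSE)
}

test_that("manifest rows group into encounters with validated vocabularies", {
  df <- rbind(manifest_row("r1", phase = "pre"),
              manifest_row("r2", phase = "post"))
  enc <- read_manifest(write_manifest_csv(df))
  expect_length(enc, 1L)
  expect_equal(nrow(enc[[1]]$recordings), 2L)
  expect_equal(enc[[1]]$dog_id, "d1")
  expect_equal(enc[[1]]$boas_grade, 1L)
})

test_that("unknown breeds map to Other with a warning; bad values error", {
  df <- manifest_row(breed = "Beagle")
  expect_warning(enc <- read_manifest(write_manifest_csv(df)), "Other")
  expect_equal(enc[[1]]$breed, "Other")

  dup <- rbind(manifest_row("r1"), manifest_row("r1", phase = "post"))
  expect_error(read_manifest(write_manifest_csv(dup)), "duplicate")

  bad_sex <- manifest_row(sex = "unknown")
  expect_error(read_manifest(write_manifest_csv(bad_sex)), "sex")

  bad_phase <- manifest_row(phase = "during")
  expect_error(read_manifest(write_manifest_csv(bad_phase)), "phase")

  two_pre <- rbind(manifest_row("r1", phase = "pre"),
                   manifest_row("r2", phase = "pre"))
  expect_error(read_manifest(write_manifest_csv(two_pre)), "phases")
})

test_that("five identical dogs land one per fold", {
  df <- do.call(rbind, lapply(1:5, function(d) {
    manifest_row(sprintf("r%d", d), sprintf("d%d", d), sprintf("e%d", d))
  }))
  enc <- read_manifest(write_manifest_csv(df))
  fa <- assign_folds(enc, n_folds = 5L, seed = 1L)
  expect_setequal(as.integer(fa), 1:5)
})

test_that("fold assignment is deterministic and rejects too few dogs", {
  enc <- make_encounters(12L, seed = 41L)
  f1 <- assign_folds(enc, seed = 9L)
  f2 <- assign_folds(enc, seed = 9L)
  expect_identical(f1, f2)
  expect_error(assign_folds(enc[1:3], n_folds = 5L), "fewer dogs")
})

test_that("stratified minimisation balances covariates within 10 points", {
  enc <- make_encounters(100L, seed = 42L)
  fa <- assign_folds(enc, n_folds = 5L, seed = 13L)
  dogs <- stertor:::dog_table(enc)
  folds <- fa[dogs$dog_id]
  for (v in c("sex", "breed", "bcs_band", "boas_grade")) {
    global <- prop.table(table(dogs[[v]]))
    for (f in 1:5) {
      local <- prop.table(table(dogs[[v]][folds == f]))
      expect_true(all(abs(local - global) <= 0.10),
                  info = sprintf("variable %s fold %d", v, f))
    }
  }
  # fold sizes stay near-equal
  expect_lte(diff(range(table(folds))), 1)
})

test_that("minimisation balances better than naive random assignment", {
  enc <- make_encounters(100L, seed = 43L)
  dogs <- stertor:::dog_table(enc)
  imbalance <- function(folds) {
    sum(vapply(c("sex", "breed", "bcs_band", "boas_grade"), function(v) {
      cm <- table(folds, dogs[[v]])
      sum(apply(cm, 2L, function(col) max(col) - min(col)))
    }, numeric(1)))
  }
  strat <- imbalance(assign_folds(enc, seed = 3L)[dogs$dog_id])
  rand <- stertor:::with_seed(3L, {
    replicate(20, imbalance(sample(rep_len(1:5, nrow(dogs)))))
  })
  expect_lt(strat, mean(rand))
})

test_that("nested CV emits repeats x folds runs partitioning the cohort", {
  enc <- make_encounters(25L, seed = 44L)
  runs <- nested_cv(enc, config = nested_cv_config(n_repeats = 2L),
                    master_seed = 5L, dry_run = TRUE)
  expect_length(runs, 10L)
  all_ids <- stertor:::encounters_to_df(enc)$recording_id
  for (r in 1:2) {
    rr <- Filter(function(x) x$repeat_index == r, runs)
    tested <- unlist(lapply(rr, function(x) x$predictions$recording_id))
    expect_setequal(tested, all_ids)
    expect_equal(length(tested), length(all_ids))  # exactly once
  }
})

test_that("no dog appears in both train and test of any run", {
  enc <- make_encounters(20L, seed = 45L)
  runs <- nested_cv(enc, config = nested_cv_config(n_repeats = 3L),
                    master_seed = 6L, dry_run = TRUE)
  for (run in runs) {
    expect_length(intersect(run$train_dog_ids, run$test_dog_ids), 0L)
    expect_true(all(run$predictions$dog_id %in% run$test_dog_ids))
  }
})

test_that("dry-run nested CV is reproducible from the master seed", {
  enc <- make_encounters(15L, seed = 46L)
  r1 <- nested_cv(enc, config = nested_cv_config(n_repeats = 1L),
                  master_seed = 2L, dry_run = TRUE)
  r2 <- nested_cv(enc, config = nested_cv_config(n_repeats = 1L),
                  master_seed = 2L, dry_run = TRUE)
  expect_identical(lapply(r1, `[[`, "test_dog_ids"),
                   lapply(r2, `[[`, "test_dog_ids"))
})
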