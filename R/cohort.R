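BREED_LEVELS <- c("Pug", "Bulldog", "French Bulldog", "Other")
SEX_LEVELS <- c("female intact", "female neutered", "male intact", "male neutered")
BCS_LEVELS <- c("1-3", "4-6", "7-9")
PHASE_LEVELS <- c("pre", "post")

#' Read a cohort manifest
#'
#' The manifest is a CSV with one row per recording and columns
#' `recording_id`, `dog_id`, `encounter_id`, `phase` (`pre`/`post`),
#' `stertor_grade`, `stridor_grade` (0-3), `breed`, `sex`, `bcs_band`,
#' `boas_grade`, `post_op` (logical), `wav_file` (path relative to the
#' audio directory). Rows are grouped into encounters; unknown breeds are
#' mapped to `"Other"` with a warning, other vocabulary violations and
#' duplicate recording IDs are errors.
#'
#' @param path Manifest CSV path.
#' @return List of `encounter` objects: each has the encounter covariates
#'   plus a `recordings` data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("recording_id", "dog_id", "encounter_id", "phase",
                "stertor_grade", "stridor_grade", "breed", "sex",
                "bcs_band", "boas_grade", "post_op", "wav_file")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$recording_id)) {
    dup <- unique(df$recording_id[duplicated(df$recording_id)])
    stop("duplicate recording_id in manifest: ", paste(dup, collapse = ", "))
  }
  unknown_breed <- !(df$breed %in% BREED_LEVELS)
  if (any(unknown_breed)) {
    warning("unknown breed value(s) mapped to 'Other': ",
            paste(unique(df$breed[unknown_breed]), collapse = ", "))
    df$breed[unknown_breed] <- "Other"
  }
  if (any(!df$sex %in% SEX_LEVELS)) {
    stop("unknown sex value(s): ",
         paste(setdiff(unique(df$sex), SEX_LEVELS), collapse = ", "))
  }
  if (any(!df$bcs_band %in% BCS_LEVELS)) {
    stop("unknown bcs_band value(s): ",
         paste(setdiff(unique(df$bcs_band), BCS_LEVELS), collapse = ", "))
  }
  if (any(!df$phase %in% PHASE_LEVELS)) {
    stop("unknown phase value(s): ",
         paste(setdiff(unique(df$phase), PHASE_LEVELS), collapse = ", "))
  }
  for (col in c("stertor_grade", "stridor_grade", "boas_grade")) {
    if (any(!df[[col]] %in% 0:3)) stop(col, " values must be in 0..3")
  }
  df$post_op <- as.logical(df$post_op)

  encounters <- lapply(split(df, df$encounter_id), function(sub) {
    if (length(unique(sub$dog_id)) != 1L) {
      stop("encounter ", sub$encounter_id[1L], " spans multiple dogs")
    }
    phases <- sub$phase
    if (anyDuplicated(phases)) {
      stop("encounter ", sub$encounter_id[1L], " has duplicated phases")
    }
    structure(
      list(dog_id = sub$dog_id[1L],
           encounter_id = sub$encounter_id[1L],
           breed = sub$breed[1L], sex = sub$sex[1L],
           bcs_band = sub$bcs_band[1L],
           boas_grade = as.integer(sub$boas_grade[1L]),
           post_op = sub$post_op[1L],
           recordings = sub[, c("recording_id", "phase", "stertor_grade",
                                "stridor_grade", "wav_file")]),
      class = "encounter"
    )
  })
  unname(encounters)
}

encounters_to_df <- function(encounters) {
  do.call(rbind, lapply(encounters, function(e) {
    data.frame(dog_id = e$dog_id, encounter_id = e$encounter_id,
               breed = e$breed, sex = e$sex, bcs_band = e$bcs_band,
               boas_grade = e$boas_grade, post_op = e$post_op,
               recording_id = e$recordings$recording_id,
               phase = e$recordings$phase,
               stertor_grade = e$recordings$stertor_grade,
               stridor_grade = e$recordings$stridor_grade,
               wav_file = e$recordings$wav_file,
               stringsAsFactors = FALSE)
  }))
}

# One covariate row per dog (first encounter's values) for fold balancing.
dog_table <- function(encounters) {
  df <- encounters_to_df(encounters)
  df <- df[!duplicated(df$dog_id), c("dog_id", "breed", "sex", "bcs_band",
                                     "boas_grade")]
  df$boas_grade <- factor(df$boas_grade, levels = 0:3)
  df$breed <- factor(df$breed, levels = BREED_LEVELS)
  df$sex <- factor(df$sex, levels = SEX_LEVELS)
  df$bcs_band <- factor(df$bcs_band, levels = BCS_LEVELS)
  df
}

#' Covariate-balanced fold assignment by stratified minimisation
#'
#' Assigns whole dogs (all their encounters and recordings move together,
#' preventing identity leakage between training and test) to `n_folds`
#' folds. Dogs are processed in a seeded random order; each is placed in
#' the fold that minimises the summed marginal imbalance — the
#' Pocock-Simon-style sum over the balancing variables (sex, breed,
#' body-condition band, BOAS grade) of the range of category counts across
#' folds after placement — with fold size as the final balancer and
#' remaining ties broken uniformly at random.
#'
#' @param encounters List of encounters from [read_manifest()].
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `fold_assignment`: named integer vector mapping `dog_id` to a
#'   fold in `1..n_folds`, with attribute `n_folds`.
#' @export
assign_folds <- function(encounters, n_folds = 5L, seed = 1L) {
  dogs <- dog_table(encounters)
  n_dogs <- nrow(dogs)
  if (n_dogs < n_folds) {
    stop("fewer dogs (", n_dogs, ") than folds (", n_folds, ")")
  }
  vars <- c("sex", "breed", "bcs_band", "boas_grade")
  # counts[[v]]: folds x categories
  counts <- lapply(vars, function(v) {
    matrix(0L, n_folds, nlevels(dogs[[v]]))
  })
  names(counts) <- vars
  sizes <- integer(n_folds)
  assignment <- integer(n_dogs)

  with_seed(seed, {
    ord <- sample.int(n_dogs)
    for (i in ord) {
      imb <- vapply(seq_len(n_folds), function(f) {
        tot <- 0
        for (v in vars) {
          cm <- counts[[v]]
          ci <- as.integer(dogs[[v]][i])
          cm[f, ci] <- cm[f, ci] + 1L
          tot <- tot + sum(apply(cm, 2L, function(col) max(col) - min(col)))
        }
        tot
      }, numeric(1))
      cand <- which(imb == min(imb))
      cand <- cand[sizes[cand] == min(sizes[cand])]
      f <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      assignment[i] <- f
      sizes[f] <- sizes[f] + 1L
      for (v in vars) {
        ci <- as.integer(dogs[[v]][i])
        counts[[v]][f, ci] <- counts[[v]][f, ci] + 1L
      }
    }
  })
  out <- assignment
  names(out) <- dogs$dog_id
  attr(out, "n_folds") <- as.integer(n_folds)
  class(out) <- "fold_assignment"
  out
}

#' Nested cross-validation configuration
#'
#' Protocol settings for [nested_cv()]. The defaults follow the full
#' evaluation protocol (10 repeats x 5 folds = 50 runs, 20 random-search
#' candidates); scale `n_repeats`, `n_iter` and the training budget down
#' for exploratory runs.
#'
#' @param n_repeats Outer repeats (fresh stratification each; default 10).
#' @param n_folds Folds per repeat (default 5).
#' @param n_iter Random-search candidates per outer fold (default 20).
#' @param space [search_space()] to sample from.
#' @param training [training_config()] for inner candidate training.
#' @param final_training [training_config()] for the final per-fold model
#'   (no validation split; early stopping inactive).
#' @param threshold Ordinal decoding threshold.
#' @param combine Encounter combination method, `"mean"` or `"max"`.
#' @param feature_scale `"log"` or `"linear"` spectrogram amplitude scale.
#' @return A config list.
#' @export
nested_cv_config <- function(n_repeats = 10L, n_folds = 5L, n_iter = 20L,
                             space = search_space(),
                             training = training_config(),
                             final_training = training,
                             threshold = 0.5, combine = "mean",
                             feature_scale = "log") {
  list(n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
       n_iter = as.integer(n_iter), space = space, training = training,
       final_training = final_training, threshold = threshold,
       combine = combine, feature_scale = feature_scale)
}

#' Scaled-down nested-CV protocol
#'
#' A desk-scale variant of the full protocol for synthetic-cohort
#' experiments on a single CPU: one outer repeat, 5 folds, 5 random-search
#' candidates drawn from a reduced space (hidden size 16 or 32, one
#' bidirectional layer, dropout up to 0.3, 5-second inputs), and a 30-epoch
#' training budget with early-stopping patience 5 on the inner folds. The
#' synthetic task is separable by construction, so this budget suffices for
#' the pipeline to demonstrate recovery; scale `n_repeats`/`n_iter`/epochs
#' up for the full protocol on real cohorts.
#'
#' @param n_repeats,n_iter Override the reduced defaults if desired.
#' @return A [nested_cv_config()].
#' @export
scaled_protocol_config <- function(n_repeats = 1L, n_iter = 5L) {
  nested_cv_config(
    n_repeats = n_repeats, n_folds = 5L, n_iter = n_iter,
    space = search_space(hidden_size = c(16L, 32L), n_recurrent_layers = 1L,
                         dropout_range = c(0, 0.3), attention_dim = 16L,
                         head_options = list(32L), input_length_s = 5),
    training = training_config(epochs = 30L, batch_size = 32L, patience = 5L),
    final_training = training_config(epochs = 30L, batch_size = 32L))
}

# Feature cache: recording_id -> feature matrix, one cache per input length
# appearing in the search space.
featurize_cohort <- function(rec_df, audio_dir, lengths, scale = "log") {
  caches <- list()
  for (len in lengths) {
    feats <- lapply(seq_len(nrow(rec_df)), function(i) {
      rec <- read_wav(file.path(audio_dir, rec_df$wav_file[i]),
                      recording_id = rec_df$recording_id[i])
      extract_features(rec, input_length_s = len, scale = scale)
    })
    names(feats) <- rec_df$recording_id
    caches[[as.character(len)]] <- feats
  }
  caches
}

#' Nested cross-validation over a cohort
#'
#' For each of `n_repeats` outer repetitions: a fresh seeded stratified
#' minimisation splits the dogs into `n_folds` folds; each fold in turn is
#' held out as the test fold while a random hyperparameter search with
#' 4-fold inner cross-validation runs on the remaining folds; the best
#' hyperparameters then train a single model on all training folds, which
#' predicts the untouched test fold. Emits `n_repeats * n_folds` run
#' results, each with its own optimised hyperparameters and per-recording
#' test predictions. Fully reproducible from `master_seed`.
#'
#' @param encounters Encounter list from [read_manifest()] or
#'   [generate_cohort()].
#' @param audio_dir Directory containing the WAV files named in the
#'   manifest.
#' @param config A [nested_cv_config()].
#' @param master_seed Integer seed for the whole protocol.
#' @param dry_run If `TRUE`, only the fold structure is computed: runs
#'   carry test membership but no trained model or outputs. Used to verify
#'   protocol arithmetic cheaply.
#' @param verbose Progress messages.
#' @return List of `stertor_run` objects with fields `repeat_index`,
#'   `fold_index`, `hyperparameters`, `search`, `predictions` (data frame),
#'   `train_dog_ids`, `test_dog_ids`.
#' @export
nested_cv <- function(encounters, audio_dir = NULL,
                      config = nested_cv_config(), master_seed = 1L,
                      dry_run = FALSE, verbose = FALSE) {
  rec_df <- encounters_to_df(encounters)
  caches <- NULL
  if (!dry_run) {
    if (is.null(audio_dir)) stop("audio_dir is required unless dry_run = TRUE")
    lengths <- unique(config$space$input_length_s)
    if (verbose) message("extracting features for input lengths: ",
                         paste(lengths, collapse = ", "), " s")
    caches <- featurize_cohort(rec_df, audio_dir, lengths,
                               scale = config$feature_scale)
  }
  runs <- list()
  for (r in seq_len(config$n_repeats)) {
    strat_seed <- (master_seed + 7919L * r) %% 2147483647L
    fa <- assign_folds(encounters, n_folds = config$n_folds, seed = strat_seed)
    rec_fold <- fa[rec_df$dog_id]
    for (f in seq_len(config$n_folds)) {
      test_idx <- which(rec_fold == f)
      train_idx <- which(rec_fold != f)
      if (length(test_idx) == 0L) {
        stop("empty test fold in repeat ", r, ", fold ", f)
      }
      run <- tryCatch(
        run_one_fold(rec_df, caches, rec_fold, r, f, config,
                     seed = (master_seed + 104729L * r + 31L * f) %% 2147483647L,
                     dry_run = dry_run, verbose = verbose),
        error = function(e) {
          stop("nested CV failed at repeat ", r, ", fold ", f, ": ",
               conditionMessage(e))
        })
      runs[[length(runs) + 1L]] <- run
    }
  }
  runs
}

run_one_fold <- function(rec_df, caches, rec_fold, r, f, config, seed,
                         dry_run, verbose) {
  test_idx <- which(rec_fold == f)
  train_folds <- setdiff(sort(unique(rec_fold)), f)
  test_df <- rec_df[test_idx, , drop = FALSE]
  train_df <- rec_df[rec_fold != f, , drop = FALSE]

  base <- list(repeat_index = r, fold_index = f,
               train_dog_ids = unique(train_df$dog_id),
               test_dog_ids = unique(test_df$dog_id))
  if (dry_run) {
    preds <- test_df[, c("recording_id", "dog_id", "encounter_id", "phase",
                         "post_op", "stertor_grade", "boas_grade")]
    return(structure(c(base, list(hyperparameters = NULL, search = NULL,
                                  predictions = preds)),
                     class = "stertor_run"))
  }

  # inner 4-fold CV reuses the outer stratified folds
  grades_by_fold <- lapply(train_folds, function(g) {
    as.integer(rec_df$stertor_grade[rec_fold == g])
  })
  features_by_length <- lapply(caches, function(cache) {
    lapply(train_folds, function(g) {
      unname(cache[rec_df$recording_id[rec_fold == g]])
    })
  })
  if (verbose) message("repeat ", r, " fold ", f, ": random search (",
                       config$n_iter, " candidates)")
  search <- random_search(features_by_length, grades_by_fold, config$space,
                          n_iter = config$n_iter, seed = seed,
                          config = config$training)
  best <- search$best

  cache <- caches[[as.character(best$input_length_s)]]
  fit <- train_model(unname(cache[train_df$recording_id]),
                     as.integer(train_df$stertor_grade), best,
                     seed = seed + 1L, config = config$final_training)
  test_feats <- unname(cache[test_df$recording_id])
  probs <- cpp_net_forward(fit$params, features_to_cube(test_feats))$probs
  preds <- test_df[, c("recording_id", "dog_id", "encounter_id", "phase",
                       "post_op", "stertor_grade", "boas_grade")]
  preds$o0 <- probs[, 1L]; preds$o1 <- probs[, 2L]
  preds$o2 <- probs[, 3L]; preds$o3 <- probs[, 4L]
  preds$severity <- severity_score(probs)
  preds$decoded_grade <- decode_outputs(probs, config$threshold)
  structure(c(base, list(hyperparameters = best, search = search$results,
                         predictions = preds, model = fit)),
            class = "stertor_run")
}

#' @export
print.stertor_run <- function(x, ...) {
  cat(sprintf("<stertor_run: repeat %d fold %d, %d test recordings%s>\n",
              x$repeat_index, x$fold_index, nrow(x$predictions),
              if (is.null(x$hyperparameters)) " (dry run)" else ""))
  invisible(x)
}

#' Evaluate nested cross-validation runs
#'
#' Builds per-run ROC curves for the recording-level binary stertor task
#' (moderate/severe vs none/mild, scored by the continuous severity) and
#' the encounter-level BOAS task (predictions combined per encounter), then
#' vertically averages the curves and pools all test predictions for a
#' pooled ROC. Post-operative encounters are excluded from the reported
#' metrics by default. Runs whose test fold lacks one of the two classes
#' contribute predictions to the pooled analysis but no individual curve.
#'
#' @param runs List of `stertor_run` objects from [nested_cv()].
#' @param include_post_op Keep post-operative encounters (default `FALSE`).
#' @param combine Encounter combination method.
#' @param threshold Decoding threshold used for hard grades.
#' @return List with `recording` and `encounter` sublists (each:
#'   `curves`, `mean_curve`, `auc_mean`, `auc_sd`, `pooled_curve`,
#'   `pooled_auc`, `operating_points`), and `per_class` metrics averaged
#'   over runs (encounter level).
#' @export
evaluate_runs <- function(runs, include_post_op = FALSE, combine = "mean",
                          threshold = 0.5) {
  stopifnot(length(runs) >= 1L)
  rec_scores <- list(); rec_labels <- list()
  enc_scores <- list(); enc_labels <- list()
  per_class_runs <- list()
  for (i in seq_along(runs)) {
    p <- runs[[i]]$predictions
    if (!include_post_op) p <- exclude_post_op(p)
    if (nrow(p) == 0L) next
    rec_scores[[length(rec_scores) + 1L]] <- p$severity
    rec_labels[[length(rec_labels) + 1L]] <- as.integer(p$stertor_grade >= 2L)
    enc <- aggregate_encounters(p, method = combine, threshold = threshold)
    enc_scores[[length(enc_scores) + 1L]] <- enc$severity
    enc_labels[[length(enc_labels) + 1L]] <- as.integer(enc$boas_grade >= 2L)
    per_class_runs[[length(per_class_runs) + 1L]] <-
      per_class_metrics(enc$grade, enc$boas_grade)
  }
  level_summary <- function(scores, labels) {
    curves <- list()
    for (j in seq_along(scores)) {
      if (length(unique(labels[[j]])) == 2L) {
        curves[[length(curves) + 1L]] <- roc_and_auc(scores[[j]], labels[[j]])
      }
    }
    pooled <- roc_and_auc(unlist(scores), unlist(labels))
    aucs <- vapply(curves, `[[`, numeric(1), "auc")
    mean_curve <- if (length(curves)) vertical_average(curves) else NULL
    list(curves = curves, mean_curve = mean_curve,
         auc_mean = if (length(aucs)) mean(aucs) else NA_real_,
         auc_sd = if (length(aucs) > 1L) stats::sd(aucs) else NA_real_,
         pooled_curve = pooled, pooled_auc = pooled$auc,
         operating_points = list(
           youden = operating_point(pooled, "youden"),
           high_sensitivity = operating_point(pooled, "high_sensitivity")))
  }
  list(recording = level_summary(rec_scores, rec_labels),
       encounter = level_summary(enc_scores, enc_labels),
       per_class = if (length(per_class_runs)) {
         summarise_per_class(per_class_runs)
       } else NULL)
}
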