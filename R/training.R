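#' Training configuration defaults
#'
#' Optimisation settings around the AdamW loop. The learning rate lives on
#' the [hyperparameter_set()]; everything else is fixed protocol: epoch
#' budget with optional early stopping on validation loss, mini-batching,
#' and decoupled weight decay.
#'
#' @param epochs Maximum epochs (default 100).
#' @param batch_size Mini-batch size (default 16).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 15; ignored without a validation set).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param class_weighting If `TRUE`, epochs draw examples with replacement
#'   with probability inversely proportional to their grade's frequency.
#'   Off by default: the cohort's skew towards grades 1-2 is part of the
#'   modelled task.
#' @return A list of settings.
#' @export
training_config <- function(epochs = 100L, batch_size = 16L, patience = 15L,
                            weight_decay = 0.01, class_weighting = FALSE) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       patience = as.integer(patience), weight_decay = weight_decay,
       class_weighting = isTRUE(class_weighting))
}

adamw_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adamw_step <- function(theta, grad, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

# Mean ordinal loss of a parameter set over a feature cube (no dropout).
eval_loss <- function(params, x, targets) {
  cpp_net_loss_grad(params, x, targets, 0, 0L)$loss
}

#' Train the stertor network
#'
#' Minimises the mean per-position sigmoid binary cross-entropy over the
#' cumulative ordinal targets with AdamW (learning rate from the
#' hyperparameter set, default 0.001), in shuffled mini-batches. When a
#' validation set is supplied, the parameters with the best validation loss
#' are kept and training stops early after `patience` epochs without
#' improvement. Fully reproducible given `seed`.
#'
#' @param features List of `[n_frames x 39]` feature matrices (equal shapes).
#' @param grades Integer stertor grades in 0..3, one per feature matrix.
#' @param h A [hyperparameter_set()].
#' @param seed Integer seed controlling initialisation, shuffling, dropout.
#' @param config A [training_config()].
#' @param val_features,val_grades Optional validation split.
#' @param verbose Print per-epoch losses.
#' @return A `stertor_model` list: `params`, `history` (per-epoch data frame
#'   of training and validation loss), `h`, `seed`.
#' @export
train_model <- function(features, grades, h, seed = 1L,
                        config = training_config(),
                        val_features = NULL, val_grades = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(h, "hyperparameter_set"))
  n <- length(features)
  if (n == 0L) stop("empty training set")
  stopifnot(length(grades) == n, all(grades %in% 0:3))
  if (length(unique(grades)) == 1L) {
    message("training set contains a single stertor grade (", grades[1L],
            "); the fitted model cannot discriminate grades")
  }
  x_all <- features_to_cube(features)
  y_all <- encode_grade(grades)
  if (n == 1L) y_all <- matrix(y_all, nrow = 1L)
  weights <- rep(1, n)
  if (config$class_weighting) {
    freq <- table(factor(grades, levels = 0:3))
    w <- 1 / pmax(as.numeric(freq), 1)
    weights <- w[grades + 1L] * n / sum(w[grades + 1L])
  }
  has_val <- !is.null(val_features)
  if (has_val) {
    xv <- features_to_cube(val_features)
    yv <- encode_grade(val_grades)
    if (length(val_features) == 1L) yv <- matrix(yv, nrow = 1L)
  }

  params <- init_model(h, seed = seed, input_dim = dim(x_all)[2L])
  theta <- flatten_params(params)
  opt <- adamw_init(length(theta))
  lr <- h$learning_rate
  n_batches <- ceiling(n / config$batch_size)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  wait <- 0L
  step_seed <- (as.integer(seed) %% 100000L) * 10000L

  with_seed(seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (config$class_weighting) {
        sample.int(n, n, replace = TRUE, prob = weights)
      } else {
        sample.int(n)
      }
      epoch_loss <- 0
      for (b in seq_len(n_batches)) {
        idx <- ord[(((b - 1L) * config$batch_size) + 1L):min(b * config$batch_size, n)]
        xb <- x_all[idx, , , drop = FALSE]
        yb <- y_all[idx, , drop = FALSE]
        step_seed <- (step_seed + 1L) %% 2147483647L
        res <- cpp_net_loss_grad(unflatten_params(theta, params), xb, yb,
                                 h$dropout_p, step_seed)
        g <- unlist(res$grads, use.names = FALSE)
        upd <- adamw_step(theta, g, opt, lr, config$weight_decay)
        theta <- upd$theta
        opt <- upd$state
        epoch_loss <- epoch_loss + res$loss * length(idx)
      }
      epoch_loss <- epoch_loss / n
      vl <- NA_real_
      if (has_val) {
        vl <- eval_loss(unflatten_params(theta, params), xv, yv)
        if (vl < best$loss - 1e-8) {
          best <- list(loss = vl, theta = theta, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      history[nrow(history) + 1L, ] <- list(epoch, epoch_loss, vl)
      if (verbose) {
        cat(sprintf("epoch %3d  train %.4f  val %s\n", epoch, epoch_loss,
                    if (is.na(vl)) "-" else sprintf("%.4f", vl)))
      }
      if (has_val && wait >= config$patience) break
    }
  })
  final_theta <- if (has_val && is.finite(best$loss)) best$theta else theta
  structure(
    list(params = unflatten_params(final_theta, params), history = history,
         h = h, seed = as.integer(seed)),
    class = "stertor_model"
  )
}

#' @export
print.stertor_model <- function(x, ...) {
  cat(sprintf(
    "<stertor_model: H=%d, layers=%d, dropout=%.2f, %d epochs trained>\n",
    x$h$hidden_size, x$h$n_recurrent_layers, x$h$dropout_p, nrow(x$history)
  ))
  invisible(x)
}

#' Default random-search space
#'
#' Ranges for the architecture hyperparameters explored by
#' [random_search()]. Each component is the set (or range, for dropout) the
#' sampler draws from uniformly.
#'
#' @param hidden_size,n_recurrent_layers,attention_dim,input_length_s
#'   Candidate values.
#' @param dropout_range Interval for the dropout probability.
#' @param head_options List of head hidden-size vectors.
#' @return A `search_space` list.
#' @export
search_space <- function(hidden_size = c(16L, 32L, 64L, 128L),
                         n_recurrent_layers = c(1L, 2L),
                         dropout_range = c(0, 0.5),
                         attention_dim = c(16L, 32L, 64L),
                         head_options = list(32L, 64L, c(64L, 32L)),
                         input_length_s = c(5, 10)) {
  structure(list(hidden_size = hidden_size,
                 n_recurrent_layers = n_recurrent_layers,
                 dropout_range = dropout_range,
                 attention_dim = attention_dim,
                 head_options = head_options,
                 input_length_s = input_length_s),
            class = "search_space")
}

sample_hyperparameters <- function(space, n) {
  pick <- function(v) v[sample.int(length(v), 1L)]
  lapply(seq_len(n), function(i) {
    hyperparameter_set(
      hidden_size = pick(space$hidden_size),
      n_recurrent_layers = pick(space$n_recurrent_layers),
      dropout_p = stats::runif(1, space$dropout_range[1], space$dropout_range[2]),
      input_length_s = pick(space$input_length_s),
      attention_dim = pick(space$attention_dim),
      head_hidden_sizes = space$head_options[[sample.int(length(space$head_options), 1L)]]
    )
  })
}

n_params_of <- function(h, input_dim = 39L) {
  H <- h$hidden_size
  tot <- 0L
  din <- input_dim
  for (l in seq_len(h$n_recurrent_layers)) {
    tot <- tot + 2L * (3L * H * din + 3L * H * H + 6L * H)
    din <- 2L * H
  }
  tot <- tot + h$attention_dim * (2L * H + 2L)
  sizes <- c(2L * H, h$head_hidden_sizes, 4L)
  tot + sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
}

# Severity scores of a trained parameter set on a feature list.
severities_of <- function(params, features) {
  x <- features_to_cube(features)
  severity_score(cpp_net_forward(params, x)$probs)
}

#' Random hyperparameter search over an inner cross-validation
#'
#' Samples `n_iter` hyperparameter sets uniformly from the space (seeded).
#' Each candidate is trained on 3 of the 4 supplied folds and validated on
#' the 4th, rotating over all folds; the candidate with the highest mean
#' validation AUC on the binary task "stertor grade >= 2" wins. Validation
#' folds with a single class contribute no AUC; a candidate with no usable
#' fold falls back to (negated) mean validation loss. Ties are broken by
#' smaller parameter count, then by sampling order.
#'
#' @param folds List of 4 folds, each a list with `features` (list of
#'   matrices, already at the right input length per candidate — see
#'   `features_by_length`) and `grades`.
#' @param features_by_length Named list mapping input length (as character,
#'   e.g. `"5"`) to a list of per-fold feature lists. Allows candidates with
#'   different `input_length_s` to reuse cached features.
#' @param grades_by_fold List of per-fold grade vectors.
#' @param space A [search_space()].
#' @param n_iter Number of sampled candidates (>= 1).
#' @param seed Integer seed.
#' @param config [training_config()] used for the candidate trainings.
#' @param verbose Print per-candidate scores.
#' @return List: `best` (the winning [hyperparameter_set()]), `results`
#'   (data frame of candidate scores), `candidates`.
#' @export
random_search <- function(features_by_length, grades_by_fold, space, n_iter,
                          seed = 1L, config = training_config(),
                          verbose = FALSE) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  n_folds <- length(grades_by_fold)
  stopifnot(n_folds >= 2L)
  candidates <- with_seed(seed, sample_hyperparameters(space, n_iter))
  scores <- numeric(n_iter)
  aucs_ok <- logical(n_iter)
  for (i in seq_len(n_iter)) {
    h <- candidates[[i]]
    feats <- features_by_length[[as.character(h$input_length_s)]]
    fold_aucs <- rep(NA_real_, n_folds)
    fold_losses <- rep(NA_real_, n_folds)
    for (v in seq_len(n_folds)) {
      tr_idx <- setdiff(seq_len(n_folds), v)
      tr_feats <- do.call(c, feats[tr_idx])
      tr_grades <- do.call(c, grades_by_fold[tr_idx])
      fit <- train_model(tr_feats, tr_grades, h,
                         seed = seed + 1000L * i + v,
                         config = config,
                         val_features = feats[[v]],
                         val_grades = grades_by_fold[[v]])
      sev <- severities_of(fit$params, feats[[v]])
      lab <- as.integer(grades_by_fold[[v]] >= 2L)
      if (length(unique(lab)) == 2L) {
        fold_aucs[v] <- roc_and_auc(sev, lab)$auc
      }
      xv <- features_to_cube(feats[[v]])
      yv <- encode_grade(grades_by_fold[[v]])
      if (length(grades_by_fold[[v]]) == 1L) yv <- matrix(yv, nrow = 1L)
      fold_losses[v] <- eval_loss(fit$params, xv, yv)
    }
    if (any(!is.na(fold_aucs))) {
      scores[i] <- mean(fold_aucs, na.rm = TRUE)
      aucs_ok[i] <- TRUE
    } else {
      scores[i] <- -mean(fold_losses, na.rm = TRUE)
    }
    if (verbose) {
      cat(sprintf("candidate %d/%d: H=%d L=%d drop=%.2f len=%gs  score=%.4f\n",
                  i, n_iter, h$hidden_size, h$n_recurrent_layers, h$dropout_p,
                  h$input_length_s, scores[i]))
    }
  }
  # maximise score; ties by smaller model then sampling order
  np <- vapply(candidates, n_params_of, integer(1))
  best_i <- order(-scores, np, seq_len(n_iter))[1L]
  list(best = candidates[[best_i]],
       results = data.frame(
         candidate = seq_len(n_iter),
         score = scores,
         score_is_auc = aucs_ok,
         hidden_size = vapply(candidates, `[[`, integer(1), "hidden_size"),
         n_layers = vapply(candidates, `[[`, integer(1), "n_recurrent_layers"),
         dropout_p = vapply(candidates, `[[`, numeric(1), "dropout_p"),
         input_length_s = vapply(candidates, `[[`, numeric(1), "input_length_s"),
         n_params = np),
       candidates = candidates,
       best_index = best_i)
}
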