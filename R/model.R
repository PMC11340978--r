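#' Hyperparameter set for the stertor network
#'
#' Bundles the tunable architecture and optimisation settings. The recurrent
#' stack is bidirectional GRU layers over the 39-bin frame features; pooling
#' is a single-head self-attentive weighted time average; the head is a
#' fully connected network with ReLU activations and 4 linear outputs (one
#' per ordinal position). Dropout acts between stacked recurrent layers and
#' on head hidden activations only.
#'
#' @param hidden_size Hidden units per GRU direction.
#' @param n_recurrent_layers Number of stacked bidirectional layers.
#' @param dropout_p Dropout probability in `[0, 1)`.
#' @param input_length_s Standardised recording length, 5 or 10 seconds.
#' @param attention_dim Hidden width of the attention scorer.
#' @param head_hidden_sizes Integer vector of head hidden-layer widths
#'   (possibly empty for a linear head).
#' @param learning_rate AdamW learning rate (default 0.001).
#' @return A `hyperparameter_set` list.
#' @export
hyperparameter_set <- function(hidden_size = 32L, n_recurrent_layers = 1L,
                               dropout_p = 0, input_length_s = 10,
                               attention_dim = 16L,
                               head_hidden_sizes = c(32L),
                               learning_rate = 0.001) {
  stopifnot(hidden_size >= 1, n_recurrent_layers >= 1,
            dropout_p >= 0, dropout_p < 1,
            input_length_s %in% c(5, 10),
            attention_dim >= 1,
            all(head_hidden_sizes >= 1) || length(head_hidden_sizes) == 0,
            learning_rate >= 0)
  structure(
    list(hidden_size = as.integer(hidden_size),
         n_recurrent_layers = as.integer(n_recurrent_layers),
         dropout_p = dropout_p,
         input_length_s = input_length_s,
         attention_dim = as.integer(attention_dim),
         head_hidden_sizes = as.integer(head_hidden_sizes),
         learning_rate = learning_rate),
    class = "hyperparameter_set"
  )
}

# Run expr with a private, seeded RNG stream, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

runif_mat <- function(nr, nc, a) matrix(stats::runif(nr * nc, -a, a), nr, nc)

#' Initialise network parameters
#'
#' Deterministic given `seed`. Recurrent weights use the conventional
#' uniform `(-1/sqrt(H), 1/sqrt(H))` range; attention and head layers use
#' `1/sqrt(fan_in)`.
#'
#' @param h A [hyperparameter_set()].
#' @param seed Integer seed.
#' @param input_dim Feature dimension per frame (default 39).
#' @return A nested parameter list (class `stertor_params`) with components
#'   `layers` (per layer: `fwd`/`bwd` gate matrices `Wx`, `Wh` and biases),
#'   `attn` (`W`, `b`, `v`) and `head` (per layer `W`, `b`).
#' @export
init_model <- function(h, seed = 1L, input_dim = 39L) {
  stopifnot(inherits(h, "hyperparameter_set"))
  H <- h$hidden_size
  with_seed(seed, {
    a <- 1 / sqrt(H)
    make_dir <- function(din) {
      list(Wx = runif_mat(3L * H, din, a), Wh = runif_mat(3L * H, H, a),
           bx = stats::runif(3L * H, -a, a), bh = stats::runif(3L * H, -a, a))
    }
    layers <- vector("list", h$n_recurrent_layers)
    din <- input_dim
    for (l in seq_len(h$n_recurrent_layers)) {
      layers[[l]] <- list(fwd = make_dir(din), bwd = make_dir(din))
      din <- 2L * H
    }
    aa <- 1 / sqrt(2L * H)
    attn <- list(W = runif_mat(h$attention_dim, 2L * H, aa),
                 b = stats::runif(h$attention_dim, -aa, aa),
                 v = stats::runif(h$attention_dim, -1 / sqrt(h$attention_dim),
                                  1 / sqrt(h$attention_dim)))
    sizes <- c(2L * H, h$head_hidden_sizes, 4L)
    head <- vector("list", length(sizes) - 1L)
    for (k in seq_along(head)) {
      ak <- 1 / sqrt(sizes[k])
      head[[k]] <- list(W = runif_mat(sizes[k + 1L], sizes[k], ak),
                        b = stats::runif(sizes[k + 1L], -ak, ak))
    }
    structure(list(layers = layers, attn = attn, head = head,
                   hyperparameters = h, input_dim = as.integer(input_dim)),
              class = "stertor_params")
  })
}

# Stack a list of [T x D] feature matrices into the (B, D, T) cube the C++
# core consumes. All matrices must share dimensions (length-standardised).
features_to_cube <- function(feature_list) {
  stopifnot(length(feature_list) >= 1L)
  d <- dim(feature_list[[1L]])
  ok <- vapply(feature_list, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all feature matrices must have identical dimensions")
  x <- array(0, dim = c(length(feature_list), d[2L], d[1L]))
  for (i in seq_along(feature_list)) x[i, , ] <- t(feature_list[[i]])
  x
}

#' Network forward pass
#'
#' Maps one feature matrix (or a list of them) to per-position sigmoid
#' outputs, decoded grades, severity scores and the attention-weight trace.
#' Deterministic given parameters (no dropout at inference).
#'
#' @param features A `[n_frames x 39]` feature matrix, or a list of equally
#'   shaped matrices (batched).
#' @param params Parameters from [init_model()] or [train_model()].
#' @param threshold Ordinal decoding threshold (default 0.5).
#' @return For a single matrix, a `recording_prediction` list with fields
#'   `outputs` (4 probabilities), `decoded_grade`, `severity`,
#'   `attention_weights`. For a list input, a list of such objects.
#' @export
forward <- function(features, params, threshold = 0.5) {
  stopifnot(inherits(params, "stertor_params"))
  single <- is.matrix(features)
  flist <- if (single) list(features) else features
  if (any(vapply(flist, nrow, 1L) < 1L)) stop("empty feature matrix")
  x <- features_to_cube(flist)
  res <- cpp_net_forward(params, x)
  out <- lapply(seq_along(flist), function(i) {
    o <- as.numeric(res$probs[i, ])
    structure(
      list(outputs = o,
           decoded_grade = decode_outputs(o, threshold),
           severity = severity_score(o),
           attention_weights = as.numeric(res$attention[i, ])),
      class = "recording_prediction"
    )
  })
  if (single) out[[1L]] else out
}

#' Self-attentive pooling of hidden states
#'
#' Scores every frame's hidden state with a one-hidden-layer tanh network,
#' normalises the scores with a softmax over frames, and returns the
#' weighted time average. With a single frame the weight is exactly 1; with
#' identical hidden states the weights are uniform `1/n_frames`.
#'
#' @param hidden_states `[n_frames x d]` matrix of hidden states.
#' @param attn_params List with `W` (`a x d`), `b` (length `a`), `v`
#'   (length `a`), as in `params$attn`.
#' @return List with `pooled` (length-`d` vector) and `weights`
#'   (length-`n_frames`, nonnegative, summing to 1).
#' @export
attention_pool <- function(hidden_states, attn_params) {
  stopifnot(is.matrix(hidden_states), nrow(hidden_states) >= 1L)
  u <- tanh(sweep(hidden_states %*% t(attn_params$W), 2L, attn_params$b, `+`))
  s <- drop(u %*% attn_params$v)
  w <- exp(s - max(s))
  w <- w / sum(w)
  list(pooled = drop(crossprod(w, hidden_states)), weights = w)
}

# ---- parameter flattening (for the optimiser) ----

flatten_params <- function(p) {
  unlist(p[c("layers", "attn", "head")], use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  res <- skeleton
  res$layers <- fill(skeleton$layers)
  res$attn <- fill(skeleton$attn)
  res$head <- fill(skeleton$head)
  res
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the parameters (which embed their
#' [hyperparameter_set()]), the feature configuration and the decoding
#' threshold, and round-trips to identical predictions.
#'
#' @param params A `stertor_params` object.
#' @param path Destination file.
#' @param feature_scale Feature amplitude scale used at training time.
#' @param threshold Decoding threshold to store.
#' @return `path` invisibly for `save_checkpoint`; the restored checkpoint
#'   list (`params`, `feature_scale`, `threshold`) for `load_checkpoint`.
#' @export
save_checkpoint <- function(params, path, feature_scale = "log",
                            threshold = 0.5) {
  stopifnot(inherits(params, "stertor_params"))
  saveRDS(list(params = params, feature_scale = feature_scale,
               threshold = threshold, format_version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck$params, "stertor_params"))
  ck
}
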