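test_that("initialisation is deterministic in the seed and validates sizes", {
  h <- hyperparameter_set(hidden_size = 8L)
  p1 <- init_model(h, seed = 3L)
  p2 <- init_model(h, seed = 3L)
  expect_identical(stertor:::flatten_params(p1), stertor:::flatten_params(p2))
  p3 <- init_model(h, seed = 4L)
  expect_false(identical(stertor:::flatten_params(p1),
                         stertor:::flatten_params(p3)))
  expect_error(hyperparameter_set(attention_dim = 0L))
  expect_error(hyperparameter_set(input_length_s = 7))
  expect_error(hyperparameter_set(dropout_p = 1))
})

test_that("forward runs on a [99 x 39] matrix with valid outputs", {
  h <- hyperparameter_set(hidden_size = 8L, input_length_s = 5)
  p <- init_model(h, seed = 1L)
  f <- matrix(rnorm(99 * 39), 99, 39)
  pred <- forward(f, p)
  expect_length(pred$outputs, 4L)
  expect_true(all(pred$outputs >= 0 & pred$outputs <= 1))
  expect_length(pred$attention_weights, 99L)
  expect_equal(sum(pred$attention_weights), 1, tolerance = 1e-12)
  expect_true(all(pred$attention_weights >= 0))
  expect_identical(pred$decoded_grade, decode_outputs(pred$outputs, 0.5))
  expect_equal(pred$severity, severity_score(pred$outputs))
  expect_error(forward(f[0, , drop = FALSE], p), "empty")
})

test_that("a single frame receives attention weight exactly 1", {
  p <- tiny_params()
  pred <- forward(matrix(rnorm(6), 1, 6), p)
  expect_identical(pred$attention_weights, 1)
})

test_that("attention pooling is a softmax-weighted time average", {
  p <- tiny_params()
  attn <- p$attn
  # identical hidden states at every frame -> uniform weights
  hmat <- matrix(rep(rnorm(8), each = 10), 10, 8)
  res <- attention_pool(hmat, attn)
  expect_equal(res$weights, rep(0.1, 10))
  expect_equal(res$pooled, hmat[1, ], tolerance = 1e-12)
  # softmax saturation: one dominant score collapses pooling to that frame
  h2 <- matrix(rnorm(5 * 8), 5, 8)
  big <- list(W = attn$W, b = attn$b, v = attn$v * 1e4)
  s <- tanh(sweep(h2 %*% t(big$W), 2, big$b, `+`)) %*% big$v
  res2 <- attention_pool(h2, big)
  k <- which.max(s)
  expect_equal(res2$weights[k], 1, tolerance = 1e-6)
  expect_equal(res2$pooled, h2[k, ], tolerance = 1e-4)
  # weights always normalise for random shapes
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    res3 <- attention_pool(matrix(rnorm(n * 8), n, 8), attn)
    expect_true(all(res3$weights >= 0))
    expect_equal(sum(res3$weights), 1, tolerance = 1e-12)
  }
})

test_that("R-level attention pooling matches the network's internal pooling", {
  p <- tiny_params(hidden = 4L)
  f <- list(matrix(rnorm(12 * 6), 12, 6), matrix(rnorm(12 * 6), 12, 6))
  x <- stertor:::features_to_cube(f)
  res <- stertor:::cpp_net_forward(p, x, return_hidden = TRUE)
  for (b in 1:2) {
    hmat <- t(res$hidden[b, , ])       # frames x 2H
    rp <- attention_pool(hmat, p$attn)
    expect_equal(rp$weights, as.numeric(res$attention[b, ]), tolerance = 1e-12)
    expect_equal(rp$pooled, as.numeric(res$pooled[b, ]), tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  h <- hyperparameter_set(hidden_size = 3L, n_recurrent_layers = 2L,
                          dropout_p = 0.3, input_length_s = 5,
                          attention_dim = 2L, head_hidden_sizes = 5L)
  p <- init_model(h, seed = 7L, input_dim = 4L)
  set.seed(42)
  x <- array(rnorm(2 * 4 * 5), dim = c(2, 4, 5))
  y <- rbind(encode_grade(2), encode_grade(0))
  for (dp in c(0, 0.3)) {
    res <- stertor:::cpp_net_loss_grad(p, x, y, dp, 99L)
    flat <- stertor:::flatten_params(p)
    gflat <- unlist(res$grads, use.names = FALSE)
    eps <- 1e-6
    idx <- seq_along(flat)
    num <- vapply(idx, function(i) {
      fp <- flat; fp[i] <- fp[i] + eps
      fm <- flat; fm[i] <- fm[i] - eps
      (stertor:::cpp_net_loss_grad(stertor:::unflatten_params(fp, p), x, y, dp, 99L)$loss -
       stertor:::cpp_net_loss_grad(stertor:::unflatten_params(fm, p), x, y, dp, 99L)$loss) /
        (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - gflat) / pmax(1, abs(num))), 1e-6)
  }
})

test_that("reversing time with mirrored directions reproduces the outputs", {
  # swapping forward/backward weight stacks (and the column blocks that
  # consume the concatenated states) must make the network equivariant to
  # time reversal
  p <- tiny_params(hidden = 4L)
  H <- 4L
  swap_cols <- function(M) M[, c((H + 1):(2 * H), 1:H), drop = FALSE]
  p2 <- p
  p2$layers[[1]] <- list(fwd = p$layers[[1]]$bwd, bwd = p$layers[[1]]$fwd)
  p2$attn$W <- swap_cols(p$attn$W)
  p2$head[[1]]$W <- swap_cols(p$head[[1]]$W)
  f <- matrix(rnorm(15 * 6), 15, 6)
  a <- forward(f, p)
  b <- forward(f[15:1, , drop = FALSE], p2)
  expect_equal(b$outputs, a$outputs, tolerance = 1e-12)
  expect_equal(b$attention_weights, rev(a$attention_weights),
               tolerance = 1e-12)
})

test_that("forward is deterministic and checkpoints round-trip predictions", {
  h <- hyperparameter_set(hidden_size = 6L, input_length_s = 5)
  p <- init_model(h, seed = 2L)
  f <- matrix(rnorm(30 * 39), 30, 39)
  a <- forward(f, p)
  b <- forward(f, p)
  expect_identical(a$outputs, b$outputs)
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(p, ck, threshold = 0.4)
  restored <- load_checkpoint(ck)
  expect_equal(restored$threshold, 0.4)
  expect_identical(forward(f, restored$params)$outputs, a$outputs)
})
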