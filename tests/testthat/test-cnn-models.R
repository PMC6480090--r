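expected_conv <- function(kernel)
  list(kind = "conv1d", filters = 64L, kernel = as.integer(kernel),
       activation = "relu", l2 = 0.01)
expected_block3 <- list(
  list(kind = "flatten"),
  list(kind = "dense", units = 64L, activation = "relu"),
  list(kind = "dense", units = 32L, activation = "relu"),
  list(kind = "dense", units = 2L, activation = "softmax"))

test_that("the three variants serialize to the exact expected layer lists", {
  pool <- list(kind = "maxpool", pool = 3L)
  drop <- list(kind = "dropout", p = 0.35)

  s <- build_stack("CNN-3B3Conv", 500)
  expect_identical(s$layers, c(
    list(expected_conv(4), expected_conv(4), expected_conv(4), pool, drop,
         expected_conv(3), expected_conv(3), expected_conv(3), pool, drop),
    expected_block3))

  s3 <- build_stack("CNN-3Conv", 118)
  expect_identical(s3$layers, c(
    list(expected_conv(4), expected_conv(4), expected_conv(4), pool, drop),
    expected_block3))

  s1 <- build_stack("CNN-1Conv", 25)
  expect_identical(s1$layers, c(list(expected_conv(4), pool, drop),
                                expected_block3))
})

test_that("shape propagation matches step-by-step arithmetic", {
  sh <- propagate_shapes(build_stack("CNN-3B3Conv", 500))
  conv_lens <- sh$out_length[sh$kind == "conv1d"]
  expect_equal(conv_lens, c(497, 494, 491, 161, 159, 157))
  expect_equal(sh$out_length[sh$kind == "maxpool"], c(163, 52))
  expect_equal(attr(sh, "flatten_size"), 52 * 64)

  sh1 <- propagate_shapes(build_stack("CNN-1Conv", 25))
  expect_equal(sh1$out_length[sh1$kind == "conv1d"], 22)
  expect_equal(sh1$out_length[sh1$kind == "maxpool"], 7)
  expect_equal(attr(sh1, "flatten_size"), 448)

  # pool of length 3 with pool size 3 leaves a single step: L=6, kernel 4 -> 3
  tiny <- fallcnn:::new_layer_stack("t", 6L, list(fallcnn:::layer_conv(4L),
                                                  fallcnn:::layer_pool()))
  expect_equal(propagate_shapes(tiny)$out_length, c(3, 1))

  expect_error(build_stack("CNN-3B3Conv", 6), class = "fallcnn_input_too_short")
})

test_that("the vectorized convolution agrees with a brute-force oracle", {
  set.seed(31)
  for (i in 1:10) {
    L <- sample(6:30, 1); k <- sample(2:4, 1); C <- sample(c(3L, 5L), 1)
    Fn <- sample(c(2L, 8L), 1)
    st <- fallcnn:::new_layer_stack("t", L, list(
      list(kind = "conv1d", filters = Fn, kernel = k, activation = "relu",
           l2 = 0)))
    x <- matrix(rnorm(L * C), L, C)
    W <- matrix(rnorm(k * C * Fn), k * C, Fn)
    b <- rnorm(Fn)
    weights <- list(list(W = W, b = b))
    X <- array(0, c(1L, L, C)); X[1, , ] <- x
    got <- fallcnn:::forward_pass(st, weights, X)$scores
    ref <- brute_conv1d(x, W, b, k)
    expect_equal(got, pmax(ref, 0), tolerance = 1e-12)
  }
})

test_that("parameter counts follow weight + bias arithmetic", {
  s1 <- build_stack("CNN-1Conv", 25)
  # 832 (conv 4*3*64+64) + dense 448*64+64, 64*32+32, 32*2+2
  expect_equal(count_parameters(s1), 832 + (448 * 64 + 64) + 2080 + 66)
  s <- build_stack("CNN-3B3Conv", 500)
  hand <- (4 * 3 * 64 + 64) + 2 * (4 * 64 * 64 + 64) + 3 * (3 * 64 * 64 + 64) +
    (3328 * 64 + 64) + (64 * 32 + 32) + (32 * 2 + 2)
  expect_equal(count_parameters(s), hand)
  expect_equal(count_parameters(fallcnn:::new_layer_stack("t", 10L, list())), 0L)
})

test_that("logcosh_loss values, symmetry, bounds and stability", {
  expect_equal(logcosh_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(logcosh_loss(1, 0), log(cosh(1)), tolerance = 1e-12)
  expect_equal(logcosh_loss(1, 0), 0.4337808, tolerance = 1e-7)
  expect_equal(logcosh_loss(0, 1), logcosh_loss(1, 0))
  set.seed(1)
  r <- rnorm(50, 0, 5)
  l <- vapply(r, function(ri) logcosh_loss(ri, 0), numeric(1))
  expect_true(all(l >= 0 & l <= abs(r)))
  # |r| > 20: stable closed form, no overflow
  expect_equal(logcosh_loss(800, 0), 800 - log(2))
  expect_error(logcosh_loss(1:3, 1:2), class = "fallcnn_bad_argument")
})

test_that("analytic gradients match finite differences on a small net", {
  set.seed(13)
  st <- fallcnn:::new_layer_stack("tiny", 14L, list(
    fallcnn:::layer_conv(3L), fallcnn:::layer_pool(), fallcnn:::layer_flat(),
    fallcnn:::layer_dense(6L, "relu"), fallcnn:::layer_dense(2L, "softmax")))
  w <- fallcnn:::init_weights(st)
  X <- array(rnorm(5 * 14 * 3), c(5, 14, 3))
  Y <- fallcnn:::onehot(sample(c("fall", "adl"), 5, TRUE))
  loss <- function(w) {
    P <- fallcnn:::forward_pass(st, w, X)$scores
    logcosh_loss(P, Y) + fallcnn:::l2_penalty(st, w)
  }
  fwd <- fallcnn:::forward_pass(st, w, X, cache = TRUE)
  grads <- fallcnn:::backward_pass(st, w, fwd,
                                   tanh(fwd$scores - Y) / length(fwd$scores))
  eps <- 1e-6
  set.seed(14)
  for (li in seq_along(w)) {
    if (is.null(w[[li]])) next
    for (par in c("W", "b")) {
      for (j in sample(length(w[[li]][[par]]), min(8, length(w[[li]][[par]])))) {
        wp <- w; wp[[li]][[par]][j] <- wp[[li]][[par]][j] + eps
        wm <- w; wm[[li]][[par]][j] <- wm[[li]][[par]][j] - eps
        expect_equal(grads[[li]][[par]][j], (loss(wp) - loss(wm)) / (2 * eps),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("training is seeded and epochs = 0 returns the initialization", {
  d <- make_dataset(rep(c("fall", "adl"), 10), L = 12L, seed = 20)
  # the CNN-1Conv chain needs L >= 12: conv 4 -> 9, pool 3 -> 3
  fit0 <- fall_cnn(d, "CNN-1Conv", config = train_config(epochs = 0, seed = 5))
  expect_equal(nrow(fit0$history), 0L)
  ref <- fallcnn:::with_seed(5L, fallcnn:::init_weights(fit0$stack))
  expect_identical(fit0$weights, ref)

  cfg <- train_config(epochs = 2, seed = 9)
  f1 <- fall_cnn(d, "CNN-1Conv", config = cfg)
  f2 <- fall_cnn(d, "CNN-1Conv", config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  f3 <- fall_cnn(d, "CNN-1Conv", config = train_config(epochs = 2, seed = 10))
  expect_false(identical(f1$history, f3$history))
})

test_that("softmax scores are proper probabilities and predictions deterministic", {
  d <- make_dataset(rep(c("fall", "adl"), 8), L = 12L, seed = 22)
  fit <- fall_cnn(d, "CNN-1Conv", config = train_config(epochs = 1, seed = 2))
  p <- predict(fit, d)
  expect_true(all(p$score_adl >= 0 & p$score_adl <= 1))
  expect_equal(p$score_adl + p$score_fall, rep(1, 16), tolerance = 1e-6)
  # duplicated window -> identical scores
  dup <- accel_dataset(d$windows[c(1, 1)])
  pd <- predict(fit, dup)
  expect_identical(pd[1, ], pd[2, ], ignore_attr = TRUE)
  expect_equal(pd$label, ifelse(pd$score_fall > pd$score_adl, "fall", "adl"))
})

test_that("training loss ends below its starting level on the separable task", {
  ok <- vapply(1:5, function(s) {
    d <- gen_dataset(sim_config(window_length = 25, seed = 60 + s), 150, 150)
    norm <- fit_min_max(d)
    fit <- fall_cnn(apply_min_max(d, norm), "CNN-1Conv",
                    config = train_config(seed = s))
    h <- fit$history$loss
    h[length(h)] <= h[1]
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("a checkpoint round-trips weights, history and predictions", {
  d <- make_dataset(rep(c("fall", "adl"), 8), L = 12L, seed = 30)
  norm <- fit_min_max(d)
  fit <- fall_cnn(apply_min_max(d, norm), "CNN-1Conv",
                  config = train_config(epochs = 2, seed = 3),
                  normalizer = norm)
  path <- withr::local_tempfile(fileext = ".json")
  save_fall_cnn(fit, path)
  back <- load_fall_cnn(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-15)
  expect_equal(back$history$loss, fit$history$loss, tolerance = 1e-15)
  p1 <- predict(fit, d)
  p2 <- predict(back, d)
  expect_equal(p1, p2, tolerance = 1e-12)
})
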