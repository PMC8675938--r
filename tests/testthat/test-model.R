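test_that("untrained forward pass emits valid probabilities of the right shape", {
  m <- build_model(small_cnn(), seed = 1)
  X <- matrix(rnorm(5 * 750), 5)
  pr <- scgrisk:::cnn_forward(m$params, m$spec, X)$probs
  expect_equal(dim(pr), c(5L, 2L))
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-6)
  expect_true(all(pr >= 0 & pr <= 1))
  ## identical seeds give identical initial weights
  m2 <- build_model(small_cnn(), seed = 1)
  expect_identical(m$params, m2$params)
  m3 <- build_model(small_cnn(), seed = 2)
  expect_false(identical(m$params$conv1$W, m3$params$conv1$W))
})

test_that("analytic gradients match finite differences on a tiny network", {
  spec <- cnn_spec(input_len = 24L, filters = c(3L, 2L, 2L), kernel = 4L,
                   fc_units = c(7L, 5L), conv_dropout = 0, fc_dropout = 0)
  set.seed(1)
  params <- scgrisk:::init_params(spec)
  X <- matrix(rnorm(5 * 24), 5)
  y <- c(0L, 1L, 1L, 0L, 1L)
  loss_fn <- function(p) {
    pr <- scgrisk:::cnn_forward(p, spec, X, training = TRUE)$probs
    -mean(log(pmax(pr[cbind(1:5, y + 1L)], 1e-12)))
  }
  fw <- scgrisk:::cnn_forward(params, spec, X, training = TRUE,
                              keep_cache = TRUE)
  g <- scgrisk:::cnn_backward(params, spec, fw$cache, fw$probs, y)
  eps <- 1e-6
  set.seed(2)
  for (ln in names(g)) for (pn in names(g[[ln]])) {
    for (i in sample(length(params[[ln]][[pn]]), min(4, length(params[[ln]][[pn]])))) {
      p2 <- params; p2[[ln]][[pn]][i] <- p2[[ln]][[pn]][i] + eps
      p3 <- params; p3[[ln]][[pn]][i] <- p3[[ln]][[pn]][i] - eps
      num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      ana <- g[[ln]][[pn]][i]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-4)
    }
  }
})

test_that("training is reproducible and selects the best validation epoch", {
  tf <- toy_features(20, shift = 1, seed = 3)
  vf <- toy_features(8, shift = 1, seed = 4)
  a <- train_channel(tf$x, tf$y, vf$x, vf$y, small_cnn(), epochs = 4, seed = 9)
  b <- train_channel(tf$x, tf$y, vf$x, vf$y, small_cnn(), epochs = 4, seed = 9)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_equal(a$selected_epoch,
               which.max(a$history$val_acc))     # earliest max by convention
  expect_length(a$history$val_acc, 4)
  one <- train_channel(tf$x, tf$y, vf$x, vf$y, small_cnn(), epochs = 1, seed = 9)
  expect_equal(one$selected_epoch, 1L)
  expect_length(one$history$train_loss, 1)
})

test_that("training rejects degenerate inputs", {
  tf <- toy_features(10)
  expect_error(train_channel(tf$x, rep("CAD", 20), tf$x, tf$y, small_cnn()),
               "both classes")
  expect_error(train_channel(tf$x, tf$y, tf$x, rep("nonCAD", 20), small_cnn()),
               "both classes")
  expect_error(train_channel(tf$x, c(tf$y[-1], "maybe"), tf$x, tf$y,
                             small_cnn()), "labels")
  expect_error(train_channel(tf$x[, 1:100], tf$y, tf$x[, 1:100], tf$y,
                             small_cnn()), "length")
})

test_that("separable features are learned to high validation accuracy", {
  tf <- toy_features(40, shift = 2.5, seed = 5)
  vf <- toy_features(15, shift = 2.5, seed = 6)
  m <- train_channel(tf$x, tf$y, vf$x, vf$y, small_cnn(), epochs = 20,
                     seed = 2)
  expect_gte(max(m$history$val_acc), 0.95)
  ## held-out separation in predicted probabilities
  hf <- toy_features(10, shift = 2.5, seed = 7)
  pr <- predict_cycles(m, hf$x)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gt(mean(pr[hf$y == "CAD"]), mean(pr[hf$y == "nonCAD"]))
})

test_that("label-permuted training stays near chance accuracy", {
  set.seed(8)
  tf <- toy_features(40, shift = 0, seed = 8)     # no signal at all
  vf <- toy_features(20, shift = 0, seed = 9)
  m <- train_channel(tf$x, sample(tf$y), vf$x, sample(vf$y), small_cnn(),
                     epochs = 6, seed = 3)
  n_val <- length(vf$y)
  band <- 1.96 * sqrt(0.25 / n_val)
  expect_lt(abs(m$history$val_acc[m$selected_epoch] - 0.5),
            band + 3 / n_val)  # best-epoch selection biases slightly upward
})

test_that("the reference architecture can memorize a small feature set", {
  set.seed(10)
  X <- matrix(runif(50 * 750), 50)
  y <- sample(c("CAD", "nonCAD"), 50, replace = TRUE)
  m <- train_channel(X, y, X, y, cnn_spec(), epochs = 60, seed = 4)
  expect_lt(min(m$history$train_loss), 0.05)
})

test_that("prediction is deterministic, bounded, and rejects bad input", {
  tf <- toy_features(15, seed = 11)
  m <- train_channel(tf$x, tf$y, tf$x, tf$y, small_cnn(), epochs = 2, seed = 1)
  x1 <- tf$x[1, ]
  pr <- predict_cycles(m, rbind(x1, x1, x1))
  expect_equal(pr[1], pr[2])
  expect_equal(pr[2], pr[3])
  expect_error(predict_cycles(build_model(small_cnn()), tf$x), "untrained")
  expect_error(predict_cycles(m, matrix(0, 2, 10)), "length")
  ## S3 predict method agrees
  expect_equal(predict(m, tf$x), predict_cycles(m, tf$x))
})

test_that("model archives restore weights, history, and predictions", {
  tf <- toy_features(12, seed = 12)
  m <- train_channel(tf$x, tf$y, tf$x, tf$y, small_cnn(), epochs = 2,
                     seed = 5, channel = "scg_y")
  path <- file.path(tempdir(), "model.json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$channel, "scg_y")
  expect_equal(back$selected_epoch, m$selected_epoch)
  expect_equal(back$history$val_acc, as.numeric(m$history$val_acc))
  expect_equal(predict_cycles(back, tf$x), predict_cycles(m, tf$x),
               tolerance = 1e-12)
})

test_that("compiled training and the R forward path agree at evaluation", {
  tf <- toy_features(20, shift = 1, seed = 13)
  vf <- toy_features(10, shift = 1, seed = 14)
  m <- train_channel(tf$x, tf$y, vf$x, vf$y, small_cnn(), epochs = 3, seed = 6)
  acc_r <- mean((predict_cycles(m, vf$x) > 0.5) == (vf$y == "CAD"))
  expect_equal(acc_r, m$history$val_acc[m$selected_epoch], tolerance = 1e-12)
})
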