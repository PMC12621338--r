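test_that("forward pass produces normalised softmax probabilities", {
  cfg <- small_model_config(seed = 3)
  m <- build_model(cfg)
  set.seed(1)
  X <- array(rnorm(4 * 30 * 12), c(4, 30, 12))
  Tt <- array(rnorm(4 * 8 * 8 * 12), c(4, 8, 8, 12))
  m$norm_stats <- list(windows = list(mean = rep(0, 12), sd = rep(1, 12)),
                       tensors = list(mean = rep(0, 12), sd = rep(1, 12)))
  probs <- predict_model(m, X, Tt)
  expect_equal(dim(probs), c(4L, 8L))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-5)

  # inference is deterministic (no dropout at prediction time)
  expect_identical(probs, predict_model(m, X, Tt))
  # duplicated input -> identical output rows
  X2 <- X[c(1, 1, 2, 2), , ]
  T2 <- Tt[c(1, 1, 2, 2), , , ]
  p2 <- predict_model(m, X2, T2)
  expect_equal(p2[1, ], p2[2, ], ignore_attr = TRUE)
})

test_that("builds are reproducible and parameter counts match hand counts", {
  a <- build_model(small_model_config(seed = 9))
  b <- build_model(small_model_config(seed = 9))
  expect_identical(a$params, b$params)
  c_ <- build_model(small_model_config(seed = 10))
  expect_false(identical(a$params, c_$params))

  # independent per-layer arithmetic for the default architecture:
  #  LSTM1: (12 + 384 + 1) * 4 * 384            = 609,792
  #  LSTM2: (384 + 256 + 1) * 4 * 256           = 656,384
  #  conv:  3*3*12 * 128 + 128                  =  13,952
  #  dense: 128 * 256 + 256                     =  33,024
  #  fusion: (256 + 4*4*256) * 256 + 256        = 1,114,368
  #  softmax: 256 * 8 + 8                       =   2,056
  hand <- (12 + 384 + 1) * 4 * 384 + (384 + 256 + 1) * 4 * 256 +
    (3 * 3 * 12 * 128 + 128) + (128 * 256 + 256) +
    ((256 + 16 * 256) * 256 + 256) + (256 * 8 + 8)
  expect_equal(param_count(model_config()), hand)
  expect_equal(hand, 2429576)

  # flatten-then-dense variant
  hand_alt <- (12 + 384 + 1) * 4 * 384 + (384 + 256 + 1) * 4 * 256 +
    (3 * 3 * 12 * 128 + 128) + (16 * 128 * 256 + 256) +
    ((256 + 256) * 256 + 256) + (256 * 8 + 8)
  expect_equal(param_count(model_config(cnn_dense_after_flatten = TRUE)),
               hand_alt)
})

test_that("initial loss is near uniform-softmax cross-entropy", {
  # full-size architecture: Glorot scaling keeps initial logits near zero
  d <- tiny_dataset(n_per_class = 3, seed = 4)
  cfg <- model_config(seed = 4, max_epochs = 1, early_stop_patience = 1,
                      batch_size = 24)
  m <- train_model(build_model(cfg), d, d)
  expect_lt(abs(m$history$train_loss[1] - log(8)), 0.3)
})

test_that("the model memorises a tiny dataset and training is seeded", {
  d <- tiny_dataset(n_per_class = 2, seed = 6)
  # memorisation check: dropout off, no early stop
  cfg <- small_model_config(seed = 6, max_epochs = 150,
                            early_stop_patience = 150, batch_size = 8,
                            lstm_dropout = c(0, 0), conv_dropout = 0)
  m1 <- train_model(build_model(cfg), d, d)
  expect_equal(tail(m1$history$train_acc, 1), 1)
  m2 <- train_model(build_model(cfg), d, d)
  expect_equal(tail(m1$history$val_loss, 1), tail(m2$history$val_loss, 1))
  expect_identical(m1$params, m2$params)

  # prediction on the training windows reproduces the labels
  pred <- classify(m1, d$windows, d$tensors)
  expect_equal(match(pred, m1$classes), d$labels)

  expect_error(train_model(build_model(cfg),
                           list(windows = d$windows, tensors = d$tensors,
                                labels = integer(0)), d),
               "empty")
})

test_that("classification breaks probability ties at the lowest index", {
  cfg <- small_model_config(seed = 2)
  m <- build_model(cfg)
  # zero out the output layer: logits all equal -> uniform probabilities
  m$params$Wo[] <- 0
  m$params$bo[] <- 0
  m$norm_stats <- list(windows = list(mean = rep(0, 12), sd = rep(1, 12)),
                       tensors = list(mean = rep(0, 12), sd = rep(1, 12)))
  set.seed(2)
  X <- array(rnorm(2 * 30 * 12), c(2, 30, 12))
  Tt <- array(rnorm(2 * 8 * 8 * 12), c(2, 8, 8, 12))
  expect_equal(classify(m, X, Tt), rep(adl_classes()[1], 2))
})

test_that("single-branch configurations train and predict", {
  d <- tiny_dataset(n_per_class = 2, seed = 8)
  for (br in c("lstm", "cnn")) {
    cfg <- small_model_config(seed = 8, max_epochs = 10,
                              early_stop_patience = 10, batch_size = 8,
                              branch = br)
    m <- train_model(build_model(cfg), d, d)
    probs <- predict_model(m, d$windows, d$tensors)
    expect_equal(rowSums(probs), rep(1, 16), tolerance = 1e-5)
  }
})

test_that("models round-trip through save/load with identical predictions", {
  d <- tiny_dataset(n_per_class = 2, seed = 12)
  cfg <- small_model_config(seed = 12, max_epochs = 5,
                            early_stop_patience = 5, batch_size = 8)
  m <- train_model(build_model(cfg), d, d)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(predict_model(m2, d$windows, d$tensors),
               predict_model(m, d$windows, d$tensors), tolerance = 1e-12)
})

test_that("fusion is no worse than either branch alone (scaled benchmark)", {
  # three seeds, small model, 4-class desk-scale pipeline; the claim under
  # test is that concatenating both modalities does not hurt accuracy
  accs <- list(fused = c(), lstm = c(), cnn = c())
  for (seed in c(101, 102, 103)) {
    cfg <- unclass(default_pipeline_config(seed))
    cfg$classes <- c("walking", "standing_still", "sitting_down",
                     "standing_up")
    cfg$simulate$reps_per_class <- 20
    cfg$simulate$reps_per_recording <- 4
    cfg$model <- utils::modifyList(cfg$model, list(
      lstm_units = c(16, 12), conv_filters = 8, cnn_dense_units = 12,
      fusion_units = 24, max_epochs = 30, early_stop_patience = 30,
      batch_size = 16))
    for (br in names(accs)) {
      cfg$model$branch <- br
      out <- withr::local_tempdir()
      res <- run_benchmark(cfg, out, verbose = FALSE)
      accs[[br]] <- c(accs[[br]], res$report$accuracy)
    }
  }
  fused <- mean(accs$fused)
  expect_gte(fused, mean(accs$lstm) - 0.01)
  expect_gte(fused, mean(accs$cnn) - 0.01)
})
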