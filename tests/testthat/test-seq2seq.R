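test_that("every architecture honours the shape contract and rejects bad input", {
  set.seed(3)
  X <- matrix(runif(5 * 11), 5, 11)
  for (arch in c("rnn", "lstm", "gru", "tcn", "tcn_lstm")) {
    m <- build_model(model_config(arch, hidden_size = 16, tcn_channels = 8),
                     seed = 1)
    Y <- predict(m, X)
    expect_equal(dim(Y), c(5, 101))
    expect_true(all(is.finite(Y)))
  }
  expect_error(model_config("transformer"), "unknown architecture")
  m <- build_model("rnn", seed = 1)
  expect_error(predict(m, matrix(0.5, 2, 12)), "12")
  expect_equal(m$config$dropout, 0.2)
})

test_that("identical seeds build identical initial weights", {
  a <- build_model("tcn_lstm", seed = 42)
  b <- build_model("tcn_lstm", seed = 42)
  expect_identical(a$params, b$params)
  c <- build_model("tcn_lstm", seed = 43)
  expect_false(identical(a$params, c$params))
})

test_that("backpropagated gradients match finite differences", {
  ns <- asNamespace("cestrecon")
  set.seed(6)
  modify_path <- function(obj, path, value) {
    if (length(path) == 0) return(value)
    obj[[path[[1]]]] <- modify_path(obj[[path[[1]]]], path[-1], value)
    obj
  }
  for (arch in c("rnn", "lstm", "gru", "tcn", "tcn_lstm")) {
    cfg <- tiny_config(arch)
    p <- ns$.model_init(cfg, 0.2)
    # nonzero biases keep ReLU pre-activations away from the kink at 0
    p <- rapply(p, function(x) x + stats::rnorm(length(x), 0, 0.05),
                how = "replace")
    X <- matrix(runif(3 * 5), 3, 5)
    Y <- matrix(runif(3 * 4), 3, 4)
    loss <- function(pp) mean((ns$.model_fwd(pp, cfg, X)$yhat - Y)^2)
    fw <- ns$.model_fwd(p, cfg, X)
    g <- ns$.model_bwd(p, cfg, fw$cache, 2 * (fw$yhat - Y) / 12)
    worst <- 0
    walk <- function(pt, gt, path) {
      if (is.list(pt)) {
        keys <- if (is.null(names(pt))) seq_along(pt) else names(pt)
        for (i in seq_along(pt)) if (!is.null(pt[[i]]))
          walk(pt[[i]], gt[[keys[[i]]]], c(path, list(keys[[i]])))
      } else {
        for (k in sample(length(pt), min(3, length(pt)))) {
          eps <- 1e-5
          leaf <- pt; leaf[k] <- pt[k] + eps
          l1 <- loss(modify_path(p, path, leaf))
          leaf[k] <- pt[k] - eps
          l0 <- loss(modify_path(p, path, leaf))
          num <- (l1 - l0) / (2 * eps)
          worst <<- max(worst, abs(num - gt[k]) /
                          max(1e-6, abs(num) + abs(gt[k])))
        }
      }
    }
    walk(p, g, list())
    expect_lt(worst, 1e-4)
  }
})

test_that("the learning-rate schedule follows its closed form", {
  expect_equal(lr_schedule(0:14, 1e-3, 5),
               1e-3 * 0.5^c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2))
  ds <- small_dataset()
  cfg <- model_config("rnn", hidden_size = 8)
  m <- fit_seq2seq(ds, config = cfg,
                   tcfg = training_config(epochs = 12, batch_size = 16,
                                          seed = 2))
  expect_equal(m$history$lr, lr_schedule(0:11))
  expect_equal(nrow(m$history), 12)
})

test_that("the split is disjoint, 7:3 sized, and validation is never trained on", {
  ds <- small_dataset()
  m <- fit_seq2seq(ds, config = model_config("rnn", hidden_size = 8),
                   tcfg = training_config(epochs = 2, batch_size = 16,
                                          seed = 5))
  tr <- m$split$train; va <- m$split$validation
  expect_length(intersect(tr, va), 0)
  expect_equal(length(tr), floor(0.7 * 40))
  expect_setequal(c(tr, va), 1:40)
})

test_that("training is reproducible and records usable history", {
  ds <- small_dataset()
  tcfg <- training_config(epochs = 3, batch_size = 16, seed = 9)
  cfg <- model_config("gru", hidden_size = 8)
  m1 <- fit_seq2seq(ds, config = cfg, tcfg = tcfg)
  m2 <- fit_seq2seq(ds, config = cfg, tcfg = tcfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$best_epoch, which.min(m1$history$val_mse))
})

test_that("a small model memorizes 32 fixed pairs and predicts consistently", {
  ds <- small_dataset()
  # 46 rows -> floor(0.7 * 46) = 32 training pairs
  sub <- structure(list(sparse_z = ds$sparse_z[rep(1:40, length.out = 46), ],
                        dense_z = ds$dense_z[rep(1:40, length.out = 46), ],
                        params = ds$params[rep(1:40, length.out = 46), ],
                        seed = ds$seed, meta = ds$meta),
                   class = "cest_dataset")
  cfg <- model_config("gru", hidden_size = 128, dropout = 0)
  m <- fit_seq2seq(sub, config = cfg,
                   tcfg = training_config(epochs = 2000, batch_size = 512,
                                          lr_halving_period_epochs = 10000,
                                          seed = 4))
  expect_lt(min(m$history$train_mse), 1e-4)
  first <- m$split$train[1]
  p <- predict(m, sub$sparse_z[first, ])
  mse_first <- mean((p - sub$dense_z[first, ])^2)
  expect_lt(mse_first, max(m$history$train_mse[nrow(m$history)] * 10, 1e-6))
})

test_that("training beats the untrained model by an order of magnitude", {
  ds <- small_dataset()
  full <- acceptance_run()$dataset
  keep <- 1:5000
  big <- structure(list(sparse_z = full$sparse_z[keep, ],
                        dense_z = full$dense_z[keep, ],
                        params = full$params[keep, ], seed = full$seed,
                        meta = full$meta), class = "cest_dataset")
  m <- fit_seq2seq(big, config = model_config("gru", hidden_size = 64),
                   tcfg = training_config(epochs = 20, batch_size = 128,
                                          seed = 3))
  expect_lt(min(m$history$val_mse), m$val_mse_untrained / 10)
})

test_that("prediction is batch-invariant and deterministic", {
  ds <- small_dataset()
  m <- fit_seq2seq(ds, config = model_config("tcn", tcn_channels = 8),
                   tcfg = training_config(epochs = 2, batch_size = 16,
                                          seed = 8))
  X <- ds$sparse_z[1:7, ]
  full <- predict(m, X)
  one <- predict(m, X[3, ])
  expect_equal(one[1, ], full[3, ], tolerance = 1e-12)
  expect_identical(predict(m, X), full)
})

test_that("checkpoints round-trip with configs and grids", {
  ds <- small_dataset()
  m <- fit_seq2seq(ds, config = model_config("rnn", hidden_size = 8),
                   tcfg = training_config(epochs = 2, batch_size = 16,
                                          seed = 2))
  path <- tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$grids, m$grids)
  expect_identical(predict(m2, ds$sparse_z[1:2, ]),
                   predict(m, ds$sparse_z[1:2, ]))
  hpath <- tempfile(fileext = ".csv")
  write_history(m, hpath)
  expect_equal(nrow(utils::read.csv(hpath)), 2)
  unlink(c(path, hpath))
})
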