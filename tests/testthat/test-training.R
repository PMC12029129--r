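make_toy_dataset <- function(n = 60, n_met = 3, n_points = 512, seed = 71,
                             augment = FALSE) {
  lib <- default_library(n_met, seed = seed, grid = tiny_grid(n_points))
  build_dataset(lib, n, sampler = conc_sampler("uniform"),
                augmentation = augmentation_config(enabled = augment),
                seed = seed + 1)
}

test_that("patience arithmetic: a flat validation trace stops on schedule", {
  ds <- make_toy_dataset(30)
  # learning rate ~0 and no decay: weights never move, the validation
  # loss never improves after the first epoch, so training runs exactly
  # 1 + patience epochs with the epoch-1 checkpoint kept
  tc <- train_config(loss_spec("mse"), learning_rate = 1e-30,
                     weight_decay = 0, effective_batch_size = 8,
                     patience = 5, max_epochs = 500, seed = 72)
  fit <- train_model(mlp_config(512, 10, "relu", 3), ds, tc)
  expect_identical(nrow(fit$history), 6L)
  expect_identical(fit$best_epoch, 1L)
})

test_that("the checkpoint's validation loss is the history minimum", {
  ds <- make_toy_dataset(40, augment = TRUE)
  tc <- train_config(loss_spec("rae"), learning_rate = 1e-3,
                     effective_batch_size = 16, patience = 10,
                     max_epochs = 25, seed = 73)
  fit <- train_model(mlp_config(512, 20, "relu", 3), ds, tc)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("accumulated gradients equal the full-batch gradient", {
  ds <- make_toy_dataset(64)
  m <- nn_init(mlp_config(512, 12, "relu", 3), seed = 74)
  ids <- ds$split$train[1:48]
  lspec <- loss_spec("mse")
  full <- nmrquant:::accumulated_gradient(m, ds$spectra, ds$truth,
                                          list(ids), lspec, c(1, 1))
  acc <- nmrquant:::accumulated_gradient(
    m, ds$spectra, ds$truth,
    nmrquant:::split_subbatches(ids, 4), lspec, c(1, 1)
  )
  for (nm in names(full$grads)) {
    denom <- pmax(abs(full$grads[[nm]]), 1e-12)
    expect_lt(max(abs(full$grads[[nm]] - acc$grads[[nm]]) / denom), 1e-6)
  }
  expect_equal(full$value, acc$value, tolerance = 1e-12)
})

test_that("a linearly solvable toy problem is learned quickly by the MLP", {
  # 3 analytes, no augmentation: the map is exactly linear, and the NNLS
  # oracle is essentially exact; the MLP must reach a small validation
  # RAE within 200 epochs
  ds <- make_toy_dataset(300, seed = 75)
  tc <- train_config(loss_spec("rae"), learning_rate = 1e-3,
                     effective_batch_size = 32, patience = 50,
                     max_epochs = 200, seed = 76)
  fit <- train_model(mlp_config(512, 200, "relu", 3), ds, tc)
  expect_lt(fit$best_val_loss, 0.05)

  lib <- default_library(3, seed = 75, grid = tiny_grid(512))
  est <- nnls_quantify(ds, lib)
  expect_lt(max(abs(est - ds$truth) / ds$truth), 1e-3)
})

test_that("training runs are bitwise reproducible under a fixed seed", {
  ds <- make_toy_dataset(40, augment = TRUE)
  tc <- train_config(loss_spec("rae"), learning_rate = 1e-3,
                     effective_batch_size = 16, max_epochs = 5, seed = 77)
  f1 <- train_model(mlp_config(512, 8, "relu", 3), ds, tc)
  f2 <- train_model(mlp_config(512, 8, "relu", 3), ds, tc)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
})

test_that("non-finite losses abort with an epoch/batch diagnostic", {
  ds <- make_toy_dataset(30)
  tc <- train_config(loss_spec("mse"), learning_rate = 1e25,
                     effective_batch_size = 8, max_epochs = 10, seed = 78)
  expect_error(
    train_model(mlp_config(512, 8, "relu", 3), ds, tc),
    "non-finite"
  )
})

test_that("presets carry the documented training parameters", {
  tbl <- baseline_presets()
  expect_setequal(tbl$preset, c("mlp-base", "cnn-base", "tx-base",
                                "mlp-opt", "cnn-opt", "tx-opt"))
  p <- model_preset("mlp-base")
  expect_equal(p$train_config$learning_rate, 1e-3)
  expect_identical(p$train_config$effective_batch_size, 169L)
  expect_identical(p$train_config$max_epochs, 5000L)
  p <- model_preset("cnn-base")
  expect_equal(p$train_config$learning_rate, 5.3e-5)
  expect_identical(p$train_config$effective_batch_size, 64L)
  p <- model_preset("tx-base")
  expect_equal(p$train_config$learning_rate, 1.5e-4)
  expect_identical(p$train_config$effective_batch_size, 76L)
  expect_identical(p$model_config$bin_size, 1000L)
  p <- model_preset("tx-opt")
  expect_equal(p$train_config$learning_rate, 5.0e-4)
  expect_identical(p$train_config$effective_batch_size, 244L)
  expect_equal(p$train_config$weight_decay, 9.6e-3)
  expect_identical(p$model_config$bin_size, 500L)
  expect_identical(p$model_config$n_heads, 16L)
  p <- model_preset("mlp-opt")
  expect_identical(p$model_config$hidden, c(222L, 463L))
  expect_identical(p$model_config$activation, "leakyrelu")
  expect_equal(p$train_config$weight_decay, 9.4e-3)
  p <- model_preset("cnn-opt")
  expect_identical(p$model_config$pooling, "none")
  expect_identical(p$train_config$loss$name, "quantile")
  # every preset satisfies the training-config invariants
  for (i in seq_len(nrow(tbl))) {
    expect_s3_class(tbl$train_config[[i]], "train_config")
    expect_gte(tbl$train_config[[i]]$patience, 1L)
  }
})

test_that("tidy and glance expose the training history", {
  ds <- make_toy_dataset(30)
  tc <- train_config(loss_spec("mse"), learning_rate = 1e-3,
                     effective_batch_size = 8, max_epochs = 3, seed = 79)
  fit <- train_model(mlp_config(512, 8, "relu", 3), ds, tc)
  expect_identical(nrow(tidy(fit)), 3L)
  g <- glance(fit)
  expect_identical(g$arch, "mlp")
  expect_identical(g$epochs, 3L)
})
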