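# Optimisation protocol: AdamW with decoupled weight decay, gradient
# accumulation over sub-batches, best-checkpoint early stopping with a
# 50-epoch patience, and per-architecture epoch caps.

#' Training configuration
#'
#' @param loss A [loss_spec()].
#' @param learning_rate AdamW learning rate.
#' @param weight_decay Decoupled weight-decay (regularisation) constant;
#'   default 0.01.
#' @param effective_batch_size Samples per optimiser step; each step
#'   accumulates gradients over `accumulation_steps` sub-batches whose
#'   sizes total the effective batch (split as evenly as possible).
#' @param accumulation_steps Sub-batches per optimiser step (default 4).
#' @param patience Epochs without a new best validation loss before
#'   stopping (default 50).
#' @param max_epochs Epoch cap (architecture baselines: MLP 5000, CNN
#'   500, transformer 1000).
#' @param seed Seed governing weight initialisation and batch shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(loss = loss_spec("rae"), learning_rate = 1e-3,
                         weight_decay = 0.01, effective_batch_size = 64L,
                         accumulation_steps = 4L, patience = 50L,
                         max_epochs = 1000L, seed = 1L) {
  stopifnot(inherits(loss, "loss_spec"), learning_rate > 0, patience >= 1,
            effective_batch_size >= accumulation_steps, max_epochs >= 1)
  structure(
    list(loss = loss, learning_rate = learning_rate,
         weight_decay = weight_decay,
         effective_batch_size = as.integer(effective_batch_size),
         accumulation_steps = as.integer(accumulation_steps),
         patience = as.integer(patience), max_epochs = as.integer(max_epochs),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# Split a batch index vector into n roughly equal contiguous sub-batches.
split_subbatches <- function(idx, n_sub) {
  n <- length(idx)
  n_sub <- min(n_sub, n)
  sizes <- rep(n %/% n_sub, n_sub) + (seq_len(n_sub) <= n %% n_sub)
  split(idx, rep(seq_len(n_sub), times = sizes))
}

# Average gradient over an effective batch computed in accumulation
# sub-batches; weights are sub-batch sizes so the result equals the
# full-batch gradient of the mean loss for sample-mean losses.
accumulated_gradient <- function(model, X, Yt, sub_idx, lspec, normalizers) {
  acc <- NULL
  total <- sum(lengths(sub_idx))
  value <- 0
  for (ids in sub_idx) {
    cache <- nn_forward(model, X[ids, , drop = FALSE], cache = TRUE)
    lv <- nn_loss(lspec, cache$Y, Yt[ids, , drop = FALSE], normalizers)
    g <- nn_backward(model, cache, lv$grad)
    w <- length(ids) / total
    acc <- if (is.null(acc)) {
      lapply(g, function(x) w * x)
    } else {
      accumulate_grads(acc, g, w)
    }
    value <- value + w * lv$value
  }
  list(grads = acc, value = value)
}

eval_loss <- function(model, X, Yt, lspec, normalizers = c(1, 1),
                      chunk = 512L) {
  pred <- predict(model, X, chunk = chunk)
  nn_loss(lspec, pred, Yt, normalizers)$value
}

#' Train a quantification model
#'
#' Optimises a model with AdamW on the dataset's training split while
#' monitoring the validation split. Per optimiser step, gradients are
#' averaged over `accumulation_steps` sub-batches totalling the effective
#' batch size. The checkpoint with the best validation loss is kept;
#' training stops when `patience` epochs pass without improvement or at
#' `max_epochs`. Fully reproducible from `train_config$seed`.
#'
#' @param config A model configuration ([mlp_config()], [cnn_config()],
#'   [transformer_config()]) or an already-initialised `nn_model`.
#' @param dataset A `spectral_dataset` with train/validation splits.
#' @param train_config A [train_config()].
#' @param prune_callback Optional `function(epoch, val_loss)` returning
#'   `TRUE` to abandon the run (hyperparameter-search pruning).
#' @param output_bias_init `"target_mean"` (default) initialises the
#'   final-layer bias at the per-analyte mean of the training targets so
#'   the network starts at the mean predictor instead of near zero — a
#'   standard regression initialisation that matters here because
#'   concentrations average ~10 mM while fan-in scaled outputs start near
#'   0; `"default"` keeps the fan-in scaled draw.
#' @param verbose Print a line per epoch?
#' @return A `trained_model`: best-checkpoint `nn_model`, full `history`
#'   tibble (epoch, train and validation loss, elapsed seconds),
#'   `best_epoch`, `best_val_loss`, and `pruned` flag.
#' @export
train_model <- function(config, dataset, train_config,
                        prune_callback = NULL,
                        output_bias_init = c("target_mean", "default"),
                        verbose = FALSE) {
  output_bias_init <- match.arg(output_bias_init)
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(train_config, "train_config"))
  tc <- train_config
  model <- if (inherits(config, "nn_model")) {
    config
  } else {
    nn_init(config, seed = tc$seed)
  }
  if (model$config$n_output != ncol(dataset$truth)) {
    abort("model output size does not match the dataset analyte count.")
  }
  tr <- dataset$split$train
  va <- dataset$split$validation
  X <- dataset$spectra
  Yt <- dataset$truth
  lspec <- tc$loss
  if (lspec$name %in% c("mape", "msle", "mse_mape") && any(Yt[tr, ] <= 0)) {
    abort(sprintf(
      "loss '%s' requires strictly positive targets; use scheme 'all_present'.",
      lspec$name))
  }
  if (output_bias_init == "target_mean" && !inherits(config, "nn_model")) {
    ob <- switch(model$config$arch, mlp = paste0("b", length(model$config$hidden) + 1),
                 cnn = "bf2",
                 transformer = if (model$config$n_head_layers == 2L) "bh2" else "bh")
    model$params[[ob]] <- colMeans(Yt[tr, , drop = FALSE])
  }

  state <- adamw_state(model$params)
  # detached running means normalising the two mse_mape terms
  norm_env <- new.env()
  norm_env$norm <- c(1, 1)
  norm_env$seen <- FALSE

  history <- vector("list", tc$max_epochs)
  best_val <- Inf
  best_epoch <- 0L
  best_params <- model$params
  since_best <- 0L
  pruned <- FALSE
  t0 <- Sys.time()

  with_seed(tc$seed + 1L, {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample(tr)
      starts <- seq(1, length(ord), by = tc$effective_batch_size)
      train_loss <- 0
      for (s in starts) {
        ids <- ord[s:min(length(ord), s + tc$effective_batch_size - 1)]
        sub <- split_subbatches(ids, tc$accumulation_steps)
        res <- accumulated_gradient(model, X, Yt, sub, lspec, norm_env$norm)
        if (!is.finite(res$value)) {
          abort(sprintf("non-finite training loss at epoch %d, batch %d.",
                        epoch, which(starts == s)))
        }
        if (lspec$name == "mse_mape") {
          comp <- nn_loss(lspec, predict(model, X[ids, , drop = FALSE]),
                          Yt[ids, , drop = FALSE], norm_env$norm)$components
          norm_env$norm <- if (!norm_env$seen) comp else
            0.99 * norm_env$norm + 0.01 * comp
          norm_env$seen <- TRUE
        }
        step <- adamw_step(model$params, res$grads, state,
                           lr = tc$learning_rate,
                           weight_decay = tc$weight_decay)
        model$params <- step$params
        state <- step$state
        train_loss <- train_loss + res$value * length(ids)
      }
      train_loss <- train_loss / length(ord)
      val_loss <- eval_loss(model, X[va, , drop = FALSE],
                            Yt[va, , drop = FALSE], lspec, norm_env$norm)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
      )
      if (verbose) {
        cat(sprintf("epoch %4d  train %.5g  val %.5g\n",
                    epoch, train_loss, val_loss))
      }
      if (val_loss < best_val) {
        best_val <- val_loss
        best_epoch <- epoch
        best_params <- model$params
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (!is.null(prune_callback) &&
          isTRUE(prune_callback(epoch, val_loss))) {
        pruned <- TRUE
        break
      }
      if (since_best >= tc$patience) break
    }
  })

  model$params <- best_params
  structure(
    list(model = model, config = model$config, train_config = tc,
         history = dplyr::bind_rows(history), best_epoch = best_epoch,
         best_val_loss = best_val, pruned = pruned),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %s, %d epochs (best %d, val %.5g%s)\n",
    x$config$arch, nrow(x$history), x$best_epoch, x$best_val_loss,
    if (x$pruned) ", pruned" else ""
  ))
  invisible(x)
}

#' @rdname predict.nn_model
#' @export
predict.trained_model <- function(object, spectra, chunk = 1024L, ...) {
  predict(object$model, spectra, chunk = chunk)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy trained_model
#' @export
tidy.trained_model <- function(x, ...) x$history

#' @method glance trained_model
#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(
    arch = x$config$arch,
    n_parameters = n_parameters(x$model),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    loss = x$train_config$loss$name,
    pruned = x$pruned
  )
}

#' Architecture and training presets
#'
#' Named presets bundling a model configuration and a training
#' configuration: the three baseline networks (`mlp-base`, `cnn-base`,
#' `tx-base`) and the three tuned counterparts (`mlp-opt`, `cnn-opt`,
#' `tx-opt`). Baselines train with RAE; the tuned MLP/transformer keep
#' RAE while the tuned CNN uses quantile loss with q = 0.5.
#'
#' @param n_input Spectrum length the models are materialised for.
#' @param n_output Number of analytes.
#' @return Tibble with columns `preset`, `arch`, and list-columns
#'   `model_config`, `train_config`.
#' @examples
#' baseline_presets()$preset
#' @export
baseline_presets <- function(n_input = 46000L, n_output = 44L) {
  mk <- function(preset, arch, model, train) {
    tibble::tibble(preset = preset, arch = arch,
                   model_config = list(model), train_config = list(train))
  }
  dplyr::bind_rows(
    mk("mlp-base", "mlp",
       mlp_config(n_input, 200L, "relu", n_output),
       train_config(loss_spec("rae"), 1e-3, 0.01, 169L, max_epochs = 5000L)),
    mk("cnn-base", "cnn",
       cnn_config(n_input, 4L, 42L, 6L, 2L, "max", 2L, 200L, n_output),
       train_config(loss_spec("rae"), 5.3e-5, 0.01, 64L, max_epochs = 500L)),
    mk("tx-base", "transformer",
       transformer_config(n_input, 1000L, 512L, 1L, 1L, 2048L, 1L, n_output),
       train_config(loss_spec("rae"), 1.5e-4, 0.01, 76L, max_epochs = 1000L)),
    mk("mlp-opt", "mlp",
       mlp_config(n_input, c(222L, 463L), "leakyrelu", n_output),
       train_config(loss_spec("rae"), 2.1e-3, 9.4e-3, 124L,
                    max_epochs = 5000L)),
    mk("cnn-opt", "cnn",
       cnn_config(n_input, 3L, 35L, 10L, 4L, "none",
                  feedforward_size = 233L, n_output = n_output),
       train_config(loss_spec("quantile", q = 0.5), 2.1e-5, 5.0e-3, 64L,
                    max_epochs = 500L)),
    mk("tx-opt", "transformer",
       transformer_config(n_input, 500L, 512L, 16L, 1L, 512L, 1L, n_output),
       train_config(loss_spec("rae"), 5.0e-4, 9.6e-3, 244L,
                    max_epochs = 1000L))
  )
}

#' Fetch one preset by name
#'
#' @param name Preset name, see [baseline_presets()].
#' @param n_input,n_output Materialisation sizes.
#' @return List with `model_config` and `train_config`.
#' @export
model_preset <- function(name, n_input = 46000L, n_output = 44L) {
  tbl <- baseline_presets(n_input, n_output)
  row <- tbl[tbl$preset == name, ]
  if (nrow(row) == 0) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(tbl$preset, collapse = ", ")))
  }
  list(model_config = row$model_config[[1]],
       train_config = row$train_config[[1]])
}
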