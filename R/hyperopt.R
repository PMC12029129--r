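# Hyperparameter-search harness: per-architecture search spaces, seeded
# random sampling (the sequential model-based optimiser slot is
# pluggable), median/threshold pruning, and a tune() loop returning the
# arg-min configuration with a complete trial table.

#' Hyperparameter search space for an architecture
#'
#' MLP: 1-4 hidden layers of 10-1000 nodes, activation in
#' ReLU/LeakyReLU/eLU, learning rate 1e-5 to 1e-1 (log-uniform),
#' regularisation 1e-6 to 1e-2 (log-uniform), effective batch 64-1024.
#' CNN: 1-4 conv layers, kernel size 3-12, stride 1-8, 5-50 channels,
#' pooling none/max/average with stride 1-2, feedforward 100-250,
#' learning rate 1e-6 to 1e-2, batch 64-512. Transformer: bin size in
#' \{100, 200, 500, 1000, 2000\}, embedding in \{256, 512, 1024\}, heads
#' in \{1, 2, 4, 8, 16\}, 1-9 encoder layers, 1-2 head layers,
#' feedforward in \{512, 1024, 2048\}, learning rate 1e-6 to 1e-2, batch
#' 32-512.
#'
#' @param arch `"mlp"`, `"cnn"` or `"transformer"`.
#' @return A `search_space` list of parameter descriptors.
#' @export
search_space <- function(arch = c("mlp", "cnn", "transformer")) {
  arch <- match.arg(arch)
  p_int <- function(name, lo, hi) list(name = name, type = "int",
                                       lo = lo, hi = hi)
  p_log <- function(name, lo, hi) list(name = name, type = "logfloat",
                                       lo = lo, hi = hi)
  p_cat <- function(name, values) list(name = name, type = "cat",
                                       values = values)
  params <- switch(arch,
    mlp = list(
      p_int("n_hidden_layers", 1, 4),
      p_cat("activation", c("relu", "leakyrelu", "elu")),
      p_int("hidden_nodes", 10, 1000),  # drawn per layer
      p_log("learning_rate", 1e-5, 1e-1),
      p_log("weight_decay", 1e-6, 1e-2),
      p_int("effective_batch_size", 64, 1024)
    ),
    cnn = list(
      p_int("n_conv_blocks", 1, 4),
      p_int("kernel_size", 3, 12),
      p_int("kernel_stride", 1, 8),
      p_int("channels", 5, 50),
      p_cat("pooling", c("none", "max", "average")),
      p_int("pool_stride", 1, 2),
      p_int("feedforward_size", 100, 250),
      p_log("learning_rate", 1e-6, 1e-2),
      p_log("weight_decay", 1e-6, 1e-2),
      p_int("effective_batch_size", 64, 512)
    ),
    transformer = list(
      p_cat("bin_size", c(100, 200, 500, 1000, 2000)),
      p_cat("embed_dim", c(256, 512, 1024)),
      p_cat("n_heads", c(1, 2, 4, 8, 16)),
      p_int("n_encoder_layers", 1, 9),
      p_int("n_head_layers", 1, 2),
      p_cat("feedforward_dim", c(512, 1024, 2048)),
      p_log("learning_rate", 1e-6, 1e-2),
      p_log("weight_decay", 1e-6, 1e-2),
      p_int("effective_batch_size", 32, 512)
    )
  )
  structure(list(arch = arch, params = params), class = "search_space")
}

draw_param <- function(p) {
  switch(p$type,
    int = sample(p$lo:p$hi, 1),
    logfloat = exp(runif(1, log(p$lo), log(p$hi))),
    cat = if (is.numeric(p$values)) {
      p$values[sample.int(length(p$values), 1)]
    } else {
      sample(p$values, 1)
    }
  )
}

#' Sample one configuration from a search space
#'
#' Seeded random search over the space (a sequential model-based sampler
#' can be plugged in behind the same interface). Configurations that
#' violate model-construction invariants (a CNN stack that exhausts the
#' spectrum, attention heads not dividing the embedding) are rejected and
#' redrawn; ten consecutive invalid CNN shape draws abort with
#' diagnostics.
#'
#' @param space A [search_space()].
#' @param n_input,n_output Materialisation sizes.
#' @param max_retry Redraw budget for invalid configurations.
#' @return List with `model_config`, `train_args` (learning rate, weight
#'   decay, effective batch size) and `draw` (the raw parameter draw).
#' @export
sample_config <- function(space, n_input, n_output, max_retry = 10L) {
  stopifnot(inherits(space, "search_space"))
  last_err <- NULL
  for (attempt in seq_len(max_retry)) {
    draw <- list()
    for (p in space$params) {
      if (p$name == "hidden_nodes") next
      draw[[p$name]] <- draw_param(p)
    }
    if (space$arch == "mlp") {
      draw$hidden_nodes <- sample(10:1000, draw$n_hidden_layers,
                                  replace = TRUE)
    }
    if (space$arch == "transformer" &&
        draw$embed_dim %% draw$n_heads != 0) next
    cfg <- tryCatch(
      switch(space$arch,
        mlp = mlp_config(n_input, draw$hidden_nodes, draw$activation,
                         n_output),
        cnn = cnn_config(n_input, draw$n_conv_blocks, draw$channels,
                         draw$kernel_size, draw$kernel_stride, draw$pooling,
                         draw$pool_stride, draw$feedforward_size, n_output),
        transformer = transformer_config(n_input, draw$bin_size,
                                         draw$embed_dim, draw$n_heads,
                                         draw$n_encoder_layers,
                                         draw$feedforward_dim,
                                         draw$n_head_layers, n_output)
      ),
      error = function(e) e
    )
    if (!inherits(cfg, "error")) {
      return(list(model_config = cfg,
                  train_args = list(
                    learning_rate = draw$learning_rate,
                    weight_decay = draw$weight_decay,
                    effective_batch_size = draw$effective_batch_size),
                  draw = draw))
    }
    last_err <- cfg
  }
  abort(sprintf("%d consecutive invalid configuration draws; last error: %s",
                max_retry, conditionMessage(last_err)))
}

#' Pruning rule for hyperparameter trials
#'
#' `"median"` prunes a trial whose validation loss at an epoch is worse
#' than the median of prior trials' losses at the same epoch (never
#' prunes without peers). `"threshold"` prunes when the loss exceeds a
#' bound at or after the paired epoch; the defaults follow the
#' per-architecture protocol (CNN: loss > 5000 after 15 epochs or
#' \> 1000 after 100 epochs; transformer: > 1000 after 100 epochs).
#'
#' @param kind `"median"` or `"threshold"`.
#' @param thresholds Tibble/data frame with columns `epoch` and `bound`
#'   (ascending epochs), required for `"threshold"`.
#' @return A `prune_rule`.
#' @export
prune_rule <- function(kind = c("median", "threshold"), thresholds = NULL) {
  kind <- match.arg(kind)
  if (kind == "threshold") {
    stopifnot(is.data.frame(thresholds),
              all(c("epoch", "bound") %in% names(thresholds)),
              !is.unsorted(thresholds$epoch))
  }
  structure(list(kind = kind, thresholds = thresholds), class = "prune_rule")
}

#' Default threshold pruning rules per architecture
#'
#' @param arch `"cnn"` or `"transformer"` (the MLP uses the median rule).
#' @return A [prune_rule()].
#' @export
default_prune_rule <- function(arch = c("mlp", "cnn", "transformer")) {
  arch <- match.arg(arch)
  switch(arch,
    mlp = prune_rule("median"),
    cnn = prune_rule("threshold",
                     data.frame(epoch = c(15, 100), bound = c(5000, 1000))),
    transformer = prune_rule("threshold",
                             data.frame(epoch = 100, bound = 1000))
  )
}

#' Should a trial be pruned?
#'
#' @param rule A [prune_rule()].
#' @param val_loss Current trial's validation loss at `epoch`.
#' @param epoch Current (1-based) epoch.
#' @param peer_losses For the median rule: numeric vector of prior
#'   trials' validation losses at the same epoch.
#' @return `TRUE` to prune. Comparisons are strict (`>`): a loss exactly
#'   at the bound survives.
#' @export
should_prune <- function(rule, val_loss, epoch, peer_losses = numeric(0)) {
  stopifnot(inherits(rule, "prune_rule"))
  if (rule$kind == "median") {
    if (length(peer_losses) == 0) return(FALSE)
    return(val_loss > median(peer_losses))
  }
  th <- rule$thresholds
  any(epoch >= th$epoch & val_loss > th$bound)
}

#' Run a seeded hyperparameter search
#'
#' Runs `n_trials` sampled train/evaluate cycles with pruning and returns
#' the arg-min configuration plus an append-only trial table. The
#' objective minimises MAPE (or quantile loss, q = 0.5, the CNN
#' convention) on a validation dataset generated without leaving out
#' metabolites; by default the dataset's own validation split is used,
#' restricted to all-present spectra.
#'
#' @param arch Architecture to search.
#' @param dataset Training `spectral_dataset`.
#' @param n_trials Number of trials (>= 1).
#' @param objective `"mape"` or `"quantile"`.
#' @param seed Integer seed; the whole search is reproducible.
#' @param max_epochs Per-trial epoch cap (desk-scale searches keep this
#'   small).
#' @param valid_dataset Optional separate all-present validation dataset.
#' @param rule Pruning rule; defaults per architecture.
#' @param prior_trials Trial table of an interrupted search with the same
#'   seed: completed trials are kept and numbering resumes after them.
#' @return List with `best` (trial row), `best_config`, and `trials`
#'   (tibble: trial, params, objective, pruned, epochs).
#' @export
tune <- function(arch, dataset, n_trials = 10, objective = c("mape", "quantile"),
                 seed = 1, max_epochs = 30, valid_dataset = NULL,
                 rule = default_prune_rule(arch), prior_trials = NULL) {
  objective <- match.arg(objective)
  stopifnot(n_trials >= 1)
  space <- search_space(arch)
  n_input <- ncol(dataset$spectra)
  n_output <- ncol(dataset$truth)

  if (is.null(valid_dataset)) {
    va <- dataset$split$validation
    keep <- va[rowSums(dataset$truth[va, , drop = FALSE] <= 0) == 0]
    if (length(keep) == 0) {
      abort("no all-present validation spectra for the objective.")
    }
    vX <- dataset$spectra[keep, , drop = FALSE]
    vY <- dataset$truth[keep, , drop = FALSE]
  } else {
    vX <- valid_dataset$spectra
    vY <- valid_dataset$truth
  }

  peer_histories <- list()
  rows <- vector("list", n_trials)
  best_obj <- Inf
  best_row <- NULL
  best_config <- NULL

  first_trial <- 1L
  if (!is.null(prior_trials) && nrow(prior_trials) > 0) {
    first_trial <- max(prior_trials$trial) + 1L
    rows <- c(list(prior_trials), rows)
  }

  for (trial in seq(first_trial, length.out = n_trials)) {
    drawn <- with_seed(seed * 1000L + trial, {
      sample_config(space, n_input, n_output)
    })
    tc <- train_config(
      loss = if (objective == "quantile") loss_spec("quantile", q = 0.5)
             else loss_spec("rae"),
      learning_rate = drawn$train_args$learning_rate,
      weight_decay = drawn$train_args$weight_decay,
      effective_batch_size = drawn$train_args$effective_batch_size,
      max_epochs = max_epochs,
      seed = seed * 1000L + trial
    )
    cb <- function(epoch, val_loss) {
      peers <- vapply(peer_histories, function(h) {
        if (length(h) >= epoch) h[epoch] else NA_real_
      }, numeric(1))
      should_prune(rule, val_loss, epoch, peers[!is.na(peers)])
    }
    fit <- train_model(drawn$model_config, dataset, tc, prune_callback = cb)
    peer_histories[[trial]] <- fit$history$val_loss
    pred <- predict(fit, vX)
    obj <- if (objective == "mape") {
      mean(mape_per_spectrum(pred, vY))
    } else {
      nn_loss(loss_spec("quantile", q = 0.5), pred, vY)$value
    }
    row <- tibble::tibble(
      trial = as.integer(trial),
      params = list(drawn$draw),
      objective = obj,
      pruned = fit$pruned,
      epochs = nrow(fit$history)
    )
    rows[[trial - first_trial + 1L + (first_trial > 1L)]] <- row
    if (!fit$pruned && obj < best_obj) {
      best_obj <- obj
      best_row <- row
      best_config <- drawn$model_config
    }
  }
  trials <- dplyr::bind_rows(rows)
  ok <- which(!trials$pruned)
  if (length(ok) > 0) {
    cand <- trials[ok[which.min(trials$objective[ok])], ]
    if (is.null(best_row) || cand$objective < best_row$objective) {
      best_row <- cand
      if (cand$trial < first_trial) best_config <- NULL  # from a prior run
    }
  }
  if (is.null(best_row)) {
    warn("all trials were pruned; returning the best pruned trial.")
    best_row <- trials[which.min(trials$objective), ]
    best_config <- NULL
  }
  list(best = best_row, best_config = best_config, trials = trials)
}
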