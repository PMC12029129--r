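# Multi-layered perceptron: affine-activation stack ending in a linear
# output layer whose values are read as concentrations in mM.

#' MLP architecture configuration
#'
#' The baseline network maps all 46,000 spectrum points through one
#' 200-node hidden layer to 44 outputs.
#'
#' @param n_input Input length (spectrum points).
#' @param hidden Integer vector of hidden-layer sizes (1-4 layers).
#' @param activation `"relu"`, `"leakyrelu"` or `"elu"`.
#' @param n_output Number of analytes.
#' @return An `mlp_config`.
#' @export
mlp_config <- function(n_input = 46000L, hidden = 200L,
                       activation = "relu", n_output = 44L) {
  hidden <- as.integer(hidden)
  stopifnot(length(hidden) >= 1, all(hidden >= 1), n_input >= 1,
            n_output >= 1)
  structure(
    list(arch = "mlp", n_input = as.integer(n_input), hidden = hidden,
         activation = activation, n_output = as.integer(n_output)),
    class = c("mlp_config", "model_config")
  )
}

#' Initialise a model from an architecture configuration
#'
#' Weights use fan-in scaled uniform initialisation; the draw is governed
#' by `seed` so construction is reproducible.
#'
#' @param config An `mlp_config`, `cnn_config` or `transformer_config`.
#' @param seed Integer seed for the weight draw.
#' @return An `nn_model`: `config` plus a flat named list `params`.
#' @export
nn_init <- function(config, seed = 1) {
  stopifnot(inherits(config, "model_config"))
  params <- with_seed(seed, init_params(config))
  structure(list(config = config, params = params), class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %s, %s parameters\n", x$config$arch,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

init_params <- function(config) UseMethod("init_params")

#' @export
init_params.mlp_config <- function(config) {
  sizes <- c(config$n_input, config$hidden, config$n_output)
  params <- list()
  for (l in seq_len(length(sizes) - 1)) {
    lin <- init_linear(sizes[l], sizes[l + 1])
    params[[paste0("W", l)]] <- lin$W
    params[[paste0("b", l)]] <- lin$b
  }
  params
}

# Forward pass; with cache = TRUE returns the intermediates needed by the
# backward pass.
nn_forward <- function(model, X, cache = FALSE) UseMethod("nn_forward", model$config)

#' @export
nn_forward.mlp_config <- function(model, X, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  stopifnot(ncol(X) == cfg$n_input)
  act <- activation_fun(cfg$activation)
  n_hidden <- length(cfg$hidden)
  H <- X
  Hs <- vector("list", n_hidden + 1)
  Zs <- vector("list", n_hidden)
  for (l in seq_len(n_hidden)) {
    Hs[[l]] <- H
    Z <- add_bias(H %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
    Zs[[l]] <- Z
    H <- act$f(Z)
  }
  Hs[[n_hidden + 1]] <- H
  L <- n_hidden + 1
  Y <- add_bias(H %*% p[[paste0("W", L)]], p[[paste0("b", L)]])
  if (!cache) return(Y)
  list(Y = Y, Hs = Hs, Zs = Zs)
}

nn_backward <- function(model, cache, dY) UseMethod("nn_backward", model$config)

#' @export
nn_backward.mlp_config <- function(model, cache, dY) {
  cfg <- model$config
  p <- model$params
  act <- activation_fun(cfg$activation)
  n_hidden <- length(cfg$hidden)
  grads <- list()
  L <- n_hidden + 1
  grads[[paste0("W", L)]] <- crossprod(cache$Hs[[L]], dY)
  grads[[paste0("b", L)]] <- colSums(dY)
  dH <- tcrossprod(dY, p[[paste0("W", L)]])
  for (l in rev(seq_len(n_hidden))) {
    Z <- cache$Zs[[l]]
    dZ <- dH * act$df(Z, act$f(Z))
    grads[[paste0("W", l)]] <- crossprod(cache$Hs[[l]], dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1) dH <- tcrossprod(dZ, p[[paste0("W", l)]])
  }
  grads
}

#' Predict concentrations for a batch of spectra
#'
#' Vectorised batch inference: spectra are processed in chunks with no
#' per-spectrum interpreter loop, so thousands of spectra are quantified
#' in one call.
#'
#' @param object An `nn_model` or `trained_model`.
#' @param spectra `B x n_input` matrix (or single spectrum vector).
#' @param chunk Spectra per forward chunk (memory control).
#' @param ... Unused.
#' @return `B x n_output` matrix of concentration estimates (mM).
#' @export
predict.nn_model <- function(object, spectra, chunk = 1024L, ...) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  B <- nrow(spectra)
  out <- matrix(0, B, object$config$n_output)
  start <- 1L
  while (start <= B) {
    idx <- start:min(B, start + chunk - 1L)
    out[idx, ] <- nn_forward(object, spectra[idx, , drop = FALSE])
    start <- start + chunk
  }
  out
}
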