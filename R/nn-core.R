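# Shared neural-network machinery: activations, fan-in scaled weight
# initialisation, and the AdamW optimiser. Parameters are flat named
# lists of numeric arrays; gradients mirror that structure.

activation_fun <- function(name = c("relu", "leakyrelu", "elu")) {
  name <- match.arg(tolower(name), c("relu", "leakyrelu", "elu"))
  switch(name,
    relu = list(
      f = function(x) pmax(x, 0),
      df = function(x, fx) (x > 0) * 1
    ),
    leakyrelu = list(
      f = function(x) ifelse(x > 0, x, 0.01 * x),
      df = function(x, fx) ifelse(x > 0, 1, 0.01)
    ),
    elu = list(
      f = function(x) ifelse(x > 0, x, exp(x) - 1),
      df = function(x, fx) ifelse(x > 0, 1, fx + 1)
    )
  )
}

# PyTorch-style Linear init: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_linear <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(
    W = matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out),
    b = runif(fan_out, -bound, bound)
  )
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' Number of trainable parameters of a model
#'
#' @param model An `nn_model` (see [nn_init()]).
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  sum(vapply(model$params, length, numeric(1)))
}

# ---- AdamW -----------------------------------------------------------------

adamw_state <- function(params) {
  list(
    t = 0L,
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One decoupled-weight-decay Adam step. Weight decay multiplies parameters
# by (1 - lr * wd) independently of the gradient-based update.
adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] * (1 - lr * weight_decay) -
      lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) {
  lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
}

accumulate_grads <- function(acc, grads, weight) {
  for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + weight * grads[[nm]]
  acc
}
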