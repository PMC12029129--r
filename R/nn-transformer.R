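# Encoder-only transformer for spectrum regression. The spectrum is split
# into contiguous bins, each bin is embedded by a shared linear layer,
# sinusoidal positional encodings are added, and one or more standard
# encoder blocks (multi-head self-attention and a position-wise
# feedforward, each with residual connection and layer normalisation)
# transform the sequence. All encoder outputs are flattened and a linear
# head maps them to the analyte concentrations.
#
# Activations are (B * S) x D matrices, rows spectrum-major with the
# sequence position fastest, so attention slices rows (b-1)*S + 1:S.

#' Transformer architecture configuration
#'
#' The baseline uses bin size 1000 (sequence length 46 on the standard
#' grid), embedding dimension 512, one encoder layer with one attention
#' head and feedforward dimension 2048, no dropout, and a linear head on
#' the flattened encoder output. The tuned preset uses bin size 500 with
#' 16 heads and feedforward dimension 512.
#'
#' @param n_input Spectrum length; zero-padded up to a bin multiple.
#' @param bin_size Points per sequence position.
#' @param embed_dim Embedding dimension; must be divisible by `n_heads`.
#' @param n_heads Number of attention heads.
#' @param n_encoder_layers Number of encoder blocks (1-9 in the search
#'   space).
#' @param feedforward_dim Hidden size of the position-wise feedforward
#'   (and of the head's hidden layer when `n_head_layers = 2`).
#' @param n_head_layers 1 = linear head; 2 = one hidden ReLU layer.
#' @param n_output Number of analytes.
#' @return A `transformer_config`.
#' @export
transformer_config <- function(n_input = 46000L, bin_size = 1000L,
                               embed_dim = 512L, n_heads = 1L,
                               n_encoder_layers = 1L,
                               feedforward_dim = 2048L,
                               n_head_layers = 1L, n_output = 44L) {
  if (embed_dim %% n_heads != 0) {
    abort("`embed_dim` must be divisible by `n_heads`.")
  }
  stopifnot(n_head_layers %in% 1:2, n_encoder_layers >= 1)
  n_bins <- as.integer(ceiling(n_input / bin_size))
  structure(
    list(arch = "transformer", n_input = as.integer(n_input),
         bin_size = as.integer(bin_size), n_bins = n_bins,
         padding = n_bins * as.integer(bin_size) - as.integer(n_input),
         embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
         head_dim = as.integer(embed_dim / n_heads),
         n_encoder_layers = as.integer(n_encoder_layers),
         feedforward_dim = as.integer(feedforward_dim),
         n_head_layers = as.integer(n_head_layers),
         n_output = as.integer(n_output)),
    class = c("transformer_config", "model_config")
  )
}

# Fixed sinusoidal positional encodings (sine on even dimensions, cosine
# on odd), S x D.
positional_encoding <- function(S, D) {
  pos <- 0:(S - 1)
  pe <- matrix(0, S, D)
  i <- seq(0, D - 1, by = 2)
  freq <- 1 / 10000^(i / D)
  ang <- outer(pos, freq)
  pe[, i + 1] <- sin(ang)
  valid <- which(i + 2 <= D)
  pe[, i[valid] + 2] <- cos(ang[, valid, drop = FALSE])
  pe
}

#' @export
init_params.transformer_config <- function(config) {
  D <- config$embed_dim
  params <- list()
  lin <- init_linear(config$bin_size, D)
  params$We <- lin$W
  params$be <- lin$b
  for (l in seq_len(config$n_encoder_layers)) {
    for (nm in c("q", "k", "v", "o")) {
      lin <- init_linear(D, D)
      params[[paste0("W", nm, l)]] <- lin$W
      params[[paste0("b", nm, l)]] <- lin$b
    }
    lin <- init_linear(D, config$feedforward_dim)
    params[[paste0("Wf1_", l)]] <- lin$W
    params[[paste0("bf1_", l)]] <- lin$b
    lin <- init_linear(config$feedforward_dim, D)
    params[[paste0("Wf2_", l)]] <- lin$W
    params[[paste0("bf2_", l)]] <- lin$b
    params[[paste0("g1_", l)]] <- rep(1, D)
    params[[paste0("be1_", l)]] <- rep(0, D)
    params[[paste0("g2_", l)]] <- rep(1, D)
    params[[paste0("be2_", l)]] <- rep(0, D)
  }
  flat <- config$n_bins * D
  if (config$n_head_layers == 2L) {
    lin <- init_linear(flat, config$feedforward_dim)
    params$Wh1 <- lin$W
    params$bh1 <- lin$b
    lin <- init_linear(config$feedforward_dim, config$n_output)
    params$Wh2 <- lin$W
    params$bh2 <- lin$b
  } else {
    lin <- init_linear(flat, config$n_output)
    params$Wh <- lin$W
    params$bh <- lin$b
  }
  params
}

#' @export
nn_forward.transformer_config <- function(model, X, cache = FALSE) {
  cfg <- model$config
  stopifnot(ncol(X) == cfg$n_input)
  Xb <- bin_spectrum(X, cfg$bin_size)
  pe <- positional_encoding(cfg$n_bins, cfg$embed_dim)
  res <- .tx_forward_cpp(model$params, unclass(cfg), Xb, pe, cache)
  if (!cache) return(res$Y)
  list(Y = res$Y, Xb = Xb, cpp = res)
}

#' @export
nn_backward.transformer_config <- function(model, cache, dY) {
  .tx_backward_cpp(model$params, unclass(model$config), cache$cpp,
                   cache$Xb, dY)
}
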