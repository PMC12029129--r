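# 1-D convolutional network. Activations are stored as (B * L) x C
# matrices with rows ordered spectrum-major, position fastest; the
# convolution is evaluated as an im2col matrix product so the heavy
# lifting stays in BLAS.

conv_out_len <- function(L, k, s) floor((L - k) / s) + 1

pool_out_len <- function(L, size, s) floor((L - size) / s) + 1

#' CNN architecture configuration
#'
#' The baseline network stacks four blocks of (convolution, ReLU, max
#' pooling) and ends with a two-layer feedforward head. Convolution
#' kernels have 42 channels, size 6 and stride 2; pooling has size 2 and
#' stride 2. All spatial lengths are computed at construction and a
#' configuration whose stack exhausts the spectrum is rejected.
#'
#' @param n_input Input length (spectrum points).
#' @param n_conv_blocks Number of conv blocks (1-4 in the search space).
#' @param channels Channels per convolutional layer (scalar).
#' @param kernel_size,kernel_stride Convolution kernel size and stride.
#' @param pooling `"max"`, `"average"` or `"none"`.
#' @param pool_stride Pooling stride (pool size is fixed at 2).
#' @param feedforward_size Hidden size of the head.
#' @param n_output Number of analytes.
#' @return A `cnn_config` with the per-block spatial lengths in `lengths`.
#' @export
cnn_config <- function(n_input = 46000L, n_conv_blocks = 4L, channels = 42L,
                       kernel_size = 6L, kernel_stride = 2L,
                       pooling = c("max", "average", "none"),
                       pool_stride = 2L, feedforward_size = 200L,
                       n_output = 44L) {
  pooling <- match.arg(pooling)
  L <- as.integer(n_input)
  lengths <- integer(0)
  for (i in seq_len(n_conv_blocks)) {
    L <- as.integer(conv_out_len(L, kernel_size, kernel_stride))
    if (L < 1) abort("conv stack reduces the spectrum below 1 point.")
    if (pooling != "none") {
      L <- as.integer(pool_out_len(L, 2L, pool_stride))
      if (L < 1) abort("pooling reduces the spectrum below 1 point.")
    }
    lengths <- c(lengths, L)
  }
  structure(
    list(arch = "cnn", n_input = as.integer(n_input),
         n_conv_blocks = as.integer(n_conv_blocks),
         channels = as.integer(channels),
         kernel_size = as.integer(kernel_size),
         kernel_stride = as.integer(kernel_stride),
         pooling = pooling, pool_stride = as.integer(pool_stride),
         feedforward_size = as.integer(feedforward_size),
         n_output = as.integer(n_output), lengths = lengths,
         flat_size = as.integer(L * as.integer(channels))),
    class = c("cnn_config", "model_config")
  )
}

#' @export
init_params.cnn_config <- function(config) {
  params <- list()
  c_in <- 1L
  for (i in seq_len(config$n_conv_blocks)) {
    lin <- init_linear(config$kernel_size * c_in, config$channels)
    params[[paste0("Wc", i)]] <- lin$W
    params[[paste0("bc", i)]] <- lin$b
    c_in <- config$channels
  }
  lin <- init_linear(config$flat_size, config$feedforward_size)
  params$Wf1 <- lin$W
  params$bf1 <- lin$b
  lin <- init_linear(config$feedforward_size, config$n_output)
  params$Wf2 <- lin$W
  params$bf2 <- lin$b
  params
}

# im2col: output row (b, p) gathers input rows (b, (p-1)*stride + j),
# j = 1..k, giving a (B*L_out) x (k*C_in) matrix for one BLAS product.
conv_gather <- function(Xin, B, L_in, L_out, k, stride) {
  base <- rep((0:(B - 1)) * L_in, each = L_out) +
    rep((seq_len(L_out) - 1) * stride, B)
  C_in <- ncol(Xin)
  Xcol <- matrix(0, B * L_out, k * C_in)
  for (j in seq_len(k)) {
    Xcol[, ((j - 1) * C_in + 1):(j * C_in)] <- Xin[base + j, , drop = FALSE]
  }
  Xcol
}

conv_scatter <- function(dXcol, B, L_in, L_out, k, stride, C_in) {
  base <- rep((0:(B - 1)) * L_in, each = L_out) +
    rep((seq_len(L_out) - 1) * stride, B)
  dXin <- matrix(0, B * L_in, C_in)
  for (j in seq_len(k)) {
    idx <- base + j
    dXin[idx, ] <- dXin[idx, , drop = FALSE] +
      dXcol[, ((j - 1) * C_in + 1):(j * C_in), drop = FALSE]
  }
  dXin
}

pool_pair_idx <- function(B, L_in, L_out, stride) {
  r1 <- rep((0:(B - 1)) * L_in, each = L_out) +
    rep((seq_len(L_out) - 1) * stride + 1, B)
  list(r1 = r1, r2 = r1 + 1)
}

#' @export
nn_forward.cnn_config <- function(model, X, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  stopifnot(ncol(X) == cfg$n_input)
  B <- nrow(X)
  H <- matrix(as.vector(t(X)), ncol = 1)  # (B * L) x 1, position fastest
  L <- cfg$n_input
  caches <- vector("list", cfg$n_conv_blocks)
  for (i in seq_len(cfg$n_conv_blocks)) {
    C_in <- ncol(H)
    L_conv <- conv_out_len(L, cfg$kernel_size, cfg$kernel_stride)
    Xcol <- conv_gather(H, B, L, L_conv, cfg$kernel_size, cfg$kernel_stride)
    Z <- add_bias(Xcol %*% p[[paste0("Wc", i)]], p[[paste0("bc", i)]])
    A <- pmax(Z, 0)
    blk <- list(L_in = L, L_conv = L_conv, C_in = C_in, Xcol = Xcol, Z = Z)
    if (cfg$pooling == "none") {
      H <- A
      L <- L_conv
    } else {
      L_pool <- pool_out_len(L_conv, 2L, cfg$pool_stride)
      idx <- pool_pair_idx(B, L_conv, L_pool, cfg$pool_stride)
      A1 <- A[idx$r1, , drop = FALSE]
      A2 <- A[idx$r2, , drop = FALSE]
      if (cfg$pooling == "max") {
        H <- pmax(A1, A2)
        blk$first_max <- A1 >= A2
      } else {
        H <- (A1 + A2) / 2
      }
      blk$idx <- idx
      blk$L_pool <- L_pool
      L <- L_pool
    }
    caches[[i]] <- blk
  }
  # flatten: row b of `flat` concatenates positions channel by channel
  A3 <- array(H, c(L, B, ncol(H)))
  flat <- t(matrix(aperm(A3, c(1, 3, 2)), ncol = B))
  Z1 <- add_bias(flat %*% p$Wf1, p$bf1)
  A1 <- pmax(Z1, 0)
  Y <- add_bias(A1 %*% p$Wf2, p$bf2)
  if (!cache) return(Y)
  list(Y = Y, caches = caches, flat = flat, Z1 = Z1, A1 = A1, B = B,
       L_final = L)
}

#' @export
nn_backward.cnn_config <- function(model, cache, dY) {
  cfg <- model$config
  p <- model$params
  B <- cache$B
  grads <- list()
  grads$Wf2 <- crossprod(cache$A1, dY)
  grads$bf2 <- colSums(dY)
  dA1 <- tcrossprod(dY, p$Wf2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  grads$Wf1 <- crossprod(cache$flat, dZ1)
  grads$bf1 <- colSums(dZ1)
  dflat <- tcrossprod(dZ1, p$Wf1)
  # un-flatten back to (B * L) x C
  L <- cache$L_final
  C <- cfg$channels
  A3 <- aperm(array(t(dflat), c(L, C, B)), c(1, 3, 2))
  dH <- matrix(A3, B * L, C)
  for (i in rev(seq_len(cfg$n_conv_blocks))) {
    blk <- cache$caches[[i]]
    if (cfg$pooling == "none") {
      dA <- dH
    } else {
      dA <- matrix(0, B * blk$L_conv, ncol(dH))
      if (cfg$pooling == "max") {
        d1 <- dH * blk$first_max
        d2 <- dH * !blk$first_max
      } else {
        d1 <- dH / 2
        d2 <- dH / 2
      }
      # scatter-add: with pool stride 1 the two index sets overlap
      for (part in list(list(i = blk$idx$r1, d = d1),
                        list(i = blk$idx$r2, d = d2))) {
        o <- order(part$i)
        agg <- rowsum(part$d[o, , drop = FALSE], part$i[o])
        rows <- as.integer(rownames(agg))
        dA[rows, ] <- dA[rows, , drop = FALSE] + agg
      }
    }
    dZ <- dA * (blk$Z > 0)
    grads[[paste0("Wc", i)]] <- crossprod(blk$Xcol, dZ)
    grads[[paste0("bc", i)]] <- colSums(dZ)
    dXcol <- tcrossprod(dZ, p[[paste0("Wc", i)]])
    dH <- conv_scatter(dXcol, B, blk$L_in, blk$L_conv, cfg$kernel_size,
                       cfg$kernel_stride, blk$C_in)
  }
  grads
}
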