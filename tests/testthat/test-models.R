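test_that("baseline MLP has the documented shape and parameter count", {
  cfg <- mlp_config(46000, 200, "relu", 44)
  m <- nn_init(cfg, seed = 1)
  expect_identical(n_parameters(m), 46000 * 200 + 200 + 200 * 44 + 44)
  x <- matrix(rnorm(2 * 46000), 2)
  y <- predict(m, x)
  expect_identical(dim(y), c(2L, 44L))
})

test_that("forward passes are deterministic and seed-reproducible", {
  cfg <- mlp_config(50, c(9, 7), "elu", 3)
  m1 <- nn_init(cfg, seed = 5)
  m2 <- nn_init(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  x <- matrix(rnorm(4 * 50), 4)
  expect_identical(predict(m1, x), predict(m1, x))
  expect_false(identical(predict(nn_init(cfg, seed = 6), x), predict(m1, x)))
})

test_that("all-zero weights give a bias-only MLP output", {
  cfg <- mlp_config(20, 5, "relu", 3)
  m <- nn_init(cfg, seed = 1)
  m$params <- lapply(m$params, function(p) {
    p[] <- 0
    p
  })
  y <- predict(m, matrix(rnorm(3 * 20), 3))
  expect_true(all(y == 0))
})

test_that("CNN spatial lengths follow the closed-form shape arithmetic", {
  cfg <- cnn_config(46000, 4, 42, 6, 2, "max", 2, 200, 44)
  L <- 46000
  for (i in 1:4) {
    L <- floor((L - 6) / 2) + 1
    L <- floor((L - 2) / 2) + 1
    expect_identical(cfg$lengths[i], as.integer(L))
  }
  expect_identical(cfg$flat_size, as.integer(L * 42))
  m <- nn_init(cfg, seed = 2)
  y <- predict(m, matrix(rnorm(46000), 1))
  expect_identical(dim(y), c(1L, 44L))
  # a stack that exhausts the spectrum is rejected at construction
  expect_error(cnn_config(50, 4, 8, 6, 8, "max", 2, 10, 4), "below 1")
})

test_that("network gradients agree with finite differences", {
  expect_lt(model_fd_check(mlp_config(40, c(7, 5), "elu", 4)), 1e-6)
  expect_lt(model_fd_check(mlp_config(40, 11, "leakyrelu", 4)), 1e-6)
  expect_lt(model_fd_check(cnn_config(60, 2, 3, 4, 2, "max", 2, 10, 4)), 1e-6)
  expect_lt(model_fd_check(cnn_config(60, 2, 3, 4, 2, "average", 1, 10, 4)),
            1e-6)
  expect_lt(model_fd_check(
    cnn_config(60, 2, 3, 4, 2, "none", feedforward_size = 10, n_output = 4)
  ), 1e-6)
  expect_lt(model_fd_check(transformer_config(48, 8, 12, 3, 2, 10, 1, 4)),
            1e-6)
  expect_lt(model_fd_check(transformer_config(50, 8, 8, 2, 1, 6, 2, 3)),
            1e-6)
})

test_that("transformer configurations honour their invariants", {
  expect_error(transformer_config(1000, 100, 512, 5), "divisible")
  cfg <- transformer_config(46000, 1000, 512, 1, 1, 2048, 1, 44)
  expect_identical(cfg$n_bins, 46L)
  # the tuned preset constructs and runs on a reduced input
  opt <- transformer_config(2000, 500, 512, 16, 1, 512, 1, 44)
  expect_identical(opt$n_bins, 4L)
  y <- predict(nn_init(opt, seed = 3), matrix(rnorm(2 * 2000), 2))
  expect_identical(dim(y), c(2L, 44L))
})

test_that("transformer reduces to the layer-norm linear path when gated", {
  # zero the attention output and feedforward projections: the encoder
  # becomes LN2(LN1(embedding + positional encoding)), and the output is
  # the linear head applied to that path
  cfg <- transformer_config(12, 12, 6, 1, 1, 5, 1, 2)
  m <- nn_init(cfg, seed = 4)
  for (nm in c("Wo1", "bo1", "Wf2_1", "bf2_1")) m$params[[nm]][] <- 0
  x <- matrix(rnorm(12), 1)
  H <- as.numeric(x %*% m$params$We + m$params$be) +
    nmrquant:::positional_encoding(1, 6)[1, ]
  ln <- function(v, g, b) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5) * g + b
  }
  H1 <- ln(H, m$params$g1_1, m$params$be1_1)
  H2 <- ln(H1, m$params$g2_1, m$params$be2_1)
  manual <- as.numeric(H2 %*% m$params$Wh + m$params$bh)
  expect_equal(as.numeric(predict(m, x)), manual, tolerance = 1e-10)
})

test_that("batch inference is vectorised over thousands of spectra", {
  cfg <- transformer_config(200, 50, 8, 2, 1, 16, 1, 4)
  m <- nn_init(cfg, seed = 5)
  X <- matrix(rnorm(5000 * 200), 5000)
  y <- predict(m, X, chunk = 1024)
  expect_identical(dim(y), c(5000L, 4L))
  # chunked and unchunked paths agree
  expect_equal(y[1:7, ], predict(m, X[1:7, , drop = FALSE]))
})

test_that("a single conv layer is equivariant to one-stride translations", {
  set.seed(7)
  k <- 4L
  stride <- 2L
  L <- 40L
  x <- rnorm(L)
  W <- matrix(rnorm(k * 3), k, 3)
  conv <- function(v) {
    nmrquant:::conv_gather(matrix(v, ncol = 1), 1, L,
                           nmrquant:::conv_out_len(L, k, stride),
                           k, stride) %*% W
  }
  y <- conv(x)
  y_shift <- conv(c(rep(0, stride), x[1:(L - stride)]))
  # shifting the input by one stride shifts the feature map one position
  expect_equal(y_shift[-1, ], y[-nrow(y), ], tolerance = 1e-12)
})
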