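# Shared small fixtures, generated in code.

tiny_grid <- function(n = 2000) ppm_grid(-0.32, 10.21, n)

tiny_library <- function(n_met = 3, n_points = 2000, seed = 7,
                         field = 400) {
  default_library(n_met, field_strength = field, seed = seed,
                  grid = tiny_grid(n_points))
}

# Finite-difference gradient check for a model configuration.
model_fd_check <- function(cfg, B = 3, eps = 1e-5, n_coord = 5, seed = 42) {
  set.seed(seed)
  m <- nn_init(cfg, seed = seed + 1)
  X <- matrix(rnorm(B * cfg$n_input), B)
  Yt <- matrix(runif(B * cfg$n_output, 0.5, 2), B)
  lspec <- loss_spec("mse")
  fwd <- nmrquant:::nn_forward(m, X, cache = TRUE)
  gr <- nmrquant:::nn_backward(m, fwd, nn_loss(lspec, fwd$Y, Yt)$grad)
  worst <- 0
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(n_coord, length(p)))) {
      up <- m
      up$params[[nm]][i] <- p[i] + eps
      dn <- m
      dn$params[[nm]][i] <- p[i] - eps
      num <- (nn_loss(lspec, nmrquant:::nn_forward(up, X), Yt)$value -
                nn_loss(lspec, nmrquant:::nn_forward(dn, X), Yt)$value) /
        (2 * eps)
      ana <- gr[[nm]][i]
      if (max(abs(num), abs(ana)) > 1e-4) {
        worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana)))
      }
    }
  }
  worst
}
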