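# Regression losses for high-dynamic-range concentration targets. Each
# loss is a pure function of a (prediction, target) batch returning the
# scalar value and its gradient with respect to the predictions, which is
# what the training loop consumes.

#' Specify a training loss
#'
#' Available losses: relative absolute error (`"rae"`), relative squared
#' error (`"rse"`), mean squared error (`"mse"`), quantile/pinball loss
#' (`"quantile"`, with `q` in (0, 1)), log-cosh (`"logcosh"`), mean
#' squared logarithmic error (`"msle"`), mean absolute percent error
#' (`"mape"`, in percent), and a 50:50 MSE + MAPE combination
#' (`"mse_mape"`). RAE/RSE normalise by the deviation of the targets from
#' their batch mean; MAPE-family losses require strictly positive
#' targets. For `"mse_mape"` the two terms are divided by detached
#' normalisers (running means during training) because raw MSE (mM^2) and
#' MAPE (%) live on incommensurate scales.
#'
#' @param name Loss name as above.
#' @param q Quantile for `"quantile"` (default 0.5; q = 0.5 is half the
#'   mean absolute error).
#' @param mix Weights of the (MSE, MAPE) combination; must sum to 1.
#' @return A `loss_spec`.
#' @export
loss_spec <- function(name = c("rae", "rse", "mse", "quantile", "logcosh",
                               "msle", "mape", "mse_mape"),
                      q = 0.5, mix = c(0.5, 0.5)) {
  name <- match.arg(name)
  if (name == "quantile" && (q <= 0 || q >= 1)) {
    abort("`q` must lie strictly inside (0, 1).")
  }
  if (abs(sum(mix) - 1) > 1e-9) abort("`mix` weights must sum to 1.")
  structure(list(name = name, q = q, mix = mix), class = "loss_spec")
}

#' Evaluate a loss and its gradient
#'
#' @param spec A [loss_spec()].
#' @param pred,target Matrices (or vectors) of identical shape, in mM.
#' @param normalizers Length-2 detached normalisers for the MSE and MAPE
#'   terms of `"mse_mape"` (the training loop maintains running means;
#'   standalone calls default to `c(1, 1)`).
#' @return List with `value` (scalar) and `grad` (d value / d pred, same
#'   shape as `pred`).
#' @examples
#' sp <- loss_spec("quantile", q = 0.5)
#' nn_loss(sp, pred = c(1, 2), target = c(2, 2))$value
#' @export
nn_loss <- function(spec, pred, target, normalizers = c(1, 1)) {
  stopifnot(inherits(spec, "loss_spec"))
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target)) {
    abort("`pred` and `target` must have identical shape.")
  }
  p <- as.numeric(pred)
  t <- as.numeric(target)
  n <- length(p)
  shape_grad <- function(g) {
    if (!is.null(dim(pred))) dim(g) <- dim(pred)
    g
  }
  if (spec$name %in% c("mape", "msle", "mse_mape")) {
    zero <- which(t <= 0)
    if (length(zero) > 0) {
      abort(sprintf("non-positive target(s) at index/indices: %s",
                    paste(head(zero, 5), collapse = ", ")))
    }
  }
  res <- switch(spec$name,
    rae = {
      denom <- sum(abs(t - mean(t)))
      if (denom == 0) abort("RAE undefined for constant targets.")
      list(value = sum(abs(p - t)) / denom, grad = sign(p - t) / denom)
    },
    rse = {
      denom <- sum((t - mean(t))^2)
      if (denom == 0) abort("RSE undefined for constant targets.")
      list(value = sum((p - t)^2) / denom, grad = 2 * (p - t) / denom)
    },
    mse = list(value = mean((p - t)^2), grad = 2 * (p - t) / n),
    quantile = {
      q <- spec$q
      r <- t - p
      list(value = mean(pmax(q * r, (q - 1) * r)),
           grad = ifelse(r > 0, -q, ifelse(r < 0, 1 - q, 0)) / n)
    },
    logcosh = {
      x <- p - t
      # |x| + log1p(exp(-2|x|)) - log 2 is log(cosh(x)) without overflow
      list(value = mean(abs(x) + log1p(exp(-2 * abs(x))) - log(2)),
           grad = tanh(x) / n)
    },
    msle = {
      if (any(p <= -1)) {
        abort(sprintf("log argument <= 0 at prediction index/indices: %s",
                      paste(head(which(p <= -1), 5), collapse = ", ")))
      }
      d <- log1p(p) - log1p(t)
      list(value = mean(d^2), grad = 2 * d / ((1 + p) * n))
    },
    mape = list(value = 100 * mean(abs(p - t) / abs(t)),
                grad = 100 * sign(p - t) / (abs(t) * n)),
    mse_mape = {
      m1 <- nn_loss(loss_spec("mse"), p, t)
      m2 <- nn_loss(loss_spec("mape"), p, t)
      list(
        value = spec$mix[1] * m1$value / normalizers[1] +
          spec$mix[2] * m2$value / normalizers[2],
        grad = spec$mix[1] * m1$grad / normalizers[1] +
          spec$mix[2] * m2$grad / normalizers[2],
        components = c(mse = m1$value, mape = m2$value)
      )
    }
  )
  res$grad <- shape_grad(res$grad)
  res
}

#' Finite-difference check of a loss gradient
#'
#' Compares the analytic gradient with central finite differences at a
#' given (pred, target) point. Kink points of the absolute-value losses
#' (entries with `pred == target`, or quantile residual 0) are skipped
#' with a notice since the loss is not differentiable there.
#'
#' @param spec A [loss_spec()].
#' @param pred,target Evaluation point.
#' @param eps Finite-difference step.
#' @return List with `max_rel_dev` (maximum relative deviation over
#'   non-kink coordinates) and `skipped` (number of kink coordinates).
#' @export
loss_gradient_check <- function(spec, pred, target, eps = 1e-6) {
  ana <- nn_loss(spec, pred, target)$grad
  p <- as.numeric(pred)
  kink <- if (spec$name %in% c("rae", "quantile", "mape")) {
    abs(p - as.numeric(target)) < 10 * eps
  } else {
    rep(FALSE, length(p))
  }
  if (any(kink)) {
    message(sprintf("skipping %d kink coordinate(s)", sum(kink)))
  }
  num <- numeric(length(p))
  for (i in which(!kink)) {
    up <- pred
    dn <- pred
    up[i] <- up[i] + eps
    dn[i] <- dn[i] - eps
    num[i] <- (nn_loss(spec, up, target)$value -
                 nn_loss(spec, dn, target)$value) / (2 * eps)
  }
  idx <- which(!kink)
  denom <- pmax(abs(num[idx]), abs(as.numeric(ana)[idx]), 1e-8)
  list(max_rel_dev = if (length(idx)) {
    max(abs(num[idx] - as.numeric(ana)[idx]) / denom)
  } else 0,
  skipped = sum(kink))
}
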