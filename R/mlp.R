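# Minimal feed-forward network (ELU hidden layers, linear scalar output)
# trained with Adam. Supports two losses:
#   - "mse":     mean squared error against a numeric target
#   - "physics": mean squared error between observed LE and
#                pm_forward(exp(output)), differentiated through the
#                quadratic Penman-Monteith operator
# This is the physics-constrained core of the hybrid models, so it is
# authored here rather than delegated to a generic fitting package.

.elu <- function(x) ifelse(x > 0, x, expm1(x))
.elu_grad <- function(x, y) ifelse(x > 0, 1, y + 1)  # y = elu(x)

mlp_init <- function(n_in, hidden = c(64, 64), seed = 1L) {
  set.seed(seed)
  sizes <- c(n_in, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                     fan_in, sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

mlp_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  pre <- vector("list", L)
  a <- X
  acts[[1L]] <- a
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]]
    z <- sweep(z, 2, net$b[[l]], "+")
    pre[[l]] <- z
    a <- if (l < L) .elu(z) else z
    acts[[l + 1L]] <- a
  }
  if (keep) list(out = drop(a), acts = acts, pre = pre) else drop(a)
}

# Backpropagate d(loss)/d(output) (length-n vector) into parameter gradients.
mlp_backward <- function(net, fwd, dout) {
  L <- length(net$W)
  n <- length(dout)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(dout, n, 1L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      delta <- delta * .elu_grad(fwd$pre[[l - 1L]], fwd$acts[[l]])
    }
  }
  list(W = gW, b = gb)
}

#' Train the internal feed-forward network
#'
#' @param X numeric matrix of (already standardized) predictors
#' @param target numeric vector: the regression target for loss = "mse",
#'   or observed LE (W m-2) for loss = "physics"
#' @param loss "mse" or "physics"
#' @param state pm_state rows aligned with X (physics loss only)
#' @param hidden hidden layer sizes
#' @param epochs,batch,lr,patience optimizer controls; 10% of the rows are
#'   held out for early stopping
#' @param seed RNG seed fixing initialization, split and shuffling
#' @param init optional warm-start network (same architecture)
#' @param out_bias initial output bias (centers exp(out) for physics loss)
#' @return list with the network, per-epoch validation loss, best epoch
#' @keywords internal
mlp_train <- function(X, target, loss = c("mse", "physics"), state = NULL,
                      hidden = c(64, 64), epochs = 200L, batch = 1024L,
                      lr = 2e-3, patience = 20L, seed = 1L, init = NULL,
                      out_bias = NULL) {
  loss <- match.arg(loss)
  stopifnot(is.matrix(X), nrow(X) == length(target))
  if (loss == "physics" && (is.null(state) || nrow(state) != nrow(X)))
    stop("physics loss needs a pm_state aligned with X")
  n <- nrow(X)
  net <- if (is.null(init)) mlp_init(ncol(X), hidden, seed) else init
  if (!is.null(out_bias)) net$b[[length(net$b)]] <- out_bias
  set.seed(seed + 1L)
  idx <- sample.int(n)
  n_val <- max(1L, floor(0.1 * n))
  val <- idx[seq_len(n_val)]
  trn <- idx[-seq_len(n_val)]

  loss_grad <- function(out, rows) {
    if (loss == "mse") {
      r <- out - target[rows]
      list(value = mean(r^2), grad = 2 * r / length(r))
    } else {
      z <- pmin(pmax(out, -5), 14)       # keep exp(z) in a sane Rs range
      rs <- exp(z)
      st <- state[rows, , drop = FALSE]
      le <- pm_forward(rs, st)
      dle <- pm_forward_dRs(rs, st)
      ok <- is.finite(le) & is.finite(dle)
      r <- ifelse(ok, le - target[rows], 0)
      g <- ifelse(ok, 2 * r * dle * rs / sum(ok), 0)
      g[out < -5 | out > 14] <- 0
      if (!is.finite(sum(r^2))) stop("non-finite physics loss: diverged")
      list(value = sum(r^2) / max(sum(ok), 1L), grad = g)
    }
  }
  eval_loss <- function(rows) {
    out <- mlp_forward(net, X[rows, , drop = FALSE])
    loss_grad(out, rows)$value
  }

  # Adam state
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  best <- list(net = net, val = eval_loss(val), epoch = 0L)
  history <- numeric(0)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(trn)
    starts <- seq(1L, length(ord), by = batch)
    for (s0 in starts) {
      rows <- ord[s0:min(s0 + batch - 1L, length(ord))]
      fwd <- mlp_forward(net, X[rows, , drop = FALSE], keep = TRUE)
      lg <- loss_grad(fwd$out, rows)
      gr <- mlp_backward(net, fwd, lg$grad)
      t <- t + 1L
      for (l in seq_along(net$W)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gr$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gr$W[[l]]^2
        net$W[[l]] <- net$W[[l]] - lr * (mW[[l]] / (1 - b1^t)) /
          (sqrt(vW[[l]] / (1 - b2^t)) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gr$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gr$b[[l]]^2
        net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / (1 - b1^t)) /
          (sqrt(vb[[l]] / (1 - b2^t)) + eps)
      }
    }
    vl <- eval_loss(val)
    history <- c(history, vl)
    if (is.finite(vl) && vl < best$val - 1e-10) {
      best <- list(net = net, val = vl, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(net = best$net, val_loss = best$val, history = history,
       best_epoch = best$epoch)
}
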