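# Multilayer perceptron for binary classification, trained with
# minibatch Adam on log-loss. No installed R package fits networks with
# more than one hidden layer, so the forward/backward passes are written
# here directly with matrix algebra; the architecture knobs mirror the
# multilayer-perceptron classifiers the model suite enumerates
# (hidden layers 25-25-25 or 30-20-10-5; logistic/tanh/relu activations;
# Adam with initial learning rate 1e-3; early stopping on a 10%
# validation split with tolerance 1e-4).

.act <- function(z, kind) {
  switch(kind,
         logistic = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         relu = pmax(z, 0),
         abort(paste0("unknown activation: ", kind)))
}

.act_grad <- function(a, kind) {
  switch(kind,
         logistic = a * (1 - a),
         tanh = 1 - a^2,
         relu = (a > 0) * 1)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_fit <- function(x, y, hidden, activation = "relu", lr = 1e-3,
                    max_epochs = 1000L, tol = 1e-4, val_fraction = 0.1,
                    patience = 10L, batch_size = 200L, alpha = 1e-4) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  sizes <- c(p, hidden, 1L)
  L <- length(sizes) - 1L

  # Glorot-uniform initialization
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mW <- map(W, function(w) w * 0); vW <- mW
  mb <- map(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L

  # held-out validation split for early stopping
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]
  xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  nt <- nrow(xt)
  bs <- min(batch_size, nt)

  forward <- function(xx) {
    A <- vector("list", L + 1L)
    A[[1L]] <- xx
    for (l in seq_len(L)) {
      z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
      A[[l + 1L]] <- if (l < L) .act(z, activation) else .sigmoid(z)
    }
    A
  }
  logloss <- function(pr, yy) {
    pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
    -mean(yy * log(pr) + (1 - yy) * log(1 - pr))
  }

  best_val <- Inf; best_W <- W; best_b <- b; stall <- 0L; epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(nt)
    for (start in seq(1L, nt, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, nt)]
      xb <- xt[idx, , drop = FALSE]; yb <- yt[idx]
      m <- length(idx)
      A <- forward(xb)
      delta <- (A[[L + 1L]] - yb) / m          # d loss / d z_out
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + (alpha / m) * W[[l]]
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * .act_grad(A[[l]], activation)
        }
        t <- t + 1L
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    val_loss <- logloss(forward(xv)[[L + 1L]][, 1L], yv)
    if (val_loss < best_val - tol) {
      best_val <- val_loss; best_W <- W; best_b <- b; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  list(W = best_W, b = best_b, activation = activation, sizes = sizes,
       epochs = epoch, val_loss = best_val)
}

mlp_predict <- function(fit, x) {
  A <- as.matrix(x)
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    A <- if (l < L) .act(z, fit$activation) else .sigmoid(z)
  }
  A[, 1L]
}
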