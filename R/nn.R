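# Minimal recurrent-network engine: a single-layer LSTM with a softmax
# readout (optionally through one hidden fully connected layer with dropout)
# and a plain softmax regression head, both trained by Adam with full
# backpropagation (through time for the LSTM). Vectorized over minibatches
# so the hot loops are BLAS matrix products. Internal: the classifier
# objects in classifiers.R are the public surface.

nn_lstm_init <- function(d, H, n_out, fc_hidden = NULL) {
  # small uniform init, forget-gate bias 1 (standard recipe for trainability)
  u <- function(nr, nc, s) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  s_in <- sqrt(1 / d); s_h <- sqrt(1 / H)
  par <- list(Wx = u(d, 4 * H, s_in), Wh = u(H, 4 * H, s_h),
              b = c(rep(0, H), rep(1, H), rep(0, 2 * H)))
  if (is.null(fc_hidden)) {
    par$Why <- u(H, n_out, s_h); par$by <- rep(0, n_out)
  } else {
    par$Wf <- u(H, fc_hidden, s_h); par$bf <- rep(0, fc_hidden)
    par$Why <- u(fc_hidden, n_out, sqrt(1 / fc_hidden)); par$by <- rep(0, n_out)
  }
  attr(par, "dims") <- list(d = d, H = H, n_out = n_out, fc_hidden = fc_hidden)
  par
}

# X: array [T, B, d]; returns list(probs, cache)
nn_lstm_forward <- function(par, X, dropout = 0, train = FALSE) {
  dm <- attr(par, "dims"); H <- dm$H
  T_ <- dim(X)[1L]; B <- dim(X)[2L]
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (train) vector("list", T_) else NULL
  bmat <- matrix(par$b, B, 4 * H, byrow = TRUE)
  for (t in seq_len(T_)) {
    Xt <- matrix(X[t, , ], B, dm$d)
    A <- Xt %*% par$Wx + h %*% par$Wh + bmat
    i <- sigmoid(A[, 1:H, drop = FALSE])
    f <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(A[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(A[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    if (train) cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c_prev,
                                  tc = tc, h_prev = h_prev, Xt = Xt)
  }
  out <- list(hT = h)
  if (is.null(dm$fc_hidden)) {
    z <- h
  } else {
    pre <- h %*% par$Wf + matrix(par$bf, B, dm$fc_hidden, byrow = TRUE)
    a <- pmax(pre, 0)
    mask <- NULL
    if (train && dropout > 0) {
      mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout), nrow(a)) / (1 - dropout)
      a <- a * mask
    }
    out$fc_pre <- pre; out$fc_act <- a; out$fc_mask <- mask
    z <- a
  }
  logits <- z %*% par$Why + matrix(par$by, B, dm$n_out, byrow = TRUE)
  out$probs <- softmax_rows(logits)
  out$cache <- cache
  out
}

# Y: one-hot B x n_out; returns gradients with the same names as par
nn_lstm_backward <- function(par, X, fwd, Y) {
  dm <- attr(par, "dims"); H <- dm$H
  T_ <- dim(X)[1L]; B <- dim(X)[2L]
  dlogits <- (fwd$probs - Y) / B
  g <- list()
  if (is.null(dm$fc_hidden)) {
    g$Why <- t(fwd$hT) %*% dlogits
    g$by <- colSums(dlogits)
    dh <- dlogits %*% t(par$Why)
  } else {
    g$Why <- t(fwd$fc_act) %*% dlogits
    g$by <- colSums(dlogits)
    da <- dlogits %*% t(par$Why)
    if (!is.null(fwd$fc_mask)) da <- da * fwd$fc_mask
    da <- da * (fwd$fc_pre > 0)
    g$Wf <- t(fwd$hT) %*% da
    g$bf <- colSums(da)
    dh <- da %*% t(par$Wf)
  }
  gWx <- matrix(0, dm$d, 4 * H); gWh <- matrix(0, H, 4 * H); gb <- rep(0, 4 * H)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    cache_t <- fwd$cache[[t]]
    do_ <- dh * cache_t$tc
    dc <- dc + dh * cache_t$o * (1 - cache_t$tc^2)
    di <- dc * cache_t$g
    dg <- dc * cache_t$i
    df <- dc * cache_t$c_prev
    dA <- cbind(di * cache_t$i * (1 - cache_t$i),
                df * cache_t$f * (1 - cache_t$f),
                do_ * cache_t$o * (1 - cache_t$o),
                dg * (1 - cache_t$g^2))
    gWx <- gWx + t(cache_t$Xt) %*% dA
    gWh <- gWh + t(cache_t$h_prev) %*% dA
    gb <- gb + colSums(dA)
    dh <- dA %*% t(par$Wh)
    dc <- dc * cache_t$f
  }
  g$Wx <- gWx; g$Wh <- gWh; g$b <- gb
  g
}

adam_new <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0), t = 0L)
}

adam_step <- function(par, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = st)
}

# X: array [T, N, d]; y: integer class ids 1..n_out
nn_train_lstm <- function(X, y, n_out, hidden, config, fc_hidden = NULL,
                          dropout = 0) {
  N <- dim(X)[2L]; d <- dim(X)[3L]
  par <- nn_lstm_init(d, hidden, n_out, fc_hidden)
  st <- adam_new(par)
  Y <- one_hot(y, n_out)
  loss_hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, N)]
      Xb <- X[, idx, , drop = FALSE]
      fwd <- nn_lstm_forward(par, Xb, dropout = dropout, train = TRUE)
      p <- pmax(fwd$probs[cbind(seq_along(idx), y[idx])], 1e-12)
      ep_loss <- ep_loss - sum(log(p))
      g <- nn_lstm_backward(par, Xb, fwd, Y[idx, , drop = FALSE])
      upd <- adam_step(par, g, st, config$learning_rate, config$beta1, config$beta2)
      par <- upd$par
      st <- upd$state
    }
    loss_hist[ep] <- ep_loss / N
  }
  list(par = par, loss = loss_hist)
}

nn_predict_lstm <- function(par, X) {
  nn_lstm_forward(par, X, train = FALSE)$probs
}

# --- plain softmax regression head (single FC layer + softmax) ------------

nn_train_softmax <- function(X, y, n_out, config) {
  X <- as.matrix(X)
  N <- nrow(X); d <- ncol(X)
  par <- list(W = matrix(stats::runif(d * n_out, -sqrt(1 / d), sqrt(1 / d)), d, n_out),
              b = rep(0, n_out))
  st <- adam_new(par)
  Y <- one_hot(y, n_out)
  loss_hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, N)]
      Xb <- X[idx, , drop = FALSE]
      P <- softmax_rows(Xb %*% par$W + matrix(par$b, length(idx), n_out, byrow = TRUE))
      ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_along(idx), y[idx])], 1e-12)))
      dl <- (P - Y[idx, , drop = FALSE]) / length(idx)
      g <- list(W = t(Xb) %*% dl, b = colSums(dl))
      upd <- adam_step(par, g, st, config$learning_rate, config$beta1, config$beta2)
      par <- upd$par; st <- upd$state
    }
    loss_hist[ep] <- ep_loss / N
  }
  list(par = par, loss = loss_hist)
}

nn_predict_softmax <- function(par, X) {
  X <- as.matrix(X)
  softmax_rows(X %*% par$W + matrix(par$b, nrow(X), length(par$b), byrow = TRUE))
}
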