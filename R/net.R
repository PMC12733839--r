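## A compact convolutional network engine written in vectorized base R.
## Activations are 4-D arrays (height, width, channel, batch); convolutions
## are 3x3/same and run as im2col matrix products so the heavy lifting sits
## in BLAS.  Only what the parameter-prediction architecture needs is
## implemented: conv + batch-norm + ReLU + 2x2 max-pool blocks, adaptive
## average pooling, fully connected layers with dropout, and Adam.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

conv_forward <- function(x, Wmat, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- array(0, c(H + 2, W + 2, C, N))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  cols <- matrix(0, H * W * N, 9 * C)
  k <- 1L
  for (ci in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    cols[, k] <- xp[(1 + dy):(H + dy), (1 + dx):(W + dx), ci, ]
    k <- k + 1L
  }
  out <- cols %*% Wmat
  out <- sweep(out, 2, b, "+")
  Cout <- ncol(Wmat)
  y <- aperm(array(out, c(H, W, N, Cout)), c(1, 2, 4, 3))
  list(y = y, cols = cols, dims = c(H, W, C, N))
}

conv_backward <- function(dy, cols, Wmat, dims) {
  H <- dims[1]; W <- dims[2]; C <- dims[3]; N <- dims[4]
  Cout <- ncol(Wmat)
  dmat <- matrix(aperm(dy, c(1, 2, 4, 3)), H * W * N, Cout)
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wmat)
  dxp <- array(0, c(H + 2, W + 2, C, N))
  k <- 1L
  for (ci in seq_len(C)) for (dx in 0:2) for (dy_ in 0:2) {
    idx_r <- (1 + dy_):(H + dy_); idx_c <- (1 + dx):(W + dx)
    dxp[idx_r, idx_c, ci, ] <- dxp[idx_r, idx_c, ci, , drop = FALSE] +
      array(dcols[, k], c(H, W, 1, N))
    k <- k + 1L
  }
  list(dx = dxp[2:(H + 1), 2:(W + 1), , , drop = FALSE], dW = dW, db = db)
}

# channel-last matrix view used by batch norm: (H*W*N) x C
to_cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}
from_cmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_forward <- function(x, gamma, beta, rmean, rvar, train) {
  d <- dim(x)
  xm <- to_cmat(x)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
  } else {
    mu <- rmean; v <- rvar
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(v + BN_EPS), "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = from_cmat(y, d), xhat = xhat, var = v, mu = mu, dims = d,
       rmean = if (train) (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu
               else rmean,
       rvar = if (train) (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * v
              else rvar)
}

bn_backward <- function(dy, cache, gamma) {
  d <- cache$dims
  dym <- to_cmat(dy)
  xhat <- cache$xhat
  m <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / m, "*")
  dxm <- sweep(t1 - t2, 2, sqrt(cache$var + BN_EPS), "/")
  list(dx = from_cmat(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  if (d[1] < 2 || d[2] < 2)   # map already collapsed; pooling is identity
    return(list(y = x, identity = TRUE, full_dims = d))
  H <- d[1] %/% 2 * 2; W <- d[2] %/% 2 * 2
  x <- x[seq_len(H), seq_len(W), , , drop = FALSE]
  o <- seq(1, H, 2); e <- seq(2, H, 2)
  oc <- seq(1, W, 2); ec <- seq(2, W, 2)
  a <- x[o, oc, , , drop = FALSE]; b <- x[e, oc, , , drop = FALSE]
  cc <- x[o, ec, , , drop = FALSE]; dd <- x[e, ec, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  list(y = y, masks = list(a == y, b == y & a != y,
                           cc == y & a != y & b != y,
                           dd == y & a != y & b != y & cc != y),
       in_dims = dim(x), full_dims = d)
}

maxpool_backward <- function(dy, cache) {
  if (isTRUE(cache$identity)) return(dy)
  d <- cache$in_dims
  dx <- array(0, cache$full_dims)
  H <- d[1]; W <- d[2]
  o <- seq(1, H, 2); e <- seq(2, H, 2)
  oc <- seq(1, W, 2); ec <- seq(2, W, 2)
  dx[o, oc, , ] <- dy * cache$masks[[1]]
  dx[e, oc, , ] <- dy * cache$masks[[2]]
  dx[o, ec, , ] <- dy * cache$masks[[3]]
  dx[e, ec, , ] <- dy * cache$masks[[4]]
  dx
}

# Adaptive average pooling to P x P (region boundaries floor(i*H/P) ..
# ceil((i+1)*H/P), the convention used by mainstream deep-learning
# frameworks; works for H < P as well).
adapt_regions <- function(H, P) {
  lapply(seq_len(P) - 1L, function(i) {
    (floor(i * H / P) + 1L):ceiling((i + 1L) * H / P)
  })
}

adaptpool_forward <- function(x, P) {
  d <- dim(x)
  ry <- adapt_regions(d[1], P); rx <- adapt_regions(d[2], P)
  y <- array(0, c(P, P, d[3], d[4]))
  for (i in seq_len(P)) for (j in seq_len(P)) {
    blk <- x[ry[[i]], rx[[j]], , , drop = FALSE]
    y[i, j, , ] <- colMeans(matrix(blk, length(ry[[i]]) * length(rx[[j]]),
                                   d[3] * d[4]))
  }
  list(y = y, ry = ry, rx = rx, dims = d)
}

adaptpool_backward <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  for (i in seq_along(cache$ry)) for (j in seq_along(cache$rx)) {
    ry <- cache$ry[[i]]; rx <- cache$rx[[j]]
    n <- length(ry) * length(rx)
    g <- dy[i, j, , , drop = FALSE] / n
    dx[ry, rx, , ] <- dx[ry, rx, , , drop = FALSE] +
      array(rep(as.vector(g), each = n), c(length(ry), length(rx),
                                           d[3], d[4]))
  }
  dx
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

init_net_params <- function(cfg) {
  conv <- list(); bn <- list()
  cin <- 1L
  for (i in seq_along(cfg$conv_channels)) {
    cout <- cfg$conv_channels[i]
    conv[[i]] <- list(W = he_init(9 * cin, cout, 9 * cin), b = rep(0, cout))
    bn[[i]] <- list(gamma = rep(1, cout), beta = rep(0, cout),
                    rmean = rep(0, cout), rvar = rep(1, cout))
    cin <- cout
  }
  fc <- list()
  din <- cfg$pooled_size^2 * cin
  for (i in seq_along(cfg$fc_widths)) {
    dout <- cfg$fc_widths[i]
    sc <- if (i == length(cfg$fc_widths)) 0.1 else 1  # head starts near 0
    fc[[i]] <- list(W = sc * he_init(din, dout, din), b = rep(0, dout))
    din <- dout
  }
  list(conv = conv, bn = bn, fc = fc)
}

# Forward pass.  x: (H, W, 1, N) array of [0,1] intensities.  Returns raw
# (N x 3) head outputs; with cache = TRUE also everything backward needs.
net_forward <- function(net, x, train = FALSE, cache = FALSE) {
  cfg <- net$cfg
  caches <- list(conv = list(), bn = list(), relu = list(), pool = list())
  for (i in seq_along(net$conv)) {
    cf <- conv_forward(x, net$conv[[i]]$W, net$conv[[i]]$b)
    bf <- bn_forward(cf$y, net$bn[[i]]$gamma, net$bn[[i]]$beta,
                     net$bn[[i]]$rmean, net$bn[[i]]$rvar, train)
    if (train) {
      net$bn[[i]]$rmean <- bf$rmean
      net$bn[[i]]$rvar <- bf$rvar
    }
    r <- bf$y > 0
    y <- bf$y * r
    pf <- maxpool_forward(y)
    if (cache) {
      caches$conv[[i]] <- cf[c("cols", "dims")]
      caches$bn[[i]] <- bf[c("xhat", "var", "mu", "dims")]
      caches$relu[[i]] <- r
      caches$pool[[i]] <- pf[setdiff(names(pf), "y")]
    }
    x <- pf$y
  }
  ap <- adaptpool_forward(x, cfg$pooled_size)
  N <- dim(x)[4]
  feat <- t(matrix(ap$y, length(ap$y) / N, N))   # N x (P*P*C)
  caches$adapt <- ap[c("ry", "rx", "dims")]
  caches$feat_dim <- dim(ap$y)
  if (cache) caches$conv_out <- x   # final conv block output (pre adapt-pool)
  h <- feat
  caches$fc_in <- list()
  caches$fc_relu <- list()
  caches$drop <- list()
  nl <- length(net$fc)
  for (i in seq_len(nl)) {
    caches$fc_in[[i]] <- h
    h <- h %*% net$fc[[i]]$W
    h <- sweep(h, 2, net$fc[[i]]$b, "+")
    if (i < nl) {
      r <- h > 0
      h <- h * r
      caches$fc_relu[[i]] <- r
      if (train && cfg$dropout_rate > 0) {
        m <- matrix(rbinom(length(h), 1, 1 - cfg$dropout_rate),
                    nrow(h)) / (1 - cfg$dropout_rate)
        h <- h * m
        caches$drop[[i]] <- m
      }
    }
  }
  out <- list(raw = h, features = feat, net = net)
  if (cache) out$caches <- caches
  out
}

# Gradient of a scalar in the raw outputs w.r.t. the final conv block's
# activations (the adaptive-pool input): backprop through the FC stack and
# average pooling only.  Used by Grad-CAM on end-to-end classifiers.
net_conv_grad <- function(net, fwd, draw) {
  caches <- fwd$caches
  nl <- length(net$fc)
  dh <- draw
  for (i in rev(seq_len(nl))) {
    if (i < nl) {
      if (length(caches$drop) >= i && !is.null(caches$drop[[i]]))
        dh <- dh * caches$drop[[i]]
      dh <- dh * caches$fc_relu[[i]]
    }
    dh <- dh %*% t(net$fc[[i]]$W)
  }
  adaptpool_backward(array(t(dh), caches$feat_dim), caches$adapt)
}

# Backward pass from d(loss)/d(raw) (N x 3); returns gradients shaped like
# the parameter lists.
net_backward <- function(net, fwd, draw) {
  caches <- fwd$caches
  cfg <- net$cfg
  g <- list(conv = list(), bn = list(), fc = list())
  nl <- length(net$fc)
  dh <- draw
  for (i in rev(seq_len(nl))) {
    if (i < nl) {
      if (length(caches$drop) >= i && !is.null(caches$drop[[i]]))
        dh <- dh * caches$drop[[i]]
      dh <- dh * caches$fc_relu[[i]]
    }
    g$fc[[i]] <- list(dW = crossprod(caches$fc_in[[i]], dh),
                      db = colSums(dh))
    dh <- dh %*% t(net$fc[[i]]$W)
  }
  dpool <- array(t(dh), caches$feat_dim)
  dx <- adaptpool_backward(dpool, caches$adapt)
  for (i in rev(seq_along(net$conv))) {
    dx <- maxpool_backward(dx, caches$pool[[i]])
    dx <- dx * caches$relu[[i]]
    bb <- bn_backward(dx, caches$bn[[i]], net$bn[[i]]$gamma)
    g$bn[[i]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
    cb <- conv_backward(bb$dx, caches$conv[[i]]$cols, net$conv[[i]]$W,
                        caches$conv[[i]]$dims)
    g$conv[[i]] <- list(dW = cb$dW, db = cb$db)
    dx <- cb$dx
  }
  g
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(t = 0,
       m = list(conv = lapply(net$conv, zero_like),
                bn = lapply(net$bn, function(b)
                  list(gamma = b$gamma * 0, beta = b$beta * 0)),
                fc = lapply(net$fc, zero_like)),
       v = list(conv = lapply(net$conv, zero_like),
                bn = lapply(net$bn, function(b)
                  list(gamma = b$gamma * 0, beta = b$beta * 0)),
                fc = lapply(net$fc, zero_like)))
}

adam_update <- function(p, gslot, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  m <- b1 * m + (1 - b1) * gslot
  v <- b2 * v + (1 - b2) * gslot^2
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_step <- function(net, grads, state, lr) {
  state$t <- state$t + 1
  t <- state$t
  for (i in seq_along(net$conv)) {
    u <- adam_update(net$conv[[i]]$W, grads$conv[[i]]$dW,
                     state$m$conv[[i]]$W, state$v$conv[[i]]$W, lr, t)
    net$conv[[i]]$W <- u$p; state$m$conv[[i]]$W <- u$m
    state$v$conv[[i]]$W <- u$v
    u <- adam_update(net$conv[[i]]$b, grads$conv[[i]]$db,
                     state$m$conv[[i]]$b, state$v$conv[[i]]$b, lr, t)
    net$conv[[i]]$b <- u$p; state$m$conv[[i]]$b <- u$m
    state$v$conv[[i]]$b <- u$v
    u <- adam_update(net$bn[[i]]$gamma, grads$bn[[i]]$dgamma,
                     state$m$bn[[i]]$gamma, state$v$bn[[i]]$gamma, lr, t)
    net$bn[[i]]$gamma <- u$p; state$m$bn[[i]]$gamma <- u$m
    state$v$bn[[i]]$gamma <- u$v
    u <- adam_update(net$bn[[i]]$beta, grads$bn[[i]]$dbeta,
                     state$m$bn[[i]]$beta, state$v$bn[[i]]$beta, lr, t)
    net$bn[[i]]$beta <- u$p; state$m$bn[[i]]$beta <- u$m
    state$v$bn[[i]]$beta <- u$v
  }
  for (i in seq_along(net$fc)) {
    u <- adam_update(net$fc[[i]]$W, grads$fc[[i]]$dW,
                     state$m$fc[[i]]$W, state$v$fc[[i]]$W, lr, t)
    net$fc[[i]]$W <- u$p; state$m$fc[[i]]$W <- u$m; state$v$fc[[i]]$W <- u$v
    u <- adam_update(net$fc[[i]]$b, grads$fc[[i]]$db,
                     state$m$fc[[i]]$b, state$v$fc[[i]]$b, lr, t)
    net$fc[[i]]$b <- u$p; state$m$fc[[i]]$b <- u$m; state$v$fc[[i]]$b <- u$v
  }
  list(net = net, state = state)
}

# Sum of all trainable parameters -- cheap checksum for determinism tests.
net_checksum <- function(net) {
  s <- 0
  for (cv in net$conv) s <- s + sum(cv$W) + sum(cv$b)
  for (b in net$bn) s <- s + sum(b$gamma) + sum(b$beta)
  for (f in net$fc) s <- s + sum(f$W) + sum(f$b)
  s
}

net_param_count <- function(net) {
  n <- 0
  for (cv in net$conv) n <- n + length(cv$W) + length(cv$b)
  for (b in net$bn) n <- n + length(b$gamma) + length(b$beta)
  for (f in net$fc) n <- n + length(f$W) + length(f$b)
  n
}
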