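# Internal neural-network primitives for the multihead separable-conv
# classifier.  Batches are stored as [n, S, C] arrays (window, time,
# channel): that layout makes the pointwise (1x1) convolution a single
# matrix product via matrix(x, n*S, C), and lets the depthwise temporal
# convolution run as K shifted element-wise products on n x S matrices.
# Gradients are exact (verified against numerical differentiation in the
# test suite).

# "same"-padded cross-correlation of each row of M (n x S) with kernel k.
conv_same <- function(M, k) {
  K <- length(k)
  S <- ncol(M); n <- nrow(M)
  pl <- (K - 1L) %/% 2L
  Mp <- cbind(matrix(0, n, pl), M, matrix(0, n, K - 1L - pl))
  out <- matrix(0, n, S)
  for (j in seq_len(K))
    out <- out + Mp[, j:(j + S - 1L), drop = FALSE] * k[j]
  out
}

# Gradient of conv_same wrt the kernel and the input.
conv_same_backward <- function(M, k, dOut) {
  K <- length(k)
  S <- ncol(M); n <- nrow(M)
  pl <- (K - 1L) %/% 2L
  Mp <- cbind(matrix(0, n, pl), M, matrix(0, n, K - 1L - pl))
  dk <- numeric(K)
  dMp <- matrix(0, n, S + K - 1L)
  for (j in seq_len(K)) {
    cols <- j:(j + S - 1L)
    dk[j] <- sum(Mp[, cols, drop = FALSE] * dOut)
    dMp[, cols] <- dMp[, cols] + dOut * k[j]
  }
  list(dk = dk, dM = dMp[, (pl + 1L):(pl + S), drop = FALSE])
}

# Depthwise conv: X [n,S,C], W [K, C*D] -> Y [n,S,C*D]; output map
# m = (c-1)*D + d comes from input channel c.
depthwise_forward <- function(X, W, D) {
  d <- dim(X); n <- d[1]; S <- d[2]; C <- d[3]
  M <- dim(W)[2]
  Y <- array(0, c(n, S, M))
  for (m in seq_len(M)) {
    cin <- (m - 1L) %/% D + 1L
    Y[, , m] <- conv_same(X[, , cin, drop = TRUE], W[, m])
  }
  Y
}

depthwise_backward <- function(X, W, D, dY, need_dX = TRUE) {
  d <- dim(X); n <- d[1]; S <- d[2]; C <- d[3]
  M <- dim(W)[2]
  dW <- matrix(0, nrow(W), M)
  dX <- if (need_dX) array(0, dim(X)) else NULL
  for (m in seq_len(M)) {
    cin <- (m - 1L) %/% D + 1L
    g <- conv_same_backward(X[, , cin, drop = TRUE], W[, m],
                            dY[, , m, drop = TRUE])
    dW[, m] <- g$dk
    if (need_dX) dX[, , cin] <- dX[, , cin] + g$dM
  }
  list(dW = dW, dX = dX)
}

# Pointwise (1x1) conv: Y [n,S,M] x P [M,F] + b -> [n,S,F].
pointwise_forward <- function(Y, P, b) {
  d <- dim(Y)
  Z <- matrix(Y, d[1] * d[2], d[3]) %*% P
  Z <- Z + rep(b, each = d[1] * d[2])
  array(Z, c(d[1], d[2], ncol(P)))
}

pointwise_backward <- function(Y, P, dZ) {
  d <- dim(Y)
  Ymat <- matrix(Y, d[1] * d[2], d[3])
  dZmat <- matrix(dZ, d[1] * d[2], ncol(P))
  list(dP = crossprod(Ymat, dZmat),
       db = colSums(dZmat),
       dY = array(dZmat %*% t(P), d))
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

# Initialise all trainable arrays for the given shape.
init_params <- function(n_channels, S, cfg) {
  C <- n_channels; F <- cfg$scl_filters; D <- cfg$depth_multiplier
  H <- cfg$head_units
  blocks <- lapply(cfg$kernel_schedule, function(K) {
    list(
      dw1 = glorot(c(K, C * D), K, K),
      pw1 = glorot(c(C * D, F), C * D, F),
      b1  = numeric(F),
      dw2 = glorot(c(K, F * D), K, K),
      pw2 = glorot(c(F * D, F), F * D, F),
      b2  = numeric(F),
      Wh  = glorot(c(S * F, H), S * F, H),
      bh  = numeric(H)
    )
  })
  list(blocks = blocks,
       Wf = glorot(c(cfg$head_units, 1L), cfg$head_units, 1L),
       bf = 0)
}

# Forward pass.  Returns probabilities and, if keep = TRUE, the caches
# needed for backprop.
mhc_forward <- function(params, X, cfg, keep = FALSE, dropout = 0) {
  d <- dim(X); n <- d[1]
  B <- length(params$blocks)
  D <- cfg$depth_multiplier
  heads <- vector("list", B)
  caches <- if (keep) vector("list", B) else NULL
  Hsum <- 0
  for (b in seq_len(B)) {
    p <- params$blocks[[b]]
    Y1 <- depthwise_forward(X, p$dw1, D)
    Z1 <- pointwise_forward(Y1, p$pw1, p$b1)
    A1 <- relu(Z1)
    Y2 <- depthwise_forward(A1, p$dw2, D)
    Z2 <- pointwise_forward(Y2, p$pw2, p$b2)
    A2 <- relu(Z2)
    flat <- matrix(A2, n, length(A2) / n)
    mask <- NULL
    if (dropout > 0) {                          # inverted dropout, train only
      mask <- matrix((runif(length(flat)) >= dropout) / (1 - dropout),
                     nrow(flat), ncol(flat))
      flat <- flat * mask
    }
    Hb <- softmax_rows(flat %*% p$Wh + rep(p$bh, each = n))
    heads[[b]] <- Hb
    Hsum <- Hsum + Hb
    if (keep)
      caches[[b]] <- list(Y1 = Y1, Z1 = Z1, A1 = A1, Y2 = Y2, Z2 = Z2,
                          A2 = A2, flat = flat, Hb = Hb, mask = mask)
  }
  A <- Hsum / B
  logit <- drop(A %*% params$Wf) + as.vector(params$bf)
  prob <- sigmoid(logit)
  out <- list(prob = prob, A = A)
  if (keep) { out$caches <- caches; out$X <- X }
  out
}

bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Backward pass for mean BCE over the batch; returns gradients in the
# same structure as params.
mhc_backward <- function(params, fw, y, cfg) {
  n <- length(fw$prob)
  B <- length(params$blocks)
  D <- cfg$depth_multiplier
  dlogit <- matrix((fw$prob - y) / n, ncol = 1L)
  grads <- list(blocks = vector("list", B),
                Wf = crossprod(fw$A, dlogit),
                bf = sum(dlogit))
  dA <- dlogit %*% t(params$Wf)
  for (b in seq_len(B)) {
    p <- params$blocks[[b]]
    cc <- fw$caches[[b]]
    dHb <- dA / B
    s <- cc$Hb
    dzh <- s * (dHb - rowSums(dHb * s))        # softmax jacobian-vector
    gWh <- crossprod(cc$flat, dzh)
    gbh <- colSums(dzh)
    dflat <- dzh %*% t(p$Wh)
    if (!is.null(cc$mask)) dflat <- dflat * cc$mask
    dA2 <- array(dflat, dim(cc$A2))
    dZ2 <- dA2 * (cc$Z2 > 0)
    g2 <- pointwise_backward(cc$Y2, p$pw2, dZ2)
    gdw2 <- depthwise_backward(cc$A1, p$dw2, D, g2$dY, need_dX = TRUE)
    dZ1 <- gdw2$dX * (cc$Z1 > 0)
    g1 <- pointwise_backward(cc$Y1, p$pw1, dZ1)
    gdw1 <- depthwise_backward(fw$X, p$dw1, D, g1$dY, need_dX = FALSE)
    grads$blocks[[b]] <- list(dw1 = gdw1$dW, pw1 = g1$dP, b1 = g1$db,
                              dw2 = gdw2$dW, pw2 = g2$dP, b2 = g2$db,
                              Wh = gWh, bh = gbh)
  }
  grads
}

# Flatten a params/grads tree to a list of numeric arrays (stable order).
flatten_params <- function(p) {
  out <- list()
  for (b in seq_along(p$blocks)) out <- c(out, p$blocks[[b]])
  c(out, list(p$Wf, p$bf))
}

unflatten_into <- function(p, flat) {
  i <- 0L
  for (b in seq_along(p$blocks)) {
    for (nm in names(p$blocks[[b]])) {
      i <- i + 1L
      p$blocks[[b]][[nm]] <- array(flat[[i]], dim(as.array(p$blocks[[b]][[nm]])))
    }
  }
  p$Wf <- array(flat[[i + 1L]], dim(p$Wf))
  p$bf <- flat[[i + 2L]]
  p
}

# One Adam update; state holds first/second moment lists and step count.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  if (is.null(state)) {
    state <- list(m = lapply(fp, function(x) array(0, dim(as.array(x)))),
                  v = lapply(fp, function(x) array(0, dim(as.array(x)))),
                  t = 0L)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - 0.9^state$t
  bc2 <- 1 - 0.999^state$t
  for (i in seq_along(fp)) {
    g <- as.array(fg[[i]])
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    fp[[i]] <- as.array(fp[[i]]) -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = unflatten_into(params, fp), state = state)
}
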