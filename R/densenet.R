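## Seeded full-batch gradient-descent trainer for the package's small dense
## networks: a logistic scoring head (hidden = 0) for the valve detector and
## a one-hidden-layer network (rectified units, sigmoid output, binary
## cross-entropy) for the calcification classifier.  Deterministic given
## (data, hyperparameters, seed): no stochastic minibatching, so repeated
## runs give bit-identical weights.

.sigmoid <- function(z) 1 / (1 + exp(-pmin(50, pmax(-50, z))))

.fitDenseNet <- function(X, y, hidden = 0L, epochs = 50L, lr = 0.5,
                         momentum = 0.9, l2 = 1e-4, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n == length(y), n > 0L)
  y <- as.numeric(y)

  ## feature standardization (stored for prediction)
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2L, stats::sd), 1e-6)
  if (n == 1L) sdv <- rep(1, d)
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")

  set.seed(seed)
  h <- as.integer(hidden)
  if (h > 0L) {
    W1 <- matrix(rnorm(d * h, sd = 1 / sqrt(d)), d, h)
    b1 <- rep(0, h)
    W2 <- matrix(rnorm(h, sd = 1 / sqrt(h)), h, 1L)
  } else {
    W1 <- NULL; b1 <- NULL
    W2 <- matrix(rnorm(d, sd = 1 / sqrt(d)), d, 1L)
  }
  b2 <- 0
  vW1 <- if (h > 0L) W1 * 0 else NULL
  vb1 <- if (h > 0L) b1 * 0 else NULL
  vW2 <- W2 * 0; vb2 <- 0

  lossLog <- data.frame(epoch = integer(), loss = numeric())
  for (ep in seq_len(epochs)) {
    if (h > 0L) {
      Z1 <- sweep(Xs %*% W1, 2L, b1, "+")
      A1 <- pmax(Z1, 0)
    } else {
      A1 <- Xs
    }
    p <- .sigmoid(drop(A1 %*% W2) + b2)
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    lossLog <- rbind(lossLog, data.frame(epoch = ep, loss = loss))

    delta <- (p - y) / n
    gW2 <- t(A1) %*% delta + l2 * W2
    gb2 <- sum(delta)
    if (h > 0L) {
      dA1 <- outer(delta, drop(W2)) * (Z1 > 0)
      gW1 <- t(Xs) %*% dA1 + l2 * W1
      gb1 <- colSums(dA1)
      vW1 <- momentum * vW1 - lr * gW1
      vb1 <- momentum * vb1 - lr * gb1
      W1 <- W1 + vW1; b1 <- b1 + vb1
    }
    vW2 <- momentum * vW2 - lr * gW2
    vb2 <- momentum * vb2 - lr * gb2
    W2 <- W2 + vW2; b2 <- b2 + vb2
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, hidden = h,
       mu = mu, sd = sdv, lossLog = lossLog)
}

## With logits = TRUE the raw pre-sigmoid score is returned: unlike the
## probability it never saturates, so callers can rank near-certain
## candidates (the sigmoid ties them all at 1 in double precision).
.predictDenseNet <- function(net, X, logits = FALSE) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2L, net$mu), 2L, net$sd, "/")
  A1 <- if (net$hidden > 0L)
    pmax(sweep(Xs %*% net$W1, 2L, net$b1, "+"), 0) else Xs
  z <- drop(A1 %*% net$W2) + net$b2
  if (logits) z else .sigmoid(z)
}
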