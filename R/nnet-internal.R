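# Minimal dense-network machinery used by the integration module: ReLU MLPs
# with hand-coded backprop, ADAM updates, and spectral normalization for the
# discriminator. Matrices are batch-in-rows; weights W are (in x out).

.mlpInit <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                           sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

.mlpForward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  Z <- vector("list", L)
  H[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(H[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    H[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(out = H[[L + 1]], H = H, Z = Z)
}

# dOut: gradient of the loss w.r.t. the (linear) output
.mlpBackward <- function(net, cache, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dZ <- dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$H[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dH <- dZ %*% t(net$W[[l]])
      dZ <- dH * (cache$Z[[l - 1]] > 0)
    } else {
      dX <- dZ %*% t(net$W[[1]])
    }
  }
  list(W = gW, b = gb, dX = dX)
}

.adamInit <- function(net) {
  zero <- function(x) lapply(x, function(p) p * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b), t = 0L)
}

.adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# One power-iteration step per call; u vectors persist across calls.
.spectralNormalize <- function(net, u = NULL, iters = 1L) {
  if (is.null(u)) u <- lapply(net$W, function(W) rnorm(ncol(W)))
  for (l in seq_along(net$W)) {
    W <- net$W[[l]]
    ul <- u[[l]]
    for (i in seq_len(iters)) {
      v <- as.vector(W %*% ul)
      v <- v / max(sqrt(sum(v^2)), 1e-12)
      ul <- as.vector(crossprod(W, v))
      ul <- ul / max(sqrt(sum(ul^2)), 1e-12)
    }
    sigma <- as.numeric(v %*% W %*% ul)
    net$W[[l]] <- W / max(abs(sigma), 1e-12)
    u[[l]] <- ul
  }
  list(net = net, u = u)
}

.checkFinite <- function(x, what, epoch = NA, batch = NA) {
  if (any(!is.finite(x)))
    stop(sprintf(
      "training fault: non-finite %s (epoch %s, batch %s); try lowering the learning rate",
      what, epoch, batch))
  invisible(TRUE)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable binary cross-entropy with logits, mean over rows
.bceWithLogits <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

.oneHot <- function(labels, levels) {
  m <- matrix(0, nrow = length(labels), ncol = length(levels))
  idx <- match(as.character(labels), levels)
  if (any(is.na(idx))) stop("labels outside the configured vocabulary")
  m[cbind(seq_along(labels), idx)] <- 1
  m
}
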