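# Internal neural-network primitives for the 1D-CNN.
#
# Activations flow as 3D arrays (batch, length, channels) through the
# convolutional stack and as matrices (batch, features) after the
# flatten. Convolutions are stride-1 with length-preserving ("same")
# zero padding and are computed position-by-position as patch-matrix
# products: spectra here have at most 12 steps, so the per-position
# loop is short and everything else is a dense matrix multiply.

conv1d_forward <- function(X, W, b, k) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  nf <- length(b)
  pad_l <- (k - 1L) %/% 2L
  Xp <- array(0, c(N, L + k - 1L, C))
  Xp[, pad_l + seq_len(L), ] <- X
  Y <- array(0, c(N, L, nf))
  patches <- vector("list", L)
  for (p in seq_len(L)) {
    P <- Xp[, p:(p + k - 1L), , drop = FALSE]
    dim(P) <- c(N, k * C)
    patches[[p]] <- P
    Y[, p, ] <- P %*% W
  }
  Y <- sweep(Y, 3, b, `+`)
  list(out = Y, cache = list(patches = patches, dims = c(N, L, C),
                             k = k, pad_l = pad_l, W = W))
}

conv1d_backward <- function(dY, cache) {
  N <- cache$dims[1]; L <- cache$dims[2]; C <- cache$dims[3]
  k <- cache$k; pad_l <- cache$pad_l; W <- cache$W
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dXp <- array(0, c(N, L + k - 1L, C))
  for (p in seq_len(L)) {
    G <- dY[, p, , drop = FALSE]
    dim(G) <- c(N, ncol(W))
    dW <- dW + crossprod(cache$patches[[p]], G)
    db <- db + colSums(G)
    dP <- G %*% t(W)
    dim(dP) <- c(N, k, C)
    dXp[, p:(p + k - 1L), ] <- dXp[, p:(p + k - 1L), , drop = FALSE] + dP
  }
  list(dX = dXp[, pad_l + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

relu_forward <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(out = X, cache = mask)
}

relu_backward <- function(dY, mask) {
  dY[!mask] <- 0
  dY
}

maxpool2_forward <- function(X) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  L2 <- L %/% 2L
  A <- X[, seq(1L, 2L * L2, by = 2L), , drop = FALSE]
  B <- X[, seq(2L, 2L * L2, by = 2L), , drop = FALSE]
  take_a <- A >= B
  Y <- A
  Y[!take_a] <- B[!take_a]
  list(out = Y, cache = list(take_a = take_a, L = L, dims = c(N, L2, C)))
}

maxpool2_backward <- function(dY, cache) {
  N <- cache$dims[1]; L2 <- cache$dims[2]; C <- cache$dims[3]
  dX <- array(0, c(N, cache$L, C))
  dA <- dY; dA[!cache$take_a] <- 0
  dB <- dY; dB[cache$take_a] <- 0
  dX[, seq(1L, 2L * L2, by = 2L), ] <- dA
  dX[, seq(2L, 2L * L2, by = 2L), ] <- dB
  dX
}

dense_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, `+`), cache = list(X = X, W = W))
}

dense_backward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - rate
  if (keep <= 0) return(list(out = X * 0, cache = 0))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) < keep) / keep
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) return(dY)
  dY * cache
}

softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  P <- exp(Z - m)
  P / rowSums(P)
}

# Cross-entropy of softmax(Z) against one-hot rows Y; returns loss and dZ.
softmax_ce <- function(Z, Y) {
  P <- softmax_rows(Z)
  eps <- 1e-12
  loss <- -mean(rowSums(Y * log(P + eps)))
  list(loss = loss, dZ = (P - Y) / nrow(Z), probs = P)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Forward pass through a layer stack; returns logits and per-layer caches.
net_forward <- function(layers, params, X, training = FALSE) {
  caches <- vector("list", length(layers))
  A <- X
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv = conv1d_forward(A, params[[ly$W]], params[[ly$b]], ly$k),
      relu = relu_forward(A),
      pool = maxpool2_forward(A),
      flatten = {
        d <- dim(A)
        dim(A) <- c(d[1], prod(d[-1]))
        list(out = A, cache = d)
      },
      dense = dense_forward(A, params[[ly$W]], params[[ly$b]]),
      dropout = dropout_forward(A, ly$rate, training),
      stop("unknown layer type ", ly$type)
    )
    A <- r$out
    caches[[i]] <- r$cache
  }
  list(logits = A, caches = caches)
}

# Backward pass: dZ is the gradient at the logits.
net_backward <- function(layers, params, caches, dZ) {
  grads <- lapply(params, function(p) p * 0)
  dA <- dZ
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      r <- conv1d_backward(dA, caches[[i]])
      grads[[ly$W]] <- grads[[ly$W]] + r$dW
      grads[[ly$b]] <- grads[[ly$b]] + r$db
      dA <- r$dX
    } else if (ly$type == "relu") {
      dA <- relu_backward(dA, caches[[i]])
    } else if (ly$type == "pool") {
      dA <- maxpool2_backward(dA, caches[[i]])
    } else if (ly$type == "flatten") {
      dim(dA) <- caches[[i]]
    } else if (ly$type == "dense") {
      r <- dense_backward(dA, caches[[i]])
      grads[[ly$W]] <- grads[[ly$W]] + r$dW
      grads[[ly$b]] <- grads[[ly$b]] + r$db
      dA <- r$dX
    } else if (ly$type == "dropout") {
      dA <- dropout_backward(dA, caches[[i]])
    }
  }
  grads
}
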