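# Minimal 1-D neural-network engine: forward passes with caches and exact
# hand-derived backward passes for fully connected, strided convolution,
# transposed convolution, batch normalization and spectral normalization.
# Batches are arrays (channels, length, n) or matrices (features, n).
# Convolutions use an im2col/col2im formulation so all heavy lifting is BLAS.

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, mask = m)
}
lrelu_fwd <- function(x, slope = 0.2) {
  m <- slope + (1 - slope) * (x > 0)
  list(y = x * m, mask = m)
}
sigmoid <- function(s) stats::plogis(s)
softplus <- function(s) pmax(s, 0) + log1p(exp(-abs(s)))
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# ---- spectral normalization -------------------------------------------------

# One power-iteration step on the weight viewed as (out x in) matrix.
# Returns the normalized weight, the spectral-norm estimate, and the updated
# left-singular vector (persisted across steps only in train mode).
sn_normalize <- function(W, u) {
  v <- crossprod(W, u)
  v <- v / max(sqrt(sum(v^2)), 1e-12)
  Wv <- W %*% v
  u2 <- Wv / max(sqrt(sum(Wv^2)), 1e-12)
  sigma <- max(as.numeric(crossprod(u2, Wv)), 1e-12)
  list(W = W / sigma, sigma = sigma, u = u2)
}

# ---- batch normalization ----------------------------------------------------

bn_make <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       rmean = rep(0, C), rvar = rep(1, C), momentum = 0.9, eps = 1e-5)
}

# x: matrix (C, m).  Per-row normalization.
bn_fwd <- function(layer, x, train) {
  m <- ncol(x)
  if (train) {
    mu <- rowMeans(x)
    xc <- x - mu
    va <- rowMeans(xc^2)
    layer$rmean <- layer$momentum * layer$rmean + (1 - layer$momentum) * mu
    layer$rvar <- layer$momentum * layer$rvar + (1 - layer$momentum) * va
  } else {
    mu <- layer$rmean
    va <- layer$rvar
    xc <- x - mu
  }
  invstd <- 1 / sqrt(va + layer$eps)
  xhat <- xc * invstd
  y <- layer$gamma * xhat + layer$beta
  list(y = y, layer = layer,
       cache = list(xhat = xhat, invstd = invstd, train = train))
}

bn_bwd <- function(layer, cache, dy) {
  xhat <- cache$xhat
  m <- ncol(dy)
  dbeta <- rowSums(dy)
  dgamma <- rowSums(dy * xhat)
  dxh <- dy * layer$gamma
  if (cache$train) {
    dx <- (cache$invstd / m) * (m * dxh - rowSums(dxh) - xhat * rowSums(dxh * xhat))
  } else {
    dx <- dxh * cache$invstd
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- convolution ------------------------------------------------------------

# W: (Cout, Cin*K) with column index c + Cin*(k-1);  x: (Cin, L, n).
# Padding (zero or edge-excluding reflection) is folded into the compiled
# im2col/col2im kernels.
conv1d_fwd <- function(W, b, x, stride, pad, pad_mode = "reflect") {
  d <- dim(x); Cin <- d[1]; L <- d[2]; n <- d[3]
  K <- ncol(W) / Cin
  stop_if((L + 2 * pad - K) %% stride != 0, "conv shape mismatch: (", L, ",",
          K, ",", stride, ",", pad, ")")
  Lout <- (L + 2 * pad - K) / stride + 1
  xcol <- cpp_im2col(x, Cin, L, n, K, stride, pad, Lout,
                     pad_mode == "reflect")
  y <- W %*% xcol + b
  dim(y) <- c(nrow(W), Lout, n)
  list(y = y, cache = list(xcol = xcol, dims = c(Cin, L, n, K, Lout),
                           stride = stride, pad = pad, pad_mode = pad_mode))
}

conv1d_bwd <- function(W, cache, dy, need_dx = TRUE) {
  dims <- cache$dims
  Cin <- dims[1]; L <- dims[2]; n <- dims[3]; K <- dims[4]; Lout <- dims[5]
  Cout <- nrow(W)
  dim(dy) <- c(Cout, Lout * n)
  dW <- tcrossprod(dy, cache$xcol)
  db <- rowSums(dy)
  dx <- NULL
  if (need_dx) {
    dxcol <- crossprod(W, dy)
    dx <- cpp_col2im(dxcol, Cin, L, n, K, cache$stride, cache$pad, Lout,
                     cache$pad_mode == "reflect")
    dim(dx) <- c(Cin, L, n)
  }
  list(dW = dW, db = db, dx = dx)
}

# Transposed convolution (zero padding).  W: (Cin, Cout*K), x: (Cin, L, n),
# output (Cout, (L-1)*stride + K - 2*pad, n).  Forward is the adjoint of a
# zero-padded convolution mapping the output length back to L, so it reuses
# the col2im/im2col kernels.
tconv1d_fwd <- function(W, b, x, stride, pad, Cout) {
  d <- dim(x); Cin <- d[1]; L <- d[2]; n <- d[3]
  K <- ncol(W) / Cout
  xmat <- x; dim(xmat) <- c(Cin, L * n)
  ucol <- crossprod(W, xmat)            # (Cout*K, L*n)
  Lout <- (L - 1) * stride + K - 2 * pad
  y <- cpp_col2im(ucol, Cout, Lout, n, K, stride, pad, L, FALSE)
  dim(y) <- c(Cout, Lout, n)
  y <- y + b
  list(y = y, cache = list(xmat = xmat, dims = c(Cin, L, n, K, Cout, Lout),
                           stride = stride, pad = pad))
}

tconv1d_bwd <- function(W, cache, dy, need_dx = TRUE) {
  dims <- cache$dims
  Cin <- dims[1]; L <- dims[2]; n <- dims[3]; K <- dims[4]
  Cout <- dims[5]; Lout <- dims[6]
  db <- rowSums(matrix(dy, Cout))
  ducol <- cpp_im2col(dy, Cout, Lout, n, K, cache$stride, cache$pad, L, FALSE)
  dW <- tcrossprod(cache$xmat, ducol)
  dx <- NULL
  if (need_dx) {
    dx <- W %*% ducol
    dim(dx) <- c(Cin, L, n)
  }
  list(dW = dW, db = db, dx = dx)
}

# ---- Adam -------------------------------------------------------------------

# Recursive Adam over a named tree of numeric arrays.  `state` mirrors the
# tree; only leaves present in `grads` are updated.
adam_update <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  if (is.null(grads)) return(list(params = params, state = state))
  if (is.numeric(params)) {
    if (is.null(state)) state <- list(m = params * 0, v = params * 0, t = 0)
    state$t <- state$t + 1
    state$m <- beta1 * state$m + (1 - beta1) * grads
    state$v <- beta2 * state$v + (1 - beta2) * grads^2
    mhat <- state$m / (1 - beta1^state$t)
    vhat <- state$v / (1 - beta2^state$t)
    params <- params - lr * mhat / (sqrt(vhat) + eps)
    return(list(params = params, state = state))
  }
  if (is.null(state)) state <- vector("list", 0)
  for (nm in names(grads)) {
    if (is.null(params[[nm]])) next
    r <- adam_update(params[[nm]], grads[[nm]], state[[nm]], lr, beta1, beta2, eps)
    params[[nm]] <- r$params
    state[[nm]] <- r$state
  }
  list(params = params, state = state)
}

# Elementwise sum of two congruent grad trees (b may be NULL).
grad_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is.numeric(a)) return(a + b)
  for (nm in names(b)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
  a
}
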