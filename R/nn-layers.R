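# Batched 1D layer primitives on arrays [channels, length, batch].
# Convolutions are im2col + BLAS matrix products; the layout is chosen so the
# column-major reshape from the gathered array to the GEMM operand is free.

BN_EPS <- 1e-5

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  x
}

conv1d_init <- function(c_in, k, c_out) {
  # He-normal fan-in initialization
  list(w = array(stats::rnorm(c_in * k * c_out, 0, sqrt(2 / (c_in * k))),
                 c(c_in, k, c_out)),
       b = numeric(c_out))
}

conv1d_fwd <- function(layer, x, stride = 1L) {
  d <- dim(x); c_in <- d[1]; L <- d[2]; B <- d[3]
  k <- dim(layer$w)[2]; c_out <- dim(layer$w)[3]
  pad <- (k - 1L) %/% 2L
  Lp <- L + 2L * pad
  xp <- array(0, c(c_in, Lp, B))
  xp[, (pad + 1):(pad + L), ] <- x
  L_out <- (Lp - k) %/% stride + 1L
  starts <- seq.int(1L, by = stride, length.out = L_out)
  idx <- outer(seq_len(k) - 1L, starts, `+`)          # k x L_out
  Xc <- xp[, as.vector(idx), , drop = FALSE]
  dim(Xc) <- c(c_in * k, L_out * B)
  W2 <- matrix(layer$w, nrow = c_in * k)              # rows: c_in fastest, then k
  out <- crossprod(W2, Xc) + layer$b
  dim(out) <- c(c_out, L_out, B)
  list(out = out,
       cache = list(Xc = Xc, idx = idx, pad = pad, L = L, Lp = Lp, B = B,
                    c_in = c_in, k = k, stride = stride))
}

# Scatter-add the columns of dXc [c_in*k, L_out*B] back onto the padded
# input, one kernel offset at a time (positions are distinct within an
# offset, so plain indexed addition is safe). Works on flat matrix views to
# avoid higher-dimensional indexing.
conv_scatter_dx <- function(dXc, cache, L_out, B) {
  c_in <- cache$c_in; k <- cache$k
  dxp <- matrix(0, c_in, cache$Lp * B)
  cols0 <- as.vector(outer(cache$idx[1L, ], (seq_len(B) - 1L) * cache$Lp, `+`))
  for (kk in seq_len(k)) {
    rr <- seq.int((kk - 1L) * c_in + 1L, kk * c_in)
    cols <- cols0 + (kk - 1L)
    dxp[, cols] <- dxp[, cols] + dXc[rr, , drop = FALSE]
  }
  dim(dxp) <- c(c_in, cache$Lp, B)
  dxp[, (cache$pad + 1):(cache$pad + cache$L), , drop = FALSE]
}

# Gradient w.r.t. input only (attribution path).
conv1d_bwd_input <- function(layer, cache, dout) {
  c_out <- dim(dout)[1]; L_out <- dim(dout)[2]; B <- dim(dout)[3]
  dm <- matrix(dout, nrow = c_out)
  W2 <- matrix(layer$w, nrow = cache$c_in * cache$k)
  dXc <- W2 %*% dm                                    # [c_in*k, L_out*B]
  conv_scatter_dx(dXc, cache, L_out, B)
}

# Gradients w.r.t. input, weights and bias (training path).
conv1d_bwd <- function(layer, cache, dout) {
  c_out <- dim(dout)[1]; L_out <- dim(dout)[2]; B <- dim(dout)[3]
  dm <- matrix(dout, nrow = c_out)
  dW2 <- tcrossprod(cache$Xc, dm)                     # [c_in*k, c_out]
  db <- rowSums(dm)
  W2 <- matrix(layer$w, nrow = cache$c_in * cache$k)
  dXc <- W2 %*% dm
  list(dx = conv_scatter_dx(dXc, cache, L_out, B),
       dw = array(dW2, dim(layer$w)), db = db)
}

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = numeric(c_out),
       run_mean = numeric(c_out), run_var = rep(1, c_out))
}

bn_fwd <- function(layer, x, training, momentum = 0.1) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- (xm - mu) * istd
    y <- layer$gamma * xhat + layer$beta
    layer$run_mean <- (1 - momentum) * layer$run_mean + momentum * mu
    layer$run_var <- (1 - momentum) * layer$run_var + momentum * v
    dim(y) <- d
    list(out = y, layer = layer, cache = list(xhat = xhat, istd = istd))
  } else {
    scale <- layer$gamma / sqrt(layer$run_var + BN_EPS)
    y <- scale * (xm - layer$run_mean) + layer$beta
    dim(y) <- d
    list(out = y, layer = layer, cache = list(scale = scale))
  }
}

bn_bwd_train <- function(layer, cache, dout) {
  d <- dim(dout)
  dy <- matrix(dout, d[1])
  n <- ncol(dy)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * layer$gamma
  dx <- (cache$istd / n) *
    (n * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_bwd_infer <- function(cache, dout) {
  d <- dim(dout)
  dx <- matrix(dout, d[1]) * cache$scale
  dim(dx) <- d
  dx
}

# ReLU backward under the three backward semantics used by the attribution
# engine: plain gradient, guided backpropagation, and the DeepLift rescale
# rule (z_ref = pre-activation on the reference input).
relu_bwd <- function(dout, z, mode = "grad", z_ref = NULL) {
  switch(mode,
    grad = dout * (z > 0),
    guided = dout * (z > 0) * (dout > 0),
    deeplift = {
      dz <- z - z_ref
      m <- ifelse(abs(dz) > 1e-10, (pmax(z, 0) - pmax(z_ref, 0)) / dz, (z > 0) * 1)
      dout * m
    },
    stop("unknown relu backward mode"))
}
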