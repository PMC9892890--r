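# Internal layer primitives for the s-Net trainer. Convolution and pooling
# loops live in C++ (src/snet_kernels.cpp); batch norm, ReLU, the FC head and
# Adam are plain vectorized R. Activation tensors are (H, W, C, N) arrays.

# Convolutions run as im2col (C++ gather) + BLAS matrix products. The kernel
# array (3, 3, Cin, Cout) flattens column-major to a (9 Cin) x Cout matrix
# whose row order matches the im2col patch order. The im2col columns are kept
# in the forward cache and reused for the weight gradient.
conv_layer_fwd <- function(x, w, b) {
  d <- dim(x); dw <- dim(w)
  cols <- im2col3(as.numeric(x), d[1], d[2], d[3], d[4])
  w2 <- matrix(w, 9L * dw[3], dw[4])
  y2 <- crossprod(w2, cols) + b  # (Cout, H*W*N); b recycles down columns
  y <- aperm(array(y2, c(dw[4], d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(y = y, cols = cols)
}

conv_layer_bwd <- function(cache_cols, dy, w, in_dim) {
  dw4 <- dim(w)
  dy2 <- matrix(aperm(dy, c(3, 1, 2, 4)), dw4[4])
  w2 <- matrix(w, 9L * dw4[3], dw4[4])
  dw <- array(cache_cols %*% t(dy2), dw4)
  db <- rowSums(dy2)
  dcols <- w2 %*% dy2
  dx <- array(col2im3(dcols, in_dim[1], in_dim[2], in_dim[3], in_dim[4]),
              in_dim)
  list(dx = dx, dw = dw, db = db)
}

pool_layer_fwd <- function(x) {
  d <- dim(x)
  r <- maxpool2_fwd(as.numeric(x), d[1], d[2], d[3], d[4])
  list(y = array(r$y, c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])),
       argmax = r$argmax, in_dim = d)
}

pool_layer_bwd <- function(dy, cache) {
  d <- cache$in_dim
  array(maxpool2_bwd(as.numeric(dy), cache$argmax, d[1], d[2], d[3], d[4]), d)
}

# Batch norm works on the (H*W, C*N) matrix view of the activation tensor:
# column j belongs to channel (j - 1) %% C + 1, so per-channel statistics are
# row sums of a (C, N) reshape of the column statistics, and broadcasting a
# per-channel vector is an indexed lookup followed by rep(each = H*W).
per_channel_sum <- function(col_stat, C) rowSums(matrix(col_stat, C))

bcast_channels <- function(v, C, N, HW) rep(v[rep(seq_len(C), N)], each = HW)

bn_fwd <- function(x, gamma, beta, running, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x); C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
  M <- matrix(x, HW)
  if (training) {
    m <- per_channel_sum(colMeans(M), C) / N
    v <- per_channel_sum(colMeans(M * M), C) / N - m^2
    running$mean <- (1 - momentum) * running$mean + momentum * m
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    m <- running$mean; v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- array((x - bcast_channels(m, C, N, HW)) *
                  bcast_channels(invstd, C, N, HW), d)
  y <- array(bcast_channels(gamma, C, N, HW) * xhat +
               bcast_channels(beta, C, N, HW), d)
  list(y = y, cache = list(xhat = xhat, invstd = invstd), running = running)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- dim(dy); C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
  M <- HW * N
  xh <- cache$xhat
  dgamma <- per_channel_sum(colSums(matrix(dy * xh, HW)), C)
  dbeta <- per_channel_sum(colSums(matrix(dy, HW)), C)
  dxh <- dy * bcast_channels(gamma, C, N, HW)
  s1 <- per_channel_sum(colSums(matrix(dxh, HW)), C)
  s2 <- per_channel_sum(colSums(matrix(dxh * xh, HW)), C)
  dx <- array(bcast_channels(cache$invstd / M, C, N, HW) *
                (M * dxh - bcast_channels(s1, C, N, HW) -
                   xh * bcast_channels(s2, C, N, HW)), d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, x) dy * (x > 0)

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dims)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}
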