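# R-side layer primitives. Tensor convention: dim c(H, W, C, N).
# Convolution / pooling / bilinear-upsampling kernels live in src/layers.cpp;
# batch normalization, ReLU, fully connected layers and global average
# pooling are cheap enough to keep vectorised in R.

conv_init <- function(k, c_in, c_out) {
  # He-style initialization for ReLU stacks
  list(w = matrix(rnorm(k * k * c_in * c_out, 0,
                        sqrt(2 / (k * k * c_in))), k * k * c_in, c_out),
       b = rep(0, c_out), k = k)
}

conv_forward <- function(layer, x) {
  .conv2d_forward(x, layer$w, layer$b, layer$k, layer$k)
}

conv_backward <- function(layer, x, dy) {
  .conv2d_backward(x, layer$w, dy, layer$k, layer$k)
}

bn_init <- function(c_out) {
  stats <- new.env(parent = emptyenv())
  stats$rm <- rep(0, c_out)
  stats$rv <- rep(1, c_out)
  list(gamma = rep(1, c_out), beta = rep(0, c_out), stats = stats)
}

bn_forward <- function(layer, x, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    fw <- .bn_train_forward(x, layer$gamma, layer$beta, layer$stats$rm,
                            layer$stats$rv, momentum, eps)
    layer$stats$rm <- fw$rm
    layer$stats$rv <- fw$rv
    list(y = fw$y, cache = list(xhat = fw$xhat, inv_std = fw$inv_std,
                                training = TRUE))
  } else {
    y <- .bn_infer_forward(x, layer$gamma, layer$beta, layer$stats$rm,
                           layer$stats$rv, eps)
    list(y = y, cache = list(x = x, training = FALSE,
                             inv_std = 1 / sqrt(layer$stats$rv + eps)))
  }
}

bn_backward <- function(layer, cache, dy) {
  if (!cache$training)
    stopf("backward through inference-mode batch norm is not supported")
  bw <- .bn_train_backward(dy, cache$xhat, cache$inv_std, layer$gamma)
  list(dx = bw$dx, dgamma = bw$dgamma, dbeta = bw$dbeta)
}

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(x, dy) dy * (x > 0)

fc_init <- function(d_in, d_out) {
  list(w = matrix(rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
       b = rep(0, d_out))
}

fc_forward <- function(layer, x) sweep(x %*% layer$w, 2, layer$b, `+`)

fc_backward <- function(layer, x, dy) {
  list(dx = dy %*% t(layer$w), dw = crossprod(x, dy), db = colSums(dy))
}

# global average pooling (H,W,C,N) -> (N,C)
gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  t(matrix(colMeans(m), d[3], d[4]))
}

gap_backward <- function(dy, d) {
  # dy: (N, C) -> broadcast back over H*W
  g <- t(dy) / (d[1] * d[2])                 # (C, N)
  x <- rep(as.vector(g), each = d[1] * d[2])
  dim(x) <- d
  x
}

# global max pooling (H,W,C,N) -> (N,C); keeps argmax for the backward
# pass so the gradient reaches only the responding location
gmp_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")   # length C*N
  vals <- m[cbind(idx, seq_along(idx))]
  list(y = t(matrix(vals, d[3], d[4])), idx = idx)
}

gmp_backward <- function(dy, idx, d) {
  x <- numeric(prod(d))
  HW <- d[1] * d[2]
  off <- (seq_along(idx) - 1L) * HW + idx
  x[off] <- as.vector(t(dy))
  dim(x) <- d
  x
}

concat_channels <- function(a, b) .concat_channels(a, b)

split_channels <- function(dy, c1) .split_channels(dy, c1)

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
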