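# Neural-network primitives with explicit reverse-mode gradients.
# Every *_fwd returns the output plus the cache its *_bwd needs; backward
# functions return the input gradient and parameter gradients. Kept
# internal: the user-facing surface is the model / layer API.

LN_EPS <- 1e-5

# row-wise LayerNorm over all columns, with affine parameters
layer_norm_fwd <- function(x, gamma, beta) {
  ln_fwd_cpp(x, gamma, beta, LN_EPS)
}

layer_norm_bwd <- function(gy, cache, gamma) {
  res <- ln_bwd_cpp(gy, cache$xhat, cache$inv_sd, gamma)
  list(gx = res$gx, ggamma = res$gg, gbeta = res$gb)
}

# exact GELU: x * Phi(x)
gelu_fwd <- function(x) list(y = gelu_fwd_mat_cpp(x), x = x)

gelu_bwd <- function(gy, cache) gelu_bwd_mat_cpp(gy, cache$x)

linear_fwd <- function(x, w, b) list(y = add_cols_cpp(x %*% w, b), x = x)

linear_bwd <- function(gy, cache, w) {
  list(gx = gy %*% t(w), gw = crossprod(cache$x, gy), gb = colSums(gy))
}

# 3x3 / 2x2 convolutions over (H, W, C) arrays; thin wrappers over the
# C++ kernels so callers stay shape-safe
conv2d_fwd <- function(x, w, b, stride, pad) {
  conv2d_fwd_cpp(x, w, b, as.integer(stride), as.integer(pad))
}

conv2d_bwd <- function(gy, x, w, stride, pad) {
  conv2d_bwd_cpp(gy, x, w, as.integer(stride), as.integer(pad))
}

# inverted dropout; identity in eval mode
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(gy, cache) {
  if (is.null(cache$mask)) gy else gy * cache$mask
}

# DropPath / stochastic depth: drop the whole residual branch with
# probability `rate` during training, rescaling survivors by 1/(1-rate)
droppath_draw <- function(rate, training) {
  if (!training || rate <= 0) return(1)
  if (stats::runif(1) < rate) 0 else 1 / (1 - rate)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}
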