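# ---------------------------------------------------------------------------
# Internal layer primitives: conv (compiled), batch normalization, ReLU,
# nearest-neighbor 2x upsampling. Feature maps are [H, W, C] arrays.
# Each *_fw returns list(y, cache); each *_bw consumes the cache and the
# upstream gradient and returns dx plus parameter gradients.
# ---------------------------------------------------------------------------

init_conv <- function(kh, kw, cin, cout, bias_init = 0, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (kh * kw * cin))  # He-normal
  w <- array(stats::rnorm(kh * kw * cin * cout, 0, sd),
             dim = c(kh, kw, cin, cout))
  list(W = w, b = rep(bias_init, length.out = cout))
}

# keep_cols = TRUE stores the im2col patch matrix for reuse in the backward
# pass (memory for speed; a full backward pass holds ~10 MB of patches at
# the 128 px training size)
conv_fw <- function(p, x, stride = 1L, keep_cols = FALSE) {
  if (keep_cols) {
    r <- .cpp_conv2d_fw_cache(x, p$W, p$b, as.integer(stride))
    list(y = r$y, cache = list(cols = r$cols, dims = dim(x),
                               stride = as.integer(stride)))
  } else {
    y <- .cpp_conv2d_fw(x, p$W, p$b, as.integer(stride))
    list(y = y, cache = list(x = x, stride = as.integer(stride)))
  }
}

conv_bw <- function(p, cache, dy, need_dx = TRUE) {
  if (!is.null(cache$cols)) {
    g <- .cpp_conv2d_bw_cache(cache$cols, p$W, cache$dims[1], cache$dims[2],
                              cache$stride, dy, need_dx)
  } else {
    g <- .cpp_conv2d_bw(cache$x, p$W, cache$stride, dy)
  }
  list(dx = g$dx, dW = g$dw, db = as.numeric(g$db))
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c))
}

init_bn_state <- function(c) {
  list(mean = rep(0, c), var = rep(1, c))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Nearest-neighbor 2x upsampling, cropped to (th, tw) when the target level
# has an odd size (ceil division makes 2 * 13 = 26 vs a 25-cell lateral map).
upsample2_fw <- function(x, th, tw) {
  d <- dim(x)
  ir <- rep(seq_len(d[1]), each = 2)[seq_len(th)]
  ic <- rep(seq_len(d[2]), each = 2)[seq_len(tw)]
  list(y = x[ir, ic, , drop = FALSE], cache = list(src = d, th = th, tw = tw))
}

upsample2_bw <- function(cache, dy) {
  th <- cache$th; tw <- cache$tw
  r1 <- seq(1, th, 2); r2 <- seq_len(floor(th / 2)) * 2
  tmp <- dy[r1, , , drop = FALSE]
  if (length(r2)) {
    tmp[seq_along(r2), , ] <- tmp[seq_along(r2), , , drop = FALSE] +
      dy[r2, , , drop = FALSE]
  }
  c1 <- seq(1, tw, 2); c2 <- seq_len(floor(tw / 2)) * 2
  out <- tmp[, c1, , drop = FALSE]
  if (length(c2)) {
    out[, seq_along(c2), ] <- out[, seq_along(c2), , drop = FALSE] +
      tmp[, c2, , drop = FALSE]
  }
  dx <- array(0, cache$src)
  dx[seq_len(dim(out)[1]), seq_len(dim(out)[2]), ] <- out
  dx
}

# CBA = convolution -> batch normalization -> ReLU, the backbone unit.
# Batch norm and ReLU run fused in compiled code.
cba_fw <- function(p, state, x, stride, train = TRUE, keep_cols = FALSE) {
  cv <- conv_fw(p$conv, x, stride, keep_cols)
  bn <- .cpp_bn_relu_fw(cv$y, p$bn$gamma, p$bn$beta, BN_EPS, train,
                        state$mean, state$var)
  if (train) {
    state$mean <- (1 - BN_MOMENTUM) * state$mean +
      BN_MOMENTUM * as.numeric(bn$mu)
    state$var <- (1 - BN_MOMENTUM) * state$var +
      BN_MOMENTUM * as.numeric(bn$var)
  }
  list(y = bn$y, state = state,
       cache = list(conv = cv$cache, y = bn$y, xhat = bn$xhat,
                    inv_sd = bn$inv_sd, train = train))
}

cba_bw <- function(p, cache, dy, need_dx = TRUE) {
  d2 <- .cpp_bn_relu_bw(dy, cache$y, cache$xhat, p$bn$gamma, cache$inv_sd,
                        cache$train)
  d3 <- conv_bw(p$conv, cache$conv, d2$dx, need_dx)
  list(dx = d3$dx,
       grads = list(conv = list(W = d3$dW, b = d3$db),
                    bn = list(gamma = as.numeric(d2$dgamma),
                              beta = as.numeric(d2$dbeta))))
}
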