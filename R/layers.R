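# Primitive differentiable layers. Each layer is a mutable environment
# holding weights (W, b, gamma, beta), gradients (g<name>), optimizer state
# and, during training, the cached activations its backward pass needs.
# Tensors are R arrays [H, W, C, N]; dense inputs are [C, N] matrices.

new_layer <- function(type, name, params) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$name <- name
  l$params <- params          # character vector of weight field names
  l$frozen <- FALSE
  class(l) <- c(paste0("echovol_", type), "echovol_layer")
  l
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

new_conv <- function(kh, cin, cout, stride = 1L, bias = FALSE,
                     name = "conv") {
  l <- new_layer("conv", name, if (bias) c("W", "b") else "W")
  l$W <- he_init(c(kh, kh, cin, cout), kh * kh * cin)
  if (bias) l$b <- numeric(cout)
  l$stride <- as.integer(stride)
  l$pad <- as.integer((kh - 1) / 2)
  l
}

new_dwconv <- function(kh, c, stride = 1L, name = "dwconv") {
  l <- new_layer("dwconv", name, "W")
  l$W <- he_init(c(kh, kh, c), kh * kh)
  l$stride <- as.integer(stride)
  l$pad <- as.integer((kh - 1) / 2)
  l
}

new_bn <- function(c, name = "bn") {
  l <- new_layer("bn", name, c("gamma", "beta"))
  l$gamma <- rep(1, c)
  l$beta <- numeric(c)
  l$rmean <- numeric(c)
  l$rvar <- rep(1, c)
  l$momentum <- 0.9
  l$eps <- 1e-3
  l
}

new_dense <- function(cin, cout, name = "dense") {
  l <- new_layer("dense", name, c("W", "b"))
  l$W <- matrix(rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout)
  l$b <- numeric(cout)
  l
}

# --- broadcast helpers over the channel axis of [H,W,C,N] arrays ------------

ch_expand <- function(v, hw) rep(v, each = hw)   # recycles over N

ch_sum <- function(x) {
  d <- dim(x)
  s <- colSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  rowSums(matrix(s, d[3], d[4]))
}

# --- forward / backward -----------------------------------------------------

conv_fwd <- function(l, x, ctx) {
  w <- l$W
  if (isTRUE(ctx$qat)) w <- fake_quantize(w)
  y <- cpp_conv2d_fwd(x, w, l$stride, l$pad)
  if (!is.null(l$b)) {
    d <- dim(y)
    y <- y + ch_expand(l$b, d[1] * d[2])
    dim(y) <- d
  }
  if (isTRUE(ctx$training)) {
    l$cache_x <- x
    l$cache_w <- w
  }
  y
}

conv_bwd <- function(l, dy) {
  r <- cpp_conv2d_bwd(l$cache_x, l$cache_w, dy, l$stride, l$pad)
  l$gW <- r$dw
  if (!is.null(l$b)) {
    d <- dim(dy)
    s <- colSums(matrix(dy, d[1] * d[2], d[3] * d[4]))
    l$gb <- rowSums(matrix(s, d[3], d[4]))
  }
  l$cache_x <- NULL; l$cache_w <- NULL
  r$dx
}

dwconv_fwd <- function(l, x, ctx) {
  w <- l$W
  if (isTRUE(ctx$qat)) w <- fake_quantize(w)
  y <- cpp_dwconv2d_fwd(x, w, l$stride, l$pad)
  if (!is.null(l$b)) {
    d <- dim(y)
    y <- y + ch_expand(l$b, d[1] * d[2])
    dim(y) <- d
  }
  if (isTRUE(ctx$training)) {
    l$cache_x <- x
    l$cache_w <- w
  }
  y
}

dwconv_bwd <- function(l, dy) {
  r <- cpp_dwconv2d_bwd(l$cache_x, l$cache_w, dy, l$stride, l$pad)
  l$gW <- r$dw
  if (!is.null(l$b)) {
    d <- dim(dy)
    s <- colSums(matrix(dy, d[1] * d[2], d[3] * d[4]))
    l$gb <- rowSums(matrix(s, d[3], d[4]))
  }
  l$cache_x <- NULL; l$cache_w <- NULL
  r$dx
}

bn_fwd <- function(l, x, ctx) {
  if (isTRUE(ctx$training)) {
    r <- cpp_bn2_train_fwd(x, l$gamma, l$beta, l$eps, FALSE)
    if (!l$frozen) {
      l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * r$mu
      l$rvar <- l$momentum * l$rvar + (1 - l$momentum) * r$var
    }
    l$cache_x <- x                      # reference, not a copy
    l$cache_mu <- r$mu
    l$cache_sdinv <- r$sdinv
    r$y
  } else {
    sdinv <- 1 / sqrt(l$rvar + l$eps)
    cpp_bn_eval_fwd(x, l$gamma * sdinv, l$beta - l$gamma * l$rmean * sdinv)
  }
}

bn_bwd <- function(l, dy) {
  r <- cpp_bn2_bwd(dy, l$cache_x, l$cache_mu, l$cache_sdinv, l$gamma,
                   l$beta, FALSE)
  l$gbeta <- r$dbeta
  l$ggamma <- r$dgamma
  l$cache_x <- NULL; l$cache_mu <- NULL; l$cache_sdinv <- NULL
  r$dx
}

dense_fwd <- function(l, x, ctx) {
  w <- l$W
  if (isTRUE(ctx$qat)) w <- fake_quantize(w)
  y <- crossprod(w, x) + l$b
  if (isTRUE(ctx$training)) {
    l$cache_x <- x
    l$cache_w <- w
  }
  y
}

dense_bwd <- function(l, dy) {
  l$gW <- l$cache_x %*% t(dy)
  l$gb <- rowSums(dy)
  dx <- l$cache_w %*% dy
  l$cache_x <- NULL; l$cache_w <- NULL
  dx
}

relu6_f <- function(x) cpp_relu6_fwd(x)

relu6_b <- function(x, dy) cpp_relu6_bwd(x, dy)

# Fused batch-norm + ReLU6 paths (the common conv -> BN -> ReLU6 motif).
# Backward recomputes the normalized activations from the cached BN input
# reference, so no xhat array is materialized.
bnact_fwd <- function(l, x, ctx) {
  if (isTRUE(ctx$training)) {
    r <- cpp_bn2_train_fwd(x, l$gamma, l$beta, l$eps, TRUE)
    if (!l$frozen) {
      l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * r$mu
      l$rvar <- l$momentum * l$rvar + (1 - l$momentum) * r$var
    }
    l$cache_x <- x                      # reference, not a copy
    l$cache_mu <- r$mu
    l$cache_sdinv <- r$sdinv
    r$y
  } else {
    sdinv <- 1 / sqrt(l$rvar + l$eps)
    cpp_bn_relu6_eval_fwd(x, l$gamma * sdinv,
                          l$beta - l$gamma * l$rmean * sdinv)
  }
}

bnact_bwd <- function(l, dy) {
  r <- cpp_bn2_bwd(dy, l$cache_x, l$cache_mu, l$cache_sdinv, l$gamma,
                   l$beta, TRUE)
  l$gbeta <- r$dbeta
  l$ggamma <- r$dgamma
  l$cache_x <- NULL; l$cache_mu <- NULL; l$cache_sdinv <- NULL
  r$dx
}

# Concatenate two [H,W,C,N] arrays along channels.
concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (any(da[c(1, 2, 4)] != db[c(1, 2, 4)])) {
    stop_echovol("concat: spatial/batch dims differ", "echovol_shape")
  }
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Global average pool [H,W,C,N] -> [C,N].
gap_f <- function(x) {
  d <- dim(x)
  matrix(rowSums(matrix(aperm(x, c(3, 4, 1, 2)), d[3] * d[4])) / (d[1] * d[2]),
         d[3], d[4])
}

# Per-pixel softmax over the channel axis of a two-class [H,W,2,N] map.
softmax_ch <- function(z) {
  d <- dim(z)
  if (d[3] != 2) stop_echovol("softmax_ch expects 2 channels", "echovol_shape")
  z1 <- z[, , 1, , drop = FALSE]
  z2 <- z[, , 2, , drop = FALSE]
  mx <- pmax(z1, z2)
  e1 <- exp(z1 - mx); e2 <- exp(z2 - mx)
  s <- e1 + e2
  out <- array(0, d)
  out[, , 1, ] <- e1 / s
  out[, , 2, ] <- e2 / s
  out
}

softmax_mat <- function(z) {
  # z: [K, N] logits
  zm <- apply(z, 2, max)
  e <- exp(sweep(z, 2, zm))
  sweep(e, 2, colSums(e), "/")
}
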