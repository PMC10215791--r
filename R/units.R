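# Composite network units built from the primitive layers: plain conv
# (conv [+ BN] [+ ReLU6]), inverted-residual bottleneck, quantizable
# squeeze-and-excitation (QSE), and depthwise-separable (DWC) blocks.
# Units are environments; forward caches live alongside the layers.

new_conv_unit <- function(kh, cin, cout, stride = 1L, norm = TRUE,
                          act = "relu6", bias = !norm, name = "convu") {
  u <- new.env(parent = emptyenv())
  u$type <- "conv_unit"
  u$name <- name
  u$conv <- new_conv(kh, cin, cout, stride, bias = bias,
                     name = paste0(name, ".conv"))
  u$bn <- if (norm) new_bn(cout, paste0(name, ".bn")) else NULL
  u$act <- act
  class(u) <- c("echovol_conv_unit", "echovol_unit")
  u
}

conv_unit_fwd <- function(u, x, ctx) {
  y <- conv_fwd(u$conv, x, ctx)
  if (!is.null(u$bn) && u$act == "relu6") {
    y <- bnact_fwd(u$bn, y, ctx)
  } else {
    if (!is.null(u$bn)) y <- bn_fwd(u$bn, y, ctx)
    if (u$act == "relu6") {
      if (isTRUE(ctx$training)) u$preact <- y
      y <- relu6_f(y)
    }
  }
  y
}

conv_unit_bwd <- function(u, dy) {
  if (!is.null(u$bn) && u$act == "relu6") {
    dy <- bnact_bwd(u$bn, dy)
  } else {
    if (u$act == "relu6") {
      dy <- relu6_b(u$preact, dy)
      u$preact <- NULL
    }
    if (!is.null(u$bn)) dy <- bn_bwd(u$bn, dy)
  }
  conv_bwd(u$conv, dy)
}

#' @noRd
new_invres_unit <- function(cin, cout, stride = 1L, expand = 6L,
                            name = "invres") {
  u <- new.env(parent = emptyenv())
  u$type <- "invres"
  u$name <- name
  mid <- cin * expand
  u$expand <- if (expand != 1L) {
    new_conv_unit(1L, cin, mid, 1L, name = paste0(name, ".expand"))
  } else NULL
  u$dw <- new_dwconv(3L, mid, stride, paste0(name, ".dw"))
  u$dwbn <- new_bn(mid, paste0(name, ".dwbn"))
  u$proj <- new_conv(1L, mid, cout, 1L, bias = FALSE,
                     name = paste0(name, ".proj"))
  u$projbn <- new_bn(cout, paste0(name, ".projbn"))
  u$use_res <- (stride == 1L && cin == cout)
  class(u) <- c("echovol_invres", "echovol_unit")
  u
}

invres_fwd <- function(u, x, ctx) {
  h <- if (!is.null(u$expand)) conv_unit_fwd(u$expand, x, ctx) else x
  h <- dwconv_fwd(u$dw, h, ctx)
  if (!is.null(u$dwbn)) {
    h <- bnact_fwd(u$dwbn, h, ctx)
  } else {
    if (isTRUE(ctx$training)) u$dw_preact <- h
    h <- relu6_f(h)
  }
  y <- conv_fwd(u$proj, h, ctx)
  if (!is.null(u$projbn)) y <- bn_fwd(u$projbn, y, ctx)
  if (u$use_res) y <- y + x
  y
}

invres_bwd <- function(u, dy) {
  dres <- if (u$use_res) dy else NULL
  dh <- if (!is.null(u$projbn)) bn_bwd(u$projbn, dy) else dy
  dh <- conv_bwd(u$proj, dh)
  if (!is.null(u$dwbn)) {
    dh <- bnact_bwd(u$dwbn, dh)
  } else {
    dh <- relu6_b(u$dw_preact, dh)
    u$dw_preact <- NULL
  }
  dh <- dwconv_bwd(u$dw, dh)
  if (!is.null(u$expand)) dh <- conv_unit_bwd(u$expand, dh)
  if (!is.null(dres)) dh <- dh + dres
  dh
}

#' Construct a quantizable squeeze-and-excitation (QSE) block
#'
#' Channel-context injection without elementwise tensor multiplication: the
#' input feature map is globally average-pooled to a 1 x 1 x C squeeze
#' vector, tiled back to the spatial grid, concatenated with the input along
#' channels (2C), and mixed by a 1 x 1 convolution + nonlinearity to
#' `c_out` channels. Unlike the classical SE block there is no
#' activation-by-activation multiply, so the block quantizes cleanly.
#'
#' @param c_in,c_out input / output channel counts.
#' @param norm include batch normalization after the convolution.
#' @param bias include a convolution bias (used when `norm = FALSE`).
#' @param name unit name.
#' @return a QSE unit usable with [forward_unit()].
#' @export
new_qse_block <- function(c_in, c_out, norm = TRUE, bias = !norm,
                          name = "qse") {
  u <- new.env(parent = emptyenv())
  u$type <- "qse"
  u$name <- name
  u$c_in <- as.integer(c_in)
  u$conv <- new_conv(1L, 2L * c_in, c_out, 1L, bias = bias,
                     name = paste0(name, ".conv"))
  u$bn <- if (norm) new_bn(c_out, paste0(name, ".bn")) else NULL
  class(u) <- c("echovol_qse", "echovol_unit")
  u
}

qse_fwd <- function(u, x, ctx) {
  d <- dim(x)
  hw <- d[1] * d[2]
  sq <- gap_f(x)                                  # [C, N] squeeze vector
  tiled <- array(rep(as.vector(sq), each = hw), d)
  xx <- concat_ch(x, tiled)
  y <- conv_fwd(u$conv, xx, ctx)
  if (isTRUE(ctx$training)) u$in_dim <- d
  if (!is.null(u$bn)) {
    y <- bnact_fwd(u$bn, y, ctx)
  } else {
    if (isTRUE(ctx$training)) u$preact <- y
    y <- relu6_f(y)
  }
  y
}

qse_bwd <- function(u, dy) {
  if (!is.null(u$bn)) {
    dy <- bnact_bwd(u$bn, dy)
  } else {
    dy <- relu6_b(u$preact, dy)
    u$preact <- NULL
  }
  dxx <- conv_bwd(u$conv, dy)
  d <- u$in_dim
  hw <- d[1] * d[2]
  C <- d[3]
  dx <- dxx[, , seq_len(C), , drop = FALSE]
  dtile <- dxx[, , C + seq_len(C), , drop = FALSE]
  ds <- matrix(colSums(matrix(dtile, hw)), C, d[4]) / hw
  dx + array(rep(as.vector(ds), each = hw), d)
}

#' Construct a depthwise-separable convolution (DWC) block
#'
#' Depthwise k x k convolution followed by a pointwise 1 x 1 convolution to
#' `c_out` channels, each optionally followed by batch normalization and a
#' ReLU6 nonlinearity.
#'
#' @param c_in,c_out input / output channel counts.
#' @param kernel depthwise kernel size (odd).
#' @param norm include batch normalization.
#' @param act `"relu6"` or `"linear"`.
#' @param name unit name.
#' @return a DWC unit usable with [forward_unit()].
#' @export
new_dwc_block <- function(c_in, c_out, kernel = 3L, norm = TRUE,
                          act = "relu6", name = "dwc") {
  u <- new.env(parent = emptyenv())
  u$type <- "dwc"
  u$name <- name
  u$dw <- new_dwconv(kernel, c_in, 1L, paste0(name, ".dw"))
  u$dwbn <- if (norm) new_bn(c_in, paste0(name, ".dwbn")) else NULL
  u$pw <- new_conv(1L, c_in, c_out, 1L, bias = FALSE,
                   name = paste0(name, ".pw"))
  u$pwbn <- if (norm) new_bn(c_out, paste0(name, ".pwbn")) else NULL
  u$act <- act
  class(u) <- c("echovol_dwc", "echovol_unit")
  u
}

dwc_fwd <- function(u, x, ctx) {
  h <- dwconv_fwd(u$dw, x, ctx)
  if (!is.null(u$dwbn) && u$act == "relu6") {
    h <- bnact_fwd(u$dwbn, h, ctx)
  } else {
    if (!is.null(u$dwbn)) h <- bn_fwd(u$dwbn, h, ctx)
    if (u$act == "relu6") {
      if (isTRUE(ctx$training)) u$preact1 <- h
      h <- relu6_f(h)
    }
  }
  y <- conv_fwd(u$pw, h, ctx)
  if (!is.null(u$pwbn) && u$act == "relu6") {
    y <- bnact_fwd(u$pwbn, y, ctx)
  } else {
    if (!is.null(u$pwbn)) y <- bn_fwd(u$pwbn, y, ctx)
    if (u$act == "relu6") {
      if (isTRUE(ctx$training)) u$preact2 <- y
      y <- relu6_f(y)
    }
  }
  y
}

dwc_bwd <- function(u, dy) {
  if (!is.null(u$pwbn) && u$act == "relu6") {
    dy <- bnact_bwd(u$pwbn, dy)
  } else {
    if (u$act == "relu6") {
      dy <- relu6_b(u$preact2, dy)
      u$preact2 <- NULL
    }
    if (!is.null(u$pwbn)) dy <- bn_bwd(u$pwbn, dy)
  }
  dh <- conv_bwd(u$pw, dy)
  if (!is.null(u$dwbn) && u$act == "relu6") {
    dh <- bnact_bwd(u$dwbn, dh)
  } else {
    if (u$act == "relu6") {
      dh <- relu6_b(u$preact1, dh)
      u$preact1 <- NULL
    }
    if (!is.null(u$dwbn)) dh <- bn_bwd(u$dwbn, dh)
  }
  dwconv_bwd(u$dw, dh)
}

unit_fwd <- function(u, x, ctx) {
  switch(u$type,
    conv_unit = conv_unit_fwd(u, x, ctx),
    invres = invres_fwd(u, x, ctx),
    qse = qse_fwd(u, x, ctx),
    dwc = dwc_fwd(u, x, ctx),
    stop_echovol(paste("unknown unit type", u$type), "echovol_internal"))
}

unit_bwd <- function(u, dy) {
  switch(u$type,
    conv_unit = conv_unit_bwd(u, dy),
    invres = invres_bwd(u, dy),
    qse = qse_bwd(u, dy),
    dwc = dwc_bwd(u, dy),
    stop_echovol(paste("unknown unit type", u$type), "echovol_internal"))
}

#' Run a single network unit forward
#'
#' Convenience wrapper for inspecting individual blocks (e.g. a QSE or DWC
#' block) outside a full model. Accepts `[H,W,C]` or `[H,W,C,N]` input.
#'
#' @param unit a unit from [new_qse_block()], [new_dwc_block()] or an
#'   internal constructor.
#' @param x input array.
#' @param training logical; use batch statistics and keep backward caches.
#' @return output array (batch axis dropped if it was absent on input).
#' @export
forward_unit <- function(unit, x, training = FALSE) {
  had_batch <- length(dim(x)) == 4
  if (!had_batch) dim(x) <- c(dim(x), 1L)
  ctx <- make_ctx(training = training)
  y <- unit_fwd(unit, x, ctx)
  if (!had_batch) dim(y) <- dim(y)[1:3]
  y
}

# All primitive layers inside a unit (for optimizers / counting / copying).
unit_layers <- function(u) {
  switch(u$type,
    conv_unit = Filter(Negate(is.null), list(u$conv, u$bn)),
    invres = Filter(Negate(is.null), c(
      if (!is.null(u$expand)) unit_layers(u$expand),
      list(u$dw, u$dwbn, u$proj, u$projbn))),
    qse = Filter(Negate(is.null), list(u$conv, u$bn)),
    dwc = Filter(Negate(is.null), list(u$dw, u$dwbn, u$pw, u$pwbn)),
    stop_echovol(paste("unknown unit type", u$type), "echovol_internal"))
}

make_ctx <- function(training = FALSE, qat = FALSE, collect = NULL,
                     aq = NULL) {
  list(training = training, qat = qat, collect = collect, aq = aq)
}
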