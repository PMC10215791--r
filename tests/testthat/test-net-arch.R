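test_that("backbone truncates at the stride-16, 96-channel stage", {
  set.seed(1)
  bb <- build_backbone(192)
  expect_identical(bb$out_channels, 96L)
  expect_identical(bb$out_size, 12L)
  x <- array(0, c(192, 192, 1, 1))
  ctx <- echovol:::make_ctx()
  h <- x
  for (u in bb$units) h <- echovol:::unit_fwd(u, h, ctx)
  expect_identical(dim(h), c(12L, 12L, 96L, 1L))

  bb96 <- build_backbone(96)
  x96 <- array(0, c(96, 96, 1, 1))
  h <- x96
  for (u in bb96$units) h <- echovol:::unit_fwd(u, h, ctx)
  expect_identical(dim(h)[1:3], c(6L, 6L, 96L))

  expect_error(build_backbone(100), class = "echovol_invalid_argument")
})

test_that("inverted-residual parameter accounting matches the closed form", {
  set.seed(1)
  # expand 16 -> 96, depthwise 3x3, project 96 -> 24, batch-norm scale+shift:
  # 16*96 + 2*96 + 9*96 + 2*96 + 96*24 + 2*24 = 5136
  u <- echovol:::new_invres_unit(16L, 24L, 1L, 6L)
  expect_identical(count_parameters(u), 5136L)
})

test_that("QSE block satisfies its averaging and counting contracts", {
  set.seed(2)
  u <- new_qse_block(4, 6)
  x <- array(rep(rnorm(4), each = 12 * 12), c(12, 12, 4))
  y <- forward_unit(u, x)
  # constant input per channel -> spatially constant output
  for (c in 1:6) expect_lt(diff(range(y[, , c])), 1e-12)

  # parameter count of the 1x1 conv over the concatenated 2*C_in channels
  ub <- new_qse_block(96, 256, norm = FALSE, bias = TRUE)
  expect_identical(count_parameters(ub), 2L * 96L * 256L + 256L)

  # zero input -> output is the bias image through the nonlinearity
  z <- array(0, c(5, 5, 96))
  yz <- forward_unit(ub, z)
  expected <- pmin(pmax(ub$conv$b, 0), 6)
  for (c in sample(256, 5)) expect_equal(unique(as.vector(yz[, , c])),
                                         expected[c])
})

test_that("DWC block counts, shapes and degenerate identity hold", {
  set.seed(3)
  u <- new_dwc_block(8, 4, norm = FALSE, act = "linear")
  expect_identical(count_parameters(u), 9L * 8L + 8L * 4L)

  big <- new_dwc_block(512, 256)
  x <- array(rnorm(12 * 12 * 512), c(12, 12, 512))
  expect_identical(dim(forward_unit(big, x)), c(12L, 12L, 256L))

  ident <- new_dwc_block(3, 3, kernel = 1, norm = FALSE, act = "linear")
  ident$dw$W <- array(1, c(1, 1, 3))
  ident$pw$W <- array(diag(3), c(1, 1, 3, 3))
  xi <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  expect_equal(forward_unit(ident, xi), xi, tolerance = 1e-12)
})

test_that("the default model respects budget, softmax and shape audits", {
  m <- build_model(model_config(), seed = 1)
  n <- count_parameters(m)
  expect_lt(n, 1e6)
  expect_gt(n, 5e5)
  expect_identical(as.integer(sum(m$graph$params)), as.integer(n))

  sh <- model_shapes(m)
  expect_identical(sh$backbone_out, c(12L, 12L, 96L))
  expect_identical(sh$squeeze, c(1L, 1L, 96L))
  expect_identical(sh$qse_out[3], 256L)
  expect_identical(sh$conv_branch_out[3], 256L)
  expect_identical(sh$concat, c(12L, 12L, 512L))
  expect_identical(sh$merge_out, c(12L, 12L, 256L))
  expect_identical(sh$seg_out, c(192L, 192L, 2L))

  x <- array(runif(192 * 192), c(192, 192, 1, 1))
  fwd <- echovol:::model_forward(m, x, echovol:::make_ctx())
  sums <- fwd$seg_prob[, , 1, 1] + fwd$seg_prob[, , 2, 1]
  expect_equal(range(sums), c(1, 1), tolerance = 1e-12)
  expect_equal(sum(fwd$clf_prob[, 1]), 1, tolerance = 1e-12)
})

test_that("a too-small parameter budget is reported with module counts", {
  expect_error(build_model(model_config(param_budget = 1e4), seed = 1),
               regexp = "backbone", class = "echovol_budget_violation")
})

test_that("the graph walker certifies quantization-friendliness", {
  m <- build_model(tiny_model_config(), seed = 1)
  expect_true(check_quantization_friendly(m))
  bad <- m
  bad$graph <- rbind(bad$graph,
                     echovol:::graph_row("seg", "se.scale", "multiply"))
  expect_error(check_quantization_friendly(bad),
               class = "echovol_quant_contract")
})

test_that("single-layer parameter counts are exact", {
  set.seed(1)
  expect_identical(count_parameters(echovol:::new_conv(1, 96, 2, bias = TRUE)),
                   194L)
  expect_identical(count_parameters(echovol:::new_dense(96, 2)), 194L)
})

test_that("preprocess and postprocess bridge the native and network grids", {
  img <- matrix(runif(330 * 570, 0, 255), 330, 570)
  small <- preprocess_image(img, 192)
  expect_identical(dim(small), c(192L, 192L))
  expect_true(all(small >= 0 & small <= 1))
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)),
               class = "echovol_invalid_argument")

  all_bg <- array(0, c(192, 192, 2))
  all_bg[, , 1] <- 1
  mask <- postprocess_segmentation(all_bg, c(330, 570))
  expect_identical(sum(mask), 0L)

  # block-constant mask survives the down/up round trip to within 5% area
  base <- ellipse_mask(110, 190, 55, 95, 30, 60)
  native <- base[rep(seq_len(110), each = 3), rep(seq_len(190), each = 3)]
  down <- matrix(as.integer(
    echovol:::cpp_resize_nearest(native + 0, 192L, 192L) > 0.5), 192, 192)
  probs <- array(0, c(192, 192, 2))
  probs[, , 2] <- down
  probs[, , 1] <- 1 - down
  back <- postprocess_segmentation(probs, dim(native))
  expect_lt(abs(sum(back) - sum(native)) / sum(native), 0.05)
})

test_that("a symmetric stride-1 check model is left-right flip equivariant", {
  set.seed(4)
  cu <- echovol:::new_conv_unit(3L, 1L, 4L, 1L)
  # symmetrize kernels across the horizontal axis
  cu$conv$W <- (cu$conv$W + cu$conv$W[, 3:1, , , drop = FALSE]) / 2
  qse <- new_qse_block(4, 4)
  x <- array(runif(24 * 24), c(24, 24, 1, 1))
  ctx <- echovol:::make_ctx()
  run <- function(inp) {
    h <- echovol:::unit_fwd(cu, inp, ctx)
    h <- echovol:::unit_fwd(qse, h, ctx)
    echovol:::cpp_resize_bilinear(h, 48L, 48L)
  }
  y <- run(x)
  xf <- x[, 24:1, , , drop = FALSE]
  yf <- run(xf)[, 48:1, , , drop = FALSE]
  expect_equal(y, yf, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(5)
  relerr <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)))
  num_grad <- function(f, x, eps = 1e-5) {
    g <- x
    for (i in seq_along(x)) {
      x1 <- x; x1[i] <- x1[i] + eps
      x2 <- x; x2[i] <- x2[i] - eps
      g[i] <- (f(x1) - f(x2)) / (2 * eps)
    }
    g
  }
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  dy <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  bwd <- echovol:::cpp_conv2d_bwd(x, w, dy, 2L, 1L)
  fx <- function(v) { dim(v) <- dim(x)
    sum(echovol:::cpp_conv2d_fwd(v, w, 2L, 1L) * dy) }
  fw <- function(v) { dim(v) <- dim(w)
    sum(echovol:::cpp_conv2d_fwd(x, v, 2L, 1L) * dy) }
  expect_lt(relerr(num_grad(fx, as.vector(x)), as.vector(bwd$dx)), 1e-7)
  expect_lt(relerr(num_grad(fw, as.vector(w)), as.vector(bwd$dw)), 1e-7)

  wd <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  dyd <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  bwdd <- echovol:::cpp_dwconv2d_bwd(x, wd, dyd, 1L, 1L)
  fxd <- function(v) { dim(v) <- dim(x)
    sum(echovol:::cpp_dwconv2d_fwd(v, wd, 1L, 1L) * dyd) }
  expect_lt(relerr(num_grad(fxd, as.vector(x)), as.vector(bwdd$dx)), 1e-7)

  # bilinear up/down sampling backward is the exact adjoint
  a <- array(rnorm(5 * 5 * 2 * 1), c(5, 5, 2, 1))
  b <- array(rnorm(9 * 9 * 2 * 1), c(9, 9, 2, 1))
  lhs <- sum(echovol:::cpp_resize_bilinear(a, 9L, 9L) * b)
  rhs <- sum(a * echovol:::cpp_resize_bilinear_bwd(b, 5L, 5L))
  expect_equal(lhs, rhs, tolerance = 1e-10)

  # batch norm (training mode)
  l <- echovol:::new_bn(2)
  l$gamma <- rnorm(2) + 1
  ctx <- echovol:::make_ctx(training = TRUE)
  xb <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  dyb <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  invisible(echovol:::bn_fwd(l, xb, ctx))
  dxb <- echovol:::bn_bwd(l, dyb)
  fb <- function(v) { dim(v) <- dim(xb)
    sum(echovol:::bn_fwd(l, v, ctx) * dyb) }
  expect_lt(relerr(num_grad(fb, as.vector(xb)), as.vector(dxb)), 1e-6)
})
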