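#' Model configuration
#'
#' Describes the multitask network: a truncated inverted-residual backbone
#' (stride 16, 96-channel output for the default width), a segmentation
#' decoder made of a QSE branch and a parallel stacked 3x3 convolution
#' branch (each ending at `head_channels`), channel concatenation, a
#' depthwise-separable merge, 1x1 channel reduction to two classes, bilinear
#' upscaling back to the input size and a per-pixel softmax; plus a
#' classification path (global average pool, dense layer, softmax).
#'
#' @param input_size square network input size in pixels; must be divisible
#'   by 16 (default 192).
#' @param width channel width multiplier (1 = reference model; smaller values
#'   give reduced test-scale models).
#' @param qse_blocks number of QSE blocks chained in the QSE branch.
#' @param conv_branch_channels channel schedule of the stacked 3x3
#'   convolution branch; the last entry must equal `head_channels`.
#' @param head_channels endpoint channels of each decoder branch (the two
#'   branches concatenate to `2 * head_channels`).
#' @param upsample_steps 1 (single x16 bilinear step) or 2 (two x4 steps).
#' @param param_budget hard upper bound on trainable parameters.
#' @return a `model_config` list.
#' @export
model_config <- function(input_size = 192L, width = 1, qse_blocks = 2L,
                         conv_branch_channels = NULL, head_channels = 256L,
                         upsample_steps = 1L, param_budget = 1e6) {
  input_size <- as.integer(input_size)
  if (input_size <= 0 || input_size %% 16L != 0L) {
    stop_echovol("input_size must be a positive multiple of 16",
                 "echovol_invalid_argument")
  }
  scale_ch <- function(c) max(4L, as.integer(round(c * width / 4) * 4))
  head_channels <- scale_ch(head_channels)
  if (is.null(conv_branch_channels)) {
    conv_branch_channels <- c(scale_ch(64L), head_channels)
  }
  if (utils::tail(conv_branch_channels, 1) != head_channels) {
    stop_echovol("conv branch must end at head_channels", "echovol_invalid_argument")
  }
  structure(list(
    input_size = input_size, width = width, qse_blocks = as.integer(qse_blocks),
    conv_branch_channels = as.integer(conv_branch_channels),
    head_channels = head_channels, upsample_steps = as.integer(upsample_steps),
    param_budget = param_budget, scale_ch = scale_ch
  ), class = "model_config")
}

# Truncated inverted-residual backbone stage plan: (expand factor, channels,
# stride, repeats). Cut immediately after the stride-16, 96-channel stage.
backbone_plan <- function(scale_ch) {
  list(
    stem = scale_ch(32L),
    stages = list(
      list(t = 1L, c = scale_ch(16L), s = 1L, n = 1L),
      list(t = 6L, c = scale_ch(24L), s = 2L, n = 2L),
      list(t = 6L, c = scale_ch(32L), s = 2L, n = 3L),
      list(t = 6L, c = scale_ch(64L), s = 2L, n = 4L),
      list(t = 6L, c = scale_ch(96L), s = 1L, n = 3L)
    )
  )
}

#' Build the shared feature-extraction backbone
#'
#' Stem 3x3 stride-2 convolution followed by inverted-residual
#' (expand, depthwise, project) bottleneck stages, truncated right after the
#' stride-16 stage whose output has 96 channels (reference width), so a
#' 192 x 192 single-channel input yields a 12 x 12 x 96 feature map.
#'
#' @param input_size square input size; must be divisible by 16.
#' @param width channel width multiplier.
#' @return list with `units`, `out_channels`, `out_size`.
#' @export
build_backbone <- function(input_size = 192L, width = 1) {
  if (input_size %% 16L != 0L) {
    stop_echovol("input_size must be divisible by 16", "echovol_invalid_argument")
  }
  scale_ch <- function(c) max(4L, as.integer(round(c * width / 4) * 4))
  plan <- backbone_plan(scale_ch)
  units <- list()
  units[[1]] <- new_conv_unit(3L, 1L, plan$stem, 2L, name = "bb01.stem")
  cin <- plan$stem
  k <- 1L
  for (st in plan$stages) {
    for (i in seq_len(st$n)) {
      k <- k + 1L
      stride <- if (i == 1L) st$s else 1L
      units[[k]] <- new_invres_unit(cin, st$c, stride, st$t,
                                    name = sprintf("bb%02d", k))
      cin <- st$c
    }
  }
  list(units = units, out_channels = cin,
       out_size = as.integer(input_size) %/% 16L)
}

#' Build the full multitask model
#'
#' Assembles backbone, QSE + 3x3 convolution segmentation decoder and the
#' global-pooled classification head, verifies the parameter budget, and
#' attaches a symbolic layer-descriptor graph.
#'
#' @param config a [model_config()].
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `echovol_model`.
#' @export
build_model <- function(config = model_config(), seed = NULL) {
  builder <- function() {
    bb <- build_backbone(config$input_size, config$width)
    C <- bb$out_channels
    E <- config$head_channels
    qse <- list()
    for (i in seq_len(config$qse_blocks)) {
      cout <- if (i == config$qse_blocks) E else C
      qse[[i]] <- new_qse_block(C, cout, name = sprintf("qse%d", i))
      C <- cout
    }
    C <- bb$out_channels
    convbr <- list()
    cin <- C
    for (i in seq_along(config$conv_branch_channels)) {
      convbr[[i]] <- new_conv_unit(3L, cin, config$conv_branch_channels[i],
                                   1L, name = sprintf("cv%d", i))
      cin <- config$conv_branch_channels[i]
    }
    merge <- new_dwc_block(2L * E, E, name = "merge")
    reduce <- new_conv(1L, E, 2L, bias = TRUE, name = "reduce")
    clf <- new_dense(C, 2L, name = "clf")
    model <- structure(list(
      config = config, backbone = bb, qse = qse, convbr = convbr,
      merge = merge, reduce = reduce, clf = clf,
      quantized = FALSE, act_ranges = NULL,
      graph = model_graph(config)
    ), class = "echovol_model")
    n <- count_parameters(model)
    if (n >= config$param_budget) {
      br <- attr(n, "breakdown")
      stop_echovol(sprintf(
        "parameter budget exceeded: %d >= %g (%s)", n, config$param_budget,
        paste(sprintf("%s=%d", names(br), br), collapse = ", ")),
        "echovol_budget_violation")
    }
    model
  }
  if (is.null(seed)) builder() else with_seed(seed, builder())
}

# Every primitive layer in the model, in forward order.
model_layers <- function(model) {
  c(unlist(lapply(model$backbone$units, unit_layers)),
    unlist(lapply(model$qse, unit_layers)),
    unlist(lapply(model$convbr, unit_layers)),
    unit_layers(model$merge),
    list(model$reduce, model$clf))
}

#' Count trainable parameters
#'
#' Exact sum over the weight arrays of every layer, with a per-module
#' breakdown in the `"breakdown"` attribute.
#'
#' @param model an `echovol_model` (or a single unit / layer).
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  layer_count <- function(l) sum(vapply(l$params, function(p) length(l[[p]]),
                                        numeric(1)))
  if (inherits(model, "echovol_layer")) {
    return(as.integer(layer_count(model)))
  }
  if (inherits(model, "echovol_unit")) {
    return(as.integer(sum(vapply(unit_layers(model), layer_count, numeric(1)))))
  }
  groups <- list(
    backbone = unlist(lapply(model$backbone$units, unit_layers)),
    qse_branch = unlist(lapply(model$qse, unit_layers)),
    conv_branch = unlist(lapply(model$convbr, unit_layers)),
    merge = unit_layers(model$merge),
    heads = list(model$reduce, model$clf)
  )
  br <- vapply(groups, function(ls) sum(vapply(ls, layer_count, numeric(1))),
               numeric(1))
  structure(as.integer(sum(br)), breakdown = as.integer(br) |>
              stats::setNames(names(br)))
}

# ---------------------------------------------------------------------------
# Symbolic graph: one descriptor row per elementary operation. Used for the
# parameter accounting cross-check, the shape audit and the
# quantization-friendliness walk.

graph_row <- function(module, name, kind, kernel = NA, stride = NA,
                      in_ch = NA, out_ch = NA, out_h = NA, out_w = NA,
                      params = 0) {
  data.frame(module = module, name = name, kind = kind, kernel = kernel,
             stride = stride, in_ch = in_ch, out_ch = out_ch,
             out_h = out_h, out_w = out_w, params = params,
             stringsAsFactors = FALSE)
}

#' Symbolic layer-descriptor graph of the model
#'
#' A data frame with one row per elementary operation (convolutions,
#' batch norms, activations, pooling, tiling, concatenation, upsampling,
#' softmax), its shape parameters and its closed-form parameter count.
#'
#' @param config a [model_config()].
#' @return a `data.frame` layer table.
#' @export
model_graph <- function(config) {
  scale_ch <- config$scale_ch
  plan <- backbone_plan(scale_ch)
  S <- config$input_size
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- graph_row(...)
  conv_rows <- function(module, name, k, cin, cout, stride, h, w,
                        norm = TRUE, act = TRUE, bias = !norm,
                        kind = "conv") {
    np <- if (kind == "depthwise_conv") k * k * cin else k * k * cin * cout
    add(module, paste0(name, ".conv"), kind, k, stride, cin, cout, h, w,
        np + if (bias) cout else 0)
    if (norm) add(module, paste0(name, ".bn"), "batch_norm", NA, NA, cout,
                  cout, h, w, 2 * cout)
    if (act) add(module, paste0(name, ".relu6"), "activation", NA, NA, cout,
                 cout, h, w, 0)
  }
  h <- S %/% 2L
  conv_rows("backbone", "bb01.stem", 3L, 1L, plan$stem, 2L, h, h)
  cin <- plan$stem
  k <- 1L
  for (st in plan$stages) {
    for (i in seq_len(st$n)) {
      k <- k + 1L
      stride <- if (i == 1L) st$s else 1L
      h <- h %/% stride
      nm <- sprintf("bb%02d", k)
      mid <- cin * st$t
      if (st$t != 1L) {
        conv_rows("backbone", paste0(nm, ".expand"), 1L, cin, mid, 1L,
                  h * stride, h * stride, kind = "pointwise_conv")
      }
      conv_rows("backbone", paste0(nm, ".dw"), 3L, mid, mid, stride, h, h,
                kind = "depthwise_conv")
      conv_rows("backbone", paste0(nm, ".proj"), 1L, mid, cin2 <- st$c, 1L,
                h, h, act = FALSE, kind = "pointwise_conv")
      if (stride == 1L && cin == st$c) {
        add("backbone", paste0(nm, ".add"), "add", NA, NA, st$c, st$c, h, h, 0)
      }
      cin <- st$c
    }
  }
  C <- cin
  hf <- S %/% 16L
  E <- config$head_channels
  qc_in <- C
  for (i in seq_len(config$qse_blocks)) {
    cout <- if (i == config$qse_blocks) E else C
    nm <- sprintf("qse%d", i)
    add("seg", paste0(nm, ".squeeze"), "global_avg_pool", NA, NA, qc_in,
        qc_in, 1L, 1L, 0)
    add("seg", paste0(nm, ".tile"), "tile", NA, NA, qc_in, qc_in, hf, hf, 0)
    add("seg", paste0(nm, ".concat"), "concat", NA, NA, qc_in, 2L * qc_in,
        hf, hf, 0)
    conv_rows("seg", nm, 1L, 2L * qc_in, cout, 1L, hf, hf,
              kind = "pointwise_conv")
    qc_in <- cout
  }
  cc_in <- C
  for (i in seq_along(config$conv_branch_channels)) {
    conv_rows("seg", sprintf("cv%d", i), 3L, cc_in,
              config$conv_branch_channels[i], 1L, hf, hf)
    cc_in <- config$conv_branch_channels[i]
  }
  add("seg", "branch.concat", "concat", NA, NA, E, 2L * E, hf, hf, 0)
  conv_rows("seg", "merge.dw", 3L, 2L * E, 2L * E, 1L, hf, hf,
            kind = "depthwise_conv")
  conv_rows("seg", "merge.pw", 1L, 2L * E, E, 1L, hf, hf,
            kind = "pointwise_conv")
  add("seg", "reduce", "pointwise_conv", 1L, 1L, E, 2L, hf, hf, E * 2L + 2L)
  for (i in seq_len(config$upsample_steps)) {
    step <- 16L^(1 / config$upsample_steps)
    add("seg", sprintf("upsample%d", i), "upsample_bilinear", NA, NA, 2L, 2L,
        as.integer(hf * step^i), as.integer(hf * step^i), 0)
  }
  add("seg", "seg.softmax", "softmax", NA, NA, 2L, 2L, S, S, 0)
  add("clf", "gap", "global_avg_pool", NA, NA, C, C, 1L, 1L, 0)
  add("clf", "clf.dense", "dense", NA, NA, C, 2L, 1L, 1L, C * 2L + 2L)
  add("clf", "clf.softmax", "softmax", NA, NA, 2L, 2L, 1L, 1L, 0)
  do.call(rbind, rows)
}

#' Audit the key intermediate tensor shapes of a model
#'
#' @param model an `echovol_model`.
#' @return named list of `c(height, width, channels)` shapes for the
#'   backbone output, the QSE squeeze vector, the branch endpoints, the
#'   concatenated decoder tensor, the merged tensor, and the segmentation
#'   output.
#' @export
model_shapes <- function(model) {
  g <- model$graph
  S <- model$config$input_size
  hf <- S %/% 16L
  C <- model$backbone$out_channels
  E <- model$config$head_channels
  shape_of <- function(name) {
    r <- g[g$name == name, ]
    c(r$out_h[1], r$out_w[1], r$out_ch[1])
  }
  list(
    input = c(S, S, 1L),
    backbone_out = c(hf, hf, C),
    squeeze = c(1L, 1L, C),
    qse_out = shape_of(sprintf("qse%d.conv", model$config$qse_blocks)),
    conv_branch_out = shape_of(
      sprintf("cv%d.conv", length(model$config$conv_branch_channels))),
    concat = shape_of("branch.concat"),
    merge_out = shape_of("merge.pw.conv"),
    seg_logits = shape_of("reduce"),
    seg_out = c(S, S, 2L),
    clf_out = c(1L, 1L, 2L)
  )
}

#' Verify the quantization-friendliness contract of the graph
#'
#' Walks every descriptor row and checks that no operation multiplies two
#' activation tensors elementwise (the failure mode that makes classical
#' squeeze-and-excitation blocks hard to quantize). Channel mixing happens
#' only through convolutions over concatenated tensors.
#'
#' @param model an `echovol_model`.
#' @return `TRUE` (invisibly) if the graph is clean; otherwise an error.
#' @export
check_quantization_friendly <- function(model) {
  allowed <- c("conv", "depthwise_conv", "pointwise_conv", "batch_norm",
               "activation", "add", "global_avg_pool", "tile", "concat",
               "dense", "upsample_bilinear", "softmax")
  kinds <- unique(model$graph$kind)
  bad <- setdiff(kinds, allowed)
  if (length(bad) || any(grepl("multiply", kinds, fixed = TRUE))) {
    stop_echovol(paste("non-quantizable ops in graph:",
                       paste(bad, collapse = ", ")), "echovol_quant_contract")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Forward / backward over the assembled model.

apply_act <- function(x, name, ctx) {
  if (!is.null(ctx$collect)) {
    r <- range(x)
    old <- ctx$collect[[name]]
    ctx$collect[[name]] <- if (is.null(old)) r else range(c(old, r))
  }
  if (!is.null(ctx$aq)) {
    r <- ctx$aq[[name]]
    if (!is.null(r)) x <- quantize_affine(x, r[1], r[2])
  }
  x
}

model_forward <- function(model, x, ctx) {
  x <- apply_act(x, "input", ctx)
  h <- x
  for (u in model$backbone$units) {
    h <- unit_fwd(u, h, ctx)
    h <- apply_act(h, u$name, ctx)
  }
  feat <- h
  q <- feat
  for (u in model$qse) {
    q <- unit_fwd(u, q, ctx)
    q <- apply_act(q, u$name, ctx)
  }
  b <- feat
  for (u in model$convbr) {
    b <- unit_fwd(u, b, ctx)
    b <- apply_act(b, u$name, ctx)
  }
  cc <- concat_ch(q, b)
  mg <- unit_fwd(model$merge, cc, ctx)
  mg <- apply_act(mg, "merge", ctx)
  z <- conv_fwd(model$reduce, mg, ctx)
  z <- apply_act(z, "seg_logits", ctx)
  S <- model$config$input_size
  Z <- z
  steps <- model$config$upsample_steps
  d <- dim(z)
  for (i in seq_len(steps)) {
    target <- if (i == steps) S else as.integer(d[1] * (S / d[1])^(i / steps))
    Z <- cpp_resize_bilinear(Z, target, target)
  }
  P <- softmax_ch(Z)
  g <- gap_f(feat)
  g <- apply_act(g, "gap", ctx)
  lg <- dense_fwd(model$clf, g, ctx)
  lg <- apply_act(lg, "clf_logits", ctx)
  pc <- softmax_mat(lg)
  list(seg_prob = P, seg_logits_up = Z, seg_logits = z, clf_prob = pc,
       clf_logits = lg, feat_dim = dim(feat))
}

# dZ: gradient w.r.t. the upsampled segmentation logits (or NULL);
# dlg: gradient w.r.t. the classification logits (or NULL).
model_backward <- function(model, fwd, dZ = NULL, dlg = NULL) {
  fd <- fwd$feat_dim
  dfeat <- array(0, fd)
  if (!is.null(dZ)) {
    steps <- model$config$upsample_steps
    hf <- fd[1]
    dz <- dZ
    for (i in rev(seq_len(steps))) {
      target <- if (i == 1L) hf else {
        as.integer(hf * (model$config$input_size / hf)^((i - 1) / steps))
      }
      dz <- cpp_resize_bilinear_bwd(dz, target, target)
    }
    dmg <- conv_bwd(model$reduce, dz)
    dcc <- unit_bwd(model$merge, dmg)
    E <- model$config$head_channels
    dq <- dcc[, , seq_len(E), , drop = FALSE]
    db <- dcc[, , E + seq_len(E), , drop = FALSE]
    for (u in rev(model$qse)) dq <- unit_bwd(u, dq)
    for (u in rev(model$convbr)) db <- unit_bwd(u, db)
    dfeat <- dfeat + dq + db
  }
  if (!is.null(dlg)) {
    dg <- dense_bwd(model$clf, dlg)
    hw <- fd[1] * fd[2]
    dfeat <- dfeat + array(rep(as.vector(dg), each = hw), fd) / hw
  }
  dh <- dfeat
  for (u in rev(model$backbone$units)) dh <- unit_bwd(u, dh)
  invisible(dh)
}

# ---------------------------------------------------------------------------
# Pre/post-processing between the native image grid and the network grid.

#' Resize a native B-mode image for the network
#'
#' Bilinear down-resize to `target x target` with intensity scaling to
#' `[0, 1]`.
#'
#' @param image numeric/integer matrix (uint8 intensity grid).
#' @param target square network input size.
#' @return `target x target` numeric matrix in `[0, 1]`.
#' @export
preprocess_image <- function(image, target = 192L) {
  if (is.null(dim(image)) || any(dim(image) == 0) || length(image) == 0) {
    stop_echovol("empty image", "echovol_invalid_argument")
  }
  x <- array(as.numeric(image) / 255, c(nrow(image), ncol(image), 1L, 1L))
  y <- cpp_resize_bilinear(x, as.integer(target), as.integer(target))
  matrix(y, target, target)
}

#' Convert a softmax segmentation map back to a native-grid binary mask
#'
#' Per-pixel argmax over the two classes followed by nearest-neighbour
#' up-resize to the original image grid.
#'
#' @param seg_prob `[S,S,2]` (or `[S,S,2,1]`) class-probability array.
#' @param native_shape `c(height, width)` of the original image.
#' @return integer 0/1 mask matrix of size `native_shape`.
#' @export
postprocess_segmentation <- function(seg_prob, native_shape) {
  if (length(dim(seg_prob)) == 4) {
    seg_prob <- array(seg_prob[, , , 1], dim(seg_prob)[1:3])
  }
  cls <- (seg_prob[, , 2] > seg_prob[, , 1]) * 1
  out <- cpp_resize_nearest(cls, as.integer(native_shape[1]),
                            as.integer(native_shape[2]))
  matrix(as.integer(out), native_shape[1], native_shape[2])
}

# Eval-mode inference on a list of native images; returns forward result.
model_infer <- function(model, images) {
  S <- model$config$input_size
  n <- length(images)
  x <- array(0, c(S, S, 1L, n))
  for (i in seq_len(n)) x[, , 1, i] <- preprocess_image(images[[i]], S)
  ctx <- make_ctx(training = FALSE, qat = FALSE,
                  aq = if (isTRUE(model$quantized)) model$act_ranges else NULL)
  model_forward(model, x, ctx)
}

#' Segment a native-grid image
#'
#' @param model a trained (or quantized) `echovol_model`.
#' @param image native uint8 image matrix.
#' @return integer 0/1 mask on the native grid.
#' @export
predict_segmentation <- function(model, image) {
  if (is.null(model)) stop_echovol("model missing", "echovol_configuration")
  fwd <- model_infer(model, list(image))
  postprocess_segmentation(fwd$seg_prob, dim(image))
}

#' Detect bladder presence on a native-grid image
#'
#' @param model a trained (or quantized) `echovol_model`.
#' @param image native uint8 image matrix.
#' @return list with `has_bladder` (logical) and `prob` (bladder-class
#'   probability).
#' @export
predict_detection <- function(model, image) {
  if (is.null(model)) stop_echovol("model missing", "echovol_configuration")
  fwd <- model_infer(model, list(image))
  p <- fwd$clf_prob[2, 1]
  list(has_bladder = p >= 0.5, prob = p)
}
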