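#' 8-bit quantization specification
#'
#' @param bit_width quantization bit width (8).
#' @param weight_scheme weight quantization scheme; per-tensor symmetric
#'   signed int8.
#' @param activation_scheme activation scheme; per-tensor affine uint8 with
#'   calibrated ranges.
#' @param calibration_size number of calibration images used to fix
#'   activation ranges.
#' @return a `quant_spec` list.
#' @export
quant_spec <- function(bit_width = 8L,
                       weight_scheme = "per_tensor_symmetric",
                       activation_scheme = "per_tensor_affine",
                       calibration_size = 32L) {
  structure(list(bit_width = as.integer(bit_width),
                 weight_scheme = weight_scheme,
                 activation_scheme = activation_scheme,
                 calibration_size = as.integer(calibration_size)),
            class = "quant_spec")
}

#' Fake-quantize a tensor onto the symmetric signed 8-bit grid
#'
#' Rounds to the per-tensor symmetric int8 grid (scale = max|x| / 127) and
#' de-quantizes again. This is the quantization-aware-training forward
#' transform; it is a projection, hence idempotent. Gradients pass straight
#' through (the caller applies updates to the float weights).
#'
#' @param x numeric tensor.
#' @param spec a [quant_spec()] (bit width is honoured).
#' @return tensor of the same shape on the quantization grid.
#' @export
fake_quantize <- function(x, spec = quant_spec()) {
  qmax <- 2^(spec$bit_width - 1) - 1
  s <- max(abs(x))
  if (s == 0) return(x)
  scale <- s / qmax
  q <- clamp(round(x / scale), -qmax, qmax)
  y <- q * scale
  dim(y) <- dim(x)
  y
}

# Integer codes + scale for storage.
quantize_sym_codes <- function(x, bit_width = 8L) {
  qmax <- 2^(bit_width - 1) - 1
  s <- max(abs(x))
  scale <- if (s == 0) 1 else s / qmax
  q <- as.integer(clamp(round(x / scale), -qmax, qmax))
  dim(q) <- dim(x)
  list(codes = q, scale = scale)
}

# Affine uint8 fake-quantization for activations given a calibrated range.
quantize_affine <- function(x, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-12) {
    warning(structure(
      class = c("echovol_degenerate_scale", "warning", "condition"),
      list(message = "degenerate activation range; falling back to scale 1",
           call = sys.call(-1))))
    scale <- 1
    zp <- 0
  } else {
    scale <- (hi - lo) / 255
    zp <- round(-lo / scale)
  }
  q <- clamp(round(x / scale) + zp, 0, 255)
  y <- (q - zp) * scale
  dim(y) <- dim(x)
  y
}

# Deep copy of a model (layer environments are duplicated).
clone_model <- function(model) {
  unserialize(serialize(model, NULL))
}

#' Extract all weights (and batch-norm running statistics) as a named list
#' @param model an `echovol_model`.
#' @return named list of parameter arrays.
#' @export
get_weights <- function(model) {
  out <- list()
  for (l in model_layers(model)) {
    flds <- c(l$params, intersect(c("rmean", "rvar"), names(l)))
    for (p in flds) out[[paste(l$name, p, sep = "/")]] <- l[[p]]
  }
  out
}

#' Load weights produced by [get_weights()] back into a model
#' @param model an `echovol_model`.
#' @param w named weight list.
#' @return the model (weights are assigned into its layers).
#' @export
set_weights <- function(model, w) {
  for (l in model_layers(model)) {
    flds <- c(l$params, intersect(c("rmean", "rvar"), names(l)))
    for (p in flds) {
      key <- paste(l$name, p, sep = "/")
      if (!key %in% names(w)) {
        stop_echovol(sprintf("weight '%s' missing", key), "echovol_structure")
      }
      l[[p]] <- w[[key]]
    }
  }
  invisible(model)
}

# Fold a batch-norm layer into the convolution that precedes it.
fold_pair <- function(conv, bn, depthwise = FALSE) {
  if (is.null(bn)) return(invisible(NULL))
  sdinv <- 1 / sqrt(bn$rvar + bn$eps)
  s <- bn$gamma * sdinv
  d <- dim(conv$W)
  if (depthwise) {
    conv$W <- conv$W * rep(s, each = d[1] * d[2])
    dim(conv$W) <- d
  } else {
    conv$W <- conv$W * rep(s, each = d[1] * d[2] * d[3])
    dim(conv$W) <- d
  }
  old_b <- conv$b %||% 0
  conv$b <- bn$beta - bn$gamma * bn$rmean * sdinv + old_b * s
  if (!"b" %in% conv$params) conv$params <- c(conv$params, "b")
  invisible(NULL)
}

# Fold all batch norms of a (cloned) model into their convolutions.
fold_batchnorm <- function(model) {
  m <- clone_model(model)
  fold_unit <- function(u) {
    switch(u$type,
      conv_unit = { fold_pair(u$conv, u$bn); u$bn <- NULL },
      invres = {
        if (!is.null(u$expand)) { fold_pair(u$expand$conv, u$expand$bn)
                                  u$expand$bn <- NULL }
        fold_pair(u$dw, u$dwbn, depthwise = TRUE); u$dwbn <- NULL
        fold_pair(u$proj, u$projbn); u$projbn <- NULL
      },
      qse = { fold_pair(u$conv, u$bn); u$bn <- NULL },
      dwc = {
        fold_pair(u$dw, u$dwbn, depthwise = TRUE); u$dwbn <- NULL
        fold_pair(u$pw, u$pwbn); u$pwbn <- NULL
      })
    invisible(NULL)
  }
  for (u in m$backbone$units) fold_unit(u)
  for (u in m$qse) fold_unit(u)
  for (u in m$convbr) fold_unit(u)
  fold_unit(m$merge)
  m
}

#' Quantize a trained model to 8-bit fixed point
#'
#' Folds batch normalization into the convolutions, quantizes every weight
#' tensor to per-tensor symmetric int8 codes, and calibrates per-node affine
#' activation ranges on a calibration set. The returned model stores the
#' integer codes and scales and simulates integer inference by de-quantized
#' arithmetic with activation fake-quantization at every node boundary.
#'
#' @param model a trained `echovol_model`.
#' @param calibration_images list of native uint8 image matrices (non-empty).
#' @param spec a [quant_spec()].
#' @return quantized model of class `c("echovol_qmodel", "echovol_model")`.
#' @export
quantize_model <- function(model, calibration_images, spec = quant_spec()) {
  if (length(calibration_images) == 0) {
    stop_echovol("calibration set must be non-empty", "echovol_invalid_argument")
  }
  if (length(calibration_images) > spec$calibration_size) {
    calibration_images <- calibration_images[seq_len(spec$calibration_size)]
  }
  m <- fold_batchnorm(model)
  for (l in model_layers(m)) {
    if (l$type %in% c("conv", "dwconv", "dense")) {
      qc <- quantize_sym_codes(l$W, spec$bit_width)
      l$W_codes <- qc$codes
      l$w_scale <- qc$scale
      l$W <- qc$codes * qc$scale
      if (!is.null(dim(l$W_codes))) dim(l$W) <- dim(l$W_codes)
      if (l$type == "dense") dim(l$W) <- dim(l$W_codes)
    }
  }
  S <- m$config$input_size
  n <- length(calibration_images)
  x <- array(0, c(S, S, 1L, n))
  for (i in seq_len(n)) x[, , 1, i] <- preprocess_image(calibration_images[[i]], S)
  collect <- new.env(parent = emptyenv())
  model_forward(m, x, make_ctx(collect = collect))
  m$act_ranges <- as.list(collect)
  m$quantized <- TRUE
  m$spec <- spec
  class(m) <- c("echovol_qmodel", "echovol_model")
  m
}

#' Save a model (float or quantized) to disk
#'
#' Weights, integer codes, scales and calibrated activation ranges are
#' serialized into a single binary container.
#'
#' @param model model object.
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path file path.
#' @return the model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop_echovol(sprintf("model file '%s' not found", path),
                 "echovol_configuration")
  }
  readRDS(path)
}
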