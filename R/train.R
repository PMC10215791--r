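#' Training configuration
#'
#' @param alpha combo-loss weight in `[0, 1]`: `alpha * CE +
#'   (1 - alpha) * (1 - softDice)`.
#' @param learning_rate initial Adam learning rate.
#' @param lr_factor multiplicative learning-rate reduction on plateau.
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is reduced.
#' @param patience early-stopping patience in epochs.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param seed RNG seed covering initialization, shuffling and augmentation.
#' @param qat_enabled apply weight fake-quantization in the forward pass
#'   (quantization-aware training).
#' @param intensity_shift_range augmentation: uniform intensity offset bound
#'   in uint8 units.
#' @param lr_flip_prob augmentation: probability of a left-right flip.
#' @return a `train_config` list.
#' @export
train_config <- function(alpha = 0.5, learning_rate = 1e-3, lr_factor = 0.5,
                         lr_patience = 5L, patience = 20L, batch_size = 4L,
                         max_epochs = 30L, seed = 1L, qat_enabled = TRUE,
                         intensity_shift_range = 25, lr_flip_prob = 0.5) {
  if (alpha < 0 || alpha > 1) {
    stop_echovol("alpha must lie in [0, 1]", "echovol_invalid_argument")
  }
  if (patience < 1) {
    stop_echovol("patience must be >= 1", "echovol_invalid_argument")
  }
  structure(list(alpha = alpha, learning_rate = learning_rate,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 qat_enabled = isTRUE(qat_enabled),
                 intensity_shift_range = intensity_shift_range,
                 lr_flip_prob = lr_flip_prob), class = "train_config")
}

#' Combo loss: weighted cross-entropy plus soft-Dice loss
#'
#' `alpha * CE + (1 - alpha) * (1 - softDice)` where CE is the mean binary
#' per-pixel cross-entropy and `softDice = 2 sum(p y) / (sum(p) + sum(y))`,
#' computed without a smoothing term whenever `sum(p) + sum(y) > 0`.
#'
#' @param pred predicted bladder-class probabilities (any shape).
#' @param gt binary ground-truth mask of the same shape.
#' @param alpha cross-entropy weight in `[0, 1]`.
#' @return non-negative scalar loss.
#' @export
combo_loss <- function(pred, gt, alpha = 0.5) {
  if (length(pred) == 0 || length(gt) == 0) {
    stop_echovol("empty tensors", "echovol_invalid_argument")
  }
  if (length(pred) != length(gt)) {
    stop_echovol("pred and gt must share shape", "echovol_invalid_argument")
  }
  p <- clamp(as.numeric(pred), 1e-12, 1 - 1e-12)
  y <- as.numeric(gt)
  ce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  denom <- sum(p) + sum(y)
  dice <- if (denom > 0) 2 * sum(p * y) / denom else 1
  alpha * ce + (1 - alpha) * (1 - dice)
}

#' Random intensity shift and left-right flip augmentation
#'
#' Applies (with the configured parameters) a uniform additive intensity
#' offset, clipped to the valid range, and/or a horizontal flip of image and
#' mask together.
#'
#' @param image image matrix.
#' @param mask binary mask matrix (flipped together with the image); may be
#'   `NULL`.
#' @param shift_range uniform offset bound (0 disables).
#' @param flip_prob flip probability (0 disables).
#' @param range valid intensity range to clip to.
#' @return list with `image`, `mask`, and the applied `shift` / `flipped`.
#' @export
augment_sample <- function(image, mask = NULL, shift_range = 25,
                           flip_prob = 0.5, range = c(0, 255)) {
  shift <- if (shift_range > 0) runif(1, -shift_range, shift_range) else 0
  flipped <- flip_prob > 0 && runif(1) < flip_prob
  img <- clamp(image + shift, range[1], range[2])
  if (flipped) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(mask)) mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  list(image = img, mask = mask, shift = shift, flipped = flipped)
}

# Early stopper: returns TRUE when `patience` epochs pass without
# improvement of the monitored loss.
make_early_stopper <- function(patience) {
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$wait <- 0L
  env$best_epoch <- 0L
  function(loss, epoch) {
    if (loss < env$best - 1e-10) {
      env$best <- loss
      env$wait <- 0L
      env$best_epoch <- epoch
      FALSE
    } else {
      env$wait <- env$wait + 1L
      env$wait >= patience
    }
  }
}

# Adam update over a list of primitive layers (skips frozen layers).
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (isTRUE(l$frozen)) next
    for (p in l$params) {
      g <- l[[paste0("g", p)]]
      if (is.null(g)) next
      mkey <- paste0("adam_m_", p)
      vkey <- paste0("adam_v_", p)
      m <- (l[[mkey]] %||% 0) * beta1 + (1 - beta1) * g
      v <- (l[[vkey]] %||% 0) * beta2 + (1 - beta2) * g^2
      l[[mkey]] <- m
      l[[vkey]] <- v
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

# SHA-independent checksum over a set of layers' weights (freeze audit).
weight_checksum <- function(layers) {
  sum(vapply(layers, function(l) {
    sum(vapply(l$params, function(p) sum(l[[p]] * seq_along(l[[p]])),
               numeric(1)))
  }, numeric(1)))
}

# Layers belonging to each trainable path.
path_layers <- function(model, path) {
  seg <- c(unlist(lapply(model$qse, unit_layers)),
           unlist(lapply(model$convbr, unit_layers)),
           unit_layers(model$merge), list(model$reduce))
  switch(path,
    segmentation = c(unlist(lapply(model$backbone$units, unit_layers)), seg),
    classification = list(model$clf),
    stop_echovol("unknown path", "echovol_invalid_argument"))
}

# Combined CE + Dice gradient w.r.t. the two-class segmentation logits.
# P: [S,S,2,N] softmax probabilities, Y: [S,S,N] binary masks.
seg_loss_grad <- function(P, Y, alpha) {
  d <- dim(P)
  N <- d[4]
  M <- d[1] * d[2] * N
  p2 <- array(P[, , 2, ], c(d[1], d[2], N))
  # cross-entropy part: (P - onehot) / M
  dZ <- P
  dZ[, , 1, ] <- (P[, , 1, ] - (1 - Y)) / M
  dZ[, , 2, ] <- (P[, , 2, ] - Y) / M
  loss_ce <- -mean(log(clamp(ifelse(Y > 0.5, p2, 1 - p2), 1e-12, 1)))
  # soft-Dice part, per image
  dice_vals <- numeric(N)
  if (alpha < 1) {
    dD <- array(0, c(d[1], d[2], N))
    for (n in seq_len(N)) {
      p <- p2[, , n]
      y <- Y[, , n]
      sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
      den <- sp + sy
      if (den > 0) {
        dice_vals[n] <- 2 * spy / den
        dD[, , n] <- (2 * y * den - 2 * spy) / den^2
      } else {
        dice_vals[n] <- 1
      }
    }
    gp <- -dD / N                        # d(mean dice loss)/d p2
    s <- gp * p2 * (1 - p2)              # chain through 2-class softmax
    dZ[, , 2, ] <- alpha * dZ[, , 2, ] + (1 - alpha) * s
    dZ[, , 1, ] <- alpha * dZ[, , 1, ] + (1 - alpha) * (-s)
  } else {
    for (n in seq_len(N)) {
      p <- p2[, , n]; y <- Y[, , n]
      den <- sum(p) + sum(y)
      dice_vals[n] <- if (den > 0) 2 * sum(p * y) / den else 1
    }
  }
  loss <- alpha * loss_ce + (1 - alpha) * mean(1 - dice_vals)
  list(dZ = dZ, loss = loss, dice = mean(dice_vals))
}

# Cross-entropy loss/gradient for the classification logits [2, N].
clf_loss_grad <- function(lg, labels) {
  N <- ncol(lg)
  pc <- softmax_mat(lg)
  onehot <- rbind(1 - labels, labels)
  idx <- cbind(labels + 1L, seq_len(N))
  loss <- -mean(log(clamp(pc[idx], 1e-12, 1)))
  list(dlg = (pc - onehot) / N, loss = loss,
       acc = mean((pc[2, ] >= 0.5) == (labels == 1)))
}

# Load per-plane training tensors from a manifest.
# Returns lists: img (native matrices), mask (native 0/1), label (0/1).
plane_records <- function(manifest, dir, split, positives_only = FALSE) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (positives_only) rows <- rows[rows$has_bladder, , drop = FALSE]
  img <- list(); mask <- list(); label <- integer(0)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    for (pl in c("sagittal", "transverse")) {
      ip <- if (pl == "sagittal") r$path_sagittal else r$path_transverse
      mp <- if (pl == "sagittal") r$mask_sagittal else r$mask_transverse
      img[[length(img) + 1L]] <- read_png_u8(file.path(dir, ip))
      mask[[length(mask) + 1L]] <- (read_png_u8(file.path(dir, mp)) > 127) * 1L
      label <- c(label, as.integer(r$has_bladder))
    }
  }
  list(img = img, mask = mask, label = label)
}

#' Train one path of the multitask model (freeze/train stage)
#'
#' Stage 1 (`"segmentation"`): backbone + segmentation decoder train on
#' bladder-positive images under the combo loss; the classification head is
#' frozen. Stage 2 (`"classification"`): backbone and decoder are frozen
#' (run in inference mode, so even their normalization statistics are
#' untouched) and only the classification head trains under cross-entropy on
#' positive + negative images. Adam optimization, plateau learning-rate
#' reduction, early stopping with best-weight restoration; fully seeded.
#'
#' @param model an `echovol_model` (not modified; a trained clone is
#'   returned).
#' @param trainable_path `"segmentation"` or `"classification"`.
#' @param manifest dataset manifest from [make_dataset()].
#' @param dir dataset directory.
#' @param cfg a [train_config()].
#' @return list with `model` (trained clone) and `history` (one row per
#'   epoch: losses, metric, learning rate).
#' @export
train_stage <- function(model, trainable_path, manifest, dir,
                        cfg = train_config()) {
  trainable_path <- match.arg(trainable_path,
                              c("segmentation", "classification"))
  if (!all(c("split", "has_bladder") %in% names(manifest))) {
    stop_echovol("manifest lacks split/has_bladder columns", "echovol_data")
  }
  model <- clone_model(model)
  trainable <- path_layers(model, trainable_path)
  for (l in model_layers(model)) l$frozen <- TRUE
  for (l in trainable) l$frozen <- FALSE
  S <- model$config$input_size
  hist <- list()
  with_seed(cfg$seed, {
    if (trainable_path == "segmentation") {
      tr <- plane_records(manifest, dir, "train", positives_only = TRUE)
      va <- plane_records(manifest, dir, "val", positives_only = TRUE)
      if (length(tr$img) == 0) stop_echovol("no masks to train on", "echovol_data")
      prep <- function(rec) {
        list(img = lapply(rec$img, preprocess_image, target = S),
             mask = lapply(rec$mask, function(m) {
               matrix(as.integer(cpp_resize_nearest(m + 0, S, S) > 0.5), S, S)
             }))
      }
      trp <- prep(tr)
      vap <- prep(va)
      n_tr <- length(trp$img)
      lr <- cfg$learning_rate
      stopper <- make_early_stopper(cfg$patience)
      plateau <- make_early_stopper(cfg$lr_patience)
      best <- NULL
      best_loss <- Inf
      t_adam <- 0L
      for (epoch in seq_len(cfg$max_epochs)) {
        ord <- sample.int(n_tr)
        tl <- 0; nb <- 0
        for (b0 in seq(1, n_tr, by = cfg$batch_size)) {
          idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n_tr)]
          B <- length(idx)
          x <- array(0, c(S, S, 1L, B))
          y <- array(0, c(S, S, B))
          for (j in seq_len(B)) {
            aug <- augment_sample(trp$img[[idx[j]]], trp$mask[[idx[j]]],
                                  shift_range = cfg$intensity_shift_range / 255,
                                  flip_prob = cfg$lr_flip_prob, range = c(0, 1))
            x[, , 1, j] <- aug$image
            y[, , j] <- aug$mask
          }
          ctx <- make_ctx(training = TRUE, qat = cfg$qat_enabled)
          fwd <- model_forward(model, x, ctx)
          lg <- seg_loss_grad(fwd$seg_prob, y, cfg$alpha)
          model_backward(model, fwd, dZ = lg$dZ, dlg = NULL)
          t_adam <- t_adam + 1L
          adam_step(trainable, lr, t_adam)
          tl <- tl + lg$loss; nb <- nb + 1
        }
        ev <- evaluate_seg_epoch(model, vap, cfg)
        hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    train_loss = tl / nb,
                                    val_loss = ev$loss, val_metric = ev$dice)
        if (ev$loss < best_loss - 1e-10) {
          best_loss <- ev$loss
          best <- get_weights(model)
        }
        if (plateau(ev$loss, epoch)) {
          lr <- lr * cfg$lr_factor
          plateau <- make_early_stopper(cfg$lr_patience)
        }
        if (stopper(ev$loss, epoch)) break
      }
      if (!is.null(best)) set_weights(model, best)
    } else {
      tr <- plane_records(manifest, dir, "train")
      va <- plane_records(manifest, dir, "val")
      if (length(unique(tr$label)) < 2) {
        stop_echovol("classification stage needs positive and negative samples",
                     "echovol_data")
      }
      # Frozen backbone: features computed once in inference mode.
      feats <- function(rec, augment = FALSE) {
        n <- length(rec$img)
        g <- matrix(0, model$backbone$out_channels, n)
        ctx <- make_ctx(training = FALSE, qat = cfg$qat_enabled)
        bs <- 16L
        for (b0 in seq(1, n, by = bs)) {
          idx <- b0:min(b0 + bs - 1L, n)
          x <- array(0, c(S, S, 1L, length(idx)))
          for (j in seq_along(idx)) {
            im <- preprocess_image(rec$img[[idx[j]]], S)
            if (augment) {
              im <- augment_sample(im, NULL,
                                   shift_range = cfg$intensity_shift_range / 255,
                                   flip_prob = cfg$lr_flip_prob,
                                   range = c(0, 1))$image
            }
            x[, , 1, j] <- im
          }
          h <- x
          for (u in model$backbone$units) h <- unit_fwd(u, h, ctx)
          g[, idx] <- gap_f(h)
        }
        g
      }
      # clean + augmented feature copies broaden the head's training set
      gtr <- cbind(feats(tr), feats(tr, augment = TRUE))
      tr$label <- c(tr$label, tr$label)
      gva <- feats(va)
      lr <- cfg$learning_rate
      stopper <- make_early_stopper(cfg$patience)
      plateau <- make_early_stopper(cfg$lr_patience)
      best <- NULL
      best_loss <- Inf
      t_adam <- 0L
      n_tr <- ncol(gtr)
      for (epoch in seq_len(cfg$max_epochs)) {
        ord <- sample.int(n_tr)
        tl <- 0; nb <- 0
        for (b0 in seq(1, n_tr, by = max(cfg$batch_size, 16L))) {
          idx <- ord[b0:min(b0 + max(cfg$batch_size, 16L) - 1L, n_tr)]
          ctx <- make_ctx(training = TRUE, qat = cfg$qat_enabled)
          lgt <- dense_fwd(model$clf, gtr[, idx, drop = FALSE], ctx)
          lo <- clf_loss_grad(lgt, tr$label[idx])
          dense_bwd(model$clf, lo$dlg)
          t_adam <- t_adam + 1L
          adam_step(trainable, lr, t_adam)
          tl <- tl + lo$loss; nb <- nb + 1
        }
        ctxe <- make_ctx(training = FALSE, qat = cfg$qat_enabled)
        lgv <- dense_fwd(model$clf, gva, ctxe)
        ev <- clf_loss_grad(lgv, va$label)
        hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    train_loss = tl / nb,
                                    val_loss = ev$loss, val_metric = ev$acc)
        if (ev$loss < best_loss - 1e-10) {
          best_loss <- ev$loss
          best <- get_weights(model)
        }
        if (plateau(ev$loss, epoch)) {
          lr <- lr * cfg$lr_factor
          plateau <- make_early_stopper(cfg$lr_patience)
        }
        if (stopper(ev$loss, epoch)) break
      }
      if (!is.null(best)) set_weights(model, best)
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

# Validation-epoch segmentation metrics on preprocessed records.
evaluate_seg_epoch <- function(model, rec, cfg) {
  n <- length(rec$img)
  if (n == 0) return(list(loss = NA_real_, dice = NA_real_))
  S <- model$config$input_size
  ctx <- make_ctx(training = FALSE, qat = cfg$qat_enabled)
  tot_loss <- 0; tot_dice <- 0
  bs <- 8L
  for (b0 in seq(1, n, by = bs)) {
    idx <- b0:min(b0 + bs - 1L, n)
    x <- array(0, c(S, S, 1L, length(idx)))
    y <- array(0, c(S, S, length(idx)))
    for (j in seq_along(idx)) {
      x[, , 1, j] <- rec$img[[idx[j]]]
      y[, , j] <- rec$mask[[idx[j]]]
    }
    fwd <- model_forward(model, x, ctx)
    lg <- seg_loss_grad(fwd$seg_prob, y, cfg$alpha)
    tot_loss <- tot_loss + lg$loss * length(idx)
    for (j in seq_along(idx)) {
      pm <- (fwd$seg_prob[, , 2, j] > fwd$seg_prob[, , 1, j]) * 1
      tot_dice <- tot_dice + dice_coefficient(pm, y[, , j])
    }
  }
  list(loss = tot_loss / n, dice = tot_dice / n)
}

#' Merge stage-1 and stage-2 weights into a single model
#'
#' Backbone and segmentation-path weights are taken from the first model,
#' classification-head weights from the second. Because the paths are
#' disjoint, the merged model's segmentation output is bit-identical to the
#' stage-1 model's and its classification output bit-identical to the
#' stage-2 model's.
#'
#' @param stage1_model model after segmentation training.
#' @param stage2_model model after classification training.
#' @return merged `echovol_model`.
#' @export
merge_paths <- function(stage1_model, stage2_model) {
  w1 <- get_weights(stage1_model)
  w2 <- get_weights(stage2_model)
  if (!identical(names(w1), names(w2)) ||
      !identical(lapply(w1, dim), lapply(w2, dim))) {
    stop_echovol("stage models come from different graphs", "echovol_structure")
  }
  merged <- clone_model(stage1_model)
  for (key in grep("^clf/", names(w2), value = TRUE)) w1[[key]] <- w2[[key]]
  set_weights(merged, w1)
  merged
}

#' Run the full three-stage training procedure
#'
#' Stage 1 trains backbone + segmentation path (classification frozen),
#' stage 2 freezes them and trains the classification head, stage 3 merges
#' the two weight sets into one model.
#'
#' @param manifest dataset manifest.
#' @param dir dataset directory.
#' @param model_cfg a [model_config()].
#' @param cfg a [train_config()].
#' @return list with `model` (merged), `stage1`, `stage2` (models +
#'   histories).
#' @export
train_pipeline <- function(manifest, dir, model_cfg = model_config(),
                           cfg = train_config()) {
  base <- build_model(model_cfg, seed = cfg$seed)
  s1 <- train_stage(base, "segmentation", manifest, dir, cfg)
  s2 <- train_stage(s1$model, "classification", manifest, dir, cfg)
  merged <- merge_paths(s1$model, s2$model)
  list(model = merged, stage1 = s1, stage2 = s2)
}
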