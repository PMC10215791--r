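test_that("combo loss matches its closed forms and degenerate limits", {
  # perfect prediction
  gt <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(combo_loss(gt, gt, 0.5), 0, tolerance = 1e-9)
  # single pixel, p = 0.5, y = 1, alpha = 0.5:
  # 0.5 * (-ln 0.5) + 0.5 * (1 - 2*0.5/1.5) = 0.34657 + 0.16667
  expect_equal(combo_loss(0.5, 1, 0.5), 0.5132, tolerance = 1e-4)
  expect_error(combo_loss(numeric(0), numeric(0)),
               class = "echovol_invalid_argument")

  # alpha limits against independently computed CE / soft-Dice
  set.seed(1)
  for (i in 1:10) {
    p <- matrix(runif(64, 0.01, 0.99), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    ce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
    dice <- 2 * sum(p * y) / (sum(p) + sum(y))
    expect_equal(combo_loss(p, y, 1), ce, tolerance = 1e-10)
    expect_equal(combo_loss(p, y, 0), 1 - dice, tolerance = 1e-10)
    expect_equal(combo_loss(p, y, 0.3), 0.3 * ce + 0.7 * (1 - dice),
                 tolerance = 1e-10)
  }
})

test_that("augmentation is an involution and respects its switches", {
  img <- matrix(50, 20, 30)
  msk <- matrix(0L, 20, 30); msk[5:10, 4:9] <- 1L
  set.seed(2)
  a <- augment_sample(img, msk, shift_range = 0, flip_prob = 1)
  b <- augment_sample(a$image, a$mask, shift_range = 0, flip_prob = 1)
  expect_identical(b$image, img)
  expect_identical(b$mask, msk)

  s <- augment_sample(img, msk, shift_range = 0, flip_prob = 0)
  expect_identical(s$image, img)
  # a pure +10 shift leaves the mask untouched
  set.seed(3)
  repeat {
    sh <- augment_sample(img, msk, shift_range = 10, flip_prob = 0)
    if (!sh$flipped) break
  }
  expect_equal(sh$image, img + sh$shift, tolerance = 1e-12)
  expect_identical(sh$mask, msk)
})

test_that("early stopping triggers after `patience` stagnant epochs", {
  stop1 <- echovol:::make_early_stopper(1)
  expect_false(stop1(1.0, 1))          # first epoch improves
  expect_true(stop1(1.2, 2))           # worsens from epoch 2 -> stop there
  stop3 <- echovol:::make_early_stopper(3)
  expect_false(stop3(1.0, 1))
  expect_false(stop3(1.1, 2))
  expect_false(stop3(1.05, 3))
  expect_true(stop3(1.0, 4))
})

test_that("training a stage leaves the frozen path bit-identical", {
  ds <- tiny_dataset()
  cfg <- train_config(seed = 7, max_epochs = 2, batch_size = 4)
  base <- build_model(tiny_model_config(), seed = 7)
  w0 <- get_weights(base)

  s1 <- train_stage(base, "segmentation", ds$manifest, ds$dir, cfg)
  w1 <- get_weights(s1$model)
  clf_keys <- grep("^clf/", names(w1), value = TRUE)
  expect_identical(w1[clf_keys], w0[clf_keys])         # clf head frozen
  seg_keys <- grep("^(bb|qse|cv|merge|reduce)", names(w1), value = TRUE)
  expect_false(identical(w1[seg_keys], w0[seg_keys]))  # seg path moved

  s2 <- train_stage(s1$model, "classification", ds$manifest, ds$dir, cfg)
  w2 <- get_weights(s2$model)
  expect_identical(w2[seg_keys], w1[seg_keys])         # backbone+seg frozen
  expect_false(identical(w2[clf_keys], w1[clf_keys]))
  expect_named(s1$history,
               c("epoch", "lr", "train_loss", "val_loss", "val_metric"))
})

test_that("the synthetic segmentation task is learnable from 32 samples", {
  dir <- file.path(tempdir(), "echovol_smoke_ds")
  unlink(dir, recursive = TRUE)
  mf <- make_dataset(16, 4, 0, 0, volume_range = c(10, 30), master_seed = 31,
                     out_dir = dir, cfg = tiny_imaging_config())
  cfg <- train_config(seed = 13, max_epochs = 30, batch_size = 4,
                      patience = 30, learning_rate = 3e-3)
  base <- build_model(model_config(input_size = 48, width = 0.5), seed = 13)
  fit <- train_stage(base, "segmentation", mf, dir, cfg)
  # evaluate Dice on the 32 training images with the trained model
  rec <- echovol:::plane_records(mf, dir, "train", positives_only = TRUE)
  S <- 48L
  prep <- list(
    img = lapply(rec$img, preprocess_image, target = S),
    mask = lapply(rec$mask, function(m) {
      matrix(as.integer(echovol:::cpp_resize_nearest(m + 0, S, S) > 0.5), S, S)
    }))
  ev <- echovol:::evaluate_seg_epoch(fit$model, prep, cfg)
  expect_gt(ev$dice, 0.8)
  unlink(dir, recursive = TRUE)
})

test_that("training histories are reproducible under a fixed seed", {
  ds <- tiny_dataset()
  cfg <- train_config(seed = 99, max_epochs = 2, batch_size = 4)
  base <- build_model(tiny_model_config(), seed = 99)
  h1 <- train_stage(base, "segmentation", ds$manifest, ds$dir, cfg)$history
  h2 <- train_stage(base, "segmentation", ds$manifest, ds$dir, cfg)$history
  expect_identical(h1, h2)
})

test_that("merging takes each path from its own stage verbatim", {
  ds <- tiny_dataset()
  cfg <- train_config(seed = 21, max_epochs = 1, batch_size = 4)
  base <- build_model(tiny_model_config(), seed = 21)
  s1 <- train_stage(base, "segmentation", ds$manifest, ds$dir, cfg)
  s2 <- train_stage(s1$model, "classification", ds$manifest, ds$dir, cfg)
  merged <- merge_paths(s1$model, s2$model)

  # idempotence
  mm <- merge_paths(s1$model, s1$model)
  expect_identical(get_weights(mm), get_weights(s1$model))

  # path disjointness on fixed inputs
  set.seed(22)
  for (i in 1:10) {
    img <- matrix(runif(120 * 160, 0, 255), 120, 160)
    expect_identical(predict_segmentation(merged, img),
                     predict_segmentation(s1$model, img))
    expect_identical(predict_detection(merged, img),
                     predict_detection(s2$model, img))
  }

  other <- build_model(model_config(input_size = 48, width = 0.5), seed = 1)
  expect_error(merge_paths(s1$model, other), class = "echovol_structure")
})

test_that("fake quantization is an exact idempotent int8 projection", {
  w <- c(-1, 0, 1)
  expect_equal(fake_quantize(w), w, tolerance = 1e-15)   # grid-representable
  expect_identical(fake_quantize(rep(0, 5)), rep(0, 5))
  set.seed(30)
  x <- array(rnorm(100), c(10, 10))
  q1 <- fake_quantize(x)
  expect_identical(fake_quantize(q1), q1)                # projection
  expect_lte(length(unique(as.vector(q1))), 255L)
  expect_lt(max(abs(q1 - x)), max(abs(x)) / 127 * 0.5 + 1e-12)
})

test_that("degenerate activation ranges fall back to scale 1 with a warning", {
  expect_warning(echovol:::quantize_affine(c(0, 0, 0), 0, 0),
                 class = "echovol_degenerate_scale")
})

test_that("batch-norm folding preserves the float model outputs", {
  ds <- tiny_dataset()
  cfg <- train_config(seed = 41, max_epochs = 2, batch_size = 4)
  base <- build_model(tiny_model_config(), seed = 41)
  s1 <- train_stage(base, "segmentation", ds$manifest, ds$dir, cfg)
  folded <- echovol:::fold_batchnorm(s1$model)
  img <- load_sample(ds$manifest, 1, ds$dir)$sagittal_image
  f1 <- echovol:::model_infer(s1$model, list(img))
  f2 <- echovol:::model_infer(folded, list(img))
  expect_equal(f1$seg_prob, f2$seg_prob, tolerance = 1e-8)
  expect_equal(f1$clf_prob, f2$clf_prob, tolerance = 1e-8)
})

test_that("8-bit quantization keeps segmentation quality on the tiny task", {
  ds <- tiny_dataset()
  cfg <- train_config(seed = 51, max_epochs = 4, batch_size = 4)
  base <- build_model(tiny_model_config(), seed = 51)
  s1 <- train_stage(base, "segmentation", ds$manifest, ds$dir, cfg)
  va <- ds$manifest[ds$manifest$split == "val" & ds$manifest$has_bladder, ]
  calib <- lapply(seq_len(nrow(va)), function(i)
    load_sample(va, i, ds$dir)$sagittal_image)
  qm <- quantize_model(s1$model, calib)
  expect_s3_class(qm, "echovol_qmodel")
  expect_true(qm$quantized)
  # integer codes are within the signed 8-bit range
  for (l in echovol:::model_layers(qm)) {
    if (!is.null(l$W_codes)) {
      expect_true(all(l$W_codes >= -127 & l$W_codes <= 127))
    }
  }
  df <- dq <- c()
  for (i in seq_len(nrow(va))) {
    smp <- load_sample(va, i, ds$dir)
    df <- c(df, dice_coefficient(
      predict_segmentation(s1$model, smp$sagittal_image), smp$sagittal_mask))
    dq <- c(dq, dice_coefficient(
      predict_segmentation(qm, smp$sagittal_image), smp$sagittal_mask))
  }
  expect_gte(mean(dq), mean(df) - 0.02)
  # model round-trips through its serialized container
  p <- tempfile(fileext = ".bin")
  save_model(qm, p)
  qm2 <- load_model(p)
  expect_identical(predict_segmentation(qm2, calib[[1]]),
                   predict_segmentation(qm, calib[[1]]))
  expect_error(quantize_model(s1$model, list()),
               class = "echovol_invalid_argument")
})
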