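#' Pipeline configuration
#'
#' One container tying together the per-stage settings and a single global
#' seed that fans out deterministically to per-stage seeds. Round-trips
#' losslessly through YAML.
#'
#' @param data_dir,model_dir,report_dir stage artifact directories.
#' @param simulator list of [imaging_config()] overrides.
#' @param train a [train_config()].
#' @param quant a [quant_spec()].
#' @param measurement list with `shape_label` and `spacing` defaults.
#' @param seed global seed.
#' @param log_level log verbosity tag.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir = "data", model_dir = "models",
                            report_dir = "reports", simulator = list(),
                            train = train_config(), quant = quant_spec(),
                            measurement = list(shape_label = "unknown",
                                               spacing = 0.35),
                            seed = 1L, log_level = "info") {
  structure(list(data_dir = data_dir, model_dir = model_dir,
                 report_dir = report_dir, simulator = simulator,
                 train = unclass(train), quant = unclass(quant),
                 measurement = measurement, seed = as.integer(seed),
                 log_level = log_level), class = "pipeline_config")
}

#' Deterministic per-stage seeds from the global pipeline seed
#' @param seed global seed.
#' @return named integer vector with `simulate`, `train`, `quantize`,
#'   `measure`, `evaluate` seeds.
#' @export
fan_out_seeds <- function(seed) {
  s <- derive_seeds(seed, 5)
  stats::setNames(s, c("simulate", "train", "quantize", "measure", "evaluate"))
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "pipeline_config")
}

#' Run the full reference study on synthetic phantoms
#'
#' The package's end-to-end protocol: simulate a seeded biplane dataset (256
#' positive + 256 negative training images, i.e. 128 + 128 image pairs, and
#' a 32 + 32 pair validation split), train the segmentation stage and the
#' classification stage with quantization-aware training, merge, quantize to
#' 8 bits, and evaluate: float-vs-quantized validation Dice, detection
#' accuracy, and automatic volume measurement of 30 spherical phantoms (10
#' each at 50 / 150 / 300 mL, spherical coefficient 0.52), both with the
#' trained model and with ground-truth masks injected (isolating the
#' geometric estimator from the learned segmentation).
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param dir working directory for stage artifacts.
#' @param seg_epochs,clf_epochs epoch caps for the two training stages.
#' @param n_train_pairs,n_val_pairs positive (and negative) image-pair
#'   counts for the train / validation splits.
#' @param keep_artifacts keep the dataset and model files under `dir`.
#' @return list of study metrics (see the acceptance script for the full
#'   set).
#' @export
run_reference_study <- function(seed = 1L, dir = tempfile("echovol_ref"),
                                seg_epochs = 8L, clf_epochs = 60L,
                                n_train_pairs = 128L, n_val_pairs = 32L,
                                keep_artifacts = FALSE) {
  seeds <- fan_out_seeds(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  mf <- make_dataset(n_train_pairs, n_val_pairs, n_train_pairs, n_val_pairs,
                     master_seed = seeds[["simulate"]], out_dir = dir)
  log_stage("simulate", seeds[["simulate"]], t0, rows = nrow(mf))

  cfg_seg <- train_config(seed = seeds[["train"]], max_epochs = seg_epochs,
                          batch_size = 4L)
  # the head-only stage is cheap: train its full epoch budget and keep the
  # best-validation-loss weights rather than stopping early
  cfg_clf <- train_config(seed = seeds[["train"]] + 1L,
                          max_epochs = clf_epochs, patience = clf_epochs)
  base <- build_model(model_config(), seed = seeds[["train"]])
  t1 <- as.numeric(Sys.time())
  s1 <- train_stage(base, "segmentation", mf, dir, cfg_seg)
  log_stage("train_seg", seeds[["train"]], t1,
            val_dice = round(utils::tail(s1$history$val_metric, 1), 4))
  t2 <- as.numeric(Sys.time())
  s2 <- train_stage(s1$model, "classification", mf, dir, cfg_clf)
  log_stage("train_clf", seeds[["train"]], t2,
            val_acc = round(utils::tail(s2$history$val_metric, 1), 4))
  model <- merge_paths(s1$model, s2$model)

  # calibration: a mixed slice of training images
  tr_rows <- mf[mf$split == "train", , drop = FALSE]
  tr_rows <- tr_rows[order(!tr_rows$has_bladder), , drop = FALSE]
  pick <- unique(round(seq(1, nrow(tr_rows), length.out = 16)))
  calib <- list()
  for (i in pick) {
    calib[[length(calib) + 1L]] <-
      read_png_u8(file.path(dir, tr_rows$path_sagittal[i]))
    calib[[length(calib) + 1L]] <-
      read_png_u8(file.path(dir, tr_rows$path_transverse[i]))
  }
  qmodel <- quantize_model(model, calib)

  # float vs quantized Dice + detection accuracy on the validation split
  va <- mf[mf$split == "val", , drop = FALSE]
  dice_f <- numeric(0); dice_q <- numeric(0)
  pred <- integer(0); truth <- integer(0)
  for (i in seq_len(nrow(va))) {
    smp <- load_sample(va, i, dir)
    for (pl in c("sagittal", "transverse")) {
      img <- if (pl == "sagittal") smp$sagittal_image else smp$transverse_image
      gt <- if (pl == "sagittal") smp$sagittal_mask else smp$transverse_mask
      if (va$has_bladder[i]) {
        dice_f <- c(dice_f, dice_coefficient(predict_segmentation(model, img), gt))
        dice_q <- c(dice_q, dice_coefficient(predict_segmentation(qmodel, img), gt))
      }
      pred <- c(pred, as.integer(predict_detection(qmodel, img)$has_bladder))
      truth <- c(truth, as.integer(va$has_bladder[i]))
    }
  }
  clf_rep <- classification_report(pred, truth)

  # volume measurement: 30 spherical phantoms, 10 per nominal volume
  vols <- rep(c(50, 150, 300), each = 10)
  t3 <- as.numeric(Sys.time())
  meas_model <- measure_phantoms(vols, model = qmodel,
                                 shape_label = "spherical",
                                 seed = seeds[["measure"]])
  meas_oracle <- measure_phantoms(vols, model = NULL,
                                  shape_label = "spherical",
                                  seed = seeds[["measure"]])
  log_stage("measure", seeds[["measure"]], t3,
            detected = sum(meas_model$detected_sagittal &
                             meas_model$detected_transverse))
  if (!keep_artifacts) unlink(dir, recursive = TRUE)
  list(
    manifest_rows = nrow(mf),
    param_count = as.integer(count_parameters(model)),
    history_seg = s1$history,
    history_clf = s2$history,
    dice_float = mean(dice_f),
    dice_quant = mean(dice_q),
    dice_drop = mean(dice_f) - mean(dice_q),
    clf_accuracy = clf_rep$accuracy,
    confusion = clf_rep$confusion,
    vol_model = meas_model,
    vol_oracle = meas_oracle,
    median_abs_err_model = median(abs(meas_model$error_pct), na.rm = TRUE),
    median_abs_err_oracle = median(abs(meas_oracle$error_pct), na.rm = TRUE),
    detection_rate = mean(meas_model$detected_sagittal &
                            meas_model$detected_transverse)
  )
}
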