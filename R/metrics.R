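#' Dice overlap coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param pred_mask,gt_mask binary matrices of equal shape.
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop_echovol("mask shapes differ", "echovol_invalid_argument")
  }
  a <- pred_mask > 0
  b <- gt_mask > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Confusion matrix and accuracy for bladder detection
#'
#' @param pred_labels,true_labels 0/1 vectors (1 = bladder) of equal length.
#' @return list with `confusion` (2 x 2 integer matrix, rows = truth,
#'   columns = prediction), `accuracy`, and `n`.
#' @export
classification_report <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    stop_echovol("label vectors differ in length", "echovol_invalid_argument")
  }
  if (!all(pred_labels %in% c(0, 1)) || !all(true_labels %in% c(0, 1))) {
    stop_echovol("labels must be 0 (no bladder) or 1 (bladder)",
                 "echovol_invalid_argument")
  }
  lv <- c(0, 1)
  confusion <- table(factor(true_labels, levels = lv),
                     factor(pred_labels, levels = lv))
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(truth = c("no_bladder", "bladder"),
                                      prediction = c("no_bladder", "bladder")))
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / length(true_labels),
       n = length(true_labels))
}

#' Signed percent volume error
#'
#' @param measured measured volume (mL).
#' @param nominal reference volume (mL, > 0).
#' @return `100 * (measured - nominal) / nominal`.
#' @export
volume_error_pct <- function(measured, nominal) {
  if (any(nominal <= 0)) {
    stop_echovol("nominal volume must be positive", "echovol_invalid_argument")
  }
  100 * (measured - nominal) / nominal
}

#' Evaluate a model over a dataset manifest
#'
#' Aggregates segmentation Dice (mean and per-image standard deviation over
#' bladder-positive images on the native grid), the detection confusion
#' matrix and accuracy over all per-plane images, and per-phantom mean
#' volume errors over `n_repeats` independently re-rendered image pairs.
#'
#' @param manifest dataset manifest.
#' @param dir dataset directory.
#' @param model trained model, or `NULL` for a ground-truth oracle run.
#' @param shape_label,coefficient volume-estimation settings.
#' @param n_repeats independent renders per phantom for the volume protocol.
#' @param seed seed for the re-renders.
#' @param split manifest split to evaluate (`"val"` by default).
#' @return an `eval_report` list: `dice_mean`, `dice_sd`, `confusion`,
#'   `accuracy`, `volume_errors_pct` (per phantom), `n_samples`.
#' @export
evaluate_run <- function(manifest, dir, model = NULL,
                         shape_label = "unknown", coefficient = NULL,
                         n_repeats = 5L, seed = 1L, split = "val") {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_echovol("manifest has no rows for the requested split",
                 "echovol_data")
  }
  dices <- numeric(0)
  pred_lab <- integer(0)
  true_lab <- integer(0)
  for (i in seq_len(nrow(rows))) {
    smp <- load_sample(rows, i, dir)
    for (pl in c("sagittal", "transverse")) {
      img <- if (pl == "sagittal") smp$sagittal_image else smp$transverse_image
      gt <- if (pl == "sagittal") smp$sagittal_mask else smp$transverse_mask
      truth <- as.integer(smp$has_bladder[[pl]])
      if (is.null(model)) {
        pred <- truth
        pm <- gt
      } else {
        pred <- as.integer(predict_detection(model, img)$has_bladder)
        pm <- if (truth == 1L) predict_segmentation(model, img) else NULL
      }
      pred_lab <- c(pred_lab, pred)
      true_lab <- c(true_lab, truth)
      if (truth == 1L) dices <- c(dices, dice_coefficient(pm, gt))
    }
  }
  rep_cls <- classification_report(pred_lab, true_lab)
  pos <- rows[rows$has_bladder, , drop = FALSE]
  vol_err <- numeric(0)
  if (nrow(pos) > 0) {
    seeds <- derive_seeds(seed, nrow(pos) * n_repeats)
    sim_yaml <- file.path(dir, "simulator.yaml")
    cfg <- if (file.exists(sim_yaml)) {
      y <- yaml::read_yaml(sim_yaml)
      imaging_config(grid_height = y$grid_height, grid_width = y$grid_width,
                     pixel_spacing = y$pixel_spacing,
                     sector_angle = y$sector_angle, sector = y$sector,
                     plane_jitter = 0)
    } else {
      imaging_config(pixel_spacing = pos$spacing_mm[1], plane_jitter = 0)
    }
    k <- 0L
    for (i in seq_len(nrow(pos))) {
      smp <- load_sample(pos, i, dir)
      errs <- numeric(0)
      for (r in seq_len(n_repeats)) {
        k <- k + 1L
        cfg$seed <- seeds[k]
        rs <- tryCatch(render_biplane(smp$phantom, cfg),
                       echovol_out_of_view = function(e) NULL)
        if (is.null(rs)) next
        est <- auto_measure(rs, model = model, shape_label = shape_label,
                            coefficient = coefficient)
        if (!is.na(est$volume_mL)) {
          errs <- c(errs, volume_error_pct(est$volume_mL,
                                           smp$phantom$true_volume / 1000))
        }
      }
      vol_err <- c(vol_err, if (length(errs)) mean(errs) else NA_real_)
    }
  }
  structure(list(
    dice_mean = if (length(dices)) mean(dices) else NA_real_,
    dice_sd = if (length(dices) > 1) sd(dices) else NA_real_,
    confusion = rep_cls$confusion,
    accuracy = rep_cls$accuracy,
    volume_errors_pct = vol_err,
    n_samples = rep_cls$n
  ), class = "eval_report")
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON and, optionally, the confusion matrix as CSV.
#'
#' @param report an `eval_report`.
#' @param json_path output JSON path.
#' @param confusion_csv optional CSV path for the confusion matrix.
#' @export
write_eval_report <- function(report, json_path, confusion_csv = NULL) {
  out <- unclass(report)
  out$confusion <- as.data.frame(as.table(report$confusion))
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(confusion_csv)) {
    write.csv(as.data.frame(report$confusion), confusion_csv)
  }
  invisible(json_path)
}
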