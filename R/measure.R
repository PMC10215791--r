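#' Shape-coefficient table for bladder volume estimation
#'
#' Empirical multipliers converting the product depth x height x width into
#' a volume, indexed by assumed bladder shape: unknown 0.72, triangular
#' prism 0.66, cylinder 0.81, cuboid 0.89, spherical 0.52.
#'
#' @return named numeric vector of coefficients (all in (0, 1]).
#' @export
shape_coefficients <- function() {
  c(unknown = 0.72, triangular_prism = 0.66, cylinder = 0.81,
    cuboid = 0.89, spherical = 0.52)
}

#' Keep only the largest 8-connected foreground component
#'
#' @param mask binary matrix.
#' @return binary matrix with all but the largest component removed; an
#'   empty mask is returned unchanged.
#' @export
largest_region <- function(mask) {
  m <- (mask > 0) * 1
  if (sum(m) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- label_components8(m)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}

# 8-connected component labelling: 4-connected labels from EBImage::bwlabel,
# then diagonally adjacent labels merged by union-find.
label_components8 <- function(m) {
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  k <- max(lab)
  if (k <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Minimum-area rotated bounding rectangle of a mask
#'
#' Rotating-calipers search over the convex hull of the foreground pixel
#' centres. Corners are ordered clockwise (in image coordinates, y down)
#' starting from the topmost, then leftmost corner.
#'
#' @param mask binary matrix.
#' @param rotated if `FALSE`, return the axis-aligned bounding box instead.
#' @return 4 x 2 matrix of corner coordinates, columns `(x, y)` =
#'   (column, row).
#' @export
min_area_bbox <- function(mask, rotated = TRUE) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_echovol("mask contains no foreground region", "echovol_no_region")
  }
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  if (!rotated) {
    r <- range(pts[, 2]); c <- range(pts[, 1])
    corners <- cbind(x = c(c[1], c[2], c[2], c[1]),
                     y = c(r[1], r[1], r[2], r[2]))
    return(corners)
  }
  hull <- pts[unique(grDevices::chull(pts)), , drop = FALSE]
  if (nrow(hull) < 3) {
    r <- range(pts[, 2]); c <- range(pts[, 1])
    return(cbind(x = c(c[1], c[2], c[2], c[1]),
                 y = c(r[1], r[1], r[2], r[2])))
  }
  nh <- nrow(hull)
  best <- NULL
  best_area <- Inf
  for (e in seq_len(nh)) {
    p1 <- hull[e, ]
    p2 <- hull[if (e == nh) 1L else e + 1L, ]
    th <- atan2(p2[2] - p1[2], p2[1] - p1[1])
    ct <- cos(-th); st <- sin(-th)
    rx <- hull[, 1] * ct - hull[, 2] * st
    ry <- hull[, 1] * st + hull[, 2] * ct
    area <- diff(range(rx)) * diff(range(ry))
    if (area < best_area) {
      best_area <- area
      xr <- range(rx); yr <- range(ry)
      cc <- cbind(c(xr[1], xr[2], xr[2], xr[1]),
                  c(yr[1], yr[1], yr[2], yr[2]))
      ct2 <- cos(th); st2 <- sin(th)
      best <- cbind(x = cc[, 1] * ct2 - cc[, 2] * st2,
                    y = cc[, 1] * st2 + cc[, 2] * ct2)
    }
  }
  cx <- mean(best[, 1]); cy <- mean(best[, 2])
  ord <- order(atan2(best[, 2] - cy, best[, 1] - cx))
  best <- best[ord, , drop = FALSE]          # clockwise in image coords
  start <- order(round(best[, 2], 6), round(best[, 1], 6))[1]
  best <- best[((seq_len(4) + start - 2L) %% 4L) + 1L, , drop = FALSE]
  rownames(best) <- NULL
  best
}

# Chord of the region along the segment p1 -> p2: distance between the first
# and last sampled point falling on foreground pixels.
segment_chord <- function(mask, p1, p2) {
  len <- sqrt(sum((p2 - p1)^2))
  nsamp <- max(2L, as.integer(ceiling(len * 8)))
  t <- seq(0, 1, length.out = nsamp)
  xs <- p1[1] + t * (p2[1] - p1[1])
  ys <- p1[2] + t * (p2[2] - p1[2])
  jj <- pmin(pmax(round(xs), 1), ncol(mask))
  ii <- pmin(pmax(round(ys), 1), nrow(mask))
  inside <- mask[cbind(ii, jj)] > 0
  if (!any(inside)) return(list(chord = 0, npix = 0L))
  f <- which(inside)[1]
  l <- which(inside)[length(which(inside))]
  npix <- length(unique(paste(ii[inside], jj[inside])))
  list(chord = sqrt((xs[l] - xs[f])^2 + (ys[l] - ys[f])^2),
       npix = as.integer(npix))
}

#' Bladder depth from a sagittal-plane mask
#'
#' The minimum-area rotated bounding box of the (largest-component) region
#' is computed; along each of its two diagonals the chord between the first
#' and last intersection with the region is measured, and the greater chord,
#' scaled to millimetres, is the depth.
#'
#' @param mask binary sagittal mask.
#' @param spacing pixel spacing in mm/px.
#' @param rotated use the rotated minimum-area box (default) or the
#'   axis-aligned box.
#' @return depth in mm.
#' @export
depth_from_sagittal <- function(mask, spacing, rotated = TRUE) {
  m <- largest_region(mask)
  if (sum(m) == 0) {
    stop_echovol("mask contains no foreground region", "echovol_no_region")
  }
  bb <- min_area_bbox(m, rotated = rotated)
  ch1 <- segment_chord(m, bb[1, ], bb[3, ])   # diagonal from top-left corner
  ch2 <- segment_chord(m, bb[2, ], bb[4, ])
  if (max(ch1$npix, ch2$npix) < 2L) {
    stop_echovol("diagonal intersects the region in fewer than 2 pixels",
                 "echovol_degenerate_region")
  }
  chord_px <- if (ch1$chord >= ch2$chord) ch1$chord else ch2$chord
  chord_px * spacing
}

#' Bladder height and width from a transverse-plane mask
#'
#' Height is the maximum vertical first-to-last foreground extent over image
#' columns; width the maximum horizontal extent over rows; both scaled to
#' millimetres.
#'
#' @param mask binary transverse mask.
#' @param spacing pixel spacing in mm/px.
#' @return named numeric vector `c(height = , width = )` in mm.
#' @export
height_width_from_transverse <- function(mask, spacing) {
  m <- largest_region(mask)
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_echovol("mask contains no foreground region", "echovol_no_region")
  }
  col_ext <- tapply(idx[, 1], idx[, 2], function(v) diff(range(v)) + 1)
  row_ext <- tapply(idx[, 2], idx[, 1], function(v) diff(range(v)) + 1)
  c(height = max(col_ext) * spacing, width = max(row_ext) * spacing)
}

#' Axis measurements container
#'
#' @param depth,height,width axis lengths in mm (all > 0).
#' @param spacing source pixel spacing in mm/px (metadata).
#' @return an `axis_measurements` object.
#' @export
axis_measurements <- function(depth, height, width, spacing = NA_real_) {
  if (any(c(depth, height, width) <= 0)) {
    stop_echovol("axis measurements must be positive", "echovol_invalid_argument")
  }
  structure(list(depth = depth, height = height, width = width,
                 spacing = spacing), class = "axis_measurements")
}

#' Estimate bladder volume from axis measurements and a shape coefficient
#'
#' `volume (mL) = c x depth x height x width` with the axes converted to cm.
#'
#' @param axes an [axis_measurements()] object (mm).
#' @param shape_label one of `names(shape_coefficients())`.
#' @param coefficient explicit coefficient overriding the table lookup.
#' @return a `volume_estimate` object with fields `volume_mL`,
#'   `coefficient`, `shape_label`, `axes`, `detected`.
#' @export
estimate_volume <- function(axes, shape_label = "unknown",
                            coefficient = NULL) {
  stopifnot(inherits(axes, "axis_measurements"))
  if (is.null(coefficient)) {
    tab <- shape_coefficients()
    if (!shape_label %in% names(tab)) {
      stop_echovol(sprintf("unknown shape label '%s'; valid labels: %s",
                           shape_label, paste(names(tab), collapse = ", ")),
                   "echovol_lookup")
    }
    coefficient <- unname(tab[shape_label])
  }
  vol <- coefficient * (axes$depth / 10) * (axes$height / 10) * (axes$width / 10)
  structure(list(volume_mL = vol, coefficient = coefficient,
                 shape_label = shape_label, axes = axes,
                 detected = c(sagittal = TRUE, transverse = TRUE)),
            class = "volume_estimate")
}

#' Fully automatic biplane volume measurement
#'
#' Runs bladder detection on both planes; if either plane is negative no
#' volume is emitted (the segmentation of a bladder-free image is invalid by
#' construction). Otherwise both planes are segmented, reduced to their
#' largest component, depth is extracted from the sagittal plane, height and
#' width from the transverse plane, and the coefficient-scaled volume is
#' returned.
#'
#' @param sample a `biplane_sample`.
#' @param model a trained (optionally quantized) `echovol_model`, or `NULL`
#'   to use the sample's ground-truth masks and labels (oracle mode,
#'   isolating the geometry from the learned segmentation).
#' @param shape_label,coefficient see [estimate_volume()].
#' @param spacing mm/px; defaults to the sample's spacing.
#' @return a `volume_estimate`; `volume_mL` is `NA` when detection is
#'   negative on either plane.
#' @export
auto_measure <- function(sample, model = NULL, shape_label = "unknown",
                         coefficient = NULL, spacing = sample$spacing) {
  stopifnot(inherits(sample, "biplane_sample"))
  if (is.null(model)) {
    det <- sample$has_bladder
    mask_s <- sample$sagittal_mask
    mask_t <- sample$transverse_mask
  } else {
    det <- c(sagittal = predict_detection(model, sample$sagittal_image)$has_bladder,
             transverse = predict_detection(model, sample$transverse_image)$has_bladder)
    mask_s <- mask_t <- NULL
  }
  if (!all(det)) {
    return(structure(list(volume_mL = NA_real_, coefficient = coefficient,
                          shape_label = shape_label, axes = NULL,
                          detected = det), class = "volume_estimate"))
  }
  if (!is.null(model)) {
    mask_s <- predict_segmentation(model, sample$sagittal_image)
    mask_t <- predict_segmentation(model, sample$transverse_image)
  }
  with_plane <- function(plane, expr) {
    tryCatch(expr, echovol_error = function(e) {
      stop_echovol(sprintf("%s plane: %s", plane, conditionMessage(e)),
                   class(e)[1])
    })
  }
  depth <- with_plane("sagittal", depth_from_sagittal(mask_s, spacing))
  hw <- with_plane("transverse", height_width_from_transverse(mask_t, spacing))
  est <- estimate_volume(
    axis_measurements(depth, hw["height"], hw["width"], spacing),
    shape_label = shape_label, coefficient = coefficient)
  est$detected <- det
  est
}

# Centre a phantom on the probe axis at a depth where it fits both the grid
# and the imaging sector (emulating deliberate probe placement during a
# volume measurement).
place_phantom_center <- function(phantom, cfg, margin = 2) {
  r <- max(phantom$semi_axes)
  depth <- cfg$grid_height * cfg$pixel_spacing
  lo <- if (cfg$sector) {
    t <- tan(cfg$sector_angle / 2 * pi / 180)
    r * sqrt(1 + 1 / t^2) + margin
  } else r + margin
  hi <- depth - r - margin
  if (lo > hi) {
    stop_echovol(sprintf(
      "phantom too large for the field of view (semi-axis %.1f mm)", r),
      "echovol_out_of_view")
  }
  phantom$center <- c(0, 0, (lo + hi) / 2)
  phantom
}

#' Measure a series of simulated phantoms
#'
#' Renders `n_repeats` independent biplane images of a spherical (or
#' eccentric) phantom per requested volume and measures each with
#' [auto_measure()].
#'
#' @param volumes_mL vector of phantom volumes.
#' @param model model for inference, or `NULL` for ground-truth-mask oracle
#'   measurements.
#' @param shape_label,coefficient passed to [auto_measure()].
#' @param n_repeats renders per phantom.
#' @param seed master seed.
#' @param cfg [imaging_config()] used for rendering (plane jitter disabled
#'   by default so the planes cut the phantom centre).
#' @param eccentricity_range passed to [sample_phantom()]; `c(1, 1)` forces
#'   spheres.
#' @return data.frame with one row per phantom x repeat: nominal and
#'   measured volume, signed percent error, detection flags.
#' @export
measure_phantoms <- function(volumes_mL, model = NULL,
                             shape_label = "spherical", coefficient = NULL,
                             n_repeats = 1L, seed = 1L,
                             cfg = imaging_config(plane_jitter = 0),
                             eccentricity_range = c(1, 1)) {
  seeds <- derive_seeds(seed, length(volumes_mL) * (n_repeats + 1L))
  out <- list()
  k <- 0L
  for (i in seq_along(volumes_mL)) {
    ph <- sample_phantom(volumes_mL[i], eccentricity_range,
                         rng_seed = seeds[(i - 1L) * (n_repeats + 1L) + 1L],
                         center_mm = c(0, 0, 0))
    ph <- place_phantom_center(ph, cfg)
    for (r in seq_len(n_repeats)) {
      k <- k + 1L
      cfg_i <- cfg
      cfg_i$seed <- seeds[(i - 1L) * (n_repeats + 1L) + 1L + r]
      smp <- render_biplane(ph, cfg_i)
      est <- auto_measure(smp, model = model, shape_label = shape_label,
                          coefficient = coefficient)
      out[[k]] <- data.frame(
        phantom = i, nominal_mL = volumes_mL[i], repeat_idx = r,
        measured_mL = est$volume_mL,
        error_pct = if (is.na(est$volume_mL)) NA_real_ else
          volume_error_pct(est$volume_mL, volumes_mL[i]),
        detected_sagittal = est$detected["sagittal"],
        detected_transverse = est$detected["transverse"])
    }
  }
  do.call(rbind, out)
}
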