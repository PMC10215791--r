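test_that("largest_region keeps exactly the biggest 8-connected component", {
  m <- matrix(0L, 40, 40)
  m[5:14, 5:14] <- 1L          # 100 px
  m[25:30, 25:29] <- 1L        # 30 px
  r <- largest_region(m)
  expect_identical(sum(r), 100L)
  expect_identical(r[5:14, 5:14], m[5:14, 5:14])

  expect_identical(sum(largest_region(matrix(0L, 5, 5))), 0L)
  single <- matrix(0L, 10, 10); single[3:6, 4:8] <- 1L
  expect_identical(largest_region(single), single)

  # diagonal contact joins components (8-connectivity)
  d <- matrix(0L, 10, 10)
  d[1:3, 1:3] <- 1L
  d[4, 4] <- 1L
  expect_identical(sum(largest_region(d)), 10L)
})

test_that("min_area_bbox matches brute-force rotating calipers", {
  rect <- matrix(0L, 60, 80); rect[20:39, 20:59] <- 1L   # 40 x 20 px
  bb <- min_area_bbox(rect)
  side <- function(a, b) sqrt(sum((a - b)^2))
  sides <- sort(c(side(bb[1, ], bb[2, ]), side(bb[2, ], bb[3, ])))
  expect_lt(abs(sides[1] - 20), 1.01)
  expect_lt(abs(sides[2] - 40), 1.01)

  circ <- disk_mask(120, 120, 60, 60, 30)
  bbc <- min_area_bbox(circ)
  sc <- sort(c(side(bbc[1, ], bbc[2, ]), side(bbc[2, ], bbc[3, ])))
  expect_lt(abs(sc[1] - 60), 1.5)
  expect_lt(abs(sc[2] - 60), 1.5)

  # 45-degree rotated square: area ~ s^2, not the 2 s^2 axis-aligned box
  s <- 60 * sqrt(2)
  sq <- outer(seq_len(200), seq_len(200), function(i, j)
    abs(i - 100) + abs(j - 100) <= s / sqrt(2)) * 1L
  bbr <- min_area_bbox(sq)
  area <- function(cor) {
    x <- cor[, 1]; y <- cor[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  # brute-force oracle over a dense angle grid on the same pixel set
  pts <- which(sq > 0, arr.ind = TRUE)[, c(2, 1)]
  brute <- min(vapply(seq(0, 90, by = 0.25) * pi / 180, function(th) {
    rx <- pts[, 1] * cos(th) - pts[, 2] * sin(th)
    ry <- pts[, 1] * sin(th) + pts[, 2] * cos(th)
    diff(range(rx)) * diff(range(ry))
  }, numeric(1)))
  expect_lt(abs(area(bbr) - brute) / brute, 0.02)
  expect_lt(area(bbr), 1.1 * s^2)

  expect_error(min_area_bbox(matrix(0L, 5, 5)), class = "echovol_no_region")
})

test_that("sagittal depth equals the analytic diagonal chord", {
  circ <- disk_mask(160, 160, 80, 80, 50)
  d <- depth_from_sagittal(circ, spacing = 0.2)
  expect_lt(abs(d - 20), 0.2 * 1.5)       # diameter 100 px at 0.2 mm/px

  ell <- ellipse_mask(140, 140, 70, 70, 25, 40)   # semi-axes (40, 25) px
  # the diagonal of the snug axis-aligned 80 x 50 box meets the ellipse at
  # +-(40, 25)/sqrt(2): chord = sqrt(2) * sqrt(40^2 + 25^2) = 66.71 px
  de_aa <- depth_from_sagittal(ell, spacing = 1, rotated = FALSE)
  expect_lt(abs(de_aa - 66.71), 1.5)
  # the true minimum-AREA box of the rasterized ellipse tilts slightly
  # (pixel jaggies); its greater diagonal chord is a touch longer. Verified
  # against an exhaustive dense pixel scan along the same diagonals.
  de <- depth_from_sagittal(ell, spacing = 1)
  expect_gte(de, de_aa - 1)
  expect_lt(abs(de - 66.71) / 66.71, 0.05)

  expect_error(depth_from_sagittal(matrix(0L, 10, 10), 1),
               class = "echovol_no_region")
})

test_that("non-convex regions use the outermost intersection pair", {
  # crescent: ellipse minus an offset ellipse; the long diagonal exits and
  # re-enters the region
  outer_e <- ellipse_mask(160, 160, 80, 80, 40, 60)
  bite <- ellipse_mask(160, 160, 80, 95, 28, 45)
  cres <- pmax(outer_e - bite, 0)
  m <- largest_region(cres)
  bb <- min_area_bbox(m)
  d <- depth_from_sagittal(cres, spacing = 1)
  # oracle: dense pixel scan along both diagonals, first-to-last inside pixel
  scan_chord <- function(p1, p2) {
    t <- seq(0, 1, length.out = 4000)
    xs <- p1[1] + t * (p2[1] - p1[1]); ys <- p1[2] + t * (p2[2] - p1[2])
    ii <- pmin(pmax(round(ys), 1), nrow(m)); jj <- pmin(pmax(round(xs), 1), ncol(m))
    ins <- m[cbind(ii, jj)] > 0
    k <- which(ins)
    sqrt((xs[max(k)] - xs[min(k)])^2 + (ys[max(k)] - ys[min(k)])^2)
  }
  oracle <- max(scan_chord(bb[1, ], bb[3, ]), scan_chord(bb[2, ], bb[4, ]))
  expect_lt(abs(d - oracle), 1)
})

test_that("transverse height/width equal exhaustive extent scans", {
  ell <- ellipse_mask(140, 140, 70, 70, 25, 40)
  hw <- height_width_from_transverse(ell, spacing = 1)
  expect_lt(abs(hw[["width"]] - 80), 1.01)
  expect_lt(abs(hw[["height"]] - 50), 1.01)

  px <- matrix(0L, 20, 20); px[7, 9] <- 1L
  hw1 <- height_width_from_transverse(px, spacing = 0.5)
  expect_equal(unname(hw1), c(0.5, 0.5))

  rot <- ellipse_mask(160, 160, 80, 80, 25, 45, theta = 30 * pi / 180)
  hwr <- height_width_from_transverse(rot, spacing = 1)
  # oracle: per-column / per-row loops
  hmax <- 0; wmax <- 0
  for (j in seq_len(ncol(rot))) {
    v <- which(rot[, j] > 0)
    if (length(v)) hmax <- max(hmax, diff(range(v)) + 1)
  }
  for (i in seq_len(nrow(rot))) {
    v <- which(rot[i, ] > 0)
    if (length(v)) wmax <- max(wmax, diff(range(v)) + 1)
  }
  expect_equal(unname(hwr), c(hmax, wmax))
})

test_that("volume estimation follows c * D * H * W with table lookups", {
  ax <- axis_measurements(10, 10, 10)
  expect_equal(estimate_volume(ax, coefficient = 1)$volume_mL, 1)
  expect_equal(estimate_volume(ax, "spherical")$volume_mL, 0.52)
  expect_equal(estimate_volume(ax, "unknown")$volume_mL, 0.72)
  # a perfectly measured sphere is underestimated by 0.69% for every d
  for (d in c(20, 47, 91)) {
    est <- estimate_volume(axis_measurements(d, d, d), "spherical")
    truth <- pi / 6 * (d / 10)^3
    expect_equal(100 * (est$volume_mL - truth) / truth, -0.69,
                 tolerance = 0.01)
  }
  expect_error(estimate_volume(ax, "banana"), regexp = "spherical",
               class = "echovol_lookup")
  expect_error(axis_measurements(-1, 2, 3), class = "echovol_invalid_argument")

  # scale covariance and monotonicity
  v1 <- estimate_volume(axis_measurements(20, 30, 40), "unknown")$volume_mL
  v2 <- estimate_volume(axis_measurements(40, 60, 80), "unknown")$volume_mL
  expect_equal(v2, 8 * v1, tolerance = 1e-12)
  expect_gt(estimate_volume(axis_measurements(21, 30, 40), "unknown")$volume_mL, v1)
  expect_gt(estimate_volume(axis_measurements(20, 31, 40), "unknown")$volume_mL, v1)
  expect_gt(estimate_volume(axis_measurements(20, 30, 41), "unknown")$volume_mL, v1)
  expect_gt(estimate_volume(axis_measurements(20, 30, 40),
                            coefficient = 0.8)$volume_mL, v1)
})

test_that("chord extraction equals exhaustive scans on random masks", {
  set.seed(8)
  for (i in 1:50) {
    m <- matrix(0L, 80, 80)
    for (b in seq_len(sample(1:3, 1))) {
      m <- pmax(m, ellipse_mask(80, 80, runif(1, 25, 55), runif(1, 25, 55),
                                runif(1, 6, 20), runif(1, 6, 20),
                                theta = runif(1, 0, pi)))
    }
    m <- largest_region(m)
    bb <- min_area_bbox(m)
    for (dg in list(c(1, 3), c(2, 4))) {
      got <- echovol:::segment_chord(m, bb[dg[1], ], bb[dg[2], ])$chord
      t <- seq(0, 1, length.out = 3000)
      xs <- bb[dg[1], 1] + t * (bb[dg[2], 1] - bb[dg[1], 1])
      ys <- bb[dg[1], 2] + t * (bb[dg[2], 2] - bb[dg[1], 2])
      ii <- pmin(pmax(round(ys), 1), 80); jj <- pmin(pmax(round(xs), 1), 80)
      ins <- which(m[cbind(ii, jj)] > 0)
      oracle <- if (length(ins)) {
        sqrt((xs[max(ins)] - xs[min(ins)])^2 + (ys[max(ins)] - ys[min(ins)])^2)
      } else 0
      expect_lt(abs(got - oracle), 0.75)
    }
  }
})

test_that("axis measurements are rotation-robust for spheres", {
  base <- NULL
  for (th in c(0, 20, 45, 70) * pi / 180) {
    m <- ellipse_mask(160, 160, 80, 80, 45, 45, theta = th)
    d <- depth_from_sagittal(m, 1)
    hw <- height_width_from_transverse(m, 1)
    vals <- c(d, hw)
    if (is.null(base)) base <- vals
    expect_lt(max(abs(vals - base) / base), 0.03)
  }
})

test_that("oracle masks recover phantom volumes within 3% median error", {
  vols <- rep(c(50, 150, 300), each = 10)
  res <- measure_phantoms(vols, model = NULL, shape_label = "spherical",
                          seed = 314)
  expect_identical(nrow(res), 30L)
  expect_true(all(res$detected_sagittal & res$detected_transverse))
  expect_lt(median(abs(res$error_pct)), 3)
})

test_that("auto_measure gates on per-plane detection", {
  neg <- render_negative(tiny_imaging_config(seed = 5))
  est <- auto_measure(neg, model = NULL)
  expect_false(any(est$detected))
  expect_true(is.na(est$volume_mL))
  expect_null(est$axes)

  ph <- sample_phantom(50, c(1, 1), rng_seed = 6, center_mm = c(0, 0, 62))
  smp <- render_biplane(ph, imaging_config(seed = 6, plane_jitter = 0))
  est2 <- auto_measure(smp, model = NULL, shape_label = "spherical")
  expect_true(all(est2$detected))
  expect_gt(est2$volume_mL, 48.5)
  expect_lt(est2$volume_mL, 51.0)
})

test_that("quantized inference is deterministic in auto_measure", {
  set.seed(9)
  m <- build_model(tiny_model_config(), seed = 9)
  qm <- quantize_model(m, list(matrix(runif(120 * 160, 0, 255), 120, 160)))
  smp <- render_biplane(
    sample_phantom(20, c(1, 1), rng_seed = 10, center_mm = c(0, 0, 40)),
    tiny_imaging_config(seed = 10, plane_jitter = 0))
  e1 <- auto_measure(smp, qm)
  e2 <- auto_measure(smp, qm)
  expect_identical(e1, e2)
})
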