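test_that("sample_phantom inverts the ellipsoid volume formula", {
  p <- sample_phantom(50, c(1, 1), rng_seed = 1)
  r_expected <- (3 * 50000 / (4 * pi))^(1 / 3)   # 22.8539 mm
  expect_equal(p$semi_axes, rep(r_expected, 3), tolerance = 1e-9)
  expect_equal(p$semi_axes[1], 22.85, tolerance = 1e-3)
  expect_equal(p$true_volume, 50000, tolerance = 1e-6)

  p10 <- sample_phantom(4 / 3 * pi * 10^3 / 1000, c(1, 1), rng_seed = 2)
  expect_equal(p10$semi_axes, rep(10, 3), tolerance = 1e-9)

  expect_identical(sample_phantom(120, c(0.8, 1), rng_seed = 7),
                   sample_phantom(120, c(0.8, 1), rng_seed = 7))
  expect_error(sample_phantom(-3), class = "echovol_invalid_argument")
  expect_error(sample_phantom(0), class = "echovol_invalid_argument")
})

test_that("volume round-trips to 1e-6 relative over many random phantoms", {
  for (i in 1:100) {
    v <- runif(1, 20, 400)
    p <- sample_phantom(v, c(0.6, 1), rng_seed = i)
    expect_equal(4 / 3 * pi * prod(p$semi_axes) / 1000, v, tolerance = 1e-6)
  }
})

test_that("rendered masks match the analytic cross-section", {
  ph <- fixed_phantom(c(20, 20, 20), center = c(0, 0, 60))
  cfg <- imaging_config(seed = 3, plane_jitter = 0)
  s <- render_biplane(ph, cfg)
  analytic <- pi * (20 / cfg$pixel_spacing)^2
  expect_lt(abs(sum(s$sagittal_mask) - analytic) / analytic, 0.02)
  expect_lt(abs(sum(s$transverse_mask) - analytic) / analytic, 0.02)
  expect_identical(dim(s$sagittal_image), dim(s$sagittal_mask))

  # equivalent-ellipse axis agreement for an axis-aligned ellipsoid
  ph2 <- fixed_phantom(c(21, 14, 10.5), center = c(0, 0, 55))
  s2 <- render_biplane(ph2, cfg)
  idx <- which(s2$sagittal_mask > 0, arr.ind = TRUE)
  width_px <- diff(range(idx[, 2])) + 1   # lateral = 2a
  depth_px <- diff(range(idx[, 1])) + 1   # axial = 2c
  expect_lt(abs(width_px - 2 * 21 / 0.35), 1.01)
  expect_lt(abs(depth_px - 2 * 10.5 / 0.35), 1.01)
})

test_that("noise-free limit gives a uniform background and exact level set", {
  ph <- fixed_phantom(c(15, 15, 15), center = c(0, 0, 50))
  cfg <- imaging_config(seed = 1, speckle_scale = 0, gain_offset = 0,
                        plane_jitter = 0, posterior_enhancement = FALSE,
                        distractors = 0L)
  s <- render_biplane(ph, cfg)
  sec <- echovol:::sector_mask(cfg)
  bg_vals <- unique(s$sagittal_image[sec & s$sagittal_mask == 0])
  in_vals <- unique(s$sagittal_image[sec & s$sagittal_mask == 1])
  expect_length(bg_vals, 1)
  expect_length(in_vals, 1)
  expect_lt(in_vals, bg_vals)
})

test_that("bladder interior is darker than the background across seeds", {
  vols <- seq(50, 240, length.out = 20)
  for (seed in 1:20) {
    cfg <- imaging_config(seed = seed, plane_jitter = 0)
    ph <- sample_phantom(vols[seed], c(0.85, 1), rng_seed = seed,
                         center_mm = c(0, 0, 65))
    s <- render_biplane(ph, cfg)
    sec <- echovol:::sector_mask(cfg)
    expect_lt(mean(s$sagittal_image[s$sagittal_mask == 1]),
              mean(s$sagittal_image[sec & s$sagittal_mask == 0]))
  }
})

test_that("negative renders have empty masks and rich speckle texture", {
  n1 <- render_negative(imaging_config(seed = 11))
  n2 <- render_negative(imaging_config(seed = 12))
  expect_identical(sum(n1$sagittal_mask) + sum(n1$transverse_mask), 0L)
  expect_false(any(n1$has_bladder))
  expect_false(isTRUE(all.equal(n1$sagittal_image, n2$sagittal_image)))
  expect_gt(length(unique(as.vector(n1$sagittal_image))), 30)
})

test_that("out-of-view phantoms are rejected with the axis named", {
  ph <- fixed_phantom(c(60, 60, 60), center = c(0, 0, 30))
  expect_error(render_biplane(ph, imaging_config(plane_jitter = 0)),
               regexp = "semi-axis", class = "echovol_out_of_view")
})

test_that("make_dataset writes the requested splits deterministically", {
  d1 <- file.path(tempdir(), "ds_det1")
  d2 <- file.path(tempdir(), "ds_det2")
  unlink(c(d1, d2), recursive = TRUE)
  mf1 <- make_dataset(4, 2, 4, 2, volume_range = c(10, 30), master_seed = 9,
                      out_dir = d1, cfg = tiny_imaging_config())
  mf2 <- make_dataset(4, 2, 4, 2, volume_range = c(10, 30), master_seed = 9,
                      out_dir = d2, cfg = tiny_imaging_config())
  expect_identical(nrow(mf1), 12L)
  expect_identical(sum(mf1$has_bladder), 6L)
  expect_identical(table(mf1$split)[["train"]], 8L)
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e6))
  expect_false(any(duplicated(mf1$path_sagittal)))
  # loading a row restores images, masks and phantom geometry
  smp <- load_sample(mf1, 1, d1)
  expect_s3_class(smp, "biplane_sample")
  expect_true(all(dim(smp$sagittal_image) == c(120, 160)))
  expect_true(smp$has_bladder[["sagittal"]])
  expect_gt(sum(smp$sagittal_mask), 0)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("dataset generation scales to the full acquisition counts", {
  d <- file.path(tempdir(), "ds_full_counts")
  unlink(d, recursive = TRUE)
  cfg <- imaging_config(grid_height = 60L, grid_width = 80L,
                        pixel_spacing = 1.2, seed = 1)
  mf <- make_dataset(1044, 262, 1675, 420, volume_range = c(5, 15),
                     master_seed = 5, out_dir = d, cfg = cfg)
  expect_identical(nrow(mf), 3401L)
  expect_identical(sum(mf$has_bladder), 1306L)
  expect_identical(sum(!mf$has_bladder), 2095L)
  unlink(d, recursive = TRUE)
})

test_that("invalid dataset arguments are rejected", {
  expect_error(make_dataset(-1, 0, 0, 0, master_seed = 1,
                            out_dir = tempdir()),
               class = "echovol_invalid_argument")
  blocker <- tempfile()
  file.create(blocker)          # a plain file cannot be a dataset directory
  expect_error(make_dataset(1, 0, 0, 0, master_seed = 1,
                            out_dir = file.path(blocker, "sub")),
               class = "echovol_io")
})
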