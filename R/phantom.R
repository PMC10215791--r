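#' Imaging configuration for the synthetic B-mode simulator
#'
#' Describes the scan-converted image grid and the acquisition-style knobs the
#' simulator randomizes (gain, depth placement, speckle). The native grid is
#' 570 x 330 pixels; pixel spacing defaults to 0.35 mm/px so a 300 mL bladder
#' fits the field of view. Identical configuration + seed produces bit-identical
#' images.
#'
#' @param grid_height,grid_width image grid size in pixels (rows, columns).
#' @param pixel_spacing isotropic physical pixel size in mm/px.
#' @param sector_angle full opening angle (degrees) of the imaging sector,
#'   apex at the top-middle of the grid. Cosmetic: masks are unaffected.
#' @param sector logical; if `FALSE` a rectilinear image is produced.
#' @param gain_offset additive brightness offset in uint8 intensity units.
#' @param depth_setting nominal depth (mm) at which sampled phantoms are
#'   centred when no explicit centre is given.
#' @param speckle_scale speckle contrast in `[0, 1]`: 1 = fully developed
#'   multiplicative speckle (exponential intensity), 0 = noise-free limit.
#' @param plane_jitter per-plane off-axis offset of the imaging plane,
#'   expressed as a fraction of the out-of-plane semi-axis (emulates free-hand
#'   probe placement). Set 0 for perfectly central cross-sections.
#' @param posterior_enhancement logical; brighten the band distal to the
#'   anechoic bladder, as fluid causes in real B-mode images.
#' @param distractors maximum number of incidental soft-tissue inhomogeneities
#'   rendered per image (drawn uniformly from 0..distractors).
#' @param seed integer RNG seed for the render.
#' @return an object of class `imaging_config`.
#' @export
imaging_config <- function(grid_height = 330L, grid_width = 570L,
                           pixel_spacing = 0.35, sector_angle = 110,
                           sector = TRUE, gain_offset = 0,
                           depth_setting = 65, speckle_scale = 1,
                           plane_jitter = 0.2, posterior_enhancement = TRUE,
                           distractors = 3L, seed = 1L) {
  if (grid_height <= 0 || grid_width <= 0) {
    stop_echovol("grid dimensions must be positive", "echovol_invalid_argument")
  }
  if (pixel_spacing <= 0) {
    stop_echovol("pixel_spacing must be positive", "echovol_invalid_argument")
  }
  if (speckle_scale < 0 || speckle_scale > 1) {
    stop_echovol("speckle_scale must lie in [0, 1]", "echovol_invalid_argument")
  }
  structure(list(
    grid_height = as.integer(grid_height), grid_width = as.integer(grid_width),
    pixel_spacing = pixel_spacing, sector_angle = sector_angle,
    sector = isTRUE(sector), gain_offset = gain_offset,
    depth_setting = depth_setting, speckle_scale = speckle_scale,
    plane_jitter = plane_jitter,
    posterior_enhancement = isTRUE(posterior_enhancement),
    distractors = as.integer(distractors), seed = as.integer(seed)
  ), class = "imaging_config")
}

#' Sample an ellipsoidal bladder phantom of a given volume
#'
#' Draws semi-axis ratios within `eccentricity_range`, solves the leading
#' semi-axis so that (4/3) pi a b c matches the target volume exactly, and
#' draws a random small rotation and a random centre position. Deterministic
#' per seed.
#'
#' @param target_volume_mL target volume in millilitres (> 0).
#' @param eccentricity_range interval within (0, 1] from which the ratios
#'   b/a and c/a are drawn. Use `c(1, 1)` to force a sphere.
#' @param rng_seed integer seed.
#' @param center_mm optional explicit centre `c(x, y, z)` in mm (x lateral in
#'   the sagittal plane, y lateral in the transverse plane, z depth). If
#'   `NULL`, a centre is drawn at random.
#' @return object of class `phantom3d` with fields `semi_axes` (mm),
#'   `center` (mm), `rotation` (Euler angles, radians), `true_volume` (mm^3).
#' @export
sample_phantom <- function(target_volume_mL, eccentricity_range = c(0.75, 1),
                           rng_seed = 1L, center_mm = NULL) {
  if (!is.numeric(target_volume_mL) || length(target_volume_mL) != 1 ||
      !is.finite(target_volume_mL) || target_volume_mL <= 0) {
    stop_echovol("target_volume_mL must be a positive number",
                 "echovol_invalid_argument")
  }
  er <- sort(as.numeric(eccentricity_range))
  if (length(er) != 2 || er[1] <= 0 || er[2] > 1) {
    stop_echovol("eccentricity_range must lie within (0, 1]",
                 "echovol_invalid_argument")
  }
  V <- target_volume_mL * 1000  # mm^3
  with_seed(rng_seed, {
    q1 <- runif(1, er[1], er[2])
    q2 <- runif(1, er[1], er[2])
    a <- (3 * V / (4 * pi * q1 * q2))^(1 / 3)
    axes <- c(a, a * q1, a * q2)
    rot <- runif(3, -0.3, 0.3)
    if (is.null(center_mm)) {
      center_mm <- c(runif(1, -10, 10), runif(1, -10, 10), runif(1, 55, 80))
    }
    structure(list(
      semi_axes = axes, center = as.numeric(center_mm), rotation = rot,
      true_volume = 4 / 3 * pi * prod(axes)
    ), class = "phantom3d")
  })
}

# 3D rotation matrix from Euler angles (Z-Y-X intrinsic order).
rotation_matrix <- function(euler) {
  cx <- cos(euler[1]); sx <- sin(euler[1])
  cy <- cos(euler[2]); sy <- sin(euler[2])
  cz <- cos(euler[3]); sz <- sin(euler[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Physical coordinates of pixel centres. Row i -> depth z, column j -> lateral.
grid_coords <- function(cfg) {
  z <- (seq_len(cfg$grid_height) - 0.5) * cfg$pixel_spacing
  lat <- (seq_len(cfg$grid_width) - (cfg$grid_width + 1) / 2) * cfg$pixel_spacing
  list(z = z, lat = lat)
}

# Binary H x W matrix: pixels inside the imaging sector.
sector_mask <- function(cfg) {
  if (!cfg$sector) {
    return(matrix(TRUE, cfg$grid_height, cfg$grid_width))
  }
  gc <- grid_coords(cfg)
  half <- cfg$sector_angle / 2 * pi / 180
  ang <- atan2(abs(matrix(gc$lat, cfg$grid_height, cfg$grid_width, byrow = TRUE)),
               matrix(gc$z, cfg$grid_height, cfg$grid_width))
  ang <= half
}

# Rasterize the cross-section of `phantom` with an imaging plane.
# plane = "sagittal" (x-z plane at y = cy + offset) or "transverse"
# (y-z plane at x = cx + offset). Returns logical H x W matrix.
cross_section_mask <- function(phantom, cfg, plane, offset = 0) {
  gc <- grid_coords(cfg)
  H <- cfg$grid_height; W <- cfg$grid_width
  latm <- matrix(gc$lat, H, W, byrow = TRUE)
  zm <- matrix(gc$z, H, W)
  if (plane == "sagittal") {
    d <- rbind(as.vector(latm) - phantom$center[1],
               rep(offset, H * W),
               as.vector(zm) - phantom$center[3])
  } else {
    d <- rbind(rep(offset, H * W),
               as.vector(latm) - phantom$center[2],
               as.vector(zm) - phantom$center[3])
  }
  R <- rotation_matrix(phantom$rotation)
  u <- crossprod(R, d) / phantom$semi_axes
  matrix(colSums(u^2) <= 1, H, W)
}

# Verify that the cross-section lies inside the grid and the sector.
# Names the most implicated semi-axis on violation.
check_in_view <- function(mask, phantom, cfg, plane) {
  sec <- sector_mask(cfg)
  edge <- mask
  edge[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] <- FALSE
  violated <- any(mask & !sec) || any(edge)
  if (violated) {
    ax <- c("a", "b", "c")[which.max(phantom$semi_axes)]
    stop_echovol(sprintf(
      "phantom exceeds the field of view on the %s plane (semi-axis %s = %.1f mm)",
      plane, ax, max(phantom$semi_axes)), "echovol_out_of_view")
  }
  invisible(TRUE)
}

# Draw soft elliptical echogenicity inhomogeneities into `mu` (background
# texture variety; also present on bladder images outside the bladder).
add_distractors <- function(mu, cfg) {
  n <- if (cfg$distractors > 0) sample.int(cfg$distractors + 1L, 1) - 1L else 0L
  if (n == 0) return(mu)
  H <- nrow(mu); W <- ncol(mu)
  for (k in seq_len(n)) {
    cy <- runif(1, 0.2, 0.9) * H
    cx <- runif(1, 0.2, 0.8) * W
    ry <- runif(1, 8, 40); rx <- runif(1, 8, 60)
    lev <- if (runif(1) < 0.5) runif(1, 0.45, 0.8) else runif(1, 1.2, 1.6)
    rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    blob <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
    mu[blob] <- mu[blob] * lev
  }
  mu
}

# Log-compressed multiplicative speckle render of an echogenicity map `mu`.
render_plane <- function(mu, cfg) {
  H <- nrow(mu); W <- ncol(mu)
  if (cfg$speckle_scale > 0) {
    E <- matrix(rexp(H * W), H, W)
    E <- 1 + cfg$speckle_scale * (E - 1)
  } else {
    E <- matrix(1, H, W)
  }
  I <- mu * E
  beta <- 30; i_ref <- 5
  g <- 255 * log1p(beta * I) / log1p(beta * i_ref) + cfg$gain_offset
  img <- matrix(as.integer(round(clamp(g, 0, 255))), H, W)
  img[!sector_mask(cfg)] <- 0L
  img
}

#' Render a biplane B-mode sample of a bladder phantom
#'
#' Produces the sagittal (x-z) and transverse (y-z) cross-sections of the
#' ellipsoid through (near) its centre, rendered as log-compressed
#' exponential-intensity speckle with an anechoic bladder interior, plus the
#' exact rasterized ground-truth masks.
#'
#' @param phantom a `phantom3d` object.
#' @param cfg an [imaging_config()].
#' @return an object of class `biplane_sample` with integer uint8 images,
#'   0/1 masks, per-plane `has_bladder` flags, the phantom, and the spacing.
#' @export
render_biplane <- function(phantom, cfg = imaging_config()) {
  stopifnot(inherits(phantom, "phantom3d"))
  with_seed(cfg$seed, {
    off_s <- if (cfg$plane_jitter > 0) {
      runif(1, -1, 1) * cfg$plane_jitter * phantom$semi_axes[2]
    } else 0
    off_t <- if (cfg$plane_jitter > 0) {
      runif(1, -1, 1) * cfg$plane_jitter * phantom$semi_axes[1]
    } else 0
    mask_s <- cross_section_mask(phantom, cfg, "sagittal", off_s)
    mask_t <- cross_section_mask(phantom, cfg, "transverse", off_t)
    check_in_view(mask_s, phantom, cfg, "sagittal")
    check_in_view(mask_t, phantom, cfg, "transverse")
    imgs <- lapply(list(mask_s, mask_t), function(m) {
      mu <- matrix(1, cfg$grid_height, cfg$grid_width)
      mu <- add_distractors(mu, cfg)
      mu[m] <- 0.03
      if (cfg$posterior_enhancement) {
        band <- 25L
        for (j in seq_len(ncol(m))) {
          rows <- which(m[, j])
          if (length(rows)) {
            lo <- max(rows) + 1L
            hi <- min(nrow(m), max(rows) + band)
            if (lo <= hi) mu[lo:hi, j] <- mu[lo:hi, j] * 1.5
          }
        }
      }
      render_plane(mu, cfg)
    })
    structure(list(
      sagittal_image = imgs[[1]], transverse_image = imgs[[2]],
      sagittal_mask = mask_s * 1L, transverse_mask = mask_t * 1L,
      has_bladder = c(sagittal = TRUE, transverse = TRUE),
      phantom = phantom, spacing = cfg$pixel_spacing
    ), class = "biplane_sample")
  })
}

#' Render a bladder-free biplane sample
#'
#' Background speckle with incidental soft-tissue inhomogeneities but no
#' anechoic bladder; masks are all-zero and `has_bladder` is `FALSE` on both
#' planes.
#'
#' @param cfg an [imaging_config()].
#' @return a `biplane_sample`.
#' @export
render_negative <- function(cfg = imaging_config()) {
  with_seed(cfg$seed, {
    imgs <- lapply(1:2, function(i) {
      mu <- add_distractors(matrix(1, cfg$grid_height, cfg$grid_width), cfg)
      render_plane(mu, cfg)
    })
    zero <- matrix(0L, cfg$grid_height, cfg$grid_width)
    structure(list(
      sagittal_image = imgs[[1]], transverse_image = imgs[[2]],
      sagittal_mask = zero, transverse_mask = zero,
      has_bladder = c(sagittal = FALSE, transverse = FALSE),
      phantom = NULL, spacing = cfg$pixel_spacing
    ), class = "biplane_sample")
  })
}

# Draw a random centre for `phantom` that keeps it inside the grid and the
# sector (approximately; the render still verifies exactly). Returns NULL
# when no depth window exists.
random_feasible_center <- function(phantom, cfg, margin = 2) {
  r <- max(phantom$semi_axes)
  depth <- cfg$grid_height * cfg$pixel_spacing
  zlo <- if (cfg$sector) {
    t <- tan(cfg$sector_angle / 2 * pi / 180)
    r * sqrt(1 + 1 / t^2) + margin
  } else r + margin
  zhi <- depth - r - margin
  if (zlo > zhi) return(NULL)
  z <- runif(1, zlo, zhi)
  half_w <- cfg$grid_width * cfg$pixel_spacing / 2
  slack <- max(0, min(
    half_w - r - margin,
    if (cfg$sector) tan(cfg$sector_angle / 2 * pi / 180) * zlo - r else Inf))
  L <- min(12, slack)
  phantom$center <- c(runif(1, -L, L), runif(1, -L, L), z)
  phantom
}

write_png_u8 <- function(img, path) {
  png::writePNG(img / 255, path)
}

read_png_u8 <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Generate a full synthetic biplane dataset with manifest
#'
#' Writes PNG images and masks for bladder-positive and bladder-negative
#' samples under `out_dir` and returns (and writes) a CSV manifest. Phantom
#' volumes, poses and centre positions are randomized per sample so that
#' regions of interest vary in size and location; generation is a pure
#' function of `master_seed`.
#'
#' @param n_pos_train,n_pos_val,n_neg_train,n_neg_val sample counts per split
#'   (each sample is one sagittal + transverse pair).
#' @param volume_range interval (mL) from which phantom volumes are drawn.
#' @param master_seed integer seed controlling the whole dataset.
#' @param out_dir output directory (created if missing).
#' @param cfg base [imaging_config()]; per-sample seeds and gain jitter are
#'   derived from `master_seed`.
#' @param eccentricity_range semi-axis ratio interval for [sample_phantom()].
#' @return the manifest `data.frame`, invisibly also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
make_dataset <- function(n_pos_train, n_pos_val, n_neg_train, n_neg_val,
                         volume_range = c(50, 300), master_seed = 1L,
                         out_dir, cfg = imaging_config(),
                         eccentricity_range = c(0.75, 1)) {
  counts <- c(n_pos_train, n_pos_val, n_neg_train, n_neg_val)
  if (!all(vapply(counts, is_count, logical(1)))) {
    stop_echovol("sample counts must be non-negative integers",
                 "echovol_invalid_argument")
  }
  ok <- tryCatch({
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    file.access(out_dir, 2) == 0
  }, error = function(e) FALSE)
  if (!isTRUE(ok)) {
    stop_echovol(sprintf("cannot write to out_dir '%s'", out_dir), "echovol_io")
  }
  n_total <- sum(counts)
  seeds <- derive_seeds(master_seed, max(1L, n_total) * 20L)
  splits <- rep(c("train", "val", "train", "val"), counts)
  positive <- rep(c(TRUE, TRUE, FALSE, FALSE), counts)
  rows <- vector("list", n_total)
  si <- 0L
  for (i in seq_len(n_total)) {
    tag <- sprintf("%s_%s_%04d", splits[i], if (positive[i]) "pos" else "neg", i)
    ps <- file.path("images", paste0(tag, "_sag.png"))
    pt <- file.path("images", paste0(tag, "_trv.png"))
    ms <- file.path("masks", paste0(tag, "_sag.png"))
    mt <- file.path("masks", paste0(tag, "_trv.png"))
    if (positive[i]) {
      sample_i <- NULL
      phant <- NULL
      for (try in 1:40) {          # deterministic retry on out-of-view poses
        si <- si + 1L
        sd_i <- seeds[si]
        vol <- with_seed(sd_i, runif(1, volume_range[1], volume_range[2]))
        cfg_i <- cfg
        cfg_i$seed <- sd_i
        cfg_i$gain_offset <- cfg$gain_offset +
          with_seed(sd_i + 1L, runif(1, -15, 15))
        phant <- sample_phantom(vol, eccentricity_range, rng_seed = sd_i)
        phant <- with_seed(sd_i + 2L, random_feasible_center(phant, cfg))
        if (is.null(phant)) next
        sample_i <- tryCatch(render_biplane(phant, cfg_i),
                             echovol_out_of_view = function(e) NULL)
        if (!is.null(sample_i)) break
      }
      if (is.null(sample_i)) {
        stop_echovol("could not place a phantom inside the field of view",
                     "echovol_out_of_view")
      }
      vol_mL <- phant$true_volume / 1000
      extra <- c(phant$semi_axes, phant$center, phant$rotation)
    } else {
      si <- si + 1L
      cfg_i <- cfg
      cfg_i$seed <- seeds[si]
      cfg_i$gain_offset <- cfg$gain_offset +
        with_seed(seeds[si] + 1L, runif(1, -15, 15))
      sample_i <- render_negative(cfg_i)
      vol_mL <- NA_real_
      extra <- rep(NA_real_, 9)
    }
    write_png_u8(sample_i$sagittal_image, file.path(out_dir, ps))
    write_png_u8(sample_i$transverse_image, file.path(out_dir, pt))
    write_png_u8(sample_i$sagittal_mask * 255L, file.path(out_dir, ms))
    write_png_u8(sample_i$transverse_mask * 255L, file.path(out_dir, mt))
    rows[[i]] <- data.frame(
      path_sagittal = ps, path_transverse = pt,
      mask_sagittal = ms, mask_transverse = mt,
      split = splits[i], has_bladder = positive[i],
      true_volume_mL = round(vol_mL, 6), spacing_mm = cfg$pixel_spacing,
      a_mm = round(extra[1], 6), b_mm = round(extra[2], 6),
      c_mm = round(extra[3], 6),
      center_x = round(extra[4], 6), center_y = round(extra[5], 6),
      center_z = round(extra[6], 6),
      rot_x = round(extra[7], 6), rot_y = round(extra[8], 6),
      rot_z = round(extra[9], 6),
      render_seed = seeds[si],
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) manifest <- data.frame()
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(
    c(unclass(cfg),
      list(master_seed = master_seed, volume_range = volume_range,
           eccentricity_range = eccentricity_range,
           counts = list(pos_train = n_pos_train, pos_val = n_pos_val,
                         neg_train = n_neg_train, neg_val = n_neg_val))),
    file.path(out_dir, "simulator.yaml"))
  manifest
}

#' Load one manifest row back into a `biplane_sample`
#'
#' @param manifest manifest data.frame from [make_dataset()].
#' @param row row index.
#' @param dir dataset directory the manifest paths are relative to.
#' @return a `biplane_sample` (without the phantom geometry unless present in
#'   the manifest columns).
#' @export
load_sample <- function(manifest, row, dir) {
  r <- manifest[row, ]
  phant <- if (!is.na(r$true_volume_mL)) {
    structure(list(
      semi_axes = c(r$a_mm, r$b_mm, r$c_mm),
      center = c(r$center_x, r$center_y, r$center_z),
      rotation = c(r$rot_x, r$rot_y, r$rot_z),
      true_volume = r$true_volume_mL * 1000
    ), class = "phantom3d")
  } else NULL
  structure(list(
    sagittal_image = read_png_u8(file.path(dir, r$path_sagittal)),
    transverse_image = read_png_u8(file.path(dir, r$path_transverse)),
    sagittal_mask = (read_png_u8(file.path(dir, r$mask_sagittal)) > 127) * 1L,
    transverse_mask = (read_png_u8(file.path(dir, r$mask_transverse)) > 127) * 1L,
    has_bladder = c(sagittal = r$has_bladder, transverse = r$has_bladder),
    phantom = phant, spacing = r$spacing_mm
  ), class = "biplane_sample")
}
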