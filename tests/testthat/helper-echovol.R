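# Shared fixtures: a reduced-scale imaging grid and network so unit tests
# run in seconds. The full-size study conditions live only in the
# acceptance tests and scripts/acceptance.R.

tiny_imaging_config <- function(seed = 1L, ...) {
  imaging_config(grid_height = 120L, grid_width = 160L, pixel_spacing = 0.6,
                 seed = seed, ...)
}

tiny_model_config <- function() {
  model_config(input_size = 48L, width = 0.25)
}

# A phantom with explicit geometry (bypasses random sampling).
fixed_phantom <- function(semi_axes, center = c(0, 0, 40),
                          rotation = c(0, 0, 0)) {
  structure(list(semi_axes = semi_axes, center = center, rotation = rotation,
                 true_volume = 4 / 3 * pi * prod(semi_axes)),
            class = "phantom3d")
}

# Small on-disk dataset reused across test files (built once per session).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (!is.null(cache) && dir.exists(cache$dir)) return(cache)
    dir <- file.path(tempdir(), "echovol_tiny_ds")
    unlink(dir, recursive = TRUE)
    mf <- make_dataset(8, 4, 8, 4, volume_range = c(10, 30),
                       master_seed = 424242L, out_dir = dir,
                       cfg = tiny_imaging_config())
    cache <<- list(dir = dir, manifest = mf)
    cache
  }
})

# Filled geometric test masks.
disk_mask <- function(h, w, cy, cx, r) {
  outer(seq_len(h), seq_len(w), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2) * 1L
}

ellipse_mask <- function(h, w, cy, cx, ry, rx, theta = 0) {
  outer(seq_len(h), seq_len(w), function(i, j) {
    di <- i - cy; dj <- j - cx
    u <- dj * cos(theta) + di * sin(theta)
    v <- -dj * sin(theta) + di * cos(theta)
    (u / rx)^2 + (v / ry)^2 <= 1
  }) * 1L
}
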