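# fixtures built in code; no binary data ships with the package

disk_mask <- function(r, pad = 3) {
  rasterize_ellipse_mask(r, r, 0, canvas = rep(2 * ceiling(r) + 2 * pad + 1, 2))
}

square_mask <- function(side, pad = 3) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

rect_mask <- function(h, w, pad = 3) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  m
}

# uniform image of one colour with a mask-shaped patch of another
patch_image <- function(mask, fg, bg = c(245, 245, 245)) {
  H <- nrow(mask); W <- ncol(mask)
  img <- array(rep(bg, each = H * W), dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- fg[ch]
    img[, , ch] <- plane
  }
  img
}

# small gridded scene that renders and measures quickly
small_scene <- function(seed = 1, n_rows = 2, n_cols = 3, shading = 0) {
  render_scene(make_grid_spec(n_rows = n_rows, n_cols = n_cols,
                              spacing = 150, n_markers = 2,
                              marker_diameter = 80, shading = shading,
                              seed = seed))
}

quiet_process <- function(...) {
  suppressMessages(suppressWarnings(process_image(...)))
}

# scale every geometric quantity of a scene spec by a factor
scale_spec <- function(spec, f) {
  b <- spec$berries
  b$cx <- b$cx * f; b$cy <- b$cy * f
  b$semi_major <- b$semi_major * f; b$semi_minor <- b$semi_minor * f
  m <- spec$markers
  m$cx <- m$cx * f; m$cy <- m$cy * f; m$diameter <- m$diameter * f
  scene_spec(round(spec$width * f), round(spec$height * f),
             berries = b, markers = m, background = spec$background,
             grid = spec$grid)
}
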