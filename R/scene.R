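#' Specify a synthetic berry
#'
#' Describes one shaded elliptical "berry" to be drawn on a synthetic stage.
#' Rotation is measured in degrees from the image x-axis toward the y-axis
#' (i.e. visually clockwise, since y points down). Shading darkens the colour
#' linearly from `base_color` at the center to `(1 - shading) * base_color` at
#' the rim, emulating the radial specular/shadow structure of real fruit that
#' motivates border erosion before colour measurement. A positive
#' `notch_depth` carves a triangular wedge from the rim toward the centroid,
#' lowering solidity for quality-control fixtures.
#'
#' @param cx,cy center in pixels (1-based, pixel centers at integers).
#' @param semi_major,semi_minor ellipse semi-axes in pixels; `semi_major >=
#'   semi_minor > 0`.
#' @param rotation degrees, direction of the major axis.
#' @param color length-3 integer RGB in `[0, 255]`.
#' @param shading fraction in `[0, 1)` of radial darkening toward the rim.
#' @param notch_depth wedge depth in pixels (0 = no notch).
#' @return A one-row tibble describing the berry.
#' @export
berry_spec <- function(cx, cy, semi_major, semi_minor, rotation = 0,
                       color = c(150, 20, 30), shading = 0, notch_depth = 0) {
  stopifnot(semi_major >= semi_minor, semi_minor > 0,
            shading >= 0, shading < 1, length(color) == 3,
            all(color >= 0 & color <= 255), notch_depth >= 0)
  tibble::tibble(cx = cx, cy = cy, semi_major = semi_major,
                 semi_minor = semi_minor, rotation = rotation,
                 R = color[1], G = color[2], B = color[3],
                 shading = shading, notch_depth = notch_depth)
}

#' Specify a synthetic stage scene
#'
#' Bundles berries, circular size markers, background colour and image size
#' into a renderable scene description. Object footprints must not overlap and
#' must lie fully inside the frame; both are checked at render time.
#'
#' @param width,height image size in pixels.
#' @param berries tibble of rows from [berry_spec()] (may be empty).
#' @param markers tibble with columns `cx`, `cy`, `diameter` (px); may be
#'   empty.
#' @param background length-3 RGB of the stage background.
#' @param grid optional integer vector `c(n_rows, n_cols)` recorded in the
#'   ground truth.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width, height, berries = NULL, markers = NULL,
                       background = c(245, 245, 245), grid = NULL) {
  empty_b <- berry_spec(0, 0, 1, 1)[0, ]
  empty_m <- tibble::tibble(cx = numeric(), cy = numeric(), diameter = numeric())
  spec <- structure(list(
    width = as.integer(width), height = as.integer(height),
    berries = berries %||% empty_b,
    markers = markers %||% empty_m,
    background = as.numeric(background),
    grid = grid
  ), class = "scene_spec")
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px, %d berries, %d markers\n",
              x$width, x$height, nrow(x$berries), nrow(x$markers)))
  invisible(x)
}

#' Rasterize an ideal ellipse mask
#'
#' A pixel is foreground iff its center lies strictly inside the ellipse
#' (pixel-center inclusion, no anti-aliasing), so mask areas and width
#' profiles are integer-exact and reproducible. Used both by the scene
#' renderer and as the fixture for the volume/surface estimator oracles.
#'
#' @param semi_major,semi_minor semi-axes in pixels (>= 2).
#' @param rotation degrees, major-axis direction.
#' @param canvas optional `c(width, height)`; defaults to a square that fits
#'   the ellipse with a 2-px margin.
#' @param center optional `c(cx, cy)`; defaults to the canvas center.
#' @return A logical matrix `[row, col]`.
#' @export
rasterize_ellipse_mask <- function(semi_major, semi_minor, rotation = 0,
                                   canvas = NULL, center = NULL) {
  stopifnot(semi_major >= semi_minor, semi_minor >= 2)
  if (is.null(canvas)) {
    side <- 2L * ceiling(semi_major) + 5L
    canvas <- c(side, side)
  }
  W <- canvas[1]; H <- canvas[2]
  if (is.null(center)) center <- c((W + 1) / 2, (H + 1) / 2)
  r_eff <- semi_major
  if (center[1] - r_eff < 0.5 || center[1] + r_eff > W + 0.5 ||
      center[2] - r_eff < 0.5 || center[2] + r_eff > H + 0.5) {
    # tight check along the actual axes before giving up
    th <- rotation * pi / 180
    ex <- sqrt((semi_major * cos(th))^2 + (semi_minor * sin(th))^2)
    ey <- sqrt((semi_major * sin(th))^2 + (semi_minor * cos(th))^2)
    if (center[1] - ex < 0.5 || center[1] + ex > W + 0.5 ||
        center[2] - ey < 0.5 || center[2] + ey > H + 0.5) {
      stop(sprintf(
        "ellipse (a=%g, b=%g) at (%g, %g) exceeds the %d x %d canvas",
        semi_major, semi_minor, center[1], center[2], W, H), call. = FALSE)
    }
  }
  th <- rotation * pi / 180
  ct <- cos(th); st <- sin(th)
  # snap near-zero trig terms so quarter-turn rotations are exactly
  # transposes (strict inclusion is sensitive to 1e-16 residue)
  if (abs(ct) < 1e-12) ct <- 0
  if (abs(st) < 1e-12) st <- 0
  dx <- rep(seq_len(W) - center[1], each = H)
  dy <- rep(seq_len(H) - center[2], times = W)
  u <- (ct * dx + st * dy) / semi_major
  v <- (-st * dx + ct * dy) / semi_minor
  matrix(u * u + v * v < 1, nrow = H, ncol = W)
}

# carve a triangular wedge from the rim toward the centroid; base of width
# `depth` sits on the boundary at the major-axis end, apex `depth` px inward
carve_notch <- function(inside_mat, center, rotation, semi_major, depth) {
  if (depth <= 0) return(inside_mat)
  th <- rotation * pi / 180
  d <- c(cos(th), sin(th))                       # outward along major axis
  tip <- center + d * semi_major                 # boundary point
  H <- nrow(inside_mat); W <- ncol(inside_mat)
  dx <- rep(seq_len(W) - tip[1], each = H)
  dy <- rep(seq_len(H) - tip[2], times = W)
  s <- -(dx * d[1] + dy * d[2])                  # inward distance from rim
  t <- -dx * d[2] + dy * d[1]                    # lateral offset
  wedge <- s >= 0 & s <= depth & abs(t) <= (depth / 2) * (1 - s / depth)
  inside_mat & !matrix(wedge, H, W)
}

#' Render a synthetic stage photograph
#'
#' Draws shaded filled ellipses for berries and near-black filled disks for
#' markers on a uniform background, returning the 8-bit RGB image together
#' with an exact ground-truth table. Rendering is a pure function of the
#' scene specification.
#'
#' @param spec a [scene_spec()].
#' @param marker_color RGB of the markers (near-black by default).
#' @return A `berry_scene` list with elements `image` (numeric array
#'   `[H, W, 3]` in 0-255) and `truth` (tibble with one row per object:
#'   `class`, `row`, `col`, `cx`, `cy`, `length_px`, `width_px`,
#'   `rotation_deg`, `area_px`, `R`, `G`, `B`).
#' @export
render_scene <- function(spec, marker_color = c(18, 18, 18)) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$width; H <- spec$height
  b <- spec$berries; m <- spec$markers
  # overlap / frame checks on bounding circles
  objs <- rbind(
    if (nrow(b)) data.frame(cx = b$cx, cy = b$cy, r = b$semi_major),
    if (nrow(m)) data.frame(cx = m$cx, cy = m$cy, r = m$diameter / 2)
  )
  if (!is.null(objs) && nrow(objs)) {
    if (any(objs$cx - objs$r < 0.5 | objs$cx + objs$r > W + 0.5 |
            objs$cy - objs$r < 0.5 | objs$cy + objs$r > H + 0.5)) {
      bad <- which(objs$cx - objs$r < 0.5 | objs$cx + objs$r > W + 0.5 |
                   objs$cy - objs$r < 0.5 | objs$cy + objs$r > H + 0.5)[1]
      stop(sprintf("object %d at (%g, %g) extends outside the %d x %d frame",
                   bad, objs$cx[bad], objs$cy[bad], W, H), call. = FALSE)
    }
    if (nrow(objs) > 1) {
      dmat <- as.matrix(stats::dist(objs[, c("cx", "cy")]))
      rsum <- outer(objs$r, objs$r, `+`)
      diag(dmat) <- Inf
      if (any(dmat <= rsum)) {
        ij <- which(dmat <= rsum, arr.ind = TRUE)[1, ]
        stop(sprintf("object footprints %d and %d overlap", ij[1], ij[2]),
             call. = FALSE)
      }
    }
  }
  img <- array(rep(spec$background, each = H * W), dim = c(H, W, 3))
  truth <- list()
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      bi <- b[i, ]
      th <- bi$rotation * pi / 180
      ct <- cos(th); st <- sin(th)
      x0 <- floor(bi$cx - bi$semi_major - 1); x1 <- ceiling(bi$cx + bi$semi_major + 1)
      y0 <- floor(bi$cy - bi$semi_major - 1); y1 <- ceiling(bi$cy + bi$semi_major + 1)
      xs <- max(1, x0):min(W, x1); ys <- max(1, y0):min(H, y1)
      dx <- rep(xs - bi$cx, each = length(ys))
      dy <- rep(ys - bi$cy, times = length(xs))
      u <- (ct * dx + st * dy) / bi$semi_major
      v <- (-st * dx + ct * dy) / bi$semi_minor
      q <- matrix(u * u + v * v, length(ys), length(xs))
      inside <- q < 1
      if (bi$notch_depth > 0) {
        inside <- carve_notch(inside,
                              c(bi$cx - xs[1] + 1, bi$cy - ys[1] + 1),
                              bi$rotation, bi$semi_major, bi$notch_depth)
      }
      rho <- sqrt(pmax(q, 0))
      fac <- 1 - bi$shading * rho
      base <- c(bi$R, bi$G, bi$B)
      idx_local <- which(inside)
      # map local box indices to full-image linear indices
      lr <- ((idx_local - 1L) %% length(ys)) + 1L
      lc <- ((idx_local - 1L) %/% length(ys)) + 1L
      gidx <- (xs[lc] - 1L) * H + ys[lr]
      shade <- fac[idx_local]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[gidx] <- round(clamp(base[ch] * shade, 0, 255))
        img[, , ch] <- plane
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        class = "berry", row = NA_integer_, col = NA_integer_,
        cx = bi$cx, cy = bi$cy,
        length_px = 2 * bi$semi_major, width_px = 2 * bi$semi_minor,
        rotation_deg = bi$rotation, area_px = length(idx_local),
        R = bi$R, G = bi$G, B = bi$B)
    }
  }
  if (nrow(m)) {
    for (i in seq_len(nrow(m))) {
      mi <- m[i, ]
      r <- mi$diameter / 2
      xs <- max(1, floor(mi$cx - r - 1)):min(W, ceiling(mi$cx + r + 1))
      ys <- max(1, floor(mi$cy - r - 1)):min(H, ceiling(mi$cy + r + 1))
      dx <- rep(xs - mi$cx, each = length(ys))
      dy <- rep(ys - mi$cy, times = length(xs))
      inside <- matrix(dx * dx + dy * dy < r * r, length(ys), length(xs))
      idx_local <- which(inside)
      lr <- ((idx_local - 1L) %% length(ys)) + 1L
      lc <- ((idx_local - 1L) %/% length(ys)) + 1L
      gidx <- (xs[lc] - 1L) * H + ys[lr]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[gidx] <- marker_color[ch]
        img[, , ch] <- plane
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        class = "marker", row = NA_integer_, col = NA_integer_,
        cx = mi$cx, cy = mi$cy,
        length_px = mi$diameter, width_px = mi$diameter,
        rotation_deg = 0, area_px = length(idx_local),
        R = marker_color[1], G = marker_color[2], B = marker_color[3])
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(class = character(), row = integer(), col = integer(),
                   cx = numeric(), cy = numeric(), length_px = numeric(),
                   width_px = numeric(), rotation_deg = numeric(),
                   area_px = numeric(), R = numeric(), G = numeric(),
                   B = numeric())
  # grid labels for berries, ordered rows top-to-bottom, columns left-to-right
  if (!is.null(spec$grid) && any(truth$class == "berry")) {
    bt <- truth$class == "berry"
    ga <- assign_grid(truth[bt, c("cx", "cy")],
                      heights = truth$width_px[bt])
    truth$row[bt] <- ga$row
    truth$col[bt] <- ga$col
  }
  structure(list(image = img, truth = truth, spec = spec),
            class = "berry_scene")
}

#' @export
print.berry_scene <- function(x, ...) {
  cat(sprintf("<berry_scene> %d x %d px, %d objects\n",
              dim(x$image)[2], dim(x$image)[1], nrow(x$truth)))
  invisible(x)
}

#' Build a gridded scene specification
#'
#' Places berries at jittered grid nodes (rows top-to-bottom, columns
#' left-to-right) with axes and colours drawn reproducibly from `seed`, and
#' adds circular size markers in the left and right margins, mimicking a
#' stage photograph of fruit arranged in rows and columns with scale markers
#' on either side.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing grid pitch in pixels.
#' @param semi_major_range,semi_minor_range ranges the semi-axes are drawn
#'   from (px). Draws are per-berry uniform; the minor axis is capped at the
#'   major.
#' @param colors matrix (n x 3) of RGB rows sampled per berry.
#' @param shading shading fraction applied to every berry.
#' @param jitter maximum absolute centre jitter in px (uniform).
#' @param n_markers number of markers, split between the two margins.
#' @param marker_diameter marker diameter in px.
#' @param seed integer seed controlling all draws.
#' @return A `scene_spec` with the grid recorded.
#' @export
make_grid_spec <- function(n_rows = 5, n_cols = 6, spacing = 170,
                           semi_major_range = c(38, 50),
                           semi_minor_range = c(30, 40),
                           colors = NULL, shading = 0, jitter = 4,
                           n_markers = 6, marker_diameter = 100,
                           seed = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (is.null(colors)) {
    colors <- rbind(c(150, 25, 35), c(170, 40, 40), c(120, 15, 30),
                    c(185, 60, 55), c(140, 30, 45))
  }
  margin <- marker_diameter + 60
  W <- as.integer(2 * margin + n_cols * spacing)
  H <- as.integer(max(n_rows * spacing + 60,
                      ceiling(n_markers / 2) * (marker_diameter + 40) + 60))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_rows)) for (cl in seq_len(n_cols)) {
    a <- stats::runif(1, semi_major_range[1], semi_major_range[2])
    b <- min(a, stats::runif(1, semi_minor_range[1], semi_minor_range[2]))
    col <- colors[sample.int(nrow(colors), 1), ]
    rot <- stats::runif(1, 0, 180)
    jx <- stats::runif(1, -jitter, jitter)
    jy <- stats::runif(1, -jitter, jitter)
    rows[[length(rows) + 1L]] <- berry_spec(
      cx = margin + (cl - 0.5) * spacing + jx,
      cy = 30 + (r - 0.5) * spacing + jy,
      semi_major = a, semi_minor = b, rotation = rot,
      color = col, shading = shading)
  }
  berries <- dplyr::bind_rows(rows)
  # spacing feasibility: neighbouring bounding circles must not touch
  if (spacing <= 2 * max(berries$semi_major) + 2 * jitter) {
    stop("grid too dense for the requested axes ranges: spacing ", spacing,
         " px cannot separate berries with semi-major up to ",
         round(max(berries$semi_major), 1), " px", call. = FALSE)
  }
  n_left <- ceiling(n_markers / 2)
  n_right <- n_markers - n_left
  mk <- function(n, x) {
    if (n < 1) return(NULL)
    tibble::tibble(cx = rep(x, n),
                   cy = 40 + marker_diameter / 2 +
                     (seq_len(n) - 1) * (marker_diameter + 40),
                   diameter = marker_diameter)
  }
  markers <- dplyr::bind_rows(mk(n_left, margin / 2),
                              mk(n_right, W - margin / 2))
  scene_spec(W, H, berries = berries, markers = markers,
             grid = c(n_rows, n_cols))
}

#' Write a scene (or any 8-bit RGB array) to a PNG or JPEG file
#'
#' PNG output is lossless and the default; JPEG (quality 95) exercises
#' robustness to the compression used by typical camera files.
#'
#' @param image `berry_scene` or numeric array `[H, W, 3]` in 0-255.
#' @param path output file; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_stage_image <- function(image, path) {
  if (inherits(image, "berry_scene")) image <- image$image
  arr <- aperm(image / 255, c(2, 1, 3))  # EBImage uses [x, y, channel]
  img <- EBImage::Image(arr, colormode = "Color")
  EBImage::writeImage(img, path, quality = 95L)
  invisible(path)
}

#' Read a stage photograph as an 8-bit RGB array
#'
#' @param path a PNG or JPEG file.
#' @return Numeric array `[H, W, 3]` with values in 0-255.
#' @export
read_stage_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2) {
    arr <- array(rep(t(img), 3), dim = c(d[2], d[1], 3))
  } else {
    arr <- aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3))
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  round(arr * 255)
}

#' Write the ground-truth table of a rendered scene to CSV
#'
#' @param scene a `berry_scene`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(scene, path) {
  stopifnot(inherits(scene, "berry_scene"))
  utils::write.csv(scene$truth, path, row.names = FALSE, na = "")
  invisible(path)
}
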