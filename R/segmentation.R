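# Classical segmentation of berries and circular size markers from a stage
# photograph: static thresholds on the HSV channels, morphological cleanup,
# hole filling and connected components. Deliberately simple and fully
# deterministic; a neural segmenter can be substituted through the pluggable
# segmenter contract (any function mapping image -> labeled components).

#' Threshold configuration for classical segmentation
#'
#' All thresholds of the HSV segmentation path live here. In `auto` mode the
#' value channel is thresholded with Otsu's method against a light background
#' (inverted for dark backgrounds, chosen from the median border-pixel
#' value); explicit hue/saturation/value windows switch the segmenter to
#' fully static thresholds. Defaults were tuned on synthetic fixtures only.
#'
#' @param background_mode `"auto"`, `"light"` or `"dark"`.
#' @param hue_lo,hue_hi optional hue window in degrees (0-360; may wrap,
#'   e.g. `hue_lo = 330, hue_hi = 30` selects reds).
#' @param sat_min optional minimum saturation (0-1) for foreground.
#' @param val_lo,val_hi optional value window (0-1) for foreground.
#' @param min_object_area components smaller than this (px) are discarded.
#' @param morph_radius radius (px) of the disk used for morphological
#'   opening and closing.
#' @param drop_border drop components touching the image border (they cannot
#'   be measured fully); dropped components are reported via a message.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(background_mode = c("auto", "light", "dark"),
                             hue_lo = NULL, hue_hi = NULL, sat_min = NULL,
                             val_lo = NULL, val_hi = NULL,
                             min_object_area = 200, morph_radius = 2,
                             drop_border = TRUE) {
  background_mode <- match.arg(background_mode)
  stopifnot(min_object_area > 0, morph_radius >= 0)
  structure(list(background_mode = background_mode,
                 hue_lo = hue_lo, hue_hi = hue_hi, sat_min = sat_min,
                 val_lo = val_lo, val_hi = val_hi,
                 min_object_area = min_object_area,
                 morph_radius = morph_radius,
                 drop_border = drop_border),
            class = "threshold_config")
}

# HSV planes (h in degrees 0-360, s and v in 0-1) from an 8-bit RGB array
image_hsv <- function(image) {
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Segment foreground components by HSV thresholding
#'
#' Pixels passing all configured channel tests form the foreground, which is
#' cleaned by morphological opening then closing with a disk of the
#' configured radius, hole-filled (specular highlights can punch holes in
#' otherwise solid fruit), and split into connected components; components
#' below the minimum area (and, by default, those touching the image border)
#' are removed.
#'
#' @param image numeric array `[H, W, 3]`, 8-bit RGB (0-255).
#' @param config a [threshold_config()].
#' @return List of logical component masks, largest first. Zero matches give
#'   an empty list.
#' @export
hsv_threshold_segment <- function(image, config = threshold_config()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  hsv <- image_hsv(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  fg <- matrix(TRUE, H, W)
  static <- !is.null(config$sat_min) || !is.null(config$val_lo) ||
    !is.null(config$val_hi) || !is.null(config$hue_lo)
  if (static) {
    if (!is.null(config$sat_min)) fg <- fg & hsv$s >= config$sat_min
    if (!is.null(config$val_lo))  fg <- fg & hsv$v >= config$val_lo
    if (!is.null(config$val_hi))  fg <- fg & hsv$v <= config$val_hi
    if (!is.null(config$hue_lo) && !is.null(config$hue_hi)) {
      if (config$hue_lo <= config$hue_hi) {
        fg <- fg & hsv$h >= config$hue_lo & hsv$h <= config$hue_hi
      } else {
        fg <- fg & (hsv$h >= config$hue_lo | hsv$h <= config$hue_hi)
      }
    }
  } else {
    mode <- config$background_mode
    if (mode == "auto") {
      border <- c(hsv$v[1, ], hsv$v[H, ], hsv$v[, 1], hsv$v[, W])
      mode <- if (stats::median(border) >= 0.5) "light" else "dark"
    }
    thr <- EBImage::otsu(EBImage::Image(t(hsv$v)), range = c(0, 1))
    fg <- if (mode == "light") hsv$v < thr else hsv$v > thr
    # saturated pixels are foreground regardless of value (bright berries on
    # a light background have high value but the background is unsaturated)
    if (mode == "light") fg <- fg | (hsv$s > 0.25 & hsv$v > 0.05)
  }
  if (config$morph_radius > 0) {
    brush <- EBImage::makeBrush(2 * config$morph_radius + 1, shape = "disc")
    m <- EBImage::closing(EBImage::opening(fg * 1L, brush), brush)
  } else {
    m <- fg * 1L
  }
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0)
  groups <- split(idx, lab[idx])
  comps <- list()
  dropped_border <- 0L
  for (g in groups) {
    if (length(g) < config$min_object_area) next
    cols <- ((g - 1L) %/% H) + 1L
    rows <- ((g - 1L) %% H) + 1L
    if (config$drop_border &&
        (min(rows) == 1L || max(rows) == H || min(cols) == 1L ||
         max(cols) == W)) {
      dropped_border <- dropped_border + 1L
      next
    }
    # store cropped to the bounding box (plus a 1-px border) for fast
    # per-object measurement; "offset" maps local back to image coordinates
    r0 <- min(rows); c0 <- min(cols)
    local <- matrix(FALSE, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
    local[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- TRUE
    comps[[length(comps) + 1L]] <- structure(local,
                                             offset = c(c0 - 2L, r0 - 2L))
  }
  if (dropped_border > 0) {
    rlang::inform(sprintf(
      "dropped %d component(s) touching the image border", dropped_border))
  }
  if (!length(comps)) return(list())
  comps[order(vapply(comps, sum, numeric(1)), decreasing = TRUE)]
}

#' Extract the outer boundary contour of a mask
#'
#' Closed polygon through the outer boundary pixel centers, traced with
#' 8-connectivity. Vertices are ordered counter-clockwise in image
#' coordinates (positive shoelace area with y pointing down) starting at the
#' topmost-then-leftmost boundary pixel. A 1-pixel mask gives a degenerate
#' single-vertex polygon.
#'
#' @param mask logical matrix, one connected component.
#' @return Numeric matrix `n x 2` with columns `x` (column) and `y` (row),
#'   1-based pixel centers.
#' @export
extract_contour <- function(mask) {
  npix <- sum(mask)
  if (npix == 0) stop("empty mask", call. = FALSE)
  if (npix == 1) {
    xy <- mask_coords(mask)
    return(cbind(x = xy[1, 1], y = xy[1, 2]))
  }
  off <- mask_offset(mask)
  m <- unclass(mask) * 1L
  oc <- EBImage::ocontour(EBImage::Image(t(m)))[[1]]
  # ocontour on the transposed image yields 0-based (x, y); back to 1-based
  # global coordinates
  p <- cbind(x = oc[, 1] + 1 + off[1], y = oc[, 2] + 1 + off[2])
  p <- unique(p)
  # start at topmost-then-leftmost
  start <- order(p[, 2], p[, 1])[1]
  if (start > 1) p <- rbind(p[start:nrow(p), , drop = FALSE],
                            p[seq_len(start - 1L), , drop = FALSE])
  if (nrow(p) >= 3 && polygon_signed_area(p) < 0) {
    p <- rbind(p[1, , drop = FALSE], p[nrow(p):2, , drop = FALSE])
  }
  p
}

#' Classify components as berries or markers
#'
#' A component is labelled `marker` iff it is circular (`4 pi A / P^2 >=
#' circularity_min`), dark (mean value channel below `darkness_max`) and of
#' plausible size (area within `[0.25, 4]` times the median area of the
#' circular-and-dark candidates). Everything else is a berry; ambiguous
#' components therefore default to berry.
#'
#' @param components list of masks from [hsv_threshold_segment()].
#' @param image the RGB array the components came from.
#' @param circularity_min minimum circularity for a marker.
#' @param darkness_max maximum mean value-channel intensity (0-1) for a
#'   marker.
#' @return Tibble with one row per component: `component`, `label`, `cx`,
#'   `cy`, `area`, `circularity`, `mean_value`, and list-columns `mask` and
#'   `contour`.
#' @export
classify_components <- function(components, image, circularity_min = 0.85,
                                darkness_max = 0.35) {
  if (!length(components)) {
    return(tibble::tibble(component = integer(), label = character(),
                          cx = numeric(), cy = numeric(), area = numeric(),
                          circularity = numeric(), mean_value = numeric(),
                          mask = list(), contour = list()))
  }
  rows <- purrr::map_dfr(seq_along(components), function(i) {
    m <- components[[i]]
    contour <- extract_contour(m)
    a <- sum(m)
    p <- mask_perimeter(contour)
    ctr <- mask_centroid(m)
    vals <- mask_image_values(image, m)
    tibble::tibble(component = i,
                   cx = ctr[["x"]], cy = ctr[["y"]], area = a,
                   circularity = if (p > 0) 4 * pi * a / p^2 else 1,
                   mean_value = mean(pmax(vals[, 1], vals[, 2], vals[, 3])) / 255,
                   mask = list(m), contour = list(contour))
  })
  cand <- rows$circularity >= circularity_min & rows$mean_value <= darkness_max
  label <- rep("berry", nrow(rows))
  if (any(cand)) {
    med <- stats::median(rows$area[cand])
    ok <- cand & rows$area >= 0.25 * med & rows$area <= 4 * med
    label[ok] <- "marker"
  }
  rows$label <- label
  rows[, c("component", "label", "cx", "cy", "area", "circularity",
           "mean_value", "mask", "contour")]
}
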