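# Per-berry colour statistics. Waxy fruit strongly reflect the background
# along the rim, so a border is eroded off the mask before any colour is
# measured; size and shape metrics always use the un-eroded mask.

#' Erode the reflective border off a mask
#'
#' Morphological erosion with a Euclidean disk. If the erosion would empty
#' the mask (small objects), the original mask is returned and the result is
#' flagged via the `eroded` attribute so downstream QC can report the
#' fallback.
#'
#' @param mask logical matrix.
#' @param radius erosion radius in px (default 10); 0 is the identity.
#' @return Logical matrix with attribute `eroded` (TRUE if erosion was
#'   applied).
#' @export
erode_interior <- function(mask, radius = 10) {
  if (!sum(mask)) stop("empty mask", call. = FALSE)
  if (radius <= 0) return(structure(mask, eroded = TRUE))
  off <- mask_offset(mask)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  er <- EBImage::erode(unclass(mask) * 1L, brush) > 0
  if (!any(er)) return(structure(mask, eroded = FALSE))
  structure(er, eroded = TRUE, offset = off)
}

#' Per-channel RGB statistics over a mask
#'
#' Mean, median and population variance of each 8-bit channel over the
#' foreground pixels. Medians use the lower-median tie rule so they stay
#' integers on integer images.
#'
#' @param image numeric array `[H, W, 3]` (0-255).
#' @param mask logical matrix within the image.
#' @return One-row tibble: `r_mean`, `g_mean`, `b_mean`, `r_median`,
#'   `g_median`, `b_median`, `r_var`, `g_var`, `b_var`, `n_pixels`.
#' @export
rgb_stats <- function(image, mask) {
  if (!sum(mask)) stop("empty mask", call. = FALSE)
  vals <- mask_image_values(image, mask)
  ch <- lapply(1:3, function(k) vals[, k])
  pvar <- function(x) mean((x - mean(x))^2)
  tibble::tibble(
    r_mean = mean(ch[[1]]), g_mean = mean(ch[[2]]), b_mean = mean(ch[[3]]),
    r_median = median_lower(ch[[1]]), g_median = median_lower(ch[[2]]),
    b_median = median_lower(ch[[3]]),
    r_var = pvar(ch[[1]]), g_var = pvar(ch[[2]]), b_var = pvar(ch[[3]]),
    n_pixels = nrow(vals))
}

#' Grayscale from channel medians
#'
#' Rec.601 luma evaluated on the per-channel medians:
#' `R_med * 0.299 + G_med * 0.587 + B_med * 0.114`. The coefficients sum to
#' 1, so gray inputs are fixed points.
#'
#' @param r_median,g_median,b_median channel medians in `[0, 255]`.
#' @return Grayscale value on the 0-255 scale.
#' @export
grayscale_from_medians <- function(r_median, g_median, b_median) {
  r_median * 0.299 + g_median * 0.587 + b_median * 0.114
}

#' Convert 8-bit sRGB to CIELAB
#'
#' Standard sRGB decoding (IEC 61966-2-1 gamma) to linear RGB, linear map to
#' CIE XYZ, then CIELAB under the D65 reference white. D65 is the native
#' white point of sRGB; it is configurable for users working with other
#' adapted whites.
#'
#' @param rgb numeric matrix `n x 3` (or length-3 vector) of 8-bit values.
#' @param white reference white XYZ (default D65, Y normalised to 1).
#' @return Matrix `n x 3` with columns `L` (0-100), `a`, `b` (signed).
#' @export
srgb_to_cielab <- function(rgb, white = c(X = 0.95047, Y = 1, Z = 1.08883)) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  c_ <- rgb / 255
  lin <- ifelse(c_ <= 0.04045, c_ / 12.92, ((c_ + 0.055) / 1.055)^2.4)
  M <- rbind(c(0.4124564, 0.3575761, 0.1804375),
             c(0.2126729, 0.7151522, 0.0721750),
             c(0.0193339, 0.1191920, 0.9503041))
  xyz <- lin %*% t(M)
  xyz <- sweep(xyz, 2, white, "/")
  d <- 6 / 29
  f <- ifelse(xyz > d^3, xyz^(1 / 3), xyz / (3 * d^2) + 4 / 29)
  out <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  out
}

#' CIELAB statistics over a mask
#'
#' Converts every foreground pixel to CIELAB and reports the per-channel
#' mean and population standard deviation. Per-pixel conversion (rather than
#' converting the mean RGB) keeps the dispersion statistics meaningful.
#'
#' @inheritParams rgb_stats
#' @return One-row tibble: `L_mean`, `a_mean`, `b_mean`, `L_sd`, `a_sd`,
#'   `b_sd`.
#' @export
lab_stats <- function(image, mask) {
  if (!sum(mask)) stop("empty mask", call. = FALSE)
  lab <- srgb_to_cielab(mask_image_values(image, mask))
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  tibble::tibble(L_mean = mean(lab[, 1]), a_mean = mean(lab[, 2]),
                 b_mean = mean(lab[, 3]),
                 L_sd = psd(lab[, 1]), a_sd = psd(lab[, 2]),
                 b_sd = psd(lab[, 3]))
}

#' HSV statistics over a mask
#'
#' Channel means with hue treated circularly: the hue mean is the direction
#' of the resultant vector of per-pixel hue angles, reported in degrees
#' `[0, 360)`, so hues straddling 0/360 average correctly.
#'
#' @inheritParams rgb_stats
#' @return One-row tibble: `h_mean` (degrees), `s_mean`, `v_mean` (0-1).
#' @export
hsv_stats <- function(image, mask) {
  if (!sum(mask)) stop("empty mask", call. = FALSE)
  hsv <- grDevices::rgb2hsv(t(mask_image_values(image, mask)),
                            maxColorValue = 255)
  ang <- hsv[1, ] * 2 * pi
  hm <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
  if (hm < 0) hm <- hm + 360
  if (hm >= 360 - 1e-9) hm <- 0
  tibble::tibble(h_mean = hm, s_mean = mean(hsv[2, ]), v_mean = mean(hsv[3, ]))
}

#' All colour metrics for one berry
#'
#' Erodes the border, then computes RGB / grayscale / HSV / CIELAB
#' statistics over the remaining pixels. Grayscale is the Rec.601 luma of
#' the channel medians; `gray_var` is the population variance of the
#' per-pixel Rec.601 gray values.
#'
#' @param image numeric array `[H, W, 3]` (0-255).
#' @param mask un-eroded berry mask.
#' @param erosion_radius border erosion radius in px (default 10).
#' @return One-row tibble combining [rgb_stats()], `grayscale`, `gray_var`,
#'   [hsv_stats()] and [lab_stats()], plus `n_pixels_used` and `eroded`.
#' @export
color_metrics <- function(image, mask, erosion_radius = 10) {
  em <- erode_interior(mask, erosion_radius)
  eroded <- attr(em, "eroded")
  rgbs <- rgb_stats(image, em)
  vals <- mask_image_values(image, em)
  gray_px <- vals[, 1] * 0.299 + vals[, 2] * 0.587 + vals[, 3] * 0.114
  dplyr::bind_cols(
    rgbs[, c("r_mean", "g_mean", "b_mean", "r_median", "g_median",
             "b_median", "r_var", "g_var", "b_var")],
    tibble::tibble(
      grayscale = grayscale_from_medians(rgbs$r_median, rgbs$g_median,
                                         rgbs$b_median),
      gray_var = mean((gray_px - mean(gray_px))^2)),
    stats::setNames(hsv_stats(image, em), c("h_mean", "s_mean", "v_mean")),
    stats::setNames(lab_stats(image, em),
                    c("L_mean", "a_star_mean", "b_star_mean",
                      "L_sd", "a_star_sd", "b_star_sd")),
    tibble::tibble(n_pixels_used = rgbs$n_pixels, eroded = eroded))
}
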