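# Scale calibration from circular markers, grid assignment, and matching of
# berries between two measurement sets by reciprocal nearest centroids.

#' Estimate the pixel-per-cm scale from detected markers
#'
#' Each marker's pixel diameter is the minimum-enclosing-circle diameter of
#' its contour (robust to small segmentation nicks). Markers deviating more
#' than 20% from the median diameter are excluded (guards against
#' mis-classified berries), and the scale is the median of the kept
#' diameters divided by the known physical diameter. With no markers an
#' uncalibrated result is returned and metrics stay in pixels.
#'
#' @param markers list of marker masks or contours (n x 2 matrices).
#' @param marker_diameter_cm known physical diameter (default 2.54 cm).
#' @return A `scale_calibration` list: `px_per_cm` (NA when uncalibrated),
#'   `marker_diameters_px`, `kept`, `marker_diameter_cm`, `n_markers_used`,
#'   `calibrated`.
#' @export
estimate_scale <- function(markers, marker_diameter_cm = 2.54) {
  stopifnot(marker_diameter_cm > 0)
  if (!length(markers)) {
    rlang::inform("no size markers detected; metrics remain in pixels")
    return(structure(list(px_per_cm = NA_real_,
                          marker_diameters_px = numeric(),
                          kept = logical(),
                          marker_diameter_cm = marker_diameter_cm,
                          n_markers_used = 0L, calibrated = FALSE),
                     class = "scale_calibration"))
  }
  diams <- vapply(markers, function(m) {
    contour <- if (is.logical(m)) extract_contour(m) else m
    2 * min_enclosing_circle(contour)$radius
  }, numeric(1))
  med <- stats::median(diams)
  kept <- abs(diams - med) <= 0.2 * med
  if (any(!kept)) {
    rlang::inform(sprintf(
      "excluded %d marker(s) deviating > 20%% from the median diameter",
      sum(!kept)))
  }
  structure(list(px_per_cm = stats::median(diams[kept]) / marker_diameter_cm,
                 marker_diameters_px = diams, kept = kept,
                 marker_diameter_cm = marker_diameter_cm,
                 n_markers_used = sum(kept), calibrated = TRUE),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  if (x$calibrated) {
    cat(sprintf("<scale_calibration> %.3f px/cm from %d marker(s)\n",
                x$px_per_cm, x$n_markers_used))
  } else {
    cat("<scale_calibration> uncalibrated (no markers)\n")
  }
  invisible(x)
}

#' Convert pixel metrics to centimetres
#'
#' Divides length-dimensioned columns by `s = px_per_cm`, area-dimensioned
#' columns by `s^2` and volume by `s^3`; dimensionless metrics are
#' untouched. Column dimension is inferred from the standard metric names.
#'
#' @param metrics tibble with `*_px` metric columns (e.g. from
#'   [shape_metrics()]).
#' @param cal a calibrated [estimate_scale()] result.
#' @return `metrics` with additional `*_cm` columns.
#' @export
to_cm <- function(metrics, cal) {
  stopifnot(inherits(cal, "scale_calibration"))
  if (!cal$calibrated) stop("calibration has no markers", call. = FALSE)
  s <- cal$px_per_cm
  powers <- c(length_px = 1, width_px = 1, perimeter_px = 1,
              area_px = 2, surface_area_px = 2, volume_px = 3)
  for (nm in names(powers)) {
    if (nm %in% names(metrics)) {
      out_nm <- sub("_px$", "_cm", nm)
      metrics[[out_nm]] <- metrics[[nm]] / s^powers[[nm]]
    }
  }
  metrics
}

#' Assign grid rows and columns from centroids
#'
#' Sorts centroids by y and starts a new row whenever the y-gap between
#' consecutive centroids exceeds the row-break threshold (half the median
#' object height by default); within each row, columns are numbered by
#' ascending x. Rows are 1-based top to bottom, columns left to right.
#'
#' @param centroids tibble or matrix with columns `cx`, `cy`.
#' @param heights per-object mask heights (px) used for the default
#'   row-break threshold; ignored when `row_break` is given.
#' @param row_break explicit y-gap threshold in px.
#' @return Tibble aligned with the input rows: `row`, `col`, plus attributes
#'   `n_rows` and `n_cols`.
#' @export
assign_grid <- function(centroids, heights = NULL, row_break = NULL) {
  cx <- centroids[["cx"]] %||% centroids[, 1]
  cy <- centroids[["cy"]] %||% centroids[, 2]
  n <- length(cx)
  stopifnot(n >= 1)
  if (is.null(row_break)) {
    if (is.null(heights)) stop("need heights or an explicit row_break",
                               call. = FALSE)
    row_break <- 0.5 * stats::median(heights)
  }
  ord <- order(cy)
  gaps <- diff(cy[ord])
  row_id <- cumsum(c(1, as.integer(gaps > row_break)))
  row <- integer(n); row[ord] <- row_id
  col <- integer(n)
  for (r in unique(row_id)) {
    idx <- which(row == r)
    col[idx][order(cx[idx])] <- seq_along(idx)
  }
  structure(tibble::tibble(row = row, col = col),
            n_rows = max(row), n_cols = max(col), row_break = row_break)
}

#' Match objects across two measurement sets by reciprocal nearest centroids
#'
#' Pair `(i, j)` is reported iff `j` is the closest B-centroid to `A_i` and
#' `i` is the closest A-centroid to `B_j`. There is no maximum-distance
#' cutoff; distances are returned so callers can filter. Ties are broken by
#' the lower index, deterministically.
#'
#' @param a,b tibbles or matrices with columns `cx`, `cy` from the same
#'   image frame.
#' @return Tibble of matched pairs `i`, `j`, `dist`, with attributes
#'   `unmatched_a` and `unmatched_b` (integer indices).
#' @export
reciprocal_match <- function(a, b) {
  ax <- a[["cx"]] %||% a[, 1]; ay <- a[["cy"]] %||% a[, 2]
  bx <- b[["cx"]] %||% b[, 1]; by <- b[["cy"]] %||% b[, 2]
  stopifnot(length(ax) >= 1, length(bx) >= 1)
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  near_b <- apply(d, 1, which.min)   # for each A_i the closest B
  near_a <- apply(d, 2, which.min)   # for each B_j the closest A
  i <- which(near_a[near_b] == seq_along(ax))
  j <- near_b[i]
  pairs <- tibble::tibble(i = as.integer(i), j = as.integer(j),
                          dist = d[cbind(i, j)])
  structure(pairs,
            unmatched_a = setdiff(seq_along(ax), pairs$i),
            unmatched_b = setdiff(seq_along(bx), pairs$j))
}
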