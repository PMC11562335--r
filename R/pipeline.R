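# End-to-end per-image driver: segment -> classify -> measure -> calibrate ->
# QC -> per-berry records, CSV and annotated images.

#' Pipeline configuration
#'
#' Bundles every tunable of the per-image pipeline. Defaults follow the
#' runtime QC rules of the method: berries with solidity below 0.95 or area
#' more than 3 standard deviations from the image mean are flagged.
#'
#' @param threshold a [threshold_config()].
#' @param marker_diameter_cm physical marker diameter (default 2.54 cm).
#' @param grid_mode assign grid rows/columns and order output by them.
#' @param solidity_qc_threshold flag berries with solidity below this.
#' @param area_sd_threshold flag berries whose area deviates more than this
#'   many within-image SDs from the image mean.
#' @param erosion_radius border erosion before colour statistics (px).
#' @param annotate write annotated overlay images in [process_image()] when
#'   an output path is supplied.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = threshold_config(),
                            marker_diameter_cm = 2.54,
                            grid_mode = TRUE,
                            solidity_qc_threshold = 0.95,
                            area_sd_threshold = 3,
                            erosion_radius = 10,
                            annotate = FALSE) {
  stopifnot(marker_diameter_cm > 0, solidity_qc_threshold > 0,
            area_sd_threshold > 0, erosion_radius >= 0)
  structure(list(threshold = threshold,
                 marker_diameter_cm = marker_diameter_cm,
                 grid_mode = grid_mode,
                 solidity_qc_threshold = solidity_qc_threshold,
                 area_sd_threshold = area_sd_threshold,
                 erosion_radius = erosion_radius,
                 annotate = annotate),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the [pipeline_config()] fields, with the threshold block
#' under `threshold:`. Missing fields take their defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(threshold_config, y$threshold %||% list())
  args <- y[setdiff(names(y), "threshold")]
  do.call(pipeline_config, c(list(threshold = thr), args))
}

#' Write a pipeline configuration to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$threshold <- Filter(Negate(is.null), unclass(lst$threshold))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Measure every berry in one stage photograph
#'
#' Runs the full pipeline on one image: HSV segmentation, berry/marker
#' classification, shape and colour measurement, scale calibration from the
#' detected markers, optional grid assignment, cm conversion and QC
#' flagging. Deterministic: identical input and configuration give identical
#' records.
#'
#' @param image path to a PNG/JPG file, a `berry_scene`, or a numeric RGB
#'   array (0-255).
#' @param config a [pipeline_config()].
#' @param image_id identifier recorded in the output; defaults to the file
#'   name (or `"image"`).
#' @param annotate_path optional path; when given (or when
#'   `config$annotate` is TRUE and this is non-NULL) an annotated PNG is
#'   written via [write_annotated()].
#' @return A `berry_records` tibble, one row per berry, ordered by
#'   `(row, col)` in grid mode and by `berry_index` otherwise. Pixel and cm
#'   columns are both always present (cm columns are NA when no markers were
#'   found). Attributes: `calibration`, `masks`, `contours`, `markers`,
#'   `obbs`.
#' @export
process_image <- function(image, config = pipeline_config(),
                          image_id = NULL, annotate_path = NULL) {
  if (is.character(image)) {
    if (is.null(image_id)) {
      image_id <- tools::file_path_sans_ext(basename(image))
    }
    image <- read_stage_image(image)
  } else if (inherits(image, "berry_scene")) {
    image <- image$image
  }
  image_id <- image_id %||% "image"
  comps <- hsv_threshold_segment(image, config$threshold)
  cls <- classify_components(comps, image)
  empty <- berry_records_prototype()
  if (!nrow(cls)) {
    rlang::warn(sprintf("no objects detected in image '%s'", image_id))
    return(empty)
  }
  markers <- cls[cls$label == "marker", ]
  berries <- cls[cls$label == "berry", ]
  cal <- if (nrow(markers)) {
    estimate_scale(markers$contour, config$marker_diameter_cm)
  } else {
    estimate_scale(list(), config$marker_diameter_cm)
  }
  if (!nrow(berries)) {
    rlang::warn(sprintf("no berries detected in image '%s'", image_id))
    return(structure(empty, calibration = cal))
  }
  shapes <- purrr::map_dfr(seq_len(nrow(berries)), function(i) {
    shape_metrics(berries$mask[[i]], contour = berries$contour[[i]])
  })
  colors <- purrr::map_dfr(berries$mask, function(m) {
    color_metrics(image, m, erosion_radius = config$erosion_radius)
  })
  rec <- dplyr::bind_cols(
    tibble::tibble(image_id = image_id,
                   berry_index = seq_len(nrow(berries)),
                   row = NA_integer_, col = NA_integer_,
                   centroid_x = berries$cx, centroid_y = berries$cy),
    shapes[, setdiff(names(shapes), "orientation_rad")], colors)
  if (config$grid_mode && nrow(rec) >= 1) {
    heights <- vapply(berries$mask, function(m) {
      xy <- mask_coords(m); diff(range(xy[, 2])) + 1
    }, numeric(1))
    ga <- assign_grid(berries[, c("cx", "cy")], heights = heights)
    rec$row <- ga$row
    rec$col <- ga$col
  }
  cm_cols <- c("length_cm", "width_cm", "perimeter_cm", "area_cm",
               "surface_area_cm", "volume_cm")
  if (cal$calibrated) {
    rec <- to_cm(rec, cal)
  } else {
    for (nm in cm_cols) rec[[nm]] <- NA_real_
  }
  rec <- qc_flags(rec,
                  solidity_threshold = config$solidity_qc_threshold,
                  area_sd_threshold = config$area_sd_threshold)
  ord <- if (config$grid_mode) order(rec$row, rec$col) else
    order(rec$berry_index)
  rec <- rec[ord, ]
  rec$berry_index <- seq_len(nrow(rec))
  obbs <- purrr::map(which(cls$label == "berry")[ord], function(i) {
    oriented_bbox(cls$mask[[i]])
  })
  out <- structure(rec,
                   calibration = cal,
                   masks = berries$mask[ord],
                   contours = berries$contour[ord],
                   markers = markers$contour,
                   obbs = obbs,
                   class = c("berry_records", class(rec)))
  rlang::inform(sprintf(
    "%s: %d berries, %d markers, %s px/cm, %d flagged",
    image_id, nrow(rec), nrow(markers),
    if (cal$calibrated) sprintf("%.2f", cal$px_per_cm) else "NA",
    sum(rec$qc_flags != "")))
  if (!is.null(annotate_path)) {
    write_annotated(image, out, annotate_path)
  }
  out
}

berry_records_prototype <- function() {
  tibble::tibble(image_id = character(), berry_index = integer(),
                 row = integer(), col = integer(),
                 centroid_x = numeric(), centroid_y = numeric(),
                 length_px = numeric(), width_px = numeric(),
                 area_px = numeric(), perimeter_px = numeric(),
                 surface_area_px = numeric(), volume_px = numeric(),
                 roundness = numeric(), solidity = numeric(),
                 r_mean = numeric(), g_mean = numeric(), b_mean = numeric(),
                 r_median = numeric(), g_median = numeric(),
                 b_median = numeric(), r_var = numeric(), g_var = numeric(),
                 b_var = numeric(), grayscale = numeric(),
                 gray_var = numeric(), h_mean = numeric(),
                 s_mean = numeric(), v_mean = numeric(),
                 L_mean = numeric(), a_star_mean = numeric(),
                 b_star_mean = numeric(), L_sd = numeric(),
                 a_star_sd = numeric(), b_star_sd = numeric(),
                 n_pixels_used = numeric(), eroded = logical(),
                 length_cm = numeric(), width_cm = numeric(),
                 perimeter_cm = numeric(), area_cm = numeric(),
                 surface_area_cm = numeric(), volume_cm = numeric(),
                 qc_flags = character())
}

#' Recompute QC flags on berry records
#'
#' `LOW_SOLIDITY` marks solidity below the threshold (typically incorrect
#' segmentation); `AREA_OUTLIER` marks areas more than `area_sd_threshold`
#' within-image standard deviations from that image's mean berry area
#' (single-berry images cannot produce it); `EROSION_FALLBACK` marks berries
#' whose colour statistics fell back to the un-eroded mask. Flags are
#' recomputed from the record values alone, so a written CSV is
#' self-consistent.
#'
#' @param records a berry-records tibble.
#' @param solidity_threshold,area_sd_threshold QC thresholds.
#' @return `records` with the `qc_flags` column (semicolon-separated) set.
#' @export
qc_flags <- function(records, solidity_threshold = 0.95,
                     area_sd_threshold = 3) {
  if (!nrow(records)) {
    records$qc_flags <- character(0)
    return(records)
  }
  flags <- purrr::map_chr(seq_len(nrow(records)), function(i) {
    f <- character()
    if (records$solidity[i] < solidity_threshold) f <- c(f, "LOW_SOLIDITY")
    same <- records$image_id == records$image_id[i]
    if (sum(same) > 1) {
      a <- records$area_px[same]
      sdev <- stats::sd(a)
      if (sdev > 0 &&
          abs(records$area_px[i] - mean(a)) > area_sd_threshold * sdev) {
        f <- c(f, "AREA_OUTLIER")
      }
    }
    if (isFALSE(records$eroded[i])) f <- c(f, "EROSION_FALLBACK")
    paste(f, collapse = ";")
  })
  records$qc_flags <- flags
  records
}

#' Write berry records to CSV
#'
#' RFC 4180 CSV with a fixed header; numeric values are written with 4
#' decimal places; rows are sorted by `(image_id, row, col, berry_index)`.
#' Zero records give a header-only file.
#'
#' @param records a berry-records tibble (possibly several images bound
#'   together).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_berry_csv <- function(records, path) {
  proto <- berry_records_prototype()
  records <- as.data.frame(records)[, names(proto), drop = FALSE]
  if (nrow(records)) {
    records <- records[order(records$image_id, records$row, records$col,
                             records$berry_index), ]
    for (nm in names(records)) {
      if (is.numeric(records[[nm]]) && !is.integer(records[[nm]])) {
        records[[nm]] <- sprintf("%.4f", records[[nm]])
        records[[nm]][records[[nm]] == "NA"] <- ""
      }
    }
  }
  utils::write.table(records, path, sep = ",", row.names = FALSE,
                     qmethod = "double", na = "", eol = "\r\n")
  invisible(path)
}

#' Read a berry CSV written by [write_berry_csv()]
#'
#' @param path CSV file.
#' @return Tibble with the standard record columns.
#' @export
read_berry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$qc_flags <- ifelse(is.na(df$qc_flags), "", as.character(df$qc_flags))
  tibble::as_tibble(df)
}

# 3x5 bitmap digits for annotation labels
.digit_font <- lapply(list(
  `0` = c("111","101","101","101","111"), `1` = c("010","110","010","010","111"),
  `2` = c("111","001","111","100","111"), `3` = c("111","001","111","001","111"),
  `4` = c("101","101","111","001","001"), `5` = c("111","100","111","001","111"),
  `6` = c("111","100","111","101","111"), `7` = c("111","001","010","010","010"),
  `8` = c("111","101","111","101","111"), `9` = c("111","101","111","001","111")
), function(rows) do.call(rbind, lapply(strsplit(rows, ""), function(r) r == "1")))

paint_pixels <- function(img, xy, color, scale = 1) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x <- round(xy[, 1]); y <- round(xy[, 2])
  ok <- x >= 1 & x <= W & y >= 1 & y <= H
  idx <- (x[ok] - 1) * H + y[ok]
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

draw_segment <- function(img, p1, p2, color) {
  n <- max(2, ceiling(2 * sqrt(sum((p2 - p1)^2))))
  t <- seq(0, 1, length.out = n)
  paint_pixels(img, cbind(p1[1] + t * (p2[1] - p1[1]),
                          p1[2] + t * (p2[2] - p1[2])), color)
}

draw_number <- function(img, number, at, color, scale = 3) {
  digits <- strsplit(as.character(number), "")[[1]]
  x0 <- at[1]
  for (d in digits) {
    glyph <- .digit_font[[d]]
    if (is.null(glyph)) next
    pos <- which(glyph, arr.ind = TRUE)
    pts <- do.call(rbind, lapply(seq_len(nrow(pos)), function(k) {
      expand.grid(x = x0 + (pos[k, 2] - 1) * scale + 0:(scale - 1),
                  y = at[2] + (pos[k, 1] - 1) * scale + 0:(scale - 1))
    }))
    img <- paint_pixels(img, as.matrix(pts), color)
    x0 <- x0 + 4 * scale
  }
  img
}

#' Write an annotated overlay image
#'
#' Paints berry mask boundaries (green; red for QC-flagged berries), marker
#' boundaries (blue), oriented bounding boxes (yellow) and berry indices
#' onto the photograph and writes a PNG.
#'
#' @param image the RGB array the records were measured from.
#' @param records a `berry_records` result of [process_image()] (its mask /
#'   contour / OBB attributes are used).
#' @param path output PNG.
#' @return `path`, invisibly.
#' @export
write_annotated <- function(image, records, path) {
  contours <- attr(records, "contours")
  obbs <- attr(records, "obbs")
  markers <- attr(records, "markers")
  img <- image
  for (i in seq_along(contours)) {
    flagged <- nzchar(records$qc_flags[i])
    col <- if (flagged) c(255, 40, 40) else c(40, 220, 40)
    img <- paint_pixels(img, contours[[i]], col)
    ob <- obbs[[i]]
    corners <- ob$corners
    for (k in 1:4) {
      img <- draw_segment(img, corners[k, ], corners[(k %% 4) + 1, ],
                          c(250, 210, 40))
    }
    img <- draw_number(img, records$berry_index[i],
                       c(records$centroid_x[i] - 5, records$centroid_y[i] - 7),
                       c(255, 255, 255))
  }
  for (mc in markers %||% list()) {
    img <- paint_pixels(img, mc, c(60, 90, 255))
  }
  write_stage_image(img, path)
  invisible(path)
}
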