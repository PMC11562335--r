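test_that("scale estimation uses the median marker with outlier rejection", {
  # exact circular contours with known diameters
  circle <- function(d) {
    th <- seq(0, 2 * pi, length.out = 200)[-1]
    cbind(x = 500 + d / 2 * cos(th), y = 500 + d / 2 * sin(th))
  }
  cal <- estimate_scale(list(circle(100)), marker_diameter_cm = 2.54)
  expect_equal(cal$px_per_cm, 100 / 2.54, tolerance = 1e-3)
  expect_equal(cal$n_markers_used, 1)

  expect_message(
    cal4 <- estimate_scale(lapply(c(100, 100, 100, 160), circle)),
    "excluded")
  expect_equal(cal4$px_per_cm, 100 / 2.54, tolerance = 1e-3)
  expect_equal(cal4$n_markers_used, 3)

  # a rasterized disk of 254 px diameter calibrates close to 100 px/cm
  cal_disk <- estimate_scale(list(disk_mask(127)))
  expect_equal(cal_disk$px_per_cm, 100, tolerance = 0.01)

  expect_message(cal0 <- estimate_scale(list()), "pixels")
  expect_false(cal0$calibrated)
  expect_true(is.na(cal0$px_per_cm))
})

test_that("cm conversion scales by metric dimension only", {
  cal <- structure(list(px_per_cm = 100, calibrated = TRUE),
                   class = "scale_calibration")
  met <- tibble::tibble(length_px = 200, area_px = 10000,
                        volume_px = 1e6, roundness = 0.8)
  out <- to_cm(met, cal)
  expect_equal(out$length_cm, 2)
  expect_equal(out$area_cm, 1)
  expect_equal(out$volume_cm, 1)
  expect_equal(out$roundness, 0.8)
  uncal <- structure(list(px_per_cm = NA_real_, calibrated = FALSE),
                     class = "scale_calibration")
  expect_error(to_cm(met, uncal), "markers")
})

test_that("grid assignment recovers the drawn grid exactly", {
  scene <- render_scene(make_grid_spec(5, 6, seed = 8))
  tr <- scene$truth[scene$truth$class == "berry", ]
  ga <- assign_grid(tr[, c("cx", "cy")], heights = tr$width_px)
  expected <- tibble::tibble(row = rep(1:5, each = 6),
                             col = rep(1:6, times = 5))
  expect_equal(ga$row, expected$row)
  expect_equal(ga$col, expected$col)
  expect_equal(attr(ga, "n_rows"), 5)
  expect_equal(attr(ga, "n_cols"), 6)

  single <- assign_grid(tibble::tibble(cx = 10, cy = 20), heights = 30)
  expect_equal(c(single$row, single$col), c(1, 1))
})

test_that("grid assignment is invariant to input order", {
  scene <- render_scene(make_grid_spec(3, 4, seed = 12))
  tr <- scene$truth[scene$truth$class == "berry", ]
  perm <- withr::with_seed(1, sample(nrow(tr)))
  ga1 <- assign_grid(tr[, c("cx", "cy")], heights = tr$width_px)
  ga2 <- assign_grid(tr[perm, c("cx", "cy")], heights = tr$width_px[perm])
  expect_equal(ga2$row, ga1$row[perm])
  expect_equal(ga2$col, ga1$col[perm])
})

test_that("reciprocal matching handles identity, shift and asymmetry", {
  a <- tibble::tibble(cx = c(10, 60, 110), cy = c(5, 5, 5))
  mm <- reciprocal_match(a, a)
  expect_equal(mm$i, 1:3)
  expect_equal(mm$j, 1:3)
  expect_equal(mm$dist, rep(0, 3))

  b <- dplyr::mutate(a, cx = cx + 1)
  mm2 <- reciprocal_match(a, b)
  expect_equal(mm2$i, mm2$j)

  # the spec's asymmetric toy case: one B point between two A points
  a3 <- tibble::tibble(cx = c(0, 10), cy = c(0, 0))
  b3 <- tibble::tibble(cx = 4, cy = 0)
  mm3 <- reciprocal_match(a3, b3)
  expect_equal(nrow(mm3), 1)
  expect_equal(c(mm3$i, mm3$j), c(1, 1))
  expect_equal(attr(mm3, "unmatched_a"), 2L)
  expect_length(attr(mm3, "unmatched_b"), 0)
})

test_that("reciprocal matching equals brute force and is symmetric", {
  brute <- function(a, b) {
    pairs <- list()
    for (i in seq_len(nrow(a))) {
      di <- sqrt((b$cx - a$cx[i])^2 + (b$cy - a$cy[i])^2)
      j <- which.min(di)
      dj <- sqrt((a$cx - b$cx[j])^2 + (a$cy - b$cy[j])^2)
      if (which.min(dj) == i) pairs[[length(pairs) + 1]] <- c(i, j)
    }
    do.call(rbind, pairs)
  }
  withr::with_seed(99, {
    for (k in 1:10) {
      na <- sample(1:40, 1); nb <- sample(1:40, 1)
      a <- tibble::tibble(cx = runif(na, 0, 500), cy = runif(na, 0, 500))
      b <- tibble::tibble(cx = runif(nb, 0, 500), cy = runif(nb, 0, 500))
      mm <- reciprocal_match(a, b)
      bf <- brute(a, b)
      expect_equal(cbind(mm$i, mm$j), unname(bf))
      # symmetry: matching B to A transposes the pairs
      rev <- reciprocal_match(b, a)
      expect_equal(cbind(rev$j, rev$i)[order(rev$j), , drop = FALSE],
                   cbind(mm$i, mm$j))
    }
  })
})

test_that("cm-denominated outputs are resolution-invariant", {
  spec <- make_grid_spec(2, 2, spacing = 150, n_markers = 2,
                         marker_diameter = 80, seed = 21)
  rec1 <- quiet_process(render_scene(spec), pipeline_config())
  rec2 <- quiet_process(render_scene(scale_spec(spec, 2)),
                        pipeline_config())
  expect_equal(nrow(rec1), nrow(rec2))
  ord1 <- order(rec1$row, rec1$col); ord2 <- order(rec2$row, rec2$col)
  expect_equal(rec2$length_cm[ord2], rec1$length_cm[ord1], tolerance = 0.01)
  expect_equal(rec2$width_cm[ord2], rec1$width_cm[ord1], tolerance = 0.01)
  expect_equal(rec2$area_cm[ord2], rec1$area_cm[ord1], tolerance = 0.01)
})
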