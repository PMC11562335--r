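test_that("principal orientation recovers the drawn major axis", {
  m0 <- rasterize_ellipse_mask(100, 50, 0)
  expect_lt(min(principal_orientation(m0), pi - principal_orientation(m0)),
            0.01)
  m30 <- rasterize_ellipse_mask(100, 50, 30)
  expect_equal(principal_orientation(m30), pi / 6, tolerance = 0.01)
  # a disk is isotropic; the tie-break gives 0
  expect_equal(principal_orientation(disk_mask(40)), 0)
})

test_that("oriented bounding box matches drawn axes and hand counts", {
  for (rot in c(0, 30, 75)) {
    ob <- oriented_bbox(rasterize_ellipse_mask(100, 50, rot))
    expect_equal(ob$length, 200, tolerance = 2 / 200 * 1.5)
    expect_equal(ob$width, 100, tolerance = 2 / 100 * 1.5)
    expect_gte(ob$length, ob$width)
  }
  obd <- oriented_bbox(disk_mask(50))
  expect_equal(obd$length, 100, tolerance = 0.02)
  expect_equal(obd$width, 100, tolerance = 0.02)
  obr <- oriented_bbox(rect_mask(10, 4), angle = pi / 2)
  expect_equal(obr$length, 10)
  expect_equal(obr$width, 4)
})

test_that("mask area counts pixels and shrinks under pixel removal", {
  expect_equal(mask_area(square_mask(10)), 100)
  expect_equal(mask_area(disk_mask(100)), pi * 100^2,
               tolerance = 0.01)
  full <- rasterize_ellipse_mask(50, 40)
  notched <- full
  notched[20:40, 45:60] <- FALSE
  expect_lt(mask_area(notched), mask_area(full))
  expect_error(mask_area(matrix(FALSE, 3, 3)), "empty")
})

test_that("solidity separates convex from notched shapes", {
  expect_gte(solidity(rasterize_ellipse_mask(100, 50, 20)), 0.99)
  expect_equal(solidity(square_mask(50)), 1, tolerance = 0.01)
  # wedge notch cut toward the centroid drops solidity below the QC gate
  spec <- scene_spec(260, 260,
                     berries = berry_spec(130, 130, 50, 40, rotation = 0,
                                          notch_depth = 30))
  scene <- render_scene(spec)
  comps <- hsv_threshold_segment(scene$image)
  expect_length(comps, 1)
  expect_lt(solidity(comps[[1]]), 0.95)
})

test_that("roundness matches circle, ellipse and square geometry", {
  expect_equal(roundness_iso(disk_mask(100)), 1, tolerance = 0.03)
  expect_equal(roundness_iso(rasterize_ellipse_mask(100, 50)), 0.5,
               tolerance = 0.03)
  expect_equal(roundness_iso(square_mask(100)), 1 / sqrt(2),
               tolerance = 0.03)
})

test_that("width profile follows chord lengths and rectangle extents", {
  pr <- width_profile(disk_mask(50), 0)
  expect_equal(pr$h, 99)  # strict pixel-center inclusion: rows |y| < 50
  expect_equal(max(pr$widths), 99, tolerance = 1e-9)
  expect_lt(pr$widths[1], 25)
  # interior rows track 2*sqrt(r^2 - d^2) within a pixel
  mid <- ceiling(pr$h / 2)
  for (k in c(-30, 0, 30)) {
    expect_equal(pr$widths[mid + k], 2 * sqrt(50^2 - k^2),
                 tolerance = 2 / (2 * sqrt(50^2 - k^2)))
  }
  prr <- width_profile(rect_mask(10, 4), pi / 2)
  expect_equal(prr$h, 10)
  expect_true(all(prr$widths == 4))
})

test_that("width profile is stable under mask rotation", {
  # both the aligned and the rotated profile track the analytic chords
  # 2*b*sqrt(1 - (d/a)^2) away from the poles, where chord slope diverges
  chord_check <- function(prof, a = 100, b = 60) {
    mid <- (1 + prof$h) / 2
    for (i in seq_len(prof$h)) {
      d <- abs(i - mid)
      if (d > a - 6) next
      expect_lt(abs(prof$widths[i] - 2 * b * sqrt(1 - (d / a)^2)), 2)
    }
  }
  p0 <- width_profile(rasterize_ellipse_mask(100, 60, 0))
  p35 <- width_profile(rasterize_ellipse_mask(100, 60, 35))
  expect_lte(abs(p0$h - p35$h), 2)
  chord_check(p0)
  chord_check(p35)
})

test_that("volume estimator: closed forms, regression bound, convergence", {
  # constant profile = stack of unit cylinders
  prof <- structure(list(angle = 0, h = 10, widths = rep(2, 10)),
                    class = "width_profile")
  expect_equal(volume_stacked_cylinders(prof), 10 * pi)
  # digital masks at working resolution stay within 1% of the spheroid
  for (ax in list(c(100, 60), c(100, 100), c(120, 40))) {
    pr <- width_profile(rasterize_ellipse_mask(ax[1], ax[2]), 0)
    ref <- spheroid_reference(ax[1], ax[2])
    expect_lt(abs(volume_stacked_cylinders(pr) - ref$volume) / ref$volume,
              0.01)
  }
  # discretization bias vanishes with resolution
  pr_big <- width_profile(rasterize_ellipse_mask(500, 300), 0)
  ref_big <- spheroid_reference(500, 300)
  expect_lt(abs(volume_stacked_cylinders(pr_big) - ref_big$volume) /
              ref_big$volume, 0.0005)
})

test_that("surface estimator: cylinder closed form and spheroid bound", {
  r <- 2; h <- 10
  prof <- structure(list(angle = 0, h = h, widths = rep(2 * r, h)),
                    class = "width_profile")
  expect_equal(surface_area_frustums(prof),
               2 * pi * r^2 + 2 * pi * r * (h - 1))
  for (ax in list(c(100, 100), c(100, 60))) {
    pr <- width_profile(rasterize_ellipse_mask(ax[1], ax[2]), 0)
    ref <- spheroid_reference(ax[1], ax[2])
    expect_lt(abs(surface_area_frustums(pr) - ref$surface) / ref$surface,
              0.05)
  }
})

test_that("spheroid reference evaluates its closed forms", {
  expect_equal(spheroid_reference(1, 1), list(volume = 4 * pi / 3,
                                              surface = 4 * pi))
  s <- spheroid_reference(2, 1)
  expect_equal(s$volume, 8 * pi / 3)
  e <- sqrt(1 - 1 / 4)
  expect_equal(s$surface, 2 * pi * (1 + (2 / e) * asin(e)))
  expect_equal(s$surface, 21.48, tolerance = 1e-3)
})

test_that("shape metrics are rotation-invariant within tolerance", {
  mets <- purrr::map_dfr(c(0, 45, 120), function(rot) {
    shape_metrics(rasterize_ellipse_mask(100, 60, rot))
  })
  spread <- function(x) (max(x) - min(x)) / mean(x)
  expect_lt(spread(mets$length_px), 0.02)
  expect_lt(spread(mets$width_px), 0.02)
  expect_lt(spread(mets$area_px), 0.02)
  expect_lt(spread(mets$perimeter_px), 0.02)
  expect_lt(spread(mets$volume_px), 0.05)
  expect_lt(spread(mets$surface_area_px), 0.05)
  expect_lt(spread(mets$roundness), 0.05)
})

test_that("metrics obey the scaling laws", {
  m1 <- shape_metrics(rasterize_ellipse_mask(60, 40))
  m2 <- shape_metrics(rasterize_ellipse_mask(120, 80))
  expect_equal(m2$area_px / m1$area_px, 4, tolerance = 0.01)
  expect_equal(m2$volume_px / m1$volume_px, 8, tolerance = 0.01)
  expect_equal(m2$perimeter_px / m1$perimeter_px, 2, tolerance = 0.01)
})

test_that("length >= width and ratios stay in range across shapes", {
  shapes <- list(disk_mask(30), square_mask(40),
                 rasterize_ellipse_mask(80, 25, 62), rect_mask(9, 21))
  for (m in shapes) {
    sm <- shape_metrics(m)
    expect_gte(sm$length_px, sm$width_px)
    expect_gt(sm$roundness, 0); expect_lte(sm$roundness, 1.01)
    expect_gt(sm$solidity, 0);  expect_lte(sm$solidity, 1.01)
    expect_lte(sm$area_px, sm$length_px * sm$width_px)
  }
})
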