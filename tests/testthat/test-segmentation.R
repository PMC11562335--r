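test_that("a clean synthetic scene yields one component per object", {
  scene <- render_scene(make_grid_spec(5, 6, seed = 2))
  comps <- hsv_threshold_segment(scene$image)
  expect_length(comps, 36)
  # largest-first ordering
  areas <- vapply(comps, sum, numeric(1))
  expect_equal(areas, sort(areas, decreasing = TRUE))
})

test_that("a uniform image has no components", {
  img <- array(200, dim = c(120, 120, 3))
  expect_length(hsv_threshold_segment(img), 0)
})

test_that("interior holes are filled before measurement", {
  mask <- disk_mask(40)
  img <- patch_image(mask, fg = c(150, 20, 30))
  # punch a 3-px background-coloured hole in the middle of the berry
  ctr <- round(dim(img)[1] / 2)
  for (ch in 1:3) img[ctr + (-1:1), ctr + (-1:1), ch] <- 245
  comps <- hsv_threshold_segment(img)
  expect_length(comps, 1)
  expect_equal(sum(comps[[1]]), sum(mask))
  expect_gte(solidity(comps[[1]]), 0.99)
})

test_that("pixel-wise F1 against ground truth exceeds 0.98", {
  scene <- render_scene(make_grid_spec(3, 4, seed = 9, shading = 0.2))
  comps <- hsv_threshold_segment(scene$image)
  H <- dim(scene$image)[1]; W <- dim(scene$image)[2]
  pred <- matrix(FALSE, H, W)
  for (m in comps) {
    xy <- berrymorph:::mask_coords(m)
    pred[cbind(xy[, 2], xy[, 1])] <- TRUE
  }
  truth <- scene$image[, , 1] != 245 | scene$image[, , 2] != 245 |
    scene$image[, , 3] != 245
  tp <- sum(pred & truth)
  f1 <- 2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
  expect_gte(f1, 0.98)
})

test_that("segmentation is deterministic", {
  scene <- small_scene(seed = 4)
  c1 <- hsv_threshold_segment(scene$image)
  c2 <- hsv_threshold_segment(scene$image)
  expect_identical(c1, c2)
})

test_that("components touching the border are dropped and reported", {
  img <- array(245, dim = c(100, 100, 3))
  for (ch in 1:3) {
    img[1:30, 40:60, ch] <- c(150, 20, 30)[ch]   # touches top border
    img[60:80, 40:60, ch] <- c(150, 20, 30)[ch]  # interior
  }
  expect_message(comps <- hsv_threshold_segment(img), "border")
  expect_length(comps, 1)
})

test_that("markers and berries are told apart", {
  scene <- render_scene(make_grid_spec(5, 6, seed = 2))
  comps <- hsv_threshold_segment(scene$image)
  cls <- classify_components(comps, scene$image)
  expect_equal(sum(cls$label == "marker"), 6)
  expect_equal(sum(cls$label == "berry"), 30)

  # a single black disk with no berries is a marker
  disk <- disk_mask(40)
  img <- patch_image(disk, fg = c(18, 18, 18))
  cls1 <- classify_components(hsv_threshold_segment(img), img)
  expect_equal(cls1$label, "marker")

  # a black 2:1 ellipse fails the circularity gate and stays a berry
  ell <- rasterize_ellipse_mask(60, 30)
  img2 <- patch_image(ell, fg = c(18, 18, 18))
  cls2 <- classify_components(hsv_threshold_segment(img2), img2)
  expect_equal(cls2$label, "berry")
  expect_lt(cls2$circularity, 0.85)
})

test_that("classification is invariant to a quarter-turn of the image", {
  scene <- small_scene(seed = 6)
  img <- scene$image
  rot <- array(0, dim = c(dim(img)[2], dim(img)[1], 3))
  for (ch in 1:3) rot[, , ch] <- t(img[dim(img)[1]:1, , ch])
  cls <- classify_components(hsv_threshold_segment(img), img)
  clsr <- classify_components(hsv_threshold_segment(rot), rot)
  expect_equal(table(cls$label), table(clsr$label))
})

test_that("contour convention: start vertex, orientation and degeneracy", {
  sq <- square_mask(10)
  ct <- extract_contour(sq)
  # first vertex is the topmost-then-leftmost boundary pixel
  expect_equal(unname(ct[1, ]), c(4, 4))
  expect_equal(nrow(ct), 36)
  expect_gt(berrymorph:::polygon_signed_area(ct), 0)

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  ct1 <- extract_contour(one)
  expect_equal(nrow(ct1), 1)
  expect_equal(mask_perimeter(ct1), 0)

  expect_error(extract_contour(matrix(FALSE, 4, 4)), "empty")
})

test_that("perimeter convention is exact on squares and near-true on disks", {
  expect_equal(mask_perimeter(square_mask(10)), 36)
  p <- mask_perimeter(disk_mask(100))
  expect_lt(abs(p - 2 * pi * 100) / (2 * pi * 100), 0.03)
})

test_that("cropped masks with offsets measure identically to full frames", {
  full <- matrix(FALSE, 200, 260)
  full[61:140, 101:220] <- rasterize_ellipse_mask(60, 40,
                                                  canvas = c(120, 80))
  img <- patch_image(full, fg = c(140, 30, 40))
  comps <- hsv_threshold_segment(img)
  expect_length(comps, 1)
  cropped <- comps[[1]]
  expect_false(is.null(attr(cropped, "offset")))
  # rebuild the same component on the full frame and compare measurements
  xy <- berrymorph:::mask_coords(cropped)
  full2 <- matrix(FALSE, 200, 260)
  full2[cbind(xy[, 2], xy[, 1])] <- TRUE
  expect_equal(shape_metrics(cropped), shape_metrics(full2))
  expect_equal(color_metrics(img, cropped), color_metrics(img, full2))
  ctr <- berrymorph:::mask_centroid(cropped)
  expect_equal(unname(ctr), c(160.5, 100.5), tolerance = 1e-6)
})
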