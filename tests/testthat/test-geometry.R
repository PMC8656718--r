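# Tilt calibration: view angles, the image-to-object proportion map, the
# fitted homography and raster warping.

test_that("pixel row offsets map to view angles", {
  cam <- camera_model(1500, 2000, beta_max = 30 * pi / 180)
  expect_equal(pixel_to_view_angle(0, cam), 0)
  expect_equal(pixel_to_view_angle(cam$h_max_px, cam), cam$beta_max)
  expect_equal(pixel_to_view_angle(-cam$h_max_px, cam), -cam$beta_max)
  # mid-frame pixel: direct trig evaluation
  expect_equal(pixel_to_view_angle(500, cam), atan(0.5 * tan(30 * pi / 180)),
               tolerance = 1e-12)
  expect_true(abs(pixel_to_view_angle(700, cam)) <= cam$beta_max)
})

test_that("image-to-object map: identity at zero tilt, fixed center row", {
  cam <- camera_model(1500, 2000, beta_max = 30 * pi / 180)
  flat <- device_orientation(0)
  pts <- cbind(runif(50, -700, 700), runif(50, -900, 900))
  expect_equal(image_to_object_point(pts, flat, cam), pts, tolerance = 1e-12)
  tilt <- device_orientation(20 * pi / 180)
  ctr <- cbind(seq(-700, 700, length.out = 9), 0)
  expect_equal(image_to_object_point(ctr, tilt, cam), ctr, tolerance = 1e-12)
})

test_that("image-to-object proportions match the per-half trig factors", {
  cam <- camera_model(1500, 2000, beta_max = 30 * pi / 180)
  alpha <- 15 * pi / 180
  orient <- device_orientation(alpha)
  # upper-half point, factors written out branch by branch
  p <- c(300, 500)
  beta <- atan(500 * tan(cam$beta_max) / cam$h_max_px)
  expect_equal(
    image_to_object_point(p, orient, cam)[1, ],
    c(300 * cos(alpha) * cos(beta) / cos(alpha - beta),
      500 * cos(beta) / cos(alpha - beta)),
    tolerance = 1e-9)
  # lower-half point uses cos(alpha + |beta|)
  q <- c(300, -500)
  expect_equal(
    image_to_object_point(q, orient, cam)[1, ],
    c(300 * cos(alpha) * cos(beta) / cos(alpha + beta),
      -500 * cos(beta) / cos(alpha + beta)),
    tolerance = 1e-9)
  # flipping the tilt sign swaps the upper/lower correction factors
  up <- image_to_object_point(c(120, 400), orient, cam)
  dn <- image_to_object_point(c(120, -400), device_orientation(-alpha), cam)
  expect_equal(up[1, 1], dn[1, 1], tolerance = 1e-12)
  expect_equal(up[1, 2], -dn[1, 2], tolerance = 1e-12)
})

test_that("vertical scale factor is continuous and finite over the frame", {
  cam <- camera_model(1500, 2000, beta_max = 33 * pi / 180)
  orient <- device_orientation(25 * pi / 180)
  y <- setdiff(seq(-cam$h_max_px, cam$h_max_px, length.out = 2001), 0)
  obj <- image_to_object_point(cbind(0, y), orient, cam)
  fac <- obj[, 2] / y
  expect_true(all(is.finite(fac)))
  expect_lt(max(abs(diff(fac))), 1e-2)
  # limit at the center row is 1/cos(alpha)
  tiny <- image_to_object_point(c(0, 1e-6), orient, cam)
  expect_equal(tiny[1, 2] / 1e-6, 1 / cos(25 * pi / 180), tolerance = 1e-6)
})

test_that("tilt degeneracy raises an error", {
  cam <- camera_model(1000, 1000, beta_max = 33 * pi / 180)
  steep <- device_orientation(80 * pi / 180)
  expect_error(image_to_object_point(c(0, -cam$h_max_px), steep, cam),
               "degenerate")
})

test_that("4-point homography is exact and rejects degenerate input", {
  sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  expect_equal(unclass(fit_homography(sq, sq)), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  m2 <- fit_homography(sq, 2 * sq)
  expect_equal(unclass(m2), diag(c(2, 2, 1)) / 1, tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(3)
  src <- sq * 50 + matrix(runif(8, -5, 5), 4, 2)
  dst <- sq * 40 + matrix(runif(8, -8, 8), 4, 2)
  m <- fit_homography(src, dst)
  expect_equal(map_points(m, src), dst, tolerance = 1e-8)
  expect_error(fit_homography(rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 1)), sq),
               "collinear")
})

test_that("depression map reproduces the analytic point map everywhere", {
  cam <- camera_model(492, 656, beta_max = 33 * pi / 180)
  orient <- device_orientation(18 * pi / 180)
  m <- build_depression_map(orient, cam)
  set.seed(11)
  pts <- cbind(runif(100, -240, 240), runif(100, -320, 320))
  expect_equal(map_points(m, pts), image_to_object_point(pts, orient, cam),
               tolerance = 1e-6)
  ident <- build_depression_map(device_orientation(0), cam)
  expect_equal(unclass(ident), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("raster warping: identity, translation, inverse round trip", {
  set.seed(4)
  img <- array(runif(100 * 80 * 3), c(100, 80, 3))
  ident <- planar_map(diag(3))
  out <- apply_map(img, ident)
  expect_equal(out, img, tolerance = 1e-12, ignore_attr = TRUE)
  # translation with expanded canvas conserves content
  tr <- planar_map(matrix(c(1, 0, 5, 0, 1, -3, 0, 0, 1), 3, 3, byrow = TRUE))
  w <- apply_map(img, tr, canvas = "bbox")
  expect_equal(sum(w), sum(img), tolerance = 1e-3)
  # forward then inverse warp restores a smooth image away from borders
  sm <- outer(1:100, 1:80, function(r, c) 0.5 + 0.4 * sin(r / 12) * cos(c / 9))
  m <- build_depression_map(device_orientation(15 * pi / 180),
                            camera_model(80, 100))
  rt <- apply_map(apply_map(sm, m), invert_map(m))
  mae <- mean(abs(rt[15:85, 15:65] - sm[15:85, 15:65])) * 255
  expect_lt(mae, 2)
  expect_error(apply_map(img, tr, max_px = 10), "exceeds")
})

test_that("rotation: identity at zero, quarter turns compose to a flip", {
  set.seed(5)
  img <- matrix(runif(60 * 60), 60, 60)
  expect_equal(rotate_upright(img, 0), img, tolerance = 1e-12,
               ignore_attr = TRUE)
  r2 <- rotate_upright(rotate_upright(img, pi / 2, expand = FALSE), pi / 2,
                       expand = FALSE)
  expect_equal(dim(r2), dim(img))
  expect_equal(unclass(r2), img[60:1, 60:1], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("orientation records validate and normalize their angles", {
  expect_error(device_orientation(pi / 2), "alpha")
  expect_equal(device_orientation(0, 3 * pi / 2)$gamma, -pi / 2)
  expect_error(camera_model(100, 100, beta_max = pi / 2))
})
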