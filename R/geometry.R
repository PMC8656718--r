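# Tilt calibration for hand-held plant images.
#
# A hand-held shot is taken with the optical axis pitched by the depression
# angle alpha and the device rolled by the rotation angle gamma, both read
# from the phone accelerometer. The pipeline first rotates the raster so the
# zenith points up, then applies a marker-free perspective correction that
# maps the tilted image onto the vertical object plane through the plant,
# producing an approximate orthographic front view. The correction needs no
# scene markers: it is derived from alpha and the camera's vertical field of
# view alone.
#
# Centered coordinates are used for all point maps: origin at the raster
# center, x to the right, y up (so y = cy - row).

#' Device orientation record
#'
#' @param alpha Depression angle in radians: angle between the screen normal
#'   and the horizontal plane. Must satisfy `|alpha| < pi/2`.
#' @param gamma Rotation angle in radians: in-plane angle between the screen
#'   y-axis and the zenith. Normalized to `(-pi, pi]`.
#' @return Object of class `device_orientation`.
#' @export
device_orientation <- function(alpha = 0, gamma = 0) {
  stopifnot(is.finite(alpha), is.finite(gamma))
  if (abs(alpha) >= pi / 2)
    stop("|alpha| must be < pi/2", call. = FALSE)
  gamma <- ((gamma + pi) %% (2 * pi)) - pi
  if (gamma == -pi) gamma <- pi
  structure(list(alpha = alpha, gamma = gamma), class = "device_orientation")
}

#' Pinhole camera model
#'
#' The implicit pinhole: a pixel `h'` above the center row is seen under the
#' view angle `beta = atan(h' tan(beta_max) / h_max_px)`, where `beta_max` is
#' the half vertical field of view and `h_max_px` half the vertical
#' resolution. The effective distance `D = h_max_px / tan(beta_max)` places
#' the image plane in pixel units.
#'
#' @param image_width_px,image_height_px Raster size in pixels.
#' @param beta_max Half vertical field of view, radians, in `(0, pi/2)`.
#'   Default 33 degrees, typical for a phone main camera.
#' @return Object of class `camera_model` with fields `beta_max`, `h_max_px`,
#'   `D`, `image_width_px`, `image_height_px`.
#' @export
camera_model <- function(image_width_px, image_height_px,
                         beta_max = 33 * pi / 180) {
  stopifnot(image_width_px >= 1, image_height_px >= 1,
            beta_max > 0, beta_max < pi / 2)
  h_max <- image_height_px / 2
  structure(list(
    beta_max = beta_max,
    h_max_px = h_max,
    D = h_max / tan(beta_max),
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px)
  ), class = "camera_model")
}

#' View angle of a pixel row offset
#'
#' @param h_prime Signed vertical offset from the center row, pixels
#'   (positive up). Vectorized.
#' @param cam A [camera_model()].
#' @return Signed view angle beta in radians; `beta = beta_max` at
#'   `h_prime = h_max_px`.
#' @export
pixel_to_view_angle <- function(h_prime, cam) {
  atan(h_prime * tan(cam$beta_max) / cam$h_max_px)
}

#' Map image-plane points to the vertical object plane
#'
#' For a point at centered image coordinates `(x', y')` seen under view angle
#' `beta`, the object-plane point is recovered by dividing out the
#' tilt-induced proportions: vertically `y = y' cos(beta) / cos(alpha - beta)`
#' and horizontally `x = x' cos(alpha) cos(beta) / cos(alpha - beta)`, with
#' `beta` signed so that the lower image half picks up the `cos(alpha + |beta|)`
#' factor. `alpha = 0` gives the identity and the center row is fixed for
#' every alpha.
#'
#' @param p Numeric matrix `n x 2` (or length-2 vector) of centered image
#'   coordinates `(x, y)`, y up.
#' @param orient A [device_orientation()] (only `alpha` is used).
#' @param cam A [camera_model()].
#' @param eps Degeneracy tolerance: error when `cos(alpha - beta) <= eps`
#'   (object plane seen edge-on at this tilt).
#' @return Matrix `n x 2` of object-plane coordinates.
#' @export
image_to_object_point <- function(p, orient, cam, eps = 1e-6) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  beta <- pixel_to_view_angle(p[, 2], cam)
  denom <- cos(orient$alpha - beta)
  if (any(denom <= eps))
    stop("object plane degenerate at this tilt: cos(alpha - beta) <= eps",
         call. = FALSE)
  f <- cos(beta) / denom
  cbind(p[, 1] * cos(orient$alpha) * f, p[, 2] * f)
}

#' Fit an exact 4-point homography
#'
#' Direct linear solve of the 8 projective parameters from 4 point
#' correspondences (bottom-right entry fixed to 1, with a Frobenius fallback
#' when it vanishes). The returned map reproduces the correspondences
#' exactly.
#'
#' @param src,dst `4 x 2` matrices of centered coordinates.
#' @return A `planar_map`: scale-normalized invertible 3x3 matrix.
#' @export
fit_homography <- function(src, dst) {
  stopifnot(nrow(src) == 4, nrow(dst) == 4)
  collinear <- function(p) {
    for (tri in utils::combn(4, 3, simplify = FALSE)) {
      a <- p[tri[2], ] - p[tri[1], ]; b <- p[tri[3], ] - p[tri[1], ]
      if (abs(a[1] * b[2] - a[2] * b[1]) < 1e-9) return(TRUE)
    }
    FALSE
  }
  if (collinear(src) || collinear(dst))
    stop("degenerate correspondences: 3 points are collinear", call. = FALSE)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b),
                error = function(e) stop("degenerate correspondences: ",
                                         conditionMessage(e), call. = FALSE))
  planar_map(matrix(c(h, 1), 3, 3, byrow = TRUE))
}

#' @rdname fit_homography
#' @param m Numeric 3x3 matrix with nonzero determinant.
#' @export
planar_map <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)), all(is.finite(m)))
  if (abs(det(m)) < 1e-12)
    stop("planar map must be invertible", call. = FALSE)
  if (abs(m[3, 3]) > 1e-8) m <- m / m[3, 3]
  else m <- m / sqrt(sum(m^2))
  structure(m, class = c("planar_map", "matrix"))
}

#' Apply or invert a planar map on points
#'
#' @param m A `planar_map`.
#' @param pts `n x 2` matrix of centered coordinates.
#' @return Transformed `n x 2` matrix (`map_points`), or the inverse map.
#' @export
map_points <- function(m, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  h <- cbind(pts, 1) %*% t(unclass(m))
  h[, 1:2, drop = FALSE] / h[, 3]
}

#' @rdname map_points
#' @export
invert_map <- function(m) planar_map(solve(unclass(m)))

#' Marker-free depression-angle correction map
#'
#' Synthesizes the four correspondences at the image corners through
#' [image_to_object_point()] and fits the image-to-object homography. The
#' analytic point map is itself exactly projective, so the fitted map
#' reproduces it everywhere, not only at the corners. At `alpha = 0` the
#' identity is returned.
#'
#' @inheritParams image_to_object_point
#' @return A `planar_map` sending centered image coordinates to centered
#'   object-plane coordinates; warping a full frame with it yields the
#'   approximate orthographic front view.
#' @export
build_depression_map <- function(orient, cam, eps = 1e-6) {
  w2 <- (cam$image_width_px - 1) / 2
  h2 <- (cam$image_height_px - 1) / 2
  corners <- rbind(c(-w2, h2), c(w2, h2), c(-w2, -h2), c(w2, -h2))
  fit_homography(corners, image_to_object_point(corners, orient, cam, eps))
}

#' Warp a raster through a planar map
#'
#' Inverse-mapped bilinear resampling: output pixel `x` takes the value of
#' the input at `m^{-1}(x)`. With `canvas = "same"` the output grid equals
#' the input grid; with `"bbox"` the canvas grows to the transformed bounding
#' quadrilateral (attribute `origin` records the centered coordinates of the
#' new canvas center in map-output space). The attribute `row_scale` records,
#' per output row, the local vertical magnification relative to the input,
#' i.e. the factor by which the mm-per-px scale of that row changed.
#'
#' @param img RGB array, gray matrix or logical mask (masks are warped as
#'   floats and re-thresholded at 0.5).
#' @param m A `planar_map` taking input coordinates to output coordinates.
#' @param canvas `"same"` or `"bbox"`.
#' @param fill Background fill value (default 0, black).
#' @param max_px Error if the output canvas would exceed this pixel count.
#' @return Warped raster of the same kind as the input.
#' @export
apply_map <- function(img, m, canvas = c("same", "bbox"), fill = 0,
                      max_px = 4e7) {
  canvas <- match.arg(canvas)
  is_mask <- is.logical(img)
  if (is_mask) img <- matrix(as.numeric(img), nrow(img), ncol(img))
  d <- dim(img)
  nr <- d[1L]; nc <- d[2L]
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  ox <- 0; oy <- 0; onr <- nr; onc <- nc
  if (canvas == "bbox") {
    crn <- rbind(c(1 - cx, cy - 1), c(nc - cx, cy - 1),
                 c(1 - cx, cy - nr), c(nc - cx, cy - nr))
    tc <- map_points(m, crn)
    onc <- ceiling(diff(range(tc[, 1]))) + 1L
    onr <- ceiling(diff(range(tc[, 2]))) + 1L
    ox <- mean(range(tc[, 1])); oy <- mean(range(tc[, 2]))
  }
  if (as.double(onr) * onc > max_px)
    stop(sprintf("output canvas %d x %d exceeds max_px", onr, onc),
         call. = FALSE)
  ocx <- (onc + 1) / 2; ocy <- (onr + 1) / 2
  gx <- rep(seq_len(onc) - ocx + ox, each = onr)
  gy <- rep(ocy - seq_len(onr) + oy, times = onc)
  src <- map_points(invert_map(m), cbind(gx, gy))
  rs <- cy - src[, 2]; cs <- src[, 1] + cx
  warp1 <- function(ch) matrix(interp_bilinear(ch, rs, cs, fill), onr, onc)
  out <- if (length(d) == 3L) {
    a <- array(0, c(onr, onc, d[3L]))
    for (k in seq_len(d[3L])) a[, , k] <- warp1(img[, , k])
    a
  } else warp1(img)
  if (is_mask) out <- out >= 0.5
  # vertical magnification per output row, measured at the canvas center line
  yrow <- ocy - seq_len(onr) + oy
  up <- map_points(invert_map(m), cbind(rep(ox, onr), yrow + 0.5))
  dn <- map_points(invert_map(m), cbind(rep(ox, onr), yrow - 0.5))
  attr(out, "row_scale") <- 1 / pmax(abs(up[, 2] - dn[, 2]), 1e-12)
  attr(out, "origin") <- c(x = ox, y = oy)
  out
}

#' Rotate an image upright
#'
#' Rotates by `-gamma` about the image center so the zenith recorded by the
#' accelerometer aligns with the +y axis, expanding the canvas to avoid
#' cropping (background fill 0).
#'
#' @param img Raster (RGB array, gray matrix or mask).
#' @param gamma Rotation angle, radians.
#' @param expand Grow the canvas to the rotated bounding box (default TRUE).
#' @return Rotated raster.
#' @export
rotate_upright <- function(img, gamma, expand = TRUE) {
  cg <- cos(-gamma); sg <- sin(-gamma)
  m <- planar_map(matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3,
                         byrow = TRUE))
  apply_map(img, m, canvas = if (expand) "bbox" else "same")
}

#' Full tilt calibration of one image
#'
#' Rotation correction first, then the depression-angle perspective
#' correction, mirroring the capture pipeline. Small-angle coupling between
#' the two angles is ignored.
#'
#' @param img Raster.
#' @param orient A [device_orientation()].
#' @param cam A [camera_model()] for the rotated raster; if `NULL`, built
#'   from the raster size with the default field of view.
#' @param canvas Passed to [apply_map()] for the depression stage.
#' @return Calibrated raster (approximate orthographic front view).
#' @export
calibrate_image <- function(img, orient, cam = NULL,
                            canvas = c("same", "bbox")) {
  canvas <- match.arg(canvas)
  if (abs(orient$gamma) > 1e-12) img <- rotate_upright(img, orient$gamma)
  if (is.null(cam))
    cam <- camera_model(ncol(img), nrow(img))
  if (abs(orient$alpha) < 1e-12) return(img)
  apply_map(img, build_depression_map(orient, cam), canvas = canvas)
}
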