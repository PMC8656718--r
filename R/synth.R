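# Parametric synthetic maize renderer.
#
# A plant is modelled in physical (mm) coordinates as a vertical, linearly
# tapered stem with alternately inserted leaves. Each leaf midline is a
# quadratic Bezier curve: insertion point on the stem, apex at the chord
# length along an upward-outward elevation direction, and a control point
# displaced perpendicular to the chord by the curvature parameter, so the
# blade arches above its chord the way a maize leaf does. The blade is swept
# along the midline with a sine-shaped width profile that stays attached at
# the stem and tapers to the tip. The topmost one or two leaves insert at
# the stem apex, emulating the whorl of a vegetative maize plant.
#
# Ground-truth leaf lengths and curvature come from the continuous model
# (numeric arc length of the Bezier); heights, widths and areas come from
# the rasterized truth mask, so raster-induced error is part of what the
# validation measures.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

bezier_points <- function(p0, p1, p2, t) {
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

leaf_width_profile <- function(t, width_mm) width_mm * sin(pi * (0.15 + 0.85 * t))

#' Synthetic plant specification
#'
#' @param stem_height_mm Height of the stem axis from soil line to apex.
#' @param stem_width_base_mm,stem_width_top_mm Stem width at base and apex
#'   (linear taper).
#' @param leaves Data frame with one row per leaf: `insertion_frac` (height
#'   fraction along the stem, non-decreasing, in (0, 1]; the topmost leaf may
#'   sit at the apex), `side` (+1 right / -1 left), `chord_mm` (straight
#'   insertion-to-tip distance), `curvature` (perpendicular control-point
#'   offset as a fraction of the chord; 0 = straight leaf), `elev_deg`
#'   (chord elevation above horizontal), `width_mm` (maximum blade width).
#' @param canvas_px `c(height, width)` of the rendered raster.
#' @param mm_per_px Physical resolution of the render.
#' @param seed RNG seed used for the (small) deterministic shading jitter.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(stem_height_mm = 750,
                       stem_width_base_mm = 22,
                       stem_width_top_mm = 14,
                       leaves = NULL,
                       canvas_px = c(656L, 492L),
                       mm_per_px = 2,
                       seed = 0L) {
  if (is.null(leaves)) {
    leaves <- data.frame(
      insertion_frac = c(0.35, 0.55, 0.75, 0.99, 1.0),
      side = c(1, -1, 1, -1, 1),
      chord_mm = c(330, 310, 280, 230, 200),
      curvature = c(0.14, 0.12, 0.10, 0.08, 0.07),
      elev_deg = c(26, 32, 40, 55, 62),
      width_mm = c(58, 56, 52, 44, 40)
    )
  }
  stopifnot(nrow(leaves) >= 1, all(diff(leaves$insertion_frac) >= 0),
            all(leaves$insertion_frac > 0), all(leaves$insertion_frac <= 1),
            all(leaves$chord_mm > 0), all(leaves$width_mm > 0),
            stem_height_mm > 0, stem_width_base_mm > 0, stem_width_top_mm > 0,
            mm_per_px > 0)
  structure(list(stem_height_mm = stem_height_mm,
                 stem_width_base_mm = stem_width_base_mm,
                 stem_width_top_mm = stem_width_top_mm,
                 leaves = leaves, canvas_px = as.integer(canvas_px),
                 mm_per_px = mm_per_px, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Draw a random plant specification
#'
#' Samples a vegetative-stage maize habit: stem 550-900 mm, 4-7 alternately
#' inserted leaves whose lower blades are long and near-horizontal and whose
#' upper blades are shorter and steeper, with the top two leaves emerging
#' together at the apex whorl.
#'
#' @param seed Integer seed; the same seed reproduces the same spec.
#' @param ... Overrides passed on to [plant_spec()].
#' @return A `plant_spec`.
#' @export
random_plant_spec <- function(seed = 0L, ...) {
  with_seed(seed, {
    n <- sample(4:7, 1)
    sh <- runif(1, 550, 900)
    base_w <- runif(1, 18, 26)
    f_lower <- sort(runif(n - 2, 0.28, 0.82))
    # enforce spacing so same-side leaves stay apart
    if (length(f_lower) > 1)
      f_lower <- 0.28 + (0.82 - 0.28) * seq(0, 1, length.out = length(f_lower)) +
        runif(length(f_lower), -0.02, 0.02)
    f <- c(f_lower, runif(1, 0.988, 0.996), 1.0)
    side0 <- sample(c(-1, 1), 1)
    leaves <- data.frame(
      insertion_frac = f,
      side = side0 * (-1)^(seq_len(n) - 1),
      chord_mm = runif(n, 230, 360) * (1.08 - 0.38 * f),
      curvature = runif(n, 0.06, 0.16),
      elev_deg = runif(n, 20, 34) + 30 * f,
      width_mm = runif(n, 46, 66) * (1.02 - 0.28 * f)
    )
    plant_spec(stem_height_mm = sh, stem_width_base_mm = base_w,
               stem_width_top_mm = base_w * runif(1, 0.55, 0.7),
               leaves = leaves, seed = seed, ...)
  })
}

# continuous leaf midline geometry in mm coordinates (origin at stem base,
# y up); returns sample points, radii, and ground-truth lengths
leaf_curve <- function(spec, i, n_samp = 600) {
  lf <- spec$leaves[i, ]
  p0 <- c(0, lf$insertion_frac * spec$stem_height_mm)
  th <- lf$elev_deg * pi / 180
  d <- c(lf$side * cos(th), sin(th))
  p2 <- p0 + lf$chord_mm * d
  perp <- c(-d[2], d[1])
  if (perp[2] < 0) perp <- -perp
  p1 <- (p0 + p2) / 2 + lf$curvature * lf$chord_mm * perp
  tt <- seq(0, 1, length.out = n_samp)
  pts <- bezier_points(p0, p1, p2, tt)
  seg <- sqrt(rowSums(diff(pts)^2))
  list(p0 = p0, p1 = p1, p2 = p2, t = tt, pts = pts,
       radius = leaf_width_profile(tt, lf$width_mm) / 2,
       sll = sum(seg), lnl = lf$chord_mm,
       lc = 1 - lf$chord_mm / sum(seg))
}

# stamp min(dist - radius) <= 0 for a sampled curve into a label matrix;
# only pixels not yet labelled are claimed
stamp_curve <- function(lab, pts_px, radius_px, label) {
  nr <- nrow(lab); nc <- ncol(lab)
  rmax <- max(radius_px)
  r0 <- max(1L, floor(min(pts_px[, 1]) - rmax - 1))
  r1 <- min(nr, ceiling(max(pts_px[, 1]) + rmax + 1))
  c0 <- max(1L, floor(min(pts_px[, 2]) - rmax - 1))
  c1 <- min(nc, ceiling(max(pts_px[, 2]) + rmax + 1))
  if (r0 > r1 || c0 > c1) return(lab)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  clearance <- rep(Inf, length(rr))
  for (i in seq_len(nrow(pts_px))) {
    di <- sqrt((rr - pts_px[i, 1])^2 + (cc - pts_px[i, 2])^2) - radius_px[i]
    clearance <- pmin(clearance, di)
  }
  inside <- clearance <= 0
  idx <- (cc[inside] - 1L) * nr + rr[inside]
  idx <- idx[lab[idx] == 0L]
  lab[idx] <- label
  lab
}

#' Render a synthetic plant with ground truth
#'
#' @param spec A [plant_spec()].
#' @return Object of class `synthetic_plant`: list with `rgb` (array),
#'   `mask` (logical truth mask), `labels` (integer organ raster: 0
#'   background, 1 stem, 2.. leaves bottom-up), `truth` (ground-truth trait
#'   list: `MPH`, `PW`, `TPA`, `SH`, `VPH`, `LN`, `TLL`, per-leaf data frame
#'   with `SLL`, `LNL`, `LC`, apex/insertion pixel positions), `mm_per_px`,
#'   `base_row`, `center_col` and the spec itself. Deterministic given the
#'   spec (same seed, bit-identical render).
#' @export
generate_plant <- function(spec) {
  nr <- spec$canvas_px[1L]; nc <- spec$canvas_px[2L]
  mpp <- spec$mm_per_px
  base_row <- round(0.95 * nr)
  cx <- (nc + 1) / 2
  to_px <- function(xy_mm) cbind(base_row - xy_mm[, 2] / mpp,
                                 cx + xy_mm[, 1] / mpp)
  lab <- matrix(0L, nr, nc)
  # stem: vertical tapered band, label 1
  sh_px <- spec$stem_height_mm / mpp
  top_row <- base_row - sh_px
  if (top_row < 2) stop("stem exceeds canvas", call. = FALSE)
  rows <- seq_len(nr)
  in_stem_rows <- rows >= ceiling(top_row) & rows <= base_row
  frac <- (base_row - rows) / sh_px
  w_px <- (spec$stem_width_base_mm +
             (spec$stem_width_top_mm - spec$stem_width_base_mm) * frac) / mpp
  for (r in rows[in_stem_rows]) {
    half <- w_px[r] / 2
    c0 <- max(1L, ceiling(cx - half)); c1 <- min(nc, floor(cx + half))
    if (c0 <= c1) lab[r, c0:c1] <- 1L
  }
  # leaves bottom-up, labels 2..
  nleaf <- nrow(spec$leaves)
  curves <- vector("list", nleaf)
  for (i in seq_len(nleaf)) {
    cv <- leaf_curve(spec, i)
    pts_px <- to_px(cv$pts)
    if (any(pts_px[, 1] < 2 | pts_px[, 1] > nr - 1 |
            pts_px[, 2] < 2 | pts_px[, 2] > nc - 1))
      stop(sprintf("leaf %d extends beyond the canvas", i), call. = FALSE)
    lab <- stamp_curve(lab, pts_px, cv$radius / mpp, i + 1L)
    curves[[i]] <- cv
  }
  mask <- lab > 0L
  # render: flat organ colours with a small seeded per-leaf shade jitter
  rgb <- array(0.04, c(nr, nc, 3))
  shade <- with_seed(spec$seed, runif(nleaf, -0.05, 0.05))
  cols <- rbind(c(0.33, 0.55, 0.18),
                t(vapply(shade, function(s) c(0.20 + s / 2, 0.62 + s, 0.16),
                         numeric(3))))
  for (k in seq_len(nleaf + 1L)) {
    sel <- lab == k
    for (ch in 1:3) {
      pl <- rgb[, , ch]; pl[sel] <- cols[k, ch]; rgb[, , ch] <- pl
    }
  }
  fg <- which(mask, arr.ind = TRUE)
  leaf_df <- data.frame(
    leaf = seq_len(nleaf),
    SLL = vapply(curves, `[[`, numeric(1), "sll"),
    LNL = vapply(curves, `[[`, numeric(1), "lnl"),
    LC = vapply(curves, `[[`, numeric(1), "lc"),
    insertion_row = vapply(curves, function(cv) to_px(rbind(cv$p0))[1], numeric(1)),
    insertion_col = vapply(curves, function(cv) to_px(rbind(cv$p0))[2], numeric(1)),
    apex_row = vapply(curves, function(cv) to_px(rbind(cv$p2))[1], numeric(1)),
    apex_col = vapply(curves, function(cv) to_px(rbind(cv$p2))[2], numeric(1)),
    side = spec$leaves$side,
    insertion_frac = spec$leaves$insertion_frac
  )
  truth <- list(
    MPH = (max(fg[, 1]) - min(fg[, 1]) + 1) * mpp,
    PW = (max(fg[, 2]) - min(fg[, 2]) + 1) * mpp,
    TPA = sum(mask) * mpp^2,
    SH = spec$stem_height_mm,
    VPH = spec$stem_height_mm,
    SPA = sum(lab == 1L) * mpp^2,
    LN = nleaf,
    TLL = sum(leaf_df$SLL),
    top_insertion_row = min(leaf_df$insertion_row),
    leaves = leaf_df
  )
  structure(list(spec = spec, rgb = rgb, mask = mask, labels = lab,
                 truth = truth, mm_per_px = mpp, base_row = base_row,
                 center_col = cx),
            class = "synthetic_plant")
}

#' Forward-render a plant at a known tilt
#'
#' Applies the exact inverse of the calibration's image-to-object map (and
#' optionally the inverse rotation correction), so that running the
#' calibration on the result recovers the flat render up to resampling.
#'
#' @param plant A `synthetic_plant` from [generate_plant()].
#' @param alpha_deg Depression angle in degrees, `|alpha| < 40`.
#' @param gamma_deg Rotation angle in degrees.
#' @param beta_max_deg Half vertical field of view used for the forward
#'   model, degrees.
#' @return List with `rgb`, `mask` (both tilted, same canvas) and `sidecar`
#'   (metadata list ready for [write_sidecar()]).
#' @export
render_tilted <- function(plant, alpha_deg, gamma_deg = 0, beta_max_deg = 33) {
  if (abs(alpha_deg) >= 40) stop("|alpha_deg| must be < 40", call. = FALSE)
  orient <- device_orientation(alpha_deg * pi / 180, gamma_deg * pi / 180)
  cam <- camera_model(ncol(plant$mask), nrow(plant$mask),
                      beta_max_deg * pi / 180)
  m_dep <- build_depression_map(orient, cam)
  g <- orient$gamma  # forward rotation undone by rotate_upright(gamma)
  rot <- planar_map(matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1),
                           3, 3, byrow = TRUE))
  forward <- planar_map(unclass(rot) %*% solve(unclass(m_dep)))
  list(rgb = apply_map(plant$rgb, forward, canvas = "same"),
       mask = apply_map(plant$mask, forward, canvas = "same"),
       sidecar = list(alpha_deg = alpha_deg, gamma_deg = gamma_deg,
                      beta_max_deg = beta_max_deg,
                      mm_per_px = plant$mm_per_px,
                      marker_len_mm = NULL, marker_len_px = NULL,
                      plant_id = sprintf("synthetic-%04d", plant$spec$seed),
                      datetime = "2026-01-01T00:00:00"))
}

#' Corruption settings for [corrupt()]
#'
#' @param noise_sd Gaussian pixel noise SD on the 0-255 scale (0 = off).
#' @param gains Per-channel RGB gains (colour cast; `c(1,1,1)` = off).
#' @param gamma Brightness gamma (1 = off).
#' @param bg_texture Amplitude of a smooth background texture field (0 = off).
#' @param seed RNG seed for the noise and texture draws.
#' @export
corrupt_config <- function(noise_sd = 0, gains = c(1, 1, 1), gamma = 1,
                           bg_texture = 0, seed = 0L) {
  list(noise_sd = noise_sd, gains = gains, gamma = gamma,
       bg_texture = bg_texture, seed = as.integer(seed))
}

#' Degrade a rendered image
#'
#' Emulates adverse capture conditions: sensor noise, a global colour cast
#' (e.g. the warm deviation of dawn light), brightness shift, and a mottled
#' backdrop texture. The identity configuration returns the input unchanged.
#'
#' @param img RGB array in `[0, 1]`.
#' @param cfg A [corrupt_config()].
#' @return Degraded RGB array, clamped to `[0, 1]`.
#' @export
corrupt <- function(img, cfg = corrupt_config()) {
  d <- dim(img)
  out <- img
  for (ch in 1:3) out[, , ch] <- out[, , ch] * cfg$gains[ch]
  if (cfg$gamma != 1) out <- out^cfg$gamma
  if (cfg$bg_texture > 0) {
    tex <- with_seed(cfg$seed + 1L, {
      coarse <- matrix(runif(81), 9, 9)
      rows <- seq(1, 9, length.out = d[1L])
      cols <- seq(1, 9, length.out = d[2L])
      outer(rows, cols, function(r, c) interp_bilinear(coarse, r, c))
    })
    dark <- apply(img, c(1, 2), max) < 0.15
    for (ch in 1:3)
      out[, , ch] <- out[, , ch] + cfg$bg_texture * tex * dark
  }
  if (cfg$noise_sd > 0) {
    noise <- with_seed(cfg$seed, array(stats::rnorm(prod(d), 0,
                                                    cfg$noise_sd / 255), d))
    out <- out + noise
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Simulate a correlated image-trait table
#'
#' Draws plausible per-plant trait values (areas, lengths, volumes) from a
#' shared lognormal plant-size factor plus independent variation, for use in
#' regression-recovery simulations where rendering full images would add
#' nothing.
#'
#' @param n Number of plants.
#' @param seed RNG seed.
#' @return Data frame with columns TPA, TLPA, TLL, SPA, SV, SH, MPH.
#' @export
simulate_trait_table <- function(n, seed = 0L) {
  with_seed(seed, {
    size <- stats::rlnorm(n, 0, 0.25)  # latent plant-size factor
    data.frame(
      TPA = 60000 * size * stats::rlnorm(n, 0, 0.10),
      TLPA = 48000 * size * stats::rlnorm(n, 0, 0.12),
      TLL = 1400 * size^0.5 * stats::rlnorm(n, 0, 0.10),
      SPA = 11000 * size * stats::rlnorm(n, 0, 0.12),
      SV = 180000 * size^1.5 * stats::rlnorm(n, 0, 0.15),
      SH = 700 * size^0.5 * stats::rlnorm(n, 0, 0.08),
      MPH = 950 * size^0.5 * stats::rlnorm(n, 0, 0.08)
    )
  })
}
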