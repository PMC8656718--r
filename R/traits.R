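# The 45-trait record: 15 plant, 25 leaf and 5 stem traits computed from
# the calibrated mask and the structural decomposition, in physical units
# via the mm-per-px scale. Five traits (TDW, LDW, TLA, TLDW, SDW) are
# estimates from fitted regression models, not direct measurements, and
# stay NA until a model is supplied. LDW and TLDW are both emitted (the
# canonical schema lists total leaf dry weight twice) and set equal.

#' The trait schema
#'
#' @return Data frame with one row per trait: `abbrev`, `category`
#'   (plant/leaf/stem), `unit`, `provenance` (`direct` from the image,
#'   `model` from a fitted biomass model). 15 + 25 + 5 = 45 rows, asserted.
#' @export
trait_schema <- function() {
  s <- rbind(
    data.frame(category = "plant",
               abbrev = c("MPH", "VPH", "PW", "TPA", "GPAR", "TBR", "PP",
                          "PAR", "PC", "FD", "HWR", "ACH", "PCH", "PCHAR",
                          "TDW"),
               unit = c("mm", "mm", "mm", "mm2", "ratio", "ratio", "mm",
                        "1/mm", "ratio", "dimensionless", "ratio", "mm2",
                        "mm", "ratio", "g"),
               provenance = c(rep("direct", 14), "model")),
    data.frame(category = "leaf",
               abbrev = c("LDW", "TLA", "TLPA", "TLL", "LN", "SDSLL", "LNL",
                          "SDLNL", "LC", "SDLC", "LTA", "SDLTA", "LSA",
                          "SDLSA", "SLL_below", "LNL_below", "LC_below",
                          "LTA_below", "LSA_below", "SLL_above", "LNL_above",
                          "LC_above", "LTA_above", "LSA_above", "TLDW"),
               unit = c("g", "mm2", "mm2", "mm", "count", "mm", "mm", "mm",
                        "ratio", "ratio", "deg", "deg", "deg", "deg", "mm",
                        "mm", "ratio", "deg", "deg", "mm", "mm", "ratio",
                        "deg", "deg", "g"),
               provenance = c("model", "model", rep("direct", 22), "model")),
    data.frame(category = "stem",
               abbrev = c("SH", "SPA", "SW", "SV", "SDW"),
               unit = c("mm", "mm2", "mm", "mm3", "g"),
               provenance = c(rep("direct", 4), "model"))
  )
  stopifnot(nrow(s) == 45L,
            sum(s$category == "plant") == 15L,
            sum(s$category == "leaf") == 25L,
            sum(s$category == "stem") == 5L)
  s
}

shoelace_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

closed_perimeter <- function(p) {
  n <- nrow(p)
  if (n < 2) return(0)
  d <- diff(rbind(p, p[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# convex hull of the foreground in pixel-corner coordinates (so a solid
# n x n square has hull area exactly n^2)
mask_hull <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  h1 <- grDevices::chull(pts)
  corners <- do.call(rbind, lapply(c(-0.5, 0.5), function(dr)
    lapply(c(-0.5, 0.5), function(dc)
      cbind(pts[h1, 1] + dr, pts[h1, 2] + dc))))
  corners <- do.call(rbind, corners)
  corners[grDevices::chull(corners), , drop = FALSE]
}

# minimum-area rotated rectangle via rotating calipers on the hull;
# returns the side extents (along, across) for each candidate edge angle
min_area_rect <- function(hull) {
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    e <- hull[if (i == n) 1 else i + 1, ] - hull[i, ]
    L <- sqrt(sum(e^2))
    if (L < 1e-9) next
    u <- e / L; v <- c(-u[2], u[1])
    a <- hull %*% u; b <- hull %*% v
    w <- diff(range(a)); h <- diff(range(b))
    if (is.null(best) || w * h < best$area)
      best <- list(area = w * h, u = u, v = v, w = w, h = h)
  }
  best
}

# total outer+inner contour length, 8-connected tracing with sqrt(2)
# diagonal steps
mask_perimeter_px <- function(mask) {
  lab <- label8(mask)
  ctrs <- EBImage::ocontour(lab)
  sum(vapply(ctrs, function(p) {
    if (nrow(p) == 1) return(4)  # lone pixel: unit square outline
    closed_perimeter(p)
  }, numeric(1)))
}

#' Box-counting fractal dimension
#'
#' Dyadic box sizes from 2 px up to a quarter of the smaller image side;
#' the dimension is the least-squares slope of log N(s) against log(1/s).
#'
#' @param mask Logical mask (nonempty).
#' @return Estimated dimension (about 1 for a curve, 2 for a filled region).
#' @export
fractal_dimension <- function(mask) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  pts <- which(mask, arr.ind = TRUE)
  smax <- min(dim(mask)) / 4
  sizes <- 2^(1:20)
  sizes <- sizes[sizes <= smax]
  if (length(sizes) < 3)
    stop("image too small for box counting (fewer than 3 box sizes)",
         call. = FALSE)
  counts <- vapply(sizes, function(s) {
    length(unique((pts[, 1] - 1) %/% s * 1e6 + (pts[, 2] - 1) %/% s))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[2])
}

#' Direct plant-level traits
#'
#' Computes the 14 directly measured plant traits (all but the
#' model-estimated total dry weight) from the calibrated mask: heights and
#' width from the soil line (the lowest foreground row), areas, contour
#' perimeter and derived shape descriptors, box-counting fractal dimension,
#' the minimum-area rotated bounding box, and the convex hull.
#'
#' @param mask Logical plant mask (calibrated view).
#' @param mm_per_px Physical scale.
#' @param rgb Optional RGB array for the green-pixel area ratio (GPAR);
#'   green is ExG above Otsu's threshold within the mask, with a fixed
#'   fallback when the within-mask ExG is nearly constant.
#' @param stem_top_row Optional image row of the stem-axis top, for VPH;
#'   defaults to the topmost foreground row (VPH = MPH).
#' @return Named list of 14 traits.
#' @export
plant_traits <- function(mask, mm_per_px, rgb = NULL, stem_top_row = NULL) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  fg <- which(mask, arr.ind = TRUE)
  r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
  c0 <- min(fg[, 2]); c1 <- max(fg[, 2])
  mph <- (r1 - r0 + 1) * mm_per_px
  pw <- (c1 - c0 + 1) * mm_per_px
  tpa <- nrow(fg) * mm_per_px^2
  vph <- if (is.null(stem_top_row)) mph else (r1 - stem_top_row + 1) * mm_per_px
  gpar <- NA_real_
  if (!is.null(rgb)) {
    exg <- exg_index(rgb)[mask]
    if (diff(range(exg)) < 1 / 255) {
      gpar <- as.numeric(mean(exg) > 0.05)
    } else {
      u <- (exg + 2) / 4
      thr <- EBImage::otsu(matrix(u), range = c(0, 1)) * 4 - 2
      gpar <- mean(exg > thr)
    }
  }
  pp_px <- mask_perimeter_px(mask)
  pp <- pp_px * mm_per_px
  hull <- mask_hull(mask)
  ach <- shoelace_area(hull) * mm_per_px^2
  pch <- closed_perimeter(hull) * mm_per_px
  rect <- min_area_rect(hull)
  # the rectangle side whose direction is closer to the image vertical is
  # the height
  vert_u <- abs(rect$u[1])  # row component of the edge direction
  hwr <- if (vert_u >= abs(rect$v[1])) rect$w / rect$h else rect$h / rect$w
  list(MPH = mph, VPH = vph, PW = pw, TPA = tpa, GPAR = gpar,
       TBR = tpa / (mph * pw), PP = pp, PAR = pp / tpa,
       PC = 4 * pi * tpa / pp^2, FD = fractal_dimension(mask),
       HWR = hwr, ACH = ach, PCH = pch, PCHAR = min(tpa / ach, 1))
}

direction_deg <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) return(NULL)
  v / n
}

angle_between_deg <- function(u, v) {
  d <- sum(u * v)
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

#' Per-leaf geometry
#'
#' Straightened leaf length (axis arc length, with the pixel path subsampled
#' to suppress staircase bias), tip-to-insertion chord, curvature
#' `1 - chord/arc`, and the tangency and straight angles between the local
#' stem direction at the insertion (oriented up) and the leaf tangent /
#' chord (oriented outward).
#'
#' @param leaf Leaf record from [extract_leaves()].
#' @param stem Stem axis path.
#' @param mm_per_px Physical scale.
#' @param tangent_window_px Pixels of leaf axis used to fit the tangent.
#' @return List with `SLL`, `LNL`, `LC`, `LTA`, `LSA`, `valid`. Axes shorter
#'   than 5 px are flagged invalid (`valid = FALSE`) and excluded from
#'   plant-level averages, though they still count toward leaf number.
#' @export
leaf_geometry <- function(leaf, stem, mm_per_px, tangent_window_px = 15L) {
  a0 <- leaf$axis_start %||% 1L
  base_len <- leaf$base_len %||% 0
  ax <- leaf$axis[a0:nrow(leaf$axis), , drop = FALSE]
  if (nrow(ax) < 5L)
    return(list(SLL = NA_real_, LNL = NA_real_, LC = NA_real_,
                LTA = NA_real_, LSA = NA_real_, valid = FALSE))
  tip_len <- leaf$tip_len %||% 0  # medial axis stops one half-width short
  sll <- (polyline_length(ax, by = 4L) + base_len + tip_len) * mm_per_px
  lnl <- (sqrt(sum((leaf$apex - leaf$insertion)^2)) + tip_len) * mm_per_px
  lc <- max(0, 1 - min(lnl / sll, 1))
  # local stem direction at the insertion, oriented upward; (x, y-up) frame
  j <- which.min((stem[, 1] - leaf$insertion[1])^2 +
                   (stem[, 2] - leaf$insertion[2])^2)
  k <- tangent_window_px
  win <- stem[max(1, j - k):min(nrow(stem), j + k), , drop = FALSE]
  sd_vec <- c(win[nrow(win), 2] - win[1, 2], win[1, 1] - win[nrow(win), 1])
  if (sd_vec[2] < 0) sd_vec <- -sd_vec
  su <- direction_deg(sd_vec)
  wl <- min(nrow(ax), k + 1L)
  lt_vec <- c(ax[wl, 2] - ax[1, 2], ax[1, 1] - ax[wl, 1])
  ch_vec <- c(leaf$apex[2] - leaf$insertion[2],
              leaf$insertion[1] - leaf$apex[1])
  lu <- direction_deg(lt_vec)
  cu <- direction_deg(ch_vec)
  lta <- if (is.null(su) || is.null(lu)) NA_real_ else angle_between_deg(su, lu)
  lsa <- if (is.null(su) || is.null(cu)) NA_real_ else angle_between_deg(su, cu)
  list(SLL = sll, LNL = lnl, LC = lc, LTA = lta, LSA = lsa, valid = TRUE)
}

#' Plant-level leaf traits
#'
#' Aggregates per-leaf geometry into the 22 directly measured leaf traits:
#' totals, leaf count, plant-level means and population standard deviations
#' (divisor N) of the five per-leaf quantities, and the lower/upper-half
#' means split at the stem midpoint height. A half with no leaves yields NA
#' for its traits.
#'
#' @param structure A [plant_structure()].
#' @param mm_per_px Physical scale.
#' @param tangent_window_px Passed to [leaf_geometry()].
#' @return Named list of leaf traits plus `mean_SLL` (the per-plant mean
#'   straightened leaf length, a non-canonical extra: the canonical schema
#'   carries only its standard deviation).
#' @export
leaf_traits <- function(structure, mm_per_px, tangent_window_px = 15L) {
  leaves <- structure$leaves
  geoms <- lapply(leaves, leaf_geometry, stem = structure$stem,
                  mm_per_px = mm_per_px,
                  tangent_window_px = tangent_window_px)
  valid <- vapply(geoms, `[[`, logical(1), "valid")
  if (any(!valid))
    warning(sprintf("%d leaf axis/axes too short for geometry; excluded from averages",
                    sum(!valid)), call. = FALSE)
  gv <- geoms[valid]
  below <- vapply(leaves, `[[`, logical(1), "below")[valid]
  pull <- function(gs, f) vapply(gs, `[[`, numeric(1), f)
  half_mean <- function(f, sel) if (any(sel)) mean(pull(gv[sel], f)) else NA_real_
  tlpa <- sum(structure$labels >= 2L) * mm_per_px^2
  out <- list(
    TLPA = tlpa,
    TLL = sum(pull(gv, "SLL")),
    LN = length(leaves),
    SDSLL = pop_sd(pull(gv, "SLL")),
    LNL = mean(pull(gv, "LNL")),
    SDLNL = pop_sd(pull(gv, "LNL")),
    LC = mean(pull(gv, "LC")),
    SDLC = pop_sd(pull(gv, "LC")),
    LTA = mean(pull(gv, "LTA")),
    SDLTA = pop_sd(pull(gv, "LTA")),
    LSA = mean(pull(gv, "LSA")),
    SDLSA = pop_sd(pull(gv, "LSA")),
    SLL_below = half_mean("SLL", below),
    LNL_below = half_mean("LNL", below),
    LC_below = half_mean("LC", below),
    LTA_below = half_mean("LTA", below),
    LSA_below = half_mean("LSA", below),
    SLL_above = half_mean("SLL", !below),
    LNL_above = half_mean("LNL", !below),
    LC_above = half_mean("LC", !below),
    LTA_above = half_mean("LTA", !below),
    LSA_above = half_mean("LSA", !below),
    mean_SLL = mean(pull(gv, "SLL"))
  )
  out
}

#' Direct stem traits
#'
#' Stem height (axis path length), projected area (stem-band label area),
#' average width (area / height) and the cylinder volume built from them:
#' the stem is treated as a cylinder of diameter SW and height SH.
#'
#' @param structure A [plant_structure()].
#' @param mm_per_px Physical scale.
#' @return Named list with `SH`, `SPA`, `SW`, `SV`.
#' @export
stem_traits <- function(structure, mm_per_px) {
  stem <- structure$stem
  if (nrow(stem) < 5L) stop("degenerate stem (< 5 px)", call. = FALSE)
  sh <- polyline_length(stem, by = 4L) * mm_per_px
  spa <- sum(structure$labels == 1L) * mm_per_px^2
  sw <- spa / sh
  list(SH = sh, SPA = spa, SW = sw, SV = pi * (sw / 2)^2 * sh)
}

#' Assemble one trait record
#'
#' Combines plant, leaf and stem traits into a single one-row data frame in
#' canonical schema order, followed by the non-canonical `mean_SLL` and the
#' metadata columns. Model-estimated traits (TDW, LDW, TLA, TLDW, SDW) are
#' filled from `models` when supplied, else NA; LDW and TLDW are emitted
#' equal.
#'
#' @param mask Calibrated plant mask.
#' @param structure A [plant_structure()] of the mask.
#' @param mm_per_px Physical scale.
#' @param rgb Optional calibrated RGB for GPAR.
#' @param models Optional named list of fitted [stepwise_fit()] models with
#'   any of the names `TDW`, `TLDW`, `TLA`, `SDW`.
#' @param meta Named list of metadata (`plant_id`, `datetime`, `alpha_deg`).
#' @return One-row data frame.
#' @export
collect_traits <- function(mask, structure, mm_per_px, rgb = NULL,
                           models = NULL, meta = list()) {
  stem_top_row <- structure$stem[nrow(structure$stem), 1]
  pt <- plant_traits(mask, mm_per_px, rgb = rgb, stem_top_row = stem_top_row)
  lt <- leaf_traits(structure, mm_per_px)
  st <- stem_traits(structure, mm_per_px)
  rec <- c(pt, TDW = NA_real_, LDW = NA_real_, TLA = NA_real_,
           lt[setdiff(names(lt), "mean_SLL")], TLDW = NA_real_,
           st, SDW = NA_real_)
  df <- as.data.frame(rec)[, trait_schema()$abbrev]
  if (!is.null(models)) {
    for (target in intersect(names(models), c("TDW", "TLDW", "TLA", "SDW"))) {
      est <- as.numeric(stats::predict(models[[target]], df))
      df[[target]] <- est
    }
    df$LDW <- df$TLDW
  }
  df$mean_SLL <- lt$mean_SLL
  df$plant_id <- meta$plant_id %||% NA_character_
  df$datetime <- meta$datetime %||% NA_character_
  df$alpha_deg <- meta$alpha_deg %||% NA_real_
  df$mask_source <- attr(mask, "provenance") %||% "external"
  df
}

#' Write trait records to CSV
#'
#' One row per plant image; metadata columns first, then the 45 canonical
#' trait columns in schema order, then the non-canonical `mean_SLL`.
#' RFC-4180 quoting via `write.csv`. An empty record set produces a
#' header-only file.
#'
#' @param records Data frame of rows from [collect_traits()] (or an empty
#'   list / NULL).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_traits_csv <- function(records, path) {
  schema <- trait_schema()$abbrev
  meta_cols <- c("plant_id", "datetime", "alpha_deg", "mask_source")
  cols <- c(meta_cols, schema, "mean_SLL")
  if (is.null(records) || (is.data.frame(records) && nrow(records) == 0L) ||
      (is.list(records) && !is.data.frame(records) && length(records) == 0L)) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  if (!is.data.frame(records)) records <- do.call(rbind, records)
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read back a trait CSV
#'
#' @param path CSV produced by [write_traits_csv()].
#' @return Data frame.
#' @export
read_traits_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
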