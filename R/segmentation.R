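# Plant segmentation against a dark backdrop.
#
# The default segmenter is a classical colour pipeline: excess-green index
# ExG = 2G - R - B, Otsu threshold, small-kernel morphological cleanup and
# largest-component selection. A precomputed binary mask (e.g. the output of
# a semantic segmentation network) can be dropped in instead via
# load_external_mask(); everything downstream is agnostic to the mask's
# provenance, which is carried along as an attribute.

#' Excess-green index
#'
#' @param img RGB array in `[0, 1]`.
#' @return Matrix `2G - R - B`, range `[-2, 2]`.
#' @export
exg_index <- function(img) 2 * img[, , 2] - img[, , 1] - img[, , 3]

#' Colour enhancement
#'
#' Standardizes image colour before segmentation: a gray-world white balance
#' (per-channel gain equalizing the channel means) followed by a 1-99
#' percentile contrast stretch computed jointly over all channels. The joint
#' stretch normalizes exposure while preserving the channel ratios that the
#' excess-green index relies on (a per-channel stretch would saturate every
#' channel at the plant's own level and flatten the colour difference).
#' Deterministic; a (near-)constant image is returned unchanged.
#'
#' @param img RGB array in `[0, 1]`.
#' @return Enhanced RGB array in `[0, 1]`.
#' @export
enhance_color <- function(img) {
  mu <- apply(img, 3, mean)
  if (all(mu < 1e-6) || diff(range(img)) < 1 / 255) return(img)
  gain <- mean(mu) / pmax(mu, 1e-6)
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch] * gain[ch]
  q <- stats::quantile(out, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] >= 1 / 255) out <- (out - q[1]) / (q[2] - q[1])
  pmin(pmax(out, 0), 1)
}

#' Segmentation settings
#'
#' @param threshold Fixed ExG threshold; `NULL` (default) uses Otsu's method
#'   on the ExG image.
#' @param open_px,close_px Box kernel sizes for morphological opening and
#'   closing, pixels.
#' @param min_frac Keep secondary components at least this fraction of the
#'   largest one (tolerates leaves severed by occlusion).
#' @param max_hole_px Fill holes smaller than this many pixels.
#' @export
seg_config <- function(threshold = NULL, open_px = 3L, close_px = 5L,
                       min_frac = 0.05, max_hole_px = 200L) {
  list(threshold = threshold, open_px = as.integer(open_px),
       close_px = as.integer(close_px), min_frac = min_frac,
       max_hole_px = as.integer(max_hole_px))
}

#' Segment the plant
#'
#' ExG threshold (Otsu unless overridden), opening then closing, selection
#' of the largest 8-connected component plus any component at least
#' `min_frac` of its size, and hole filling.
#'
#' @param img RGB array (ideally after [enhance_color()]).
#' @param cfg A [seg_config()].
#' @return Logical mask with attribute `provenance = "classical"`.
#' @export
segment_plant <- function(img, cfg = seg_config()) {
  exg <- exg_index(img)
  thr <- cfg$threshold
  if (is.null(thr)) {
    u <- (exg + 2) / 4  # map to [0,1] for Otsu
    if (diff(range(u)) < 1e-6) thr <- 0.1
    else thr <- EBImage::otsu(u, range = c(0, 1)) * 4 - 2
  }
  mask <- exg > thr
  if (!any(mask)) stop("no plant found: zero foreground after thresholding",
                       call. = FALSE)
  m <- EBImage::opening(mask * 1, EBImage::makeBrush(cfg$open_px, "box"))
  m <- EBImage::closing(m, EBImage::makeBrush(cfg$close_px, "box"))
  mask <- as_mask(m)
  if (!any(mask)) stop("no plant found: empty after morphology", call. = FALSE)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= cfg$min_frac * sizes[1L])
  mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  # fill small holes: background (4-connected) components not touching the
  # border, below the size cap
  bg <- EBImage::bwlabel((!mask) * 1)
  border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole_sizes <- tabulate(bg[bg > 0])
  for (h in setdiff(seq_along(hole_sizes), border_labs))
    if (hole_sizes[h] > 0 && hole_sizes[h] < cfg$max_hole_px)
      mask[bg == h] <- TRUE
  attr(mask, "provenance") <- "classical"
  mask
}

#' Load an externally produced mask
#'
#' Drop-in replacement for the built-in segmenter: any nonzero pixel is
#' foreground; no cleanup is applied, the mask is taken verbatim.
#'
#' @param path PNG path (single channel or RGB).
#' @param expected_shape `c(rows, cols)` the mask must match.
#' @return Logical mask with attribute `provenance = "external"`.
#' @export
load_external_mask <- function(path, expected_shape) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE],
                                       c(1, 2), max)
  if (!all(dim(a) == expected_shape))
    stop(sprintf("mask shape %d x %d does not match expected %d x %d",
                 nrow(a), ncol(a), expected_shape[1], expected_shape[2]),
         call. = FALSE)
  mask <- a > 0
  attr(mask, "provenance") <- "external"
  mask
}

#' Segmentation quality metrics
#'
#' Precision, recall, F1 and IoU of a predicted mask against ground truth.
#' Undefined ratios (0/0) are reported as `NA`, distinct from 0.
#'
#' @param pred,truth Logical masks of the same shape.
#' @return List with `precision`, `recall`, `f1`, `iou`.
#' @export
evaluate_mask <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have the same shape", call. = FALSE)
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       iou = ratio(tp, tp + fp + fn))
}

#' Batch segmentation report
#'
#' Evaluates a set of predicted masks against ground truth and reports
#' per-image and mean metrics, optionally as a JSON file.
#'
#' @param preds,truths Lists of logical masks, pairwise same shape.
#' @param file Optional JSON output path.
#' @return Invisibly, a list with `per_image` (data frame) and `mean`.
#' @export
segmentation_report <- function(preds, truths, file = NULL) {
  stopifnot(length(preds) == length(truths))
  rows <- lapply(seq_along(preds), function(i) {
    m <- evaluate_mask(preds[[i]], truths[[i]])
    data.frame(image = i, precision = m$precision, recall = m$recall,
               f1 = m$f1, iou = m$iou)
  })
  per_image <- do.call(rbind, rows)
  means <- colMeans(per_image[, -1, drop = FALSE], na.rm = TRUE)
  rep <- list(per_image = per_image,
              mean = as.list(means),
              n_images = length(preds))
  if (!is.null(file))
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  invisible(rep)
}
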