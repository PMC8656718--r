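# Batch orchestration: capture -> calibrate -> segment -> skeletonize ->
# decompose -> traits -> CSV, plus fixture simulation and biomass fitting.
# All module parameters live in a single nested configuration that can be
# round-tripped through YAML; unknown keys are rejected so a typo cannot
# silently fall back to a default.

#' Pipeline configuration
#'
#' @param segmentation A [seg_config()].
#' @param skeleton A [skeleton_config()].
#' @param tangent_window_px Leaf tangent window for [leaf_geometry()].
#' @param single_route_frac Stem fraction for single-leaf plants.
#' @param p_enter,p_remove Stepwise regression thresholds.
#' @param beta_max_deg Default half vertical field of view when a sidecar
#'   does not state one.
#' @param mm_per_px Default scale when a sidecar states neither a scale nor
#'   a marker length.
#' @param seed Base RNG seed for simulation commands.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = seg_config(),
                            skeleton = skeleton_config(),
                            tangent_window_px = 15L,
                            single_route_frac = 0.6,
                            p_enter = 0.05, p_remove = 0.10,
                            beta_max_deg = 33,
                            mm_per_px = 2,
                            seed = 0L) {
  structure(list(segmentation = segmentation, skeleton = skeleton,
                 tangent_window_px = tangent_window_px,
                 single_route_frac = single_route_frac,
                 p_enter = p_enter, p_remove = p_remove,
                 beta_max_deg = beta_max_deg, mm_per_px = mm_per_px,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load / save a pipeline configuration as YAML
#'
#' Round-trips losslessly; unknown keys (at top level or inside a section)
#' are an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` (load) or the path (save).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- pipeline_config()
  bad <- setdiff(names(raw), names(def))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (sec in c("segmentation", "skeleton")) {
    if (!is.null(raw[[sec]])) {
      badk <- setdiff(names(raw[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop("unknown config key(s) in ", sec, ": ",
             paste(badk, collapse = ", "), call. = FALSE)
      def[[sec]][names(raw[[sec]])] <- raw[[sec]]
    }
  }
  for (k in setdiff(names(raw), c("segmentation", "skeleton")))
    def[[k]] <- raw[[k]]
  def
}

#' @rdname load_config
#' @param cfg A `pipeline_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Analyze one plant image
#'
#' The full chain on a single image: rotation + depression calibration from
#' the sidecar angles, colour enhancement and segmentation (or an external
#' mask), skeletonization, structural decomposition, and the 45-trait
#' record.
#'
#' @param img RGB array or PNG path.
#' @param sidecar Sidecar metadata list (see [read_sidecar()]) or JSON path;
#'   `NULL` applies defaults (no tilt) with a warning.
#' @param mask Optional external mask (logical matrix or PNG path),
#'   replacing the built-in segmenter. It is calibrated with the image.
#' @param config A [pipeline_config()].
#' @param models Optional named list of biomass models (see
#'   [collect_traits()]).
#' @return List with `record` (one-row data frame), `structure`, `mask`,
#'   `image` (calibrated RGB) and `timings` (per-stage seconds).
#' @export
analyze_image <- function(img, sidecar = NULL, mask = NULL,
                          config = pipeline_config(), models = NULL) {
  if (is.character(img)) img <- read_image(img)
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)
  if (is.null(sidecar)) {
    warning("missing sidecar: assuming no tilt and default scale",
            call. = FALSE)
    sidecar <- list(alpha_deg = 0, gamma_deg = 0,
                    beta_max_deg = config$beta_max_deg)
  }
  if (is.character(mask)) mask <- load_external_mask(mask, dim(img)[1:2])
  mm_per_px <- sidecar$mm_per_px %||%
    (if (!is.null(sidecar$marker_len_mm) && !is.null(sidecar$marker_len_px))
      sidecar$marker_len_mm / sidecar$marker_len_px else config$mm_per_px)
  orient <- device_orientation(sidecar$alpha_deg * pi / 180,
                               sidecar$gamma_deg * pi / 180)
  beta_max <- (sidecar$beta_max_deg %||% config$beta_max_deg) * pi / 180
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  cam <- camera_model(ncol(img), nrow(img), beta_max)
  img_cal <- calibrate_image(img, orient, cam)
  provenance <- "classical"
  if (!is.null(mask)) {
    provenance <- attr(mask, "provenance") %||% "external"
    mask_cal <- calibrate_image(mask, orient, cam)
  }
  timings["calibration"] <- tic() - t0
  t0 <- tic()
  if (is.null(mask)) {
    mask_cal <- segment_plant(enhance_color(img_cal), config$segmentation)
  }
  attr(mask_cal, "provenance") <- provenance
  timings["segmentation"] <- tic() - t0
  t0 <- tic()
  skel <- skeletonize(mask_cal, config$skeleton)
  timings["skeletonization"] <- tic() - t0
  t0 <- tic()
  struct <- plant_structure(mask_cal, skel)
  record <- collect_traits(mask_cal, struct, mm_per_px, rgb = img_cal,
                           models = models,
                           meta = list(plant_id = sidecar$plant_id,
                                       datetime = sidecar$datetime,
                                       alpha_deg = sidecar$alpha_deg))
  timings["traits"] <- tic() - t0
  list(record = record, structure = struct, mask = mask_cal,
       image = img_cal, timings = timings)
}

#' Batch analysis to CSV
#'
#' Processes images in order, appending one CSV row each; failures are
#' logged and skipped so a partial CSV is preserved. Per-stage timings go
#' to the log.
#'
#' @param image_paths Character vector of PNG paths.
#' @param sidecar_paths Matching sidecar JSON paths (NA allowed).
#' @param out_dir Output directory (created if needed): `traits.csv`,
#'   per-image QC label PNGs, `log.txt`.
#' @param mask_paths Optional matching external mask paths (NA allowed).
#' @param config A [pipeline_config()].
#' @param models Optional biomass models.
#' @param qc Write QC organ-label composites (default TRUE).
#' @return Invisibly, the trait data frame; attribute `n_failed` counts
#'   failed images.
#' @export
analyze_images <- function(image_paths, sidecar_paths = NULL,
                           out_dir = ".", mask_paths = NULL,
                           config = pipeline_config(), models = NULL,
                           qc = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat("", file = logf)
  logline("pipeline config: %s", jsonlite::toJSON(unclass(config),
                                                  auto_unbox = TRUE))
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(image_paths)) {
    sc <- if (!is.null(sidecar_paths) && !is.na(sidecar_paths[i]))
      sidecar_paths[i] else NULL
    mk <- if (!is.null(mask_paths) && !is.na(mask_paths[i]))
      mask_paths[i] else NULL
    res <- tryCatch(
      analyze_image(image_paths[i], sc, mask = mk, config = config,
                    models = models),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      logline("FAIL %s: %s", image_paths[i], conditionMessage(res))
      next
    }
    logline("ok %s: %s", image_paths[i],
            paste(sprintf("%s=%.2fs", names(res$timings), res$timings),
                  collapse = " "))
    rows[[length(rows) + 1L]] <- res$record
    if (qc)
      write_image(label_composite(res$structure$labels),
                  file.path(out_dir, sprintf("qc_%03d.png", i)))
    df <- do.call(rbind, rows)
    write_traits_csv(df, file.path(out_dir, "traits.csv"))
  }
  if (length(rows) == 0L) {
    write_traits_csv(NULL, file.path(out_dir, "traits.csv"))
    df <- read_traits_csv(file.path(out_dir, "traits.csv"))
  }
  attr(df, "n_failed") <- n_failed
  invisible(df)
}

# QC render: stem red, leaves cycling colours
label_composite <- function(labels) {
  pal <- rbind(c(0.85, 0.15, 0.15), c(0.20, 0.65, 0.20), c(0.20, 0.45, 0.85),
               c(0.90, 0.75, 0.10), c(0.70, 0.30, 0.75), c(0.10, 0.75, 0.75),
               c(0.95, 0.50, 0.10), c(0.55, 0.80, 0.25))
  out <- array(0, c(nrow(labels), ncol(labels), 3))
  mx <- max(labels)
  for (k in seq_len(mx)) {
    col <- pal[(k - 1L) %% nrow(pal) + 1L, ]
    sel <- labels == k
    for (ch in 1:3) {
      pl <- out[, , ch]; pl[sel] <- col[ch]; out[, , ch] <- pl
    }
  }
  out
}

#' Simulate a fixture set
#'
#' Renders `n` seeded synthetic plants (optionally tilted), writing images,
#' truth masks, sidecars and a ground-truth CSV. Byte-identical for a given
#' seed.
#'
#' @param n Number of plants.
#' @param seed Base seed; plant i uses `seed + i - 1`.
#' @param out_dir Output directory.
#' @param alpha_deg Depression angle applied to the rendered image (0 =
#'   front view).
#' @param spec_fn Function `seed -> plant_spec`; defaults to
#'   [random_plant_spec()].
#' @return Invisibly, the ground-truth data frame.
#' @export
simulate_plants <- function(n, seed = 0L, out_dir = ".", alpha_deg = 0,
                            spec_fn = random_plant_spec) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth_rows <- list()
  for (i in seq_len(n)) {
    s <- seed + i - 1L
    plant <- generate_plant(spec_fn(s))
    if (alpha_deg != 0) {
      tilted <- render_tilted(plant, alpha_deg)
      img <- tilted$rgb; msk <- tilted$mask; sc <- tilted$sidecar
    } else {
      img <- plant$rgb; msk <- plant$mask
      sc <- list(alpha_deg = 0, gamma_deg = 0, beta_max_deg = 33,
                 mm_per_px = plant$mm_per_px,
                 plant_id = sprintf("synthetic-%04d", s),
                 datetime = "2026-01-01T00:00:00")
    }
    base <- file.path(out_dir, sprintf("plant_%04d", s))
    write_image(img, paste0(base, ".png"))
    write_image(msk, paste0(base, "_mask.png"))
    write_sidecar(sc, paste0(base, ".json"))
    tr <- plant$truth
    truth_rows[[i]] <- data.frame(
      plant_id = sc$plant_id, seed = s, MPH = tr$MPH, PW = tr$PW,
      TPA = tr$TPA, SH = tr$SH, SPA = tr$SPA, LN = tr$LN, TLL = tr$TLL)
  }
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(truth)
}

#' Fit biomass models from trait and target tables
#'
#' Runs [stepwise_fit()] for every target column, writes one model JSON per
#' target plus a JSON report of training MAPE and R-squared.
#'
#' @param traits Data frame or CSV path of image traits.
#' @param targets Data frame or CSV path of measured targets (columns =
#'   target names), same row order.
#' @param out_dir Output directory for `model_<target>.json` and
#'   `biomass_report.json`.
#' @param config A [pipeline_config()] (stepwise thresholds).
#' @param candidates Candidate predictor names (default trait set).
#' @return Invisibly, a named list of `trait_model`s.
#' @export
fit_biomass <- function(traits, targets, out_dir = ".",
                        config = pipeline_config(), candidates = NULL) {
  if (is.character(traits)) traits <- utils::read.csv(traits)
  if (is.character(targets)) targets <- utils::read.csv(targets)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- list()
  report <- list()
  for (tg in names(targets)) {
    m <- stepwise_fit(traits, targets[[tg]], candidates = candidates,
                      p_enter = config$p_enter, p_remove = config$p_remove,
                      target = tg)
    models[[tg]] <- m
    model_to_json(m, file.path(out_dir, sprintf("model_%s.json", tg)))
    report[[tg]] <- list(predictors = m$predictors, r2 = m$r2, mape = m$mape,
                         n = m$n)
  }
  jsonlite::write_json(report, file.path(out_dir, "biomass_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(models)
}
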