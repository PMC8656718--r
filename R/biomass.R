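# Stepwise multiple linear regression linking image traits to destructively
# measured targets (leaf area, leaf/stem/total dry weight). Forward entry
# by partial-F test (p-to-enter 0.05), backward removal (p-to-remove 0.10),
# deterministic given the input: ties are broken by larger partial F, then
# alphabetically. Model accuracy is reported as MAPE and as the square of
# the Pearson correlation between prediction and truth (which differs from
# 1 - SSE/SST off the 1:1 line).

default_candidates <- c("TPA", "TLPA", "TLL", "SPA", "SV", "SH", "MPH")

partial_f_p <- function(fit0, fit1) {
  rss0 <- sum(stats::resid(fit0)^2)
  rss1 <- sum(stats::resid(fit1)^2)
  df1 <- stats::df.residual(fit1)
  if (df1 <= 0 || rss1 <= 0) return(c(f = Inf, p = 0))
  f <- (rss0 - rss1) / (rss1 / df1)
  c(f = f, p = stats::pf(f, 1, df1, lower.tail = FALSE))
}

#' Stepwise linear model for a biomass target
#'
#' @param X Data frame of candidate predictor columns (image traits).
#' @param y Numeric target vector (destructive measurement).
#' @param candidates Candidate predictor names; defaults to the trait set
#'   TPA, TLPA, TLL, SPA, SV, SH, MPH (those present in `X`).
#' @param p_enter,p_remove Partial-F thresholds for forward entry and
#'   backward removal.
#' @param target Name recorded on the model (for reports).
#' @return Object of class `trait_model`: selected predictors, coefficients,
#'   training R-squared (squared Pearson correlation) and MAPE. An empty
#'   selection yields an intercept-only model.
#' @export
stepwise_fit <- function(X, y, candidates = NULL, p_enter = 0.05,
                         p_remove = 0.10, target = "target") {
  candidates <- sort(candidates %||% intersect(default_candidates, names(X)))
  stopifnot(all(candidates %in% names(X)), length(y) == nrow(X))
  if (anyNA(X[, candidates]) || anyNA(y))
    stop("missing values in candidates or target", call. = FALSE)
  if (nrow(X) <= length(candidates) + 2)
    stop("need more rows than candidate predictors + 2", call. = FALSE)
  dat <- cbind(X[, candidates, drop = FALSE], .y = y)
  sel <- character(0)
  sst <- sum((y - mean(y))^2)
  repeat {
    changed <- FALSE
    # forward: best candidate by partial F
    pool <- setdiff(candidates, sel)
    fit0 <- stats::lm(mk_formula(sel), data = dat)
    perfect <- sum(stats::resid(fit0)^2) <= 1e-10 * max(sst, 1e-300)
    if (length(pool) && !perfect) {
      stats_in <- t(vapply(pool, function(v)
        partial_f_p(fit0, stats::lm(mk_formula(c(sel, v)), data = dat)),
        numeric(2)))
      ord <- order(stats_in[, "p"], -stats_in[, "f"], pool)
      bi <- ord[1]
      if (is.finite(stats_in[bi, "p"]) && stats_in[bi, "p"] <= p_enter) {
        sel <- c(sel, pool[bi])
        changed <- TRUE
      }
    }
    # backward: worst selected by partial F
    if (length(sel) > 0) {
      fit1 <- stats::lm(mk_formula(sel), data = dat)
      if (anyNA(stats::coef(fit1))) {
        drop <- names(which(is.na(stats::coef(fit1))))[1]
        warning("dropping aliased predictor ", drop, call. = FALSE)
        sel <- setdiff(sel, drop)
        changed <- TRUE
      } else {
        stats_out <- t(vapply(sel, function(v)
          partial_f_p(stats::lm(mk_formula(setdiff(sel, v)), data = dat),
                      fit1), numeric(2)))
        ord <- order(-stats_out[, "p"], stats_out[, "f"], sel)
        wi <- ord[1]
        if (stats_out[wi, "p"] > p_remove) {
          sel <- setdiff(sel, sel[wi])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  fit <- stats::lm(mk_formula(sel), data = dat)
  pred <- stats::fitted(fit)
  ev <- evaluate_predictions(pred, y, clip = FALSE)
  structure(list(target = target, predictors = sel,
                 coefficients = stats::coef(fit),
                 r2 = ev$r2, mape = ev$mape, n = nrow(X)),
            class = "trait_model")
}

mk_formula <- function(sel) {
  stats::as.formula(paste(".y ~", if (length(sel)) paste(sel, collapse = " + ")
                          else "1"))
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("trait_model for %s: %s (R2 = %.3f, MAPE = %.2f%%, n = %d)\n",
              x$target,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "(intercept only)",
              x$r2, x$mape, x$n))
  invisible(x)
}

#' Predict a biomass target from traits
#'
#' Linear prediction; negative estimates are clipped to 0 (biomass cannot
#' be negative) with a warning counting the clipped rows.
#'
#' @param object A `trait_model`.
#' @param newdata Data frame containing the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of estimates with attribute `n_clipped`.
#' @export
predict.trait_model <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  co <- object$coefficients
  est <- rep(co[["(Intercept)"]], nrow(newdata))
  for (v in object$predictors) est <- est + co[[v]] * newdata[[v]]
  ncl <- sum(est < 0)
  if (ncl > 0) {
    warning(sprintf("%d negative estimate(s) clipped to 0", ncl),
            call. = FALSE)
    est[est < 0] <- 0
  }
  attr(est, "n_clipped") <- ncl
  est
}

#' MAPE and R-squared of predictions
#'
#' MAPE is the mean absolute percentage error over entries with nonzero
#' truth (excluded entries are counted); R-squared is the squared Pearson
#' correlation between prediction and truth.
#'
#' @param pred,truth Equal-length numeric vectors (length >= 2).
#' @param clip Clip negative predictions to zero first (default FALSE).
#' @return List with `mape` (percent), `r2`, `n`, `n_zero_excluded`.
#' @export
evaluate_predictions <- function(pred, truth, clip = FALSE) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  if (clip) pred <- pmax(pred, 0)
  nz <- truth != 0
  mape <- if (any(nz)) mean(abs(pred[nz] - truth[nz]) / abs(truth[nz])) * 100
  else NA_real_
  r2 <- if (stats::sd(pred) < 1e-12 || stats::sd(truth) < 1e-12) NA_real_
  else stats::cor(pred, truth)^2
  list(mape = mape, r2 = r2, n = length(truth), n_zero_excluded = sum(!nz))
}

#' Serialize / restore a trait model
#'
#' @param model A `trait_model`.
#' @param path JSON file path.
#' @export
model_to_json <- function(model, path) {
  obj <- unclass(model)
  obj$coefficients <- as.list(obj$coefficients)  # keep names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  m$predictors <- as.character(m$predictors %||% character(0))
  structure(m, class = "trait_model")
}
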