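# Internal helpers shared across modules. Raster conventions used throughout
# the package:
#   * RGB images  : numeric array [row, col, 3], values in [0, 1]
#   * gray rasters: numeric matrix [row, col]
#   * masks       : logical matrix [row, col]
# Row 1 is the top of the image. Centered coordinates (geometry module) put
# the origin at the raster center with y pointing up.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 8-neighbourhood offsets, fixed order (row-major around the pixel)
NB8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("'%s' must be a logical matrix", arg), call. = FALSE)
  invisible(mask)
}

as_mask <- function(x) {
  if (is.logical(x) && is.matrix(x)) return(x)
  m <- x > 0
  storage.mode(m) <- "logical"
  m
}

# shift matrix content by (dr, dc); vacated cells get `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) < 1L || length(sc) < 1L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

# number of TRUE 8-neighbours per cell of a logical matrix
neighbour_count <- function(mask) {
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(NB8)))
    acc <- acc + shift_mat(mask, NB8[k, 1L], NB8[k, 2L], FALSE)
  acc
}

# Pixel adjacency graph over the linear indices `idx` of an nr x nc grid.
# Edges between 8-adjacent members; weight = step length (1 or sqrt(2)),
# optionally scaled by the mean of a per-pixel cost.
pixel_graph <- function(idx, dim, cost = NULL) {
  nr <- dim[1L]; nc <- dim[2L]
  idx <- sort(idx)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0); w <- numeric(0)
  dirs <- cbind(dr = c(0L, 1L, 1L, 1L), dc = c(1L, 0L, 1L, -1L))
  for (k in 1:4) {
    dr <- dirs[k, 1L]; dc <- dirs[k, 2L]
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    p <- pos[nb]
    keep <- p > 0L
    f <- pos[idx[ok]][keep]; t <- p[keep]
    step <- if (dr != 0L && dc != 0L) sqrt(2) else 1
    wk <- rep(step, length(f))
    if (!is.null(cost)) wk <- wk * (cost[idx[ok]][keep] + cost[nb[keep]]) / 2
    from <- c(from, f); to <- c(to, t); w <- c(w, wk)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  igraph::set_vertex_attr(g, "pixel", value = idx)
}

# 8-connected labelling of a logical matrix; returns integer matrix (0 = bg),
# labels ordered by decreasing component size
label8 <- function(mask) {
  assert_mask(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  g <- pixel_graph(idx, dim(mask))
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relab <- integer(comp$no)
  relab[ord] <- seq_len(comp$no)
  lab[sort(idx)] <- relab[comp$membership]
  lab
}

# bilinear sampling of a matrix at fractional (row, col); out-of-range -> fill
interp_bilinear <- function(m, rs, cs, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(fill, length(rs))
  eps <- 1e-6  # tolerate FP jitter at the exact grid border
  ok <- rs >= 1 - eps & rs <= nr + eps & cs >= 1 - eps & cs <= nc + eps &
    is.finite(rs) & is.finite(cs)
  if (!any(ok)) return(out)
  r <- pmin(pmax(rs[ok], 1), nr); c <- pmin(pmax(cs[ok], 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  v <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  out[ok] <- v
  out
}

# length of a pixel polyline (n x 2 matrix of row, col), optionally
# subsampled every `by` vertices to suppress digital staircase bias
polyline_length <- function(path, by = 1L) {
  n <- nrow(path)
  if (is.null(n) || n < 2L) return(0)
  if (by > 1L) {
    keep <- unique(c(seq(1L, n, by = by), n))
    path <- path[keep, , drop = FALSE]
  }
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Read an 8-bit RGB image
#'
#' @param path PNG file path.
#' @return Numeric array `[row, col, 3]` with values in `[0, 1]`. Grayscale
#'   input is replicated across channels; an alpha channel is dropped.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Write an RGB image or mask as PNG
#'
#' @param img RGB array, gray matrix, or logical mask (written as 0/255).
#' @param path Output PNG path.
#' @export
write_image <- function(img, path) {
  if (is.logical(img)) img <- matrix(as.numeric(img), nrow(img), ncol(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Read a sidecar metadata record
#'
#' Sidecar JSON per image mirrors what the capture app records: device
#' angles, camera field of view, pixel scale and plant identity.
#'
#' @param path JSON file path.
#' @return Named list with at least `alpha_deg`, `gamma_deg`, `beta_max_deg`.
#'   Missing angles default to 0; missing `beta_max_deg` defaults to 33.
#' @export
read_sidecar <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$alpha_deg <- s$alpha_deg %||% 0
  s$gamma_deg <- s$gamma_deg %||% 0
  s$beta_max_deg <- s$beta_max_deg %||% 33
  s
}

#' @rdname read_sidecar
#' @param sidecar Named list to serialize.
#' @export
write_sidecar <- function(sidecar, path) {
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
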