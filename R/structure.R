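# Organ decomposition of the skeleton.
#
# The lowest skeleton endpoint is the plant root. Shortest routes from the
# root to every other endpoint are traced along the skeleton and overlaid:
# pixels crossed by two or more routes form the stem axis (the shared trunk
# of the route bundle), and what remains of each route past its divergence
# point is that leaf's mid axis. Every foreground pixel is then assigned to
# an organ: a stem band whose half-width follows the local distance
# transform, and geodesic (within-mask) nearest-axis assignment for the
# leaves, so an overhanging leaf cannot capture pixels of the leaf below it
# across background.

#' Skeleton endpoints, lowest first
#'
#' @param g A [skeleton_graph()].
#' @return `n x 2` row/col matrix of degree-1 pixels, sorted by image row
#'   descending (first row = root candidate).
#' @export
find_endpoints <- function(g) {
  eps <- g$endpoints
  if (nrow(eps) < 2L)
    stop("degenerate skeleton: fewer than 2 endpoints", call. = FALSE)
  eps[order(-eps[, 1L], eps[, 2L]), , drop = FALSE]
}

#' Trace root-to-endpoint routes
#'
#' Shortest pixel paths (unit steps, sqrt(2) diagonals) from the root (the
#' lowest endpoint) to every other endpoint, plus the per-pixel traversal
#' multiplicity of the overlaid bundle. A disconnected skeleton is handled
#' by processing its largest component (with a warning).
#'
#' @param g A [skeleton_graph()].
#' @return Object of class `route_set`: `root` (row, col), `routes` (list of
#'   pixel paths, root first), `multiplicity` (integer matrix).
#' @export
trace_routes <- function(g) {
  skel <- g$pixels
  comp <- label8(skel)
  if (max(comp) > 1L) {
    warning("disconnected skeleton: tracing routes on the largest component",
            call. = FALSE)
    skel <- comp == 1L
  }
  ncnt <- neighbour_count(skel)
  eps <- which(skel & ncnt == 1L, arr.ind = TRUE)
  if (nrow(eps) < 2L)
    stop("degenerate skeleton: fewer than 2 endpoints", call. = FALSE)
  eps <- eps[order(-eps[, 1L], eps[, 2L]), , drop = FALSE]
  nr <- nrow(skel)
  idx <- which(skel)
  gg <- pixel_graph(idx, dim(skel))
  pix <- igraph::vertex_attr(gg, "pixel")
  vid <- function(r, c) match((c - 1L) * nr + r, pix)
  root <- eps[1L, ]
  targets <- eps[-1L, , drop = FALSE]
  paths <- igraph::shortest_paths(
    gg, from = vid(root[1L], root[2L]),
    to = vapply(seq_len(nrow(targets)),
                function(i) vid(targets[i, 1L], targets[i, 2L]), integer(1)),
    output = "vpath")$vpath
  mult <- matrix(0L, nrow(skel), ncol(skel))
  routes <- lapply(paths, function(vp) {
    p <- pix[as.integer(vp)]
    cbind(row = ((p - 1L) %% nr) + 1L, col = ((p - 1L) %/% nr) + 1L)
  })
  for (rt in routes) mult[rt] <- mult[rt] + 1L
  structure(list(root = root, routes = routes, multiplicity = mult),
            class = "route_set")
}

#' Extract the stem axis
#'
#' The stem is the maximal shared run of the route bundle: the connected
#' stretch of pixels with traversal multiplicity at least 2, starting at the
#' root and ordered bottom-up. A single-leaf plant (one route) has no shared
#' run; its stem is the route truncated at the highest junction if one
#' exists, else at a configured fraction of the route.
#'
#' @param r A `route_set` from [trace_routes()].
#' @param single_route_frac Stem fraction of the only route when just one
#'   route exists and the skeleton has no junction.
#' @return `n x 2` ordered pixel path, root first.
#' @export
extract_stem <- function(r, single_route_frac = 0.6) {
  if (length(r$routes) == 1L) {
    rt <- r$routes[[1L]]
    n <- nrow(rt)
    return(rt[seq_len(max(2L, round(single_route_frac * n))), , drop = FALSE])
  }
  shared <- r$multiplicity >= 2L
  best <- NULL
  for (rt in r$routes) {
    inshared <- shared[rt]
    k <- if (all(inshared)) nrow(rt) else which(!inshared)[1L] - 1L
    if (k >= 1L && (is.null(best) || k > nrow(best)))
      best <- rt[seq_len(k), , drop = FALSE]
  }
  if (is.null(best)) best <- r$routes[[1L]][1L, , drop = FALSE]
  best
}

#' Extract individual leaves
#'
#' Each non-root endpoint is a leaf apex; its mid axis is its route minus
#' the stem pixels, and its insertion node is the last route pixel still on
#' the stem. Leaves are ordered by insertion height bottom-up and split into
#' lower/upper halves at the stem's midpoint height.
#'
#' Where a leaf blade merges into the stem the skeleton branch point is
#' displaced along the stem by roughly the local half-width, and the first
#' stretch of the skeletal leaf axis cuts across the merge wedge. When a
#' distance map is supplied, the insertion is therefore refined: the leaf
#' midline tangent is fitted just past the wedge (skipping one local
#' half-width of arc) and extrapolated back to the stem axis; the
#' intersection becomes the insertion node and the buried straight segment
#' is credited to the leaf axis (`base_len`, used by [leaf_geometry()]).
#'
#' @param r A `route_set`.
#' @param stem Stem axis from [extract_stem()].
#' @param dmap Optional distance map enabling insertion refinement.
#' @param tangent_window_px Arc length over which the base tangent is fitted.
#' @return List of leaf records: `apex`, `insertion` (row/col, fractional
#'   after refinement), `branch` (the raw skeleton branch point), `axis`
#'   (ordered pixel path from branch to apex), `axis_start` (index into
#'   `axis` where the blade midline becomes reliable), `base_len` (buried
#'   axis length in px), `below` (inserted in the lower half of the stem).
#' @export
extract_leaves <- function(r, stem, dmap = NULL, tangent_window_px = 15L) {
  stem_key <- paste(stem[, 1L], stem[, 2L])
  mid_row <- (stem[1L, 1L] + stem[nrow(stem), 1L]) / 2
  if (!is.null(dmap)) {
    stem_smooth <- smooth_stem_axis(stem)
    half_w <- stats::median(dmap[stem])
  }
  leaves <- list()
  for (rt in r$routes) {
    on_stem <- paste(rt[, 1L], rt[, 2L]) %in% stem_key
    if (all(on_stem)) next  # the route that *is* the stem top
    if (!any(on_stem)) {
      warning("leaf route never touches the stem; inserting at root",
              call. = FALSE)
      ins_i <- 1L
    } else {
      ins_i <- max(which(on_stem))
    }
    axis <- rt[ins_i:nrow(rt), , drop = FALSE]
    if (nrow(axis) < 2L) next
    branch <- as.numeric(rt[ins_i, ])
    leaf <- list(apex = rt[nrow(rt), ], insertion = branch, branch = branch,
                 axis = axis, axis_start = 1L, base_len = 0,
                 tip_len = if (is.null(dmap)) 0
                           else dmap[rt[nrow(rt), 1L], rt[nrow(rt), 2L]])
    if (!is.null(dmap))
      leaf <- refine_insertion(leaf, stem_smooth, dmap, half_w,
                               tangent_window_px)
    leaf$below <- leaf$insertion[1L] > mid_row
    leaves[[length(leaves) + 1L]] <- leaf
  }
  ord <- order(-vapply(leaves, function(l) l$insertion[1L], numeric(1)))
  leaves[ord]
}

# Quadratic backtracking of the blade midline into the stem. The detected
# axis outside the merge wedge is a clean sample of the blade midline; both
# coordinates are fitted as quadratics in arc length over the first clear
# stretch and extrapolated backward until the curve meets the stem axis
# (argmin of the distance to the stem polyline, capped at a plausible
# buried arc). Returns NULL when the extrapolation does not come close to
# the stem, in which case the caller falls back to a straight tangent
# intersection.
quad_backtrack <- function(ax, a0, stem_smooth) {
  n <- nrow(ax)
  b <- min(n, a0 + 40L)
  if (b - a0 < 10L) return(NULL)
  seg <- ax[a0:b, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(seg)^2))))
  X <- cbind(1, s, s^2)
  cr <- stats::lm.fit(X, seg[, 1L])$coefficients
  cc <- stats::lm.fit(X, seg[, 2L])$coefficients
  perp <- sqrt(min((stem_smooth[, 1L] - ax[a0, 1L])^2 +
                     (stem_smooth[, 2L] - ax[a0, 2L])^2))
  cap <- 3 * perp + 10
  sb <- seq(0, -cap, by = -0.5)
  pr <- cr[1L] + cr[2L] * sb + cr[3L] * sb^2
  pc <- cc[1L] + cc[2L] * sb + cc[3L] * sb^2
  d <- vapply(seq_along(sb), function(i)
    min((stem_smooth[, 1L] - pr[i])^2 + (stem_smooth[, 2L] - pc[i])^2),
    numeric(1))
  i0 <- which.min(d)
  dmin <- sqrt(d[i0])
  if (dmin > 5 || i0 == 1L) return(NULL)
  j <- which.min((stem_smooth[, 1L] - pr[i0])^2 +
                   (stem_smooth[, 2L] - pc[i0])^2)
  list(S = as.numeric(stem_smooth[j, ]), base_len = abs(sb[i0]) + dmin)
}

# Locally weighted smoothing of the stem axis. Inside a leaf-stem merge
# wedge the medial axis bulges toward the blade; smoothing both coordinates
# against arc index recovers the underlying near-straight stem line.
smooth_stem_axis <- function(stem) {
  n <- nrow(stem)
  if (n < 10L) return(stem)
  f <- max(0.25, min(0.5, 40 / n))
  cbind(stats::lowess(seq_len(n), stem[, 1L], f = f)$y,
        stats::lowess(seq_len(n), stem[, 2L], f = f)$y)
}

refine_insertion <- function(leaf, stem_smooth, dmap, half_w,
                             tangent_window_px = 15L) {
  ax <- leaf$axis
  n <- nrow(ax)
  # distance of each axis pixel to the smoothed stem line, and the index
  # where the axis has genuinely cleared the stem band
  nearest <- vapply(seq_len(n), function(i) {
    d2 <- (stem_smooth[, 1L] - ax[i, 1L])^2 + (stem_smooth[, 2L] - ax[i, 2L])^2
    j <- which.min(d2)
    c(sqrt(d2[j]), j)
  }, numeric(2))
  # cleared once the blade tube no longer overlaps the stem tube
  blade_hw <- pmax(dmap[ax], 2)
  clear <- nearest[1L, ] > half_w + blade_hw
  a <- which(clear)[1L]
  if (is.na(a) || a > n - 4L) return(leaf)
  qb <- quad_backtrack(ax, a, stem_smooth)
  if (!is.null(qb)) {
    leaf$insertion <- qb$S
    leaf$axis_start <- a
    leaf$base_len <- qb$base_len
    return(leaf)
  }
  cum <- c(0, cumsum(sqrt(rowSums(diff(ax)^2))))
  b <- which(cum >= cum[a] + tangent_window_px)[1L]
  if (is.na(b)) b <- n
  if (b - a < 3L) return(leaf)
  u <- as.numeric(ax[a, ] - ax[b, ])  # base tangent, pointing stemward
  un <- sqrt(sum(u^2))
  if (un < 1e-9) return(leaf)
  u <- u / un
  # local direction of the smoothed stem around the nearest point
  j <- nearest[2L, a]
  w <- stem_smooth[max(1L, j - tangent_window_px):
                     min(nrow(stem_smooth), j + tangent_window_px), ,
                   drop = FALSE]
  s <- as.numeric(w[nrow(w), ] - w[1L, ])
  sn <- sqrt(sum(s^2))
  if (sn < 1e-9) return(leaf)
  s <- s / sn
  p0 <- as.numeric(stem_smooth[j, ])
  A <- cbind(s, -u)
  if (abs(det(A)) < 1e-6) return(leaf)  # near-parallel: keep branch
  t12 <- solve(A, as.numeric(ax[a, ]) - p0)
  if (t12[2L] < 0 || t12[2L] > 3 * (half_w + 2) + cum[a])
    return(leaf)  # implausible extrapolation: keep branch
  S <- p0 + t12[1L] * s
  leaf$insertion <- S
  leaf$axis_start <- a
  leaf$base_len <- sqrt(sum((S - as.numeric(ax[a, ]))^2))
  leaf
}

#' Assign every foreground pixel to an organ
#'
#' Stem first: pixels within the local distance-transform half-width of the
#' stem axis form the stem band. Remaining foreground is assigned to the
#' leaf whose mid axis is geodesically nearest within the mask. The labels
#' partition the foreground exactly.
#'
#' @param mask Logical plant mask.
#' @param stem Stem axis pixel path.
#' @param leaves Leaf records from [extract_leaves()].
#' @param dmap Distance map of `mask`.
#' @param max_radius Optional cap on the stem half-width (prevents the band
#'   from swallowing blade pixels inside leaf-stem merge wedges, where the
#'   distance transform is inflated).
#' @return Integer matrix: 0 background, 1 stem, `1 + i` for leaf `i`
#'   (bottom-up insertion order).
#' @export
assign_pixels <- function(mask, stem, leaves, dmap, max_radius = Inf) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  # stem band: stamp a disc of the local half-width at every axis pixel
  for (i in seq_len(nrow(stem))) {
    r <- stem[i, 1L]; c <- stem[i, 2L]
    rad <- min(dmap[r, c], max_radius) + 0.5
    ri <- max(1L, floor(r - rad)):min(nr, ceiling(r + rad))
    ci <- max(1L, floor(c - rad)):min(nc, ceiling(c + rad))
    sub <- outer(ri - r, ci - c, function(a, b) sqrt(a^2 + b^2)) <= rad
    lab[ri, ci][sub & mask[ri, ci]] <- 1L
  }
  nleaf <- length(leaves)
  if (nleaf == 0L) {
    lab[mask & lab == 0L] <- 1L
    return(lab)
  }
  remaining <- mask & lab == 0L
  seed_idx <- lapply(leaves, function(l)
    unique((l$axis[, 2L] - 1L) * nr + l$axis[, 1L]))
  universe <- sort(unique(c(which(remaining), unlist(seed_idx))))
  g <- pixel_graph(universe, dim(mask))
  pix <- igraph::vertex_attr(g, "pixel")
  nv <- igraph::vcount(g)
  g <- igraph::add_vertices(g, nleaf)
  for (j in seq_len(nleaf)) {
    members <- which(pix %in% seed_idx[[j]])
    g <- igraph::add_edges(g, rbind(nv + j, members),
                           weight = rep(1e-9, length(members)))
  }
  d <- igraph::distances(g, v = nv + seq_len(nleaf), to = seq_len(nv))
  nearest <- apply(d, 2L, which.min)
  reach <- apply(d, 2L, function(x) any(is.finite(x)))
  tgt <- pix[reach]
  keepmask <- remaining[tgt]
  lab[tgt[keepmask]] <- nearest[reach][keepmask] + 1L
  # pixels cut off by the stem band: fall back to nearest axis by Euclidean
  left <- which(mask & lab == 0L)
  if (length(left)) {
    lr <- ((left - 1L) %% nr) + 1L; lc <- ((left - 1L) %/% nr) + 1L
    for (ii in seq_along(left)) {
      best <- 1L; bestd <- Inf
      for (j in seq_len(nleaf)) {
        ax <- leaves[[j]]$axis
        dj <- min((ax[, 1L] - lr[ii])^2 + (ax[, 2L] - lc[ii])^2)
        if (dj < bestd) { bestd <- dj; best <- j + 1L }
      }
      lab[left[ii]] <- best
    }
  }
  lab
}

#' Decompose a plant mask into stem and leaves
#'
#' Full structural decomposition: endpoints, route overlay, stem extraction,
#' leaf extraction and per-pixel organ assignment.
#'
#' @param mask Logical plant mask.
#' @param skel A [skeleton_graph()] of `mask` (computed if `NULL`).
#' @param cfg A [skeleton_config()] used when `skel` is `NULL`.
#' @return Object of class `plant_structure`: `stem` (axis path), `leaves`
#'   (records from [extract_leaves()]), `labels` (organ raster), `routes`
#'   (the `route_set`), `dmap`.
#' @export
plant_structure <- function(mask, skel = NULL, cfg = skeleton_config()) {
  if (is.null(skel)) skel <- skeletonize(mask, cfg)
  routes <- trace_routes(skel)
  stem_raw <- extract_stem(routes)
  dmap <- skel$dt
  leaves <- extract_leaves(routes, stem_raw, dmap)
  # medial-axis bulges inside leaf-stem wedges are smoothed out of the stem
  # axis; the shared-route overlay also overshoots into the apex blob where
  # the top leaves merge, so the stem is truncated at the topmost refined
  # insertion
  stem <- smooth_stem_axis(stem_raw)
  half_w <- stats::median(dmap[stem_raw])
  if (length(leaves)) {
    # the shared-route overlay overshoots into the apex blob where the top
    # leaves merge; truncate the stem at the topmost refined insertion
    top_row <- min(vapply(leaves, function(l) l$insertion[1L], numeric(1)))
    cut <- which(stem[, 1L] <= top_row)[1L]
    if (!is.na(cut) && cut >= 2L) stem <- stem[seq_len(cut), , drop = FALSE]
    mid_row <- (stem[1L, 1L] + stem[nrow(stem), 1L]) / 2
    for (i in seq_along(leaves))
      leaves[[i]]$below <- leaves[[i]]$insertion[1L] > mid_row
  }
  labels <- assign_pixels(mask, round(stem), leaves, dmap,
                          max_radius = half_w + 1)
  structure(list(stem = stem, stem_raw = stem_raw, leaves = leaves,
                 labels = labels, routes = routes, dmap = dmap,
                 skeleton = skel),
            class = "plant_structure")
}

#' @export
print.plant_structure <- function(x, ...) {
  cat(sprintf("plant_structure: stem of %d px, %d leaves\n",
              nrow(x$stem), length(x$leaves)))
  invisible(x)
}
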