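# Two-step distance-transform skeletonization.
#
# Step 1 ranks every foreground pixel by how many of its 8 neighbours have a
# strictly smaller distance-transform value. Pixels beating at least 3
# neighbours form the seed set (ridge fragments); pixels beating at least 2
# form a looser routing pool. Step 2 connects the seed fragments into one
# curve per foreground component by lowest-cost paths through the pool,
# stepping preferentially along the distance-transform ridge (cost of
# entering a pixel q is 1/(1 + DT(q))), and finally applies
# connectivity-preserving conditional thinning so the result is at most two
# pixels wide without losing endpoints.

#' Euclidean distance transform
#'
#' Exact Euclidean distance to the nearest background pixel, with the image
#' border treated as background.
#'
#' @param mask Logical foreground mask; must contain at least one pixel.
#' @return Numeric matrix: 0 on background, positive on foreground.
#' @export
distance_transform <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  d <- EBImage::distmap(pad, metric = "euclidean")
  matrix(d@.Data[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)],
         nrow(mask), ncol(mask))
}

#' Skeleton candidate set
#'
#' Pixels whose distance-transform value strictly exceeds that of at least
#' `n` of their 8 neighbours; neighbours outside the image count as distance
#' 0. Larger `n` is a stricter test, so `candidate_set(d, n+1)` is nested in
#' `candidate_set(d, n)`.
#'
#' @param dmap Distance map from [distance_transform()].
#' @param n Minimum number of strictly smaller neighbours, in 2..8.
#' @return Logical matrix with attribute `n`.
#' @export
candidate_set <- function(dmap, n) {
  stopifnot(n >= 2, n <= 8)
  smaller <- matrix(0L, nrow(dmap), ncol(dmap))
  for (k in seq_len(nrow(NB8))) {
    nb <- shift_mat(dmap, NB8[k, 1L], NB8[k, 2L], 0)
    smaller <- smaller + (dmap > nb)
  }
  out <- dmap > 0 & smaller >= n
  attr(out, "n") <- as.integer(n)
  out
}

# conditional thinning of the seed/connector union: two-subiteration
# parallel thinning (vectorized) for the bulk reduction, then a sequential
# polish that deletes redundant staircase-corner pixels (simple points of
# degree >= 2, lowest distance-transform value first) so the result is a
# minimal 8-connected curve and degree >= 3 occurs only at true junctions.
# Connectivity and endpoints are preserved throughout.
thin_conditional <- function(skel, dmap) {
  skel <- zhang_thinning(skel)
  nr <- nrow(skel)
  repeat {
    idx <- which(skel)
    idx <- idx[order(dmap[idx])]
    removed <- FALSE
    for (i in idx) {
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      if (local_degree(skel, r, c) < 2L) next
      if (yokoi8(skel, r, c) == 1L) {
        skel[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

# circular 8-neighbourhood order used by the connectivity number
NB8_CIRC <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                  dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L))

# Yokoi connectivity number for 8-connected foreground; a pixel whose
# neighbourhood has connectivity number 1 can be deleted without changing
# the local topology
yokoi8 <- function(skel, r, c) {
  nr <- nrow(skel); nc <- ncol(skel)
  x <- integer(8L)
  for (k in 1:8) {
    rr <- r + NB8_CIRC[k, 1L]; cc <- c + NB8_CIRC[k, 2L]
    x[k] <- if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && skel[rr, cc])
      1L else 0L
  }
  xb <- 1L - x
  s <- 0L
  for (k in c(1L, 3L, 5L, 7L)) {
    k1 <- if (k == 8L) 1L else k + 1L
    k2 <- if (k >= 7L) k - 6L else k + 2L
    s <- s + xb[k] - xb[k] * xb[k1] * xb[k2]
  }
  s
}

# degree of one pixel within a skeleton raster
local_degree <- function(skel, r, c) {
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- 0L
  for (k in 1:8) {
    rr <- r + NB8[k, 1L]; cc <- c + NB8[k, 2L]
    if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && skel[rr, cc])
      deg <- deg + 1L
  }
  deg
}

#' Skeleton graph object
#'
#' Bundles the skeleton pixel raster with its distance-transform values and
#' the derived node structure (endpoints: exactly one skeleton neighbour;
#' junctions: three or more).
#'
#' @param pixels Logical matrix of skeleton pixels.
#' @param dmap Distance map of the originating mask.
#' @return Object of class `skeleton_graph` with fields `pixels`, `dt`,
#'   `endpoints` and `junctions` (n x 2 row/col matrices).
#' @export
skeleton_graph <- function(pixels, dmap) {
  ncnt <- neighbour_count(pixels)
  structure(list(
    pixels = pixels,
    dt = dmap,
    endpoints = which(pixels & ncnt == 1L, arr.ind = TRUE),
    junctions = which(pixels & ncnt >= 3L, arr.ind = TRUE)
  ), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d px, %d endpoints, %d junctions\n",
              sum(x$pixels), nrow(x$endpoints), nrow(x$junctions)))
  invisible(x)
}

#' Connect candidate fragments into a skeleton
#'
#' Seeds (the stricter candidate set) are connected component-by-component
#' through the looser routing pool by lowest-cost ridge paths; the union is
#' then conditionally thinned. If the pool fails to connect two seed
#' fragments that share a foreground component, routing falls back to the
#' whole foreground of that component (with a warning).
#'
#' @param s2,s3 Candidate sets from [candidate_set()] on the same distance
#'   map (order-insensitive: the stricter set is detected from attribute
#'   `n`). The stricter set must be nested in the looser one.
#' @param dmap Distance map.
#' @param mask Originating mask.
#' @return A [skeleton_graph()].
#' @export
connect_skeleton <- function(s2, s3, dmap, mask) {
  if ((attr(s3, "n") %||% 3L) < (attr(s2, "n") %||% 2L)) {
    tmp <- s2; s2 <- s3; s3 <- tmp
  }
  if (any(s3 & !s2))
    stop("stricter candidate set must be contained in the looser one",
         call. = FALSE)
  seeds <- s3 & mask
  pool <- (s2 | s3) & mask
  comp <- label8(mask)
  skel <- matrix(FALSE, nrow(mask), ncol(mask))
  for (ci in seq_len(max(comp))) {
    inc <- comp == ci
    seeds_c <- seeds & inc
    if (!any(seeds_c)) {
      top <- which(inc)[which.max(dmap[inc])]
      seeds_c[top] <- TRUE
    }
    skel_c <- connect_component(seeds_c, pool & inc, inc, dmap)
    skel <- skel | skel_c
  }
  skel <- fill_candidate_holes(skel, mask)
  skeleton_graph(thin_conditional(skel, dmap), dmap)
}

# Interior gaps of the candidate union (pixels that narrowly failed the
# neighbour test inside an otherwise solid candidate region) would survive
# topology-preserving thinning as spurious loops. Fill every hole of the
# union that lies entirely inside the mask foreground; genuine mask holes
# are left open so they still induce skeleton cycles.
fill_candidate_holes <- function(skel, mask) {
  bg <- EBImage::bwlabel((!skel) * 1)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  for (h in setdiff(seq_len(max(bg)), border)) {
    hole <- bg == h
    if (all(mask[hole])) skel[hole] <- TRUE
  }
  skel
}

connect_component <- function(seeds, pool, fg, dmap) {
  seed_lab <- label8(seeds)
  k <- max(seed_lab)
  if (k <= 1L) return(seeds)
  route_set <- pool | seeds
  result <- try_route(seeds, seed_lab, k, route_set, dmap)
  if (is.null(result)) {
    warning("routing pool does not connect all seed fragments; ",
            "falling back to full-foreground routing", call. = FALSE)
    result <- try_route(seeds, seed_lab, k, fg, dmap)
    if (is.null(result)) return(seeds)  # genuinely disconnected foreground
  }
  result
}

# connect k seed components through `through` pixels; NULL if impossible
try_route <- function(seeds, seed_lab, k, through, dmap) {
  idx <- which(through)
  g <- pixel_graph(idx, dim(dmap), cost = 1 / (1 + dmap))
  pix <- igraph::vertex_attr(g, "pixel")
  # one virtual terminal per seed fragment, tied to its pixels
  nv <- igraph::vcount(g)
  g <- igraph::add_vertices(g, k)
  for (j in seq_len(k)) {
    members <- which(pix %in% which(seed_lab == j))
    if (length(members) == 0L) return(NULL)
    g <- igraph::add_edges(g, rbind(nv + j, members),
                           weight = rep(1e-9, length(members)))
  }
  virt <- nv + seq_len(k)
  d <- igraph::distances(g, v = virt, to = virt)
  if (any(!is.finite(d))) return(NULL)
  mst <- igraph::mst(igraph::graph_from_adjacency_matrix(
    d, mode = "undirected", weighted = TRUE, diag = FALSE))
  out <- seeds
  for (e in seq_len(igraph::ecount(mst))) {
    ends <- igraph::ends(mst, e)
    sp <- igraph::shortest_paths(g, from = virt[ends[1]], to = virt[ends[2]],
                                 output = "vpath")$vpath[[1]]
    ids <- as.integer(sp)
    ids <- ids[ids <= nv]
    out[pix[ids]] <- TRUE
  }
  out
}

#' Prune short skeleton spurs
#'
#' Iteratively removes endpoint branches shorter than
#' `max(min_len_px, 1.5 * DT(junction))` — short twigs caused by boundary
#' bumps, whose length is on the order of the local half-width. Branches
#' that span a whole component (endpoint to endpoint) are never removed,
#' so connectivity and all surviving endpoints are preserved. Idempotent.
#'
#' @param g A [skeleton_graph()].
#' @param min_len_px Absolute minimum spur length, pixels.
#' @return Pruned `skeleton_graph`.
#' @export
prune_spurs <- function(g, min_len_px = 10) {
  skel <- g$pixels
  dmap <- g$dt
  nr <- nrow(skel)
  repeat {
    ncnt <- neighbour_count(skel)
    eps <- which(skel & ncnt == 1L, arr.ind = TRUE)
    removed <- FALSE
    if (nrow(eps) > 0) for (i in seq_len(nrow(eps))) {
      r <- eps[i, 1L]; c <- eps[i, 2L]
      if (!skel[r, c] || local_degree(skel, r, c) != 1L) next
      path <- walk_branch(skel, r, c)
      if (is.null(path$junction)) next  # reached another endpoint: keep
      len <- polyline_length(path$pixels)
      if (len < max(min_len_px, 1.5 * dmap[path$junction[1], path$junction[2]])) {
        skel[path$pixels] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
    # removing both branches of a tip fork can leave a junction cluster
    # with no degree-1 pixel; re-thinning collapses it to a clean endpoint
    skel <- thin_conditional(skel, dmap)
  }
  skeleton_graph(skel, dmap)
}

# walk from an endpoint until a junction (>=3 neighbours) or a dead end;
# returns the branch pixels (excluding the junction) and the junction
walk_branch <- function(skel, r, c) {
  nr <- nrow(skel); nc <- ncol(skel)
  path <- matrix(c(r, c), 1, 2)
  prev <- c(0L, 0L)
  cur <- c(r, c)
  repeat {
    nbs <- NULL
    for (k in 1:8) {
      rr <- cur[1] + NB8[k, 1L]; cc <- cur[2] + NB8[k, 2L]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && skel[rr, cc] &&
          !(rr == prev[1] && cc == prev[2]))
        nbs <- rbind(nbs, c(rr, cc))
    }
    if (is.null(nbs)) return(list(pixels = path, junction = NULL))
    if (nrow(nbs) > 1)
      return(list(pixels = path, junction = cur))  # cur adjacent to branchpoint
    nxt <- nbs[1, ]
    deg <- 0L
    for (k in 1:8) {
      rr <- nxt[1] + NB8[k, 1L]; cc <- nxt[2] + NB8[k, 2L]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && skel[rr, cc])
        deg <- deg + 1L
    }
    if (deg >= 3L) return(list(pixels = path, junction = nxt))
    path <- rbind(path, nxt)
    prev <- cur
    cur <- nxt
  }
}

#' Skeletonization settings
#'
#' @param min_len_px Spur-pruning floor at the reference resolution.
#' @param ref_height_px Reference image height the floor is quoted at; the
#'   effective floor scales linearly with the actual image height.
#' @export
skeleton_config <- function(min_len_px = 10, ref_height_px = 2000) {
  list(min_len_px = min_len_px, ref_height_px = ref_height_px)
}

#' Full skeletonization pipeline
#'
#' Distance transform, candidate sets (n = 2 and 3), ridge-path connection
#' and spur pruning.
#'
#' @param mask Logical plant mask.
#' @param cfg A [skeleton_config()].
#' @return A [skeleton_graph()].
#' @export
skeletonize <- function(mask, cfg = skeleton_config()) {
  dmap <- distance_transform(mask)
  s2 <- candidate_set(dmap, 2L)
  s3 <- candidate_set(dmap, 3L)
  g <- connect_skeleton(s2, s3, dmap, mask)
  prune_spurs(g, min_len_px = cfg$min_len_px * nrow(mask) / cfg$ref_height_px)
}

#' Zhang-Suen thinning (baseline)
#'
#' Classical two-subiteration parallel thinning, used as the comparison
#' baseline for [compare_skeletons()].
#'
#' @param mask Logical mask.
#' @return Logical skeleton matrix.
#' @export
zhang_thinning <- function(mask) {
  assert_mask(mask)
  m <- mask
  # neighbour order P2..P9 clockwise from north
  offs <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- lapply(seq_len(8L), function(k)
        shift_mat(m, -offs[k, 1L], -offs[k, 2L], FALSE))
      B <- Reduce(`+`, p)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        k2 <- if (k == 8L) 1L else k + 1L
        A <- A + (!p[[k]] & p[[k2]])
      }
      cond <- m & B >= 2L & B <= 6L & A == 1L
      if (step == 1L)
        cond <- cond & !(p[[1]] & p[[3]] & p[[5]]) & !(p[[3]] & p[[5]] & p[[7]])
      else
        cond <- cond & !(p[[1]] & p[[3]] & p[[7]]) & !(p[[1]] & p[[5]] & p[[7]])
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# distance-transform ridge (local maxima); intentionally unconnected, used
# only as a comparison baseline
medial_axis_ridge <- function(mask) {
  dmap <- distance_transform(mask)
  mx <- matrix(0, nrow(dmap), ncol(dmap))
  for (k in seq_len(nrow(NB8)))
    mx <- pmax(mx, shift_mat(dmap, NB8[k, 1L], NB8[k, 2L], 0))
  dmap > 0 & dmap >= mx
}

#' Compare skeletonization methods
#'
#' Runs the selected methods on one mask and tabulates pixel count, endpoint
#' count, a centredness score (mean distance-transform value on the skeleton
#' minus the foreground mean: larger = closer to the medial ridge) and
#' runtime.
#'
#' @param mask Logical mask.
#' @param methods Subset of `"ours"`, `"zhang_thinning"`, `"medial_axis"`.
#' @return Data frame with one row per method.
#' @export
compare_skeletons <- function(mask,
                              methods = c("ours", "zhang_thinning",
                                          "medial_axis")) {
  known <- c("ours", "zhang_thinning", "medial_axis")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "),
         call. = FALSE)
  dmap <- distance_transform(mask)
  fg_mean <- mean(dmap[mask])
  one <- function(name) {
    t0 <- proc.time()[["elapsed"]]
    px <- switch(name,
                 ours = skeletonize(mask)$pixels,
                 zhang_thinning = zhang_thinning(mask),
                 medial_axis = medial_axis_ridge(mask))
    dt <- proc.time()[["elapsed"]] - t0
    ncnt <- neighbour_count(px)
    data.frame(method = name,
               n_pixels = sum(px),
               n_endpoints = sum(px & ncnt == 1L),
               centredness = mean(dmap[px]) - fg_mean,
               runtime_s = dt)
  }
  do.call(rbind, lapply(methods, one))
}
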