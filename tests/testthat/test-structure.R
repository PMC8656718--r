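# Route overlay, stem/leaf decomposition and per-pixel organ assignment.

line_skeleton <- function() {
  m <- matrix(FALSE, 30, 30)
  m[25:5, 15] <- TRUE
  skeleton_graph(m, distance_transform(m))
}

y_skeleton <- function() {
  # trunk up the middle, forking into two diagonal branches
  m <- matrix(FALSE, 40, 40)
  m[39:20, 20] <- TRUE
  for (i in 1:12) { m[20 - i, 20 - i] <- TRUE; m[20 - i, 20 + i] <- TRUE }
  skeleton_graph(m, distance_transform(m))
}

test_that("endpoints are found and ordered lowest-first", {
  g <- line_skeleton()
  eps <- find_endpoints(g)
  expect_equal(nrow(eps), 2)
  expect_equal(unname(eps[1, 1]), 25)  # lowest first (root candidate)
  expect_equal(nrow(find_endpoints(skeletonize(make_plus()))), 4)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_error(find_endpoints(skeleton_graph(one, distance_transform(one))),
               "degenerate")
})

test_that("route multiplicity marks the shared trunk", {
  gy <- y_skeleton()
  r <- trace_routes(gy)
  expect_equal(length(r$routes), 2)
  expect_true(all(r$multiplicity[39:21, 20] == 2))
  expect_equal(r$multiplicity[8, 8], 1)
  # straight line: one route, multiplicity 1 everywhere on it
  rl <- trace_routes(line_skeleton())
  expect_equal(length(rl$routes), 1)
  expect_true(all(rl$multiplicity[rl$routes[[1]]] == 1))
  # synthetic plant: all routes start at the root
  an <- cached_analysis(0)
  rp <- an$structure$routes
  expect_equal(rp$multiplicity[rp$root[1], rp$root[2]], length(rp$routes))
  # multiplicity never increases along a route away from the root
  for (rt in rp$routes)
    expect_true(all(diff(rp$multiplicity[rt]) <= 0))
})

test_that("stem is the shared run; single-route plants fall back", {
  gy <- y_skeleton()
  r <- trace_routes(gy)
  stem <- extract_stem(r)
  expect_true(all(stem[, 2] == 20))
  expect_gte(min(stem[, 1]), 19)  # stops at the fork
  rl <- trace_routes(line_skeleton())
  stem1 <- extract_stem(rl, single_route_frac = 0.6)
  expect_equal(nrow(stem1), round(0.6 * 21))
  # stem is a prefix of every route up to its divergence point
  an <- cached_analysis(1)
  mult <- an$structure$routes$multiplicity
  for (rt in an$structure$routes$routes) {
    shared <- mult[rt] >= 2
    if (any(!shared))
      expect_true(all(shared[seq_len(which(!shared)[1] - 1)]))
  }
})

test_that("disconnected skeletons are traced on the largest component", {
  m <- matrix(FALSE, 30, 30)
  m[25:5, 10] <- TRUE
  m[25:15, 20] <- TRUE
  g <- skeleton_graph(m, distance_transform(m))
  expect_warning(r <- trace_routes(g), "disconnected")
  expect_equal(length(r$routes), 1)
})

test_that("leaves split at the stem and sort bottom-up", {
  gy <- y_skeleton()
  r <- trace_routes(gy)
  stem <- extract_stem(r)
  leaves <- extract_leaves(r, stem)
  expect_equal(length(leaves), 2)
  # both leaves insert where the trunk forks
  expect_equal(leaves[[1]]$branch[1], leaves[[2]]$branch[1])
  an <- cached_analysis(0)
  st <- an$structure
  ins <- vapply(st$leaves, function(l) l$insertion[1], numeric(1))
  expect_true(all(diff(ins) <= 0))  # bottom-up ordering
  expect_equal(length(st$leaves), an$plant$truth$LN)
})

test_that("six-leaf plant splits three leaves below, three above", {
  spec <- plant_spec(
    stem_height_mm = 800,
    leaves = data.frame(
      insertion_frac = c(0.2, 0.32, 0.46, 0.62, 0.99, 1.0),
      side = c(1, -1, 1, -1, 1, -1),
      chord_mm = c(330, 320, 300, 280, 230, 210),
      curvature = c(0.13, 0.12, 0.11, 0.1, 0.08, 0.07),
      elev_deg = c(25, 30, 36, 44, 56, 62),
      width_mm = c(58, 56, 52, 48, 44, 40)))
  p <- generate_plant(spec)
  st <- plant_structure(p$mask)
  expect_equal(length(st$leaves), 6)
  below <- vapply(st$leaves, `[[`, logical(1), "below")
  expect_equal(sum(below), 3)
  expect_equal(sum(!below), 3)
  # leaf axis lengths track the programmed arc lengths
  gt <- p$truth$leaves
  for (l in st$leaves) {
    i <- which.min((gt$apex_row - l$apex[1])^2 + (gt$apex_col - l$apex[2])^2)
    geo <- leaf_geometry(l, st$stem, p$mm_per_px)
    expect_lt(abs(geo$SLL / gt$SLL[i] - 1), 0.08)
  }
})

test_that("stem top lands at the topmost insertion", {
  for (s in 0:2) {
    an <- cached_analysis(s)
    top <- an$structure$stem[nrow(an$structure$stem), 1]
    expect_lt(abs(top - an$plant$truth$top_insertion_row), 8)
  }
})

test_that("organ labels partition the foreground exactly", {
  for (s in 0:2) {
    an <- cached_analysis(s)
    lab <- an$structure$labels
    mask <- an$plant$mask
    expect_identical(unname(lab > 0), unname(mask[, ]))  # no unlabeled, no spill
    expect_equal(sum(lab == 1) + sum(lab >= 2), sum(mask))
  }
})

test_that("per-leaf pixel assignment matches rendered organ labels", {
  an <- cached_analysis(0)
  lab <- an$structure$labels
  gt <- an$plant$labels
  # match detected leaves to rendered leaves via apex proximity, then IoU
  gtl <- an$plant$truth$leaves
  for (k in seq_along(an$structure$leaves)) {
    l <- an$structure$leaves[[k]]
    i <- which.min((gtl$apex_row - l$apex[1])^2 + (gtl$apex_col - l$apex[2])^2)
    inter <- sum(lab == k + 1 & gt == i + 1)
    uni <- sum(lab == k + 1 | gt == i + 1)
    expect_gte(inter / uni, 0.85)
  }
})
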