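# Distance transform, candidate sets (against a brute-force oracle),
# ridge-path connection, pruning and the comparison harness.

test_that("distance transform treats the border as background", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(distance_transform(one)[3, 3], 1)
  solid <- matrix(TRUE, 7, 7)
  d <- distance_transform(solid)
  expect_equal(d[4, 4], 4)  # brute force: nearest outside pixel is 4 away
  expect_equal(d[1, 1], 1)
  bar <- matrix(FALSE, 9, 30); bar[4:6, ] <- TRUE
  db <- distance_transform(bar)
  expect_true(all(db[5, 5:26] == 2))
  expect_true(all(db[!bar] == 0))
  expect_error(distance_transform(matrix(FALSE, 3, 3)), "empty")
})

test_that("candidate sets equal the brute-force oracle on a fixture suite", {
  shapes <- list(make_square(9, 15), make_disc(5, 15), make_plus(4, 3, 15),
                 make_annulus(6, 3, 15))
  set.seed(21)
  for (i in 1:20) shapes <- c(shapes, list(matrix(runif(225) > 0.5, 15, 15)))
  for (i in 1:10) shapes <- c(shapes, list(make_blob(i)))
  for (m in shapes) {
    if (!any(m)) next
    d <- distance_transform(m)
    prev <- NULL
    for (n in c(2, 3, 5, 8)) {
      cs <- candidate_set(d, n)
      expect_identical(unname(cs[, ]), oracle_candidate_set(d, n))
      if (!is.null(prev)) expect_true(all(prev[cs]))  # nesting: stricter set inside looser
      prev <- cs
    }
  }
})

test_that("candidate membership: plateaus excluded, thin lines included", {
  # synthetic flat distance plateau: strict comparison admits no interior pixel
  flat <- matrix(2, 9, 9)
  cs <- candidate_set(flat, 2)
  expect_false(any(cs[3:7, 3:7]))
  # 1-px line: >= 6 zero neighbours, so in both working sets
  line <- matrix(FALSE, 7, 20); line[4, 3:18] <- TRUE
  d <- distance_transform(line)
  expect_true(all(candidate_set(d, 2)[4, 4:17]))
  expect_true(all(candidate_set(d, 3)[4, 4:17]))
  expect_error(candidate_set(d, 1))
  expect_error(candidate_set(d, 9))
})

test_that("connect_skeleton requires nested candidate sets", {
  m <- make_disc(6)
  d <- distance_transform(m)
  s2 <- candidate_set(d, 2); s3 <- candidate_set(d, 3)
  # hand-built "stricter" set with a member outside the looser set
  bogus <- matrix(FALSE, nrow(d), ncol(d))
  bogus[which(m & !s3)[1]] <- TRUE
  bogus <- bogus | s3
  attr(bogus, "n") <- 3L
  loose <- s3; attr(loose, "n") <- 2L
  expect_error(connect_skeleton(loose, bogus, d, m), "contained")
  # argument order is detected from the strictness attribute
  g1 <- connect_skeleton(s2, s3, d, m)
  g2 <- connect_skeleton(s3, s2, d, m)
  expect_identical(g1$pixels, g2$pixels)
})

test_that("plus sign skeletonizes to its midlines", {
  m <- make_plus()
  g <- skeletonize(m)
  expect_true(all(m[g$pixels]))
  expect_equal(nrow(g$endpoints), 4)
  junc <- matrix(FALSE, nrow(m), ncol(m))
  junc[g$junctions] <- TRUE
  expect_equal(max(phenomaize:::label8(junc)), 1)  # one junction cluster
})

test_that("disc collapses to a central cluster", {
  g <- skeletonize(make_disc(15))
  expect_lte(sum(g$pixels), 5)
})

test_that("skeleton homotopy matches the mask", {
  # one skeleton component per mask component
  two <- matrix(FALSE, 40, 80)
  two[5:35, 5:35] <- make_disc(12, 31)
  two[5:35, 45:75] <- make_disc(12, 31)
  g <- skeletonize(two)
  expect_equal(max(phenomaize:::label8(g$pixels)),
               max(phenomaize:::label8(two)))
  # a mask hole induces a skeleton cycle: one component, no endpoints
  ga <- skeletonize(make_annulus())
  expect_equal(max(phenomaize:::label8(ga$pixels)), 1)
  expect_equal(nrow(ga$endpoints), 0)
  expect_gt(sum(ga$pixels), 20)
})

test_that("synthetic plants give one endpoint per leaf plus the root", {
  for (s in 0:2) {
    an <- cached_analysis(s)
    g <- an$skel
    mask <- an$plant$mask
    expect_true(all(mask[g$pixels]))
    expect_equal(max(phenomaize:::label8(g$pixels)), 1)
    expect_equal(nrow(g$endpoints), an$plant$truth$LN + 1)
    # ridge property: skeleton pixels sit higher on the distance map
    expect_gte(mean(g$dt[g$pixels]), mean(g$dt[mask]))
  }
})

test_that("spur pruning removes short twigs, keeps real branches, idempotent", {
  # long path with a 3-px spur
  m <- matrix(FALSE, 30, 60)
  m[15, 5:55] <- TRUE
  m[14:12, 30] <- TRUE
  d <- distance_transform(m)
  g <- skeleton_graph(m, d)
  pr <- prune_spurs(g, min_len_px = 10)
  expect_equal(nrow(pr$endpoints), 2)
  expect_false(any(pr$pixels[12:14, 30]))
  # nothing shorter than threshold: unchanged
  pr2 <- prune_spurs(pr, min_len_px = 10)
  expect_identical(pr$pixels, pr2$pixels)
})

test_that("comparison harness tabulates methods and flags unknown ones", {
  m <- make_plus()
  rep <- compare_skeletons(m)
  expect_equal(nrow(rep), 3)
  expect_setequal(rep$method, c("ours", "zhang_thinning", "medial_axis"))
  ours <- rep[rep$method == "ours", ]
  zh <- rep[rep$method == "zhang_thinning", ]
  expect_equal(ours$n_endpoints, zh$n_endpoints)
  disc_rep <- compare_skeletons(make_disc(15),
                                methods = c("ours", "zhang_thinning"))
  expect_lte(disc_rep$n_pixels[disc_rep$method == "ours"],
             disc_rep$n_pixels[disc_rep$method == "zhang_thinning"])
  expect_error(compare_skeletons(m, methods = "voronoi"), "unknown")
})
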