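# Shared fixtures: small geometric masks, a brute-force candidate-set
# oracle, and a cache of rendered synthetic plants with their full analyses
# so that expensive stages run once per session.

make_square <- function(side = 100, canvas = side + 20) {
  m <- matrix(FALSE, canvas, canvas)
  off <- (canvas - side) %/% 2
  m[off + seq_len(side), off + seq_len(side)] <- TRUE
  m
}

make_disc <- function(r = 15, canvas = 2 * r + 11) {
  ctr <- (canvas + 1) / 2
  xy <- as.matrix(expand.grid(seq_len(canvas), seq_len(canvas)))
  m <- matrix(FALSE, canvas, canvas)
  m[xy[(xy[, 1] - ctr)^2 + (xy[, 2] - ctr)^2 <= r^2, , drop = FALSE]] <- TRUE
  m
}

make_annulus <- function(r_out = 17, r_in = 9, canvas = 2 * r_out + 7) {
  ctr <- (canvas + 1) / 2
  xy <- as.matrix(expand.grid(seq_len(canvas), seq_len(canvas)))
  rr <- sqrt((xy[, 1] - ctr)^2 + (xy[, 2] - ctr)^2)
  m <- matrix(FALSE, canvas, canvas)
  m[xy[rr <= r_out & rr >= r_in, , drop = FALSE]] <- TRUE
  m
}

make_plus <- function(arm = 12, thick = 5, canvas = 2 * arm + thick + 6) {
  m <- matrix(FALSE, canvas, canvas)
  mid <- (canvas - thick) %/% 2
  m[mid + seq_len(thick), 4:(canvas - 3)] <- TRUE
  m[4:(canvas - 3), mid + seq_len(thick)] <- TRUE
  m
}

make_blob <- function(seed, canvas = 64) {
  set.seed(seed)
  z <- matrix(rnorm(canvas^2), canvas, canvas)
  sm <- EBImage::gblur(z, sigma = 4)
  m <- sm > stats::quantile(sm, 0.75)
  lab <- phenomaize:::label8(m)
  lab == 1L
}

sierpinski_mask <- function(iters = 6) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(iters)) {
    z <- matrix(FALSE, nrow(m) * 2, ncol(m) * 2)
    z[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    z[nrow(m) + seq_len(nrow(m)), seq_len(ncol(m))] <- m
    z[nrow(m) + seq_len(nrow(m)), ncol(m) + seq_len(ncol(m))] <- m
    m <- z
  }
  m
}

# brute-force double-loop oracle for the candidate set definition
oracle_candidate_set <- function(dmap, n) {
  out <- matrix(FALSE, nrow(dmap), ncol(dmap))
  for (r in seq_len(nrow(dmap))) for (c in seq_len(ncol(dmap))) {
    if (dmap[r, c] <= 0) next
    cnt <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      v <- if (r + dr >= 1 && r + dr <= nrow(dmap) &&
               c + dc >= 1 && c + dc <= ncol(dmap)) dmap[r + dr, c + dc] else 0
      if (dmap[r, c] > v) cnt <- cnt + 1L
    }
    out[r, c] <- cnt >= n
  }
  out
}

# straight-leaf plant structure built by hand (unit scale) for closed-form
# trait checks: vertical stem plus horizontal leaves of given pixel lengths
fake_leaf <- function(row, len, col0 = 60) {
  ax <- cbind(rep(row, len + 1), col0 + 0:len)
  list(apex = ax[nrow(ax), ], insertion = ax[1, ], branch = ax[1, ],
       axis = ax, axis_start = 1L, base_len = 0, tip_len = 0, below = row > 100)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_plant <- function(seed) {
  key <- paste0("plant", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_plant(random_plant_spec(seed))
  .fixture_cache[[key]]
}

cached_analysis <- function(seed) {
  key <- paste0("an", seed)
  if (is.null(.fixture_cache[[key]])) {
    p <- cached_plant(seed)
    sk <- skeletonize(p$mask)
    st <- plant_structure(p$mask, sk)
    rec <- collect_traits(p$mask, st, p$mm_per_px, rgb = p$rgb)
    .fixture_cache[[key]] <- list(plant = p, skel = sk, structure = st,
                                  record = rec)
  }
  .fixture_cache[[key]]
}
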