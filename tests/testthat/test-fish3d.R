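# Filters, segmentation, distance maps, contact scoring, volumes, Ki-67.

test_that("hybrid median leaves constants alone and kills lone speckles", {
  const <- matrix(3.7, 9, 9)
  expect_equal(hybrid_median_despeckle(const), const)
  speck <- matrix(0, 9, 9)
  speck[5, 5] <- 100
  out <- hybrid_median_despeckle(speck)
  expect_equal(out[5, 5], 0)
  expect_equal(sum(out), 0)
  expect_warning(small <- hybrid_median_despeckle(matrix(1, 2, 2)), "3x3")
  expect_equal(small, matrix(1, 2, 2))
})

test_that("hybrid median equals the brute-force oracle on random images", {
  for (seed in 1:6) {
    m <- with_seed(seed, matrix(rnorm(81), 9, 9))
    expect_equal(hybrid_median_despeckle(m), hybrid_median_oracle(m))
  }
})

test_that("edm_slice handles trivial masks by definition", {
  empty <- matrix(FALSE, 5, 7)
  expect_equal(edm_slice(empty, c(0.1, 0.2)), matrix(0, 5, 7))
  one <- matrix(FALSE, 5, 5)
  one[3, 3] <- TRUE
  d <- edm_slice(one, c(0.3, 0.2))
  expect_equal(d[3, 3], 0.2)  # nearest background one column step away
  expect_equal(sum(d > 0), 1L)
  full <- matrix(TRUE, 3, 3)
  expect_true(all(is.infinite(edm_slice(full, c(1, 1)))))
})

test_that("edm_slice equals the O(n^2) nearest-background oracle exactly", {
  for (seed in 1:20) {
    m <- with_seed(seed, matrix(runif(144) < 0.6, 12, 12))
    for (sp in list(c(1, 1), c(0.08, 0.12), c(0.2, 0.07))) {
      expect_equal(edm_slice(m, sp), edm_oracle(m, sp), tolerance = 1e-12)
    }
  }
})

test_that("segmentation recovers a bimodal ellipsoid within a 1-voxel band", {
  tr <- nucleus_truth(semi_axes_um = c(2, 1.6, 1.2), psf_sigma_um = 0.06,
                      snr = 30, seed = 2)
  st <- make_nucleus_stack(tr, voxel_xy = 0.1, voxel_z = 0.12)
  mask <- segment_mask(st$grid$channels$dapi, keep_largest = TRUE)
  d <- dim(mask)
  vs <- unname(st$grid$voxel_size)
  cen <- unname(st$truth$grid_center_um)
  xs <- (seq_len(d[2]) - 0.5) * vs[1] - cen[1]
  ys <- (seq_len(d[1]) - 0.5) * vs[2] - cen[2]
  zs <- (seq_len(d[3]) - 0.5) * vs[3] - cen[3]
  q <- outer(outer((ys / 1.6)^2, (xs / 2)^2, `+`), (zs / 1.2)^2, `+`)
  truth_mask <- q <= 1
  # voxels misclassified beyond a one-voxel boundary band
  band <- abs(sqrt(q) - 1) < max(vs) / min(c(2, 1.6, 1.2)) * 1.5
  expect_equal(sum((mask != truth_mask) & !band), 0)
})

test_that("interior cavities are filled and smaller components dropped", {
  v <- array(0, c(12, 12, 3))
  v[3:9, 3:9, ] <- 1
  v[5:6, 5:6, 2] <- 0      # interior dark cavity
  v[11, 11, 1] <- 1        # small separate blob
  m <- segment_mask(v, method = "fixed", value = 0.5, keep_largest = TRUE)
  expect_true(all(m[5:6, 5:6, 2]))
  expect_false(m[11, 11, 1])
  m2 <- segment_mask(v, method = "fixed", value = 0.5, keep_largest = FALSE,
                     fill_holes = FALSE)
  expect_false(any(m2[5:6, 5:6, 2]))
  expect_true(m2[11, 11, 1])
  expect_error(segment_mask(array(0, c(4, 4, 2))), "no foreground")
})

test_that("two-plane edge distance bounds and matches the 3D oracle", {
  for (seed in 1:8) {
    nuc <- with_seed(seed, {
      a <- array(FALSE, c(14, 14, 8))
      a[4:11, 4:11, 2:7] <- array(runif(8 * 8 * 6) < 0.85, c(8, 8, 6))
      a
    })
    terr <- array(FALSE, dim(nuc))
    terr[6:8, 6:8, 4:5] <- TRUE
    vs <- c(0.1, 0.1, 0.15)
    d3 <- territory_min_edge_distance(terr, nuc, vs, mode = "3d")
    two <- territory_min_edge_distance(terr, nuc, vs, mode = "two-plane")
    if (any(terr & !nuc)) {
      expect_equal(two, 0)
      expect_equal(d3, 0)
    } else {
      expect_equal(d3, min_dist_3d_oracle(terr, nuc, vs), tolerance = 1e-9)
      expect_gte(two + 1e-9, d3)
    }
  }
  expect_error(territory_min_edge_distance(array(FALSE, c(3, 3, 3)),
                                           array(TRUE, c(3, 3, 3)),
                                           c(1, 1, 1)), "empty")
})

test_that("distances are translation invariant and non-negative", {
  nuc <- array(FALSE, c(16, 16, 10))
  nuc[3:12, 3:12, 2:8] <- TRUE
  terr <- array(FALSE, dim(nuc))
  terr[6:7, 6:7, 4:5] <- TRUE
  vs <- c(0.08, 0.08, 0.12)
  base <- territory_min_edge_distance(terr, nuc, vs)
  sh <- function(a, dy, dx, dz) {
    out <- array(FALSE, dim(a))
    idx <- which(a, arr.ind = TRUE)
    out[cbind(idx[, 1] + dy, idx[, 2] + dx, idx[, 3] + dz)] <- TRUE
    out
  }
  moved <- territory_min_edge_distance(sh(terr, 2, 1, 1), sh(nuc, 2, 1, 1), vs)
  expect_equal(moved, base)
  expect_gte(base, 0)
})

test_that("interlocus_distance is plain 3D Euclidean distance", {
  expect_equal(interlocus_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(interlocus_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  for (seed in 1:5) {
    p <- with_seed(seed, list(rnorm(3), rnorm(3)))
    expect_equal(interlocus_distance(p[[1]], p[[2]]),
                 sqrt(sum((p[[1]] - p[[2]])^2)))
  }
})

test_that("lamina contact flips exactly at the 26-adjacency boundary", {
  lam <- array(FALSE, c(11, 11, 7))
  lam[, 9, ] <- TRUE  # planar shell
  mk_sig <- function(col) {
    s <- array(FALSE, c(11, 11, 7))
    s[5:6, col, 3:4] <- TRUE
    s
  }
  expect_equal(lamina_contact(mk_sig(9), lam), 1L)  # coincident
  expect_equal(lamina_contact(mk_sig(8), lam), 1L)  # face-adjacent
  expect_equal(lamina_contact(mk_sig(7), lam), 0L)  # one empty plane between
  expect_equal(lamina_contact(mk_sig(2), lam), 0L)
  # diagonal-only touch counts as 26-adjacency
  sig <- array(FALSE, c(11, 11, 7))
  sig[4, 8, 2] <- TRUE
  lam2 <- array(FALSE, c(11, 11, 7))
  lam2[5, 9, 3] <- TRUE
  expect_equal(lamina_contact(sig, lam2), 1L)
  expect_error(lamina_contact(array(FALSE, c(2, 2, 2)), lam2[1:2, 1:2, 1:2]),
               "empty")
})

test_that("territory volumes count voxels and normalize to the nucleus", {
  nuc <- array(FALSE, c(10, 10, 6))
  nuc[2:9, 2:9, 2:5] <- TRUE
  vs <- c(0.1, 0.1, 0.2)
  same <- territory_volume(nuc, nuc, vs)
  expect_equal(same$volume_ratio, 1)
  expect_equal(same$nuclear_volume_um3, sum(nuc) * prod(vs))
  none <- territory_volume(array(FALSE, dim(nuc)), nuc, vs)
  expect_equal(none$volume_um3, 0)
  expect_equal(none$volume_ratio, 0)

  # 2 um sphere at the study's voxel size: 4/3 pi 8 within 5%
  tr <- nucleus_truth(semi_axes_um = 2.6,
                      territory_specs = list(list(offset_um = c(0, 0, 0),
                                                  radius_um = 2)),
                      psf_sigma_um = 0, snr = Inf, seed = 1)
  st <- make_nucleus_stack(tr, voxel_xy = 0.08, voxel_z = 0.12)
  terr <- st$grid$channels$terr1 > 0.5
  nucm <- st$grid$channels$dapi > 0.5
  got <- territory_volume(terr, nucm, unname(st$grid$voxel_size))
  expect_lt(abs(got$volume_um3 - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.05)
})

test_that("Ki-67 index classifies with boundary values as intermediate", {
  young <- ki67_index(88, 100)
  expect_equal(young$fraction, 0.88)
  expect_equal(young$class, "young")
  expect_equal(ki67_index(1, 100)$class, "senescent")
  expect_equal(ki67_index(40, 100)$class, "intermediate")  # exactly 0.4
  expect_equal(ki67_index(2, 100)$class, "intermediate")   # exactly 0.02
  expect_equal(ki67_index(66, 100)$class, "young")
  expect_error(ki67_index(5, 0))
  expect_error(ki67_index(7, 5))
})
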