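test_that("central moments of symmetric patches vanish where symmetry demands", {
  u <- matrix(5, 15, 15)
  m <- central_moments(u)
  expect_equal(m$mu[2, 2], 0, tolerance = 1e-9 * m$mass) # mu11
  expect_equal(m$mu[3, 1], m$mu[1, 3], tolerance = 1e-9 * m$mass) # mu20 == mu02
  for (pq in list(c(3, 0), c(2, 1), c(1, 2), c(0, 3))) {
    expect_equal(m$mu[pq[1] + 1, pq[2] + 1], 0, tolerance = 1e-6)
  }
  # first-order central moments are zero by definition
  expect_equal(m$mu[2, 1], 0, tolerance = 1e-9 * m$mass)
  expect_equal(m$mu[1, 2], 0, tolerance = 1e-9 * m$mass)
})

test_that("a point mass has no central moments beyond its mass", {
  d <- matrix(0, 15, 15); d[4, 11] <- 255
  m <- central_moments(d)
  expect_equal(m$mass, 255)
  expect_equal(m$centroid, c(x = 11, y = 4))
  for (p in 0:3) for (q in 0:(3 - p)) {
    if (p + q >= 1) expect_equal(m$mu[p + 1, q + 1], 0, tolerance = 1e-9)
  }
})

test_that("central moments match the brute-force double-sum oracle", {
  v <- matrix(as.numeric(1:25), 5, 5, byrow = TRUE)
  m <- central_moments(v)
  om <- oracle_central_moments(v)
  expect_equal(m$centroid[["x"]], om$xc, tolerance = 1e-12)
  expect_equal(m$centroid[["y"]], om$yc, tolerance = 1e-12)
  for (p in 0:3) for (q in 0:(3 - p)) {
    expect_equal(m$mu[p + 1, q + 1], om$mu(p, q),
                 tolerance = 1e-9 * max(1, abs(om$mu(p, q))))
  }
  expect_error(central_moments(matrix(0, 5, 5)), "degenerate")
})

test_that("Hu vector of a uniform patch is zero beyond phi1", {
  h <- hu_invariants(central_moments(matrix(9, 15, 15)))
  expect_gt(h[["phi1"]], 0)
  expect_equal(as.numeric(h[2:7]), rep(0, 6), tolerance = 1e-9)
})

test_that("Hu invariants agree with an independently coded textbook oracle", {
  for (s in 1:10) {
    v <- structured_patch(s)
    h <- hu_invariants(central_moments(v))
    expect_lt(max(rel_diff(as.numeric(h), oracle_hu(v))), 1e-9)
  }
})

test_that("Hu invariants survive grid rotations and intensity scaling", {
  for (s in 1:20) {
    v <- structured_patch(s)
    h <- hu_invariants(central_moments(v))
    r <- v
    for (k in 1:3) {
      r <- rot90m(r)
      hr <- hu_invariants(central_moments(r))
      expect_lt(max(rel_diff(as.numeric(h[1:6]), as.numeric(hr[1:6]))), 1e-9)
      expect_lt(rel_diff(abs(h[["phi7"]]), abs(hr[["phi7"]])), 1e-9)
    }
    for (cc in c(0.5, 3)) {
      hs <- hu_invariants(central_moments(cc * v))
      expect_lt(max(rel_diff(as.numeric(h), as.numeric(hs))), 1e-9)
    }
  }
})

test_that("phi7 flips sign under mirroring while keeping its magnitude", {
  for (s in 1:20) {
    v <- structured_patch(s)
    h7 <- hu_invariants(central_moments(v))[["phi7"]]
    m7 <- hu_invariants(central_moments(v[, ncol(v):1]))[["phi7"]]
    expect_lt(rel_diff(abs(h7), abs(m7)), 1e-9)
    if (abs(h7) > 1e-12) expect_lt(h7 * m7, 0)
  }
})

test_that("the mirror test is the strict sign product", {
  expect_true(mirror_discordant(0.3, -0.2))
  expect_false(mirror_discordant(0.3, 0.3))
  expect_false(mirror_discordant(0, -5)) # boundary of the strict inequality
  a <- c(rep(1, 6), 0.3); b <- c(rep(1, 6), -0.1)
  expect_true(mirror_discordant(a, b))
  expect_error(mirror_discordant(NaN, 1), "finite")
})

test_that("the feature store matches per-patch computation and flags degeneracy", {
  img <- example_phantom(24, 24, seed = 8)
  fs <- patch_feature_store(img, 7)
  expect_equal(dim(fs$hu), c(24L * 24L, 7L))
  pad <- pad_reflect(img, 7)
  for (ctr in list(c(1, 1), c(12, 17), c(24, 24))) {
    idx <- (ctr[1] - 1) * 24 + ctr[2]
    pv <- extract_patch(pad, ctr + 7, 7)$values
    # border patches are mirror-symmetric, so high-order terms cancel to ~0;
    # compare on the scale of the whole vector rather than component-wise
    expect_equal(fs$hu[idx, ], as.numeric(hu_invariants(central_moments(pv))),
                 tolerance = 1e-9)
    cen <- patch_centroid(pv)
    expect_equal(c(fs$cx[idx], fs$cy[idx]), unname(cen$vec), tolerance = 1e-10)
  }
  # all-zero image: zero features rather than errors at the pipeline layer
  fz <- patch_feature_store(matrix(0, 20, 20), 7)
  expect_true(all(fz$hu == 0))
})
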