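test_that("patch centroids follow the mass distribution", {
  expect_equal(unname(patch_centroid(matrix(4, 15, 15))$vec), c(0, 0))
  d <- matrix(0, 15, 15); d[8, 8] <- 10 # delta at the center
  expect_equal(unname(patch_centroid(d)$vec), c(0, 0))
  d2 <- matrix(0, 15, 15); d2[8, 11] <- 1 # offset (x = +3, y = 0)
  cen <- patch_centroid(d2)
  expect_equal(unname(cen$vec), c(3, 0))
  expect_equal(cen$norm, 3)
  expect_equal(unname(cen$unit), c(1, 0))
  # zero-mass patch: flagged degeneracy, not an exception
  z <- patch_centroid(matrix(0, 15, 15))
  expect_equal(z$norm, 0)
  expect_null(z$unit)
})

test_that("patch centroids match the brute-force double sum", {
  set.seed(41)
  v <- matrix(runif(225, 0, 255), 15, 15)
  msk <- circular_mask(7)
  num_x <- 0; num_y <- 0; den <- 0
  for (r in 1:15) for (c in 1:15) {
    if (msk[r, c]) {
      num_x <- num_x + (c - 8) * v[r, c]
      num_y <- num_y + (r - 8) * v[r, c]
      den <- den + v[r, c]
    }
  }
  cen <- patch_centroid(v)
  expect_equal(unname(cen$vec), c(num_x / den, num_y / den), tolerance = 1e-12)
})

test_that("rotation frames are orthogonal rotations mapping target onto candidate", {
  mkc <- function(x, y) patch_centroid({
    d <- matrix(0, 15, 15); d[8 + y, 8 + x] <- 1; d
  })
  ci <- mkc(1, 0)
  expect_equal(rotation_frame(ci, ci, FALSE)$R, diag(2), tolerance = 1e-12)

  cj <- mkc(0, 1)
  fr <- rotation_frame(ci, cj, FALSE)
  expect_true(fr$valid)
  expect_equal(unname(fr$R %*% c(1, 0)), cbind(c(0, 1)), tolerance = 1e-12)
  expect_equal(det(fr$R), 1, tolerance = 1e-12)
  expect_equal(t(fr$R) %*% fr$R, diag(2), tolerance = 1e-12)

  degen <- patch_centroid(matrix(3, 15, 15))
  expect_false(rotation_frame(ci, degen, FALSE)$valid)
  expect_false(rotation_frame(degen, cj, FALSE)$valid)
})

test_that("point mapping is an isometry with the mirror flip applied outside", {
  idf <- structure(list(R = diag(2), mirrored = FALSE, valid = TRUE),
                   class = "ribm_frame")
  expect_equal(unname(map_point(idf, c(2.5, -1))), c(2.5, -1))

  rot <- structure(list(R = matrix(c(0, 1, -1, 0), 2, 2), mirrored = FALSE,
                        valid = TRUE), class = "ribm_frame")
  q <- c(1, 0); p <- map_point(rot, q)
  expect_equal(sqrt(sum(p^2)), 1, tolerance = 1e-12)
  expect_equal(sum(p * q), 0, tolerance = 1e-12)

  mir <- structure(list(R = diag(2), mirrored = TRUE, valid = TRUE),
                   class = "ribm_frame")
  expect_equal(unname(map_point(mir, c(1, 2))), c(-1, 2))

  expect_error(map_point(invalid_frame(), c(1, 0)), "invalid")
})

test_that("bilinear sampling is exact at nodes and reproduces bilinear functions", {
  img <- matrix(c(0, 0, 0, 4), 2, 2)
  expect_equal(bilinear_sample(img, c(1, 1), c(0, 0)), 0)
  expect_equal(bilinear_sample(img, c(1, 1), c(0.5, 0.5)), 1)

  ramp <- outer(1:10, 1:10, function(r, c) 3 * c + 5 * r)
  for (off in list(c(0.3, 0.7), c(1.25, -0.5), c(0, 0.9))) {
    expect_equal(bilinear_sample(ramp, c(5, 5), off),
                 3 * (5 + off[1]) + 5 * (5 + off[2]), tolerance = 1e-12)
  }
  expect_error(bilinear_sample(ramp, c(1, 1), c(-0.5, 0)), "bounds")
})

test_that("dR vanishes on self, is non-negative, and identity frame = plain distance", {
  set.seed(43)
  img <- pad_reflect(matrix(runif(24 * 24, 0, 255), 24, 24), 10)
  idf <- structure(list(R = diag(2), mirrored = FALSE, valid = TRUE),
                   class = "ribm_frame")
  for (ctr in list(c(12, 12), c(15, 28), c(30, 11))) {
    expect_equal(distance_dR(img, ctr, ctr, idf, 7), 0)
  }
  msk_off <- support_offsets_for_tests(7)
  for (s in 1:25) {
    i <- c(sample(11:33, 1), sample(11:33, 1))
    j <- c(sample(11:33, 1), sample(11:33, 1))
    dr <- distance_dR(img, i, j, idf, 7)
    expect_gte(dr, 0)
    plain <- sum((img[cbind(i[1] + msk_off[, 2], i[2] + msk_off[, 1])] -
                  img[cbind(j[1] + msk_off[, 2], j[2] + msk_off[, 1])])^2)
    expect_equal(dr, plain, tolerance = 1e-12)
  }
})

test_that("rotation compensation collapses the distance for exact rotated copies", {
  set.seed(44)
  img <- matrix(runif(60 * 60, 0, 255), 60, 60)
  pa <- img[13:27, 13:27] # patch at (20, 20)
  img[33:47, 33:47] <- rot90m(pa) # rotated copy at (40, 40)
  ci <- patch_centroid(img[13:27, 13:27])
  cj <- patch_centroid(img[33:47, 33:47])
  fr <- rotation_frame(ci, cj, FALSE)
  expect_true(fr$valid)
  dr <- distance_dR(img, c(20, 20), c(40, 40), fr, 7)
  plain <- distance_dR(img, c(20, 20), c(40, 40), invalid_frame(), 7)
  energy <- sum(pa[circular_mask(7)]^2)
  expect_lt(dr, plain)
  expect_lt(dr, 1e-9 * energy)
})

test_that("centroid frames recover continuous rotation angles within 5 degrees", {
  base <- anisotropic_patch(0)
  ci <- patch_centroid(base)
  for (theta in c(15, 30, 45, 60)) {
    cj <- patch_centroid(anisotropic_patch(theta))
    fr <- rotation_frame(ci, cj, FALSE)
    expect_true(fr$valid)
    ang <- atan2(fr$R[2, 1], fr$R[1, 1]) * 180 / pi
    expect_lt(abs(ang - theta), 5)
    expect_equal(det(fr$R), 1, tolerance = 1e-9)
    expect_equal(t(fr$R) %*% fr$R, diag(2), tolerance = 1e-9)
  }
})
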