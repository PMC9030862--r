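# Independent brute-force oracles and structured-patch generators used across
# the suite. These deliberately use naive nested-loop formulations so they
# stay independent of the package's implementation paths.

# direct O(n^2 k^2) convolution with mirror boundary (edge not duplicated)
oracle_convolve <- function(img, kernel) {
  m <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  reflect_idx <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- 0
      for (dy in -m:m) {
        for (dx in -m:m) {
          rr <- reflect_idx(r - dy, h)
          cc <- reflect_idx(c - dx, w)
          acc <- acc + kernel[dy + m + 1L, dx + m + 1L] * img[rr, cc]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# textbook central moments by direct double sum about the intensity centroid
oracle_central_moments <- function(v) {
  n <- nrow(v)
  mass <- sum(v)
  xs <- 0; ys <- 0
  for (r in seq_len(n)) for (c in seq_len(n)) {
    xs <- xs + v[r, c] * c
    ys <- ys + v[r, c] * r
  }
  xc <- xs / mass; yc <- ys / mass
  mu <- function(p, q) {
    acc <- 0
    for (r in seq_len(n)) for (c in seq_len(n)) {
      acc <- acc + v[r, c] * (c - xc)^p * (r - yc)^q
    }
    acc
  }
  list(mu = mu, xc = xc, yc = yc, mass = mass)
}

# textbook Hu invariants of the unit-mass patch, coded from the formulas
oracle_hu <- function(v) {
  om <- oracle_central_moments(v)
  e <- function(p, q) om$mu(p, q) / om$mass
  n20 <- e(2, 0); n02 <- e(0, 2); n11 <- e(1, 1)
  n30 <- e(3, 0); n03 <- e(0, 3); n21 <- e(2, 1); n12 <- e(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# 90 deg counter-clockwise grid rotation of a square matrix
rot90m <- function(m) t(m)[seq(nrow(m), 1L), ]

# structured random patch: a few Gaussian bumps on a gray base -> anisotropic
# content with meaningful third-order moments (and hence nonzero phi7)
structured_patch <- function(seed, n = 15L) {
  set.seed(seed)
  r <- (n - 1) / 2
  x <- matrix(seq(-r, r), n, n, byrow = TRUE)
  y <- matrix(seq(-r, r), n, n)
  v <- matrix(30, n, n)
  for (b in seq_len(3L)) {
    cx <- runif(1, -r / 2, r / 2); cy <- runif(1, -r / 2, r / 2)
    sx <- runif(1, 1, 3); sy <- runif(1, 1, 3)
    amp <- runif(1, 40, 180)
    v <- v + amp * exp(-((x - cx)^2 / (2 * sx^2) + (y - cy)^2 / (2 * sy^2)))
  }
  v + matrix(runif(n * n, 0, 5), n, n)
}

# continuous anisotropic blob evaluated on the patch grid, with the content
# rotated by `theta_deg`; this is exact continuous resampling (closed form),
# so centroid-based angle recovery is tested without interpolation noise
anisotropic_patch <- function(theta_deg, n = 15L) {
  r <- (n - 1) / 2
  th <- theta_deg * pi / 180
  x <- matrix(seq(-r, r), n, n, byrow = TRUE)
  y <- matrix(seq(-r, r), n, n)
  # rotate coordinates back by theta, then evaluate the base blob
  xr <- cos(th) * x + sin(th) * y
  yr <- -sin(th) * x + cos(th) * y
  # off-center elongated bump: strongly anisotropic intensity centroid
  100 * exp(-((xr - 3)^2 / (2 * 2.5^2) + yr^2 / (2 * 1.2^2))) + 10
}

invalid_frame <- function() {
  structure(list(R = diag(2), mirrored = FALSE, valid = FALSE), class = "ribm_frame")
}

rel_diff <- function(a, b, floor = 1e-30) abs(a - b) / pmax(abs(a), abs(b), floor)

# independent circular-support enumeration: (dx, dy) with dx^2 + dy^2 <= r^2
support_offsets_for_tests <- function(r) {
  out <- NULL
  for (dy in -r:r) for (dx in -r:r) {
    if (dx * dx + dy * dy <= r * r) out <- rbind(out, c(dx, dy))
  }
  colnames(out) <- c("dx", "dy")
  out
}

# K scaling rule stated by the pipeline docs: 675 clusters per 225^2 pixels
auto_k_for_tests <- function(npix) max(1L, as.integer(round(675 * npix / 50625)))
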