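#' Intensity-weighted central moments of a patch
#'
#' Computes `mu[p, q] = sum v(x, y) (x - xc)^p (y - yc)^q` for `p + q <= 3`
#' over the square patch, where `(xc, yc)` is the intensity centroid,
#' `x` indexes columns and `y` rows. Moments are intensity-weighted (the patch
#' is a gray-valued mass distribution, consistent with the centroid used by
#' the rotation estimation), not binary shape moments.
#'
#' @param patch An [extract_patch()] result or an odd-sided square matrix.
#' @return A list with `mu` (4 x 4 matrix, `mu[p + 1, q + 1]`, `NA` above
#'   order 3), `centroid = c(x, y)` in patch coordinates, and `mass`
#'   (`mu[0, 0]`).
#' @export
central_moments <- function(patch) {
  v <- patch_values(patch)
  mass <- sum(v)
  if (!is.finite(mass) || mass <= 0) {
    stop("degenerate patch: total intensity (mass) must be > 0",
         call. = FALSE)
  }
  n <- nrow(v)
  x <- matrix(seq_len(n), n, n, byrow = TRUE) # column index
  y <- matrix(seq_len(n), n, n)               # row index
  xc <- sum(v * x) / mass
  yc <- sum(v * y) / mass
  dx <- x - xc; dy <- y - yc
  mu <- matrix(NA_real_, 4L, 4L)
  for (p in 0:3) {
    for (q in 0:(3 - p)) {
      mu[p + 1L, q + 1L] <- sum(v * dx^p * dy^q)
    }
  }
  list(mu = mu, centroid = c(x = xc, y = yc), mass = mass)
}

#' Hu's seven rotation-invariant moments
#'
#' Normalizes the central moments to the unit-mass patch,
#' `eta[p, q] = mu[p, q] / mu[0, 0]` (the textbook Hu normalization applied
#' to `v / mu[0, 0]`; since patches have a fixed size, there is no spatial
#' scale to normalize away, and dividing by the mass makes the features
#' invariant to intensity scaling), then evaluates the standard Hu invariants
#' `phi1 ... phi7`. `phi1 ... phi6` are invariant to translation, rotation
#' and intensity scale; `phi7` additionally flips sign under mirroring, which
#' is what the mirror test of the block matcher relies on.
#'
#' @param moments A [central_moments()] result (or a patch, for convenience).
#' @return A named numeric vector `phi1 ... phi7`.
#' @export
hu_invariants <- function(moments) {
  if (!is.list(moments) || is.null(moments$mu)) moments <- central_moments(moments)
  if (moments$mass <= 0) stop("degenerate patch: mass must be > 0", call. = FALSE)
  mu <- moments$mu
  m00 <- mu[1L, 1L]
  eta <- function(p, q) mu[p + 1L, q + 1L] / m00
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  a <- n30 + n12; b <- n21 + n03
  phi <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    a^2 + b^2,
    (n30 - 3 * n12) * a * (a^2 - 3 * b^2) + (3 * n21 - n03) * b * (3 * a^2 - b^2),
    (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    (3 * n21 - n03) * a * (a^2 - 3 * b^2) - (n30 - 3 * n12) * b * (3 * a^2 - b^2)
  )
  names(phi) <- paste0("phi", 1:7)
  phi
}

#' Mirror test on two Hu feature vectors
#'
#' Two patches are flagged as mirror-discordant when the product of their
#' `phi7` components is strictly negative — the sign of `phi7` changes only
#' under mirroring, so a negative product indicates that one patch is
#' (approximately) a mirrored version of the other.
#'
#' @param a,b Hu vectors (length 7) or bare `phi7` scalars.
#' @return `TRUE` iff `phi7(a) * phi7(b) < 0`.
#' @export
mirror_discordant <- function(a, b) {
  p7 <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 7L) x[[7L]] else if (length(x) == 1L) x[[1L]] else
      stop("expected a length-7 Hu vector or a phi7 scalar", call. = FALSE)
  }
  pa <- p7(a); pb <- p7(b)
  if (!is.finite(pa) || !is.finite(pb)) stop("phi7 values must be finite", call. = FALSE)
  pa * pb < 0
}

#' Per-pixel patch feature store
#'
#' Computes, for every pixel of `img` (after internal mirror padding), the Hu
#' invariant vector of its square patch and the intensity centroid over the
#' inscribed circular support. Degenerate (zero-mass) patches get the zero
#' feature vector and a zero centroid. Pixels are indexed row-major
#' (`idx = (row - 1) * width + col`).
#'
#' @param img Numeric matrix — normally the Gaussian-blurred guide image.
#' @param radius Patch radius (default 7, i.e. 15 x 15 patches).
#' @return A list of class `ribm_feature_store`: `hu` (`N x 7` matrix), `cx`,
#'   `cy` (centroid offsets from the patch center, in pixels), `mass`
#'   (circular-support intensity sum), `radius`, `dim`.
#' @export
patch_feature_store <- function(img, radius = 7L) {
  assert_image(img)
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  p <- pad_reflect(img, radius)
  fs <- cpp_patch_features(p, nrow(img), ncol(img), radius)
  fs$radius <- radius
  fs$dim <- dim(img)
  class(fs) <- "ribm_feature_store"
  fs
}
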