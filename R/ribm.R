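#' Intensity centroid of a patch
#'
#' Computes the intensity-weighted centroid over the patch's circular support,
#' in a coordinate system centered on the patch center
#' (`x` = column offset, `y` = row offset):
#' `c = (sum x v / sum v, sum y v / sum v)`. The direction of this vector is
#' what the block matcher uses to estimate the rotation between two patches.
#'
#' @param patch An [extract_patch()] result or an odd-sided square matrix.
#' @param mask Optional logical support mask; defaults to the inscribed
#'   circle.
#' @return A list of class `ribm_centroid`: `vec = c(x, y)`, `norm`, `unit`
#'   (`NULL` when `norm` is 0), and `mass` (support intensity sum). A zero
#'   total intensity yields a valid centroid with `norm = 0` (a flagged
#'   degeneracy, not an error).
#' @export
patch_centroid <- function(patch, mask = NULL) {
  v <- patch_values(patch)
  n <- nrow(v)
  r <- (n - 1L) %/% 2L
  if (is.null(mask)) mask <- circular_mask(r)
  d <- seq(-r, r)
  x <- matrix(d, n, n, byrow = TRUE)
  y <- matrix(d, n, n)
  mass <- sum(v[mask])
  if (mass == 0) {
    vec <- c(x = 0, y = 0)
  } else {
    vec <- c(x = sum((v * x)[mask]) / mass, y = sum((v * y)[mask]) / mass)
  }
  nrm <- sqrt(sum(vec^2))
  structure(list(vec = vec, norm = nrm,
                 unit = if (nrm > 0) vec / nrm else NULL,
                 mass = mass),
            class = "ribm_centroid")
}

#' Rotation frame between two patches
#'
#' Builds the 2 x 2 rotation matrix aligning the candidate patch `j` with the
#' target patch `i` from their unit centroid directions:
#' `R = Ru(ci)^-1 Ru(m(cj))`, where `Ru(u) = [[u1, -u2], [u2, u1]]` and the
#' mirror map `m` flips the x component when the patches are mirror-discordant.
#' `R` maps the target's centroid direction onto the (mirror-compensated)
#' candidate's, so a point of patch `i` is carried to its corresponding
#' location in patch `j`. When either centroid is degenerate (norm below
#' `eps_c`), no rotation is estimable and the frame is flagged invalid — the
#' distance computation then falls back to the unrotated comparison.
#'
#' @param ci,cj [patch_centroid()] results for the target and candidate.
#' @param mirrored Logical, from [mirror_discordant()] on the patches' Hu
#'   vectors.
#' @param eps_c Degeneracy threshold on the centroid norm (pixels).
#' @return A list of class `ribm_frame`: `R` (2 x 2), `mirrored`, `valid`.
#' @export
rotation_frame <- function(ci, cj, mirrored, eps_c = 1e-6) {
  if (ci$norm < eps_c || cj$norm < eps_c) {
    return(structure(list(R = diag(2), mirrored = isTRUE(mirrored), valid = FALSE),
                     class = "ribm_frame"))
  }
  ui <- ci$vec / ci$norm
  uj <- cj$vec / cj$norm
  if (isTRUE(mirrored)) uj[1L] <- -uj[1L]
  # R = Ru(ui)^-1 %*% Ru(uj): rotation by angle(uj) - angle(ui)
  A <- ui[1L] * uj[1L] + ui[2L] * uj[2L]
  B <- ui[1L] * uj[2L] - ui[2L] * uj[1L]
  R <- matrix(c(A, B, -B, A), 2L, 2L) # column-major: [[A, -B], [B, A]]
  structure(list(R = R, mirrored = isTRUE(mirrored), valid = TRUE),
            class = "ribm_frame")
}

#' Map a patch point through a rotation frame
#'
#' Applies `q -> m(R q)`: the frame's rotation followed by the mirror map
#' (x-component sign flip) when the frame is mirrored. An isometry: the norm
#' of `q` is preserved.
#'
#' @param frame A valid [rotation_frame()].
#' @param q Numeric pair `c(x, y)` (column offset, row offset).
#' @return The mapped pair `c(x, y)`.
#' @export
map_point <- function(frame, q) {
  if (!isTRUE(frame$valid)) {
    stop("cannot map through an invalid (degenerate-centroid) frame", call. = FALSE)
  }
  p <- as.numeric(frame$R %*% as.numeric(q))
  if (frame$mirrored) p[1L] <- -p[1L]
  c(x = p[1L], y = p[2L])
}

#' Bilinear interpolation around a pixel
#'
#' Samples the image at `center + offset` (fractional coordinates) from the
#' four surrounding integer pixels. Exact at integer offsets.
#'
#' @param img Numeric matrix (padded so the sample stays in bounds).
#' @param center Integer pair `c(row, col)`.
#' @param offset Numeric pair `c(x, y)` = (column offset, row offset).
#' @return The interpolated intensity.
#' @export
bilinear_sample <- function(img, center, offset) {
  r <- center[[1L]] + offset[[2L]]
  c_ <- center[[2L]] + offset[[1L]]
  r0 <- floor(r); c0 <- floor(c_)
  if (r0 < 1 || c0 < 1 || r0 + 1 > nrow(img) || c0 + 1 > ncol(img)) {
    # exact-node sampling at the far edge is still fine
    if (r0 >= 1 && c0 >= 1 && r == r0 && c_ == c0 && r0 <= nrow(img) && c0 <= ncol(img)) {
      return(img[r0, c0])
    }
    stop("bilinear sample out of image bounds (insufficient padding)", call. = FALSE)
  }
  fr <- r - r0; fc <- c_ - c0
  (1 - fr) * ((1 - fc) * img[r0, c0] + fc * img[r0, c0 + 1]) +
    fr * ((1 - fc) * img[r0 + 1, c0] + fc * img[r0 + 1, c0 + 1])
}

# Vectorized bilinear sampling at rows r, cols c (numeric vectors).
bilinear_many <- function(img, r, c_) {
  r0 <- floor(r); c0 <- floor(c_)
  if (any(r0 < 1 | c0 < 1 | r0 + 1 > nrow(img) | c0 + 1 > ncol(img))) {
    stop("bilinear sample out of image bounds (insufficient padding)", call. = FALSE)
  }
  fr <- r - r0; fc <- c_ - c0
  (1 - fr) * ((1 - fc) * img[cbind(r0, c0)] + fc * img[cbind(r0, c0 + 1)]) +
    fr * ((1 - fc) * img[cbind(r0 + 1, c0)] + fc * img[cbind(r0 + 1, c0 + 1)])
}

#' Rotation-compensated patch distance
#'
#' The rotationally invariant similarity term: the sum over the target
#' patch's circular support of squared differences between the target
#' intensity at `q` and the candidate intensity bilinearly sampled at the
#' rotated (and mirror-compensated) location `m(R q)`. With an invalid frame
#' (degenerate centroid) it falls back to the plain unrotated squared
#' difference sum over the same support; with the identity frame it equals
#' the plain squared Euclidean patch distance exactly.
#'
#' @param img Numeric matrix, padded by at least `ceiling(radius * sqrt(2))`
#'   around the two centers.
#' @param i,j Integer pairs `c(row, col)`: target and candidate patch centers
#'   in `img`.
#' @param frame A [rotation_frame()].
#' @param radius Patch radius.
#' @return A non-negative scalar distance.
#' @export
distance_dR <- function(img, i, j, frame, radius) {
  assert_image(img)
  Q <- support_offsets(radius)
  vi <- img[cbind(i[[1L]] + Q[, "dy"], i[[2L]] + Q[, "dx"])]
  if (isTRUE(frame$valid)) {
    P <- Q %*% t(frame$R)
    if (frame$mirrored) P[, 1L] <- -P[, 1L]
    vj <- bilinear_many(img, j[[1L]] + P[, 2L], j[[2L]] + P[, 1L])
  } else {
    vj <- img[cbind(j[[1L]] + Q[, "dy"], j[[2L]] + Q[, "dx"])]
  }
  sum((vi - vj)^2)
}
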