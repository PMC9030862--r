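#' Read a grayscale image from PNG or TIFF
#'
#' Reads a single-channel image as a numeric matrix of intensities on the
#' 0--255 scale. Multi-channel (RGB/RGBA) inputs are converted to luminance
#' with the Rec. 601 weights (0.299 R + 0.587 G + 0.114 B); an alpha channel
#' is ignored.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (rows x columns) with values on the 0--255 scale.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file does not exist: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' for '%s' (PNG or TIFF expected)",
                 ext, path), call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  img <- arr * 255
  assert_image(img, arg = path)
  img
}

#' Write a grayscale image to PNG or TIFF
#'
#' Intensities are clipped to \[0, 255\], rounded half-to-even to 8-bit
#' levels, and written as 8-bit grayscale. The format follows the file
#' extension.
#'
#' @param img Numeric matrix on the 0--255 scale.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  q <- round(pmin(pmax(img, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q, target = path),
    tif = ,
    tiff = tiff::writeTIFF(q, where = path, bits.per.sample = 8L),
    stop(sprintf("unsupported output format '%s' (PNG or TIFF expected)", ext),
         call. = FALSE)
  )
  invisible(path)
}

#' Mirror-pad an image
#'
#' Pads all four sides by `margin` pixels with mirror reflection that does not
#' duplicate the edge pixel, so every pixel of the original image owns a full
#' patch after padding.
#'
#' @param img Numeric matrix.
#' @param margin Non-negative integer padding width.
#' @return An `(h + 2 margin) x (w + 2 margin)` matrix whose interior equals
#'   `img`.
#' @export
pad_reflect <- function(img, margin) {
  assert_image(img)
  margin <- as.integer(margin)
  if (margin < 0L) stop("`margin` must be >= 0", call. = FALSE)
  if (margin == 0L) return(img)
  # a singleton dimension has nothing to reflect and passes through unpadded
  bad <- dim(img) > 1L & margin >= dim(img)
  if (any(bad)) {
    stop(sprintf("reflection undefined: margin %d >= image dimension %d",
                 margin, min(dim(img)[bad])), call. = FALSE)
  }
  refl <- function(n, m) {
    if (n == 1L) return(seq_len(n))
    c(rev(seq_len(m)) + 1L, seq_len(n), n - seq_len(m))
  }
  img[refl(nrow(img), margin), refl(ncol(img), margin), drop = FALSE]
}

#' Circular support mask of a square patch
#'
#' Logical `(2 radius + 1)^2` mask marking the pixels whose Euclidean distance
#' from the patch center is at most `radius` — the support used by the
#' rotation-dependent computations (a rotated circle stays inside the square
#' patch).
#'
#' @param radius Patch radius (patch side is `2 radius + 1`).
#' @return A logical matrix.
#' @export
circular_mask <- function(radius) {
  radius <- as.integer(radius)
  if (radius < 0L) stop("`radius` must be >= 0", call. = FALSE)
  d <- seq(-radius, radius)
  outer(d^2, d^2, `+`) <= radius^2
}

# Circular-support offsets as an S x 2 integer matrix of (dx, dy) pairs,
# enumerated row-major over the square window.
support_offsets <- function(radius) {
  d <- seq(-radius, radius)
  g <- expand.grid(dx = d, dy = d)
  keep <- g$dx^2 + g$dy^2 <= radius^2
  as.matrix(g[keep, c("dx", "dy")])
}

#' Extract a square patch around a pixel
#'
#' @param img Numeric matrix, already padded so the window fits (or with the
#'   center at least `radius` away from every edge).
#' @param center Integer pair `c(row, col)` (1-based).
#' @param radius Patch radius; the patch is `(2 radius + 1)` on a side.
#' @return A list of class `ribm_patch` with elements `values` (the window,
#'   copied), `center`, `radius` and `mask` (the inscribed circular support).
#' @export
extract_patch <- function(img, center, radius) {
  assert_image(img)
  radius <- as.integer(radius)
  r0 <- as.integer(center[[1L]]); c0 <- as.integer(center[[2L]])
  if (r0 - radius < 1L || c0 - radius < 1L ||
      r0 + radius > nrow(img) || c0 + radius > ncol(img)) {
    stop(sprintf("patch window at (%d, %d) with radius %d exceeds image bounds %d x %d",
                 r0, c0, radius, nrow(img), ncol(img)), call. = FALSE)
  }
  structure(
    list(values = img[(r0 - radius):(r0 + radius), (c0 - radius):(c0 + radius)],
         center = c(row = r0, col = c0),
         radius = radius,
         mask = circular_mask(radius)),
    class = "ribm_patch")
}

# Accept either an ribm_patch or a plain odd-sided square matrix.
patch_values <- function(patch) {
  if (inherits(patch, "ribm_patch")) return(patch$values)
  if (is.matrix(patch) && nrow(patch) == ncol(patch) && nrow(patch) %% 2L == 1L) {
    return(patch)
  }
  stop("`patch` must be an `ribm_patch` or an odd-sided square matrix", call. = FALSE)
}
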