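#' Normalized Gaussian convolution kernel
#'
#' Builds the `(2m+1) x (2m+1)` mask `exp(-(x^2 + y^2) / (2 sigma^2))` for
#' `x, y` in `[-m, m]`, normalized to unit sum so that convolution preserves
#' the mean brightness level.
#'
#' @param sigma Positive standard deviation (in pixels).
#' @param m Kernel radius (side is `2m + 1`), at least 1.
#' @return A numeric matrix summing to 1, with attributes `sigma` and `m`.
#' @export
gaussian_kernel <- function(sigma, m) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be an integer >= 1", call. = FALSE)
  d <- seq(-m, m)
  g <- exp(-outer(d^2, d^2, `+`) / (2 * sigma^2))
  k <- g / sum(g)
  attr(k, "sigma") <- sigma
  attr(k, "m") <- m
  k
}

#' Gaussian pre-filter (2-D convolution with reflect boundary)
#'
#' Convolves the image with a normalized kernel, mirror-padding the borders so
#' the output has the input's shape and constant images are fixed points. The
#' blurred image serves as the guide for feature extraction and clustering;
#' restoration always reads the original (unblurred) intensities.
#'
#' @param img Numeric matrix.
#' @param kernel A kernel from [gaussian_kernel()] (any odd-sided unit-sum
#'   mask works).
#' @return A numeric matrix of the same shape as `img`.
#' @export
gaussian_blur <- function(img, kernel) {
  assert_image(img)
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel) || nrow(kernel) %% 2L == 0L) {
    stop("`kernel` must be an odd-sided square matrix", call. = FALSE)
  }
  m <- (nrow(kernel) - 1L) %/% 2L
  if (nrow(kernel) > nrow(img) || ncol(kernel) > ncol(img)) {
    stop("kernel is larger than the image", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  p <- pad_reflect(img, m)
  out <- matrix(0, h, w)
  for (dy in -m:m) {
    for (dx in -m:m) {
      # convolution: output(x) = sum_k kernel(k) * img(x - k)
      out <- out + kernel[dy + m + 1L, dx + m + 1L] *
        p[(1L + m - dy):(h + m - dy), (1L + m - dx):(w + m - dx)]
    }
  }
  out
}
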