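#' Mean squared error between two images
#'
#' @param x,y Numeric matrices of identical shape.
#' @return The mean of squared elementwise differences.
#' @export
mse <- function(x, y) {
  assert_image(x); assert_image(y); assert_same_shape(x, y)
  mean((x - y)^2)
}

#' Root mean squared error
#'
#' @inheritParams mse
#' @return `sqrt(mse(x, y))`.
#' @export
rmse <- function(x, y) sqrt(mse(x, y))

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(L^2 / MSE)` with `L` the dynamic range. Identical images give
#' `Inf` (the zero-error sentinel), never an error.
#'
#' @inheritParams mse
#' @param dynamic_range Peak-to-peak intensity magnitude `L` (default 255).
#' @return PSNR in decibels, or `Inf` when `mse(x, y) == 0`.
#' @export
psnr <- function(x, y, dynamic_range = 255) {
  if (dynamic_range <= 0) stop("`dynamic_range` must be > 0", call. = FALSE)
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(dynamic_range^2 / m)
}

#' Structural similarity index
#'
#' The luminance/contrast/structure similarity
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. The default `"windowed"`
#' variant computes the statistics in Gaussian-weighted local windows
#' (11 x 11, window sigma 1.5, reflect boundary) and returns the mean local
#' SSIM, matching standard practice; `"global"` uses one whole-image
#' statistic.
#'
#' @inheritParams psnr
#' @param method `"windowed"` (default) or `"global"`.
#' @return A scalar in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(x, y, dynamic_range = 255, method = c("windowed", "global")) {
  assert_image(x); assert_image(y); assert_same_shape(x, y)
  if (dynamic_range <= 0) stop("`dynamic_range` must be > 0", call. = FALSE)
  method <- match.arg(method)
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  if (method == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  if (min(dim(x)) < 11L) {
    stop("windowed SSIM needs images at least 11 x 11; use method = \"global\"",
         call. = FALSE)
  }
  k <- gaussian_kernel(1.5, 5L)
  mx <- gaussian_blur(x, k); my <- gaussian_blur(y, k)
  vx <- gaussian_blur(x * x, k) - mx^2
  vy <- gaussian_blur(y * y, k) - my^2
  cxy <- gaussian_blur(x * y, k) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Full quality record for a (reference, test) image pair
#'
#' @param ref,test Numeric matrices of identical shape (reference first).
#' @param dynamic_range Intensity magnitude `L` for PSNR/SSIM (default 255).
#' @return A one-row tibble with columns `ssim`, `psnr`, `mse`, `rmse`.
#' @export
evaluate_images <- function(ref, test, dynamic_range = 255) {
  m <- mse(ref, test)
  tibble::tibble(
    ssim = ssim(ref, test, dynamic_range),
    psnr = psnr(ref, test, dynamic_range),
    mse = m,
    rmse = sqrt(m)
  )
}
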