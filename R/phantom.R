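#' Describe an elliptical lesion for a synthetic phantom
#'
#' @param row,col Center of the ellipse (1-based pixel coordinates).
#' @param a,b Semi-axes in pixels along the (unrotated) column and row
#'   directions respectively.
#' @param angle Orientation in degrees (counter-clockwise).
#' @param offset Intensity offset added inside the ellipse: negative for
#'   hypo-echoic (dark, cyst-like) lesions, positive for hyper-echoic ones.
#' @return A one-row tibble; bind several with [dplyr::bind_rows()].
#' @export
lesion <- function(row, col, a, b, angle = 0, offset = -50) {
  tibble::tibble(row = row, col = col, a = a, b = b, angle = angle, offset = offset)
}

#' Generate a piecewise-smooth ultrasound-like phantom
#'
#' Builds a noiseless test image: a constant background, elliptical
#' hypo-/hyper-echoic lesions, and an optional smooth pseudo-random texture
#' emulating tissue echotexture. Deterministic given `seed`.
#'
#' @param height,width Image size in pixels.
#' @param lesions A tibble of ellipse records as produced by [lesion()], or
#'   `NULL` for none. Every ellipse must lie fully inside the image.
#' @param background Background intensity in \[0, 255\].
#' @param texture_amplitude Standard deviation (gray levels) of the smooth
#'   texture field; 0 disables texture.
#' @param seed Integer seed for the texture field.
#' @return A numeric matrix with values in \[0, 255\].
#' @export
make_phantom <- function(height, width, lesions = NULL, background = 128,
                         texture_amplitude = 0, seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("phantom dimensions must be positive", call. = FALSE)
  if (background < 0 || background > 255) {
    stop("`background` must lie in [0, 255]", call. = FALSE)
  }
  if (texture_amplitude < 0) stop("`texture_amplitude` must be >= 0", call. = FALSE)

  img <- matrix(background, height, width)
  if (!is.null(lesions) && nrow(lesions) > 0L) {
    lv <- background + lesions$offset
    if (any(lv < 0 | lv > 255)) {
      stop("background + lesion offset must stay within [0, 255]", call. = FALSE)
    }
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (i in seq_len(nrow(lesions))) {
      th <- lesions$angle[i] * pi / 180
      a <- lesions$a[i]; b <- lesions$b[i]
      # bounding box of the rotated ellipse must stay inside the image
      bx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
      by <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
      if (lesions$col[i] - bx < 1 || lesions$col[i] + bx > width ||
          lesions$row[i] - by < 1 || lesions$row[i] + by > height) {
        stop(sprintf("lesion %d extends beyond the image bounds", i), call. = FALSE)
      }
      dx <- cols - lesions$col[i]
      dy <- rows - lesions$row[i]
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      img[inside] <- img[inside] + lesions$offset[i]
    }
  }
  if (texture_amplitude > 0) {
    tex <- with_seed(seed, matrix(rnorm(height * width), height, width))
    k <- gaussian_kernel(1.5, 4L) # smooth, speckle-scale correlation length
    tex <- gaussian_blur(tex, k)
    tex <- tex / stats::sd(tex) * texture_amplitude
    img <- img + tex
  }
  pmin(pmax(img, 0), 255)
}

#' Default demonstration phantom
#'
#' A 128 x 128 anatomy-like phantom used throughout the package's examples
#' and experiments: mid-gray background with smooth echotexture, one
#' hypo-echoic (cyst-like) and one hyper-echoic elliptical lesion.
#'
#' @param height,width Image size.
#' @param seed Seed for the texture field.
#' @return A numeric matrix in \[0, 255\].
#' @export
example_phantom <- function(height = 128L, width = 128L, seed = 1L) {
  sc <- min(height, width) / 128
  les <- dplyr::bind_rows(
    lesion(row = 0.38 * height, col = 0.36 * width, a = 16 * sc, b = 10 * sc,
           angle = 25, offset = -60),
    lesion(row = 0.70 * height, col = 0.66 * width, a = 12 * sc, b = 18 * sc,
           angle = -40, offset = 70)
  )
  make_phantom(height, width, lesions = les, background = 120,
               texture_amplitude = 12, seed = seed)
}

#' Degrade an image with a seeded noise model
#'
#' Two models are provided: `additive_gaussian` adds zero-mean Gaussian noise
#' with standard deviation `sigma` on the 0--255 intensity scale;
#' `multiplicative_speckle` multiplies each pixel by an i.i.d. unit-mean
#' log-normal factor whose standard deviation is `sigma / 255`, reflecting the
#' multiplicative character of speckle. The output is not clipped — clipping
#' is a write-out concern ([write_image()]).
#'
#' @param img Numeric matrix.
#' @param sigma Noise level (standard deviation on the 0--255 scale).
#' @param model `"additive_gaussian"` or `"multiplicative_speckle"`.
#' @param seed Integer seed; the realization is fully determined by it.
#' @return A numeric matrix of the same shape.
#' @export
add_noise <- function(img, sigma, model = c("additive_gaussian", "multiplicative_speckle"),
                      seed = 1L) {
  assert_image(img)
  model <- match.arg(model)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  n <- length(img)
  if (model == "additive_gaussian") {
    img + with_seed(seed, matrix(rnorm(n, mean = 0, sd = sigma), nrow(img), ncol(img)))
  } else {
    # log-normal multiplier with E[eta] = 1 and SD[eta] = sigma/255
    s2 <- log(1 + (sigma / 255)^2)
    eta <- with_seed(seed, matrix(exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2))),
                                  nrow(img), ncol(img)))
    img * eta
  }
}
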