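#' Tunables of the de-speckling pipeline
#'
#' Collects every pipeline parameter with defaults tied to the assumed noise
#' level `sigma`: the filtering bandwidth is `h = 12 sigma`, the pre-filter
#' kernel uses `kernel_sigma = 0.5 sigma` with radius `m = 4`, patches are
#' 15 x 15 (`patch_radius = 7`), and `K = NULL` auto-scales the number of
#' clusters proportionally to the pixel count (675 clusters for a 225 x 225
#' image, minimum 1).
#'
#' @param sigma Assumed noise standard deviation (0--255 scale); drives the
#'   `h` and `kernel_sigma` defaults.
#' @param patch_radius Patch radius `r`; the patch is `(2r + 1)` on a side.
#' @param K Number of clusters, or `NULL` to scale with image size.
#' @param h Filtering bandwidth of the exponential weight kernel.
#' @param kernel_sigma,kernel_radius Gaussian pre-filter parameters.
#' @param seed Integer seed (cluster initialization and any subsampling).
#' @param standardize_features Standardize Hu components before clustering.
#' @param rotation_enabled Apply rotation/mirror compensation in the patch
#'   distance (disable to get plain cluster-restricted NLM).
#' @param eps_centroid Centroid-norm threshold (pixels) below which a patch is
#'   treated as isotropic and matched without rotation.
#' @param max_candidates Optional cap on candidates per cluster (deterministic
#'   subsample); `NULL` (default) uses every cluster member.
#' @param kmeans_max_iter,kmeans_tol K-means stopping parameters.
#' @return A list of class `denoise_config`.
#' @export
denoise_config <- function(sigma = 20, patch_radius = 7L, K = NULL, h = NULL,
                           kernel_sigma = NULL, kernel_radius = 4L, seed = 1L,
                           standardize_features = TRUE, rotation_enabled = TRUE,
                           eps_centroid = 1e-6, max_candidates = NULL,
                           kmeans_max_iter = 100L, kmeans_tol = 1e-10) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  cfg <- list(
    sigma = sigma,
    patch_radius = as.integer(patch_radius),
    K = if (is.null(K)) NULL else as.integer(K),
    # at sigma = 0 the defaults degenerate gracefully: a near-delta kernel and
    # a vanishing bandwidth, so only exact patch matches receive weight
    h = h %||% max(12 * sigma, 1e-8),
    kernel_sigma = kernel_sigma %||% max(0.5 * sigma, 0.01),
    kernel_radius = as.integer(kernel_radius),
    seed = as.integer(seed),
    standardize_features = isTRUE(standardize_features),
    rotation_enabled = isTRUE(rotation_enabled),
    eps_centroid = eps_centroid,
    max_candidates = if (is.null(max_candidates)) NULL else as.integer(max_candidates),
    kmeans_max_iter = as.integer(kmeans_max_iter),
    kmeans_tol = kmeans_tol
  )
  if (cfg$h <= 0) stop("`h` must be > 0 (set `sigma` or `h` explicitly)", call. = FALSE)
  if (cfg$patch_radius < 1L) stop("`patch_radius` must be >= 1", call. = FALSE)
  structure(cfg, class = "denoise_config")
}

# Number of clusters scaled with pixel count: 675 for a 225 x 225 image.
auto_K <- function(npix) max(1L, as.integer(round(675 * npix / (225 * 225))))

#' Conventional non-local means (baseline)
#'
#' The classical filter: every pixel is restored as a weighted average over
#' all pixels of the image, with weights
#' `w(i, j) = exp(-d_a(i, j) / h^2) / Z(i)` where `d_a` is the
#' Gaussian-weighted (width `alpha`, normalized to unit sum) squared patch
#' distance over the square patch. Quadratic cost — intended for small images
#' and as the reference baseline/oracle substrate.
#'
#' @param img Numeric matrix.
#' @param h Filtering bandwidth.
#' @param radius Patch radius (default 7).
#' @param alpha Gaussian width of the patch weighting (default `radius / 2`).
#' @return The filtered image (same shape).
#' @export
nlm_conventional <- function(img, h, radius = 7L, alpha = radius / 2) {
  assert_image(img)
  if (h <= 0) stop("`h` must be > 0", call. = FALSE)
  radius <- as.integer(radius)
  hh <- nrow(img); ww <- ncol(img)
  N <- hh * ww
  p <- pad_reflect(img, radius)
  d <- seq(-radius, radius)
  G <- exp(-outer(d^2, d^2, `+`) / (2 * alpha^2))
  G <- G / sum(G)
  # patch matrix, one row per pixel (row-major), columns scaled by sqrt(G)
  n2 <- (2L * radius + 1L)^2
  P <- matrix(0, N, n2)
  idx <- 0L
  sg <- sqrt(as.vector(G))
  for (r0 in seq_len(hh)) {
    for (c0 in seq_len(ww)) {
      idx <- idx + 1L
      P[idx, ] <- as.vector(p[(r0):(r0 + 2L * radius), (c0):(c0 + 2L * radius)]) * sg
    }
  }
  v <- as.vector(t(img)) # row-major intensities
  sq <- rowSums(P^2)
  out <- numeric(N)
  chunk <- max(1L, floor(2e7 / N))
  for (s in seq(1L, N, by = chunk)) {
    e <- min(N, s + chunk - 1L)
    D <- pmax(outer(sq[s:e], sq, `+`) - 2 * tcrossprod(P[s:e, , drop = FALSE], P), 0)
    W <- exp(-D / h^2)
    out[s:e] <- (W %*% v) / rowSums(W)
  }
  matrix(out, hh, ww, byrow = TRUE)
}

#' Cluster-restricted rotation-compensated NLM weights for one pixel
#'
#' Computes the weight set a single pixel receives from its cluster's
#' candidate list: for each candidate the mirror flag comes from the stored
#' `phi7` signs, the rotation frame from the stored centroids, the distance
#' from [distance_dR()], and the raw weight is `exp(-dR / h^2)`. The
#' self-candidate (`j = i`) has distance 0 and hence the maximum raw weight.
#'
#' @param img Numeric matrix (the noisy image; padded internally).
#' @param i Integer pair `c(row, col)`: the target pixel.
#' @param candidates `L x 2` matrix (columns row, col) of candidate centers —
#'   normally the LUT members of `i`'s cluster.
#' @param h Filtering bandwidth.
#' @param features A [patch_feature_store()] (computed on the blurred guide).
#' @param rotation_enabled Apply rotation/mirror compensation.
#' @param eps_centroid Centroid degeneracy threshold.
#' @return A tibble with columns `row`, `col`, `d` (distance), `raw`, and
#'   `weight` (normalized, summing to 1), with the normalizer as attribute
#'   `Z`.
#' @export
weights_ribm <- function(img, i, candidates, h, features,
                         rotation_enabled = TRUE, eps_centroid = 1e-6) {
  assert_image(img)
  if (is.null(dim(candidates))) candidates <- matrix(candidates, ncol = 2L, byrow = TRUE)
  if (nrow(candidates) < 1L) stop("empty candidate list", call. = FALSE)
  radius <- features$radius
  w <- features$dim[2L]
  M <- ceiling(radius * sqrt(2))
  p <- pad_reflect(img, M)
  sidx <- function(rc) (rc[[1L]] - 1L) * w + rc[[2L]] # row-major store index
  ii <- sidx(i)
  ci <- store_centroid(features, ii)
  d <- numeric(nrow(candidates))
  for (l in seq_len(nrow(candidates))) {
    j <- candidates[l, ]
    jj <- sidx(j)
    if (jj == ii && all(j == i)) { d[l] <- 0; next }
    mir <- features$hu[ii, 7L] * features$hu[jj, 7L] < 0
    fr <- if (rotation_enabled) {
      rotation_frame(ci, store_centroid(features, jj), mir, eps_c = eps_centroid)
    } else {
      structure(list(R = diag(2), mirrored = FALSE, valid = FALSE), class = "ribm_frame")
    }
    d[l] <- distance_dR(p, c(i[[1L]] + M, i[[2L]] + M), c(j[[1L]] + M, j[[2L]] + M),
                        fr, radius)
  }
  raw <- exp(-d / h^2)
  Z <- sum(raw)
  out <- tibble::tibble(row = candidates[, 1L], col = candidates[, 2L],
                        d = d, raw = raw, weight = raw / Z)
  attr(out, "Z") <- Z
  out
}

# Centroid record for store index idx, matching patch_centroid()'s shape.
store_centroid <- function(features, idx) {
  vec <- c(x = features$cx[idx], y = features$cy[idx])
  nrm <- sqrt(sum(vec^2))
  structure(list(vec = vec, norm = nrm,
                 unit = if (nrm > 0) vec / nrm else NULL,
                 mass = features$mass[idx]),
            class = "ribm_centroid")
}

#' De-speckle an image with cluster-restricted rotation-compensated NLM
#'
#' The full pipeline: Gaussian pre-filter to a guide image; per-pixel Hu
#' moment features and intensity centroids on the guide; K-means
#' pre-classification into a cluster look-up table; then, for every pixel,
#' a non-local-means weighted average over the members of its own cluster,
#' with each candidate patch rotation- and mirror-aligned before the patch
#' distance is measured. Restored intensities are read from the original
#' noisy image (the blurred guide only steers feature extraction and
#' clustering). Fully reproducible given `config$seed`.
#'
#' @param img Numeric matrix on the 0--255 scale.
#' @param config A [denoise_config()].
#' @return The filtered image (same shape), with attributes `config` (the
#'   resolved parameter set, including the `K` actually used) and
#'   `cluster_sizes`.
#' @export
despeckle_ribm_nlm <- function(img, config = denoise_config()) {
  assert_image(img)
  if (!inherits(config, "denoise_config")) {
    stop("`config` must be a `denoise_config()`", call. = FALSE)
  }
  r <- config$patch_radius
  K <- config$K %||% auto_K(length(img))
  if (K > length(img)) {
    stop(sprintf("clustering: K = %d exceeds the pixel count %d", K, length(img)),
         call. = FALSE)
  }

  kern <- gaussian_kernel(config$kernel_sigma, config$kernel_radius)
  guide <- tryCatch(gaussian_blur(img, kern),
                    error = function(e) stop("pre-filter: ", conditionMessage(e),
                                             call. = FALSE))
  fs <- patch_feature_store(guide, r)
  X <- if (config$standardize_features && nrow(fs$hu) >= 2L) {
    feature_standardize(fs$hu)
  } else {
    fs$hu
  }
  fit <- tryCatch(
    kmeans_fit(X, K, max_iter = config$kmeans_max_iter,
               tol = config$kmeans_tol, seed = config$seed),
    error = function(e) stop("clustering: ", conditionMessage(e), call. = FALSE))

  members <- fit$members
  if (!is.null(config$max_candidates)) {
    cap <- config$max_candidates
    members <- lapply(seq_along(members), function(k) {
      mk <- members[[k]]
      if (length(mk) <= cap) mk else
        sort(with_seed(config$seed + k, sample(mk, cap)))
    })
  }

  M <- ceiling(r * sqrt(2))
  padded <- pad_reflect(img, M)
  out <- cpp_ribm_restore(padded, nrow(img), ncol(img), M,
                          fit$labels, members, fs$hu[, 7L], fs$cx, fs$cy,
                          config$h^2, config$rotation_enabled,
                          config$eps_centroid, support_offsets(r))
  resolved <- unclass(config)
  resolved$K <- K
  attr(out, "config") <- resolved
  attr(out, "cluster_sizes") <- lengths(fit$members)
  out
}
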