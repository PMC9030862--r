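#' Standardize a feature matrix component-wise
#'
#' Hu invariant components span wildly different magnitudes; unstandardized
#' Euclidean distance is dominated by `phi1`. This transform centers each
#' component to zero mean and scales it to unit variance; zero-variance
#' components pass through as zeros. The transform parameters are recorded as
#' attributes for reproducibility.
#'
#' @param features Numeric matrix (patches x components).
#' @return A matrix of the same shape with attributes `center` and `scale`.
#' @export
feature_standardize <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 feature vectors", call. = FALSE)
  ctr <- colMeans(features)
  sc <- apply(features, 2L, stats::sd)
  out <- sweep(features, 2L, ctr, `-`)
  nz <- sc > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sc[nz], `/`)
  out[, !nz] <- 0
  attr(out, "center") <- ctr
  attr(out, "scale") <- sc
  out
}

#' K-means pre-classification of patch features
#'
#' Lloyd's algorithm with seeded k-means++ initialization and Euclidean
#' distance, producing the cluster membership lists (the look-up table) that
#' restrict each pixel's non-local-means candidate search. Fully reproducible
#' given `seed`; assignment ties break to the lowest cluster index; a cluster
#' that empties during iteration is re-seeded at the feature farthest from its
#' current center. The within-cluster sum-of-squares objective is recorded
#' after every assignment step and is non-increasing.
#'
#' @param features Numeric matrix (N x d) of feature vectors, one per patch,
#'   in row-major pixel order.
#' @param K Number of clusters, `1 <= K <= N`.
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Stop when the objective decreases by less than `tol`.
#' @param seed Integer seed for the initialization.
#' @return A list of class `cluster_table`: `labels` (integer vector, 1-based
#'   cluster per patch), `members` (list of K integer vectors of patch
#'   indices), `centers` (K x d), `objective` (per-iteration trace), `iter`,
#'   and `params`.
#' @export
kmeans_fit <- function(features, K, max_iter = 100L, tol = 1e-10, seed = 1L) {
  if (!is.matrix(features)) features <- as.matrix(features)
  N <- nrow(features)
  if (N < 1L) stop("`features` must be non-empty", call. = FALSE)
  if (!all(is.finite(features))) {
    bad <- which(!apply(features, 1L, function(r) all(is.finite(r))))[1L]
    stop(sprintf("non-finite feature vector at patch index %d", bad), call. = FALSE)
  }
  K <- as.integer(K)
  if (K < 1L || K > N) {
    stop(sprintf("`K` must satisfy 1 <= K <= %d (number of patches)", N), call. = FALSE)
  }

  centers <- with_seed(seed, kmeanspp_init(features, K))
  objective <- numeric(0)
  labels <- integer(N)
  for (it in seq_len(max_iter)) {
    asg <- cpp_assign_clusters(features, centers)
    new_labels <- asg$labels
    obj <- sum(asg$dist2)

    # empty-cluster repair: reseed at the feature farthest from the empty
    # cluster's current center, then re-assign (objective cannot increase:
    # centers only gain options)
    counts <- tabulate(new_labels, nbins = K)
    if (any(counts == 0L)) {
      for (k in which(counts == 0L)) {
        d2k <- rowSums(sweep(features, 2L, centers[k, ], `-`)^2)
        centers[k, ] <- features[which.max(d2k), ]
      }
      asg <- cpp_assign_clusters(features, centers)
      new_labels <- asg$labels
      obj <- sum(asg$dist2)
    }
    objective <- c(objective, obj)

    converged <- identical(new_labels, labels) ||
      (length(objective) > 1L &&
         objective[length(objective) - 1L] - obj < tol)
    labels <- new_labels
    for (k in seq_len(K)) {
      mk <- labels == k
      if (any(mk)) centers[k, ] <- colMeans(features[mk, , drop = FALSE])
    }
    if (converged) break
  }

  structure(
    list(labels = labels,
         members = split(seq_len(N), factor(labels, levels = seq_len(K))),
         centers = centers,
         objective = objective,
         iter = length(objective),
         params = list(K = K, max_iter = max_iter, tol = tol, seed = seed)),
    class = "cluster_table")
}

# Seeded k-means++ initialization (expects an active RNG state).
kmeanspp_init <- function(X, K) {
  N <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  i <- sample.int(N, 1L)
  centers[1L, ] <- X[i, ]
  if (K == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ], `-`)^2)
  for (k in 2L:K) {
    if (sum(d2) <= 0) {
      i <- sample.int(N, 1L)
    } else {
      i <- sample.int(N, 1L, prob = d2)
    }
    centers[k, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ], `-`)^2))
  }
  centers
}

#' Build the cluster look-up table of patch-center coordinates
#'
#' Converts an image-shaped label grid into the per-cluster lists of member
#' patch-center coordinates, each list in row-major order.
#'
#' @param labels Integer matrix of cluster indices (1-based), image-shaped.
#' @return A list with one `n_k x 2` matrix (columns `row`, `col`) per
#'   cluster index present in `labels`.
#' @export
build_lut <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be an image-shaped matrix", call. = FALSE)
  h <- nrow(labels); w <- ncol(labels)
  coords <- cbind(row = rep(seq_len(h), each = w), col = rep(seq_len(w), times = h))
  lab_rowmajor <- as.integer(t(labels))
  lapply(split(seq_len(h * w), factor(lab_rowmajor)), function(i) {
    coords[i, , drop = FALSE]
  })
}

#' Dump a look-up table as a plain-text table
#'
#' Writes one line per patch: `cluster_id<TAB>row<TAB>col`.
#'
#' @param lut A [build_lut()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_lut <- function(lut, path) {
  rows <- do.call(rbind, lapply(names(lut), function(k) {
    cbind(cluster_id = as.integer(k), lut[[k]])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
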