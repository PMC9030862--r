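# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite intensities", arg), call. = FALSE)
  }
  invisible(img)
}

assert_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  invisible(NULL)
}
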