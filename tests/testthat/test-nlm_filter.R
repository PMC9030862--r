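test_that("conventional NLM fixes constant images and flattens at huge bandwidth", {
  img <- matrix(77, 10, 10)
  expect_equal(nlm_conventional(img, h = 100, radius = 3), img, tolerance = 1e-12)

  set.seed(51)
  img2 <- matrix(runif(100, 0, 255), 10, 10)
  out <- nlm_conventional(img2, h = 1e9, radius = 3)
  expect_equal(out, matrix(mean(img2), 10, 10), tolerance = 1e-5)
})

test_that("conventional NLM matches an independent triple-loop implementation", {
  set.seed(52)
  img <- matrix(runif(144, 0, 255), 12, 12)
  radius <- 3L; h <- 120; alpha <- radius / 2
  d <- seq(-radius, radius)
  G <- exp(-outer(d^2, d^2, `+`) / (2 * alpha^2)); G <- G / sum(G)
  p <- pad_reflect(img, radius)
  oracle <- matrix(0, 12, 12)
  for (r in 1:12) for (c in 1:12) {
    wsum <- 0; acc <- 0
    Pi <- p[r:(r + 2 * radius), c:(c + 2 * radius)]
    for (rj in 1:12) for (cj in 1:12) {
      Pj <- p[rj:(rj + 2 * radius), cj:(cj + 2 * radius)]
      w <- exp(-sum(G * (Pi - Pj)^2) / h^2)
      wsum <- wsum + w; acc <- acc + w * img[rj, cj]
    }
    oracle[r, c] <- acc / wsum
  }
  expect_equal(nlm_conventional(img, h = h, radius = radius), oracle,
               tolerance = 1e-10)
})

test_that("singleton candidate lists give weight one; two candidates the softmax", {
  img <- example_phantom(24, 24, seed = 6)
  noisy <- add_noise(img, 10, seed = 7)
  fs <- patch_feature_store(gaussian_blur(noisy, gaussian_kernel(5, 4)), 7)
  ws <- weights_ribm(noisy, c(12, 12), matrix(c(12, 12), 1, 2), h = 120, fs)
  expect_equal(ws$weight, 1)
  expect_equal(ws$d, 0)

  ws2 <- weights_ribm(noisy, c(12, 12), rbind(c(12, 12), c(7, 17)), h = 120, fs)
  d <- ws2$d[2]
  expect_equal(ws2$d[1], 0)
  e <- exp(-d / 120^2)
  expect_equal(ws2$weight, c(1, e) / (1 + e), tolerance = 1e-12)
})

test_that("weights are a proper convex combination, invariant to candidate order", {
  img <- example_phantom(24, 24, seed = 8)
  noisy <- add_noise(img, 15, seed = 9)
  fs <- patch_feature_store(gaussian_blur(noisy, gaussian_kernel(7.5, 4)), 7)
  set.seed(53)
  for (rep in 1:30) {
    i <- c(sample(24, 1), sample(24, 1))
    L <- sample(2:12, 1)
    cand <- cbind(sample(24, L, replace = TRUE), sample(24, L, replace = TRUE))
    ws <- weights_ribm(noisy, i, cand, h = 180, fs)
    expect_equal(sum(ws$weight), 1, tolerance = 1e-9)
    expect_true(all(ws$weight >= 0 & ws$weight <= 1))
    # permutation invariance of the restored value
    perm <- sample(L)
    ws2 <- weights_ribm(noisy, i, cand[perm, , drop = FALSE], h = 180, fs)
    v1 <- sum(ws$weight * noisy[cbind(ws$row, ws$col)])
    v2 <- sum(ws2$weight * noisy[cbind(ws2$row, ws2$col)])
    expect_equal(v1, v2, tolerance = 1e-12)
  }
  expect_error(weights_ribm(noisy, c(1, 1), matrix(numeric(0), 0, 2), 120, fs),
               "empty")
})

test_that("the full pipeline fixes constant images and is seed-deterministic", {
  img <- matrix(42, 20, 20)
  cfg <- denoise_config(sigma = 10, seed = 3)
  out <- despeckle_ribm_nlm(img, cfg)
  expect_equal(unclass(out), img, tolerance = 1e-12, ignore_attr = TRUE)

  noisy <- add_noise(example_phantom(24, 24, seed = 2), 15, seed = 4)
  a <- despeckle_ribm_nlm(noisy, denoise_config(sigma = 15, seed = 5))
  b <- despeckle_ribm_nlm(noisy, denoise_config(sigma = 15, seed = 5))
  expect_identical(unclass(a), unclass(b))
  # convex combination: output range inside input range
  expect_gte(min(a), min(noisy))
  expect_lte(max(a), max(noisy))
  # resolved config travels with the output
  expect_equal(attr(a, "config")$K, auto_k_for_tests(24 * 24))
})

test_that("K = 1 without rotation reduces to brute-force unrestricted NLM", {
  img <- add_noise(example_phantom(24, 24, seed = 1), 20, seed = 2)
  cfg <- denoise_config(sigma = 20, K = 1, rotation_enabled = FALSE)
  out <- despeckle_ribm_nlm(img, cfg)

  M <- 10L; pad <- pad_reflect(img, M)
  off <- support_offsets_for_tests(7)
  h2 <- (12 * 20)^2
  oracle <- matrix(0, 24, 24)
  for (r in 1:24) for (c in 1:24) {
    vi <- pad[cbind(M + r + off[, "dy"], M + c + off[, "dx"])]
    wsum <- 0; acc <- 0
    for (rj in 1:24) for (cj in 1:24) {
      vj <- pad[cbind(M + rj + off[, "dy"], M + cj + off[, "dx"])]
      w <- exp(-sum((vi - vj)^2) / h2)
      wsum <- wsum + w; acc <- acc + w * img[rj, cj]
    }
    oracle[r, c] <- acc / wsum
  }
  expect_equal(unclass(out), oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the C++ restoration agrees with the R-level weight module", {
  p <- example_phantom(20, 20, seed = 3)
  n <- add_noise(p, 15, seed = 4)
  cfg <- denoise_config(sigma = 15, K = 4, seed = 5)
  d <- despeckle_ribm_nlm(n, cfg)
  g <- gaussian_blur(n, gaussian_kernel(cfg$kernel_sigma, cfg$kernel_radius))
  fs <- patch_feature_store(g, 7)
  fit <- kmeans_fit(feature_standardize(fs$hu), 4, seed = 5)
  lab <- matrix(fit$labels, 20, 20, byrow = TRUE)
  lut <- build_lut(lab)
  out <- matrix(0, 20, 20)
  for (r in 1:20) for (c in 1:20) {
    ws <- weights_ribm(n, c(r, c), lut[[as.character(lab[r, c])]], cfg$h, fs)
    out[r, c] <- sum(ws$weight * n[cbind(ws$row, ws$col)])
  }
  expect_equal(unclass(d), out, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("denoising improves fidelity on a noisy phantom", {
  clean <- example_phantom(48, 48, seed = 10)
  noisy <- add_noise(clean, 20, seed = 11)
  den <- despeckle_ribm_nlm(noisy, denoise_config(sigma = 20, seed = 12))
  expect_gt(psnr(clean, den), psnr(clean, noisy))
})
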