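test_that("gaussian kernels are symmetric, unit-sum and validated", {
  k <- gaussian_kernel(1.4)
  expect_equal(sum(k$weights), 1, tolerance = 1e-12)
  expect_equal(k$weights, rev(k$weights))
  expect_error(gaussian_kernel(0), "positive")
})

test_that("smoothing preserves constants and the global mean", {
  cst <- matrix(77, 20, 20)
  expect_equal(gaussian_smooth(cst, 2), cst, tolerance = 1e-10)
  set.seed(2)
  img <- matrix(runif(900, 0, 255), 30, 30)
  expect_equal(mean(gaussian_smooth(img, 1.4)), mean(img), tolerance = 1e-8)
})

test_that("impulse response is the outer product of the 1-D kernels", {
  img <- matrix(0, 15, 15); img[8, 8] <- 1
  sm <- gaussian_smooth(img, 1)
  k <- gaussian_kernel(1)
  r <- k$radius
  expect_equal(sm[(8 - r):(8 + r), (8 - r):(8 + r)],
               outer(k$weights, k$weights), tolerance = 1e-12)
})

test_that("separable smoothing equals direct 2-D convolution", {
  set.seed(4)
  img <- matrix(runif(256, 0, 255), 16, 16)
  k <- gaussian_kernel(1.2)
  expect_equal(gaussian_smooth(img, 1.2), brute_conv2_reflect(img, k$weights),
               tolerance = 1e-10)
})

test_that("gradient stencils reproduce hand-evaluated cases", {
  g <- image_gradients(matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(g$ex[1, 1], 1)
  expect_equal(g$ey[1, 1], 0)
  gy <- image_gradients(matrix(c(1, 0, 1, 0), 2, 2))
  expect_equal(gy$ex[1, 1], 0)
  expect_equal(gy$ey[1, 1], 1)
  expect_error(image_gradients(matrix(1, 1, 1)), "2 x 2")
})

test_that("magnitude and direction are elementwise-consistent with (ex, ey)", {
  set.seed(6)
  img <- matrix(runif(400, 0, 255), 20, 20)
  g <- image_gradients(img)
  expect_equal(g$magnitude, sqrt(g$ex^2 + g$ey^2), tolerance = 1e-12)
  expect_equal(g$direction, atan2(g$ey, g$ex), tolerance = 1e-12)
  expect_true(all(g$direction > -pi & g$direction <= pi))
  # brute-force recomputation of the stencil at every pixel
  H <- nrow(img); W <- ncol(img)
  for (i in c(1, 7, H - 1)) for (j in c(1, 11, W - 1)) {
    ex <- (img[i, j + 1] - img[i, j] + img[i + 1, j + 1] - img[i + 1, j]) / 2
    ey <- (img[i, j] - img[i + 1, j] + img[i, j + 1] - img[i + 1, j + 1]) / 2
    expect_equal(g$ex[i, j], ex, tolerance = 1e-12)
    expect_equal(g$ey[i, j], ey, tolerance = 1e-12)
  }
  # 3-4-5 magnitude and 45-degree direction sanity
  expect_equal(sqrt(3^2 + 4^2), 5)
  expect_equal(atan2(1, 1), pi / 4)
})

test_that("canny finds a vertical step within one column and nothing on flats", {
  expect_equal(sum(canny(matrix(42, 32, 32))$edges), 0)
  img <- matrix(0, 64, 64); img[, 33:64] <- 100
  em <- canny(img)
  idx <- which(em$edges, arr.ind = TRUE)
  expect_gt(nrow(idx), 32)
  expect_true(all(abs(idx[, 2] - 32.5) <= 1))
})

test_that("edge pixels always clear the low threshold", {
  ph <- generate_phantom(phantom_spec(64, 64, geometry_seed = 9))
  em <- canny(ph$image)
  mag <- matrix(0, 64, 64)
  mag[seq_len(nrow(em$magnitude)), seq_len(ncol(em$magnitude))] <- em$magnitude
  expect_true(all(mag[em$edges] >= em$low_thresh))
})

test_that("edge maps are invariant to adding a constant to the image", {
  ph <- generate_phantom(phantom_spec(64, 64, geometry_seed = 10))
  expect_identical(canny(ph$image)$edges, canny(ph$image + 13)$edges)
})

test_that("filter diagnostics scale with noise and match quadrature oracles", {
  x <- seq(-6, 6, by = 0.1)
  H <- -x * exp(-x^2 / 2)                       # gaussian-derivative kernel
  G <- as.numeric(x >= 0)                       # step edge
  d1 <- filter_diagnostics(H, noise_sigma = 1, edge_profile = G, dx = 0.1)
  d2 <- filter_diagnostics(H, noise_sigma = 2, edge_profile = G, dx = 0.1)
  expect_equal(d2$noise_response, 2 * d1$noise_response, tolerance = 1e-12)
  expect_equal(d2$localization, d1$localization / 2, tolerance = 1e-12)
  # boxcar edge response against an independent trapezoid loop
  box <- as.numeric(abs(x) <= 2)
  db <- filter_diagnostics(box, 1, G, dx = 0.1)
  expect_equal(db$edge_response, brute_trapz(x, rev(G) * box), tolerance = 1e-12)
  # zero-crossing spacing against brute-force evaluation on the same grid
  H1 <- brute_gradient(H, 0.1); H2 <- brute_gradient(H1, 0.1)
  expect_equal(d1$zero_crossing_spacing,
               pi * sqrt(brute_trapz(x, H1^2) / brute_trapz(x, H2^2)),
               tolerance = 1e-8)
  expect_error(filter_diagnostics(rep(0, 5)), "zero-energy")
})
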