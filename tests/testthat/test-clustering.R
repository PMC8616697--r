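test_that("quantile center initialization matches hand-computed quantiles", {
  two <- matrix(rep(c(0, 255), each = 32), 8, 8)
  expect_equal(init_centers(two, 2), c(0, 255))
  ramp <- matrix(0:255, 16, 16)
  expect_equal(init_centers(ramp, 3), c(42.5, 127.5, 212.5))
  expect_identical(init_centers(ramp, 4), init_centers(ramp, 4))
  expect_error(init_centers(matrix(1, 4, 4), 2), "degenerate")
})

test_that("collapsed quantiles fall back to distinct centers", {
  # heavily unbalanced two-value histogram would put both plain quantiles on 0
  img <- matrix(c(rep(0, 60), rep(200, 4)), 8, 8)
  v <- init_centers(img, 2)
  expect_false(anyDuplicated(v) > 0)
})

test_that("fuzzy factor vanishes in agreement cases and matches brute force", {
  img <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90), 3, 3)
  v <- c(30, 70)
  # all neighbour memberships to cluster 1 equal 1 -> B_i1 = 0
  mu1 <- array(0, c(3, 3, 2)); mu1[, , 1] <- 1
  expect_equal(fuzzy_factor(img, mu1, v, m = 2)[, , 1], matrix(0, 3, 3))
  # all neighbour intensities equal the center -> B = 0 for that cluster
  flat <- matrix(30, 3, 3)
  muh <- array(0.5, c(3, 3, 2))
  expect_equal(fuzzy_factor(flat, muh, v, m = 2)[, , 1], matrix(0, 3, 3))
  # brute-force neighbourhood sums on random fields
  set.seed(42)
  rimg <- matrix(runif(20, 0, 255), 4, 5)
  rmu <- array(runif(40), c(4, 5, 2))
  rmu <- rmu / rep(apply(rmu, c(1, 2), sum), times = 2)
  B <- fuzzy_factor(rimg, rmu, v, m = 2)
  for (i in 1:4) for (j in 1:5) for (k in 1:2)
    expect_equal(B[i, j, k], brute_fuzzy_factor_at(rimg, rmu, v, 2, i, j, k),
                 tolerance = 1e-12)
})

test_that("membership update reproduces hand-computed values and normalizes", {
  # x = 0, centers (-1, 3), B = 0, m = 2 -> mu = (0.9, 0.1)
  mu <- update_membership(matrix(0, 1, 1), c(-1, 3), NULL, m = 2)
  expect_equal(as.vector(mu), c(0.9, 0.1))
  # exact center hit with zero local penalty -> crisp membership
  mu2 <- update_membership(matrix(5, 1, 1), c(5, 9), NULL, m = 2)
  expect_equal(as.vector(mu2), c(1, 0))
  # normalization property on random inputs
  set.seed(7)
  img <- matrix(runif(64, 0, 255), 8, 8)
  B <- array(runif(64 * 3, 0, 100), c(8, 8, 3))
  mu3 <- update_membership(img, c(50, 120, 200), B, m = 2)
  expect_true(all(mu3 >= 0 & mu3 <= 1))
  expect_equal(apply(mu3, c(1, 2), sum), matrix(1, 8, 8), tolerance = 1e-10)
})

test_that("center update is the mu^m-weighted mean with hand-checked value", {
  img <- matrix(c(0, 1), 1, 2)
  mu <- array(c(0.9, 0.5, 0.1, 0.5), c(1, 2, 2))
  v <- update_centers(img, mu, m = 2)
  expect_equal(v[1], (0.81 * 0 + 0.25 * 1) / (0.81 + 0.25), tolerance = 1e-12)
  # crisp memberships give the arithmetic class mean
  imgc <- matrix(c(2, 4, 10, 14), 2, 2)
  muc <- array(0, c(2, 2, 2)); muc[, 1, 1] <- 1; muc[, 2, 2] <- 1
  expect_equal(as.numeric(update_centers(imgc, muc, 2)), c(3, 12))
  # centers always inside the intensity hull
  set.seed(8)
  ri <- matrix(runif(36, 0, 255), 6, 6)
  rmu <- array(runif(72), c(6, 6, 2))
  rmu <- rmu / rep(apply(rmu, c(1, 2), sum), times = 2)
  rv <- update_centers(ri, rmu, 2)
  expect_true(all(rv >= min(ri) & rv <= max(ri)))
})

test_that("objective matches a brute-force double sum and is nonnegative", {
  set.seed(9)
  img <- matrix(runif(16, 0, 255), 4, 4)
  v <- c(60, 180)
  mu <- update_membership(img, v, NULL, 2)
  flat <- matrix(mu, 16, 2)
  expect_equal(flicm_objective(img, mu, v, NULL, 2),
               brute_fcm_objective(img, flat, v, 2), tolerance = 1e-8)
  expect_gte(flicm_objective(img, mu, v, NULL, 2), 0)
  # perfect crisp fit scores exactly zero
  imgp <- matrix(c(10, 10, 90, 90), 2, 2)
  mup <- array(0, c(2, 2, 2)); mup[, 1, 1] <- 1; mup[, 2, 2] <- 1
  expect_equal(flicm_objective(imgp, mup, c(10, 90), NULL, 2), 0)
})

test_that("the FCM reduction matches the brute-force oracle", {
  set.seed(10)
  img <- matrix(runif(36, 0, 255), 6, 6)
  v0 <- init_centers(img, 2)
  fit <- flicm(img, K = 2, tol = 1e-300, max_iter = 20, local = FALSE,
               centers = v0)
  oracle <- brute_fcm(img, 2, v0, m = 2, iters = 20)
  expect_lt(max(abs(matrix(fit$membership, 36, 2) - oracle$mu)), 1e-8)
  expect_equal(fit$centers, oracle$centers, tolerance = 1e-8)
})

test_that("the FCM objective trace is non-increasing", {
  set.seed(11)
  img <- matrix(runif(144, 0, 255), 12, 12)
  fit <- flicm(img, K = 3, local = FALSE, max_iter = 60)
  expect_true(all(diff(fit$trace$objective) <= 1e-8))
})

test_that("a separable two-valued image is segmented exactly by both variants", {
  img <- matrix(0, 16, 16); img[, 9:16] <- 255
  for (loc in c(TRUE, FALSE)) {
    fit <- flicm(img, K = 2, local = loc)
    expect_identical(fit$labels, matrix(as.integer(img == 255), 16, 16))
  }
})

test_that("fits are deterministic for fixed input and configuration", {
  ph <- generate_phantom(phantom_spec(48, 48, geometry_seed = 6))
  noisy <- add_noise(ph$image, noise_spec("gaussian", 10, 2))
  f1 <- flicm(noisy, K = 5, max_iter = 30)
  f2 <- flicm(noisy, K = 5, max_iter = 30)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$labels, f2$labels)
})

test_that("FLICM errors on a noiseless phantom stay confined to class boundaries", {
  # interior pixels (2+ px from any class boundary) are always recovered;
  # the local term only disputes the 1-2 px interface band
  ph <- generate_phantom(phantom_spec(96, 96, geometry_seed = 12))
  fit <- flicm(ph$image, K = 5)
  matched <- match_labels(fit$labels, ph$labels)
  err <- matched != ph$labels
  interior <- matrix(TRUE, 96, 96)
  for (k in 0:4) {
    m <- ph$labels == k
    d <- as.matrix(EBImage::distmap(matrix(as.numeric(m), 96, 96)))
    interior[m & d <= 2] <- FALSE
  }
  expect_true(all(!err[interior]))
})

test_that("label matching recovers permutations and beats all alternatives", {
  truth <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  expect_identical(match_labels(truth, truth)[, ], truth)
  swapped <- matrix(c(1L, 0L, 2L)[truth + 1], 8, 8)
  m <- match_labels(swapped, truth)
  expect_identical(m[, ], truth)
  # optimality against exhaustive enumeration on a random pair
  set.seed(13)
  pred <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  best <- match_labels(pred, truth)
  score <- function(p) sum(matrix(p[pred + 1], 8, 8) == truth)
  perms <- list(c(0,1,2), c(0,2,1), c(1,0,2), c(1,2,0), c(2,0,1), c(2,1,0))
  expect_equal(sum(best[, ] == truth), max(vapply(perms, score, numeric(1))))
})
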