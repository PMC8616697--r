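test_that("a 3x3 solid square traces to its 8 border pixels, counterclockwise", {
  lab <- matrix(0L, 5, 5); lab[2:4, 2:4] <- 1L
  ct <- trace_boundary(lab, 1L)
  pts <- unclass(ct)
  expect_identical(nrow(pts), 8L)
  # every border pixel visited once, centre excluded
  expect_false(any(pts[, 1] == 2 & pts[, 2] == 2))
  expect_identical(anyDuplicated(pts), 0L)
  xs <- pts[, 1]; ys <- pts[, 2]
  area <- 0.5 * sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
  expect_gt(area, 0)
})

test_that("a single-row region traverses out and back as a closed 8-point path", {
  lab <- matrix(0L, 3, 7); lab[2, 2:6] <- 1L
  ct <- trace_boundary(lab, 1L)
  pts <- unclass(ct)
  expect_identical(nrow(pts), 8L)
  expect_true(all(pts[, 2] == 1))                  # stays on its row (0-based)
  expect_setequal(unique(pts[, 1]), 1:5)
  # consecutive points (and the closure) are 8-connected
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  expect_true(all(pmax(abs(nxt[, 1] - pts[, 1]), abs(nxt[, 2] - pts[, 2])) == 1))
})

test_that("largest component is traced and the count reported", {
  lab <- matrix(0L, 10, 10)
  lab[2:6, 2:6] <- 1L
  lab[9, 9] <- 1L
  ct <- trace_boundary(lab, 1L)
  expect_identical(attr(ct, "n_components"), 2L)
  expect_true(all(unclass(ct)[, 1] <= 6))
  expect_error(trace_boundary(lab, 7L), "empty region")
})

test_that("descriptors match the O(N^2) direct transform and Parseval holds", {
  set.seed(14)
  th <- sort(runif(16, 0, 2 * pi))
  pts <- cbind(round(10 + 6 * cos(th)), round(10 + 6 * sin(th)))
  d <- fourier_descriptor(pts)
  s <- complex(real = pts[, 1], imaginary = pts[, 2])
  expect_lt(max(Mod(d$coeffs - brute_dft(s))), 1e-10)
  expect_equal(d$coeffs[1], mean(s), tolerance = 1e-12)
  expect_lt(abs(sum(Mod(s)^2) / 16 - sum(Mod(d$coeffs)^2)), 1e-8)
})

test_that("translation moves only the zeroth coefficient", {
  set.seed(15)
  pts <- cbind(sample(0:20, 12), sample(0:20, 12))
  d0 <- fourier_descriptor(pts)
  d1 <- fourier_descriptor(pts + matrix(c(3, -5), 12, 2, byrow = TRUE))
  expect_equal(d1$coeffs[1] - d0$coeffs[1], 3 - 5i, tolerance = 1e-12)
  expect_lt(max(Mod(d1$coeffs[-1] - d0$coeffs[-1])), 1e-10)
})

test_that("normalized descriptors are similarity-invariant and idempotent", {
  lab <- matrix(0L, 40, 40); lab[10:28, 14:25] <- 1L; lab[15:20, 5:33] <- 1L
  ct <- unclass(trace_boundary(lab, 1L))
  d <- fourier_descriptor(ct)
  nd <- normalize_descriptor(d)
  expect_equal(nd$coeffs[1], 1)
  expect_equal(normalize_descriptor(nd)$coeffs, nd$coeffs, tolerance = 1e-14)
  # scaling the same point sequence by 2
  d2 <- fourier_descriptor(ct * 2)
  expect_lt(max(abs(normalize_descriptor(d2)$coeffs - nd$coeffs)), 1e-10)
  # rotating 90 degrees: (x, y) -> (-y, x)
  d3 <- fourier_descriptor(cbind(-ct[, 2], ct[, 1]))
  expect_lt(max(abs(normalize_descriptor(d3)$coeffs - nd$coeffs)), 1e-10)
})

test_that("descriptor distance is a symmetric pseudo-metric on shapes", {
  sq <- matrix(0L, 20, 20); sq[5:15, 5:15] <- 1L
  ds <- fourier_descriptor(trace_boundary(sq, 1L))
  ring <- matrix(0L, 30, 30); ring[disk_mask(30, 15, 15, 9)] <- 1L
  dr <- fourier_descriptor(trace_boundary(ring, 1L))
  expect_equal(descriptor_distance(ds, dr), descriptor_distance(dr, ds),
               tolerance = 1e-12)
  expect_equal(descriptor_distance(ds, ds), 0)
  expect_gt(descriptor_distance(ds, dr), 0)
})

test_that("the phantom H region matches the template across scales", {
  tpl <- h_template()
  for (size in c(128, 256)) {
    ph <- generate_phantom(phantom_spec(size, size, geometry_seed = 16))
    d <- fourier_descriptor(trace_boundary(ph$labels, 4L))
    expect_lt(descriptor_distance(d, tpl), 0.25)
  }
})

test_that("the H component is preferred over a disk decoy", {
  ph <- generate_phantom(phantom_spec(128, 128, geometry_seed = 17))
  lab <- ph$labels
  decoy <- disk_mask(128, 64, 36, 4) & lab == 2L
  lab[decoy] <- 4L
  hm <- match_h_region(lab, 4L, min_size = 20)
  expect_true(hm$matched)
  expect_equal(jaccard(hm$mask, ph$labels == 4L), 1)
  # the decoy alone scores worse than the H alone
  only_h <- fourier_descriptor(trace_boundary(ph$labels, 4L))
  lab_d <- matrix(0L, 128, 128); lab_d[decoy] <- 1L
  only_d <- fourier_descriptor(trace_boundary(lab_d, 1L))
  tpl <- h_template()
  expect_gt(descriptor_distance(only_d, tpl), descriptor_distance(only_h, tpl))
})

test_that("self-match returns the exact mask at distance zero", {
  ph <- generate_phantom(phantom_spec(96, 96, geometry_seed = 18))
  tpl <- normalize_descriptor(fourier_descriptor(trace_boundary(ph$labels, 4L)))
  hm <- match_h_region(ph$labels, 4L, template = tpl)
  expect_true(hm$matched)
  expect_lt(hm$distance, 1e-10)
  expect_equal(hm$mask, ph$labels == 4L)
  expect_error(match_h_region(ph$labels, 9L), "no CSF pixels")
})
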