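#' Discretized 1-D Gaussian kernel
#'
#' Samples the Gaussian at integer offsets -radius..radius and normalizes to
#' unit sum, so smoothing preserves constants exactly. The separable 2-D
#' Gaussian is the outer product of this kernel with itself; the arbitrary
#' amplitude constant of the analytic filter cancels under normalization.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param radius Half-width; default `ceiling(3 * sigma)`.
#' @return Object of class `"gaussian_kernel"`: `sigma`, `radius`, `weights`.
#' @export
gaussian_kernel <- function(sigma, radius = NULL) {
  if (sigma <= 0) stop("invalid spec: sigma must be positive")
  if (is.null(radius)) radius <- ceiling(3 * sigma)
  x <- -radius:radius
  w <- exp(-x^2 / (2 * sigma^2))
  structure(list(sigma = sigma, radius = as.integer(radius),
                 weights = w / sum(w)),
            class = "gaussian_kernel")
}

# 1-D convolution along rows then columns with symmetric (reflective) borders.
.conv_sep <- function(m, w) {
  r <- (length(w) - 1L) / 2L
  conv_cols <- function(m) {                       # filter along dim 1
    H <- nrow(m)
    pad <- rbind(m[r:1, , drop = FALSE], m, m[H:(H - r + 1), , drop = FALSE])
    out <- 0
    for (k in seq_along(w)) out <- out + w[k] * pad[(k - 1) + seq_len(H), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Gaussian smoothing by separable convolution
#'
#' Convolves the image with the discretized unit-sum Gaussian in each axis
#' (the separable decomposition of the 2-D filter), with reflective border
#' handling.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Smoothed image, same shape.
#' @export
gaussian_smooth <- function(image, sigma) {
  k <- gaussian_kernel(sigma)
  if (min(dim(image)) <= k$radius)           # shrink support for tiny images
    k <- gaussian_kernel(sigma, radius = max(1L, min(dim(image)) - 1L))
  .conv_sep(image, k$weights)
}

#' Discrete image gradients, magnitude and direction
#'
#' Forward-averaged 2x2 difference stencils:
#' \deqn{E_x(i,j) = [I(i,j+1) - I(i,j) + I(i+1,j+1) - I(i+1,j)]/2,}
#' \deqn{E_y(i,j) = [I(i,j) - I(i+1,j) + I(i,j+1) - I(i+1,j+1)]/2,}
#' evaluated on the (H-1) x (W-1) grid and assigned to the top-left pixel of
#' each 2x2 block. x increases with column, y with decreasing row (so E_y is
#' positive where intensity grows upwards). Magnitude is
#' \eqn{\sqrt{E_x^2 + E_y^2}} and direction the full-quadrant
#' \eqn{\mathrm{atan2}(E_y, E_x)} in (-pi, pi].
#'
#' @param image Numeric matrix, at least 2 x 2.
#' @return Object of class `"gradient_field"`: `ex`, `ey`, `magnitude`,
#'   `direction` ((H-1) x (W-1) matrices).
#' @export
image_gradients <- function(image) {
  H <- nrow(image); W <- ncol(image)
  if (H < 2 || W < 2) stop("contract error: image must be at least 2 x 2")
  A <- image[1:(H - 1), 1:(W - 1), drop = FALSE]
  Bm <- image[1:(H - 1), 2:W, drop = FALSE]
  Cm <- image[2:H, 1:(W - 1), drop = FALSE]
  Dm <- image[2:H, 2:W, drop = FALSE]
  ex <- (Bm - A + Dm - Cm) / 2
  ey <- (A - Cm + Bm - Dm) / 2
  structure(list(ex = ex, ey = ey,
                 magnitude = sqrt(ex^2 + ey^2),
                 direction = atan2(ey, ex)),
            class = "gradient_field")
}

# Non-maximum suppression: keep pixels whose magnitude is not exceeded along
# the quantized gradient direction (4 direction bins, 8 neighbours).
.nms <- function(mag, dir) {
  ang <- dir %% pi
  bin <- round(ang / (pi / 4)) %% 4              # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  nb <- function(dr, dc) { s <- .shift_mat(mag, dr, dc); s[is.na(s)] <- 0; s }
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  pairs <- list(`0` = list(c(0, 1), c(0, -1)),
                `1` = list(c(-1, 1), c(1, -1)),
                `2` = list(c(-1, 0), c(1, 0)),
                `3` = list(c(-1, -1), c(1, 1)))
  for (b in 0:3) {
    p <- pairs[[as.character(b)]]
    n1 <- nb(p[[1]][1], p[[1]][2]); n2 <- nb(p[[2]][1], p[[2]][2])
    keep <- keep | (bin == b & mag >= n1 & mag >= n2)
  }
  keep & mag > 0
}

# Hysteresis: retain weak candidate pixels 8-connected to a strong pixel.
.hysteresis <- function(cand, strong) {
  if (!any(strong)) return(strong)
  H <- nrow(cand); W <- ncol(cand)
  visited <- strong
  frontier <- which(strong)
  off <- .nbhd_offsets()
  while (length(frontier)) {
    r0 <- (frontier - 1L) %% H + 1L
    c0 <- (frontier - 1L) %/% H + 1L
    nxt <- integer(0)
    for (k in seq_len(nrow(off))) {
      r <- r0 + off$dr[k]; c <- c0 + off$dc[k]
      ok <- r >= 1L & r <= H & c >= 1L & c <= W
      idx <- (c[ok] - 1L) * H + r[ok]
      idx <- idx[cand[idx] & !visited[idx]]
      if (length(idx)) { visited[idx] <- TRUE; nxt <- c(nxt, idx) }
    }
    frontier <- unique(nxt)
  }
  visited
}

#' Canny edge detection
#'
#' Gaussian smoothing, the 2x2 gradient stencils of [image_gradients()],
#' non-maximum suppression along the quantized gradient direction, and
#' double-threshold hysteresis (pixels at or above `high` seed the edge set;
#' pixels at or above `low` are kept when 8-connected to a seed). Thresholds
#' are fractions of the maximum gradient magnitude when `relative = TRUE`
#' (the default), which makes the detector invariant to adding a constant to
#' the image.
#'
#' @param image Numeric matrix.
#' @param sigma Smoothing scale in pixels (default 1.4).
#' @param low,high Hysteresis thresholds, `high >= low >= 0`; interpreted as
#'   fractions of the maximum magnitude unless `relative = FALSE`. Defaults
#'   0.1 and 0.2.
#' @param relative Treat `low`/`high` as fractions of the maximum gradient
#'   magnitude.
#' @return Object of class `"edge_map"`: `edges` (logical matrix, same shape
#'   as the image; the gradient grid is anchored at top-left pixels),
#'   `low_thresh`, `high_thresh`, `magnitude`.
#' @export
canny <- function(image, sigma = 1.4, low = 0.1, high = 0.2, relative = TRUE) {
  if (low < 0 || high < low) stop("contract error: need high >= low >= 0")
  sm <- gaussian_smooth(image, sigma)
  g <- image_gradients(sm)
  mmax <- max(g$magnitude)
  lo <- if (relative) low * mmax else low
  hi <- if (relative) high * mmax else high
  keep <- .nms(g$magnitude, g$direction)
  strong <- keep & g$magnitude >= hi & g$magnitude > 0
  cand <- keep & g$magnitude >= lo & g$magnitude > 0
  sel <- .hysteresis(cand, strong)
  edges <- matrix(FALSE, nrow(image), ncol(image))
  edges[seq_len(nrow(sel)), seq_len(ncol(sel))] <- sel
  structure(list(edges = edges, low_thresh = lo, high_thresh = hi,
                 magnitude = g$magnitude),
            class = "edge_map")
}

#' Filter-design quality functionals of an edge-detection kernel
#'
#' Evaluates, by trapezoidal quadrature on the sampled grid, the classical
#' design criteria of a 1-D edge filter H with finite support: the edge
#' response \eqn{F_G = \int G(-x) H(x) dx} against an edge profile G, the
#' noise response \eqn{F_Z = \sigma \sqrt{\int H^2}}, the localization
#' \eqn{D = |\int G'(-x) H'(x) dx| / (\sigma \sqrt{\int H'^2})}, and the mean
#' zero-crossing spacing of the response derivative
#' \eqn{S(f) = \pi \sqrt{\int H'^2 / \int H''^2}}. These are diagnostics of a
#' supplied kernel, not an optimization target.
#'
#' @param kernel Samples of the impulse response H on a symmetric grid.
#' @param noise_sigma Noise standard deviation (scales F_Z, and inversely D).
#' @param edge_profile Samples of the edge function G on the same grid;
#'   defaults to a unit step centered on the grid.
#' @param dx Grid spacing (default 1).
#' @return Object of class `"filter_diagnostics"`: `edge_response`,
#'   `noise_response`, `localization`, `zero_crossing_spacing`.
#' @export
filter_diagnostics <- function(kernel, noise_sigma = 1, edge_profile = NULL,
                               dx = 1) {
  kernel <- as.numeric(kernel)
  if (all(kernel == 0)) stop("contract error: zero-energy kernel")
  n <- length(kernel)
  x <- (seq_len(n) - (n + 1) / 2) * dx
  if (is.null(edge_profile)) edge_profile <- as.numeric(x >= 0)
  if (length(edge_profile) != n)
    stop("contract error: edge_profile must be sampled on the kernel grid")
  Gm <- rev(edge_profile)                               # G(-x)
  H1 <- pracma::gradient(kernel, dx)
  H2 <- pracma::gradient(H1, dx)
  Gp_rev <- rev(pracma::gradient(edge_profile, dx))     # G'(-x)
  structure(list(
    edge_response = pracma::trapz(x, Gm * kernel),
    noise_response = noise_sigma * sqrt(pracma::trapz(x, kernel^2)),
    localization = abs(pracma::trapz(x, Gp_rev * H1)) /
      (noise_sigma * sqrt(pracma::trapz(x, H1^2))),
    zero_crossing_spacing = pi * sqrt(pracma::trapz(x, H1^2) /
                                        pracma::trapz(x, H2^2))),
    class = "filter_diagnostics")
}
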