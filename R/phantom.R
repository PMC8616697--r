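#' Specification for a synthetic brain phantom
#'
#' Describes a 2-D T1-like brain slice built from piecewise-constant tissue
#' classes: background, a bright skull ring, white matter (WM), gray matter
#' (GM) and, optionally, a central H-shaped cerebrospinal-fluid (CSF) region.
#' The phantom stands in for patient MRI slices in all experiments and carries
#' exact ground-truth labels.
#'
#' @param height,width Image dimensions in pixels; both must be >= 32.
#' @param class_means Intensities of the five classes on the 0-255 scale, in
#'   the order background, skull, white matter, gray matter, CSF. Must be
#'   pairwise distinct and within \[0, 255\]. The defaults follow the T1
#'   ordering (WM bright, CSF dark) with a minimum separation of 30 units so
#'   that noiseless phantoms are exactly separable by intensity.
#' @param geometry_seed Integer seed driving the procedural geometry (head
#'   ellipse axes jittered by +/-10 percent), so replicate experiments get
#'   distinct but reproducible anatomies.
#' @param include_h_region Render the central H-shaped CSF region.
#' @param skull_thickness Thickness of the skull ring in pixels.
#' @return An object of class `"phantom_spec"`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         class_means = c(background = 0, skull = 230,
                                         white_matter = 190, gray_matter = 125,
                                         csf = 60),
                         geometry_seed = 1L,
                         include_h_region = TRUE,
                         skull_thickness = 3L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 32L || width < 32L)
    stop("invalid phantom spec: height and width must be at least 32 pixels")
  class_means <- as.numeric(class_means)
  if (length(class_means) != 5L)
    stop("invalid phantom spec: class_means must have 5 entries (background, skull, WM, GM, CSF)")
  if (any(class_means < 0) || any(class_means > 255))
    stop("invalid phantom spec: class_means must lie in [0, 255]")
  if (anyDuplicated(class_means))
    stop("invalid phantom spec: class_means must be pairwise distinct")
  if (skull_thickness < 0)
    stop("invalid phantom spec: skull_thickness must be nonnegative")
  structure(list(height = height, width = width, class_means = class_means,
                 geometry_seed = as.integer(geometry_seed),
                 include_h_region = isTRUE(include_h_region),
                 skull_thickness = as.integer(skull_thickness)),
            class = "phantom_spec")
}

#' Specification for calibrated image noise
#'
#' @param kind `"gaussian"` (additive, zero-mean) or `"salt_pepper"`
#'   (impulse corruption).
#' @param level For gaussian noise, the standard deviation in intensity units
#'   on the 0-255 scale; for salt-and-pepper, the corruption density in
#'   \[0, 1\].
#' @param seed Integer seed; [add_noise()] is a pure function of
#'   (image, kind, level, seed).
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("gaussian", "salt_pepper"), level, seed = 1L) {
  kind <- match.arg(kind)
  level <- as.numeric(level)
  if (length(level) != 1L || is.na(level) || level < 0)
    stop("invalid noise spec: level must be a single nonnegative number")
  if (kind == "salt_pepper" && level > 1)
    stop("invalid noise spec: salt_pepper density must not exceed 1")
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

# Run code under a temporary RNG state so generators never disturb the
# caller's random stream.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rasterize the central letter-H mask used for the CSF region; proportions are
# shared between the phantom and the matching template so descriptor distances
# compare like with like.
.h_mask <- function(height, width, cy = (height + 1) / 2, cx = (width + 1) / 2,
                    scale = 1) {
  bar_w <- max(3L, round(0.09 * width * scale))
  bar_h <- max(7L, round(0.38 * height * scale))
  sep   <- max(4L, round(0.16 * width * scale))
  rows <- max(1L, round(cy - bar_h / 2)):min(height, round(cy + bar_h / 2))
  lcols <- max(1L, round(cx - sep / 2 - bar_w)):round(cx - sep / 2)
  rcols <- round(cx + sep / 2):min(width, round(cx + sep / 2 + bar_w))
  crows <- max(1L, round(cy - bar_w / 2)):min(height, round(cy + bar_w / 2))
  ccols <- round(cx - sep / 2):round(cx + sep / 2)
  m <- matrix(FALSE, height, width)
  m[rows, lcols] <- TRUE
  m[rows, rcols] <- TRUE
  m[crows, ccols] <- TRUE
  m
}

.ellipse_mask <- function(height, width, cy, cx, a, b) {
  X <- matrix(seq_len(width), height, width, byrow = TRUE)
  Y <- matrix(seq_len(height), height, width)
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
}

#' Generate a synthetic brain phantom with ground-truth labels
#'
#' Draws an elliptical head with a bright skull ring, a gray-matter mantle, a
#' white-matter core and (optionally) a central H-shaped CSF region, and
#' renders the piecewise-constant image at the spec's class means. Labels are
#' integers 0-4 in the order background, skull, WM, GM, CSF. Deterministic for
#' a fixed `geometry_seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `image` (numeric matrix, 0-255), `labels`
#'   (integer matrix, values 0-4), `class_names`, `class_means` and
#'   `peak` (255).
#' @examples
#' ph <- generate_phantom(phantom_spec(64, 64, geometry_seed = 7))
#' table(ph$labels)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, as.list(spec))
  H <- spec$height; W <- spec$width; t <- spec$skull_thickness
  jit <- .with_seed(spec$geometry_seed, stats::runif(2, -0.1, 0.1))
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  # base axes leave a background margin even at the +10% jitter extreme,
  # so the head (and its skull ring) is always fully inside the frame
  a <- 0.40 * W * (1 + jit[1])
  b <- 0.42 * H * (1 + jit[2])
  head  <- .ellipse_mask(H, W, cy, cx, a, b)
  inner <- .ellipse_mask(H, W, cy, cx, a - t, b - t)
  wm    <- .ellipse_mask(H, W, cy, cx, 0.70 * (a - t), 0.70 * (b - t))
  labels <- matrix(0L, H, W)
  labels[head & !inner] <- 1L
  labels[inner & !wm]   <- 3L
  labels[wm]            <- 2L
  if (spec$include_h_region)
    labels[.h_mask(H, W, cy, cx) & wm] <- 4L
  image <- matrix(spec$class_means[labels + 1L], H, W)
  list(image = image, labels = labels,
       class_names = c("background", "skull", "white_matter", "gray_matter", "csf"),
       class_means = spec$class_means, peak = 255)
}

#' Inject calibrated noise into an image
#'
#' Gaussian noise adds independent N(0, level^2) per pixel and clips to
#' \[0, peak\]; salt-and-pepper replaces a fraction `level` of pixels by 0 or
#' `peak` with equal probability. Seeded and reproducible: the same inputs
#' always give bit-identical output, and the caller's RNG stream is untouched.
#'
#' @param image Numeric matrix of intensities.
#' @param noise A [noise_spec()].
#' @param peak Maximum representable intensity (clipping bound and impulse
#'   value), default 255.
#' @return Noisy image, same shape as the input.
#' @export
add_noise <- function(image, noise, peak = 255) {
  stopifnot(is.matrix(image), inherits(noise, "noise_spec"))
  n <- length(image)
  .with_seed(noise$seed, {
    if (noise$kind == "gaussian") {
      out <- image + stats::rnorm(n, mean = 0, sd = noise$level)
      out[out < 0] <- 0; out[out > peak] <- peak
    } else {
      out <- image
      k <- round(noise$level * n)
      if (k > 0) {
        idx <- sample.int(n, k)
        out[idx] <- sample(c(0, peak), k, replace = TRUE)
      }
    }
    matrix(out, nrow(image), ncol(image))
  })
}
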