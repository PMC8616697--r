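# Moore-neighbour boundary tracing with Jacob's stopping criterion.
# Returns the ordered boundary pixels of a binary mask as (row, col) pairs;
# thin (1-pixel) structures are traversed out and back, as the algorithm
# visits each boundary pixel once per side.
.moore_trace <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  M <- matrix(FALSE, H + 2L, W + 2L)
  M[2:(H + 1L), 2:(W + 1L)] <- mask
  idx <- which(M)
  if (!length(idx)) stop("empty region: nothing to trace")
  r0 <- (idx - 1L) %% (H + 2L) + 1L
  c0 <- (idx - 1L) %/% (H + 2L) + 1L
  first <- order(r0, c0)[1L]
  start <- c(r0[first], c0[first])
  # clockwise neighbour order starting west (row axis points down)
  offs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  p <- start
  b <- start + offs[1L, ]            # backtrack: the west neighbour (background)
  pts <- matrix(start, 1L, 2L)
  # Jacob's criterion: stop when a (pixel, backtrack) state recurs — for
  # solid blobs that is the start state; thin out-and-back paths recur at
  # the first step after revisiting the start
  seen <- new.env(parent = emptyenv())
  assign(paste(c(p, b), collapse = ","), TRUE, envir = seen)
  maxit <- 8L * (sum(M) + 2L)
  for (step in seq_len(maxit)) {
    rel <- b - p
    k0 <- which(offs[, 1] == rel[1] & offs[, 2] == rel[2])
    found <- FALSE
    prev <- b
    for (k in seq_len(8L)) {
      kk <- ((k0 + k - 1L) %% 8L) + 1L
      q <- p + offs[kk, ]
      if (M[q[1], q[2]]) {
        b <- prev
        p <- q
        found <- TRUE
        break
      }
      prev <- q
    }
    if (!found) break                # isolated pixel
    key <- paste(c(p, b), collapse = ",")
    if (exists(key, envir = seen, inherits = FALSE)) break
    assign(key, TRUE, envir = seen)
    pts <- rbind(pts, p)
  }
  n <- nrow(pts)
  if (n > 1L && all(pts[n, ] == pts[1L, ]))   # drop a duplicated closure point
    pts <- pts[-n, , drop = FALSE]
  pts - 1L                           # undo padding -> 1-based mask coordinates
}

#' Trace the closed boundary of a labeled region
#'
#' Moore-neighbour tracing of the largest connected component of the given
#' class, returned as an ordered closed sequence of (x, y) = (column, row)
#' coordinates, 0-based, with counterclockwise orientation enforced (the
#' sequence is reversed when its signed area is negative).
#'
#' @param labels Integer label matrix.
#' @param class_id Label value of the region to trace.
#' @return Object of class `"contour"`: an N x 2 matrix with columns `x`, `y`;
#'   the number of connected components found is attached as attribute
#'   `"n_components"`.
#' @export
trace_boundary <- function(labels, class_id) {
  mask <- labels == class_id
  if (!any(mask)) stop("empty region: class not present in label map")
  comp <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  comp <- as.matrix(comp)
  ncomp <- max(comp)
  if (ncomp > 1L) {
    sizes <- tabulate(comp[comp > 0], nbins = ncomp)
    mask <- comp == which.max(sizes)
  }
  rc <- .moore_trace(mask)
  pts <- cbind(x = rc[, 2] - 1L, y = rc[, 1] - 1L)   # 0-based (col, row)
  n <- nrow(pts)
  if (n >= 3L) {
    xs <- pts[, 1]; ys <- pts[, 2]
    x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
    area <- 0.5 * sum(xs * y2 - x2 * ys)
    if (area < 0) pts <- pts[c(1L, n:2L), , drop = FALSE]
  }
  structure(pts, class = "contour", n_components = ncomp)
}

#' Complex Fourier descriptor of a closed contour
#'
#' Encodes each boundary point as the complex number s(k) = x(k) + j y(k) and
#' takes the discrete Fourier transform
#' \deqn{\lambda(u) = \frac{1}{N} \sum_{k=0}^{N-1} s(k) e^{-j 2\pi u k / N}.}
#' The zeroth coefficient is the contour centroid; translation changes only
#' \eqn{\lambda(0)}, and rotation or a shifted starting point change only the
#' coefficient phases, which is what the normalization exploits.
#'
#' @param contour An N x 2 matrix of (x, y) coordinates (a `"contour"`).
#' @return Object of class `"fourier_desc"`: `coeffs` (complex, length N),
#'   `n`, `normalized = FALSE`.
#' @export
fourier_descriptor <- function(contour) {
  pts <- unclass(contour)
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 1)
  s <- complex(real = pts[, 1], imaginary = pts[, 2])
  structure(list(coeffs = stats::fft(s) / length(s), n = length(s),
                 normalized = FALSE),
            class = "fourier_desc")
}

#' Similarity-invariant normalization of a Fourier descriptor
#'
#' Drops \eqn{\lambda(0)} (translation), divides by \eqn{|\lambda(1)|}
#' (scale) and keeps coefficient magnitudes only (rotation and starting-point
#' phase). Idempotent.
#'
#' @param d A `"fourier_desc"`.
#' @return A `"fourier_desc"` whose `coeffs` are the normalized real
#'   magnitudes of harmonics u = 1..N-1 (first entry exactly 1).
#' @export
normalize_descriptor <- function(d) {
  stopifnot(inherits(d, "fourier_desc"))
  mags <- if (d$normalized) as.numeric(d$coeffs) else Mod(d$coeffs[-1])
  if (length(mags) == 0 || mags[1] == 0)
    stop("degenerate shape: |lambda(1)| is zero")
  structure(list(coeffs = mags / mags[1], n = d$n, normalized = TRUE),
            class = "fourier_desc")
}

#' Euclidean distance between truncated normalized descriptors
#'
#' Normalizes both descriptors, truncates (or zero-pads) to the first
#' `harmonics` magnitudes and returns the Euclidean distance. Low-order
#' harmonics carry the gross shape, so a short truncation compares overall
#' form while ignoring boundary pixelation.
#'
#' @param d1,d2 `"fourier_desc"` objects.
#' @param harmonics Number of leading harmonics compared (default 16).
#' @return Nonnegative distance; 0 iff the truncated normalized descriptors
#'   coincide. Symmetric in its arguments.
#' @export
descriptor_distance <- function(d1, d2, harmonics = 16) {
  v1 <- normalize_descriptor(d1)$coeffs
  v2 <- normalize_descriptor(d2)$coeffs
  pad <- function(v) { length(v) <- harmonics; v[is.na(v)] <- 0; v }
  sqrt(sum((pad(v1) - pad(v2))^2))
}

#' Reference descriptor of the H-shaped CSF region
#'
#' Builds the normalized Fourier descriptor of an ideal letter-H region
#' rendered with the same proportions the phantom uses, for use as the
#' matching template in [match_h_region()].
#'
#' @param size Canvas side length in pixels (default 64).
#' @return A normalized `"fourier_desc"`.
#' @export
h_template <- function(size = 64) {
  m <- .h_mask(size, size)
  lab <- matrix(0L, size, size); lab[m] <- 1L
  normalize_descriptor(fourier_descriptor(trace_boundary(lab, 1L)))
}

#' Identify the H-shaped region in the cerebrospinal-fluid class
#'
#' Traces every connected component of the CSF class, compares its truncated
#' normalized Fourier descriptor with the template, and returns the mask of
#' the best-matching component when its distance is within the acceptance
#' threshold. If no candidate passes, the threshold is relaxed in +5% steps
#' (at most `max_relax` iterations, the adjust-until-termination loop); when
#' even the relaxed threshold fails, an empty mask and the best distance are
#' returned.
#'
#' @param labels Integer label matrix.
#' @param csf_class Label value of the CSF class.
#' @param template Normalized descriptor of the target shape
#'   (default [h_template()]).
#' @param threshold Acceptance threshold on the descriptor distance
#'   (default 0.25).
#' @param harmonics Harmonics compared (default 16).
#' @param min_size Smallest component (pixels) considered a candidate.
#' @param max_relax Maximum threshold-relaxation iterations (default 10).
#' @return Object of class `"h_match"`: `mask` (logical matrix), `distance`
#'   (best candidate distance), `matched` (flag), `threshold_final`,
#'   `relax_iterations`, `n_candidates`.
#' @export
match_h_region <- function(labels, csf_class, template = h_template(),
                           threshold = 0.25, harmonics = 16,
                           min_size = 25, max_relax = 10) {
  stopifnot(inherits(template, "fourier_desc"))
  mask <- labels == csf_class
  if (!any(mask)) stop("empty region: no CSF pixels in label map")
  comp <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask),
                                            nrow(mask), ncol(mask))))
  ncomp <- max(comp)
  sizes <- tabulate(comp[comp > 0], nbins = ncomp)
  cand <- which(sizes >= min_size)
  if (!length(cand)) cand <- which.max(sizes)
  dist <- vapply(cand, function(ci) {
    sub <- matrix(0L, nrow(labels), ncol(labels)); sub[comp == ci] <- 1L
    d <- tryCatch(fourier_descriptor(trace_boundary(sub, 1L)),
                  error = function(e) NULL)
    if (is.null(d)) return(Inf)
    tryCatch(descriptor_distance(d, template, harmonics),
             error = function(e) Inf)
  }, numeric(1))
  best <- which.min(dist)
  th <- threshold; relax <- 0L
  while (dist[best] > th && relax < max_relax) { th <- th * 1.05; relax <- relax + 1L }
  matched <- dist[best] <= th
  out_mask <- matrix(FALSE, nrow(labels), ncol(labels))
  if (matched) out_mask[comp == cand[best]] <- TRUE
  structure(list(mask = out_mask, distance = dist[best], matched = matched,
                 threshold_final = th, relax_iterations = relax,
                 n_candidates = length(cand)),
            class = "h_match")
}
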