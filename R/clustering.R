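# Shifted copy of a matrix: entry (i, j) holds m[i + dr, j + dc], NA where the
# neighbour falls outside the image (truncated windows at borders).
.shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(NA_real_, H, W)
  ri <- seq_len(H) + dr; ci <- seq_len(W) + dc
  keep_r <- ri >= 1L & ri <= H; keep_c <- ci >= 1L & ci <= W
  out[keep_r, keep_c] <- m[ri[keep_r], ci[keep_c]]
  out
}

# The eight 3x3 neighbourhood offsets (centre excluded) with the spatial decay
# weight 1/(1 + c), c the Euclidean distance between pixel coordinates.
.nbhd_offsets <- function() {
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  off$w <- 1 / (1 + sqrt(off$dr^2 + off$dc^2))
  off
}

#' Initialize cluster centers from intensity quantiles
#'
#' Centers are placed at the K evenly spaced quantiles q = (j - 0.5)/K of the
#' image's intensity distribution, j = 1..K. This is deterministic for a fixed
#' image, which makes every downstream fit reproducible and lets the FCM and
#' FLICM variants share an identical initialization.
#'
#' @param image Numeric matrix of intensities.
#' @param K Number of clusters (>= 2).
#' @param seed Accepted for interface compatibility; the quantile rule is
#'   deterministic and ignores it.
#' @return Numeric vector of K initial centers, ascending.
#' @export
init_centers <- function(image, K, seed = NULL) {
  stopifnot(is.matrix(image), K >= 2)
  vals <- unique(as.vector(image))
  if (length(vals) < K)
    stop("degenerate input: fewer distinct intensities than clusters")
  probs <- (seq_len(K) - 0.5) / K
  v <- as.numeric(stats::quantile(image, probs = probs, type = 7, names = FALSE))
  # a heavily quantized histogram can collapse several quantiles onto one
  # value; fall back to quantiles of the distinct intensities so every
  # cluster starts from its own center
  if (anyDuplicated(v))
    v <- as.numeric(stats::quantile(sort(vals), probs = probs, type = 7,
                                    names = FALSE))
  v
}

#' Fuzzy local-information factor
#'
#' Computes, for every pixel i and cluster j, the spatially weighted penalty
#' \deqn{B_{ij} = \sum_{r \in N_i} \frac{1}{1 + c_{ir}} (1 - \mu_{rj})^m
#'   \lVert x_r - v_j \rVert^2,}
#' where the sum runs over the 3x3 window centered on i (center excluded,
#' truncated at image borders) and c_ir is the Euclidean distance between the
#' pixel coordinates of i and r. B_ij is large where the neighbours of i
#' disagree with cluster j, which is what makes the FLICM update resistant to
#' isolated noise pixels without any tuning parameter.
#'
#' @param image Numeric matrix of intensities.
#' @param mu Membership array of dimension (nrow, ncol, K), rows summing to 1.
#' @param centers Numeric vector of K cluster centers.
#' @param m Fuzzifier exponent (> 1); also applied to (1 - mu).
#' @return Array of dimension (nrow, ncol, K) with nonnegative entries.
#' @export
fuzzy_factor <- function(image, mu, centers, m = 2) {
  stopifnot(is.matrix(image), is.array(mu), length(dim(mu)) == 3L)
  if (!all(dim(mu)[1:2] == dim(image)))
    stop("contract error: membership and image shapes differ")
  K <- length(centers)
  if (dim(mu)[3] != K)
    stop("contract error: membership depth and number of centers differ")
  H <- nrow(image); W <- ncol(image)
  B <- array(0, dim = c(H, W, K))
  off <- .nbhd_offsets()
  for (r in seq_len(nrow(off))) {
    xs <- .shift_mat(image, off$dr[r], off$dc[r])
    for (j in seq_len(K)) {
      mus <- .shift_mat(mu[, , j], off$dr[r], off$dc[r])
      term <- off$w[r] * (1 - mus)^m * (xs - centers[j])^2
      term[is.na(term)] <- 0
      B[, , j] <- B[, , j] + term
    }
  }
  B
}

#' Membership update
#'
#' Applies the closed-form minimizer of the FLICM objective with centers held
#' fixed:
#' \deqn{\mu_{ij} = 1 / \sum_k \left[ (\lVert x_i - v_j \rVert^2 + B_{ij}) /
#'   (\lVert x_i - v_k \rVert^2 + B_{ik}) \right]^{1/(m-1)}.}
#' Pixels for which some denominator term vanishes (the pixel sits exactly on
#' a center with zero local penalty) receive crisp membership split equally
#' among the zero-distance clusters.
#'
#' @inheritParams fuzzy_factor
#' @param B Fuzzy-factor array as returned by [fuzzy_factor()], or `NULL` for
#'   the plain FCM update (B = 0).
#' @return Membership array (nrow, ncol, K); each pixel's memberships sum to 1.
#' @export
update_membership <- function(image, centers, B = NULL, m = 2) {
  stopifnot(is.matrix(image), m > 1)
  K <- length(centers)
  H <- nrow(image); W <- ncol(image)
  A <- array(0, dim = c(H, W, K))
  for (j in seq_len(K)) {
    A[, , j] <- (image - centers[j])^2
    if (!is.null(B)) A[, , j] <- A[, , j] + B[, , j]
  }
  p <- 1 / (m - 1)
  n <- H * W
  Aflat <- matrix(A, n, K)
  Wt <- Aflat^(-p)                  # Inf where A == 0
  mu <- Wt / rowSums(Wt)
  zero <- Aflat == 0
  nz <- rowSums(zero)
  sel <- nz > 0
  if (any(sel)) mu[sel, ] <- zero[sel, , drop = FALSE] / nz[sel]
  array(mu, dim = c(H, W, K))
}

#' Center update
#'
#' Weighted mean of the intensities with weights \eqn{\mu_{ij}^m}:
#' \deqn{v_j = \sum_i \mu_{ij}^m x_i / \sum_i \mu_{ij}^m.}
#' A cluster with zero total weight keeps its previous center and the event is
#' reported via the `"empty"` attribute.
#'
#' @inheritParams fuzzy_factor
#' @param centers Previous centers, used as fallback for empty clusters.
#' @return Numeric vector of K updated centers, with attribute `"empty"`
#'   (logical vector) flagging clusters that received no weight.
#' @export
update_centers <- function(image, mu, m = 2, centers = NULL) {
  K <- dim(mu)[3]
  v <- numeric(K); empty <- logical(K)
  for (j in seq_len(K)) {
    w <- mu[, , j]^m
    den <- sum(w)
    if (den == 0) {
      empty[j] <- TRUE
      v[j] <- if (is.null(centers)) NA_real_ else centers[j]
    } else {
      v[j] <- sum(w * image) / den
    }
  }
  attr(v, "empty") <- empty
  v
}

#' FLICM objective function
#'
#' \deqn{J = \sum_i \sum_j \mu_{ij}^m (\lVert x_i - v_j \rVert^2 + B_{ij}).}
#' With B = 0 this is the classical FCM objective. Note that FLICM's
#' alternating updates are not a provable minimizer of this functional (a
#' known property of the algorithm); the per-iteration trace is diagnostic,
#' and monotone decrease is only guaranteed for the B = 0 reduction.
#'
#' @inheritParams update_membership
#' @return A single nonnegative number.
#' @export
flicm_objective <- function(image, mu, centers, B = NULL, m = 2) {
  K <- length(centers)
  total <- 0
  for (j in seq_len(K)) {
    A <- (image - centers[j])^2
    if (!is.null(B)) A <- A + B[, , j]
    total <- total + sum(mu[, , j]^m * A)
  }
  total
}

#' Fit a fuzzy local information C-means segmentation model
#'
#' Segments a 2-D grayscale image into `K` intensity clusters by fuzzy
#' clustering. With `local = TRUE` (the default) the fit is FLICM: each
#' pixel's distance to a cluster is penalized by the fuzzy factor
#' [fuzzy_factor()], a 3x3 neighbourhood term that pulls pixels towards the
#' consensus of their neighbours and thereby suppresses impulse and Gaussian
#' noise without any smoothing parameter. With `local = FALSE` the fuzzy
#' factor is forced to zero and the fit is classical FCM, the nested baseline.
#'
#' The algorithm alternates fuzzy factor, membership update and center update
#' until the largest center displacement falls below `tol` or `max_iter`
#' sweeps have run. Initial centers come from [init_centers()] unless
#' supplied, so FCM and FLICM can be compared from identical initializations.
#' The fit is fully deterministic for a fixed image and configuration.
#'
#' @param image Numeric matrix of intensities (one 2-D slice).
#' @param K Number of clusters (>= 2).
#' @param m Fuzzifier (> 1), default 2; controls membership softness.
#' @param tol Convergence tolerance on the maximum center shift, in intensity
#'   units (default 1e-5).
#' @param max_iter Maximum number of alternating sweeps (default 100). If the
#'   fit does not converge the best-so-far state is returned and
#'   `$converged` is `FALSE`.
#' @param local Use the local-information (FLICM) term; `FALSE` gives FCM.
#' @param centers Optional initial centers (length K); default quantile
#'   initialization.
#' @return An object of class `"flicm"` with components `centers`,
#'   `membership` (array nrow x ncol x K), `labels` (integer matrix, 0-based,
#'   argmax membership with ties to the lowest cluster index), `objective`,
#'   `trace` (data frame of iteration, objective, max center shift),
#'   `iterations`, `converged`, `K`, `m`, `local`, `image`, and `call`.
#'   Methods: [print.flicm()], [summary.flicm()], [coef.flicm()],
#'   [fitted.flicm()], [predict.flicm()], [residuals.flicm()],
#'   [plot.flicm()].
#' @examples
#' ph <- generate_phantom(phantom_spec(64, 64))
#' fit <- flicm(ph$image, K = 5)
#' fit
#' coef(fit)
#' @export
flicm <- function(image, K, m = 2, tol = 1e-5, max_iter = 100,
                  local = TRUE, centers = NULL) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (K < 2) stop("K must be at least 2")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (tol <= 0 || max_iter < 1) stop("invalid convergence configuration")
  v <- if (is.null(centers)) init_centers(image, K) else as.numeric(centers)
  if (length(v) != K) stop("contract error: centers must have length K")
  mu <- update_membership(image, v, B = NULL, m = m)
  trace <- data.frame(iteration = integer(), objective = numeric(),
                      max_shift = numeric())
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    B <- if (local) fuzzy_factor(image, mu, v, m) else NULL
    mu <- update_membership(image, v, B, m)
    v_new <- update_centers(image, mu, m, v)
    shift <- max(abs(v_new - v))
    v <- as.numeric(v_new)
    obj <- flicm_objective(image, mu, v, B, m)
    trace <- rbind(trace, data.frame(iteration = it, objective = obj,
                                     max_shift = shift))
    if (shift < tol) { converged <- TRUE; break }
  }
  labels <- defuzzify(mu)
  structure(list(centers = v, membership = mu, labels = labels,
                 objective = trace$objective[nrow(trace)], trace = trace,
                 iterations = it, converged = converged,
                 K = as.integer(K), m = m, local = local, tol = tol,
                 image = image, call = match.call()),
            class = "flicm")
}

#' Defuzzify a membership field
#'
#' Per-pixel argmax of the memberships; ties are broken towards the lowest
#' cluster index so the result is deterministic.
#'
#' @param mu Membership array (nrow, ncol, K).
#' @return Integer matrix of labels in 0..K-1.
#' @export
defuzzify <- function(mu) {
  d <- dim(mu)
  flat <- matrix(mu, d[1] * d[2], d[3])
  matrix(max.col(flat, ties.method = "first") - 1L, d[1], d[2])
}

#' Relabel a segmentation to best match a reference
#'
#' Finds the label permutation maximizing the total overlap (trace of the
#' permuted confusion matrix) between a predicted label map and the ground
#' truth, then applies it. Needed before per-class metrics because cluster
#' indices are arbitrary.
#'
#' @param pred,truth Integer label matrices of the same shape with labels in
#'   0..K-1.
#' @return `pred` relabeled; the chosen permutation (new label of old label
#'   j+1 at position j+1) is attached as attribute `"permutation"`.
#' @export
match_labels <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("contract error: label maps must share a shape")
  K <- max(pred, truth) + 1L
  conf <- table(factor(pred, levels = 0:(K - 1)),
                factor(truth, levels = 0:(K - 1)))
  perms <- .permutations(K)
  best <- perms[[which.max(vapply(
    perms, function(p) sum(conf[cbind(seq_len(K), p)]), numeric(1)))]]
  out <- matrix(best[pred + 1L] - 1L, nrow(pred), ncol(pred))
  attr(out, "permutation") <- best - 1L
  out
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in .permutations(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
  out
}
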