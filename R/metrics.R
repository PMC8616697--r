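#' Jaccard overlap of two masks
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 1 when both masks are empty
#' (perfect agreement on an absent class), 0 when exactly one is empty.
#'
#' @param truth_mask,pred_mask Logical matrices of the same shape.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(truth_mask, pred_mask) {
  if (!all(dim(truth_mask) == dim(pred_mask)))
    stop("contract error: masks must share a shape")
  u <- sum(truth_mask | pred_mask)
  if (u == 0) return(1)
  sum(truth_mask & pred_mask) / u
}

#' Dice overlap of two masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 when both masks are empty. Related to
#' Jaccard by Dice = 2J / (1 + J).
#'
#' @inheritParams jaccard
#' @return A number in \[0, 1\].
#' @export
dice <- function(truth_mask, pred_mask) {
  if (!all(dim(truth_mask) == dim(pred_mask)))
    stop("contract error: masks must share a shape")
  s <- sum(truth_mask) + sum(pred_mask)
  if (s == 0) return(1)
  2 * sum(truth_mask & pred_mask) / s
}

#' Peak signal-to-noise ratio in decibels
#'
#' \eqn{10 \log_{10}(M^2 / \mathrm{MSE})} with M the peak representable
#' intensity. Identical images have zero MSE and return the `Inf` sentinel.
#'
#' @param reference,test Numeric matrices of the same shape.
#' @param peak Peak signal M (default 255 for 8-bit data).
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(reference, test, peak = 255) {
  if (!all(dim(reference) == dim(test)))
    stop("contract error: images must share a shape")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean over sliding windows of the luminance, contrast and structure factors
#' \deqn{L = \frac{2\mu_a\mu_b + c_1}{\mu_a^2 + \mu_b^2 + c_1},\quad
#'       C = \frac{2\sigma_a\sigma_b + c_2}{\sigma_a^2 + \sigma_b^2 + c_2},\quad
#'       S = \frac{\sigma_{ab} + c_3}{\sigma_a\sigma_b + c_3},}
#' with the standard stabilizers c1 = (0.01 M)^2, c2 = (0.03 M)^2,
#' c3 = c2 / 2 and a 7x7 uniform window (valid positions only; images smaller
#' than the window fall back to a single global window). Window moments are
#' population moments.
#'
#' @inheritParams psnr
#' @param window Side of the square sliding window (default 7).
#' @return SSIM value; 1 iff the images are identical.
#' @export
ssim <- function(reference, test, peak = 255, window = 7) {
  if (!all(dim(reference) == dim(test)))
    stop("contract error: images must share a shape")
  c1 <- (0.01 * peak)^2; c2 <- (0.03 * peak)^2; c3 <- c2 / 2
  H <- nrow(reference); W <- ncol(reference)
  if (H < window || W < window) {
    slide <- function(m) matrix(mean(m), 1, 1)
  } else {
    hh <- H - window + 1L; ww <- W - window + 1L
    slide <- function(m) {
      acc <- matrix(0, hh, ww)
      for (di in 0:(window - 1L)) for (dj in 0:(window - 1L))
        acc <- acc + m[di + seq_len(hh), dj + seq_len(ww)]
      acc / (window * window)
    }
  }
  mu_a <- slide(reference); mu_b <- slide(test)
  va <- pmax(slide(reference^2) - mu_a^2, 0)
  vb <- pmax(slide(test^2) - mu_b^2, 0)
  cov <- slide(reference * test) - mu_a * mu_b
  sa <- sqrt(va); sb <- sqrt(vb)
  L <- (2 * mu_a * mu_b + c1) / (mu_a^2 + mu_b^2 + c1)
  C <- (2 * sa * sb + c2) / (va + vb + c2)
  S <- (cov + c3) / (sa * sb + c3)
  mean(L * C * S)
}

#' Overall pixel accuracy
#'
#' Fraction of pixels whose (matched) labels agree.
#'
#' @param truth,pred Integer label matrices of the same shape.
#' @return Fraction in \[0, 1\].
#' @export
pixel_accuracy <- function(truth, pred) {
  if (!all(dim(truth) == dim(pred)))
    stop("contract error: label maps must share a shape")
  mean(truth == pred)
}

#' Full metric report for one segmentation-vs-truth pair
#'
#' Per-class Jaccard and Dice for every requested class, overall pixel
#' accuracy, and (when both images are supplied) PSNR and SSIM between them.
#' Whether the image pair is segmentation-vs-reference or denoised-vs-clean
#' is the caller's choice; both pairings are meaningful and are reported as
#' given.
#'
#' @param truth,pred Integer label matrices (labels already matched, see
#'   [match_labels()]).
#' @param classes Class labels to report (default: all labels in `truth`).
#' @param reference,test Optional image pair for PSNR/SSIM.
#' @param peak Peak intensity for PSNR/SSIM.
#' @return Object of class `"metric_report"`: `per_class` (data frame with
#'   class, jaccard, dice), `pixel_accuracy`, `psnr`, `ssim`.
#' @export
metric_report <- function(truth, pred, classes = NULL,
                          reference = NULL, test = NULL, peak = 255) {
  if (is.null(classes)) classes <- sort(unique(as.vector(truth)))
  per <- data.frame(
    class = classes,
    jaccard = vapply(classes, function(k) jaccard(truth == k, pred == k),
                     numeric(1)),
    dice = vapply(classes, function(k) dice(truth == k, pred == k),
                  numeric(1)))
  p <- s <- NA_real_
  if (!is.null(reference) && !is.null(test)) {
    p <- psnr(reference, test, peak)
    s <- ssim(reference, test, peak)
  }
  structure(list(per_class = per, pixel_accuracy = pixel_accuracy(truth, pred),
                 psnr = p, ssim = s),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("Pixel accuracy: %.4f", x$pixel_accuracy))
  if (!is.na(x$psnr)) cat(sprintf("   PSNR: %.2f dB   SSIM: %.4f", x$psnr, x$ssim))
  cat("\n")
  invisible(x)
}
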