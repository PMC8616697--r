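#' @export
print.flicm <- function(x, ...) {
  cat(if (x$local) "FLICM" else "FCM (fuzzy C-means, no local term)",
      "segmentation fit\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Clusters: %d   fuzzifier m = %g   image: %d x %d\n",
              x$K, x$m, nrow(x$image), ncol(x$image)))
  cat(sprintf("Converged: %s after %d iteration(s) (tol %g on max center shift)\n",
              if (x$converged) "yes" else "NO (max_iter reached)",
              x$iterations, x$tol))
  cat("Centers:", paste(format(x$centers, digits = 6), collapse = "  "), "\n")
  invisible(x)
}

#' Summarize a FLICM fit
#'
#' @param object A fitted `"flicm"` object.
#' @param ... Unused.
#' @return An object of class `"summary.flicm"`: the fit plus cluster pixel
#'   counts, mean maximum membership (a crispness diagnostic) and the final
#'   objective value.
#' @export
summary.flicm <- function(object, ...) {
  sizes <- tabulate(object$labels + 1L, nbins = object$K)
  d <- dim(object$membership)
  mumax <- matrix(object$membership, d[1] * d[2], d[3])
  structure(list(fit = object, cluster_sizes = sizes,
                 mean_max_membership = mean(apply(mumax, 1, max)),
                 objective = object$objective),
            class = "summary.flicm")
}

#' @export
print.summary.flicm <- function(x, ...) {
  print(x$fit)
  tab <- data.frame(cluster = seq_along(x$cluster_sizes) - 1L,
                    center = x$fit$centers, pixels = x$cluster_sizes)
  print(tab, row.names = FALSE)
  cat(sprintf("Mean maximum membership: %.4f   final objective: %.6g\n",
              x$mean_max_membership, x$objective))
  invisible(x)
}

#' @export
coef.flicm <- function(object, ...) {
  stats::setNames(object$centers, paste0("v", seq_len(object$K) - 1L))
}

#' Extract fitted values from a FLICM model
#'
#' @param object A fitted `"flicm"` object.
#' @param type `"labels"` (default) for the defuzzified label matrix,
#'   `"membership"` for the full membership array, or `"response"` for the
#'   membership-weighted soft reconstruction \eqn{\sum_j \mu_{ij} v_j}.
#' @param ... Unused.
#' @export
fitted.flicm <- function(object, type = c("labels", "membership", "response"),
                         ...) {
  type <- match.arg(type)
  switch(type,
         labels = object$labels,
         membership = object$membership,
         response = .soft_reconstruction(object$membership, object$centers))
}

.soft_reconstruction <- function(mu, centers) {
  d <- dim(mu)
  matrix(matrix(mu, d[1] * d[2], d[3]) %*% centers, d[1], d[2])
}

#' Residuals of a FLICM fit
#'
#' Difference between the observed intensities and the membership-weighted
#' reconstruction from the cluster centers.
#' @param object A fitted `"flicm"` object.
#' @param ... Unused.
#' @export
residuals.flicm <- function(object, ...) {
  object$image - .soft_reconstruction(object$membership, object$centers)
}

#' Classify new pixels with a fitted FLICM model
#'
#' Applies the membership rule with the fitted centers to new data. The local
#' term is not recomputed for new images (it is a property of the fit's own
#' neighbourhood field), so prediction is the intensity-only FCM rule at the
#' FLICM-estimated centers.
#'
#' @param object A fitted `"flicm"` object.
#' @param newdata Numeric matrix of intensities; defaults to the training
#'   image.
#' @param type `"labels"` or `"membership"`.
#' @param ... Unused.
#' @export
predict.flicm <- function(object, newdata = NULL,
                          type = c("labels", "membership"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$image
  stopifnot(is.matrix(newdata))
  mu <- update_membership(newdata, object$centers, B = NULL, m = object$m)
  if (type == "membership") mu else defuzzify(mu)
}

#' Plot a FLICM segmentation
#'
#' Shows the input image and the defuzzified label map side by side, plus the
#' objective trace when `trace = TRUE`.
#'
#' @param x A fitted `"flicm"` object.
#' @param trace Also plot the per-iteration objective.
#' @param ... Passed to [graphics::image()].
#' @export
plot.flicm <- function(x, trace = FALSE, ...) {
  op <- graphics::par(mfrow = c(1, if (trace) 3 else 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  img <- t(x$image)[, nrow(x$image):1]
  graphics::image(img, col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  main = "image", useRaster = TRUE, ...)
  lab <- t(x$labels)[, nrow(x$labels):1]
  graphics::image(lab, col = grDevices::hcl.colors(x$K, "viridis"),
                  axes = FALSE, main = "segmentation", useRaster = TRUE, ...)
  if (trace)
    graphics::plot(x$trace$iteration, x$trace$objective, type = "b", pch = 20,
                   xlab = "iteration", ylab = "objective", main = "trace")
  invisible(x)
}
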