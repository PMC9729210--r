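#' @export
print.pm_segment <- function(x, ...) {
  lab <- switch(x$model,
                powermean = "Power-mean fuzzy segmentation",
                cv = "Chan-Vese (relaxed membership) segmentation",
                febm = "Fuzzy energy-based (FEBM) segmentation")
  cat(lab, "\n", sep = "")
  cat(sprintf("  image: %d x %d   init: %s\n",
              nrow(x$image), ncol(x$image), x$init))
  if (x$degenerate) {
    cat("  degenerate (constant) image: single-region result\n")
    return(invisible(x))
  }
  cat(sprintf("  centers: c1 = %.4f (foreground), c2 = %.4f (background)\n",
              x$centers[1], x$centers[2]))
  cat(sprintf("  iterations: %d (%s), final energy %.4f\n",
              x$iterations,
              if (x$converged) "converged" else "not converged",
              utils::tail(x$energy, 1)))
  cat(sprintf("  foreground pixels: %d of %d (%.1f%%)\n",
              sum(x$mask), length(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
summary.pm_segment <- function(object, ...) {
  structure(list(fit = object,
                 fg_pixels = sum(object$mask),
                 n_pixels = length(object$mask),
                 energy_first = if (length(object$energy)) object$energy[1] else NA_real_,
                 energy_last = if (length(object$energy)) utils::tail(object$energy, 1) else NA_real_,
                 membership_quartiles = stats::quantile(object$membership)),
            class = "summary.pm_segment")
}

#' @export
print.summary.pm_segment <- function(x, ...) {
  print(x$fit)
  if (!x$fit$degenerate) {
    cat(sprintf("  energy: %.4f -> %.4f over %d iterations\n",
                x$energy_first, x$energy_last, x$fit$iterations))
    cat("  membership quartiles:\n")
    print(round(x$membership_quartiles, 4))
  }
  invisible(x)
}

#' @export
coef.pm_segment <- function(object, ...) object$centers

#' Extract model quantities from a segmentation fit
#'
#' `fitted()` returns the final fuzzy membership; `residuals()` the
#' difference between the observed image and its two-phase reconstruction
#' \eqn{c_1 z + c_2 (1 - z)}; `predict()` selects among the binary mask, the
#' membership, or the reconstruction.
#'
#' @param object A `"pm_segment"` fit.
#' @param type For `predict()`: `"mask"`, `"membership"` or
#'   `"reconstruction"`.
#' @param ... Unused.
#' @return A matrix of the same shape as the segmented image (logical for
#'   `type = "mask"`).
#' @name pm_segment-extractors
NULL

#' @rdname pm_segment-extractors
#' @export
fitted.pm_segment <- function(object, ...) object$membership

#' @rdname pm_segment-extractors
#' @export
residuals.pm_segment <- function(object, ...) {
  object$image - (object$centers[1] * object$membership +
                    object$centers[2] * (1 - object$membership))
}

#' @rdname pm_segment-extractors
#' @export
predict.pm_segment <- function(object, type = c("mask", "membership",
                                                "reconstruction"), ...) {
  type <- match.arg(type)
  switch(type,
         mask = object$mask,
         membership = object$membership,
         reconstruction = object$centers[1] * object$membership +
           object$centers[2] * (1 - object$membership))
}

#' Plot a segmentation fit
#'
#' Draws the input image with the segmentation boundary (the 0.5 level line
#' of the membership) overlaid, next to the fuzzy membership itself, and the
#' energy trace when available.
#'
#' @param x A `"pm_segment"` fit.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.pm_segment <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (length(x$energy) > 1) 3 else 2),
                      mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  img_show <- function(mat, main) {
    graphics::image(t(mat)[, nrow(mat):1], col = grDevices::gray.colors(256),
                    axes = FALSE, main = main, useRaster = TRUE, ...)
  }
  img_show(x$image, "image + contour")
  graphics::contour(t(x$membership)[, nrow(x$membership):1], levels = 0.5,
                    add = TRUE, drawlabels = FALSE, col = "red", lwd = 2)
  img_show(x$membership, "membership")
  if (length(x$energy) > 1)
    graphics::plot(x$energy, type = "l", xlab = "iteration",
                   ylab = "energy", main = "energy trace")
  invisible(x)
}
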