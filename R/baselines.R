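#' Chan-Vese two-phase segmentation (relaxed membership form)
#'
#' Classical piecewise-constant two-phase model: both regions are summarized
#' by their plain means and every pixel contributes its squared distance with
#' equal weight, so the fit is the least-squares one. Implemented on the
#' relaxed membership representation (values in `[0, 1]`) rather than with a
#' signed-distance level set, so that the comparison with [pm_segment()]
#' isolates the data term. The membership evolves by the classical clipped
#' gradient flow \eqn{z \leftarrow \mathrm{clip}(z + \Delta t\,[\mu\kappa -
#' \lambda_1 d_1 + \lambda_2 d_2])}: boundary regularity comes from the
#' model's own curvature (length) term, as in the original formulation — the
#' Gaussian membership smoothing of the fuzzy models is *not* applied, since
#' it is an algorithmic device of that family, and grafting it onto this
#' model either biases the boundary (small steps against heavy smoothing) or
#' turns the baseline into a different, majority-filtered algorithm.
#'
#' @inheritParams pm_segment
#' @param lambda1,lambda2 Non-negative data-term weights for the foreground
#'   and background fitting terms.
#' @return A `"pm_segment"` object with `model = "cv"`.
#' @export
cv_segment <- function(image, init = "disk", control = seg_control(),
                       lambda1 = 1, lambda2 = 1, seed = 0L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  prep <- prepare_image(image)
  u <- prep$image
  if (prep$degenerate)
    return(degenerate_result(u, "cv", control, init))
  z <- resolve_init(init, dim(u), seed)
  init_label <- if (is.character(init)) init else "matrix"
  centers <- initial_centers(u, z, 1L)

  energy <- numeric(0)
  delta <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    s1 <- sum(z); s2 <- sum(1 - z)
    if (s1 > 0) centers[1] <- sum(z * u) / s1
    if (s2 > 0) centers[2] <- sum((1 - z) * u) / s2
    d1 <- (u - centers[1])^2
    d2 <- (u - centers[2])^2
    vel <- -lambda1 * d1 + lambda2 * d2
    if (control$mu > 0)
      vel <- vel + control$mu * curvature_term(z, control$eps_tv)
    z_new <- clip01(z + control$dt * vel)
    d <- max(abs(z_new - z))
    z <- z_new
    e <- sum(lambda1 * d1 * z + lambda2 * d2 * (1 - z))
    if (control$mu > 0) e <- e + control$mu * tv_norm(z, control$eps_tv)
    energy[iter] <- e
    delta[iter] <- d
    if (d <= control$tol) {
      converged <- TRUE
      break
    }
  }
  if (centers[1] < centers[2]) {
    centers <- c(c1 = unname(centers[2]), c2 = unname(centers[1]))
    z <- 1 - z
  }
  names(centers) <- c("c1", "c2")
  new_pm_segment(u, z, centers, energy, delta, iter, converged,
                 FALSE, "cv", control, init_label)
}

#' Fuzzy energy-based segmentation (FEBM)
#'
#' The least-squares fuzzy membership model: region centers are
#' `z^m`-weighted plain means and the membership has the closed form
#' \eqn{z = 1 / (1 + (\eta_1 d_1 / (\eta_2 d_2))^{1/(m-1)})}. This is exactly
#' the power-mean model at `p = 1` (unit robust weights) with data weights
#' `eta1`, `eta2`; it shares the alternating-minimization engine of
#' [pm_segment()], including the Gaussian regularization.
#'
#' @inheritParams pm_segment
#' @param eta1,eta2 Positive data-term weights.
#' @return A `"pm_segment"` object with `model = "febm"`.
#' @export
febm_segment <- function(image, init = "disk", control = seg_control(),
                         eta1 = 1, eta2 = 1, seed = 0L) {
  stopifnot(eta1 > 0, eta2 > 0)
  control$p <- 1
  fuzzy_fit(image, init, control, seed, model = "febm",
            eta1 = eta1, eta2 = eta2)
}
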