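#' Robust pixel weights for one region
#'
#' The weight field \eqn{w = ((u - c)^2 + \epsilon)^{p-1}} that the
#' power-mean data term assigns to each pixel given a region representative
#' intensity `c`. For `p < 1` pixels far from `c` (outliers with respect to
#' that region) receive small weights; `p = 1` gives the unit grid, i.e. the
#' classical least-squares treatment.
#'
#' @param image Numeric matrix of intensities in `[0, 1]`.
#' @param center Region representative intensity (finite scalar).
#' @param p Power-mean exponent in `(0, 1]`.
#' @param eps Positive smoothing of the squared distance (added before
#'   exponentiation, as in [pm_weights()]).
#' @return Matrix of strictly positive, finite weights.
#' @export
robust_weights <- function(image, center, p = 0.5, eps = 1e-8) {
  stopifnot(is.matrix(image), is.finite(center), eps > 0)
  ((image - center)^2 + eps)^(p - 1)
}

# guarded squared distances to both centers plus their p-th powers;
# a1 = alpha * d1 and a2 = beta * d2 collapse to d^p under the shared guard
region_terms <- function(image, centers, control) {
  d1 <- (image - centers[1])^2 + control$eps
  d2 <- (image - centers[2])^2 + control$eps
  list(d1 = d1, d2 = d2, a1 = d1^control$p, a2 = d2^control$p)
}

#' Weighted fuzzy update of the region centers
#'
#' Updates the foreground/background representative intensities as
#' \eqn{c_1 = \sum \alpha u z^m / \sum \alpha z^m} and
#' \eqn{c_2 = \sum \beta u (1-z)^m / \sum \beta (1-z)^m}, where the robust
#' weights \eqn{\alpha, \beta} are evaluated at the *previous* centers
#' (the lagged, majorize-minimize convention). If a region is empty (its
#' denominator vanishes, e.g. `z` identically 0), the previous center is kept
#' and the result is flagged with attribute `degenerate = TRUE`.
#'
#' @param image Numeric matrix of intensities in `[0, 1]`.
#' @param z Membership matrix, values in `[0, 1]`, same shape as `image`.
#' @param centers Numeric length-2 vector: previous `(c1, c2)` at which the
#'   robust weights are evaluated.
#' @param control A [seg_control()] list.
#' @return Named numeric vector `c(c1 = , c2 = )`, both within the intensity
#'   range of the image.
#' @export
update_centers <- function(image, z, centers, control = seg_control()) {
  stopifnot(is.matrix(image), is.matrix(z), all(dim(image) == dim(z)))
  alpha <- robust_weights(image, centers[1], control$p, control$eps)
  beta  <- robust_weights(image, centers[2], control$p, control$eps)
  m <- control$m
  w1 <- alpha * z^m
  w2 <- beta * (1 - z)^m
  s1 <- sum(w1); s2 <- sum(w2)
  degenerate <- FALSE
  if (s1 > 0) c1 <- sum(w1 * image) / s1 else { c1 <- centers[1]; degenerate <- TRUE }
  if (s2 > 0) c2 <- sum(w2 * image) / s2 else { c2 <- centers[2]; degenerate <- TRUE }
  out <- c(c1 = c1, c2 = c2)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Closed-form membership update
#'
#' With the centers fixed and no length penalty, the energy is minimized
#' pixelwise by \eqn{z = 1 / (1 + (\alpha d_1 / (\beta d_2))^{1/(m-1)})}
#' with guarded distances \eqn{d_k = (u - c_k)^2 + \epsilon}. Because
#' \eqn{\alpha d_1 = d_1^p} and \eqn{\beta d_2 = d_2^p}, for `m = 2` this is
#' \eqn{z = d_2^p / (d_1^p + d_2^p)}: a pixel's membership is governed by the
#' *compressed* distances, which is what blunts the pull of outliers.
#'
#' @inheritParams update_centers
#' @param centers Numeric length-2 vector `(c1, c2)` at which both the robust
#'   weights and the distances are evaluated.
#' @return Membership matrix with values in `[0, 1]`.
#' @export
membership_closed_form <- function(image, centers, control = seg_control()) {
  rt <- region_terms(image, centers, control)
  ratio <- (rt$a1 / rt$a2)^(1 / (control$m - 1))
  1 / (1 + ratio)
}

#' Mean-curvature of the membership level sets
#'
#' Central-difference discretization of \eqn{\mathrm{div}(\nabla z /
#' |\nabla z|)} with the gradient magnitude regularized as
#' \eqn{\sqrt{|\nabla z|^2 + \epsilon^2}} and replicate (zero normal
#' derivative) boundary handling. This is the gradient flow of the
#' total-variation term: it shrinks boundary length, smoothing wiggly
#' contours while leaving straight edges untouched.
#'
#' @param z Membership matrix.
#' @param eps_tv Positive gradient-magnitude guard.
#' @return Matrix of curvature values, same shape as `z`.
#' @export
curvature_term <- function(z, eps_tv = 1e-8) {
  stopifnot(is.matrix(z), eps_tv > 0)
  zx <- (shift_mat(z, 0L, 1L) - shift_mat(z, 0L, -1L)) / 2
  zy <- (shift_mat(z, 1L, 0L) - shift_mat(z, -1L, 0L)) / 2
  g <- sqrt(zx^2 + zy^2 + eps_tv^2)
  nx <- zx / g
  ny <- zy / g
  (shift_mat(nx, 0L, 1L) - shift_mat(nx, 0L, -1L)) / 2 +
    (shift_mat(ny, 1L, 0L) - shift_mat(ny, -1L, 0L)) / 2
}

#' One explicit time-marching step of the membership flow
#'
#' Gradient-descent update of the membership:
#' \eqn{z \leftarrow \mathrm{clip}(z + \Delta t\,[\mu\kappa
#' - m \alpha z^{m-1} d_1 + m \beta (1-z)^{m-1} d_2],\ 0,\ 1)},
#' where \eqn{\kappa} is [curvature_term()]. The signs follow the descent
#' direction of the energy: membership grows where the pixel is closer to the
#' foreground center and shrinks where it is closer to the background.
#'
#' @inheritParams membership_closed_form
#' @param z Current membership matrix.
#' @return Updated membership matrix, clipped to `[0, 1]`.
#' @export
membership_time_step <- function(z, image, centers, control = seg_control()) {
  rt <- region_terms(image, centers, control)
  m <- control$m
  alpha <- rt$d1^(control$p - 1)
  beta <- rt$d2^(control$p - 1)
  vel <- -m * alpha * z^(m - 1) * rt$d1 + m * beta * (1 - z)^(m - 1) * rt$d2
  if (control$mu > 0)
    vel <- vel + control$mu * curvature_term(z, control$eps_tv)
  clip01(z + control$dt * vel)
}

#' Gaussian regularization of the membership
#'
#' Convolves the membership with a normalized Gaussian kernel of width
#' `sigma` (replicate boundaries) and clips to `[0, 1]`. This smoothing
#' stands in for the boundary-length penalty in the default closed-form
#' solver: it removes the isolated misclassified pixels that per-pixel
#' minimization leaves behind in noisy images. `sigma = 0` is the identity.
#'
#' @param z Membership matrix.
#' @param sigma Gaussian width in pixels (>= 0).
#' @return Smoothed membership matrix, values in `[0, 1]`.
#' @export
regularize_membership <- function(z, sigma = 3) {
  stopifnot(is.matrix(z), is.finite(sigma), sigma >= 0)
  if (sigma == 0) return(z)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  kern <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  clip01(EBImage::filter2(z, kern, boundary = "replicate"))
}

#' Segmentation energy functional
#'
#' Evaluates \eqn{\mu \sum \sqrt{|\nabla z|^2 + \epsilon^2} +
#' \sum \alpha d_1 z^m + \sum \beta d_2 (1-z)^m} with forward-difference
#' gradients and the robust weights frozen at the supplied centers (so that
#' the data coefficients are the compressed distances \eqn{d_k^p}). With the
#' centers and weights frozen and `m = 2`, this functional is convex in `z`,
#' which is why the final segmentation does not depend on the initial
#' contour.
#'
#' @inheritParams membership_closed_form
#' @param z Membership matrix.
#' @return Single non-negative number.
#' @export
seg_energy <- function(image, z, centers, control = seg_control()) {
  rt <- region_terms(image, centers, control)
  e <- sum(rt$a1 * z^control$m + rt$a2 * (1 - z)^control$m)
  if (control$mu > 0)
    e <- e + control$mu * tv_norm(z, control$eps_tv)
  e
}

# total variation with forward differences and replicate boundary
tv_norm <- function(z, eps_tv) {
  gx <- shift_mat(z, 0L, 1L) - z
  gy <- shift_mat(z, 1L, 0L) - z
  sum(sqrt(gx^2 + gy^2 + eps_tv^2))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Robust power-mean fuzzy segmentation
#'
#' Fits the two-phase power-mean fuzzy segmentation model to a grayscale
#' image by alternating minimization. Each outer iteration (i) evaluates the
#' robust weights at the current centers, (ii) updates the region centers as
#' weighted fuzzy means, (iii) updates the membership either in closed form
#' or by one explicit descent step, and (iv) applies Gaussian regularization.
#' Iteration stops when the maximum absolute membership change falls below
#' `control$tol` or after `control$max_iter` iterations. On return the labels
#' are oriented so that the foreground is the brighter phase (`c1 >= c2`).
#'
#' @param image Numeric matrix of intensities. Values outside `[0, 1]` are
#'   rescaled with [normalize_image()]; a constant image yields a degenerate
#'   single-region result (flagged in the returned object).
#' @param init Either an initialization mode name accepted by
#'   [init_membership()] or a membership matrix of the same shape as `image`.
#' @param control A [seg_control()] list of model parameters.
#' @param seed Integer seed for the `"random"` initialization mode.
#' @return An object of class `"pm_segment"`: a list with components
#'   `membership` (final fuzzy membership), `mask` (logical matrix,
#'   `membership > 0.5`; ties go to background), `centers` (named
#'   `c(c1, c2)`, foreground first), `energy` (per-iteration energy trace),
#'   `delta` (per-iteration maximum membership change), `iterations`,
#'   `converged`, `degenerate`, `model`, `control`, `init` (mode label) and
#'   `image` (the normalized input).
#' @examples
#' ph <- make_phantom(shape = c(64, 64),
#'                    objects = list(list(kind = "disk", center = c(32, 32),
#'                                        radius = 14, intensity = 0.9)),
#'                    background = 0.1)
#' fit <- pm_segment(ph$image, control = seg_control(max_iter = 30))
#' jaccard(fit$mask, ph$truth)
#' @export
pm_segment <- function(image, init = "disk", control = seg_control(),
                       seed = 0L) {
  fuzzy_fit(image, init, control, seed, model = "powermean")
}

# shared alternating-minimization engine for the power-mean model and FEBM
# (FEBM = p = 1 with data weights eta1/eta2)
fuzzy_fit <- function(image, init, control, seed, model,
                      eta1 = 1, eta2 = 1) {
  prep <- prepare_image(image)
  u <- prep$image
  if (prep$degenerate)
    return(degenerate_result(u, model, control, init))
  z <- resolve_init(init, dim(u), seed)
  init_label <- if (is.character(init)) init else "matrix"
  centers <- initial_centers(u, z, control$m)

  energy <- numeric(0)
  delta <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    centers <- update_centers(u, z, centers, control)
    z_new <- if (control$solver == "closed_form") {
      fuzzy_membership(u, centers, control, eta1, eta2)
    } else {
      membership_time_step(z, u, centers, control)
    }
    z_new <- regularize_membership(z_new, control$sigma)
    d <- max(abs(z_new - z))
    z <- z_new
    energy[iter] <- fuzzy_energy(u, z, centers, control, eta1, eta2)
    delta[iter] <- d
    if (d <= control$tol) {
      converged <- TRUE
      break
    }
  }
  if (centers[1] < centers[2]) {   # foreground = brighter phase
    centers <- c(c1 = unname(centers[2]), c2 = unname(centers[1]))
    z <- 1 - z
  }
  new_pm_segment(u, z, centers, energy, delta, iter, converged,
                 FALSE, model, control, init_label)
}

# eta-weighted closed-form membership (eta1 = eta2 = 1 for the power-mean
# model; FEBM keeps p = 1 so a_k are the plain squared distances)
fuzzy_membership <- function(u, centers, control, eta1 = 1, eta2 = 1) {
  rt <- region_terms(u, centers, control)
  ratio <- ((eta1 * rt$a1) / (eta2 * rt$a2))^(1 / (control$m - 1))
  1 / (1 + ratio)
}

fuzzy_energy <- function(u, z, centers, control, eta1 = 1, eta2 = 1) {
  rt <- region_terms(u, centers, control)
  e <- sum(eta1 * rt$a1 * z^control$m + eta2 * rt$a2 * (1 - z)^control$m)
  if (control$mu > 0)
    e <- e + control$mu * tv_norm(z, control$eps_tv)
  e
}

prepare_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || any(dim(image) < 2L))
    stop("'image' must be a numeric matrix with at least 2 rows and 2 columns")
  if (!all(is.finite(image)))
    stop("'image' contains non-finite pixels")
  rng <- range(image)
  if (rng[1] == rng[2])
    return(list(image = matrix(0.5, nrow(image), ncol(image)),
                degenerate = TRUE))
  if (rng[1] < 0 || rng[2] > 1)
    image <- normalize_image(image)
  list(image = image, degenerate = FALSE)
}

resolve_init <- function(init, shape, seed) {
  if (is.matrix(init)) {
    if (!all(dim(init) == shape))
      stop("initial membership shape does not match the image")
    if (any(init < 0 | init > 1))
      stop("initial membership values must lie in [0, 1]")
    init
  } else {
    init_membership(shape, mode = init, seed = seed)
  }
}

# plain fuzzy means from the initialization; a median split breaks the exact
# symmetry of uninformative initializations (e.g. constant z = 0.5)
initial_centers <- function(u, z, m) {
  s1 <- sum(z^m); s2 <- sum((1 - z)^m)
  c1 <- if (s1 > 0) sum(z^m * u) / s1 else mean(u)
  c2 <- if (s2 > 0) sum((1 - z)^m * u) / s2 else mean(u)
  if (abs(c1 - c2) < 1e-3) {
    med <- stats::median(u)
    hi <- u[u > med]; lo <- u[u <= med]
    c1 <- if (length(hi)) mean(hi) else max(u)
    c2 <- if (length(lo)) mean(lo) else min(u)
  }
  c(c1 = c1, c2 = c2)
}

degenerate_result <- function(u, model, control, init) {
  new_pm_segment(u, matrix(0, nrow(u), ncol(u)),
                 c(c1 = 0.5, c2 = 0.5), numeric(0), numeric(0), 0L,
                 TRUE, TRUE, model, control,
                 if (is.character(init)) init else "matrix")
}

new_pm_segment <- function(u, z, centers, energy, delta, iterations,
                           converged, degenerate, model, control, init) {
  structure(list(membership = z,
                 mask = z > 0.5,
                 centers = centers,
                 energy = energy,
                 delta = delta,
                 iterations = iterations,
                 converged = converged,
                 degenerate = degenerate,
                 model = model,
                 control = control,
                 init = init,
                 image = u),
            class = "pm_segment")
}
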