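#' Control parameters for the fuzzy segmentation models
#'
#' Collects every tunable of [pm_segment()] and the baselines in one place,
#' in the spirit of `glm.control()`. The defaults are the settings used
#' throughout the experiments that motivated the model: `p = 0.5`, `mu = 0.7`,
#' `sigma = 3`, `m = 2`.
#'
#' @param p Power-mean exponent in `(0, 1]`. `p = 1` recovers the classical
#'   least-squares (FEBM) data term; decreasing `p` damps outliers more
#'   aggressively. Reported working range `0.5 <= p <= 0.9`, best at `0.5`.
#' @param mu Non-negative weight of the total-variation (boundary length)
#'   regularizer.
#' @param sigma Width (in pixels, >= 0) of the Gaussian smoothing applied to
#'   the membership after each update; `0` disables smoothing.
#' @param m Integer fuzzy weight exponent (>= 2; conventionally 2).
#' @param dt Positive explicit time step for the `time_marching` solver and
#'   the Chan-Vese baseline.
#' @param eps Positive floor applied to squared intensity distances before
#'   raising to `p - 1` (the weights are singular at zero distance).
#' @param eps_tv Positive regularizer of the gradient magnitude inside the
#'   total-variation term and the curvature operator.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   membership between outer iterations.
#' @param max_iter Maximum number of outer iterations.
#' @param solver Membership update rule: `"closed_form"` (exact minimizer of
#'   the data terms, then Gaussian regularization) or `"time_marching"` (one
#'   explicit gradient-descent step of the full flow per outer iteration).
#' @return A list of validated parameters with class `"seg_control"`.
#' @export
seg_control <- function(p = 0.5, mu = 0.7, sigma = 3, m = 2L, dt = 0.1,
                        eps = 1e-8, eps_tv = 1e-8, tol = 1e-4,
                        max_iter = 100L, solver = c("closed_form",
                                                    "time_marching")) {
  solver <- match.arg(solver)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("'p' must lie in (0, 1]")
  m <- as.integer(m)
  stopifnot(is.finite(mu), mu >= 0,
            is.finite(sigma), sigma >= 0,
            m >= 2L,
            is.finite(dt), dt >= 0,
            is.finite(eps), eps > 0,
            is.finite(eps_tv), eps_tv > 0,
            is.finite(tol), tol > 0,
            max_iter >= 1L)
  structure(list(p = p, mu = mu, sigma = sigma, m = m, dt = dt, eps = eps,
                 eps_tv = eps_tv, tol = tol, max_iter = as.integer(max_iter),
                 solver = solver),
            class = "seg_control")
}

#' Rescale an image to the unit intensity range
#'
#' Affine rescale `(x - min) / (max - min)` onto `[0, 1]`. A constant image
#' has no contrast to rescale; it maps to the all-`0.5` grid and is flagged
#' with the attribute `degenerate = TRUE`.
#'
#' @param raw Numeric matrix (at least 2 x 2) of finite intensities.
#' @return Matrix with values in `[0, 1]`; attribute `degenerate` is `TRUE`
#'   for constant input.
#' @export
normalize_image <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw) || any(dim(raw) < 2L))
    stop("'raw' must be a numeric matrix with at least 2 rows and 2 columns")
  if (!all(is.finite(raw)))
    stop("'raw' contains non-finite pixels")
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    out <- matrix(0.5, nrow(raw), ncol(raw))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Initial membership grids
#'
#' Deterministic initializations for the fuzzy membership. Because the energy
#' is convex in the membership, the final segmentation is essentially
#' independent of this choice; the modes exist to demonstrate exactly that.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param mode One of `"disk"` (1 inside the centered disk of radius
#'   `min(shape)/4`), `"half_plane"` (1 on the left half), `"random"`
#'   (seeded uniform values), `"constant"` (all 0.5).
#' @param seed Integer seed used by `mode = "random"`.
#' @return Matrix with values in `[0, 1]` of the requested shape.
#' @export
init_membership <- function(shape, mode = c("disk", "half_plane", "random",
                                            "constant"), seed = 0L) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L))
    stop("'shape' must be two integers >= 2")
  n <- shape[1]; m <- shape[2]
  switch(mode,
    constant = matrix(0.5, n, m),
    half_plane = {
      z <- matrix(0, n, m)
      z[, seq_len(m %/% 2)] <- 1
      z
    },
    disk = {
      r <- min(n, m) / 4
      ctr <- c((n + 1) / 2, (m + 1) / 2)
      rr <- matrix(seq_len(n), n, m)
      cc <- matrix(seq_len(m), n, m, byrow = TRUE)
      ifelse((rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2, 1, 0)
    },
    random = with_seed(seed, matrix(stats::runif(n * m), n, m))
  )
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# index-clamped shift: out[i, j] = z[clamp(i + dr), clamp(j + dc)]
# (replicate / Neumann boundary handling)
shift_mat <- function(z, dr = 0L, dc = 0L) {
  n <- nrow(z); m <- ncol(z)
  z[pmin(pmax(seq_len(n) + dr, 1L), n),
    pmin(pmax(seq_len(m) + dc, 1L), m), drop = FALSE]
}
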