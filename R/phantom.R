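#' Piecewise-constant phantom images with ground truth
#'
#' Renders a clean multi-object scene: a constant background with disks,
#' rectangles and rings painted at constant intensities, plus the
#' ground-truth foreground mask (the union of all objects). The phantom is a
#' pure function of its arguments; noise and bias fields are added separately
#' with [add_noise()] and [add_bias_field()] so that the truth mask is fixed
#' before any corruption.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param objects List of object descriptions. Each is a list with element
#'   `kind` (`"disk"`, `"rectangle"` or `"ring"`), an `intensity` in
#'   `[0, 1]`, and geometry in pixels: disks take `center = c(row, col)` and
#'   `radius`; rectangles take `rows = c(first, last)` and
#'   `cols = c(first, last)`; rings take `center`, `r_inner`, `r_outer`.
#' @param background Background intensity in `[0, 1]`.
#' @param min_contrast Required minimum |object intensity - background|
#'   (separability guard; default 0.2).
#' @return List with `image` (numeric matrix) and `truth` (logical matrix).
#' @examples
#' ph <- make_phantom(c(64, 64),
#'                    list(list(kind = "disk", center = c(32, 32),
#'                              radius = 12, intensity = 0.8)),
#'                    background = 0.2)
#' sum(ph$truth)  # ~ pi * 12^2
#' @export
make_phantom <- function(shape = c(128L, 128L), objects = list(),
                         background = 0.2, min_contrast = 0.2) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 2L),
            background >= 0, background <= 1)
  n <- shape[1]; m <- shape[2]
  img <- matrix(background, n, m)
  truth <- matrix(FALSE, n, m)
  rr <- matrix(seq_len(n), n, m)
  cc <- matrix(seq_len(m), n, m, byrow = TRUE)
  for (ob in objects) {
    if (is.null(ob$kind) || is.null(ob$intensity))
      stop("each object needs a 'kind' and an 'intensity'")
    if (ob$intensity < 0 || ob$intensity > 1)
      stop("object intensity must lie in [0, 1]")
    if (abs(ob$intensity - background) < min_contrast)
      stop("object intensity too close to the background (< min_contrast)")
    mask <- switch(ob$kind,
      disk = {
        if (ob$center[1] - ob$radius < 1 || ob$center[1] + ob$radius > n ||
            ob$center[2] - ob$radius < 1 || ob$center[2] + ob$radius > m)
          stop("disk out of bounds")
        (rr - ob$center[1])^2 + (cc - ob$center[2])^2 <= ob$radius^2
      },
      rectangle = {
        if (ob$rows[1] < 1 || ob$rows[2] > n || ob$cols[1] < 1 ||
            ob$cols[2] > m || ob$rows[1] > ob$rows[2] ||
            ob$cols[1] > ob$cols[2])
          stop("rectangle out of bounds")
        rr >= ob$rows[1] & rr <= ob$rows[2] &
          cc >= ob$cols[1] & cc <= ob$cols[2]
      },
      ring = {
        if (ob$r_inner >= ob$r_outer) stop("ring requires r_inner < r_outer")
        if (ob$center[1] - ob$r_outer < 1 || ob$center[1] + ob$r_outer > n ||
            ob$center[2] - ob$r_outer < 1 || ob$center[2] + ob$r_outer > m)
          stop("ring out of bounds")
        d2 <- (rr - ob$center[1])^2 + (cc - ob$center[2])^2
        d2 <= ob$r_outer^2 & d2 > ob$r_inner^2
      },
      stop("unknown object kind: ", ob$kind))
    img[mask] <- ob$intensity
    truth <- truth | mask
  }
  list(image = img, truth = truth)
}

#' The three-object benchmark phantom
#'
#' The package's standard noisy-segmentation scene: three bright objects of
#' mildly distinct intensities (disk 0.90, rectangle 0.85, ring 0.80) on a
#' dark background (0.1), emulating the classical multi-object test image
#' used to stress two-phase models under speckle noise. Geometry scales with
#' the requested shape.
#'
#' @param shape Integer vector `c(rows, cols)`, default 128 x 128.
#' @return List with `image` and `truth`, as [make_phantom()].
#' @export
three_object_phantom <- function(shape = c(128L, 128L)) {
  s <- min(shape) / 128
  make_phantom(
    shape = shape,
    objects = list(
      list(kind = "disk", center = round(c(38, 38) * s),
           radius = round(20 * s), intensity = 0.90),
      list(kind = "rectangle", rows = round(c(78, 113) * s),
           cols = round(c(18, 63) * s), intensity = 0.85),
      list(kind = "ring", center = round(c(40, 92) * s),
           r_inner = round(9 * s), r_outer = round(22 * s),
           intensity = 0.80)
    ),
    background = 0.1)
}

#' Corrupt an image with seeded noise
#'
#' Supported models, all deterministic given `seed` and clipped to `[0, 1]`:
#' * `speckle` — multiplicative noise `u * (1 + n)` with `n` zero-mean
#'   uniform of variance `level` (the coherent-imaging convention; a level
#'   of 0.2 is the heavy-noise condition used in the benchmark scenes);
#' * `gaussian` — additive `u + n`, `n ~ N(0, level)` (`level` = variance);
#' * `salt_pepper` — a fraction `level` of pixels forced to 0 or 1 with
#'   equal probability;
#' * `none` — identity.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param model Noise model name.
#' @param level Non-negative noise level; `0` returns the image unchanged.
#' @param seed Integer seed (the caller's RNG state is left untouched).
#' @return Corrupted image matrix, values in `[0, 1]`.
#' @export
add_noise <- function(image, model = c("speckle", "gaussian", "salt_pepper",
                                       "none"), level = 0.2, seed = 0L) {
  model <- match.arg(model)
  stopifnot(is.matrix(image), level >= 0)
  if (model == "none" || level == 0) return(image)
  n <- length(image)
  with_seed(seed, {
    out <- switch(model,
      speckle = {
        a <- sqrt(3 * level)
        image * (1 + matrix(stats::runif(n, -a, a), nrow(image)))
      },
      gaussian = image + matrix(stats::rnorm(n, 0, sqrt(level)), nrow(image)),
      salt_pepper = {
        k <- round(level * n)
        idx <- sample.int(n, k)
        out <- image
        out[idx] <- sample(c(0, 1), k, replace = TRUE)
        out
      })
    clip01(out)
  })
}

#' Smooth low-frequency bias field
#'
#' A seeded smooth field `g` with values in `[-1, 1]`, built as a weighted
#' sum of three random-direction, random-phase sinusoids of wavelength
#' `2 * pi * scale` pixels (weights 0.5/0.3/0.2, so the amplitude bound and
#' the per-pixel slope bound `1/scale` are exact, not asymptotic).
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param scale Positive smoothness scale in pixels: larger values give a
#'   flatter field.
#' @param seed Integer seed.
#' @return Matrix of field values in `[-1, 1]`.
#' @export
bias_field <- function(shape, scale = 32, seed = 0L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, scale > 0)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  with_seed(seed, {
    amps <- c(0.5, 0.3, 0.2)
    g <- matrix(0, shape[1], shape[2])
    for (a in amps) {
      theta <- stats::runif(1, 0, 2 * pi)
      phase <- stats::runif(1, 0, 2 * pi)
      g <- g + a * sin((cos(theta) * rr + sin(theta) * cc) / scale + phase)
    }
    g
  })
}

#' Apply a multiplicative intensity-inhomogeneity field
#'
#' Multiplies the image by `1 + strength * g` with `g` the smooth
#' [bias_field()], then clips to `[0, 1]`. Emulates the slowly varying
#' illumination/gain inhomogeneity of real acquisitions. `strength = 0` is
#' the identity.
#'
#' @inheritParams add_noise
#' @param strength Non-negative relative amplitude of the field.
#' @param scale Smoothness scale in pixels, passed to [bias_field()].
#' @return Biased image matrix, values in `[0, 1]`.
#' @export
add_bias_field <- function(image, strength = 0.3, scale = 32, seed = 0L) {
  stopifnot(is.matrix(image), strength >= 0, scale > 0)
  if (strength == 0) return(image)
  g <- bias_field(dim(image), scale = scale, seed = seed)
  clip01(image * (1 + strength * g))
}
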