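# Fixtures built in code: phantoms and oracles shared across test files.

# Two-value phantom with straight edges only: a full-width horizontal band.
# Symmetric Gaussian smoothing preserves the 0.5 crossing on straight edges,
# so exact recovery is attainable at the default sigma.
band_phantom <- function(n = 128L, lo = 0.2, hi = 0.8) {
  make_phantom(c(n, n),
               list(list(kind = "rectangle", rows = c(round(n * 0.35),
                                                      round(n * 0.65)),
                         cols = c(1L, n), intensity = hi)),
               background = lo)
}

disk_phantom <- function(n = 128L, radius = 20, fg = 0.8, bg = 0.2) {
  ctr <- round(n / 2)
  make_phantom(c(n, n),
               list(list(kind = "disk", center = c(ctr, ctr),
                         radius = radius, intensity = fg)),
               background = bg)
}

# Independent 1-D oracle for the generalized sample mean: dense grid search
# over the sample range followed by local refinement (golden-section /
# parabolic via optimize). Never touches the fixed-point path it checks.
oracle_location <- function(values, p, step = 1e-4) {
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(lo)
  grid <- seq(lo, hi, by = step)
  obj <- vapply(grid, function(a) sum(((values - a)^2)^p), numeric(1))
  i <- which.min(obj)
  left <- grid[max(1L, i - 2L)]
  right <- grid[min(length(grid), i + 2L)]
  stats::optimize(function(a) sum(((values - a)^2)^p),
                  interval = c(left, right), tol = 1e-10)$minimum
}

random_mask <- function(n, m, prob = 0.5, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(n * m) < prob, n, m)
}
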