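test_that("power_mean reproduces hand-computed values and validates input", {
  expect_equal(power_mean(c(2, 2, 2), 0.5), 2)
  expect_equal(power_mean(c(1, 4), 1), 2.5)
  expect_equal(power_mean(c(1, 4), 0.5), 2.25)  # ((sqrt(1)+sqrt(4))/2)^2
  expect_equal(power_mean(c(2, 8), -1), 3.2)    # harmonic mean
  expect_error(power_mean(c(1, 2), 0), "nonzero")
  expect_error(power_mean(c(-1, 2), 0.5), "non-negative")
  expect_error(power_mean(c(0, 2), -1), "strictly positive")
  # always between min and max
  set.seed(42)
  for (i in 1:20) {
    x <- runif(sample(2:30, 1))
    p <- sample(c(-1, 0.3, 0.5, 1, 2), 1)
    mp <- power_mean(x, p)
    expect_gte(mp, min(x) - 1e-12)
    expect_lte(mp, max(x) + 1e-12)
  }
})

test_that("pm_objective matches hand evaluation and is zero at a perfect fit", {
  expect_equal(pm_objective(c(1, 4), a = 1, p = 1), 9)
  expect_equal(pm_objective(c(1, 4), a = 1, p = 0.5), 3)
  expect_equal(pm_objective(rep(0.7, 5), a = 0.7, p = 0.8), 0)
  expect_error(pm_objective(c(1, 2), a = 1, p = -0.5), "positive")
})

test_that("pm_weights down-weight large residuals for p < 1", {
  expect_equal(pm_weights(c(0.3, 0.9, 0.1), a = 0.4, p = 1), rep(1, 3))
  expect_equal(pm_weights(c(1, 4), a = 2, p = 0.5), c(1, 0.5))
  # zero-distance guard: eps^(p-1)
  expect_equal(pm_weights(2, a = 2, p = 0.5, eps = 1e-8), 1e4)
  # monotone non-increasing in distance for p < 1
  x <- seq(0, 1, by = 0.1)
  w <- pm_weights(x, a = 0, p = 0.5)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w > 0))
})

test_that("pm_mean_iterate is a bounded weighted average", {
  x <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(pm_mean_iterate(x, 0.7, p = 1), mean(x))
  expect_equal(pm_mean_iterate(c(0, 0, 0, 10), 2.5, p = 0.5), 1.0)
  expect_equal(pm_mean_iterate(rep(0.4, 6), 0.1, p = 0.5), 0.4)
  set.seed(7)
  for (i in 1:20) {
    x <- runif(10)
    a <- pm_mean_iterate(x, runif(1), p = 0.6)
    expect_gte(a, min(x)); expect_lte(a, max(x))
  }
})

test_that("power_mean_location recovers closed-form cases", {
  x <- runif(25)
  fit <- power_mean_location(x, p = 1)
  expect_equal(fit$estimate, mean(x), tolerance = 1e-12)
  expect_identical(fit$iterations, 1L)
  expect_true(fit$converged)
  # p = 0.5 objective is sum |u - a|: minimized at the median (0 here)
  fit2 <- power_mean_location(c(0, 0, 0, 10), p = 0.5)
  expect_lt(abs(fit2$estimate), 1e-3)
  expect_equal(power_mean_location(rep(0.3, 9), p = 0.7)$estimate, 0.3)
  expect_error(power_mean_location(runif(5), p = 1.5), "\\(0, 1\\]")
})

test_that("fixed point agrees with the brute-force objective minimizer", {
  # odd sample sizes keep the p = 0.5 minimizer (the median) unique, so the
  # location comparison is well posed
  set.seed(11)
  for (i in 1:15) {
    x <- runif(sample(seq(3L, 49L, by = 2L), 1))
    for (p in c(0.5, 0.7, 1.0)) {
      est <- power_mean_location(x, p)$estimate
      expect_lt(abs(est - oracle_location(x, p)), 1e-3)
    }
  }
})

test_that("the reweighted iteration monotonically decreases the objective", {
  # the iteration is an MM scheme for the eps-smoothed objective, which is
  # what must descend; the raw objective agrees with it to within n * eps^p
  guarded <- function(x, a, p, eps = 1e-8) sum(((x - a)^2 + eps)^p)
  set.seed(23)
  for (i in 1:10) {
    x <- runif(sample(5:40, 1))
    p <- sample(c(0.5, 0.6, 0.8, 1), 1)
    a <- mean(x)
    obj <- guarded(x, a, p)
    for (k in 1:50) {
      a <- pm_mean_iterate(x, a, p)
      obj_new <- guarded(x, a, p)
      expect_lte(obj_new, obj + 1e-12)
      expect_lte(pm_objective(x, a, p), obj_new)  # raw <= smoothed
      obj <- obj_new
    }
  }
})

test_that("an extreme outlier moves the robust location less than the mean", {
  x <- c(0.2, 0.25, 0.3, 0.22, 0.28)
  base_fit <- power_mean_location(c(x, 0.3), p = 0.5)$estimate
  base_mean <- mean(c(x, 0.3))
  for (outlier in c(5, 50, 500)) {
    fit_shift <- abs(power_mean_location(c(x, outlier), p = 0.5)$estimate -
                       base_fit)
    mean_shift <- abs(mean(c(x, outlier)) - base_mean)
    expect_lt(fit_shift, mean_shift)
  }
  # and the robust estimate stays near the data cluster
  expect_lt(power_mean_location(c(x, 500), p = 0.5)$estimate, 1)
})
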