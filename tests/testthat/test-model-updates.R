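test_that("normalize_image rescales affinely and flags constant input", {
  raw <- matrix(c(0, 100, 200, 255), 2, 2)
  nm <- normalize_image(raw)
  expect_equal(nm[1, 1], 0)
  expect_equal(nm[2, 2], 1)
  expect_equal(nm[1, 2], 200 / 255)
  # idempotence
  expect_equal(normalize_image(nm), nm)
  cst <- normalize_image(matrix(3, 4, 4))
  expect_true(all(cst == 0.5))
  expect_true(attr(cst, "degenerate"))
  expect_error(normalize_image(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("robust_weights follow the guarded (d^2)^(p-1) law", {
  u <- matrix(runif(36), 6, 6)
  expect_equal(robust_weights(u, 0.3, p = 1), matrix(1, 6, 6))
  expect_equal(robust_weights(matrix(0.7, 2, 2), 0.5, p = 0.5),
               matrix(5, 2, 2), tolerance = 1e-6)  # ~0.04^(-1/2)
  expect_equal(robust_weights(matrix(0.5, 2, 2), 0.5, p = 0.5, eps = 1e-8),
               matrix(1e4, 2, 2))          # eps guard at zero distance
  w <- robust_weights(u, 0.5, p = 0.5)
  expect_true(all(w > 0 & is.finite(w)))
})

test_that("update_centers reduces to region means for crisp z at p = 1", {
  set.seed(5)
  u <- matrix(runif(64), 8, 8)
  z <- random_mask(8, 8, seed = 9) * 1
  ctl <- seg_control(p = 1)
  ctr <- update_centers(u, z, c(0.5, 0.5), ctl)
  expect_equal(unname(ctr[1]), mean(u[z == 1]), tolerance = 1e-12)
  expect_equal(unname(ctr[2]), mean(u[z == 0]), tolerance = 1e-12)
  # constant region recovers its intensity exactly
  u2 <- matrix(0.2, 8, 8); u2[z == 1] <- 0.9
  ctr2 <- update_centers(u2, z, c(0.8, 0.3), seg_control())
  expect_equal(unname(ctr2), c(0.9, 0.2), tolerance = 1e-9)
})

test_that("iterated c1 with z == 1 matches the generalized sample mean", {
  set.seed(31)
  u <- matrix(runif(100), 10, 10)
  ctl <- seg_control(p = 0.5)
  ctr <- c(mean(u), 0)
  for (k in 1:200) ctr <- update_centers(u, matrix(1, 10, 10), ctr, ctl)
  expect_true(attr(ctr, "degenerate"))     # empty background region
  expect_equal(unname(ctr[2]), 0)          # previous center kept
  loc <- power_mean_location(as.vector(u), p = 0.5)
  expect_equal(unname(ctr[1]), loc$estimate, tolerance = 1e-6)
})

test_that("closed-form membership matches the compressed-distance formula", {
  # symmetric pixel: d1 = d2 -> 0.5
  u <- matrix(0.5, 3, 3)
  z <- membership_closed_form(u, c(0.6, 0.4), seg_control())
  expect_equal(z, matrix(0.5, 3, 3))
  # perfect foreground pixel -> z ~ 1
  z2 <- membership_closed_form(matrix(0.8, 2, 2), c(0.8, 0.2), seg_control())
  expect_true(all(z2 > 0.99))
  # hand case: d1 = 1, d2 = 4, p = 0.5, m = 2 -> 2/3
  z3 <- membership_closed_form(matrix(1, 2, 2), c(0, 3), seg_control())
  expect_equal(z3, matrix(2 / 3, 2, 2), tolerance = 1e-8)
  # pixelwise identity z = d2^p / (d1^p + d2^p) for m = 2
  set.seed(13)
  for (i in 1:10) {
    u <- matrix(runif(64), 8, 8)
    ctr <- sort(runif(2), decreasing = TRUE)
    ctl <- seg_control(p = runif(1, 0.3, 1))
    d1 <- ((u - ctr[1])^2 + ctl$eps)^ctl$p
    d2 <- ((u - ctr[2])^2 + ctl$eps)^ctl$p
    expect_equal(membership_closed_form(u, ctr, ctl), d2 / (d1 + d2),
                 tolerance = 1e-12)
    expect_true(all(membership_closed_form(u, ctr, ctl) >= 0 &
                      membership_closed_form(u, ctr, ctl) <= 1))
  }
})

test_that("curvature vanishes on constants and ramps, equals 1/r on a cone", {
  expect_equal(curvature_term(matrix(0.7, 10, 10)), matrix(0, 10, 10),
               tolerance = 1e-9)
  ramp <- matrix(seq(0, 1, length.out = 50), 50, 50)
  k <- curvature_term(ramp)
  expect_lt(max(abs(k[3:48, 3:48])), 1e-6)
  n <- 201L
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  r <- sqrt((rr - ctr)^2 + (t(rr) - ctr)^2)
  k <- curvature_term(r)
  sel <- r >= 5 & r <= 50
  expect_lt(max(abs(k[sel] * r[sel] - 1)), 0.10)
})

test_that("time-marching step is stationary at the closed-form membership", {
  set.seed(3)
  u <- matrix(runif(100), 10, 10)
  ctr <- c(0.8, 0.2)
  ctl <- seg_control(mu = 0)
  z <- membership_closed_form(u, ctr, ctl)
  expect_equal(membership_time_step(z, u, ctr, ctl), z, tolerance = 1e-9)
  # dt = 0 is the identity
  ctl0 <- seg_control(dt = 0)
  z0 <- matrix(runif(100), 10, 10)
  expect_identical(membership_time_step(z0, u, ctr, ctl0), z0)
  # at z = 0.5 with d1 < d2 and mu = 0 the membership must grow
  u1 <- matrix(0.75, 4, 4)
  z1 <- membership_time_step(matrix(0.5, 4, 4), u1, c(0.8, 0.2),
                             seg_control(mu = 0))
  expect_true(all(z1 > 0.5))
})

test_that("Gaussian regularization preserves mass and constants", {
  z <- matrix(0.37, 20, 20)
  expect_equal(regularize_membership(z, 3), z, tolerance = 1e-9)
  expect_identical(regularize_membership(z, 0), z)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- regularize_membership(imp, 3)
  expect_lt(max(sm), 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)  # interior impulse: mass kept
  expect_true(all(sm >= 0 & sm <= 1))
})

test_that("energy matches algebraic special cases and the disk perimeter", {
  # perfect crisp fit at mu = 0 is (numerically) zero
  ph <- band_phantom(64)
  ctl <- seg_control(mu = 0)
  e <- seg_energy(ph$image, ph$truth * 1, c(0.8, 0.2), ctl)
  expect_lt(e, 2 * 64 * 64 * ctl$eps^ctl$p)
  # z = 0.5, mu = 0, m = 2: energy = 0.25 * sum(a1 + a2)
  u <- matrix(runif(64), 8, 8)
  ctr <- c(0.7, 0.3)
  a1 <- ((u - 0.7)^2 + ctl$eps)^0.5
  a2 <- ((u - 0.3)^2 + ctl$eps)^0.5
  expect_equal(seg_energy(u, matrix(0.5, 8, 8), ctr, ctl),
               0.25 * sum(a1 + a2), tolerance = 1e-10)
  # TV of a disk indicator ~ its circumference; the forward-difference
  # discretization overshoots a rasterized circle by the staircase
  # anisotropy (measured ~ +18%), so assert a 25% band
  dp <- disk_phantom(128, radius = 20)
  z <- dp$truth * 1
  ctlA <- seg_control(mu = 1); ctlB <- seg_control(mu = 0)
  tv <- seg_energy(dp$image, z, c(0.8, 0.2), ctlA) -
    seg_energy(dp$image, z, c(0.8, 0.2), ctlB)
  expect_lt(abs(tv - 2 * pi * 20) / (2 * pi * 20), 0.25)
})

test_that("energy is convex in z with weights and centers frozen (m = 2)", {
  set.seed(17)
  u <- matrix(runif(144), 12, 12)
  ctr <- c(0.75, 0.25)
  ctl <- seg_control()
  for (i in 1:40) {
    z0 <- matrix(runif(144), 12, 12)
    z1 <- matrix(runif(144), 12, 12)
    tt <- runif(1)
    lhs <- seg_energy(u, tt * z0 + (1 - tt) * z1, ctr, ctl)
    rhs <- tt * seg_energy(u, z0, ctr, ctl) +
      (1 - tt) * seg_energy(u, z1, ctr, ctl)
    expect_lte(lhs, rhs + 1e-9)
  }
})

test_that("closed-form z minimizes the mu = 0 energy (coordinate descent)", {
  set.seed(29)
  u <- matrix(runif(100), 10, 10)
  ctr <- c(0.8, 0.3)
  ctl <- seg_control(mu = 0)
  zstar <- membership_closed_form(u, ctr, ctl)
  estar <- seg_energy(u, zstar, ctr, ctl)
  for (i in 1:25) {
    zp <- pmin(pmax(zstar + matrix(rnorm(100, 0, 0.2), 10, 10), 0), 1)
    expect_lte(estar, seg_energy(u, zp, ctr, ctl))
  }
})

test_that("init_membership honours its contracts", {
  expect_equal(init_membership(c(6, 6), "constant"), matrix(0.5, 6, 6))
  hp <- init_membership(c(6, 8), "half_plane")
  expect_equal(hp[, 1:4], matrix(1, 6, 4))
  expect_equal(hp[, 5:8], matrix(0, 6, 4))
  dk <- init_membership(c(40, 40), "disk")
  expect_equal(dk[20, 20], 1)
  expect_equal(dk[1, 1], 0)
  expect_equal(sum(dk), sum(dk == 1))   # binary
  expect_identical(init_membership(c(9, 9), "random", seed = 4),
                   init_membership(c(9, 9), "random", seed = 4))
  expect_error(init_membership(c(9, 9), "blob"))
})
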