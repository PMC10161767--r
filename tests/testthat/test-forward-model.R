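test_that("tilt rotations are proper and match explicit trigonometric matrices", {
  expect_equal(rotation_from_tilts(0, 0), diag(3))

  # independent construction of Ry(b) %*% Rx(a), entry by entry
  explicit <- function(a, b) {
    a <- a * pi / 180
    b <- b * pi / 180
    rbind(
      c(cos(b), sin(a) * sin(b), cos(a) * sin(b)),
      c(0, cos(a), -sin(a)),
      c(-sin(b), sin(a) * cos(b), cos(a) * cos(b))
    )
  }
  set.seed(11)
  for (i in 1:100) {
    a <- runif(1, -90, 90)
    b <- runif(1, -90, 90)
    R <- rotation_from_tilts(a, b)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(R, explicit(a, b), tolerance = 1e-12)
  }
})

test_that("a 180-degree tilt is equivalent to no tilt on the induced curve", {
  p0 <- orientation_params(0, 0, 35, 25, 0, 0, -50, 40, lam_ratio = 1.4)
  p180 <- p0
  p180$alpha1 <- 180
  expect_identical(norm_angle180(180), 0)
  expect_lt(
    max(abs(simulate_ichi(p180)$intensity - simulate_ichi(p0)$intensity)),
    1e-9
  )
})

test_that("group fiber axes follow the documented convention", {
  g <- group_fiber_axes(0, 0, 0, 0, n_samples = 1)
  expect_equal(drop(g$axes), c(1, 0, 0), tolerance = 1e-12)
  g90 <- group_fiber_axes(0, 0, 90, 0, n_samples = 1)
  expect_equal(drop(g90$axes), c(0, 1, 0), tolerance = 1e-12)

  fan <- group_fiber_axes(0, 0, 30, 40, n_samples = 1001)
  expect_equal(sqrt(colSums(fan$axes^2)), rep(1, 1001), tolerance = 1e-9)
  expect_equal(sum(fan$weights), 1, tolerance = 1e-12)
  mean_dir <- fan$axes %*% fan$weights
  mean_dir <- mean_dir / sqrt(sum(mean_dir^2))
  expect_equal(
    drop(mean_dir), c(cos(30 * pi / 180), sin(30 * pi / 180), 0),
    tolerance = 1e-6
  )

  expect_error(group_fiber_axes(0, 0, 0, 10, n_samples = 0), "n_samples")
})

test_that("axes are unit vectors and weights normalized for random groups", {
  set.seed(4)
  for (i in 1:20) {
    g <- group_fiber_axes(
      runif(1, -90, 90), runif(1, -90, 90), runif(1, -90, 90),
      runif(1, 0, 180),
      n_samples = 51,
      weighting = sample(c("uniform", "gaussian"), 1)
    )
    expect_equal(sqrt(colSums(g$axes^2)), rep(1, 51), tolerance = 1e-12)
    expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  }
})

test_that("two identical groups reduce to a single group's curve", {
  p <- orientation_params(12, -8, 25, 50, 12, -8, 25, 50, lam_ratio = 1)
  combined <- simulate_ichi(p)
  grid <- chi_grid()
  m <- fiborient:::group_mass(12, -8, 25, 50, 360, 721L, waxd_geometry(), "gaussian")
  single <- fiborient:::smear_mass(m, fiborient:::smear_kernel_fft(360, 5))
  single <- single / max(single)
  expect_lt(max(abs(combined$intensity - single)), 1e-9)
})

test_that("swapping the groups while inverting the ratio leaves the curve unchanged", {
  set.seed(21)
  for (i in 1:5) {
    p <- random_params(1, seed = 100 + i)
    ps <- p
    ps[c(1:4, 5:8)] <- p[c(5:8, 1:4)]
    names(ps) <- names(p)
    ps$lam_ratio <- 1 / p$lam_ratio
    expect_lt(
      max(abs(simulate_ichi(p)$intensity - simulate_ichi(ps)$intensity)),
      1e-12
    )
  }
})

test_that("the combined deposit is linear in the group masses", {
  p <- random_params(1, seed = 5)
  geom <- waxd_geometry()
  m1 <- fiborient:::group_mass(
    p$alpha1, p$beta1, p$gamma1, p$dgamma1, 360, 721L, geom, "uniform"
  )
  m2 <- fiborient:::group_mass(
    p$alpha2, p$beta2, p$gamma2, p$dgamma2, 360, 721L, geom, "uniform"
  )
  kf <- fiborient:::smear_kernel_fft(360, 5)
  lhs <- fiborient:::smear_mass(p$lam_ratio * m1 + m2, kf)
  rhs <- p$lam_ratio * fiborient:::smear_mass(m1, kf) +
    fiborient:::smear_mass(m2, kf)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("every angle is periodic with period 180", {
  for (i in 1:10) {
    p <- random_params(1, seed = 300 + i)
    base <- simulate_ichi(p)$intensity
    for (nm in c("alpha1", "beta1", "gamma1", "alpha2", "beta2", "gamma2")) {
      ps <- p
      ps[[nm]] <- ps[[nm]] + 180
      expect_lt(max(abs(simulate_ichi(ps)$intensity - base)), 1e-9)
    }
  }
})

test_that("simulation is deterministic", {
  p <- random_params(1, seed = 9)
  expect_identical(simulate_ichi(p)$intensity, simulate_ichi(p)$intensity)
})

test_that("degenerate geometry yields a flagged zero curve with a warning", {
  # a single narrow fan pointing along the beam never meets the Ewald circle
  p <- orientation_params(0, 90, 0, 0, 0, 90, 0, 0, lam_ratio = 1)
  expect_warning(cu <- simulate_ichi(p), "degenerate")
  expect_true(cu$degenerate)
  expect_equal(max(cu$intensity), 0)
})

test_that("Monte-Carlo simulation is reproducible under a fixed seed", {
  p <- random_params(1, seed = 13)
  a <- simulate_ichi_mc(p, n_draws = 2000, seed = 42)
  b <- simulate_ichi_mc(p, n_draws = 2000, seed = 42)
  expect_identical(a$intensity, b$intensity)
})

test_that("quadrature matches the Monte-Carlo oracle within 3 standard errors", {
  # the batch-based SE is itself an estimate (19 df), so a small absolute
  # allowance covers its sampling noise over 25 x 360 bin comparisons
  allowance <- 1e-3
  for (i in 1:25) {
    p <- random_params(1, seed = 400 + i)
    quad <- simulate_ichi(p)
    mc <- simulate_ichi_mc(p, n_draws = 120000, seed = 500 + i)
    se <- attr(mc, "mc_se")
    d <- abs(quad$intensity - mc$intensity)
    expect_lt(max(d - 3 * se), allowance)
  }
  # one high-precision check
  p <- random_params(1, seed = 77)
  quad <- simulate_ichi(p)
  mc <- simulate_ichi_mc(p, n_draws = 1e6, seed = 78)
  expect_lt(
    max(abs(quad$intensity - mc$intensity) - 3 * attr(mc, "mc_se")), allowance
  )
})

test_that("Monte-Carlo error shrinks like one over sqrt(n)", {
  p <- orientation_params(10, -20, 40, 60, 5, 15, -30, 80, lam_ratio = 2)
  quad <- simulate_ichi(p)$intensity
  rms_dev <- function(n_draws, seed) {
    mc <- simulate_ichi_mc(p, n_draws = n_draws, seed = seed)
    sqrt(mean((mc$intensity - quad)^2))
  }
  r1 <- vapply(1:20, function(s) rms_dev(4000, s), double(1))
  r2 <- vapply(1:20, function(s) rms_dev(8000, 100 + s), double(1))
  ratio <- mean(r2) / mean(r1)
  expect_gt(ratio, 1 / sqrt(2) * 0.8)
  expect_lt(ratio, 1 / sqrt(2) * 1.25)
})

test_that("with no fan spread the MC and quadrature supports coincide", {
  p <- orientation_params(15, 10, 30, 0, 15, 10, 30, 0, lam_ratio = 1)
  quad <- simulate_ichi(p)
  mc <- simulate_ichi_mc(p, n_draws = 5000, seed = 3)
  expect_identical(which(quad$intensity > 1e-12), which(mc$intensity > 1e-12))
})
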