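test_that("normal field is exact for planar and radial level sets", {
  h <- 0.02
  xs <- seq(0, 1, by = h)
  # planar phi = x: uniform gradient; the regularizing solve is the identity
  # on constants, so n = (1, 0) everywhere
  pl <- scalar_field(matrix(xs, length(xs), length(xs)), h)
  n <- normal_field(pl, eps = 1e-4)
  expect_equal(max(abs(n[[1]]$values - 1)), 0, tolerance = 1e-8)
  expect_equal(max(abs(n[[2]]$values)), 0, tolerance = 1e-8)
  # eps = 0 returns the raw normalized gradient exactly
  f <- radial_phi(0.5, h)
  n0 <- normal_field(f, eps = 0)
  g <- neotissue:::grad_arr(f$values, h)
  mag <- pmax(sqrt(g[[1]]^2 + g[[2]]^2), 1e-8)
  expect_equal(n0[[1]]$values, g[[1]] / mag, tolerance = 1e-12)
  # circular void: n = +r_hat (toward the neotissue on the wall side)
  n <- normal_field(f, eps = 1e-4)
  ax <- field_axes(f)
  i <- which.min(abs(ax[[1]] - 0.3)); j <- which.min(abs(ax[[2]]))
  expect_equal(n[[1]]$values[i, j], 1, tolerance = 0.01)
  expect_equal(n[[2]]$values[i, j], 0, tolerance = 0.01)
})

test_that("curvature has the void-concave-positive sign and analytic values", {
  h <- 0.02
  xs <- seq(0, 1, by = h)
  pl <- scalar_field(matrix(xs, length(xs), length(xs)), h)
  kf <- curvature_field(pl, eps = 1e-4)
  expect_lt(max(abs(kf$values)), 1e-6)
  # 2D circular void r = 0.5: kappa = 1/r = 2 at the interface
  f <- radial_phi(0.5, h)
  k <- curvature_field(f, eps = 1e-4)
  ax <- field_axes(f)
  j <- which.min(abs(ax[[2]]))
  i <- which.min(abs(ax[[1]] - 0.5))
  expect_equal(k$values[i, j], 2, tolerance = 0.05 * 2)
  # brute-force cross-check: divergence of the exact radial normal, 1/r
  i4 <- which.min(abs(ax[[1]] - 0.4))
  expect_equal(k$values[i4, j], 1 / 0.4, tolerance = 0.05 / 0.4)
  # 3D spherical void r = 0.5: kappa = 2/r = 4
  fs <- sphere_sdf(0.5, 0.02)
  ks <- curvature_field(scalar_field(-fs$values, fs$spacing, fs$origin),
                        eps = 1e-4)
  axs <- field_axes(fs)
  ii <- which.min(abs(axs[[1]] - 0.5)); jj <- which.min(abs(axs[[2]]))
  expect_equal(ks$values[ii, jj, jj], 4, tolerance = 0.05 * 4)
})

test_that("growth velocity follows V = A g(kappa) n with one-sided g", {
  h <- 0.02
  f <- radial_phi(0.5, h)
  n <- normal_field(f, eps = 0)
  # kappa = 2 everywhere, A = 0.01: |V| = 0.02 directed opposite n
  k2 <- scalar_field(matrix(2, nrow(f$values), ncol(f$values)), h, f$origin)
  V <- growth_velocity(k2, n, 0.01)
  ax <- field_axes(f)
  i <- which.min(abs(ax[[1]] - 0.4)); j <- which.min(abs(ax[[2]]))
  expect_equal(V[[1]]$values[i, j], -0.02, tolerance = 1e-6)
  # kappa < 0: stationary (no retraction ever)
  km <- scalar_field(matrix(-1, nrow(f$values), ncol(f$values)), h, f$origin)
  Vm <- growth_velocity(km, n, 0.01)
  expect_true(all(Vm[[1]]$values == 0) && all(Vm[[2]]$values == 0))
  # A = 0 freezes everything
  V0 <- growth_velocity(k2, n, 0)
  expect_true(all(V0[[1]]$values == 0))
  expect_error(growth_velocity(k2, n, -1), "non-negative")
})

test_that("advection is exact for V = 0 and translates level sets uniformly", {
  h <- 0.02
  f <- radial_phi(0.3, h, extent = 0.6)
  zero <- lapply(1:2, function(k)
    scalar_field(matrix(0, nrow(f$values), ncol(f$values)), h, f$origin))
  expect_identical(advect(f, zero, 0.5)$values, f$values)
  # uniform V = (c, 0): the zero set translates by c*dt
  cvel <- 0.05
  V <- zero
  V[[1]]$values[] <- cvel
  dt <- 0.2
  f2 <- f
  for (s in 1:5) f2 <- advect(f2, V, dt)
  # locate the zero crossings along the x axis: both ends of the circle
  # must have moved by 5 * c * dt
  shift <- 5 * cvel * dt
  right <- uniroot(function(x) field_at(f2, c(x, 0)), c(0.1, 0.55))$root
  left <- uniroot(function(x) field_at(f2, c(x, 0)), c(-0.55, -0.1))$root
  expect_equal(right, 0.3 + shift, tolerance = 0.1 * h)
  expect_equal(left, -0.3 + shift, tolerance = 0.1 * h)
  # displacement bound is enforced
  expect_error(advect(f, V, 10), "CFL")
})

test_that("redistance restores the distance property without moving the zero set", {
  h <- 0.02
  f <- radial_phi(0.5, h)
  # idempotence on the narrow band: already a distance function
  r1 <- redistance(f)
  band <- abs(f$values) < h / 2  # the interface-adjacent pinned ring
  expect_lt(max(abs(r1$values[band] - f$values[band])), h / 10)
  # rescaled input: |grad phi| returns to 1 on the band
  r3 <- redistance(scalar_field(3 * f$values, h, f$origin))
  g <- neotissue:::grad_arr(r3$values, h)
  mag <- sqrt(g[[1]]^2 + g[[2]]^2)
  expect_true(all(abs(mag[abs(r3$values) < 3 * h] - 1) < 0.1))
  # checkerboard-perturbed circle: zero set stays within spacing/2 of the
  # clean circle (brute-force distance to the extracted contour)
  noisy <- f
  chk <- outer(seq_len(nrow(f$values)), seq_len(ncol(f$values)),
               function(i, j) (-1)^(i + j))
  noisy$values <- noisy$values * (1 + 0.2 * chk)
  rn <- redistance(noisy)
  cl <- zero_contours(rn)
  for (cc in cl)
    expect_lt(max(abs(sqrt(cc$x^2 + cc$y^2) - 0.5)), h / 2)
  # a field without an interface is flagged, not destroyed
  allpos <- scalar_field(matrix(1, 5, 5), h)
  out <- redistance(allpos)
  expect_true(attr(out, "empty_interface"))
  expect_identical(out$values, allpos$values)
})

test_that("the full step reproduces the shrinking-circle exact solution", {
  # closed-loop oracle: dr/dt = -A/r gives r(t) = sqrt(r0^2 - 2At)
  h <- 0.02
  A <- 0.003
  f <- channel_sdf(channel_spec("circle", 1.0), h)
  st <- initial_levelset(f, 0)
  sim <- simulate_growth(st, growth_params(A), t_end = 32,
                         record_at = seq(4, 32, 4))
  r_sim <- 0.5 * sqrt(pmax(1 - sim$filling_fraction, 0))
  r_exact <- sqrt(pmax(0.25 - 2 * A * sim$time_days, 0))
  expect_true(all(abs(r_sim - r_exact) < 2 * h))
})

test_that("A = 0 freezes the filling fraction", {
  f <- channel_sdf(channel_spec("square", 0.7), 0.7 / 25)
  st <- initial_levelset(f, 0.01)
  sim <- simulate_growth(st, growth_params(0), t_end = 10, record_at = c(5, 10))
  expect_equal(sim$filling_fraction[1], sim$filling_fraction[2])
  expect_equal(sim$filling_fraction[1], filling_fraction(st), tolerance = 1e-12)
})

test_that("triangles fill at least as fast as circles of the same size", {
  cfg <- test_config(30)
  days <- c(5, 10, 15, 21)
  tri <- neotissue:::sim_channel_filling("triangle", 1, 0.003, days, cfg)
  cir <- neotissue:::sim_channel_filling("circle", 1, 0.003, days, cfg)
  expect_true(all(tri >= cir))
})

test_that("filling never decreases within a run", {
  cfg <- test_config(30)
  f <- channel_sdf(channel_spec("hexagon", 0.7), 0.7 / 30)
  st <- initial_levelset(f, 0.01)
  sim <- simulate_growth(st, growth_params(0.003), t_end = 21)
  steps <- attr(sim, "steps")
  expect_true(all(diff(steps$filling_fraction) > -1e-3))
  expect_true(all(diff(sim$filling_fraction) >= 0))
})

test_that("time to half filling scales with the square of the circle size", {
  cfg <- test_config(30)
  A <- 0.005
  t50 <- sapply(c(0.5, 1.0), function(d) {
    f <- channel_sdf(channel_spec("circle", d), d / 30)
    st <- initial_levelset(f, 0)
    sim <- simulate_growth(st, growth_params(A), t_end = 60)
    steps <- attr(sim, "steps")
    steps$time_days[which(steps$filling_fraction >= 0.5)[1]]
  })
  expect_equal(t50[2] / t50[1], 4, tolerance = 0.1)
})
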