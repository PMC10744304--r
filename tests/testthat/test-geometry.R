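test_that("channel signed distance matches analytic in-radii at the centroid", {
  h <- 0.02
  # circle: distance at the centre is the radius
  fc <- channel_sdf(channel_spec("circle", 1.0), h)
  expect_equal(field_at(fc, c(0, 0)), 0.5, tolerance = h)
  # square: half the side
  fs <- channel_sdf(channel_spec("square", 1.0), h)
  expect_equal(field_at(fs, c(0, 0)), 0.5, tolerance = h)
  # triangle: in-radius d/(2*sqrt(3)), cross-checked by brute-force minimum
  # distance from the centroid to the three edges
  verts <- neotissue:::channel_vertices("triangle", 1.0)
  edge_dist <- sapply(1:3, function(i) {
    v1 <- verts[i, ]; v2 <- verts[if (i == 3) 1 else i + 1, ]
    tt <- seq(0, 1, length.out = 2001)
    min(sqrt((v1[1] + tt * (v2[1] - v1[1]))^2 +
               (v1[2] + tt * (v2[2] - v1[2]))^2))
  })
  expect_equal(min(edge_dist), 1 / (2 * sqrt(3)), tolerance = 1e-6)
  ft <- channel_sdf(channel_spec("triangle", 1.0), h)
  expect_equal(field_at(ft, c(0, 0)), min(edge_dist), tolerance = h)
})

test_that("circle psi equals the analytic distance within one spacing", {
  h <- 0.02
  f <- channel_sdf(channel_spec("circle", 1.0), h)
  ax <- field_axes(f)
  r <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
  inside <- r < 0.5
  expect_lt(max(abs(f$values[inside] - (0.5 - r[inside]))), h)
})

test_that("voxel-counted void area matches analytic areas within 2% at d/50", {
  d <- 1.0
  h <- d / 50
  areas <- c(circle = pi * d^2 / 4, square = d^2,
             triangle = sqrt(3) * d^2 / 4, hexagon = sqrt(3) / 2 * d^2)
  for (s in names(areas)) {
    f <- channel_sdf(channel_spec(s, d), h)
    w <- pmin(pmax(0.5 + f$values / h, 0), 1)  # sub-cell void coverage
    expect_equal(sum(w) * h^2, unname(areas[s]), tolerance = 0.02,
                 label = paste(s, "area"))
  }
})

test_that("channel_sdf validates its inputs", {
  expect_error(channel_spec("pentagon", 1), "arg")
  expect_error(channel_spec("circle", -1), "positive")
  expect_error(channel_sdf(channel_spec("circle", 1.0), 0.2), "coarse")
})

test_that("initial level set seeds a layer on the wall", {
  h <- 0.02
  f <- channel_sdf(channel_spec("circle", 1.0), h)
  # layer = 0: the interface coincides with the wall
  st0 <- initial_levelset(f, 0)
  expect_equal(void_radius(st0$phi), 0.5, tolerance = h / 2)
  expect_equal(st0$time, 0)
  expect_true(all(st0$void0_mask == (f$values > 0)))
  # layer = 0.1 on the d = 1 circle: annulus filling 1 - (0.4/0.5)^2
  st1 <- initial_levelset(f, 0.1)
  expect_equal(filling_fraction(st1), 1 - (0.4 / 0.5)^2, tolerance = 0.01)
  # |grad phi| close to 1 on the narrow band after redistancing
  g <- neotissue:::grad_arr(st1$phi$values, h)
  mag <- sqrt(g[[1]]^2 + g[[2]]^2)
  band <- abs(st1$phi$values) < 3 * h & f$values > 2 * h
  expect_true(all(mag[band] > 0.5 & mag[band] < 1.5))
  # a layer deeper than the void is rejected
  expect_error(initial_levelset(f, 0.6), "fill")
})

test_that("gyroid wall contains the midsurface and thins to nothing", {
  spec <- gyroid_spec(wall_thickness = 0.2, period = 1.2)
  f <- gyroid_sdf(spec, 0.05)
  # F(0,0,0) = 0 lies on the midsurface, inside the wall for any thickness
  expect_lt(field_at(f, c(0, 0, 0)), 0)
  # pore fraction grows toward 1 as the wall thins (solid fraction is about
  # surface-area * thickness / volume, so ~0.9 pore at a 0.04 mm wall)
  pore_frac <- function(wall, h) {
    s <- gyroid_spec(wall_thickness = wall, period = 1.2)
    g <- gyroid_sdf(s, h)
    mean(g$values > 0)
  }
  p_thin <- pore_frac(0.04, 0.02)
  expect_gt(p_thin, pore_frac(0.12, 0.04))
  expect_gt(pore_frac(0.12, 0.04), pore_frac(0.2, 0.04))
  expect_gt(p_thin, 0.85)
})

test_that("measured gyroid wall thickness matches the request within 10%", {
  spec <- gyroid_spec(wall_thickness = 0.2, period = 1.2)
  h <- 0.02
  f <- gyroid_sdf(spec, h)
  # independent voxel oracle: cast rays along the grid axes and record solid
  # runs that actually cross the midsurface (F changes sign inside the run);
  # tangential slivers graze the wall without crossing it and are shorter
  # than the true pore-to-pore thickness
  solid <- f$values <= 0
  ax <- field_axes(f)
  crossing_runs <- function(sol, Fv) {
    r <- rle(sol)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & vapply(seq_along(ends), function(i) {
      seg <- Fv[starts[i]:ends[i]]
      min(seg) < 0 && max(seg) > 0
    }, TRUE)
    r$lengths[keep]
  }
  d <- dim(solid)
  lens <- c()
  for (j in seq(2, d[2] - 1, by = 2)) for (k in seq(2, d[3] - 1, by = 2)) {
    Fv <- neotissue:::gyroid_F(ax[[1]], ax[[2]][j], ax[[3]][k], spec$period)
    lens <- c(lens, crossing_runs(solid[, j, k], Fv))
  }
  # shortest crossing: a ray nearly normal to the wall measures its
  # thickness; a run of m voxels represents a chord of (m +/- 1) cells
  min_run <- min(lens) * f$spacing
  expect_lt(abs(min_run - 0.2), 0.1 * 0.2 + f$spacing)
})

test_that("gyroid midsurface has near-zero mean curvature on average", {
  # the tau = 0 surface is a minimal surface: sampled discrete mean curvature
  # should average to ~0
  L <- 1.2
  n <- 49
  xs <- seq(0, L, length.out = n)
  h <- xs[2] - xs[1]
  XY <- expand.grid(x = xs, y = xs, z = xs)
  F <- neotissue:::gyroid_F(XY$x, XY$y, XY$z, L)
  f <- redistance(scalar_field(array(F, c(n, n, n)), h))
  k <- curvature_field(f, eps = 1e-4)
  band <- abs(f$values) < h
  expect_lt(abs(mean(k$values[band])), 0.05 / L)
})

test_that("thinner initial layers start the gyroid at lower filling", {
  spec <- gyroid_spec(wall_thickness = 0.2, period = 1.2)
  f <- gyroid_sdf(spec, 0.04)
  fill_L1 <- filling_fraction(initial_levelset(f, 0.010))
  fill_L2 <- filling_fraction(initial_levelset(f, 0.001))
  expect_lt(fill_L2, fill_L1)
  expect_gt(fill_L2, 0)
})

test_that("gyroid period can be solved from the pore size", {
  # solve for the period at a coarse verification resolution, then confirm
  # the inscribed-pore diameter round-trips
  L <- neotissue:::gyroid_pore_diameter(1.4, 0.2, cells_across = 32)
  expect_gt(L, 0)
  spec <- gyroid_spec(wall_thickness = 0.2, pore_size = 0.9)
  dia <- neotissue:::gyroid_pore_diameter(spec$period, 0.2, cells_across = 32)
  expect_equal(dia, 0.9, tolerance = 0.08)
})
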