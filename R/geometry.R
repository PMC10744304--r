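#' Channel geometry specification
#'
#' Describes one prismatic channel of the perforated disk design: a 2 mm high
#' prism whose cross-section is an equilateral triangle, square, regular
#' hexagon, or circle of size `d`. Size conventions: `d` is the diameter for
#' the circle, the side length for the square and triangle, and the
#' across-flats diameter for the hexagon (so circle and hexagon share the same
#' inradius `d/2`).
#'
#' @param shape one of `"triangle"`, `"square"`, `"hexagon"`, `"circle"`.
#' @param d size parameter in mm (> 0).
#' @param height prism height in mm (default 2, informational: growth from the
#'   lateral walls is translation-invariant along the channel axis, so the
#'   cross-section is simulated in 2D).
#' @return object of class `channel_spec`.
#' @export
channel_spec <- function(shape = c("triangle", "square", "hexagon", "circle"),
                         d, height = 2.0) {
  shape <- match.arg(shape)
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    stop("`d` must be a single positive length in mm")
  structure(list(shape = shape, d = d, height = height),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> %s, d = %g mm, height = %g mm\n",
              x$shape, x$d, x$height))
  invisible(x)
}

# Vertices of the supported convex cross-sections, centred on the centroid,
# counter-clockwise. Returns NULL for the circle.
channel_vertices <- function(shape, d) {
  switch(shape,
    circle = NULL,
    square = {
      s <- d / 2
      cbind(c(-s, s, s, -s), c(-s, -s, s, s))
    },
    triangle = {
      rc <- d / sqrt(3)  # circumradius of an equilateral triangle of side d
      ang <- pi / 2 + c(0, 2, 4) * pi / 3
      cbind(rc * cos(ang), rc * sin(ang))
    },
    hexagon = {
      rc <- d / sqrt(3)  # across-flats d implies circumradius d/sqrt(3)
      ang <- (0:5) * pi / 3 + pi / 6
      cbind(rc * cos(ang), rc * sin(ang))
    },
    stop("unknown shape: ", shape)
  )
}

# Exact signed distance (positive inside) to a convex CCW polygon, vectorised
# over query points px, py.
polygon_sdist <- function(px, py, verts) {
  nv <- nrow(verts)
  inside_min <- rep(Inf, length(px))
  seg_min <- rep(Inf, length(px))
  for (i in seq_len(nv)) {
    v1 <- verts[i, ]
    v2 <- verts[if (i == nv) 1L else i + 1L, ]
    e <- v2 - v1
    len <- sqrt(sum(e^2))
    # inward normal for a CCW polygon
    nin <- c(-e[2], e[1]) / len
    s <- (px - v1[1]) * nin[1] + (py - v1[2]) * nin[2]
    inside_min <- pmin(inside_min, s)
    # distance to the edge segment
    t <- ((px - v1[1]) * e[1] + (py - v1[2]) * e[2]) / len^2
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (v1[1] + t * e[1])
    dy <- py - (v1[2] + t * e[2])
    seg_min <- pmin(seg_min, sqrt(dx * dx + dy * dy))
  }
  ifelse(inside_min >= 0, inside_min, -seg_min)
}

#' Signed distance field of a channel cross-section
#'
#' Builds psi, the signed distance from the channel wall measured into the
#' void: psi > 0 inside the channel, psi = 0 on the wall, psi < 0 in the solid
#' material. The grid is padded at least 2 cells beyond the wall.
#'
#' @param spec a [channel_spec()].
#' @param spacing grid spacing in mm; must satisfy `spacing <= d/20`.
#' @return a [scalar_field()] holding psi.
#' @export
channel_sdf <- function(spec, spacing) {
  stopifnot(inherits(spec, "channel_spec"))
  if (spacing > spec$d / 20 + 1e-12)
    stop("spacing too coarse: need spacing <= d/20 to resolve the channel")
  verts <- channel_vertices(spec$shape, spec$d)
  bbox <- if (is.null(verts)) {
    r <- spec$d / 2
    rbind(c(-r, -r), c(r, r))
  } else {
    rbind(apply(verts, 2, min), apply(verts, 2, max))
  }
  pad <- 3 * spacing
  mlo <- floor((bbox[1, ] - pad) / spacing)
  mhi <- ceiling((bbox[2, ] + pad) / spacing)
  xs <- (mlo[1]:mhi[1]) * spacing
  ys <- (mlo[2]:mhi[2]) * spacing
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  psi <- if (is.null(verts)) {
    spec$d / 2 - sqrt(px^2 + py^2)
  } else {
    polygon_sdist(px, py, verts)
  }
  scalar_field(matrix(psi, nrow = length(xs)), spacing,
               origin = c(xs[1], ys[1]))
}

#' Signed distance field of a spherical void
#'
#' A sphere of void space surrounded by solid material: psi > 0 inside the
#' sphere. Used as the 3D analytic benchmark geometry.
#'
#' @param radius sphere radius, mm.
#' @param spacing grid spacing, mm.
#' @param pad padding beyond the sphere, in cells (default 4).
#' @return a [scalar_field()] holding psi.
#' @export
sphere_sdf <- function(radius, spacing, pad = 4) {
  stopifnot(radius > 0, spacing > 0)
  m <- ceiling(radius / spacing) + pad
  xs <- (-m:m) * spacing
  n <- length(xs)
  r2 <- outer(outer(xs^2, xs^2, `+`), xs^2, `+`)
  psi <- radius - sqrt(r2)
  scalar_field(array(psi, dim = c(n, n, n)), spacing,
               origin = rep(xs[1], 3))
}

# --- gyroid -----------------------------------------------------------------

gyroid_F <- function(x, y, z, L) {
  k <- 2 * pi / L
  sin(k * x) * cos(k * y) + sin(k * y) * cos(k * z) + sin(k * z) * cos(k * x)
}

gyroid_gradF <- function(x, y, z, L) {
  k <- 2 * pi / L
  cbind(k * (cos(k * x) * cos(k * y) - sin(k * z) * sin(k * x)),
        k * (-sin(k * x) * sin(k * y) + cos(k * y) * cos(k * z)),
        k * (-sin(k * y) * sin(k * z) + cos(k * z) * cos(k * x)))
}

# Project seed points onto the gyroid midsurface F = 0 by Newton steps along
# the gradient; returns points that converged.
gyroid_midsurface_points <- function(L, n_seed = 4) {
  u <- (seq_len(n_seed) - 0.5) / n_seed * L
  pts <- as.matrix(expand.grid(x = u, y = u, z = u))
  for (it in 1:30) {
    f <- gyroid_F(pts[, 1], pts[, 2], pts[, 3], L)
    g <- gyroid_gradF(pts[, 1], pts[, 2], pts[, 3], L)
    g2 <- rowSums(g^2)
    g2 <- pmax(g2, 1e-12)
    pts <- pts - (f / g2) * g
  }
  f <- gyroid_F(pts[, 1], pts[, 2], pts[, 3], L)
  g <- gyroid_gradF(pts[, 1], pts[, 2], pts[, 3], L)
  ok <- abs(f) < 1e-9 & sqrt(rowSums(g^2)) > 0.1 * 2 * pi / L
  pts[ok, , drop = FALSE]
}

# Thickness of the wall |F| <= tau at midsurface point p, measured along the
# surface normal: distance between the F = +tau and F = -tau crossings.
gyroid_crossing_thickness <- function(p, L, tau) {
  g <- gyroid_gradF(p[1], p[2], p[3], L)[1, ]
  nrm <- g / sqrt(sum(g^2))
  fs <- function(s) gyroid_F(p[1] + s * nrm[1], p[2] + s * nrm[2],
                             p[3] + s * nrm[3], L)
  first_cross <- function(target, sgn) {
    step <- L / 400
    s_prev <- 0
    for (i in 1:400) {
      s <- i * step
      if (sgn * fs(sgn * s) >= sgn * target) {
        r <- stats::uniroot(function(t) fs(sgn * t) - target,
                            c(s_prev, s), tol = 1e-10)
        return(r$root)
      }
      s_prev <- s
    }
    NA_real_
  }
  sp <- first_cross(tau, 1)
  sm <- first_cross(-tau, -1)
  sp + sm
}

# Minimum pore-to-pore crossing thickness of the wall band |F| <= tau.
gyroid_wall_thickness <- function(L, tau, pts = NULL) {
  if (is.null(pts)) pts <- gyroid_midsurface_points(L)
  th <- apply(pts, 1, gyroid_crossing_thickness, L = L, tau = tau)
  min(th, na.rm = TRUE)
}

# Level-set threshold tau such that the measured (minimum) wall thickness
# equals the requested one.
gyroid_tau_for_wall <- function(L, wall_thickness) {
  pts <- gyroid_midsurface_points(L)
  f <- function(tau) gyroid_wall_thickness(L, tau, pts) - wall_thickness
  tau_hi <- 1.4
  if (f(tau_hi) < 0)
    stop("wall thicker than achievable at the given period")
  stats::uniroot(f, c(1e-6, tau_hi), tol = 1e-6)$root
}

# Largest inscribed-sphere diameter of the pore network, from the redistanced
# field on a single unit cell.
gyroid_pore_diameter <- function(L, wall_thickness, cells_across = 40) {
  # a period too small for the requested wall leaves no pore at all
  tau <- tryCatch(gyroid_tau_for_wall(L, wall_thickness),
                  error = function(e) NA_real_)
  if (is.na(tau)) return(0)
  n <- cells_across + 1
  xs <- seq(0, L, length.out = n)
  h <- xs[2] - xs[1]
  XY <- expand.grid(x = xs, y = xs, z = xs)
  w <- abs(gyroid_F(XY$x, XY$y, XY$z, L)) - tau
  f <- scalar_field(array(w, dim = c(n, n, n)), h, origin = c(0, 0, 0))
  psi <- redistance(f)
  2 * max(psi$values)
}

.gyroid_cache <- new.env(parent = emptyenv())

#' Gyroid scaffold specification
#'
#' A gyroid wall is the band `|F| <= tau` around the triply periodic minimal
#' surface F(x,y,z) = sin(kx)cos(ky) + sin(ky)cos(kz) + sin(kz)cos(kx),
#' k = 2*pi/period. `tau` is chosen numerically so that the shortest
#' pore-to-pore crossing of the wall equals `wall_thickness`. If `period` is
#' not given it is solved so that the largest sphere inscribed in the pore
#' network has diameter `pore_size`.
#'
#' @param wall_thickness wall thickness in mm.
#' @param pore_size pore size (inscribed-sphere diameter) in mm; used to solve
#'   for the period when `period` is `NULL`.
#' @param period unit-cell edge length in mm, or `NULL` to derive from
#'   `pore_size`.
#' @param n_cells number of unit cells per axis (>= 1).
#' @param initial_layer initial neotissue layer thickness in mm (default
#'   0.010 mm; the low-seeding preset uses 0.001 mm).
#' @return object of class `gyroid_spec` with the resolved `period` and `tau`.
#' @export
gyroid_spec <- function(wall_thickness = 0.2, pore_size = 0.9, period = NULL,
                        n_cells = 1L, initial_layer = 0.010) {
  stopifnot(wall_thickness > 0, n_cells >= 1)
  if (is.null(period)) {
    key <- sprintf("%.6g|%.6g", pore_size, wall_thickness)
    if (is.null(.gyroid_cache[[key]])) {
      f <- function(L) gyroid_pore_diameter(L, wall_thickness) - pore_size
      .gyroid_cache[[key]] <- stats::uniroot(
        f, c(wall_thickness * 2.2, 6 * (pore_size + wall_thickness)),
        tol = 1e-3)$root
    }
    period <- .gyroid_cache[[key]]
  }
  if (wall_thickness >= period / 2)
    stop("invalid gyroid: need wall_thickness < period/2")
  tau <- gyroid_tau_for_wall(period, wall_thickness)
  structure(list(period = period, wall_thickness = wall_thickness,
                 pore_size = pore_size, n_cells = as.integer(n_cells),
                 initial_layer = initial_layer, tau = tau),
            class = "gyroid_spec")
}

#' @export
print.gyroid_spec <- function(x, ...) {
  cat(sprintf(
    "<gyroid_spec> period %0.4g mm, wall %g mm (tau = %0.4g), %d cell(s)/axis, initial layer %g mm\n",
    x$period, x$wall_thickness, x$tau, x$n_cells, x$initial_layer))
  invisible(x)
}

#' Signed distance field of a gyroid scaffold
#'
#' Voxelizes the gyroid wall `|F| <= tau` on `n_cells` unit cells per axis and
#' redistances to a true signed distance: psi > 0 in the pore space, psi <= 0
#' in the wall.
#'
#' @param spec a [gyroid_spec()].
#' @param spacing target grid spacing, mm; must satisfy
#'   `spacing <= wall_thickness/2`. The actual spacing is adjusted so the grid
#'   covers the periodic box exactly and is recorded in the returned field.
#' @return a [scalar_field()] holding psi.
#' @export
gyroid_sdf <- function(spec, spacing) {
  stopifnot(inherits(spec, "gyroid_spec"))
  if (spacing > spec$wall_thickness / 2 + 1e-12)
    stop("spacing too coarse: need spacing <= wall_thickness/2")
  ext <- spec$n_cells * spec$period
  n <- max(8L, round(ext / spacing)) + 1L
  xs <- seq(0, ext, length.out = n)
  h <- xs[2] - xs[1]
  XY <- expand.grid(x = xs, y = xs, z = xs)
  w <- abs(gyroid_F(XY$x, XY$y, XY$z, spec$period)) - spec$tau
  f <- scalar_field(array(w, dim = c(n, n, n)), h, origin = c(0, 0, 0))
  redistance(f)
}

#' Initial level set for neotissue growth
#'
#' Seeds a neotissue layer of the given thickness on the scaffold wall and
#' returns the evolving state. The level-set convention is phi > 0 in
#' neotissue, phi < 0 in the void, phi = 0 on the interface; the solid
#' material (psi <= 0) is masked out of the computation and the initial void
#' region (psi > 0) is remembered for filling-fraction quantification.
#'
#' @param domain a [scalar_field()] holding psi (signed distance into the
#'   void, from [channel_sdf()], [gyroid_sdf()] or [sphere_sdf()]).
#' @param layer initial neotissue layer thickness in mm (>= 0).
#' @return object of class `levelset_state`.
#' @export
initial_levelset <- function(domain, layer = 0) {
  stopifnot(inherits(domain, "scalar_field"), layer >= 0)
  psi <- domain$values
  if (layer >= max(psi))
    stop("initial layer fills the whole void: filling = 1, nothing to simulate")
  phi <- layer - psi
  f <- scalar_field(phi, domain$spacing, domain$origin)
  if (layer > 0) f <- redistance(f)  # offset surface: restore the distance property
  # sub-cell void coverage per node: nodes straddling the wall count
  # fractionally, so numerator and denominator of the filling fraction are
  # measured consistently
  void_w <- pmin(pmax(0.5 + psi / domain$spacing, 0), 1)
  state <- structure(
    list(phi = f, time = 0,
         void0_mask = psi > 0,
         void0_weights = void_w,
         solid_mask = psi <= 0,
         solid_values = phi[psi <= 0]),
    class = "levelset_state")
  state
}

#' @export
print.levelset_state <- function(x, ...) {
  cat(sprintf(
    "<levelset_state> t = %g days, %s grid, filling %0.3f of initial void\n",
    x$time, paste(dim(x$phi$values), collapse = " x "),
    filling_fraction(x)))
  invisible(x)
}
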