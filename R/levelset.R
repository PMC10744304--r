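#' Growth parameters
#'
#' Parameters of the curvature-driven growth law and its numerical controls.
#' The interface advances into the void with speed `A * kappa` wherever the
#' local mean curvature `kappa` (1/mm, positive where the void is concave as
#' seen from the neotissue) is positive, and is stationary elsewhere, so the
#' neotissue never retracts.
#'
#' @param A growth coefficient in mm^2/day (>= 0).
#' @param eps curvature/normal regularization coefficient in mm^2
#'   (default 1e-4): the normal and curvature fields are smoothed by solving
#'   (I - eps*Laplacian) u = f with homogeneous Neumann conditions.
#' @param max_step_frac maximum interface displacement per time step, as a
#'   fraction of the grid spacing (default 0.3; the adaptive step keeps the
#'   velocity-frozen-over-a-step error below the spatial error).
#' @param redistance_every number of steps between redistancing passes
#'   (default 5).
#' @param kappa_cap curvature clamp in 1/mm; `NULL` (default) uses
#'   `1/spacing` at simulation time. The clamp bounds the corner speed of
#'   polygonal channels, whose corners carry unbounded curvature.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(A, eps = 1e-4, max_step_frac = 0.3,
                          redistance_every = 5L, kappa_cap = NULL) {
  if (!is.numeric(A) || length(A) != 1L || A < 0)
    stop("`A` must be a single non-negative growth coefficient (mm^2/day)")
  stopifnot(eps >= 0, max_step_frac > 0, max_step_frac <= 1,
            redistance_every >= 1)
  structure(list(A = A, eps = eps, max_step_frac = max_step_frac,
                 redistance_every = as.integer(redistance_every),
                 kappa_cap = kappa_cap),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> A = %g mm^2/day, eps = %g mm^2, max step %g h, redistance every %d steps\n",
    x$A, x$eps, x$max_step_frac, x$redistance_every))
  invisible(x)
}

# Raw normalized gradient of phi, with a magnitude floor so that plateau
# regions (clamped far field) carry a near-zero rather than random normal.
raw_normal <- function(phi, h) {
  g <- grad_arr(phi, h)
  mag <- sqrt(Reduce(`+`, lapply(g, function(a) a * a)))
  lapply(g, function(a) a / pmax(mag, 1e-8))
}

#' Regularized interface normal field
#'
#' Computes the unit normal n = grad(phi)/|grad(phi)|, smoothed componentwise
#' by solving (I - eps*Laplacian) n = grad(phi)/|grad(phi)| with homogeneous
#' Neumann boundary conditions, then renormalized to unit length on the
#' narrow band. The normal points toward increasing phi, i.e. toward the
#' neotissue.
#'
#' @param phi a [scalar_field()] level-set function.
#' @param eps regularization coefficient, mm^2.
#' @return list of [scalar_field()]s, one per spatial component.
#' @export
normal_field <- function(phi, eps = 1e-4) {
  stopifnot(inherits(phi, "scalar_field"))
  h <- phi$spacing
  n <- raw_normal(phi$values, h)
  if (eps > 0) n <- lapply(n, helmholtz_solve, h = h, eps = eps)
  mag <- sqrt(Reduce(`+`, lapply(n, function(a) a * a)))
  # renormalize where the field is meaningful (near the band |n| ~ 1);
  # plateau regions keep their near-zero magnitude
  scale <- ifelse(mag > 0.5, mag, 1)
  n <- lapply(n, function(a) a / scale)
  lapply(n, scalar_field, spacing = h, origin = phi$origin)
}

#' Regularized mean curvature field
#'
#' kappa = div(n), smoothed by (I - eps*Laplacian) kappa = div(n) with
#' homogeneous Neumann conditions and clamped to `+/- kappa_cap`. Sign
#' convention: a circular or cylindrical void of radius r surrounded by
#' neotissue has kappa = +1/r at the interface; a spherical void has +2/r;
#' a flat wall has 0.
#'
#' @param phi a [scalar_field()] level-set function.
#' @param eps regularization coefficient, mm^2.
#' @param kappa_cap clamp in 1/mm; default `1/spacing`.
#' @param normal optional precomputed result of [normal_field()].
#' @return a [scalar_field()] of curvature values, 1/mm.
#' @export
curvature_field <- function(phi, eps = 1e-4, kappa_cap = NULL, normal = NULL) {
  stopifnot(inherits(phi, "scalar_field"))
  h <- phi$spacing
  if (is.null(kappa_cap)) kappa_cap <- 1 / h
  if (is.null(normal)) normal <- normal_field(phi, eps)
  dv <- div_arr(lapply(normal, `[[`, "values"), h)
  if (eps > 0) dv <- helmholtz_solve(dv, h, eps)
  dv <- pmin(pmax(dv, -kappa_cap), kappa_cap)
  scalar_field(dv, h, phi$origin)
}

#' Curvature-driven growth velocity
#'
#' V = A * g(kappa) * n with g(kappa) = -kappa where kappa > 0 and 0
#' elsewhere: where the void is locally concave from the neotissue side
#' (channel corners, circular pore walls) the interface advances into the
#' void; flat and convex regions are stationary. There is never retraction.
#'
#' @param kappa a [scalar_field()] from [curvature_field()].
#' @param n normal field (list of [scalar_field()]s) from [normal_field()].
#' @param A growth coefficient, mm^2/day (>= 0).
#' @return list of [scalar_field()] velocity components, mm/day.
#' @export
growth_velocity <- function(kappa, n, A) {
  if (A < 0) stop("`A` must be non-negative")
  g <- -pmax(kappa$values, 0)
  lapply(n, function(comp)
    scalar_field(A * g * comp$values, kappa$spacing, kappa$origin))
}

#' Advect a level-set field
#'
#' Solves d(phi)/dt + V . grad(phi) = 0 for one step of length `dt` by
#' semi-Lagrangian characteristic tracing with a midpoint (second-order)
#' departure point: phi(x, t+dt) = phi(x - dt * V(x - dt/2 * V(x)), t), using
#' bi/trilinear interpolation and clamping at the box boundary (homogeneous
#' Neumann). Optionally holds the solid region fixed.
#'
#' @param phi a [scalar_field()].
#' @param V velocity field: list of [scalar_field()] components, mm/day.
#' @param dt time step, days. Must satisfy `max|V| * dt <= spacing` (CFL-like
#'   displacement bound).
#' @param solid_mask optional logical array: nodes held at their current value.
#' @return the advected [scalar_field()].
#' @export
advect <- function(phi, V, dt, solid_mask = NULL) {
  stopifnot(inherits(phi, "scalar_field"), dt >= 0)
  h <- phi$spacing
  d <- dim(phi$values)
  nd <- length(d)
  vmax <- max(vapply(V, function(c) max(abs(c$values)), 0))
  if (vmax * dt > h + 1e-12)
    stop("CFL violation: max|V|*dt exceeds one grid spacing")
  if (vmax == 0 || dt == 0) return(phi)
  axes <- field_axes(phi)
  co <- lapply(seq_len(nd), function(k)
    switch(k,
           rep(axes[[1]], times = prod(d[-1])),
           rep(rep(axes[[2]], each = d[1]),
               times = if (nd == 3) d[3] else 1),
           rep(axes[[3]], each = d[1] * d[2])))
  mid <- vapply(seq_len(nd), function(k)
    co[[k]] - 0.5 * dt * as.vector(V[[k]]$values), numeric(prod(d)))
  dep <- vapply(seq_len(nd), function(k)
    co[[k]] - dt * interp_values(V[[k]]$values, h, phi$origin, mid),
    numeric(prod(d)))
  new_vals <- interp_values(phi$values, h, phi$origin, dep)
  dim(new_vals) <- d
  if (!is.null(solid_mask)) new_vals[solid_mask] <- phi$values[solid_mask]
  scalar_field(new_vals, h, phi$origin)
}

#' Redistance a level-set field
#'
#' Restores the signed-distance property |grad(phi)| = 1 without moving the
#' zero set (interface-adjacent nodes are pinned to their sub-cell interface
#' distance, obtained by linear interpolation along grid edges; the far field
#' is filled by iterative fast-sweeping solves of the eikonal equation).
#'
#' @param phi a [scalar_field()].
#' @param band optional clamp distance in mm: distances beyond `band` are
#'   clamped (useful inside the simulation loop where only the narrow band
#'   matters). Default `Inf` computes the full distance field.
#' @return a [scalar_field()] signed distance function with the same sign
#'   pattern. If the field has no zero crossing it is returned unchanged with
#'   attribute `empty_interface = TRUE`.
#' @export
redistance <- function(phi, band = Inf) {
  stopifnot(inherits(phi, "scalar_field"))
  v <- phi$values
  h <- phi$spacing
  d <- dim(v)
  nd <- length(d)
  big <- sum(d) * h * 10
  inv2 <- array(0, d)  # sum over axes of 1/dist_axis^2
  frozen <- array(FALSE, d)
  any_cross <- FALSE
  for (ax in seq_len(nd)) {
    ax_dist <- array(Inf, d)
    for (by in c(-1L, 1L)) {
      nb <- shift_arr(v, ax, by)
      cross <- (v > 0 & nb < 0) | (v < 0 & nb > 0)
      if (any(cross)) {
        any_cross <- TRUE
        sub <- h * abs(v) / (abs(v) + abs(nb))
        ax_dist[cross] <- pmin(ax_dist[cross], sub[cross])
        frozen <- frozen | cross
      }
    }
    has <- is.finite(ax_dist)
    inv2[has] <- inv2[has] + 1 / ax_dist[has]^2
  }
  # combine the per-axis crossings (exact for a planar interface): the
  # one-axis distance overestimates oblique interfaces by 1/cos(theta)
  dist <- array(big, d)
  dist[frozen] <- 1 / sqrt(inv2[frozen])
  frozen <- frozen | (v == 0)
  dist[v == 0] <- 0
  if (!any_cross && !any(v == 0)) {
    out <- phi
    attr(out, "empty_interface") <- TRUE
    return(out)
  }
  cap <- if (is.finite(band)) band else big
  n_iter <- min(ceiling(cap / h) + 2L, 2L * sum(d))
  free <- !frozen
  for (it in seq_len(n_iter)) {
    nbmin <- lapply(seq_len(nd), function(ax)
      pmin(shift_arr_big(dist, ax, -1L, big), shift_arr_big(dist, ax, 1L, big)))
    upd <- eikonal_update(nbmin, h)
    new_dist <- dist
    new_dist[free] <- pmin(dist[free], upd[free])
    delta <- max(abs(new_dist - dist))
    dist <- new_dist
    if (delta < 1e-4 * h) break
  }
  dist <- pmin(dist, cap)
  sgn <- ifelse(v >= 0, 1, -1)
  out <- scalar_field(sgn * dist, h, phi$origin)
  attr(out, "empty_interface") <- FALSE
  out
}

# One Jacobi pass of the eikonal update |grad d| = 1 from per-axis neighbour
# minima (Zhao's fast-sweeping local solver, vectorised).
eikonal_update <- function(nbmin, h) {
  nd <- length(nbmin)
  if (nd == 2L) {
    a <- pmin(nbmin[[1]], nbmin[[2]])
    b <- pmax(nbmin[[1]], nbmin[[2]])
    u1 <- a + h
    two <- u1 > b
    u <- u1
    if (any(two)) {
      s <- a[two] + b[two]
      q <- 2 * h^2 - (a[two] - b[two])^2
      u[two] <- (s + sqrt(pmax(q, 0))) / 2
    }
    u
  } else {
    # sort the three neighbour minima per node
    x <- nbmin[[1]]; y <- nbmin[[2]]; z <- nbmin[[3]]
    a <- pmin(x, y, z)
    c3 <- pmax(x, y, z)
    b <- x + y + z - a - c3
    u <- a + h
    two <- u > b
    if (any(two)) {
      s <- a[two] + b[two]
      q <- 2 * h^2 - (a[two] - b[two])^2
      u[two] <- (s + sqrt(pmax(q, 0))) / 2
    }
    three <- u > c3
    if (any(three)) {
      s <- a[three] + b[three] + c3[three]
      q <- s^2 - 3 * (a[three]^2 + b[three]^2 + c3[three]^2 - h^2)
      u[three] <- (s + sqrt(pmax(q, 0))) / 3
    }
    u
  }
}

#' Simulate curvature-driven neotissue growth
#'
#' Outer time loop: redistance (every `redistance_every` steps), regularized
#' normal and curvature, growth velocity, adaptive time step from the
#' maximum-displacement rule, semi-Lagrangian advection. The filling fraction
#' of the initial void is recorded at the requested days (and at every step
#' internally); the run terminates early once the void is essentially full
#' (filling >= 0.999), recording the time of full filling.
#'
#' @param state a [levelset_state] from [initial_levelset()].
#' @param params a [growth_params()].
#' @param t_end end time, days (> 0).
#' @param record_at days at which to record the filling fraction (default:
#'   integer days up to `t_end`).
#' @param snapshots if `TRUE`, keep a copy of phi at each recorded day
#'   (attribute `"snapshots"`).
#' @return a `filling_series` data frame with columns `time_days`,
#'   `filling_fraction` and `interface_area` (mm in 2D, mm^2 in 3D), with
#'   attributes `full_fill_time` (days or `NA`), `final_state`, and `steps`
#'   (the per-step time/filling log).
#' @export
simulate_growth <- function(state, params, t_end, record_at = NULL,
                            snapshots = FALSE) {
  stopifnot(inherits(state, "levelset_state"),
            inherits(params, "growth_params"), t_end > 0)
  h <- state$phi$spacing
  kcap <- if (is.null(params$kappa_cap)) 1 / h else params$kappa_cap
  record_at <- if (is.null(record_at)) seq_len(ceiling(t_end)) else
    sort(unique(record_at))
  record_at <- record_at[record_at > 0 & record_at <= t_end + 1e-9]
  if (!length(record_at) || max(record_at) < t_end - 1e-9)
    record_at <- c(record_at, t_end)
  band <- max(12 * h, 4 * h)

  phi <- state$phi
  t <- state$time
  fill <- filling_fraction_phi(phi, state$void0_weights)
  step_times <- t
  step_fills <- fill
  rec <- data.frame(time_days = numeric(0), filling_fraction = numeric(0),
                    interface_area = numeric(0))
  snaps <- list()
  full_fill_time <- NA_real_
  step_i <- 0L
  max_steps <- 200000L

  record_now <- function(tt) {
    rec[nrow(rec) + 1L, ] <<- list(tt, fill, interface_measure(phi))
    if (snapshots) snaps[[length(snaps) + 1L]] <<- phi
  }

  if (fill >= 0.999) full_fill_time <- t
  if (params$A == 0) {
    # the velocity is identically zero: the state is exactly stationary
    for (tt in record_at) record_now(tt)
    final_state <- state
    return(structure(rec,
                     class = c("filling_series", "data.frame"),
                     full_fill_time = full_fill_time,
                     final_state = final_state,
                     steps = data.frame(time_days = step_times,
                                        filling_fraction = step_fills),
                     snapshots = if (snapshots) snaps else NULL,
                     params = params))
  }
  while (is.na(full_fill_time) && t < t_end - 1e-9 && step_i < max_steps) {
    # The solid scaffold needs no pinning: the growth velocity points strictly
    # into the void, so the solid stays on the tissue side of the zero set and
    # its values track the distance to the receding interface.
    if (step_i %% params$redistance_every == 0L)
      phi <- redistance(phi, band = band)
    n <- normal_field(phi, params$eps)
    kappa <- curvature_field(phi, params$eps, kappa_cap = kcap, normal = n)
    V <- growth_velocity(kappa, n, params$A)
    # growth acts at the interface: zero the velocity outside the narrow band
    # (the redistanced far field is a clamped plateau whose normals carry no
    # information, and it is rebuilt at the next redistancing anyway)
    far <- abs(phi$values) > 8 * h
    V <- lapply(V, function(c) { c$values[far] <- 0; c })
    vmax <- max(vapply(V, function(c) max(abs(c$values)), 0))
    pending <- record_at[record_at > t + 1e-9]
    t_next <- if (length(pending)) pending[1] else t_end
    dt <- if (vmax > 0) params$max_step_frac * h / vmax else (t_next - t)
    dt <- min(dt, t_next - t)
    phi <- advect(phi, V, dt)
    if (!all(is.finite(phi$values)))
      stop("non-finite level-set values: simulation aborted")
    t <- t + dt
    step_i <- step_i + 1L
    fill_raw <- filling_fraction_phi(phi, state$void0_weights)
    # growth never retracts; redistancing may jitter the measured area by a
    # sub-cell amount, so the reported series is the running maximum while the
    # raw per-step values are kept in the step log
    fill <- max(fill, fill_raw)
    step_times <- c(step_times, t)
    step_fills <- c(step_fills, fill_raw)
    if (abs(t - t_next) < 1e-9 && t_next %in% record_at) record_now(t_next)
    if (is.na(full_fill_time) && fill >= 0.999) {
      full_fill_time <- t
      break
    }
  }
  # fill forward any remaining record days (void full or A = 0 stationary)
  for (tt in record_at[record_at > t + 1e-9]) {
    rec[nrow(rec) + 1L, ] <- list(tt, fill, interface_measure(phi))
    if (snapshots) snaps[[length(snaps) + 1L]] <- phi
  }
  final_state <- state
  final_state$phi <- phi
  final_state$time <- t
  structure(rec,
            class = c("filling_series", "data.frame"),
            full_fill_time = full_fill_time,
            final_state = final_state,
            steps = data.frame(time_days = step_times,
                               filling_fraction = step_fills),
            snapshots = if (snapshots) snaps else NULL,
            params = params)
}

#' @export
print.filling_series <- function(x, ...) {
  fft <- attr(x, "full_fill_time")
  cat(sprintf("<filling_series> %d recorded times, final filling %0.3f%s\n",
              nrow(x), x$filling_fraction[nrow(x)],
              if (!is.na(fft)) sprintf(", full at %0.2f days", fft) else ""))
  print.data.frame(x, ...)
  invisible(x)
}

# Filling fraction from a raw phi field and sub-cell void coverage weights
# (internal hot path). Per node, the void part of the cell not yet reached by
# tissue is clip(0.5 - phi/h): the tissue-in-void part is the void coverage
# minus that, floored at zero.
filling_fraction_phi <- function(phi, void0_weights) {
  h <- phi$spacing
  not_tissue <- pmin(pmax(0.5 - phi$values / h, 0), 1)
  tissue_in_void <- pmax(void0_weights - not_tissue, 0)
  sum(tissue_in_void) / sum(void0_weights)
}

# interface length (2D) or area (3D) by the co-area formula with a smoothed
# delta function of half-width 1.5 h
interface_measure <- function(phi) {
  h <- phi$spacing
  w <- 1.5 * h
  v <- phi$values
  delta <- ifelse(abs(v) < w, (1 + cos(pi * v / w)) / (2 * w), 0)
  g <- grad_arr(v, h)
  mag <- sqrt(Reduce(`+`, lapply(g, function(a) a * a)))
  sum(delta * mag) * h^length(dim(v))
}
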