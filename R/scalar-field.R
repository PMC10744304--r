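#' Scalar fields on a regular grid
#'
#' A `scalar_field` carries nodal values on a uniform 2D or 3D grid together
#' with the grid origin and spacing (mm). It is the discrete carrier for the
#' level-set function phi, geometry distance functions psi, and curvature
#' fields.
#'
#' @param values numeric matrix (2D) or 3D array of nodal values; the first
#'   index runs along x, the second along y (and the third along z).
#' @param spacing grid spacing in mm (uniform across axes).
#' @param origin numeric vector of the coordinates of node `[1,1(,1)]`, mm.
#' @return an object of class `scalar_field`.
#' @export
scalar_field <- function(values, spacing, origin = NULL) {
  if (is.null(dim(values))) stop("`values` must be a matrix or 3D array")
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("only 2D and 3D fields are supported")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number")
  if (is.null(origin)) origin <- rep(0, nd)
  if (length(origin) != nd) stop("`origin` must have one coordinate per axis")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         dim = nd),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scalar_field> %s grid, spacing %g mm, origin (%s)\n",
              paste(d, collapse = " x "), x$spacing,
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  values in [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Grid node coordinates along each axis
#' @param field a `scalar_field`.
#' @return list of numeric vectors, one per axis.
#' @export
field_axes <- function(field) {
  d <- dim(field$values)
  lapply(seq_along(d), function(k)
    field$origin[k] + (seq_len(d[k]) - 1) * field$spacing)
}

#' Interpolate a field at arbitrary points
#'
#' Bilinear (2D) or trilinear (3D) interpolation with clamping at the domain
#' boundary (consistent with homogeneous Neumann conditions).
#'
#' @param field a `scalar_field`.
#' @param points numeric matrix with one row per point and one column per axis
#'   (mm), or a numeric vector for a single point.
#' @return numeric vector of interpolated values.
#' @export
field_at <- function(field, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  interp_values(field$values, field$spacing, field$origin, points)
}

# --- internal array helpers -------------------------------------------------

# Shift an array by `by` cells along `axis`, replicating the boundary slice
# (the discrete analogue of a homogeneous Neumann extension).
shift_arr <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Shifted neighbour values with a large constant outside the domain
# (used by the eikonal sweeps, where a missing neighbour carries no bound).
shift_arr_big <- function(a, axis, by, big) {
  out <- shift_arr(a, axis, by)
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- if (by < 0) seq_len(-by) else (d[axis] - by + 1L):d[axis]
  do.call(`[<-`, c(list(out), idx, list(value = big)))
}

# Central-difference gradient with replicated edges; returns list of arrays.
grad_arr <- function(a, h) {
  nd <- length(dim(a))
  lapply(seq_len(nd), function(ax)
    (shift_arr(a, ax, 1L) - shift_arr(a, ax, -1L)) / (2 * h))
}

# Divergence of a list of component arrays (central differences).
div_arr <- function(comps, h) {
  out <- 0
  for (ax in seq_along(comps))
    out <- out + (shift_arr(comps[[ax]], ax, 1L) -
                    shift_arr(comps[[ax]], ax, -1L)) / (2 * h)
  out
}

# Bi/trilinear interpolation of array values at physical points (rows).
interp_values <- function(a, h, origin, points) {
  d <- dim(a)
  nd <- length(d)
  # fractional index coordinates, clamped to the grid
  fi <- lapply(seq_len(nd), function(k) {
    u <- (points[, k] - origin[k]) / h
    pmin(pmax(u, 0), d[k] - 1)
  })
  i0 <- lapply(seq_len(nd), function(k) pmin(floor(fi[[k]]), d[k] - 2) + 1)
  fr <- lapply(seq_len(nd), function(k) fi[[k]] - (i0[[k]] - 1))
  if (nd == 2L) {
    g <- function(ii, jj) a[cbind(ii, jj)]
    i <- i0[[1]]; j <- i0[[2]]; fx <- fr[[1]]; fy <- fr[[2]]
    (1 - fx) * (1 - fy) * g(i, j) + fx * (1 - fy) * g(i + 1, j) +
      (1 - fx) * fy * g(i, j + 1) + fx * fy * g(i + 1, j + 1)
  } else {
    g <- function(ii, jj, kk) a[cbind(ii, jj, kk)]
    i <- i0[[1]]; j <- i0[[2]]; k <- i0[[3]]
    fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
    (1 - fx) * (1 - fy) * (1 - fz) * g(i, j, k) +
      fx * (1 - fy) * (1 - fz) * g(i + 1, j, k) +
      (1 - fx) * fy * (1 - fz) * g(i, j + 1, k) +
      fx * fy * (1 - fz) * g(i + 1, j + 1, k) +
      (1 - fx) * (1 - fy) * fz * g(i, j, k + 1) +
      fx * (1 - fy) * fz * g(i + 1, j, k + 1) +
      (1 - fx) * fy * fz * g(i, j + 1, k + 1) +
      fx * fy * fz * g(i + 1, j + 1, k + 1)
  }
}

# --- spectral Helmholtz solve (I - eps * Laplacian) u = f, Neumann BC -------

# Orthonormal DCT-II matrices are cached per grid size: the half-sample
# reflection they encode diagonalizes the Neumann Laplacian on the node grid.
.dct_cache <- new.env(parent = emptyenv())

dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  j <- seq_len(n) - 1
  C <- sqrt(2 / n) * cos(outer(j, j + 0.5) * pi / n)
  C[1, ] <- C[1, ] / sqrt(2)
  .dct_cache[[key]] <- C
  C
}

dct_eigen <- function(n, h) (2 * cos(pi * (seq_len(n) - 1) / n) - 2) / h^2

# Apply matrix M along axis `ax` of array a (mode product).
mode_mult <- function(a, M, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(seq_along(d), ax))
  b <- aperm(a, perm)
  dim(b) <- c(d[ax], prod(d[-ax]))
  b <- M %*% b
  dim(b) <- d[perm]
  aperm(b, order(perm))
}

# Exact solve of (I - eps * Laplacian) u = f with homogeneous Neumann BC.
# The resolvent diagonal 1/(1 - eps*(lam_x + lam_y (+ lam_z))) is cached per
# grid signature: it is reused every step of a simulation.
.helm_cache <- new.env(parent = emptyenv())

helmholtz_solve <- function(f, h, eps) {
  if (eps <= 0) return(f)
  d <- dim(f)
  key <- paste(c(d, signif(h, 10), signif(eps, 10)), collapse = "|")
  denom <- .helm_cache[[key]]
  if (is.null(denom)) {
    lams <- lapply(seq_along(d), function(ax) dct_eigen(d[ax], h))
    tot <- if (length(d) == 2L) {
      outer(lams[[1]], lams[[2]], `+`)
    } else {
      outer(outer(lams[[1]], lams[[2]], `+`), lams[[3]], `+`)
    }
    denom <- 1 / (1 - eps * tot)
    .helm_cache[[key]] <- denom
  }
  u <- f
  for (ax in seq_along(d)) u <- mode_mult(u, dct_matrix(d[ax]), ax)
  u <- u * denom
  for (ax in seq_along(d)) u <- mode_mult(u, t(dct_matrix(d[ax])), ax)
  u
}
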