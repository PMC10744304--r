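#' Filling fraction of the initial void
#'
#' Fraction of the initial void region (channel or pore space at day 0,
#' before seeding) currently occupied by neotissue (phi > 0), with sub-cell
#' correction: nodes within half a spacing of the interface contribute
#' fractionally, by linear interpolation of phi. The seeded initial layer
#' counts as filled tissue. Deterministic for a given state.
#'
#' @param state a [levelset_state].
#' @return filling fraction in `[0, 1]`.
#' @export
filling_fraction <- function(state) {
  stopifnot(inherits(state, "levelset_state"))
  if (!any(state$void0_mask)) stop("empty initial void region")
  filling_fraction_phi(state$phi, state$void0_weights)
}

#' Circularity (2D) or sphericity (3D) of the void region
#'
#' In 2D, the isoperimetric ratio 4*pi*Area/Perimeter^2 of the void region
#' enclosed by the phi = 0 contour (marching squares); 1 for a circle.
#' In 3D, the sphericity analogue pi^(1/3)*(6V)^(2/3)/S with the interface
#' area S from the co-area formula. Curvature-driven growth rounds polygonal
#' voids, so this diagnostic increases toward 1 over time.
#'
#' @param state a [levelset_state].
#' @return a value in `(0, 1]` (up to small discretization slack).
#' @export
circularity <- function(state) {
  stopifnot(inherits(state, "levelset_state"))
  phi <- state$phi
  v <- phi$values
  if (all(v > 0) || all(v < 0)) stop("empty interface")
  if (length(dim(v)) == 2L) {
    ax <- field_axes(phi)
    cl <- grDevices::contourLines(ax[[1]], ax[[2]], v, levels = 0)
    if (!length(cl)) stop("empty interface")
    area <- 0
    perim <- 0
    for (cc in cl) {
      x <- cc$x; y <- cc$y
      # close the loop if needed
      if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
        x <- c(x, x[1]); y <- c(y, y[1])
      }
      n <- length(x)
      area <- area + abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
      perim <- perim + sum(sqrt(diff(x)^2 + diff(y)^2))
    }
    4 * pi * area / perim^2
  } else {
    h <- phi$spacing
    w <- pmin(pmax(0.5 - v / h, 0), 1)  # void indicator with sub-cell ramp
    V <- sum(w[state$void0_mask]) * h^3
    S <- interface_measure(phi)
    pi^(1 / 3) * (6 * V)^(2 / 3) / S
  }
}
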