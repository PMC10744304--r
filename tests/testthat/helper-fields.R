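# Shared fixtures, built in code.

# Analytic signed distance of a circular void of radius r0 (void negative
# phi, neotissue outside), on a grid of spacing h covering radius `extent`.
radial_phi <- function(r0, h, extent = r0 * 1.2) {
  m <- ceiling(extent / h)
  xs <- (-m:m) * h
  r <- sqrt(outer(xs^2, xs^2, `+`))
  scalar_field(r - r0, h, origin = c(xs[1], xs[1]))
}

# Brute-force distance from grid nodes to a polyline (the independent oracle
# for zero-set displacement checks): min over segments of point-segment
# distance.
dist_to_polyline <- function(px, py, x, y) {
  out <- rep(Inf, length(px))
  for (i in seq_len(length(x) - 1)) {
    ex <- x[i + 1] - x[i]; ey <- y[i + 1] - y[i]
    len2 <- ex^2 + ey^2
    t <- pmin(pmax(((px - x[i]) * ex + (py - y[i]) * ey) / len2, 0), 1)
    out <- pmin(out, sqrt((px - (x[i] + t * ex))^2 + (py - (y[i] + t * ey))^2))
  }
  out
}

# Extract the phi = 0 contour(s) of a 2D field as a list of polylines.
zero_contours <- function(field) {
  ax <- field_axes(field)
  grDevices::contourLines(ax[[1]], ax[[2]], field$values, levels = 0)
}

# Mean radius of the void boundary (2D): average distance of the phi = 0
# contour points from the origin.
void_radius <- function(field) {
  cl <- zero_contours(field)
  mean(unlist(lapply(cl, function(cc) sqrt(cc$x^2 + cc$y^2))))
}

# Coarse-but-fast simulation config for tests.
test_config <- function(cells = 30) sim_config(cells_across = cells)
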