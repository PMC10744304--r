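#' Simulation configuration for calibration
#'
#' Fixes the numerical setup shared by all simulations inside one calibration:
#' grid resolution relative to the channel size, initial seeded layer, and the
#' regularization coefficient.
#'
#' @param cells_across number of grid cells across the channel size `d`
#'   (spacing = d / cells_across; default 50).
#' @param layer initial neotissue layer thickness, mm (default 0.010 mm,
#'   matching near-confluent seeding of the disks).
#' @param eps regularization coefficient, mm^2.
#' @param pooled_shapes shapes averaged when an observation row is pooled
#'   across cross-sections.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(cells_across = 50, layer = 0.010, eps = 1e-4,
                       pooled_shapes = c("triangle", "square", "hexagon",
                                         "circle")) {
  stopifnot(cells_across >= 20, layer >= 0, eps >= 0)
  structure(list(cells_across = cells_across, layer = layer, eps = eps,
                 pooled_shapes = pooled_shapes),
            class = "sim_config")
}

#' RMSE calibration objective
#'
#' Runs the growth simulation with coefficient `A` for every distinct geometry
#' in the observation table, records the simulated percent filling at the
#' observed days, and returns the root-mean-square error against the observed
#' percentages (percentage points). Rows with `shape == "pooled"` are compared
#' against the mean simulated filling over `config$pooled_shapes`.
#' Deterministic given `A` and the configuration.
#'
#' @param A growth coefficient, mm^2/day.
#' @param obs an observation table (see [load_observations()]).
#' @param config a [sim_config()].
#' @return RMSE in percentage points.
#' @export
rmse_objective <- function(A, obs, config = sim_config()) {
  stopifnot(nrow(obs) > 0)
  days <- sort(unique(obs$day))
  sim_pct <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    shapes <- if (obs$shape[i] == "pooled") config$pooled_shapes else
      obs$shape[i]
    vals <- vapply(shapes, function(s)
      sim_channel_filling(s, obs$d_mm[i], A, days, config)[
        as.character(obs$day[i])], 0)
    sim_pct[i] <- mean(vals)
  }
  sqrt(mean((sim_pct - obs$filling_pct)^2))
}

# --- sequential model-based optimization (GP surrogate + EI) ----------------

# Fit a zero-mean GP with squared-exponential kernel to standardized data;
# the lengthscale is picked from a small grid by marginal likelihood.
gp_fit <- function(x, y) {
  ys <- (y - mean(y)) / max(stats::sd(y), 1e-12)
  D2 <- outer(x, x, `-`)^2
  best <- NULL
  for (ell in c(0.03, 0.06, 0.12, 0.25, 0.5)) {
    K <- exp(-0.5 * D2 / ell^2) + diag(1e-6, length(x))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll)
      best <- list(ell = ell, chol = ch, alpha = alpha, ll = ll,
                   x = x, ymean = mean(y), ysd = max(stats::sd(y), 1e-12))
  }
  best
}

gp_predict <- function(fit, xnew) {
  k <- exp(-0.5 * outer(xnew, fit$x, `-`)^2 / fit$ell^2)
  mu <- as.numeric(k %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(k))
  s2 <- pmax(1 + 1e-6 - colSums(v^2), 1e-12)
  list(mean = mu * fit$ysd + fit$ymean, sd = sqrt(s2) * fit$ysd)
}

#' Minimize a scalar objective by sequential model-based optimization
#'
#' One-dimensional Bayesian optimization: a Gaussian-process surrogate
#' (squared-exponential kernel) is fit to all past evaluations and the next
#' point is chosen by maximizing expected improvement over a dense candidate
#' grid. With `log_scale = TRUE` (the default) the search runs over
#' `log10(parameter)`. Fully reproducible for a fixed seed.
#'
#' @param fn objective function of one numeric argument.
#' @param lower,upper search bounds (original scale; both > 0 when
#'   `log_scale`).
#' @param n_iter total number of objective evaluations (>= 5).
#' @param seed integer seed.
#' @param log_scale search over log10 of the parameter.
#' @param n_init size of the initial space-filling design (default 5).
#' @return list with `x_star`, `y_star`, `trace` (data frame `param`,
#'   `objective` in evaluation order), `n_evals`, `seed`, `surrogate`.
#' @export
smbo_minimize <- function(fn, lower, upper, n_iter = 25, seed = 1L,
                          log_scale = TRUE, n_init = 5L) {
  stopifnot(lower < upper, n_iter >= n_init, n_init >= 2)
  if (log_scale) stopifnot(lower > 0)
  to_x <- if (log_scale) function(p) (log10(p) - log10(lower)) /
    (log10(upper) - log10(lower)) else
      function(p) (p - lower) / (upper - lower)
  to_p <- if (log_scale) function(x) 10^(log10(lower) +
    x * (log10(upper) - log10(lower))) else
      function(x) lower + x * (upper - lower)
  rng <- local_rng(seed)

  # jittered space-filling initial design on [0, 1]
  x <- (seq_len(n_init) - 0.5) / n_init +
    (rng$runif(n_init) - 0.5) * 0.6 / n_init
  x <- pmin(pmax(x, 0), 1)
  y <- vapply(x, function(xx) fn(to_p(xx)), 0)
  if (!all(is.finite(y))) stop("non-finite objective in the initial design")

  cand0 <- seq(0, 1, length.out = 2001)
  while (length(x) < n_iter) {
    fit <- gp_fit(x, y)
    xn <- if (is.null(fit)) {
      rng$runif(1)
    } else {
      cand <- pmin(pmax(cand0 + (rng$runif(length(cand0)) - 0.5) * 5e-4,
                        0), 1)
      pr <- gp_predict(fit, cand)
      ymin <- min(y)
      z <- (ymin - pr$mean) / pr$sd
      ei <- (ymin - pr$mean) * stats::pnorm(z) + pr$sd * stats::dnorm(z)
      # avoid re-evaluating an existing point
      ei[vapply(cand, function(cc) any(abs(cc - x) < 1e-6), TRUE)] <- -Inf
      cand[which.max(ei)]
    }
    yn <- fn(to_p(xn))
    if (!is.finite(yn)) stop("non-finite objective at parameter ", to_p(xn))
    x <- c(x, xn)
    y <- c(y, yn)
  }
  best <- which.min(y)
  list(x_star = to_p(x[best]), y_star = y[best],
       trace = data.frame(param = to_p(x), objective = y),
       n_evals = length(x), seed = seed,
       surrogate = "Gaussian process (squared-exponential) + expected improvement, log10 scale")
}

#' Bayesian calibration of the growth coefficient
#'
#' Sequential model-based optimization of the growth coefficient `A` over
#' `log10(A)` against an observation table, minimizing the RMSE between
#' simulated and observed filling percentages at the observed days (see
#' [rmse_objective()]).
#'
#' @param obs observation table; ignored when `objective` is supplied.
#' @param bounds search bounds for A, mm^2/day (default `c(1e-4, 1)`: spans
#'   full-fill times from under a day to over a year for 1 mm channels).
#' @param n_iter total objective evaluations (default 25, >= 10 recommended).
#' @param seed integer seed (reproducible trace).
#' @param config a [sim_config()].
#' @param objective optional objective function of `A` overriding the RMSE
#'   objective (used for analytic checks of the optimizer).
#' @return a `calibration_result`: list with `A_star`, `objective_star`,
#'   `trace`, `n_evals`, `seed`, `surrogate`.
#' @export
bayes_optimize <- function(obs = NULL, bounds = c(1e-4, 1), n_iter = 25,
                           seed = 1L, config = sim_config(),
                           objective = NULL) {
  if (is.null(objective)) {
    stopifnot(!is.null(obs), nrow(obs) > 0)
    objective <- function(A) rmse_objective(A, obs, config)
  }
  res <- smbo_minimize(objective, bounds[1], bounds[2], n_iter = n_iter,
                       seed = seed, log_scale = TRUE)
  structure(list(A_star = res$x_star, objective_star = res$y_star,
                 trace = res$trace, n_evals = res$n_evals, seed = seed,
                 bounds = bounds, surrogate = res$surrogate),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> A* = %0.5g mm^2/day, objective %0.3f (%d evaluations, seed %d)\n",
    x$A_star, x$objective_star, x$n_evals, x$seed))
  invisible(x)
}

#' Fit the curvature-driven growth model to filling observations
#'
#' The central model-fitting routine: calibrates the growth coefficient `A`
#' (mm^2/day) of the curvature-driven neotissue growth law by Bayesian
#' optimization against observed channel-filling percentages, and returns a
#' fitted-model object with the usual accessors (`coef`, `summary`,
#' `predict`, `residuals`, `plot`, `simulate`).
#'
#' @param obs an observation table (see [load_observations()]); alternatively
#'   give `material` to use the packaged observations.
#' @param material optional material name (`"HAp"`, `"TCP"`, `"BCP"`) whose
#'   packaged observations are used when `obs` is missing.
#' @param bounds,n_iter,seed,config passed to [bayes_optimize()].
#' @return an object of class `growth_fit`.
#' @export
calibrate_growth <- function(obs = NULL, material = NULL,
                             bounds = c(1e-4, 1), n_iter = 25, seed = 1L,
                             config = sim_config()) {
  if (is.null(obs)) {
    stopifnot(!is.null(material))
    obs <- load_observations(material)
  }
  cal <- bayes_optimize(obs, bounds = bounds, n_iter = n_iter, seed = seed,
                        config = config)
  fitted_pct <- fitted_filling(cal$A_star, obs, config)
  structure(list(A_star = cal$A_star, objective_star = cal$objective_star,
                 trace = cal$trace, n_evals = cal$n_evals, seed = seed,
                 bounds = bounds, surrogate = cal$surrogate,
                 observations = obs, fitted_pct = fitted_pct,
                 sim_config = config,
                 material = if (!is.null(material)) material else
                   paste(unique(obs$material), collapse = "+")),
            class = "growth_fit")
}

fitted_filling <- function(A, obs, config) {
  days <- sort(unique(obs$day))
  vapply(seq_len(nrow(obs)), function(i) {
    shapes <- if (obs$shape[i] == "pooled") config$pooled_shapes else
      obs$shape[i]
    mean(vapply(shapes, function(s)
      sim_channel_filling(s, obs$d_mm[i], A, days, config)[
        as.character(obs$day[i])], 0))
  }, 0)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Curvature-driven neotissue growth model\n")
  cat(sprintf("  material:     %s\n", x$material))
  cat(sprintf("  A (growth coefficient): %0.5g mm^2/day\n", x$A_star))
  cat(sprintf("  RMSE at optimum: %0.2f percentage points\n",
              x$objective_star))
  cat(sprintf("  calibration: %d evaluations, seed %d\n", x$n_evals, x$seed))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) c(A = object$A_star)

#' @export
residuals.growth_fit <- function(object, ...) {
  object$observations$filling_pct - object$fitted_pct
}

#' @export
fitted.growth_fit <- function(object, ...) object$fitted_pct

#' @export
summary.growth_fit <- function(object, ...) {
  tab <- object$observations
  tab$fitted_pct <- object$fitted_pct
  tab$residual <- tab$filling_pct - tab$fitted_pct
  out <- list(A_star = object$A_star, rmse = object$objective_star,
              n_evals = object$n_evals, seed = object$seed,
              surrogate = object$surrogate, table = tab)
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat(sprintf("A* = %0.5g mm^2/day; RMSE = %0.2f pp; %d evaluations (%s)\n\n",
              x$A_star, x$rmse, x$n_evals, x$surrogate))
  print(x$table, digits = 4)
  invisible(x)
}

#' Predict channel filling from a fitted growth model
#'
#' Simulates the calibrated model for new channel geometries and days.
#'
#' @param object a `growth_fit`.
#' @param newdata data frame with columns `shape`, `d_mm` and `day`.
#' @param ... unused.
#' @return `newdata` with an added `filling_pct` column.
#' @export
predict.growth_fit <- function(object, newdata, ...) {
  stopifnot(all(c("shape", "d_mm", "day") %in% names(newdata)))
  cfg <- object$sim_config
  newdata$filling_pct <- vapply(seq_len(nrow(newdata)), function(i) {
    days <- sort(unique(newdata$day[newdata$shape == newdata$shape[i] &
                                      newdata$d_mm == newdata$d_mm[i]]))
    sim_channel_filling(newdata$shape[i], newdata$d_mm[i], object$A_star,
                        days, cfg)[as.character(newdata$day[i])]
  }, 0)
  newdata
}

#' @export
plot.growth_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  tr <- x$trace
  graphics::plot(tr$param, tr$objective, log = "x",
                 xlab = "A (mm^2/day)", ylab = "RMSE (pp)",
                 main = "Calibration trace", pch = 19, col = "grey40")
  graphics::abline(v = x$A_star, col = "red3", lty = 2)
  graphics::plot(x$fitted_pct, x$observations$filling_pct,
                 xlab = "simulated filling (%)", ylab = "observed filling (%)",
                 main = sprintf("A* = %0.4g", x$A_star), pch = 19)
  graphics::abline(0, 1, col = "grey60")
  invisible(x)
}

#' Simulate pseudo observation tables from a fitted model
#'
#' Generates synthetic observation tables at the calibrated coefficient, with
#' optional observation noise (see [generate_pseudo_observations()]).
#'
#' @param object a `growth_fit`.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param geometries data frame of `shape`, `d_mm` (default: the distinct
#'   pooled geometries expanded over the pooled shapes).
#' @param noise_sd noise standard deviation, percentage points.
#' @param ... unused.
#' @return a list of observation tables (a single table when `nsim = 1`).
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = 1L,
                                geometries = NULL, noise_sd = 0, ...) {
  if (is.null(geometries)) {
    ds <- unique(object$observations$d_mm)
    geometries <- expand.grid(shape = object$sim_config$pooled_shapes,
                              d_mm = ds, stringsAsFactors = FALSE)
  }
  days <- sort(unique(object$observations$day))
  out <- lapply(seq_len(nsim), function(k)
    generate_pseudo_observations(object$A_star, geometries, days = days,
                                 noise_sd = noise_sd, seed = seed + k - 1L,
                                 config = object$sim_config))
  if (nsim == 1) out[[1]] else out
}
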