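#' Packaged channel-filling observations
#'
#' Percent filling of the disk channels with neotissue at days 10 and 21 of
#' in vitro culture, pooled across the four cross-section shapes, for channel
#' sizes 0.7 mm and 1 mm and the three calcium-phosphate ceramics:
#' hydroxyapatite (HAp), tricalcium phosphate (TCP), and their 60/40 biphasic
#' blend (BCP). These are the values the growth coefficient is calibrated
#' against.
#'
#' @param material `"HAp"`, `"TCP"`, `"BCP"`, or `"all"`.
#' @return an observation table: data frame with columns `material`, `shape`
#'   (`"pooled"`), `d_mm`, `day`, `filling_pct`.
#' @export
load_observations <- function(material = c("HAp", "TCP", "BCP", "all")) {
  material <- match.arg(material)
  path <- system.file("extdata", "channel_filling_observations.csv",
                      package = "neotissue", mustWork = TRUE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (material != "all") obs <- obs[obs$material == material, ]
  rownames(obs) <- NULL
  obs
}

# simulation cache shared by the pseudo-data generator and objective probes:
# one entry per (shape, d, A, max day, grid/layer config)
.sim_cache <- new.env(parent = emptyenv())

sim_channel_filling <- function(shape, d, A, days, config) {
  key <- sprintf("%s|%.8g|%.10g|%.8g|%d|%.6g|%.6g", shape, d, A, max(days),
                 config$cells_across, config$layer, config$eps)
  hit <- .sim_cache[[key]]
  if (!is.null(hit) && all(as.character(days) %in% names(hit)))
    return(hit[as.character(days)])
  spacing <- d / config$cells_across
  field <- channel_sdf(channel_spec(shape, d), spacing)
  state <- initial_levelset(field, config$layer)
  params <- growth_params(A, eps = config$eps)
  sim <- simulate_growth(state, params, t_end = max(days), record_at = days)
  out <- 100 * sim$filling_fraction
  names(out) <- as.character(sim$time_days)
  .sim_cache[[key]] <- out
  out[as.character(days)]
}

#' Generate synthetic observation tables from a known growth coefficient
#'
#' Runs the growth simulation at `A_true` for each requested geometry, samples
#' the percent filling at the given days, and adds seeded Gaussian noise
#' (clipped to `[0, 100]`). Used for parameter-recovery experiments: the
#' generating simulator is the oracle.
#'
#' @param A_true growth coefficient used to generate the data, mm^2/day.
#' @param geometries a data frame with columns `shape` and `d_mm` (one row per
#'   channel geometry), or a list of [channel_spec()] objects.
#' @param days observation days (default `c(10, 21)`).
#' @param noise_sd standard deviation of the added noise, percentage points.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param config a [sim_config()] fixing grid resolution and initial layer.
#' @return an observation table (same columns as [load_observations()], with
#'   `material = "synthetic"`).
#' @export
generate_pseudo_observations <- function(A_true, geometries,
                                         days = c(10, 21), noise_sd = 0,
                                         seed = 1L,
                                         config = sim_config()) {
  stopifnot(noise_sd >= 0, A_true >= 0)
  if (inherits(geometries, "channel_spec")) geometries <- list(geometries)
  if (is.list(geometries) && !is.data.frame(geometries)) {
    geometries <- data.frame(
      shape = vapply(geometries, `[[`, "", "shape"),
      d_mm = vapply(geometries, `[[`, 0, "d"))
  }
  stopifnot(nrow(geometries) > 0)
  rows <- list()
  for (i in seq_len(nrow(geometries))) {
    filling <- sim_channel_filling(geometries$shape[i], geometries$d_mm[i],
                                   A_true, days, config)
    rows[[i]] <- data.frame(material = "synthetic",
                            shape = geometries$shape[i],
                            d_mm = geometries$d_mm[i],
                            day = days,
                            filling_pct = as.numeric(filling))
  }
  obs <- do.call(rbind, rows)
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    obs$filling_pct <- pmin(pmax(
      obs$filling_pct + rng$rnorm(nrow(obs), 0, noise_sd), 0), 100)
  }
  rownames(obs) <- NULL
  obs
}

# Seeded RNG isolated from the global stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }
  draw <- function(fn, ...) {
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    restore()
    out
  }
  restore()
  list(
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    sample_int = function(n, size) draw(base::sample.int, n, size)
  )
}
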