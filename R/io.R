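#' Write a filling series to CSV
#'
#' Columns `time_days`, `filling_fraction`, `interface_area`.
#'
#' @param series a `filling_series` from [simulate_growth()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filling_series <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("time_days", "filling_fraction",
                                             "interface_area")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a scalar field as VTK ImageData (.vti)
#'
#' ASCII XML VTK ImageData, loadable in ParaView for inspection of phi,
#' curvature, or geometry distance fields.
#'
#' @param field a [scalar_field()].
#' @param path output file path (conventionally `.vti`).
#' @param name name of the point-data array (default `"phi"`).
#' @return `path`, invisibly.
#' @export
write_vti <- function(field, path, name = "phi") {
  stopifnot(inherits(field, "scalar_field"))
  d <- dim(field$values)
  nd <- length(d)
  ext3 <- c(d, rep(1L, 3 - nd))
  origin3 <- c(field$origin, rep(0, 3 - nd))
  whole <- paste(vapply(ext3, function(n) sprintf("0 %d", n - 1L), ""),
                 collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <ImageData WholeExtent="%s" Origin="%g %g %g" Spacing="%g %g %g">',
            whole, origin3[1], origin3[2], origin3[3],
            field$spacing, field$spacing, field$spacing),
    sprintf('    <Piece Extent="%s">', whole),
    '      <PointData Scalars="field">',
    sprintf('        <DataArray type="Float64" Name="%s" format="ascii">',
            name)), con)
  # VTK expects x fastest, then y, then z: matches R's column-major layout
  vals <- as.vector(field$values)
  writeLines(paste(formatC(vals, format = "g", digits = 8), collapse = " "),
             con)
  writeLines(c('        </DataArray>', '      </PointData>', '    </Piece>',
               '  </ImageData>', '</VTKFile>'), con)
  invisible(path)
}

config_error <- function(msg) {
  stop(structure(class = c("neotissue_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

get_field <- function(config, path, default = NULL, required = is.null(default)) {
  node <- config
  for (key in path) {
    if (!is.list(node) || is.null(node[[key]])) {
      if (required)
        config_error(sprintf("missing required config field: %s",
                             paste(path, collapse = ".")))
      return(default)
    }
    node <- node[[key]]
  }
  node
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or a YAML file path")
  config
}

run_metadata <- function(config, extra = list()) {
  c(list(package = "neotissue",
         version = as.character(utils::packageVersion("neotissue")),
         config = config),
    extra)
}

#' Run a channel-filling simulation from a configuration
#'
#' Executes the full pipeline geometry -> initial level set -> growth
#' simulation -> quantification and writes the filling series (CSV), a
#' metadata JSON sidecar sufficient to re-run the simulation, and optional
#' field snapshots (.vti).
#'
#' Config keys (YAML mapping or R list): `geometry` (`shape`, `d`, optional
#' `height`), `params` (`A`, optional `eps`, `layer`), `output` (optional
#' `dir`, `record_days`, `snapshots`), optional `grid` (`cells_across`),
#' `t_end` (default 21), `seed`.
#'
#' @param config an R list or path to a YAML file.
#' @return the `filling_series`, invisibly, with attribute `paths` naming the
#'   written artifacts (when an output dir is configured).
#' @export
run_channel <- function(config) {
  config <- read_config(config)
  shape <- get_field(config, c("geometry", "shape"))
  d <- get_field(config, c("geometry", "d"))
  if (!is.numeric(d) || d <= 0) config_error("geometry.d must be positive")
  if (!shape %in% c("triangle", "square", "hexagon", "circle"))
    config_error("geometry.shape must be triangle/square/hexagon/circle")
  A <- get_field(config, c("params", "A"))
  if (!is.numeric(A) || A < 0) config_error("params.A must be non-negative")
  eps <- get_field(config, c("params", "eps"), 1e-4)
  layer <- get_field(config, c("params", "layer"), 0.010)
  cells <- get_field(config, c("grid", "cells_across"), 50)
  t_end <- get_field(config, c("t_end"), 21)
  record <- get_field(config, c("output", "record_days"), seq_len(ceiling(t_end)))

  spec <- channel_spec(shape, d, get_field(config, c("geometry", "height"), 2))
  field <- channel_sdf(spec, d / cells)
  state <- initial_levelset(field, layer)
  series <- simulate_growth(state, growth_params(A, eps = eps),
                            t_end = t_end, record_at = record)
  paths <- write_run_outputs(config, series, label = sprintf("%s_d%g", shape, d))
  attr(series, "paths") <- paths
  invisible(series)
}

#' Run a gyroid-filling simulation from a configuration
#'
#' 3D pipeline on the gyroid scaffold. Config keys: `geometry`
#' (`wall_thickness`, `pore_size` or `period`, optional `n_cells`), `params`
#' (`A`, optional `eps`, `layer` or `layer_preset` = `"L1"` (10 um) / `"L2"`
#' (1 um)), optional `grid` (`cells_across` per unit cell, default 40;
#' refused above `max_voxels`, default 2^24), `t_end` (default 21), `output`.
#'
#' @param config an R list or path to a YAML file.
#' @return the `filling_series`, invisibly, with attribute `paths`.
#' @export
run_gyroid <- function(config) {
  config <- read_config(config)
  wall <- get_field(config, c("geometry", "wall_thickness"), 0.2)
  pore <- get_field(config, c("geometry", "pore_size"), 0.9)
  period <- get_field(config, c("geometry", "period"), NULL, required = FALSE)
  n_cells <- get_field(config, c("geometry", "n_cells"), 1)
  A <- get_field(config, c("params", "A"))
  if (!is.numeric(A) || A < 0) config_error("params.A must be non-negative")
  eps <- get_field(config, c("params", "eps"), 1e-4)
  preset <- get_field(config, c("params", "layer_preset"), NULL, required = FALSE)
  layer <- if (!is.null(preset)) {
    if (!preset %in% c("L1", "L2"))
      config_error("params.layer_preset must be 'L1' (10 um) or 'L2' (1 um)")
    if (preset == "L1") 0.010 else 0.001
  } else get_field(config, c("params", "layer"), 0.010)
  cells <- get_field(config, c("grid", "cells_across"), 40)
  max_vox <- get_field(config, c("grid", "max_voxels"), 2^24)
  t_end <- get_field(config, c("t_end"), 21)
  record <- get_field(config, c("output", "record_days"), c(10, 21))

  spec <- gyroid_spec(wall_thickness = wall, pore_size = pore,
                      period = period, n_cells = n_cells,
                      initial_layer = layer)
  n_axis <- cells * n_cells + 1
  if (n_axis^3 > max_vox)
    config_error(sprintf("grid of %d^3 voxels exceeds grid.max_voxels", n_axis))
  field <- gyroid_sdf(spec, spec$period / cells)
  state <- initial_levelset(field, layer)
  series <- simulate_growth(state, growth_params(A, eps = eps),
                            t_end = t_end, record_at = record)
  paths <- write_run_outputs(
    config, series, label = sprintf("gyroid_L%g", spec$period),
    extra_meta = list(period = spec$period, tau = spec$tau, layer = layer))
  attr(series, "paths") <- paths
  invisible(series)
}

write_run_outputs <- function(config, series, label, extra_meta = list()) {
  dir <- get_field(config, c("output", "dir"), NULL, required = FALSE)
  if (is.null(dir)) return(NULL)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(label, "_filling.csv"))
  write_filling_series(series, csv)
  meta <- file.path(dir, paste0(label, "_metadata.json"))
  jsonlite::write_json(
    run_metadata(config, c(extra_meta, list(
      full_fill_time = attr(series, "full_fill_time")))),
    meta, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  paths <- c(csv = csv, metadata = meta)
  if (isTRUE(get_field(config, c("output", "snapshots"), FALSE))) {
    st <- attr(series, "final_state")
    vti <- file.path(dir, paste0(label, "_phi.vti"))
    write_vti(st$phi, vti)
    paths <- c(paths, vti = vti)
  }
  paths
}
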