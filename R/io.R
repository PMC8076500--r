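## Configuration loading with unit normalization, and standard-format
## writers (legacy-VTK structured grids, RFC 4180 CSV monitors, JSON
## summaries) shared by all scenarios. All quantities are SI internally;
## configs may state values in the human-friendly units the field uses
## (um/s, hours, exosomes per hour per 1e5 cells) via {value, unit}
## records, converted once at load.

unitFactors <- list(
  "m"   = 1, "mm" = 1e-3, "um" = 1e-6,
  "m/s" = 1, "mm/s" = 1e-3, "um/s" = 1e-6,
  "s"   = 1, "min" = 60, "h" = 3600,
  "m2/s" = 1,
  "Pa"  = 1, "kg/m3" = 1, "Pa.s" = 1,
  "exo/s" = 1, "exo/h" = 1 / 3600,
  "exo/h/1e5cells" = NA  # handled by releaseFlux, kept verbatim
)

normalizeUnits <- function(x, path = "") {
  if (is.list(x) && !is.null(x$unit) && !is.null(x$value)) {
    f <- unitFactors[[x$unit]]
    if (is.null(f))
      stop("load_config: unknown unit '", x$unit, "' at ", path, call. = FALSE)
    if (is.na(f)) return(x$value)          # rate units resolved downstream
    return(x$value * f)
  }
  if (is.list(x))
    return(lapply(seq_along(x), function(i) {
      normalizeUnits(x[[i]], paste0(path, "/", names(x)[i]))
    }) |> stats::setNames(names(x)))
  x
}

configSchema <- list(
  scenario = c("benchmark", "transwell", "tme"),
  common = c("scenario", "seed", "output_dir", "n_checkpoints"),
  benchmark = c("U", "lambda", "M", "D", "L", "t_init", "t_end", "variant",
                "nx", "scheme", "cfl"),
  transwell = c("condition", "per_cell_rate", "cell_count", "gamma",
                "duration", "well_radius", "insert_radius", "insert_wall",
                "membrane_height", "height", "nr", "nz", "n_steps",
                "counting"),
  tme = c("stage", "layout_file", "nx", "domain", "inlet_velocity",
          "release_rate", "gamma", "duration", "scheme", "cfl",
          "n_macrophages", "n_tcells", "n_mdsc", "density", "viscosity")
)

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, rejects unknown keys, converts
#' \code{{value, unit}} records to SI, fills defaults and records which
#' fields were defaulted.
#'
#' @param path JSON file path.
#' @return object of class \code{exo_config}: the validated, SI-unit
#'   fields plus attributes \code{defaulted} (character vector) and
#'   \code{source_path}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    stop("load_config: file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$scenario) ||
      !raw$scenario %in% configSchema$scenario)
    stop("load_config: 'scenario' must be one of ",
         paste(configSchema$scenario, collapse = ", "), call. = FALSE)
  allowed <- c(configSchema$common, configSchema[[raw$scenario]])
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("load_config: unknown key(s) for scenario '", raw$scenario, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- normalizeUnits(raw)
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  defaults <- switch(raw$scenario,
    benchmark = list(U = 5e-6, lambda = 5e-4, M = 1, D = 1e-8, L = 0.1,
                     t_init = 60, t_end = 60 + 2700, variant = "standard",
                     nx = 200L, scheme = "quick", cfl = 0.5, seed = 1L),
    transwell = list(condition = "NF", cell_count = 3.6e6, gamma = 2e-3,
                     duration = 72 * 3600, seed = 1L),
    tme = list(stage = "early", nx = 256L, domain = 400e-6,
               inlet_velocity = 0.75e-6, gamma = 1e-12, duration = 2700,
               scheme = "muscl", cfl = 0.5, n_macrophages = 6L,
               n_tcells = 8L, n_mdsc = 0L, density = 1000,
               viscosity = 1e-3, seed = 1L))
  defaulted <- setdiff(names(defaults), names(cfg))
  for (k in defaulted) cfg[[k]] <- defaults[[k]]
  # basic physical-validity checks
  for (k in intersect(c("D", "gamma"), names(cfg)))
    if (cfg[[k]] <= 0)
      stop("load_config: ", k, " must be positive", call. = FALSE)
  for (k in intersect(c("inlet_velocity", "release_rate", "per_cell_rate"),
                      names(cfg)))
    if (!is.null(cfg[[k]]) && cfg[[k]] < 0)
      stop("load_config: ", k, " must be >= 0", call. = FALSE)
  structure(cfg, class = "exo_config", defaulted = defaulted,
            source_path = normalizePath(path))
}

#' Write a configuration back to JSON (SI units)
#' @param config an \code{exo_config}.
#' @param path output path.
#' @export
dumpConfig <- function(config, path) {
  x <- unclass(config)
  attributes(x) <- list(names = names(x))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a legacy-VTK structured-points file of cell fields
#'
#' ASCII VTK (STRUCTURED_POINTS, CELL_DATA) with the grid spacing and
#' origin; the title line records SI units and the out-of-plane depth
#' convention. Solid cells carry their field value as stored (0 for
#' concentrations, NaN for pressure).
#'
#' @param fields named list of nx x ny matrices.
#' @param grid an \code{exo_grid}.
#' @param path output file.
#' @export
writeVtk <- function(fields, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("exotran cell fields (SI units; 2-D depth = %g m; coord = %s)",
            grid$depth, grid$coord),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", grid$nx + 1, grid$ny + 1),
    sprintf("ORIGIN %.10g %.10g 0", grid$xf[1], grid$yf[1]),
    sprintf("SPACING %.10g %.10g 1", grid$dx, grid$dy),
    sprintf("CELL_DATA %d", grid$nx * grid$ny)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK cell ordering: x fastest
    writeLines(formatC(as.vector(f), format = "g", digits = 10), con)
  }
  invisible(path)
}

#' Read back a cell field written by [writeVtk()]
#' @param path VTK file.
#' @return named list of matrices.
#' @export
readVtk <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(sub("DIMENSIONS ", "", lines[5]), " ")[[1]])
  nx <- dims[1] - 1L; ny <- dims[2] - 1L
  out <- list(); i <- 9L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "SCALARS")) {
      nm <- strsplit(lines[i], " ")[[1]][2]
      vals <- as.numeric(lines[(i + 2):(i + 1 + nx * ny)])
      out[[nm]] <- matrix(vals, nx, ny)
      i <- i + 2L + nx * ny
    } else i <- i + 1L
  }
  out
}

#' Write scenario outputs and a manifest
#'
#' Writes one VTK file per checkpoint field, the monitor series as CSV
#' (column names carry SI units), a JSON summary, and a manifest listing
#' every written file with its md5 plus the md5 of the dumped
#' configuration.
#'
#' @param fields named list of nx x ny matrices (final/checkpoint fields).
#' @param monitors data.frame of per-step monitor values.
#' @param summary named list of scalar summaries.
#' @param dir output directory (created if needed).
#' @param grid an \code{exo_grid}.
#' @param config optional \code{exo_config} (dumped and hashed).
#' @return manifest as a named list (also written to manifest.json).
#' @export
writeOutputs <- function(fields, monitors, summary, dir, grid,
                         config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (length(fields)) {
    p <- file.path(dir, "fields.vtk")
    writeVtk(fields, grid, p)
    written <- c(written, p)
  }
  if (!is.null(monitors) && nrow(monitors)) {
    p <- file.path(dir, "monitors.csv")
    utils::write.csv(monitors, p, row.names = FALSE)
    written <- c(written, p)
  }
  summary$units <- "SI; concentrations in exosomes/m^3"
  summary$depth_m <- grid$depth
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  written <- c(written, p)
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    p <- file.path(dir, "config.json")
    dumpConfig(config, p)
    written <- c(written, p)
    cfg_hash <- unname(tools::md5sum(p))
  }
  manifest <- list(
    files = lapply(written, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    config_md5 = cfg_hash)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
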