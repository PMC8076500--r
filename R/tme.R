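## Two-stage tumor-microenvironment scenario: steady interstitial flow
## around the rasterized cell obstacles (stage 1), then exosome transport
## on the frozen velocity field (stage 2) - one-way (staggered) coupling.

#' TME scenario configuration
#'
#' Measured/stated inputs: interstitial fluid enters from the left at
#' 0.75 um/s; the tumor releases exosomes at 2.5 (early stage) or 7.5
#' (late stage) exosomes per second, reported after 45 min of transport.
#' Domain size, cell geometry and the exosome diffusion coefficient are
#' artifact defaults (declared in the shipped example configs): a
#' 400x400 um domain and Gamma = 1e-12 m^2/s (Stokes-Einstein scale for
#' ~100 nm vesicles in water).
#'
#' @param layout an \code{exo_layout} (e.g. from [generateTmeLayout()] or
#'   [segmentImage()]).
#' @param nx grid resolution per side (default 256).
#' @param domain square side (m; default 400 um). Must contain the layout.
#' @param inlet_velocity m/s (default 0.75e-6, from the left).
#' @param release_rate exosomes/s from the tumor boundary (default 2.5
#'   early / 7.5 late by stage).
#' @param gamma exosome diffusion coefficient (m^2/s; default 1e-12).
#' @param duration transport window (s; default 45 min).
#' @param fluid an \code{exo_fluid_props}.
#' @param scheme advective scheme (default \code{"muscl"}).
#' @param cfl advective CFL used to pick dt (default 0.5).
#' @param depth out-of-plane thickness (m; default 1 m, so 2-D
#'   concentrations integrate to counts per metre of depth).
#' @export
tmeConfig <- function(layout, nx = 256L, domain = 400e-6,
                      inlet_velocity = 0.75e-6,
                      release_rate = NULL, gamma = 1e-12,
                      duration = 45 * 60, fluid = fluidProps(),
                      scheme = "muscl", cfl = 0.5, depth = 1) {
  stopifnot(inherits(layout, "exo_layout"))
  if (is.null(release_rate))
    release_rate <- if (layout$stage == "late") 7.5 else 2.5
  if (release_rate < 0) stop("tmeConfig: release rate must be >= 0", call. = FALSE)
  if (inlet_velocity < 0)
    stop("tmeConfig: inlet velocity must be >= 0", call. = FALSE)
  structure(list(layout = layout, nx = as.integer(nx), domain = domain,
                 inlet_velocity = inlet_velocity,
                 release_rate = release_rate, gamma = gamma,
                 duration = duration, fluid = fluid, scheme = scheme,
                 cfl = cfl, depth = depth),
            class = "exo_tme_config")
}

#' Run the staggered flow + transport TME scenario
#'
#' Stage 1 solves steady incompressible laminar flow around the
#' rasterized cell obstacles; stage 2 integrates exosome transport on the
#' frozen velocity field with the tumor-boundary source. Exosomes enter
#' with zero concentration at the inlet and leave through the outlet
#' (Dirichlet c = 0 there); lateral boundaries are closed symmetry
#' planes.
#'
#' @param config an \code{exo_tme_config}.
#' @param streamline_seeds number of inlet-seeded streamlines to trace
#'   (0 to skip).
#' @param n_checkpoints field checkpoints.
#' @return object of class \code{exo_tme_result}: \code{flow},
#'   \code{history}, \code{concentration} (final field), \code{summary}
#'   (mean/max concentration over FLUID cells, max pressure, pressure
#'   drop, mass balance), \code{streamlines}, \code{grid}, \code{mask}.
#' @export
runTme <- function(config, streamline_seeds = 12L, n_checkpoints = 1L) {
  nx <- config$nx
  d <- config$domain / nx
  grid <- buildGrid(gridSpec(nx, nx, d, d, origin = c(0, 0),
                             depth = config$depth))
  mask <- rasterizeLayout(config$layout, grid)
  flow <- solveFlow(grid, mask, config$fluid,
                    flowBCs(config$inlet_velocity, lateral = "slip"))
  src <- sourceSpec(config$release_rate,
                    faces = list(fx = mask$source_fx, fy = mask$source_fy))
  tp <- transportParams(gamma = config$gamma, scheme = config$scheme,
                        diffusion = "implicit")
  cfl_den <- max(abs(flow$uf)) / d + max(abs(flow$vf)) / d
  dt_target <- if (cfl_den > 0) config$cfl / cfl_den else config$duration / 200
  nsteps <- max(200L, ceiling(config$duration / dt_target))
  dt <- config$duration / nsteps
  bc <- transportBC(left = bcSide("dirichlet", 0),
                    right = bcSide("dirichlet", 0),
                    bottom = bcSide("wall"), top = bcSide("wall"))
  prob <- makeTransportProblem(grid, mask, list(uf = flow$uf, vf = flow$vf),
                               tp, sources = src, bc = bc, dt = dt)
  hist <- runTransport(prob, c0 = 0, t0 = 0, t_end = config$duration,
                       n_checkpoints = n_checkpoints)
  cfin <- hist$final
  fluid <- !mask$solid
  mean_c <- sum((cfin * grid$V)[fluid]) / sum(grid$V[fluid])
  # mass balance over the whole run: injected = accumulated + out - in
  injected <- sum(hist$source_rate[, 1]) * dt
  outflow <- sum(hist$advective_outflow[, 1] + hist$diffusive_outflow[, 1]) * dt
  final_mass <- hist$mass[length(hist$times), 1]
  balance_residual <- abs(injected - outflow - final_mass) /
    max(injected, .Machine$double.xmin)
  streams <- list()
  if (streamline_seeds > 0) {
    ys <- seq(grid$yf[1] + d, grid$yf[nx + 1] - d,
              length.out = streamline_seeds)
    seeds <- cbind(grid$xf[1] + d / 2, ys)
    ok <- !mask$solid[cbind(1L, pmin(nx, 1L + floor((ys - grid$yf[1]) / d)))]
    streams <- computeStreamlines(grid, flow, mask, seeds[ok, , drop = FALSE])
  }
  summary <- list(mean_concentration = mean_c,
                  max_concentration = max(cfin),
                  max_pressure = max(flow$p, na.rm = TRUE),
                  pressure_drop = mean(flow$p[1, !mask$solid[1, ]]) -
                    mean(flow$p[nx, !mask$solid[nx, ]]),
                  balance_residual = balance_residual,
                  released_total = injected,
                  stage = config$layout$stage,
                  release_rate = config$release_rate)
  structure(list(flow = flow, history = hist, concentration = cfin,
                 summary = summary, streamlines = streams,
                 grid = grid, mask = mask, config = config),
            class = "exo_tme_result")
}

#' @export
print.exo_tme_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<exo_tme_result> stage %s: mean c %.4g, max c %.4g, max p %.4g Pa\n",
              s$stage, s$mean_concentration, s$max_concentration,
              s$max_pressure))
  invisible(x)
}

#' Compare an early- and a late-stage TME run
#'
#' @param early_run,late_run \code{exo_tme_result} objects on the same
#'   domain extent and duration.
#' @return list of late/early ratios: \code{concentration_ratio} (mean
#'   concentration over FLUID cells), \code{max_pressure_ratio},
#'   \code{pressure_drop_ratio}.
#' @export
stageSummary <- function(early_run, late_run) {
  se <- early_run$summary; sl <- late_run$summary
  if (se$mean_concentration == 0)
    stop("stageSummary: early-run mean concentration is zero", call. = FALSE)
  list(concentration_ratio = sl$mean_concentration / se$mean_concentration,
       max_pressure_ratio = sl$max_pressure / se$max_pressure,
       pressure_drop_ratio = sl$pressure_drop / se$pressure_drop)
}
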