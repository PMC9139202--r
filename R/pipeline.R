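#' Run the full aneurysm-to-chip pipeline
#'
#' Executes geometry -> flow -> WSS -> shear sites -> chip operating points
#' from one configuration, writing all stage artifacts plus a JSON manifest
#' (config hash, per-stage timings, output paths, warnings). The pipeline is
#' deterministic: identical configurations produce identical numerical
#' outputs.
#'
#' @param config a [load_config()] object (or a path to a YAML config).
#' @param out_dir output directory; defaults to the config's
#'   `output.directory`.
#' @return the manifest, invisibly, as a list; also written as
#'   `manifest.json`. Stage failures propagate as errors after writing a
#'   partial manifest that marks later stages as skipped.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "pipeline_config"))
    abort_aneuflow("config must be a pipeline_config or a path",
                   "aneuflow_validation_error")
  out_dir <- out_dir %||% config$output$directory
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_info <- function(...) {
    if (identical(config$output$log_level, "info") ||
          identical(config$output$log_level, "debug"))
      message(sprintf(...))
  }
  cfg_path <- file.path(out_dir, "config_used.yaml")
  dump_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stage_names <- c("geometry", "solve", "wss", "sites", "chip_map")
  manifest <- list(config_hash = cfg_hash, config_path = cfg_path,
                   stages = stats::setNames(
                     rep(list(list(status = "skipped")), length(stage_names)),
                     stage_names),
                   outputs = list(), warnings = list())
  warns <- character(0)
  finish <- function() {
    manifest$warnings <- warns
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
                                         error = conditionMessage(e))
        finish()
        abort_aneuflow(sprintf("pipeline stage '%s' failed: %s", name,
                               conditionMessage(e)),
                       class(e)[1])
      }),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  ## geometry ---------------------------------------------------------------
  gm <- config$geometry
  mask <- run_stage("geometry", function() {
    m <- switch(gm$kind,
      straight_vessel = make_straight_vessel(
        aneurysm_params(vessel_diameter = gm$vessel_diameter,
                        vessel_length = gm$vessel_length),
        gm$spacing, gm$ndim,
        domain_height = gm$domain_height %||% (2 * gm$vessel_diameter)),
      sidewall_aneurysm = make_sidewall_aneurysm(
        aneurysm_params(vessel_diameter = gm$vessel_diameter,
                        vessel_length = gm$vessel_length,
                        sac_radius = gm$sac_radius,
                        neck_width = gm$neck_width,
                        sac_side = gm$sac_side,
                        sac_center_offset = gm$sac_center_offset),
        gm$spacing, gm$ndim),
      stl = voxelize_stl(gm$stl_path, gm$spacing,
                         label_open_boundaries = TRUE),
      abort_aneuflow(sprintf("unknown geometry kind '%s'", gm$kind),
                     "aneuflow_validation_error"))
    if (gm$refine_factor > 1L) m <- refine_mask(m, gm$refine_factor)
    if (gm$smoothing_radius > 0L) m <- smooth_mask(m, gm$smoothing_radius)
    paths <- write_mask(m, out_dir, "mask")
    manifest$outputs$mask <<- unname(paths)
    log_info("geometry: %s grid, fluid fraction %.3f",
             paste(dim(m$indicator), collapse = " x "), fluid_fraction(m))
    m
  })

  ## solve ------------------------------------------------------------------
  ph <- config$physics
  sv <- config$solver
  scfg <- solver_config(
    reynolds = sv$reynolds_effective,
    penalization_eta = sv$penalization_eta, cfl = sv$cfl,
    steady_tol = sv$steady_tol, poisson_tol = sv$poisson_tol,
    max_steps = sv$max_steps,
    waveform = inlet_waveform(1, ph$waveform_amplitude, ph$waveform_period),
    inlet_profile = sv$inlet_profile, ramp_time = sv$ramp_time)
  pulsatile <- ph$waveform_amplitude > 0
  state <- run_stage("solve", function() {
    st <- if (pulsatile)
      solve_pulsatile(mask, scfg, n_periods = sv$n_periods,
                      n_phases = sv$n_phases)
    else solve_steady(mask, scfg, on_nonconvergence = "warn")
    vtk <- file.path(out_dir, "flow.vtk")
    write_flow_vtk(st, vtk)
    rescsv <- file.path(out_dir, "residuals.csv")
    utils::write.csv(residuals(st), rescsv, row.names = FALSE)
    manifest$outputs$flow <<- c(vtk, rescsv)
    s <- summary(st)
    log_info("solve: %d steps to t = %.3g, max fluid div %.3g",
             s$steps, s$time, s$max_fluid_divergence)
    st
  })

  ## wss --------------------------------------------------------------------
  scaling <- list(rho = ph$density, nu = ph$kinematic_viscosity,
                  U = ph$inlet_speed, D = ph$diameter)
  wfield <- run_stage("wss", function() {
    f <- if (pulsatile) {
      stats <- pulsatile_wss(state, mask, scaling)
      stats[[config$wss$temporal_statistic]]
    } else compute_wss(state, mask, scaling)
    csv <- file.path(out_dir, "wss.csv")
    write_wss_csv(f, csv)
    vtk <- file.path(out_dir, "wss.vtk")
    write_wss_vtk(f, vtk)
    manifest$outputs$wss <<- c(csv, vtk)
    log_info("wss: %d wall faces, median tau %.3g Pa", nrow(f),
             stats::median(f$tau_Pa))
    f
  })

  ## sites ------------------------------------------------------------------
  sites <- run_stage("sites", function() {
    s <- find_extreme_sites(wfield, config$wss$low_percentile,
                            config$wss$high_percentile,
                            config$wss$min_region_faces)
    js <- file.path(out_dir, "sites.json")
    write_sites_json(s, js)
    scsv <- file.path(out_dir, "sites.csv")
    write_sites_csv(s, scsv)
    manifest$outputs$sites <<- c(js, scsv)
    log_info("sites: %d low, %d high", length(s$low_sites),
             length(s$high_sites))
    s
  })

  ## chip map ---------------------------------------------------------------
  run_stage("chip_map", function() {
    chip <- chip_spec(config$chip$length, config$chip$width,
                      config$chip$height, config$chip$viscosity,
                      config$chip$density)
    mapped <- map_sites(sites, chip)
    tab <- operating_table(mapped)
    csv <- file.path(out_dir, "operating_points.csv")
    utils::write.csv(tab, csv, row.names = FALSE)
    js <- file.path(out_dir, "operating_points.json")
    jsonlite::write_json(tab, js, auto_unbox = TRUE, digits = NA)
    manifest$outputs$chip_map <<- c(csv, js)
    log_info("chip map: %d operating points", nrow(tab))
    tab
  })
  manifest$site_summary <- list(
    n_low = length(sites$low_sites), n_high = length(sites$high_sites),
    tau_low_Pa = if (length(sites$low_sites))
      sites$low_sites[[1]]$tau_median_Pa else NULL,
    tau_high_Pa = if (length(sites$high_sites))
      sites$high_sites[[1]]$tau_median_Pa else NULL)
  invisible(finish())
}
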