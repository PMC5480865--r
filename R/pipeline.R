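#' Run configuration
#'
#' Single source of truth for a pipeline run, loadable from YAML. Fields:
#' `coil` (preset name or coil_spec fields), `pose` (rotation_z_deg and
#' translation), `drive` (machine_output, plus optional pulse fields and
#' `base_current`), `grid` (phantom fixture parameters), `mesh` (path to a
#' `.msh`/`.vtk` mesh or sphere fixture parameters), `roi` (gyrus fixture
#' parameters or a vertex-index CSV), `integration` (step, min_distance),
#' `seed`, `tolerances` (fem residual), `output_dir`.
#'
#' @param ... Config fields (see above); unset fields take defaults.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- modifyList(default_run_config(), list(...))
  validate_run_config(cfg)
}

default_run_config <- function() {
  list(coil = "bsm819",
       pose = list(rotation_z_deg = 0, translation = c(0, 0, 0)),
       drive = list(machine_output = 0.01, base_current = NULL),
       grid = list(diameter = 0.125, height = 0.2, spacing = 0.005),
       mesh = list(target_edge = 0.012),
       roi = list(width = 0.02, length = 0.02, amplitude = 0.003,
                  wavelength = 0.01, spacing = 0.002, center = NULL),
       integration = list(step = 1e-3, min_distance = NULL),
       tolerances = list(fem_residual = 1e-4),
       seed = 1L,
       output_dir = NULL)
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$tolerances$fem_residual) && cfg$tolerances$fem_residual <= 0)
    stopf("tolerances must be positive")
  for (f in c("mesh", "roi")) {
    p <- cfg[[f]]$path
    if (!is.null(p) && !file.exists(p)) stopf("%s file not found: %s", f, p)
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to load.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_coil <- function(cfg) {
  if (is.character(cfg$coil)) coil_preset(cfg$coil)
  else do.call(coil_spec, cfg$coil)
}

config_pose <- function(cfg) {
  rigid_pose(rot_z((cfg$pose$rotation_z_deg %||% 0) * pi / 180),
             cfg$pose$translation %||% c(0, 0, 0))
}

config_pulse <- function(cfg) {
  d <- cfg$drive
  pulse_spec(frequency = d$frequency %||% 2500,
             duration = d$duration %||% 4e-4,
             peak_current_100 = d$peak_current_100 %||% 5500,
             peak_voltage_100 = d$peak_voltage_100 %||% 1650,
             damping = d$damping %||% 0)
}

build_coil_from_spec <- function(spec, current = 1, layer_pitch = 1e-3) {
  if (spec$n_layers > 1L)
    build_stacked_spiral_figure8(spec, layer_pitch = layer_pitch, current = current)
  else if (spec$n_windings > 1L) build_spiral_figure8(spec, current = current)
  else build_single_loop_figure8(spec, current = current)
}

config_integration <- function(cfg, spec) {
  step <- cfg$integration$step %||% spec$integration_step
  integration_config(step, cfg$integration$min_distance %||% (2 * step))
}

provenance <- function(cfg, seed) {
  list(package = "tmsfield",
       version = as.character(utils::packageVersion("tmsfield")),
       seed = seed,
       config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_artifact_json <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(file)
}

#' Compute coil field maps on the phantom grid
#'
#' Composes the pipeline up to the incident field: build the configured
#' coil, pose it, evaluate B (and A) on the cylindrical phantom grid at the
#' equivalent drive current times the model's distribution factor, and
#' return (optionally write) the Bz map plus full vector samples.
#' Deterministic given the config.
#'
#' @param config A [run_config()].
#' @param write If `TRUE` and `config$output_dir` is set, write the Bz map
#'   (NIfTI), the full B and A samples (CSV), and a provenance JSON.
#' @return A list with `bz_map` ([field_map()]), `B` and `A`
#'   (`field_samples` at the valid voxel centers), `path` (the posed
#'   [wire_path()]) and `drive` (the drive report).
#' @export
run_field <- function(config, write = !is.null(config$output_dir)) {
  stopifnot(inherits(config, "run_config"))
  spec <- config_coil(config)
  pulse <- config_pulse(config)
  mo <- config$drive$machine_output
  base <- config$drive$base_current %||%
    (if (pulse$damping > 0) abs(dc_equivalent_current(pulse, mo))
     else mo * pulse$peak_current_100)
  w <- spec$distribution_factor
  path <- apply_pose(build_coil_from_spec(spec, current = base), config_pose(config))
  cfg_i <- config_integration(config, spec)
  grid <- do.call(make_phantom_grid, config$grid)
  pts <- map_points(grid, masked_only = TRUE)
  B <- magnetic_field(path, pts, current = base, w = w, cfg = cfg_i)
  A <- vector_potential(path, pts, current = base, w = w, cfg = cfg_i)
  grid$bz[grid$mask] <- B$vectors[, 3]
  drive <- drive_report(pulse, mo, w = w, base_current = base)
  out <- list(bz_map = grid, B = B, A = A, path = path, drive = drive)
  if (write) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_field_map(grid, file.path(config$output_dir, "bz.nii"))
    write.csv(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                         Bx = B$vectors[, 1], By = B$vectors[, 2], Bz = B$vectors[, 3],
                         Ax = A$vectors[, 1], Ay = A$vectors[, 2], Az = A$vectors[, 3]),
              file.path(config$output_dir, "field_samples.csv"), row.names = FALSE)
    write_artifact_json(c(provenance(config, config$seed), list(drive = drive)),
                        file.path(config$output_dir, "field_provenance.json"))
  }
  out
}

#' Run the FEM + activation-metric pipeline
#'
#' Composes the full chain on a labeled mesh: build and pose the coil,
#' sample its vector potential per unit current at the mesh nodes, scale by
#' the model's maximum dI/dt (times the distribution factor) into dA/dt,
#' assemble and solve the quasi-static scalar-potential problem, form the
#' total E-field, sample it on the ROI patch and evaluate the activation
#' metric.
#'
#' @param config A [run_config()]. `config$mesh$path` loads a `.msh` or
#'   `.vtk` mesh; otherwise the concentric-sphere fixture is built from
#'   `config$mesh`. The ROI patch is the gyrus fixture from `config$roi`
#'   (optionally translated to `config$roi$center`).
#' @param write As in [run_field()]: writes potential + E-field (VTK),
#'   metric JSON and provenance into `config$output_dir`.
#' @return A list with `metric` (`metric_result`), `potential`
#'   (`potential_solution`), `efield` (`efield_solution`), `patch`, `mesh`,
#'   `path` and `drive`.
#' @export
run_brain <- function(config, write = !is.null(config$output_dir)) {
  stopifnot(inherits(config, "run_config"))
  spec <- config_coil(config)
  pulse <- config_pulse(config)
  mo <- config$drive$machine_output
  w <- spec$distribution_factor
  didt <- max_didt(pulse, mo)
  path <- apply_pose(build_coil_from_spec(spec), config_pose(config))
  cfg_i <- config_integration(config, spec)
  mesh <- if (!is.null(config$mesh$path)) {
    if (grepl("\\.msh$", config$mesh$path)) read_mesh_msh(config$mesh$path)
    else read_mesh_vtk(config$mesh$path)
  } else do.call(make_sphere_head, config$mesh)
  roi <- config$roi
  patch <- make_gyrus_patch(roi$width, roi$length, roi$amplitude,
                            roi$wavelength, roi$spacing)
  if (!is.null(roi$center))
    patch <- translate_patch(patch, roi$center)
  A_unit <- vector_potential(path, mesh$nodes, current = 1, w = 1, cfg = cfg_i)
  dAdt <- A_unit$vectors * (didt * w)
  sys <- assemble_system(mesh, dAdt)
  sol <- solve_potential(sys, tol = config$tolerances$fem_residual %||% 1e-4)
  ef <- total_efield(mesh, sol, dAdt)
  fvals <- sample_field_on_patch(ef, mesh, patch)
  metric <- ec_metric(patch, fvals)
  out <- list(metric = metric, potential = sol, efield = ef, patch = patch,
              mesh = mesh, path = path,
              drive = drive_report(pulse, mo, w = w))
  if (write) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_mesh_fields_vtk(mesh, file.path(config$output_dir, "solution.vtk"),
                          point_data = list(phi = sol$phi),
                          cell_data = list(Et = ef$total, Ep = ef$primary,
                                           Es = ef$secondary))
    write_metric_json(metric, file.path(config$output_dir, "metric.json"),
                      meta = list(coil = spec$name %||% "custom",
                                  machine_output = mo,
                                  residual = sol$residual,
                                  iterations = sol$iterations))
    write_artifact_json(c(provenance(config, config$seed),
                          list(residual = sol$residual,
                               iterations = sol$iterations)),
                        file.path(config$output_dir, "brain_provenance.json"))
  }
  out
}

#' Translate a surface patch rigidly
#'
#' @param patch A [surface_patch()].
#' @param offset Length-3 translation (m).
#' @return The translated [surface_patch()].
#' @export
translate_patch <- function(patch, offset) {
  v <- patch$vertices + matrix(offset, nrow(patch$vertices), 3, byrow = TRUE)
  p <- surface_patch(v, patch$faces)
  # translation cannot flip orientation; keep the original normals' sense
  flip <- rowSums(p$normal * patch$normal) < 0
  p$normal[flip, ] <- -p$normal[flip, ]
  p$faces[flip, c(2, 3)] <- p$faces[flip, c(3, 2), drop = FALSE]
  p
}
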