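#' Geometric specification of a figure-of-eight coil model
#'
#' A `coil_spec` collects the geometric parameters that define one of the
#' three coil models: a single outer loop per wing, a single layer of spiral
#' winding turns, or several stacked layers of the same spiral. All lengths
#' are in meters; millimeter catalogue values must be converted at the call
#' boundary (the shipped presets already are).
#'
#' @param inner_radius Radius of the innermost winding turn (m).
#' @param outer_radius Radius of the outermost winding turn (m).
#' @param n_windings Number of spiral winding turns per wing (1 for the
#'   single-loop model).
#' @param n_layers Number of stacked layers per wing.
#' @param wing_gap Outer inter-wing distance (m): the gap between the
#'   outermost windings of the two wings, so wing centers sit at
#'   `+/-(outer_radius + wing_gap/2)` on the x axis.
#' @param segments_per_wing Number of straight segments used to discretize
#'   one wing, summed over layers for a stacked coil (so each layer of a
#'   stacked wing gets `segments_per_wing / n_layers`).
#' @param integration_step Sub-segment integration step (m) used when
#'   evaluating Biot-Savart integrals for this coil.
#' @param distribution_factor Scalar current distribution factor `w` that
#'   rescales the drive current so geometrically different models deliver
#'   comparable ampere-turns (wire-length ratio for the single-loop model,
#'   1 for the spiral, `1/n_layers` per layer for the stacked model).
#' @param name Optional model name.
#'
#' @return An object of class `coil_spec`.
#' @seealso [coil_preset()] for the three shipped models,
#'   [build_single_loop_figure8()], [build_spiral_figure8()],
#'   [build_stacked_spiral_figure8()].
#' @export
#' @examples
#' coil_spec(0.044, 0.044, n_windings = 1, segments_per_wing = 92)
coil_spec <- function(inner_radius, outer_radius,
                      n_windings = 1L, n_layers = 1L,
                      wing_gap = 0.002, segments_per_wing = 92L,
                      integration_step = 2.5e-5,
                      distribution_factor = 1, name = NULL) {
  spec <- structure(list(
    inner_radius = as.numeric(inner_radius),
    outer_radius = as.numeric(outer_radius),
    n_windings = as.integer(n_windings),
    n_layers = as.integer(n_layers),
    wing_gap = as.numeric(wing_gap),
    segments_per_wing = as.integer(segments_per_wing),
    integration_step = as.numeric(integration_step),
    distribution_factor = as.numeric(distribution_factor),
    name = name
  ), class = "coil_spec")
  validate_coil_spec(spec)
  spec
}

#' @noRd
validate_coil_spec <- function(spec) {
  with(spec, {
    if (inner_radius > outer_radius)
      stopf("inner_radius (%g) must not exceed outer_radius (%g)",
            inner_radius, outer_radius)
    if (n_windings < 1L) stopf("n_windings must be >= 1")
    if (n_layers < 1L) stopf("n_layers must be >= 1")
    if (segments_per_wing < 8L) stopf("segments_per_wing must be >= 8")
    if (integration_step <= 0) stopf("integration_step must be > 0")
    if (distribution_factor <= 0) stopf("distribution_factor must be > 0")
    if (n_windings == 1L && inner_radius != outer_radius)
      stopf("a single-loop spec requires inner_radius == outer_radius")
    if (n_windings > 1L && inner_radius == outer_radius)
      stopf("a spiral spec with n_windings > 1 requires inner_radius < outer_radius (zero pitch)")
  })
  invisible(spec)
}

#' Shipped coil model presets
#'
#' Returns the specification of one of the three modeled coils. The three
#' presets mirror the catalogue of the studied figure-of-eight coil family:
#' `bsm811` is the idealized single 44 mm loop per wing (92 segments),
#' `bsm819` a single layer of 9 spiral winding turns from 26 to 44 mm
#' (763 segments per wing), and `bsm879` seven stacked layers of the same
#' spiral (5341 segments per wing). Distribution factors are 7, 1 and 1/7
#' respectively.
#'
#' @param name One of `"bsm811"`, `"bsm819"`, `"bsm879"`.
#' @return A [coil_spec()].
#' @export
#' @examples
#' coil_preset("bsm819")
coil_preset <- function(name = c("bsm811", "bsm819", "bsm879")) {
  name <- match.arg(tolower(name), c("bsm811", "bsm819", "bsm879"))
  path <- system.file("extdata", "coils", paste0(name, ".yaml"),
                      package = "tmsfield")
  if (!nzchar(path)) stopf("preset %s not found", name)
  read_coil_spec(path)
}

#' Read and write coil specifications as YAML
#'
#' @param path File path.
#' @return `read_coil_spec` returns a [coil_spec()]; `write_coil_spec`
#'   returns `path` invisibly.
#' @export
read_coil_spec <- function(path) {
  y <- yaml::read_yaml(path)
  coil_spec(inner_radius = y$inner_radius, outer_radius = y$outer_radius,
            n_windings = y$n_windings, n_layers = y$n_layers,
            wing_gap = y$wing_gap, segments_per_wing = y$segments_per_wing,
            integration_step = y$integration_step,
            distribution_factor = eval(parse(text = as.character(y$distribution_factor))),
            name = y$name)
}

#' @rdname read_coil_spec
#' @param spec A [coil_spec()].
#' @export
write_coil_spec <- function(spec, path) {
  stopifnot(inherits(spec, "coil_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 12)
  invisible(path)
}

#' @export
print.coil_spec <- function(x, ...) {
  cat(sprintf("coil_spec%s\n", if (!is.null(x$name)) paste0(" <", x$name, ">") else ""))
  cat(sprintf("  radii          : %.1f -> %.1f mm\n",
              1e3 * x$inner_radius, 1e3 * x$outer_radius))
  cat(sprintf("  windings/layers: %d x %d\n", x$n_windings, x$n_layers))
  cat(sprintf("  wing gap       : %.1f mm, %d segments/wing, step %.3g mm\n",
              1e3 * x$wing_gap, x$segments_per_wing, 1e3 * x$integration_step))
  cat(sprintf("  distribution factor w: %.4g\n", x$distribution_factor))
  invisible(x)
}
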