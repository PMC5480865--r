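#' Integration configuration for discretized line integrals
#'
#' @param step Sub-segment interpolation step (m): every polyline segment is
#'   subdivided into `ceiling(length/step)` equal pieces and the piece
#'   midpoint is used as the source location (second-order accurate).
#' @param min_distance Singularity guard (m): evaluation points closer than
#'   this to any source midpoint raise an error. Defaults to `2 * step`,
#'   which keeps the discretization error near the wire bounded.
#' @return An object of class `integration_config`.
#' @export
integration_config <- function(step = 1e-3, min_distance = 2 * step) {
  if (step <= 0) stopf("step must be > 0")
  if (min_distance <= 0) stopf("min_distance must be > 0")
  structure(list(step = as.numeric(step),
                 min_distance = as.numeric(min_distance)),
            class = "integration_config")
}

# Expand a wire path into sub-segment midpoints and signed dl vectors.
# Segment sign scales dl, which reverses the traversal direction.
subdivide_path <- function(path, step) {
  a <- path$nodes[path$segments[, 1], , drop = FALSE]
  b <- path$nodes[path$segments[, 2], , drop = FALSE]
  v <- b - a
  len <- sqrt(rowSums(v^2))
  nsub <- pmax(1L, as.integer(ceiling(len / step)))
  idx <- rep.int(seq_along(nsub), nsub)
  frac <- (unlist(lapply(nsub, seq_len)) - 0.5) / nsub[idx]
  src <- a[idx, , drop = FALSE] + v[idx, , drop = FALSE] * frac
  sgn <- sign(path$segment_current[idx])
  dl <- v[idx, , drop = FALSE] * (sgn / nsub[idx])
  list(src = src, dl = dl)
}

field_samples <- function(points, vectors, kind) {
  structure(list(points = points, vectors = vectors, field_kind = kind),
            class = "field_samples")
}

#' @export
print.field_samples <- function(x, ...) {
  cat(sprintf("field_samples <%s>: %d points, |v| in [%.3g, %.3g]\n",
              x$field_kind, nrow(x$points),
              min(rownorm(x$vectors)), max(rownorm(x$vectors))))
  invisible(x)
}

bs_eval <- function(path, points, current, w, cfg, potential) {
  stopifnot(inherits(path, "wire_path"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stopf("points must be n x 3")
  if (is.null(current)) current <- abs(path$segment_current[1])
  sub <- subdivide_path(path, cfg$step)
  raw <- bs_kernel(sub$src, sub$dl, points, potential, cfg$min_distance)
  raw * (MU0 * current * w / (4 * pi))
}

#' Magnetic field of a discretized wire path (Biot-Savart)
#'
#' Evaluates `B(r) = mu0 I w / (4 pi) * sum dl x (r - r0) / |r - r0|^3`
#' over sub-segments of the wire, where `r0` runs over sub-segment
#' midpoints and the segment current sign reverses the traversal
#' direction. Linear in both `current` and `w`.
#'
#' @param path A [wire_path()].
#' @param points Evaluation positions, n x 3 matrix (m).
#' @param current Drive current magnitude (A); defaults to the magnitude
#'   stored on the path.
#' @param w Scalar current distribution factor (see [coil_spec()]).
#' @param cfg An [integration_config()].
#' @return A `field_samples` object with per-point 3-vectors in tesla.
#' @export
#' @examples
#' loop <- build_single_loop_figure8(coil_preset("bsm811"))
#' magnetic_field(loop, c(0, 0, -0.04), cfg = integration_config(5e-4))
magnetic_field <- function(path, points, current = NULL, w = 1,
                           cfg = integration_config()) {
  v <- bs_eval(path, points, current, w, cfg, potential = FALSE)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  field_samples(as.matrix(points), v, "B")
}

#' Magnetic vector potential of a discretized wire path
#'
#' Evaluates `A(r) = mu0 I w / (4 pi) * sum dl / |r - r0|` over
#' sub-segments; `curl A = B` up to discretization error.
#'
#' @inheritParams magnetic_field
#' @return A `field_samples` object with per-point 3-vectors in V s / m.
#' @export
vector_potential <- function(path, points, current = NULL, w = 1,
                             cfg = integration_config()) {
  v <- bs_eval(path, points, current, w, cfg, potential = TRUE)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  field_samples(as.matrix(points), v, "A")
}

#' Analytic on-axis field of a circular loop
#'
#' Closed form `mu0 I R^2 / (2 (R^2 + z^2)^(3/2))` for the axial magnetic
#' field of a perfectly circular loop of radius `R` carrying current `I`,
#' evaluated a distance `z` along the loop axis. This is the tuning oracle
#' used to pick the Biot-Savart discretization.
#'
#' @param radius Loop radius (m).
#' @param current Loop current (A).
#' @param z On-axis offset(s) from the loop center (m).
#' @return Axial field magnitude(s) in tesla.
#' @export
#' @examples
#' analytic_onaxis_loop(0.044, 1, 0)  # mu0 I / 2R at the center
analytic_onaxis_loop <- function(radius, current, z) {
  if (radius <= 0) stopf("radius must be > 0")
  MU0 * current * radius^2 / (2 * (radius^2 + z^2)^1.5)
}

#' Discretization tuning report for a circular loop
#'
#' For a single circular loop spec, evaluates the discretized Biot-Savart
#' field on-axis at `probe_z` for a list of segment counts and reports the
#' relative error against [analytic_onaxis_loop()]. The attribute
#' `"n_for_tol"` holds the smallest tested count achieving `tol`.
#'
#' @param spec A single-loop [coil_spec()] (only `outer_radius` is used;
#'   a bare radius is also accepted).
#' @param probe_z On-axis evaluation offset (m).
#' @param steps Integer vector of segment counts to test.
#' @param tol Requested relative tolerance.
#' @return A data.frame with columns `segments` and `rel_error`.
#' @export
#' @examples
#' convergence_report(0.044, 0.01, c(8, 16, 32, 64))
convergence_report <- function(spec, probe_z, steps = c(8, 16, 32, 64, 128),
                               tol = 0.01) {
  radius <- if (inherits(spec, "coil_spec")) {
    if (spec$n_windings != 1L) stopf("convergence_report needs a single circular loop spec")
    spec$outer_radius
  } else as.numeric(spec)
  exact <- analytic_onaxis_loop(radius, 1, probe_z)
  err <- vapply(steps, function(n) {
    wing <- circle_wing(radius, as.integer(n))
    p <- wire_path(wing$nodes, wing$segments, 1)
    b <- magnetic_field(p, c(0, 0, probe_z), current = 1,
                        cfg = integration_config(step = radius,
                                                 min_distance = 1e-6))
    abs(sqrt(sum(b$vectors^2)) - exact) / exact
  }, 0)
  out <- data.frame(segments = as.integer(steps), rel_error = err)
  ok <- out$segments[out$rel_error <= tol]
  attr(out, "n_for_tol") <- if (length(ok)) min(ok) else NA_integer_
  out
}
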