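#' Discretized coil wire paths
#'
#' A `wire_path` is an ordered polyline describing the coil windings as
#' consumed by the Biot-Savart evaluators: a matrix of 3-D node positions
#' (m), a matrix of segment node-index pairs, and a signed current per
#' segment (A). All segments of one path carry the same current magnitude;
#' a negative sign means the current flows against the stored traversal
#' direction of that segment (the integrators treat it as a direction
#' reversal).
#'
#' @param nodes Numeric n x 3 matrix of node positions (m).
#' @param segments Integer m x 2 matrix of node indices.
#' @param segment_current Signed current per segment (A); recycled if
#'   length 1.
#' @return An object of class `wire_path`.
#' @export
wire_path <- function(nodes, segments, segment_current = 1) {
  nodes <- as.matrix(nodes)
  segments <- matrix(as.integer(segments), ncol = 2)
  if (ncol(nodes) != 3L) stopf("nodes must be an n x 3 matrix")
  if (any(segments < 1L) || any(segments > nrow(nodes)))
    stopf("segment indices out of range")
  segment_current <- rep_len(as.numeric(segment_current), nrow(segments))
  mags <- unique(round(abs(segment_current), 12))
  if (length(mags) > 1L)
    stopf("all segments of a wire path must share one current magnitude")
  structure(list(nodes = nodes, segments = segments,
                 segment_current = segment_current),
            class = "wire_path")
}

#' @export
print.wire_path <- function(x, ...) {
  cat(sprintf("wire_path: %d nodes, %d segments, |I| = %g A, length %.4f m\n",
              nrow(x$nodes), nrow(x$segments), abs(x$segment_current[1]),
              wire_length(x)))
  invisible(x)
}

# --- wing primitives -------------------------------------------------------

# Closed polygonal circle of given radius in z = 0, CCW viewed from +z.
circle_wing <- function(radius, n_seg) {
  th <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  nodes <- cbind(radius * cos(th), radius * sin(th), 0)
  segments <- cbind(seq_len(n_seg), c(seq_len(n_seg)[-1L], 1L))
  list(nodes = nodes, segments = segments)
}

# Apportion `total` segments over half-circle radii proportionally (largest
# remainder), keeping the arc length per segment roughly uniform.
apportion_segments <- function(radii, total) {
  raw <- total * radii / sum(radii)
  n <- floor(raw)
  short <- total - sum(n)
  if (short > 0) {
    ord <- order(raw - n, decreasing = TRUE)
    n[ord[seq_len(short)]] <- n[ord[seq_len(short)]] + 1
  }
  pmax(as.integer(n), 2L)
}

# One spiral wing assembled from 2*n_windings half-circles. Per half-circle
# the radius grows by dr/2 = (outer-inner)/(2 n_windings) and the half-circle
# center shifts along x by an alternating +/- dr/2 so consecutive endpoints
# coincide. First node sits at radius `inner` from the wing origin, last at
# `outer`. Open polyline, CCW.
spiral_wing <- function(inner, outer, n_windings, n_seg_total) {
  dr <- (outer - inner) / n_windings
  k <- seq_len(2L * n_windings)
  radii <- inner + (k - 1L) * dr / 2
  offs <- ifelse(k %% 2L == 1L, 0, dr / 2)
  nseg <- apportion_segments(radii, n_seg_total)
  pts <- vector("list", length(k))
  for (i in k) {
    th0 <- if (i %% 2L == 1L) 0 else pi
    th <- th0 + pi * seq(0, 1, length.out = nseg[i] + 1L)
    p <- cbind(offs[i] + radii[i] * cos(th), radii[i] * sin(th), 0)
    if (i > 1L) p <- p[-1L, , drop = FALSE]  # junction shared with previous
    pts[[i]] <- p
  }
  nodes <- do.call(rbind, pts)
  n <- nrow(nodes)
  list(nodes = nodes, segments = cbind(seq_len(n - 1L), 2:n))
}

# Mirror a wing through the y-z plane. With `reverse` the node order is
# also flipped so that, combined with the opposite current sign, the two
# wings' currents run in the same direction through the central region
# (standard figure-8 focality).
mirror_wing <- function(wing, reverse = TRUE) {
  nodes <- wing$nodes
  nodes[, 1] <- -nodes[, 1]
  segs <- wing$segments
  if (reverse) {
    n <- nrow(nodes)
    perm <- rev(seq_len(n))
    nodes <- nodes[perm, , drop = FALSE]
    inv <- integer(n); inv[perm] <- seq_len(n)
    segs <- cbind(inv[segs[, 2]], inv[segs[, 1]])[rev(seq_len(nrow(segs))), , drop = FALSE]
  }
  list(nodes = nodes, segments = segs)
}

shift_wing <- function(wing, dx, dz = 0) {
  wing$nodes[, 1] <- wing$nodes[, 1] + dx
  wing$nodes[, 3] <- wing$nodes[, 3] + dz
  wing
}

join_wings <- function(right, left, current) {
  n_r <- nrow(right$nodes)
  nodes <- rbind(right$nodes, left$nodes)
  segments <- rbind(right$segments, left$segments + n_r)
  cur <- c(rep(current, nrow(right$segments)),
           rep(-current, nrow(left$segments)))
  wire_path(nodes, segments, cur)
}

# --- builders --------------------------------------------------------------

#' Build the single-loop figure-8 coil model
#'
#' Generates two closed polygonal circles of radius `outer_radius` in the
#' z = 0 plane, centered at `+/-(outer_radius + wing_gap/2)` on the x axis,
#' carrying opposite signed currents. The local coil frame follows the
#' package convention: coil plane z = 0, subject-facing side -z, handle
#' (long) axis y.
#'
#' @param spec A [coil_spec()] with `n_windings == 1`.
#' @param current Current magnitude assigned to every segment (A).
#' @param central_reinforce If `TRUE` (default) the wing handedness is
#'   chosen so the two wings' currents are co-directed in the central
#'   region, the standard figure-8 focality arrangement.
#' @return A [wire_path()] with `segments_per_wing` segments per wing.
#' @export
#' @examples
#' p <- build_single_loop_figure8(coil_preset("bsm811"))
#' wire_length(p)
build_single_loop_figure8 <- function(spec, current = 1,
                                      central_reinforce = TRUE) {
  validate_coil_spec(spec)
  if (spec$n_windings > 1L)
    stopf("spec has n_windings > 1: use build_spiral_figure8()")
  if (spec$n_layers > 1L)
    stopf("spec has n_layers > 1: use build_stacked_spiral_figure8()")
  xc <- spec$outer_radius + spec$wing_gap / 2
  right <- shift_wing(circle_wing(spec$outer_radius, spec$segments_per_wing), xc)
  left <- shift_wing(mirror_wing(shift_wing(right, -xc),
                                 reverse = central_reinforce), -xc)
  join_wings(right, left, current)
}

#' Build the in-plane spiral figure-8 coil model
#'
#' Each wing is an Archimedean-like spiral assembled from half-circles: per
#' half-circle the radius increments by `dr/2` with
#' `dr = (outer_radius - inner_radius)/n_windings` and the half-circle
#' center offset alternates along x by the same amount, so the spiral spans
#' `inner_radius` to `outer_radius` with coincident half-circle endpoints.
#' The two wings carry opposite-signed currents.
#'
#' @inheritParams build_single_loop_figure8
#' @param spec A [coil_spec()] with `n_windings >= 2` and `n_layers == 1`.
#' @return A [wire_path()].
#' @export
#' @examples
#' p <- build_spiral_figure8(coil_preset("bsm819"))
build_spiral_figure8 <- function(spec, current = 1, central_reinforce = TRUE) {
  validate_coil_spec(spec)
  if (spec$n_windings < 2L)
    stopf("spec has n_windings == 1: use build_single_loop_figure8()")
  if (spec$n_layers > 1L)
    stopf("spec has n_layers > 1: use build_stacked_spiral_figure8()")
  xc <- spec$outer_radius + spec$wing_gap / 2
  right <- shift_wing(spiral_wing(spec$inner_radius, spec$outer_radius,
                                  spec$n_windings, spec$segments_per_wing), xc)
  left <- shift_wing(mirror_wing(shift_wing(right, -xc),
                                 reverse = central_reinforce), -xc)
  join_wings(right, left, current)
}

#' Build the stacked-spiral figure-8 coil model
#'
#' Stacks `n_layers` copies of the spiral wing pair along z at spacing
#' `layer_pitch`, distributed symmetrically about the nominal coil plane
#' z = 0 so the stack represents the thickness of the winding pack (its
#' mean plane coincides with the single-layer models). Each layer's
#' segments carry the full signed `current`; the per-layer current division
#' of the stacked model (the "/ n_layers" distribution-factor semantics) is
#' applied through the distribution factor `w` at field-evaluation time, so
#' that evaluating the stacked path at `w = 1/n_layers` equals averaging
#' `n_layers` single-layer coils at their shifted heights.
#'
#' @inheritParams build_single_loop_figure8
#' @param spec A [coil_spec()]; `n_layers == 1` degenerates to the plain
#'   spiral geometry.
#' @param layer_pitch Spacing between consecutive layers (m). The physical
#'   coil's layer pitch is not published; 1.0 mm is a plausible default and
#'   the layer thickness has little effect on the field.
#' @return A [wire_path()] with `segments_per_wing` segments per wing
#'   (apportioned as `segments_per_wing / n_layers` per layer).
#' @export
build_stacked_spiral_figure8 <- function(spec, layer_pitch = 1e-3,
                                         current = 1, central_reinforce = TRUE) {
  validate_coil_spec(spec)
  if (layer_pitch <= 0) stopf("layer_pitch must be > 0")
  if (spec$n_layers == 1L)  # degenerate stack: plain spiral geometry
    return(build_spiral_figure8(spec, current = current,
                                central_reinforce = central_reinforce))
  per_layer <- spec$segments_per_wing %/% spec$n_layers
  lay_spec <- spec
  lay_spec$n_layers <- 1L
  lay_spec$segments_per_wing <- as.integer(per_layer)
  base <- build_spiral_figure8(lay_spec, current = current,
                               central_reinforce = central_reinforce)
  offsets <- (seq_len(spec$n_layers) - 1L - (spec$n_layers - 1L) / 2) * layer_pitch
  parts <- lapply(offsets, function(dz) {
    p <- base
    p$nodes[, 3] <- p$nodes[, 3] + dz
    p
  })
  nodes <- do.call(rbind, lapply(parts, `[[`, "nodes"))
  off <- cumsum(c(0L, vapply(parts, function(p) nrow(p$nodes), 1L)))
  segments <- do.call(rbind, Map(function(p, o) p$segments + o,
                                 parts, off[-length(off)]))
  wire_path(nodes, segments,
            unlist(lapply(parts, `[[`, "segment_current")))
}

# --- pose and measurement --------------------------------------------------

#' Rigid pose of a coil in world coordinates
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation Length-3 vector (m).
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stopf("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_pose")
}

#' Elementary rotations about the coordinate axes
#'
#' @param angle Rotation angle (rad).
#' @return 3 x 3 rotation matrix.
#' @export
rot_z <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Rigidly transform a wire path
#'
#' Applies `x -> R x + t` to every node; segment currents and wire length
#' are unchanged.
#'
#' @param path A [wire_path()].
#' @param pose A [rigid_pose()].
#' @return The transformed [wire_path()].
#' @export
apply_pose <- function(path, pose) {
  stopifnot(inherits(path, "wire_path"), inherits(pose, "rigid_pose"))
  path$nodes <- path$nodes %*% t(pose$rotation) +
    matrix(pose$translation, nrow(path$nodes), 3, byrow = TRUE)
  path
}

#' Total polyline length of a wire path
#'
#' @param path A [wire_path()].
#' @return Sum of segment Euclidean lengths (m).
#' @export
wire_length <- function(path) {
  stopifnot(inherits(path, "wire_path"))
  if (nrow(path$segments) == 0L) stopf("empty wire path")
  d <- path$nodes[path$segments[, 2], , drop = FALSE] -
    path$nodes[path$segments[, 1], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}
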