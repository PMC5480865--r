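#' Regular-grid scalar field map
#'
#' A `field_map` stores a scalar Bz volume on a regular grid: the center of
#' the first voxel (`origin`, m), per-axis spacing (m), dimensions, the
#' values, and a logical validity mask (dropout/missing voxels are
#' `FALSE`; their values are `NA`).
#'
#' @param origin Length-3 center of voxel (1,1,1) (m).
#' @param spacing Length-3 voxel spacing (m), all positive.
#' @param dims Length-3 integer grid dimensions, all >= 1.
#' @param bz Numeric array of dimension `dims` (T); defaults to zeros.
#' @param mask Logical array of dimension `dims`; defaults to all `TRUE`.
#' @return An object of class `field_map`.
#' @export
field_map <- function(origin, spacing, dims, bz = NULL, mask = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3)
  dims <- rep_len(as.integer(dims), 3)
  if (any(spacing <= 0)) stopf("spacing must be > 0")
  if (any(dims < 1L)) stopf("dims must be >= 1")
  bz <- bz %||% array(0, dims)
  mask <- mask %||% array(TRUE, dims)
  if (!all(dim(bz) == dims) || !all(dim(mask) == dims))
    stopf("bz and mask must have dimension dims")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, bz = bz, mask = mask),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field_map: %s voxels at %s mm, %d valid (%.1f%%)\n",
              paste(x$dims, collapse = "x"),
              paste(signif(1e3 * x$spacing, 3), collapse = "x"),
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Voxel-center coordinates of a field map
#'
#' @param map A [field_map()].
#' @param masked_only If `TRUE`, only centers of valid voxels.
#' @return n x 3 matrix of voxel centers (m), in array (column-major) order.
#' @export
map_points <- function(map, masked_only = FALSE) {
  g <- expand.grid(x = map$origin[1] + (seq_len(map$dims[1]) - 1) * map$spacing[1],
                   y = map$origin[2] + (seq_len(map$dims[2]) - 1) * map$spacing[2],
                   z = map$origin[3] + (seq_len(map$dims[3]) - 1) * map$spacing[3])
  pts <- as.matrix(g)
  if (masked_only) pts[as.vector(map$mask), , drop = FALSE] else pts
}

#' Cylindrical phantom evaluation grid
#'
#' Regular grid of voxel centers covering an upright cylinder (axis z,
#' centered at the origin), mirroring the agar phantom used for field
#' validation (12.5 cm diameter, 20 cm height) and the scan resolution
#' (1 x 1 x 2 mm). Voxels outside the cylinder are masked out.
#'
#' @param diameter Cylinder diameter (m).
#' @param height Cylinder height (m).
#' @param spacing Voxel spacing (m), scalar or length 3.
#' @return A [field_map()] with mask `TRUE` inside the cylinder.
#' @export
#' @examples
#' make_phantom_grid(0.125, 0.2, 0.01)
make_phantom_grid <- function(diameter = 0.125, height = 0.2,
                              spacing = c(0.001, 0.001, 0.002)) {
  if (diameter <= 0 || height <= 0) stopf("dimensions must be positive")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (spacing[1] > diameter || spacing[2] > diameter || spacing[3] > height)
    stopf("spacing larger than the phantom dimensions")
  dims <- pmax(1L, as.integer(floor(c(diameter, diameter, height) / spacing)))
  origin <- -(dims - 1) / 2 * spacing
  m <- field_map(origin, spacing, dims)
  pts <- map_points(m)
  inside <- pts[, 1]^2 + pts[, 2]^2 <= (diameter / 2)^2
  m$mask <- array(inside, dims)
  m$bz[!m$mask] <- NA_real_
  m
}

# --- icosphere --------------------------------------------------------------

# unit icosphere: subdivide an icosahedron n times, project to the sphere
icosphere <- function(n_subdiv) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(n_subdiv)) {
    nv <- nrow(v)
    ekey <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
    keys <- c(ekey(f[, 1], f[, 2]), ekey(f[, 2], f[, 3]), ekey(f[, 3], f[, 1]))
    uk <- unique(keys)
    mid_id <- match(keys, uk) + nv
    i1 <- c(f[, 1], f[, 2], f[, 3]); i2 <- c(f[, 2], f[, 3], f[, 1])
    first <- !duplicated(match(keys, uk))
    mids <- (v[i1[first], , drop = FALSE] + v[i2[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids[order(match(keys, uk)[first]), , drop = FALSE])
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

#' Five-shell concentric-sphere head mesh
#'
#' Builds a labeled tetrahedral mesh of nested spherical shells standing in
#' for a segmented head: white matter innermost, then gray matter, CSF,
#' skull and scalp, with the standard isotropic conductivities attached.
#' The mesh is constructed radially: an icosphere surface (subdivision
#' level chosen from `target_edge`) is replicated at radial layers spanning
#' each shell, consecutive layers are joined by prisms split into three
#' tetrahedra with index-ordered diagonals (conforming), and the innermost
#' layer is joined to the center by one tet per surface triangle.
#'
#' @param radii Strictly ascending outer radii (m) of the wm, gm, csf,
#'   skull and scalp shells. Default 70/78/82/86/92 mm.
#' @param target_edge Target edge length (m); controls both the surface
#'   subdivision and the radial layer count.
#' @param conductivity Named conductivity table (S/m).
#' @return A [tetra_mesh()] with labels `wm`, `gm`, `csf`, `skull`, `scalp`.
#' @export
#' @examples
#' mesh <- make_sphere_head(target_edge = 0.03)
make_sphere_head <- function(radii = c(0.070, 0.078, 0.082, 0.086, 0.092),
                             target_edge = 0.012,
                             conductivity = tissue_conductivities()) {
  if (any(diff(radii) <= 0)) stopf("radii must be strictly ascending")
  if (target_edge <= 0) stopf("target_edge must be > 0")
  labels <- c("wm", "gm", "csf", "skull", "scalp")[seq_along(radii)]
  r_out <- radii[length(radii)]
  n_sub <- max(1L, ceiling(log2(1.0515 * r_out / target_edge)))
  surf <- icosphere(n_sub)
  nv <- nrow(surf$vertices)
  # radial layer positions: every shell boundary, subdivided to ~target_edge
  bounds <- c(0, radii)
  rads <- unique(unlist(lapply(seq_along(radii), function(k) {
    n <- max(1L, ceiling((bounds[k + 1] - bounds[k]) / target_edge))
    seq(bounds[k], bounds[k + 1], length.out = n + 1L)
  })))
  rads <- rads[rads > 0]
  nodes <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(rads, function(r) surf$vertices * r)))
  layer0 <- function(k) 1L + (k - 1L) * nv  # offset of layer k (1-based rads)
  f <- surf$faces
  tets <- vector("list", length(rads))
  # center fan to the first layer
  tets[[1]] <- cbind(1L, f[, 1] + layer0(1), f[, 2] + layer0(1), f[, 3] + layer0(1))
  # prisms between consecutive layers, split 3 ways on index-ordered diagonals
  for (k in seq_len(length(rads) - 1L)) {
    lo <- layer0(k); hi <- layer0(k + 1L)
    prism_tets <- lapply(seq_len(nrow(f)), function(i) {
      tri <- f[i, ]
      o <- order(tri)
      a <- tri[o[1]]; b <- tri[o[2]]; c3 <- tri[o[3]]
      rbind(c(a + lo, b + lo, c3 + lo, c3 + hi),
            c(a + lo, b + lo, c3 + hi, b + hi),
            c(a + lo, b + hi, c3 + hi, a + hi))
    })
    tets[[k + 1L]] <- do.call(rbind, prism_tets)
  }
  tets <- do.call(rbind, tets)
  # label by centroid radius
  cen <- (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
            nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
  shell <- findInterval(sqrt(rowSums(cen^2)), radii) + 1L
  shell[shell > length(labels)] <- length(labels)
  tetra_mesh(nodes, tets, labels[shell], conductivity)
}

#' Sinusoidal gyrus-like surface patch
#'
#' Triangulated sheet `z = amplitude * cos(2 pi x / wavelength)` over a
#' `width x length` rectangle: a synthetic stand-in for a cortical gyrus
#' with ridges running along y, used to test the orientation dependence of
#' the activation metric. Normals are consistently +z-biased (outward).
#'
#' @param width Extent along x (m, across the ridges).
#' @param length Extent along y (m, along the ridges).
#' @param amplitude Fold amplitude (m); 0 gives a flat sheet.
#' @param wavelength Fold wavelength along x (m).
#' @param spacing Target in-plane vertex spacing (m).
#' @return A [surface_patch()].
#' @export
#' @examples
#' make_gyrus_patch(0.02, 0.02, 0.003, 0.01, 0.002)
make_gyrus_patch <- function(width = 0.02, length = 0.02,
                             amplitude = 0.003, wavelength = 0.01,
                             spacing = 0.001) {
  if (width <= 0 || length <= 0 || wavelength <= 0 || spacing <= 0 ||
      amplitude < 0)
    stopf("parameters must be positive (amplitude may be 0)")
  nx <- max(2L, ceiling(width / spacing) + 1L)
  ny <- max(2L, ceiling(length / spacing) + 1L)
  xs <- seq(-width / 2, width / 2, length.out = nx)
  ys <- seq(-length / 2, length / 2, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  vertices <- cbind(g$x, g$y, amplitude * cos(2 * pi * g$x / wavelength))
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  faces <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                 cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  surface_patch(vertices, faces, orient_reference = c(0, 0, 1))
}

#' Synthetic noise specification for pseudo-measured field maps
#'
#' @param sigma Gaussian field-noise standard deviation (T).
#' @param dropout_threshold Field magnitude (T) above which voxels are
#'   masked out, emulating the near-coil signal loss from over-phasing
#'   beyond +/- pi. Defaults to `pi / (gamma * tau)` with the proton
#'   gyromagnetic ratio and the 0.4 ms pulse duration.
#' @param seed Integer seed for reproducible noise.
#' @return An object of class `synth_noise_spec`.
#' @export
synth_noise_spec <- function(sigma = 5e-7,
                             dropout_threshold = pi / (GAMMA_PROTON * 4e-4),
                             seed = 1L) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (dropout_threshold <= 0) stopf("dropout_threshold must be > 0")
  structure(list(sigma = sigma, dropout_threshold = dropout_threshold,
                 seed = as.integer(seed)),
            class = "synth_noise_spec")
}

#' Generate a noisy pseudo-measured field map
#'
#' Adds iid Gaussian noise to a ground-truth map and masks voxels whose
#' true magnitude exceeds the dropout threshold (near-coil over-phasing).
#' Reproducible under the spec's seed; already-masked voxels stay masked.
#'
#' @param truth A [field_map()] of the simulated ground truth.
#' @param noise A [synth_noise_spec()].
#' @return A [field_map()] of the pseudo-measurement.
#' @export
synth_measurement <- function(truth, noise) {
  stopifnot(inherits(truth, "field_map"), inherits(noise, "synth_noise_spec"))
  out <- truth
  set.seed(noise$seed)
  out$bz <- truth$bz + array(rnorm(prod(truth$dims), 0, noise$sigma), truth$dims)
  drop <- !is.na(truth$bz) & abs(truth$bz) > noise$dropout_threshold
  out$mask <- truth$mask & !drop
  out$bz[!out$mask] <- NA_real_
  out
}

#' Voxelwise absolute difference of two field maps
#'
#' `AD = |measured - simulated|` on identical grids; a voxel missing in
#' either input is missing in the result.
#'
#' @param measured,simulated [field_map()]s on the same grid.
#' @return A [field_map()] holding the AD values.
#' @export
absolute_difference <- function(measured, simulated) {
  stopifnot(inherits(measured, "field_map"), inherits(simulated, "field_map"))
  if (!isTRUE(all.equal(measured$dims, simulated$dims)) ||
      !isTRUE(all.equal(measured$spacing, simulated$spacing)) ||
      !isTRUE(all.equal(measured$origin, simulated$origin)))
    stopf("field maps are on different grids")
  out <- measured
  out$mask <- measured$mask & simulated$mask
  out$bz <- abs(measured$bz - simulated$bz)
  out$bz[!out$mask] <- NA_real_
  out
}

#' Trilinear 1-D profile through a field map
#'
#' Samples the map along a straight line by trilinear interpolation, at
#' steps of the smallest grid spacing, for `depth` meters from the origin
#' point. Samples falling outside the grid (or on missing voxels) are `NA`.
#'
#' @param map A [field_map()].
#' @param line_origin Length-3 start point (m).
#' @param line_direction Length-3 direction (normalized internally).
#' @param depth Line length to sample (m).
#' @return A data.frame with `position` (m along the line) and `value`.
#' @export
profile_1d <- function(map, line_origin, line_direction, depth) {
  d <- as.numeric(line_direction)
  d <- d / sqrt(sum(d^2))
  step <- min(map$spacing)
  pos <- seq(0, depth, by = step)
  pts <- matrix(line_origin, length(pos), 3, byrow = TRUE) + outer(pos, d)
  vals <- interp_trilinear(map, pts)
  if (all(is.na(vals))) stopf("line lies fully outside the grid")
  data.frame(position = pos, value = vals)
}

# trilinear interpolation at arbitrary points; NA outside or on masked voxels
interp_trilinear <- function(map, pts) {
  u <- sweep(sweep(pts, 2, map$origin), 2, map$spacing, "/")  # voxel coords, 0-based
  i0 <- floor(u)
  fr <- u - i0
  n <- nrow(pts)
  vals <- rep(NA_real_, n)
  bz <- map$bz
  bz[!map$mask] <- NA_real_
  dims <- map$dims
  ok <- i0[, 1] >= -1 & i0[, 1] <= dims[1] - 1 &
    i0[, 2] >= -1 & i0[, 2] <= dims[2] - 1 &
    i0[, 3] >= -1 & i0[, 3] <= dims[3] - 1
  # clamp so points exactly on the upper boundary interpolate from the last cell
  for (idx in which(ok)) {
    c0 <- pmin(pmax(i0[idx, ], 0), dims - 2L)
    c0[dims == 1L] <- 0L
    f <- u[idx, ] - c0
    if (any(f < -1e-9) || any(f > 1 + 1e-9)) { next }
    f <- pmin(pmax(f, 0), 1)
    acc <- 0; wsum <- 0; bad <- FALSE
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- c0 + c(dx, dy, dz)
      ii[dims == 1L] <- 0L
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f)[dims > 1L])
      if (dims[1] == 1L && dx == 1L) next
      if (dims[2] == 1L && dy == 1L) next
      if (dims[3] == 1L && dz == 1L) next
      v <- bz[ii[1] + 1L, ii[2] + 1L, ii[3] + 1L]
      if (is.na(v)) { if (w > 1e-12) bad <- TRUE; next }
      acc <- acc + w * v; wsum <- wsum + w
    }
    if (!bad && wsum > 0) vals[idx] <- acc / wsum
  }
  vals
}

#' Convert a Bz map to an MR phase map
#'
#' Optional converter `phi = gamma * Bz * tau` between field and phase
#' accumulation, with the proton gyromagnetic ratio
#' `gamma = 2.675e8 rad/s/T`.
#'
#' @param map A [field_map()].
#' @param tau Accumulation time (s); default the 0.4 ms pulse duration.
#' @param invert If `TRUE`, interpret the map as phase and return field.
#' @return A [field_map()] with converted values.
#' @export
phase_from_bz <- function(map, tau = 4e-4, invert = FALSE) {
  out <- map
  fac <- GAMMA_PROTON * tau
  out$bz <- if (invert) map$bz / fac else map$bz * fac
  out
}
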