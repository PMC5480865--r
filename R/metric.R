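#' Triangulated cortical surface patch
#'
#' A `surface_patch` holds a region of interest on a triangulated surface
#' (typically the CSF/GM boundary): vertex positions (m), triangle vertex
#' indices, per-triangle areas, outward unit normals and centroids. The
#' outward convention points from gray matter into CSF, matching the
#' orientation of pyramidal axons perpendicular to the pial surface.
#'
#' @param vertices Numeric n x 3 matrix (m).
#' @param faces Integer k x 3 matrix of vertex indices; the winding order
#'   defines the normals.
#' @param orient_reference Optional: a length-3 vector, or the string
#'   `"radial"`. Normals whose dot product with the reference direction
#'   (the vector, or the face centroid for `"radial"`) is negative are
#'   flipped, giving a consistent outward orientation. Use `c(0, 0, 1)`
#'   for a +z-biased sheet, `"radial"` for an origin-centered sphere.
#' @return An object of class `surface_patch`.
#' @export
surface_patch <- function(vertices, faces, orient_reference = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (ncol(vertices) != 3L) stopf("vertices must be n x 3")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stopf("face indices out of range")
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  nrm <- vcross(b - a, c3 - a)
  area <- rownorm(nrm) / 2
  if (any(area <= 0)) stopf("degenerate triangle at index %d", which.min(area))
  nrm <- nrm / (2 * area)
  centroid <- (a + b + c3) / 3
  if (!is.null(orient_reference)) {
    ref <- if (identical(orient_reference, "radial")) centroid
    else matrix(orient_reference, nrow(faces), 3, byrow = TRUE)
    flip <- rowSums(nrm * ref) < 0
    nrm[flip, ] <- -nrm[flip, ]
    faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  }
  structure(list(vertices = vertices, faces = faces, area = area,
                 normal = nrm, centroid = centroid),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("surface_patch: %d vertices, %d triangles, area %.4g cm^2\n",
              nrow(x$vertices), nrow(x$faces), 1e4 * sum(x$area)))
  invisible(x)
}

#' Total area of a surface patch
#' @param patch A [surface_patch()].
#' @return Total area (m^2).
#' @export
patch_area <- function(patch) sum(patch$area)

# minimal union-find for the largest edge-connected component
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, 1L)
}

#' Extract a masked ROI patch from a triangle surface
#'
#' Keeps the triangles whose three vertices are all inside the binary mask,
#' then retains the largest edge-connected component (a warning reports how
#' many components were dropped). Areas and outward normals are computed on
#' the result.
#'
#' @param surface A [surface_patch()] or a list with `vertices` and `faces`.
#' @param mask Logical per-vertex vector, or an integer vector of vertex
#'   indices.
#' @param orient_reference Passed to [surface_patch()].
#' @return A [surface_patch()] restricted to the ROI.
#' @export
extract_patch <- function(surface, mask, orient_reference = NULL) {
  vertices <- surface$vertices
  faces <- surface$faces
  if (!is.logical(mask)) {
    idx <- as.integer(mask)
    mask <- rep(FALSE, nrow(vertices))
    mask[idx] <- TRUE
  }
  if (!any(mask)) stopf("empty ROI mask")
  keep <- mask[faces[, 1]] & mask[faces[, 2]] & mask[faces[, 3]]
  if (!any(keep)) stopf("mask selects no complete triangle")
  faces <- faces[keep, , drop = FALSE]
  # connect faces sharing an edge
  nf <- nrow(faces)
  nn1 <- nrow(vertices) + 1
  ekey <- function(i, j) pmin(i, j) * nn1 + pmax(i, j)
  keys <- c(ekey(faces[, 1], faces[, 2]), ekey(faces[, 2], faces[, 3]),
            ekey(faces[, 3], faces[, 1]))
  fid <- rep(seq_len(nf), times = 3)
  grp <- split(fid, keys)
  edges <- do.call(rbind, lapply(grp[lengths(grp) > 1L], function(g)
    cbind(g[1], g[-1])))
  comp <- uf_components(nf, if (is.null(edges)) matrix(0L, 0, 2) else edges)
  tab <- table(comp)
  if (length(tab) > 1L)
    warning(sprintf("ROI has %d disconnected components; keeping the largest (%d of %d faces)",
                    length(tab), max(tab), nf), call. = FALSE)
  faces <- faces[comp == as.integer(names(tab)[which.max(tab)]), , drop = FALSE]
  # compact the vertex set
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(vertices))
  remap[used] <- seq_along(used)
  surface_patch(vertices[used, , drop = FALSE],
                matrix(remap[faces], ncol = 3),
                orient_reference = orient_reference)
}

# node -> incident tets adjacency
node_tet_index <- function(mesh) {
  split(rep(seq_len(nrow(mesh$tets)), 4L), as.vector(mesh$tets))
}

# barycentric coordinates of point p in tet t (returns length-4 weights)
tet_barycentric <- function(nodes, tet, p) {
  a <- nodes[tet[1], ]
  Jm <- cbind(nodes[tet[2], ] - a, nodes[tet[3], ] - a, nodes[tet[4], ] - a)
  lam <- tryCatch(solve(Jm, p - a), error = function(e) rep(NA_real_, 3))
  c(1 - sum(lam), lam)
}

#' Sample a tetrahedral field on a surface patch
#'
#' Assigns to each patch triangle centroid the linearly interpolated field
#' of its containing tetrahedron: nodal values are interpolated with the
#' barycentric weights of the centroid. A per-tet field (one row per tet,
#' e.g. an `efield_solution` component) is first averaged to the nodes with
#' volume weights; a per-node field is interpolated directly.
#'
#' @param field Numeric matrix with 3 columns and one row per tet or per
#'   node, or an `efield_solution` (its `total` component is used).
#' @param mesh A [tetra_mesh()].
#' @param patch A [surface_patch()] lying on or inside the mesh.
#' @param tol Barycentric tolerance for point-in-tet tests (relative).
#' @return Numeric k x 3 matrix of field vectors at the triangle centroids.
#' @export
sample_field_on_patch <- function(field, mesh, patch, tol = 1e-6) {
  if (inherits(field, "efield_solution")) field <- field$total
  field <- as.matrix(field)
  nn <- nrow(mesh$nodes)
  nt <- nrow(mesh$tets)
  if (nrow(field) == nt && nt != nn) {
    vol <- tet_volumes(mesh)
    nodal <- matrix(0, nn, ncol(field))
    wsum <- numeric(nn)
    for (i in 1:4) {
      idx <- mesh$tets[, i]
      acc <- rowsum(field * vol, group = idx)
      rid <- as.integer(rownames(acc))
      nodal[rid, ] <- nodal[rid, ] + acc
      accw <- rowsum(vol, group = idx)
      wsum[rid] <- wsum[rid] + accw[, 1]
    }
    field <- nodal / wsum
  } else if (nrow(field) != nn) {
    stopf("field must have one row per tet (%d) or per node (%d)", nt, nn)
  }
  inc <- node_tet_index(mesh)
  cents <- patch$centroid
  # nearest mesh node per centroid (chunked distance computation)
  near <- integer(nrow(cents))
  for (i in seq_len(nrow(cents))) {
    d2 <- (mesh$nodes[, 1] - cents[i, 1])^2 +
      (mesh$nodes[, 2] - cents[i, 2])^2 + (mesh$nodes[, 3] - cents[i, 3])^2
    near[i] <- which.min(d2)
  }
  out <- matrix(NA_real_, nrow(cents), ncol(field))
  for (i in seq_len(nrow(cents))) {
    p <- cents[i, ]
    cand <- inc[[as.character(near[i])]] %||% integer(0)
    # widen once to the tets of the candidate tets' nodes
    cand2 <- unique(unlist(inc[as.character(unique(as.vector(mesh$tets[cand, , drop = FALSE])))]))
    best_w <- NULL; best_min <- -Inf
    for (t in unique(c(cand, cand2))) {
      wgt <- tet_barycentric(mesh$nodes, mesh$tets[t, ], p)
      if (anyNA(wgt)) next
      m <- min(wgt)
      if (m > best_min) {
        best_min <- m
        best_w <- list(t = t, w = wgt)
      }
      if (m >= 0) break
    }
    if (is.null(best_w) || best_min < -tol)
      stopf("triangle %d centroid lies outside the mesh (best barycentric %.3g)",
            i, best_min)
    tet <- mesh$tets[best_w$t, ]
    out[i, ] <- colSums(field[tet, , drop = FALSE] * best_w$w)
  }
  out
}

#' Cortical activation metric Ec
#'
#' Area-weighted sum of the absolute normal field over a surface patch,
#' `Ec = sum_i S_i |Et_i . n_i|` (V m): a proxy for activation of pyramidal
#' neurons oriented normal to the cortical sheet. Zero iff the field is
#' everywhere tangential; invariant to triangle renumbering; linear in a
#' global field scale.
#'
#' @param patch A [surface_patch()].
#' @param field Numeric k x 3 matrix of field vectors at the triangle
#'   centroids (V/m), e.g. from [sample_field_on_patch()].
#' @return A list of class `metric_result` with `ec` (V m), `per_triangle`
#'   (the per-face `|Et . n|`, V/m) and `patch_area` (m^2).
#' @export
#' @examples
#' sq <- surface_patch(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'                     rbind(c(1, 2, 3), c(1, 3, 4)))
#' ec_metric(sq, matrix(rep(c(0, 0, 2), 2), 2, 3, byrow = TRUE))$ec  # 2 * area
ec_metric <- function(patch, field) {
  stopifnot(inherits(patch, "surface_patch"))
  field <- as.matrix(field)
  if (nrow(field) != nrow(patch$faces))
    stopf("field must have one row per patch triangle")
  per <- abs(rowSums(field * patch$normal))
  structure(list(ec = sum(patch$area * per), per_triangle = per,
                 patch_area = sum(patch$area)),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("metric_result: Ec = %.6g V m over %.4g cm^2 (%d triangles)\n",
              x$ec, 1e4 * x$patch_area, length(x$per_triangle)))
  invisible(x)
}

#' Relative activation differences between coil models
#'
#' Reports `(ec_i - ec_baseline) / ec_baseline` for a list of metric
#' results (or bare Ec values).
#'
#' @param results List of `metric_result` objects or numeric Ec values.
#' @param baseline_index Index of the baseline entry.
#' @return Numeric vector of relative differences (the baseline entry is 0).
#' @export
compare_models <- function(results, baseline_index = 1L) {
  ec <- vapply(results, function(r)
    if (inherits(r, "metric_result")) r$ec else as.numeric(r), 0)
  if (length(ec) < 2L) stopf("need at least two results to compare")
  base <- ec[baseline_index]
  if (base == 0) stopf("baseline ec is zero")
  (ec - base) / base
}
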