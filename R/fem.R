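#' Default tissue conductivities
#'
#' Isotropic conductivities (S/m) for the five head compartments plus the
#' agar phantom: scalp 0.5, skull 0.02, CSF 1.6, gray matter 0.3, white
#' matter 0.25, phantom 1.6.
#'
#' @return Named numeric vector (S/m).
#' @export
tissue_conductivities <- function() {
  c(scalp = 0.5, skull = 0.02, csf = 1.6, gm = 0.3, wm = 0.25, phantom = 1.6)
}

#' Labeled tetrahedral volume mesh
#'
#' A `tetra_mesh` holds node positions (m), tetrahedra as 4-tuples of node
#' indices, a per-tet tissue label and a per-label conductivity table.
#' Tetrahedra are reoriented on construction so that every signed volume is
#' positive; degenerate (zero-volume) tets are rejected.
#'
#' @param nodes Numeric n x 3 matrix of node positions (m).
#' @param tets Integer m x 4 matrix of node indices.
#' @param tissue_label Character or factor of length m; every level must
#'   appear in `names(conductivity)`.
#' @param conductivity Named numeric vector of per-tissue conductivities
#'   (S/m), all positive. Defaults to [tissue_conductivities()].
#' @return An object of class `tetra_mesh`.
#' @export
tetra_mesh <- function(nodes, tets, tissue_label,
                       conductivity = tissue_conductivities()) {
  nodes <- as.matrix(nodes)
  tets <- matrix(as.integer(tets), ncol = 4)
  if (ncol(nodes) != 3L) stopf("nodes must be n x 3")
  if (any(tets < 1L) || any(tets > nrow(nodes)))
    stopf("tet indices out of range")
  tissue_label <- as.character(tissue_label)
  if (length(tissue_label) != nrow(tets))
    stopf("one tissue label per tet required")
  missing_lab <- setdiff(unique(tissue_label), names(conductivity))
  if (length(missing_lab))
    stopf("no conductivity for label(s): %s", paste(missing_lab, collapse = ", "))
  if (any(conductivity <= 0)) stopf("conductivities must be > 0")
  v6 <- tet_volume6(nodes, tets)
  flip <- v6 < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  v6 <- abs(v6)
  if (any(v6 < .Machine$double.eps * 10))
    stopf("degenerate (zero-volume) tetrahedron at index %d", which.min(v6))
  structure(list(nodes = nodes, tets = tets,
                 tissue_label = tissue_label,
                 conductivity = conductivity),
            class = "tetra_mesh")
}

#' @export
print.tetra_mesh <- function(x, ...) {
  cat(sprintf("tetra_mesh: %d nodes, %d tets, labels: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(sort(unique(x$tissue_label)), collapse = ", ")))
  invisible(x)
}

# 6x signed volume of each tet
tet_volume6 <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  rowSums(e1 * vcross(e2, e3))
}

#' Per-tet volumes of a mesh
#' @param mesh A [tetra_mesh()].
#' @return Numeric vector of tet volumes (m^3).
#' @export
tet_volumes <- function(mesh) {
  abs(tet_volume6(mesh$nodes, mesh$tets)) / 6
}

# Constant P1 basis gradients per tet: list of four m x 3 matrices (one per
# local vertex) plus the 6x volumes. grad psi_2 = (e2 x e3)/V6, etc.,
# grad psi_1 = -(sum of the others).
tet_gradients <- function(mesh) {
  nodes <- mesh$nodes; tets <- mesh$tets
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  v6 <- rowSums(e1 * vcross(e2, e3))
  g2 <- vcross(e2, e3) / v6
  g3 <- vcross(e3, e1) / v6
  g4 <- vcross(e1, e2) / v6
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), v6 = v6)
}

per_tet_sigma <- function(mesh) {
  unname(mesh$conductivity[mesh$tissue_label])
}

#' Assemble the quasi-static scalar-potential system
#'
#' Galerkin linear-tetrahedron (P1) discretization of
#' `div(sigma grad Phi) = -div(sigma dA/dt)` with the natural Neumann
#' boundary `sigma (grad Phi + dA/dt) . n = 0` (no current leaves the
#' domain). The stiffness operator is symmetric positive semi-definite
#' with the constants as its null space (zero row sums); the load vector
#' `b_i = -sum_e sigma_e V_e (Abar_e . grad psi_i)` uses one-point
#' (centroid) quadrature of the nodal `dA/dt` field and sums to zero
#' (pure-Neumann compatibility).
#'
#' @param mesh A [tetra_mesh()].
#' @param dAdt Numeric n_nodes x 3 matrix: the time derivative of the coil
#'   vector potential at the mesh nodes (V/m), i.e. `A` per unit current
#'   scaled by the maximum dI/dt (see [max_didt()]).
#' @return A list of class `fem_system` with the sparse stiffness matrix
#'   `K` (dsCMatrix), load vector `b`, and the mesh.
#' @export
assemble_system <- function(mesh, dAdt) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  nn <- nrow(mesh$nodes)
  dAdt <- as.matrix(dAdt)
  if (!all(dim(dAdt) == c(nn, 3L)))
    stopf("dAdt must be a %d x 3 matrix sampled at mesh nodes", nn)
  gr <- tet_gradients(mesh)
  vol <- abs(gr$v6) / 6
  sig <- per_tet_sigma(mesh)
  sv <- sig * vol
  tets <- mesh$tets
  # stiffness triplets: K_e[i,j] = sigma V (g_i . g_j)
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    ii[[k]] <- tets[, i]
    jj[[k]] <- tets[, j]
    xx[[k]] <- sv * rowSums(gr$g[[i]] * gr$g[[j]])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nn, nn), symmetric = FALSE)
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  # load: centroid dA/dt per element
  Abar <- (dAdt[tets[, 1], , drop = FALSE] + dAdt[tets[, 2], , drop = FALSE] +
             dAdt[tets[, 3], , drop = FALSE] + dAdt[tets[, 4], , drop = FALSE]) / 4
  b <- numeric(nn)
  for (i in 1:4) {
    contrib <- -sv * rowSums(Abar * gr$g[[i]])
    acc <- rowsum(contrib, group = tets[, i])
    idx <- as.integer(rownames(acc))
    b[idx] <- b[idx] + acc[, 1]
  }
  structure(list(K = K, b = b, mesh = mesh), class = "fem_system")
}

#' Solve the assembled potential system
#'
#' Jacobi-preconditioned conjugate gradients on the pure-Neumann system,
#' with the one-dimensional constant null space handled by deflation
#' (iterates and residuals are kept zero-mean), so the returned potential
#' obeys the zero-mean gauge. Convergence is declared when the RMS of the
#' residual falls below `tol` times the RMS of the load (relative residual).
#'
#' @param system A `fem_system` from [assemble_system()].
#' @param tol Relative residual RMS target (default `1e-4`).
#' @param max_iter Iteration cap.
#' @return A list of class `potential_solution` with `phi` (per-node
#'   potential, V, zero-mean), `residual` (achieved relative RMS),
#'   `iterations`, and `residual_history`.
#' @export
solve_potential <- function(system, tol = 1e-4, max_iter = 10000L) {
  stopifnot(inherits(system, "fem_system"))
  K <- system$K
  b <- system$b - mean(system$b)  # enforce compatibility to round-off
  n <- length(b)
  b_rms <- sqrt(mean(b^2))
  if (b_rms == 0)
    return(structure(list(phi = numeric(n), residual = 0, iterations = 0L,
                          residual_history = numeric(0)),
                     class = "potential_solution"))
  dK <- Matrix::diag(K)
  dK[dK <= 0] <- 1
  x <- numeric(n)
  r <- b
  z <- r / dK
  z <- z - mean(z)
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    Kp <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    r <- r - mean(r)
    res <- sqrt(mean(r^2)) / b_rms
    hist <- c(hist, res)
    if (res <= tol || it >= max_iter) break
    z <- r / dK
    z <- z - mean(z)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (hist[it] > tol)
    stopf("CG did not reach tol %.2g in %d iterations (residual %.3g); history in traceback",
          tol, it, hist[it])
  structure(list(phi = x - mean(x), residual = hist[it], iterations = it,
                 residual_history = hist),
            class = "potential_solution")
}

#' @export
print.potential_solution <- function(x, ...) {
  cat(sprintf("potential_solution: %d nodes, residual %.3g after %d iterations\n",
              length(x$phi), x$residual, x$iterations))
  invisible(x)
}

#' Total induced electric field per element
#'
#' Combines the primary field `-dA/dt` (per-tet average of the four nodal
#' values) with the secondary field `-grad Phi` (constant per tet for the
#' P1 potential) into the total induced field `Et = Ep + Es`.
#'
#' @param mesh A [tetra_mesh()].
#' @param phi A `potential_solution` from [solve_potential()] (or a bare
#'   numeric per-node potential).
#' @param dAdt Numeric n_nodes x 3 matrix (V/m), as in [assemble_system()].
#' @return A list of class `efield_solution` with per-tet 3-vector
#'   matrices `primary`, `secondary` and `total` (V/m).
#' @export
total_efield <- function(mesh, phi, dAdt) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  if (inherits(phi, "potential_solution")) phi <- phi$phi
  dAdt <- as.matrix(dAdt)
  tets <- mesh$tets
  gr <- tet_gradients(mesh)
  gradphi <- gr$g[[1]] * phi[tets[, 1]] + gr$g[[2]] * phi[tets[, 2]] +
    gr$g[[3]] * phi[tets[, 3]] + gr$g[[4]] * phi[tets[, 4]]
  primary <- -(dAdt[tets[, 1], , drop = FALSE] + dAdt[tets[, 2], , drop = FALSE] +
                 dAdt[tets[, 3], , drop = FALSE] + dAdt[tets[, 4], , drop = FALSE]) / 4
  structure(list(primary = primary, secondary = -gradphi,
                 total = primary - gradphi),
            class = "efield_solution")
}

#' @export
print.efield_solution <- function(x, ...) {
  cat(sprintf("efield_solution: %d tets, median |Et| = %.4g V/m\n",
              nrow(x$total), median(rownorm(x$total))))
  invisible(x)
}

#' Boundary faces of a tetrahedral mesh
#'
#' Triangular faces that belong to exactly one tetrahedron, with outward
#' unit normals and areas.
#'
#' @param mesh A [tetra_mesh()].
#' @return A list with `faces` (k x 3 node indices), `tet` (owning tet
#'   index), `normal` (k x 3 outward unit normals) and `area` (k).
#' @export
boundary_faces <- function(mesh) {
  tets <- mesh$tets
  m <- nrow(tets)
  # the four faces of each tet (local opposite-vertex ordering)
  loc <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  fidx <- do.call(rbind, lapply(1:4, function(f) {
    cbind(tets[, loc[f, 1]], tets[, loc[f, 2]], tets[, loc[f, 3]])
  }))
  owner <- rep(seq_len(m), times = 4)
  # sorted-index face key (vectorized; safe while n_nodes^3 < 2^53)
  s1 <- pmin(fidx[, 1], fidx[, 2], fidx[, 3])
  s3 <- pmax(fidx[, 1], fidx[, 2], fidx[, 3])
  s2 <- fidx[, 1] + fidx[, 2] + fidx[, 3] - s1 - s3
  nn1 <- nrow(mesh$nodes) + 1
  key <- (s1 * nn1 + s2) * nn1 + s3
  keep <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  faces <- fidx[keep, , drop = FALSE]
  owner <- owner[keep]
  a <- mesh$nodes[faces[, 1], , drop = FALSE]
  e1 <- mesh$nodes[faces[, 2], , drop = FALSE] - a
  e2 <- mesh$nodes[faces[, 3], , drop = FALSE] - a
  nrm <- vcross(e1, e2)
  area <- rownorm(nrm) / 2
  nrm <- nrm / (2 * area)
  # orient outward: away from the owning tet centroid
  cen_t <- (mesh$nodes[tets[owner, 1], , drop = FALSE] +
              mesh$nodes[tets[owner, 2], , drop = FALSE] +
              mesh$nodes[tets[owner, 3], , drop = FALSE] +
              mesh$nodes[tets[owner, 4], , drop = FALSE]) / 4
  cen_f <- (a + mesh$nodes[faces[, 2], , drop = FALSE] +
              mesh$nodes[faces[, 3], , drop = FALSE]) / 3
  flip <- rowSums(nrm * (cen_f - cen_t)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  list(faces = faces, tet = owner, normal = nrm, area = area)
}

#' Normal-current jump across an internal tissue interface
#'
#' For every face shared by a tet labeled `tissue_a` and one labeled
#' `tissue_b`, compares the normal current density `sigma Et . n` on the
#' two sides. The area-weighted signed mean of the jump, normalized by the
#' median interface current magnitude, measures how well the discrete
#' solution conserves current across the conductivity step (it holds
#' weakly for the P1 Galerkin solution).
#'
#' @param mesh A [tetra_mesh()].
#' @param efield An `efield_solution` from [total_efield()].
#' @param tissue_a,tissue_b Labels of the two tissues.
#' @return A list with `n_faces`, `mean_jump` (area-weighted signed mean,
#'   A/m^2), `scale` (median interface `|sigma Et . n|`) and
#'   `relative_mean`.
#' @export
interface_flux_jump <- function(mesh, efield, tissue_a, tissue_b) {
  tets <- mesh$tets
  m <- nrow(tets)
  loc <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  fidx <- do.call(rbind, lapply(1:4, function(f)
    cbind(tets[, loc[f, 1]], tets[, loc[f, 2]], tets[, loc[f, 3]])))
  owner <- rep(seq_len(m), times = 4)
  s1 <- pmin(fidx[, 1], fidx[, 2], fidx[, 3])
  s3 <- pmax(fidx[, 1], fidx[, 2], fidx[, 3])
  s2 <- fidx[, 1] + fidx[, 2] + fidx[, 3] - s1 - s3
  nn1 <- nrow(mesh$nodes) + 1
  key <- (s1 * nn1 + s2) * nn1 + s3
  ord <- order(key)
  same <- key[ord][-1] == key[ord][-length(key)]
  t1 <- owner[ord][c(same, FALSE)]
  t2 <- owner[ord][c(FALSE, same)]
  lab <- mesh$tissue_label
  sel <- (lab[t1] == tissue_a & lab[t2] == tissue_b) |
    (lab[t1] == tissue_b & lab[t2] == tissue_a)
  if (!any(sel)) stopf("no %s/%s interface faces found", tissue_a, tissue_b)
  fi <- fidx[ord, , drop = FALSE][c(same, FALSE), , drop = FALSE][sel, , drop = FALSE]
  a <- mesh$nodes[fi[, 1], , drop = FALSE]
  e1 <- mesh$nodes[fi[, 2], , drop = FALSE] - a
  e2 <- mesh$nodes[fi[, 3], , drop = FALSE] - a
  nrm <- vcross(e1, e2)
  area <- rownorm(nrm) / 2
  nrm <- nrm / (2 * area)
  sig <- per_tet_sigma(mesh)
  j1 <- sig[t1[sel]] * rowSums(efield$total[t1[sel], , drop = FALSE] * nrm)
  j2 <- sig[t2[sel]] * rowSums(efield$total[t2[sel], , drop = FALSE] * nrm)
  scale <- median(abs(c(j1, j2)))
  mean_jump <- sum(area * (j1 - j2)) / sum(area)
  list(n_faces = sum(sel), mean_jump = mean_jump, scale = scale,
       relative_mean = abs(mean_jump) / scale)
}

#' Discrete Neumann residual of an E-field solution
#'
#' Area-weighted mean of the normal current density `sigma Et . n` over the
#' boundary faces, normalized by the median interior current density
#' `sigma |Et|`. For a converged pure-Neumann solve this is a small
#' fraction of the interior scale (the no-current-leaves-the-domain
#' condition holds weakly).
#'
#' @param mesh A [tetra_mesh()].
#' @param efield An `efield_solution` from [total_efield()].
#' @return A list with `mean_normal_current` (signed, area-weighted mean of
#'   `sigma Et . n`, A/m^2), `interior_scale` (median interior
#'   `sigma |Et|`), and their ratio `relative`.
#' @export
neumann_residual <- function(mesh, efield) {
  bf <- boundary_faces(mesh)
  sig <- per_tet_sigma(mesh)
  jn <- sig[bf$tet] * rowSums(efield$total[bf$tet, , drop = FALSE] * bf$normal)
  interior <- setdiff(seq_len(nrow(mesh$tets)), unique(bf$tet))
  if (!length(interior)) interior <- seq_len(nrow(mesh$tets))
  scale <- median(sig[interior] * rownorm(efield$total[interior, , drop = FALSE]))
  mean_jn <- sum(bf$area * jn) / sum(bf$area)
  list(mean_normal_current = mean_jn, interior_scale = scale,
       relative = abs(mean_jn) / scale)
}
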