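test_that("mesh construction validates and reorients tetrahedra", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # inverted ordering is repaired to positive volume
  mesh <- tetra_mesh(nodes, rbind(c(1, 3, 2, 4)), "gm")
  expect_gt(tmsfield:::tet_volume6(mesh$nodes, mesh$tets), 0)
  expect_equal(tet_volumes(mesh), 1 / 6)
  expect_error(tetra_mesh(nodes, rbind(c(1, 2, 3, 4)), "bone"), "no conductivity")
  expect_error(tetra_mesh(nodes, rbind(c(1, 2, 3, 5)), "gm"), "out of range")
  expect_error(tetra_mesh(rbind(nodes, c(0.5, 0.5, 0)),
                          rbind(c(1, 2, 3, 5)), "gm"), "degenerate")
})

test_that("assembled system has the pure-Neumann structure", {
  mesh <- shared_sphere(0.03)
  set.seed(11)
  dAdt <- matrix(rnorm(3 * nrow(mesh$nodes)), ncol = 3)
  sys <- assemble_system(mesh, dAdt)
  # zero row sums: constants in the null space
  expect_lt(max(abs(Matrix::rowSums(sys$K))), 1e-12 * max(abs(sys$K)))
  # compatibility: load sums to ~0
  expect_lt(abs(sum(sys$b)), 1e-10 * sum(abs(sys$b)))
  # symmetry
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))), 1e-15)
  # zero drive -> zero load
  expect_equal(assemble_system(mesh, 0 * dAdt)$b, numeric(nrow(mesh$nodes)))
})

test_that("uniform dA/dt in a homogeneous mesh loads only the boundary", {
  mesh <- shared_sphere(0.03)
  hom <- tetra_mesh(mesh$nodes, mesh$tets, rep("gm", nrow(mesh$tets)))
  dAdt <- matrix(rep(c(1, 2, -3), each = nrow(hom$nodes)), ncol = 3)
  b <- assemble_system(hom, dAdt)$b
  bnodes <- sort(unique(as.vector(boundary_faces(hom)$faces)))
  interior <- setdiff(seq_len(nrow(hom$nodes)), bnodes)
  expect_lt(max(abs(b[interior])), 1e-12 * max(abs(b[bnodes])))
})

test_that("potential solve matches a dense direct solve on a toy mesh", {
  mesh <- make_two_tet_mesh()
  set.seed(3)
  dAdt <- matrix(rnorm(15), 5, 3)
  sys <- assemble_system(mesh, dAdt)
  sol <- solve_potential(sys, tol = 1e-12)
  # dense oracle: pin the mean with a Lagrange multiplier
  K <- as.matrix(sys$K)
  aug <- rbind(cbind(K, 1), c(rep(1, 5), 0))
  x <- solve(aug, c(sys$b - mean(sys$b), 0))[1:5]
  expect_equal(sol$phi, x - mean(x), tolerance = 1e-10)
  expect_lte(sol$residual, 1e-12)
})

test_that("zero load returns the zero potential under the zero-mean gauge", {
  mesh <- make_two_tet_mesh()
  sys <- assemble_system(mesh, matrix(0, 5, 3))
  sol <- solve_potential(sys)
  expect_equal(sol$phi, numeric(5))
  expect_equal(sol$iterations, 0L)
})

test_that("solution is invariant under joint conductivity and load scaling", {
  mesh <- shared_sphere(0.03)
  set.seed(5)
  dAdt <- matrix(rnorm(3 * nrow(mesh$nodes)), ncol = 3)
  sol1 <- solve_potential(assemble_system(mesh, dAdt), tol = 1e-8)
  scaled <- tetra_mesh(mesh$nodes, mesh$tets, mesh$tissue_label,
                       10 * tissue_conductivities())
  sol2 <- solve_potential(assemble_system(scaled, dAdt), tol = 1e-8)
  expect_equal(sol2$phi, sol1$phi, tolerance = 1e-5)
})

test_that("non-convergence raises a diagnostic error", {
  mesh <- shared_sphere(0.03)
  set.seed(6)
  dAdt <- matrix(rnorm(3 * nrow(mesh$nodes)), ncol = 3)
  sys <- assemble_system(mesh, dAdt)
  expect_error(solve_potential(sys, tol = 1e-14, max_iter = 2L),
               "did not reach")
})

test_that("total E-field assembles primary and secondary parts", {
  mesh <- make_two_tet_mesh()
  # linear potential phi = k x, no drive: secondary = (-k, 0, 0) exactly
  k <- 2.5
  ef <- total_efield(mesh, k * mesh$nodes[, 1], matrix(0, 5, 3))
  expect_equal(ef$secondary, matrix(rep(c(-k, 0, 0), each = 2), 2, 3),
               tolerance = 1e-14)
  expect_equal(ef$total, ef$primary + ef$secondary)
  # primary is the per-tet nodal average of -dA/dt
  dAdt <- matrix(seq_len(15), 5, 3)
  ef2 <- total_efield(mesh, numeric(5), dAdt)
  expect_equal(ef2$primary[1, ],
               -colMeans(dAdt[1:4, ]), tolerance = 1e-14)
})

test_that("E-field is linear in the drive rate", {
  mesh <- shared_sphere(0.03)
  path <- apply_pose(build_spiral_figure8(coil_preset("bsm819")),
                     rigid_pose(diag(3), c(0, 0, 0.098)))
  A <- vector_potential(path, mesh$nodes, current = 1, w = 1, cfg = coarse_cfg())
  solve_et <- function(didt) {
    dAdt <- A$vectors * didt
    sol <- solve_potential(assemble_system(mesh, dAdt), tol = 1e-8)
    total_efield(mesh, sol, dAdt)$total
  }
  e1 <- solve_et(38.5e6)
  e2 <- solve_et(77.0e6)
  expect_equal(e2, 2 * e1, tolerance = 1e-6)
})

test_that("discrete Neumann condition and flux conservation hold on the sphere", {
  mesh <- shared_sphere(0.015)
  path <- apply_pose(build_spiral_figure8(coil_preset("bsm819")),
                     rigid_pose(diag(3), c(0, 0, 0.098)))
  A <- vector_potential(path, mesh$nodes, current = 1, w = 1, cfg = coarse_cfg())
  dAdt <- A$vectors * 38.5e6
  sol <- solve_potential(assemble_system(mesh, dAdt), tol = 1e-6)
  ef <- total_efield(mesh, sol, dAdt)
  nr <- neumann_residual(mesh, ef)
  expect_lt(nr$relative, 1e-2)
})

test_that("normal current is conserved across the csf/gm interface (weakly)", {
  mesh <- shared_sphere(0.015)
  path <- apply_pose(build_spiral_figure8(coil_preset("bsm819")),
                     rigid_pose(diag(3), c(0, 0, 0.098)))
  A <- vector_potential(path, mesh$nodes, current = 1, w = 1, cfg = coarse_cfg())
  dAdt <- A$vectors * 38.5e6
  sol <- solve_potential(assemble_system(mesh, dAdt), tol = 1e-6)
  ef <- total_efield(mesh, sol, dAdt)
  jump <- interface_flux_jump(mesh, ef, "csf", "gm")
  expect_lt(jump$relative_mean, 0.05)
})

test_that("homogeneous sphere under figure-8 drive has little radial surface field", {
  mesh <- shared_sphere(0.015)
  hom <- tetra_mesh(mesh$nodes, mesh$tets, rep("gm", nrow(mesh$tets)))
  path <- apply_pose(build_spiral_figure8(coil_preset("bsm819")),
                     rigid_pose(diag(3), c(0, 0, 0.098)))
  A <- vector_potential(path, hom$nodes, current = 1, w = 1, cfg = coarse_cfg())
  dAdt <- A$vectors * 38.5e6
  sol <- solve_potential(assemble_system(hom, dAdt), tol = 1e-6)
  ef <- total_efield(hom, sol, dAdt)
  bf <- boundary_faces(hom)
  Et <- ef$total[bf$tet, ]
  radial <- abs(rowSums(Et * bf$normal))
  expect_lt(median(radial) / median(sqrt(rowSums(Et^2))), 0.1)
})

test_that("surface-patch field converges under mesh refinement", {
  patch <- shared_patch()
  path <- apply_pose(build_spiral_figure8(coil_preset("bsm819")),
                     rigid_pose(diag(3), c(0, 0, 0.098)))
  mean_et <- vapply(c(0.03, 0.02, 0.015), function(edge) {
    mesh <- shared_sphere(edge)
    A <- vector_potential(path, mesh$nodes, current = 1, w = 1, cfg = coarse_cfg())
    dAdt <- A$vectors * 38.5e6
    sol <- solve_potential(assemble_system(mesh, dAdt), tol = 1e-6)
    f <- sample_field_on_patch(total_efield(mesh, sol, dAdt), mesh, patch)
    mean(sqrt(rowSums(f^2)))
  }, 0)
  expect_lt(abs(mean_et[3] - mean_et[2]) / mean_et[3], 0.05)
})
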