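# Shared fixtures, all built in code.

# closed polygonal circular loop in z = 0
make_loop <- function(radius = 0.044, n_seg = 64L, current = 1) {
  th <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  nodes <- cbind(radius * cos(th), radius * sin(th), 0)
  segs <- cbind(seq_len(n_seg), c(seq_len(n_seg)[-1L], 1L))
  wire_path(nodes, segs, current)
}

# two-tet mesh with an analytic dense solve available
make_two_tet_mesh <- function(label = "gm") {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tetra_mesh(nodes, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), rep(label, 2))
}

# coarse integration config with a permissive singularity guard
coarse_cfg <- function(step = 2e-3, min_distance = 1e-3) {
  integration_config(step, min_distance)
}

# small sphere-head mesh reused by the FEM and acceptance tests
shared_sphere <- local({
  cache <- NULL
  function(target_edge = 0.015) {
    key <- as.character(target_edge)
    if (is.null(cache[[key]]))
      cache[[key]] <<- make_sphere_head(target_edge = target_edge)
    cache[[key]]
  }
})

# gyrus ROI placed inside the gray-matter shell at the top of the sphere
shared_patch <- function() {
  translate_patch(make_gyrus_patch(0.02, 0.02, 0.003, 0.01, 0.002),
                  c(0, 0, 0.073))
}

# one full FEM pipeline evaluation of the activation metric
pipeline_ec <- function(preset, rot_z_angle, mesh, patch,
                        machine_output = 0.7, tol = 1e-4) {
  spec <- coil_preset(preset)
  path <- tmsfield:::build_coil_from_spec(spec)
  path <- apply_pose(path, rigid_pose(rot_z(rot_z_angle), c(0, 0, 0.098)))
  A <- vector_potential(path, mesh$nodes, current = 1, w = 1, cfg = coarse_cfg())
  dAdt <- A$vectors * (max_didt(pulse_spec(), machine_output) *
                         spec$distribution_factor)
  sol <- solve_potential(assemble_system(mesh, dAdt), tol = tol)
  f <- sample_field_on_patch(total_efield(mesh, sol, dAdt), mesh, patch)
  ec_metric(patch, f)$ec
}
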