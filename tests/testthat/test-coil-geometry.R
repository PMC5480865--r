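test_that("single-loop builder places two opposite-current wings of the right size", {
  spec <- coil_preset("bsm811")
  p <- build_single_loop_figure8(spec)
  expect_equal(nrow(p$segments), 2L * 92L)
  expect_equal(nrow(p$nodes), 2L * 92L)  # node count per wing == segments (closed)

  cur_r <- unique(sign(p$segment_current[1:92]))
  cur_l <- unique(sign(p$segment_current[93:184]))
  expect_equal(cur_r, -cur_l)

  # wing centers at +/-(R + gap/2) = +/-0.045
  seg_r <- seq_len(92)
  cen_r <- colMeans(p$nodes[unique(as.vector(p$segments[seg_r, ])), , drop = FALSE])
  cen_l <- colMeans(p$nodes[unique(as.vector(p$segments[-seg_r, ])), , drop = FALSE])
  expect_equal(cen_r, c(0.045, 0, 0), tolerance = 1e-12)
  expect_equal(cen_l, c(-0.045, 0, 0), tolerance = 1e-12)

  # all wing nodes at radius R from the wing center
  rad <- sqrt((p$nodes[1:92, 1] - 0.045)^2 + p$nodes[1:92, 2]^2)
  expect_equal(rad, rep(0.044, 92), tolerance = 1e-12)

  expect_error(build_single_loop_figure8(coil_preset("bsm819")), "n_windings")
})

test_that("closed wings sum segment direction vectors to zero", {
  p <- build_single_loop_figure8(coil_preset("bsm811"))
  d <- p$nodes[p$segments[, 2], ] - p$nodes[p$segments[, 1], ]
  expect_equal(colSums(d[1:92, ]), c(0, 0, 0), tolerance = 1e-15)
  expect_equal(colSums(d[93:184, ]), c(0, 0, 0), tolerance = 1e-15)
})

test_that("wings are mirror images with opposite currents and co-directed center", {
  for (builder in list(build_single_loop_figure8, build_spiral_figure8)) {
    spec <- if (identical(builder, build_single_loop_figure8))
      coil_preset("bsm811") else coil_preset("bsm819")
    p <- builder(spec)
    pos <- p$segment_current > 0
    # mirror symmetry of the node sets through the y-z plane
    right_nodes <- p$nodes[unique(as.vector(p$segments[pos, ])), ]
    left_nodes <- p$nodes[unique(as.vector(p$segments[!pos, ])), ]
    mirrored <- right_nodes %*% diag(c(-1, 1, 1))
    ord1 <- order(mirrored[, 1], mirrored[, 2], mirrored[, 3])
    ord2 <- order(left_nodes[, 1], left_nodes[, 2], left_nodes[, 3])
    expect_equal(mirrored[ord1, ], left_nodes[ord2, ], tolerance = 1e-12)
    # co-directed central currents: effective flow near x = 0 has the same y sign
    dirs <- (p$nodes[p$segments[, 2], ] - p$nodes[p$segments[, 1], ]) *
      sign(p$segment_current)
    mid <- (p$nodes[p$segments[, 1], ] + p$nodes[p$segments[, 2], ]) / 2
    central <- abs(mid[, 1]) < 0.01
    ysign <- sign(dirs[central, 2])
    ysign <- ysign[ysign != 0]
    expect_true(all(ysign == ysign[1]))
  }
})

test_that("spiral wing spans inner to outer radius with the catalogue pitch", {
  spec <- coil_preset("bsm819")
  expect_equal((spec$outer_radius - spec$inner_radius) / spec$n_windings, 0.002)

  p <- build_spiral_figure8(spec)
  # first node of the + wing lies at inner_radius from the wing origin,
  # the last at outer_radius
  xc <- spec$outer_radius + spec$wing_gap / 2
  wing_nodes <- p$nodes[seq_len(764), ]  # 763 segments -> 764 nodes, open
  r_first <- sqrt((wing_nodes[1, 1] - xc)^2 + wing_nodes[1, 2]^2)
  r_last <- sqrt((wing_nodes[764, 1] - xc)^2 + wing_nodes[764, 2]^2)
  expect_equal(r_first, spec$inner_radius, tolerance = 1e-12)
  expect_equal(r_last, spec$outer_radius, tolerance = 1e-12)

  # consecutive half-circle endpoints coincide: polyline is continuous
  d <- p$nodes[p$segments[, 2], ] - p$nodes[p$segments[, 1], ]
  expect_lt(max(sqrt(rowSums(d^2))), 0.006)

  expect_error(build_spiral_figure8(coil_spec(0.044, 0.044, n_windings = 1,
                                              segments_per_wing = 92)),
               "n_windings")
  expect_error(coil_spec(0.044, 0.044, n_windings = 9), "zero pitch")
})

test_that("spiral wing length matches the closed-form half-circle sum", {
  spec <- coil_preset("bsm819")
  p <- build_spiral_figure8(spec)
  wing_len <- wire_length(p) / 2
  # 18 half circles at radii 26, 27, ..., 43 mm
  radii <- (26:43) * 1e-3
  closed_form <- pi * sum(radii)
  expect_equal(wing_len, closed_form, tolerance = 2e-3)  # inscribed chords
  expect_lt(wing_len, closed_form)
})

test_that("wire-length ratio of the spiral to single-loop model is near 7", {
  ratio <- length_ratio_factor(build_single_loop_figure8(coil_preset("bsm811")),
                               build_spiral_figure8(coil_preset("bsm819")))
  expect_gt(ratio, 6.5)
  expect_lt(ratio, 7.5)
  expect_equal(round(ratio), 7)
})

test_that("stacked builder reproduces the catalogue segment counts and superposition", {
  spec <- coil_preset("bsm879")
  p <- build_stacked_spiral_figure8(spec)
  expect_equal(nrow(p$segments), 2L * 5341L)

  # degenerate stack equals the plain spiral
  spec1 <- spec
  spec1$n_layers <- 1L
  spec1$segments_per_wing <- 763L
  expect_equal(build_stacked_spiral_figure8(spec1)$nodes,
               build_spiral_figure8(spec1)$nodes)

  # layers straddle the coil plane symmetrically
  expect_equal(mean(p$nodes[, 3]), 0, tolerance = 1e-12)
  expect_equal(sort(unique(round(p$nodes[, 3], 9))),
               ((0:6) - 3) * 1e-3, tolerance = 1e-9)

  expect_error(build_stacked_spiral_figure8(spec, layer_pitch = 0), "layer_pitch")
})

test_that("stacked field at w = 1/n equals the mean of shifted single-layer fields", {
  spec <- coil_spec(0.026, 0.044, n_windings = 9, n_layers = 3,
                    segments_per_wing = 300L)
  pitch <- 2e-3
  stacked <- build_stacked_spiral_figure8(spec, layer_pitch = pitch)
  lay <- spec
  lay$n_layers <- 1L
  lay$segments_per_wing <- 100L
  single <- build_spiral_figure8(lay)
  set.seed(42)
  pts <- cbind(runif(10, -0.05, 0.05), runif(10, -0.05, 0.05),
               runif(10, -0.09, -0.05))
  cfg <- coarse_cfg()
  b_stacked <- magnetic_field(stacked, pts, current = 1, w = 1 / 3, cfg = cfg)$vectors
  b_mean <- Reduce(`+`, lapply(((0:2) - 1) * pitch, function(dz) {
    p <- single
    p$nodes[, 3] <- p$nodes[, 3] + dz
    magnetic_field(p, pts, current = 1, w = 1, cfg = cfg)$vectors
  })) / 3
  expect_equal(b_stacked, b_mean, tolerance = 1e-12)
})

test_that("polyline length converges to the arc length from below, monotonically", {
  lens <- vapply(c(16L, 32L, 64L, 128L, 256L),
                 function(n) wire_length(make_loop(0.044, n)), 0)
  arc <- 2 * pi * 0.044
  expect_true(all(lens < arc))
  expect_true(all(diff(lens) > 0))
  expect_equal(lens[5], arc, tolerance = 1e-4)
  # BSM-811 total polyline length per wing approaches 2 pi R = 0.27646 m
  expect_equal(wire_length(make_loop(0.044, 4096L)), 0.27646, tolerance = 1e-4)
})

test_that("apply_pose is rigid: identity, rotation, lengths and distances", {
  p <- build_spiral_figure8(coil_preset("bsm819"))
  expect_identical(apply_pose(p, rigid_pose())$nodes, p$nodes)

  q <- apply_pose(build_single_loop_figure8(coil_preset("bsm811")),
                  rigid_pose(rot_z(pi / 2)))
  cen <- colMeans(q$nodes[1:92, ])
  expect_equal(cen, c(0, 0.045, 0), tolerance = 1e-12)

  pose <- rigid_pose(rot_z(0.7) %*% rot_x(-0.3), c(0.01, -0.02, 0.05))
  pp <- apply_pose(p, pose)
  expect_equal(wire_length(pp), wire_length(p), tolerance = 1e-13)
  idx <- seq(1, nrow(p$nodes), by = 97)
  d_before <- as.matrix(dist(p$nodes[idx, ]))
  d_after <- as.matrix(dist(pp$nodes[idx, ]))
  expect_lt(max(abs(d_after - d_before) / (d_before + diag(nrow(d_before)))), 1e-12)

  expect_error(rigid_pose(matrix(1, 3, 3)), "orthonormal")
})

test_that("wire_length sums Euclidean segment lengths", {
  sq <- wire_path(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                  rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 1)
  expect_equal(wire_length(sq), 4)
  # inscribed polygon: slightly below the arc length
  expect_lt(wire_length(make_loop(0.044, 92L)), 2 * pi * 0.044)
  expect_equal(wire_length(make_loop(0.044, 92L)), 2 * pi * 0.044,
               tolerance = 1e-3)
})

test_that("coil specs validate their invariants and round-trip through YAML", {
  expect_error(coil_spec(0.05, 0.044), "outer_radius")
  expect_error(coil_spec(0.044, 0.044, segments_per_wing = 4), "segments_per_wing")
  expect_error(coil_spec(0.044, 0.044, integration_step = 0), "integration_step")

  spec <- coil_preset("bsm879")
  expect_equal(spec$distribution_factor, 1 / 7)
  f <- tempfile(fileext = ".yaml")
  write_coil_spec(spec, f)
  back <- read_coil_spec(f)
  expect_equal(back[setdiff(names(back), "name")],
               spec[setdiff(names(spec), "name")])
})
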