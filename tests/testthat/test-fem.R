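test_that("default geometry instantiates the full focal-adhesion census", {
  model <- build_cell_geometry(cell_model_config())
  expect_identical(nrow(model$fa), 56L)
  expect_identical(sum(model$fa$class == "CFA"), 42L)
  expect_identical(sum(model$fa$class == "ACAFA"), 14L)
  expect_length(model$fibers, 7L)
  # every fiber starts and ends at basal height inside an ACAFA sector
  half <- nucmorph:::deg2rad(model$fiber_sector_half_angle)
  for (pl in model$fibers) {
    expect_equal(unname(pl[1, "z"]), 0)
    expect_equal(unname(pl[nrow(pl), "z"]), 0)
    for (idx in c(1, nrow(pl))) {
      ang <- atan2(pl[idx, "y"], pl[idx, "x"])
      expect_true(abs(ang) <= half + 1e-9 || abs(abs(ang) - pi) <= half + 1e-9)
    }
  }
})

test_that("meshing is conforming, boundary-fitted and correctly labelled", {
  mesh <- default_cell_mesh()
  model <- mesh$model
  # FA nodes on the basal plane
  fa_nodes <- unique(unlist(mesh$fa$node_set))
  expect_true(all(abs(mesh$nodes[fa_nodes, 3]) < 1e-9))
  # FA node sets are disjoint
  expect_identical(anyDuplicated(unlist(mesh$fa$node_set)), 0L)
  # each fiber endpoint is tied to exactly one ACAFA patch node
  ends <- mesh$tie_end
  expect_length(ends, 2L * model$n_fibers)
  for (e in ends) {
    tie <- mesh$ties[[e$beam_node]]
    expect_length(tie$nodes, 1L)
    expect_identical(tie$nodes, mesh$fa$snap_node[e$fa_row])
    expect_identical(mesh$fa$class[e$fa_row], "ACAFA")
  }
  # meshed region volumes approach the geometric volumes on refinement
  vol_dome <- stats::integrate(function(r) {
    2 * pi * r * nucmorph:::dome_height(model, r)
  }, 0, model$cell_radius)$value
  vol_nuc <- 4 / 3 * pi * prod(model$nucleus_semi_axes)
  fine <- mesh_cell(build_cell_geometry(cell_model_config(mesh_h = 1, n_layers = 6)))
  pv <- nucmorph:::mesh_phase_volumes(fine)
  expect_rel(sum(pv), vol_dome, 0.02)
  expect_rel(pv[["nucleus"]], vol_nuc, 0.02)
})

test_that("tetrahedral elements pass rigid-body and patch tests", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mid <- (co[rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))[, 1], ] +
            co[rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))[, 2], ]) / 2
  for (corners in list(co, rbind(co, mid))) {
    K <- tet_stiffness(corners, E = 1000, nu = 0.3)
    expect_equal(K, t(K), tolerance = 1e-9)
    # rigid translation produces zero force
    ut <- rep(c(1, -2, 0.5), nrow(corners))
    expect_lt(max(abs(K %*% ut)), 1e-8 * max(abs(K)))
    # exactly 6 rigid-body modes
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_identical(sum(ev < max(ev) * 1e-9), 6L)
  }
  # patch test: a linear displacement field gives identical constant stress
  # in every element of an assembled patch
  mesh <- default_cell_mesh()
  A <- matrix(c(0.01, 0.002, 0, 0.001, -0.004, 0.003, 0, 0.002, 0.005), 3, 3)
  u <- mesh$nodes %*% t(A)
  sol <- list(displacements = u, mesh = mesh)
  class(sol) <- "cell_fem_solution"
  eps <- (A + t(A)) / 2
  D <- nucmorph:::elastic_D(mesh$model$materials$cytoplasm$E,
                            mesh$model$materials$cytoplasm$nu)
  sig <- D %*% c(eps[1, 1], eps[2, 2], eps[3, 3],
                 2 * eps[1, 2], 2 * eps[2, 3], 2 * eps[3, 1])
  vm_ref <- nucmorph:::von_mises(sig)
  vm <- nucmorph:::element_von_mises(sol)
  sel <- mesh$tet_phase == "cytoplasm"
  expect_lt(max(abs(vm[sel] - vm_ref)) / vm_ref, 1e-8)
  expect_error(tet_stiffness(co[c(1, 2, 3, 3), ] + 0, 1000, 0.3))
})

test_that("Timoshenko beams match the shear-deformable closed forms", {
  L <- 10; E <- 1e6; G <- E / 2.6; r <- 0.5
  A <- pi * r^2; I <- pi * r^4 / 4; kap <- 0.9
  K <- timoshenko_beam_stiffness(L, E, G, A, I, kap)
  free <- 7:18
  # transverse tip load: delta = PL^3/3EI + PL/(kGA) within 0.5%
  f <- numeric(18); f[14] <- 1
  u <- solve(K[free, free], f[free])
  expect_rel(u[14 - 6], L^3 / (3 * E * I) + L / (kap * G * A), 0.005)
  # kGA -> infinity limit: Euler-Bernoulli deflection
  K2 <- timoshenko_beam_stiffness(L, E, G * 1e8, A, I, kap)
  u2 <- solve(K2[free, free], f[free])
  expect_rel(u2[14 - 6], L^3 / (3 * E * I), 0.005)
  # axial load: PL/EA exactly
  fa <- numeric(18); fa[13] <- 1
  ua <- solve(K[free, free], fa[free])
  expect_rel(ua[13 - 6], L / (E * A), 1e-9)
  expect_error(timoshenko_beam_stiffness(-1, E, G, A, I), "L")
})

test_that("boundary conditions implement the prescribed stretch", {
  mesh <- default_cell_mesh()
  bc <- apply_stretch_bc(mesh, strain = 0.08)
  ux_idx <- bc$idx[bc$idx %% 3 == 1]
  nodes <- (ux_idx - 1) %/% 3 + 1
  expect_equal(bc$val[match(ux_idx, bc$idx)], 0.08 * mesh$nodes[nodes, 1])
  # all basal nodes restrained out of plane
  uz_idx <- 3 * (mesh$basal_nodes - 1) + 3
  expect_true(all(uz_idx %in% bc$idx))
  # zero strain gives the zero solution
  s0 <- solve_cell_fem(mesh, with_cap = TRUE, strain = 0)
  expect_lt(max(abs(s0$displacements)), 1e-12)
})

test_that("static solves are equilibrated and positive definite", {
  mesh <- default_cell_mesh()
  ns <- 3 * nrow(mesh$nodes)
  for (cap in c(TRUE, FALSE)) {
    sol <- solve_cell_fem(mesh, with_cap = cap)
    expect_lt(sol$residual, 1e-8)
    expect_gt(sol$strain_energy, 0)
    # external force balance over the solid translation DOFs (beam-end
    # rotation clamps carry moment reactions, not forces)
    r <- sol$reactions[seq_len(ns)]
    expect_lt(abs(sum(r[seq(1, ns, 3)])) / sum(abs(r)), 1e-6)
    expect_lt(abs(sum(r[seq(3, ns, 3)])) / sum(abs(r)), 1e-6)
  }
})

test_that("reaction reports are complete and near-symmetric", {
  mesh <- default_cell_mesh()
  rep <- fa_reaction_report(solve_cell_fem(mesh, with_cap = FALSE))
  expect_identical(nrow(rep), 56L)
  fr <- attr(rep, "class_fractions")
  expect_equal(sum(fr$fraction_pct), 100, tolerance = 0.1)
  # ACAFA fan mirror pairs: equal within 15% (the CFA sunflower packing is
  # chiral, so exact mirror symmetry of the load does not hold)
  aca <- rep[rep$class == "ACAFA", ]
  pair_of <- match(round(-aca$y, 6), round(aca$y, 6))
  same_side <- abs(aca$x - aca$x[pair_of]) < 1e-6
  mism <- abs(aca$fmag - aca$fmag[pair_of]) / pmax(aca$fmag, aca$fmag[pair_of])
  expect_lt(max(mism[same_side]), 0.15)
})

test_that("von Mises invariant matches canonical stress states", {
  expect_equal(nucmorph:::von_mises(c(7, 0, 0, 0, 0, 0)), 7)
  expect_equal(nucmorph:::von_mises(c(-3, -3, -3, 0, 0, 0)), 0)
  expect_equal(nucmorph:::von_mises(c(0, 0, 0, 2, 0, 0)), 2 * sqrt(3))
})

test_that("cap comparison isolates the fiber contribution", {
  cmp <- default_cap_comparison()
  expect_identical(nrow(cmp$fa_with), 56L)
  expect_identical(nrow(cmp$fa_without), 56L)
  expect_gt(cmp$cfa_fraction_without, cmp$cfa_fraction_with)
  # vanishing fiber stiffness removes the cap effect (within 2 points)
  cfg0 <- cell_model_config(materials = list(
    cytoplasm = list(E = 1000, nu = 0.37), nucleus = list(E = 5000, nu = 0.37),
    fiber = list(E = 1e-3, nu = 0.3)))
  cmp0 <- compare_cap(cfg0)
  expect_lt(abs(cmp0$cfa_reduction_pct), 2)
  expect_lt(abs(cmp0$stress_reduction_pct), 2)
  td <- tidy(cmp)
  expect_identical(nrow(td), 2L)
  expect_named(td, c("quantity", "without_cap", "with_cap", "reduction_pct"))
  gl <- glance(cmp)
  expect_lt(gl$residual_with, 1e-8)
})

test_that("nuclear stress statistics respond monotonically to fiber stiffness", {
  # in the fully tied (embedded-fiber) model, stiffer cap fibers transmit
  # more of the prescribed stretch into the nucleus they arch over
  sw <- fiber_stiffness_sweep(cell_model_config(),
                              fiber_E = 1.45e6 * c(0.1, 1, 10))
  expect_identical(nrow(sw), 3L)
  expect_true(all(diff(sw$mean_vm_with) > 0))
  ns <- nuclear_stress_report(default_cap_comparison()$solution_without)
  expect_true(all(c("mean_vm", "median_vm", "p95_vm", "mean_vm_unweighted") %in%
                    names(ns)))
  expect_gte(ns$p95_vm, ns$median_vm)
})

test_that("nuclear stress converges under mesh refinement (no cap)", {
  v <- vapply(list(c(2, 4), c(1, 6)), function(p) {
    cfg <- cell_model_config(mesh_h = p[1], n_layers = p[2])
    sol <- solve_cell_fem(mesh_cell(build_cell_geometry(cfg)), with_cap = FALSE)
    nuclear_stress_report(sol)$mean_vm
  }, numeric(1))
  expect_lt(abs(v[2] - v[1]) / v[2], 0.15)
})
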