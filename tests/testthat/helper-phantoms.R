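# shared fixtures, built once per test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

ellipsoid_mask <- function() {
  fixture("ellipsoid_mask", function() {
    spec <- nucleus_phantom_spec(semi_axes = c(8, 6, 3), voxel_size = c(0.2, 0.2, 0.2))
    segment_nucleus(make_nucleus_stack(spec))
  })
}

sphere_mask <- function() {
  fixture("sphere_mask", function() {
    spec <- nucleus_phantom_spec(semi_axes = c(1, 1, 1), voxel_size = c(0.05, 0.05, 0.05))
    segment_nucleus(make_nucleus_stack(spec))
  })
}

lobed_mask <- function() {
  fixture("lobed_mask", function() {
    spec <- nucleus_phantom_spec(semi_axes = c(8, 6, 3), lobe_count = 5,
                                 lobe_amplitude = 0.15, voxel_size = c(0.2, 0.2, 0.2))
    segment_nucleus(make_nucleus_stack(spec))
  })
}

default_cell_mesh <- function() {
  fixture("default_cell_mesh", function() {
    model <- build_cell_geometry(cell_model_config())
    mesh <- mesh_cell(model)
    mesh$K_solid <- nucmorph:::assemble_solid(mesh)
    mesh
  })
}

default_cap_comparison <- function() {
  fixture("default_cap_comparison", function() compare_cap(cell_model_config()))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
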