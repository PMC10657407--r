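test_that("surface_mesh validates its inputs", {
  expect_error(surface_mesh(matrix(0, 3, 2), matrix(1L, 1, 3)), "n x 3")
  expect_error(surface_mesh(matrix(0, 3, 3), matrix(c(1L, 2L, 5L), 1, 3)),
               "out of range")
})

test_that("boundary loops and enclosed volume behave on canonical shapes", {
  fx <- fix_tube_straight()
  loops <- boundary_loops(fx$mesh)
  expect_length(loops, 2)
  infos <- lapply(loops, pamorph:::loop_info, mesh = fx$mesh)
  expect_equal(sort(vapply(infos, `[[`, numeric(1), "radius")), c(5, 5),
               tolerance = 0.01)
  expect_equal(mesh_volume(fx$mesh), pi * 25 * 100, tolerance = 0.01)

  sm <- sphere_mesh(r = 10)
  expect_length(boundary_loops(sm), 0)
  expect_equal(mesh_volume(sm), 4 / 3 * pi * 1000, tolerance = 0.02)
})

test_that("STL and PLY round-trip preserves geometry", {
  fx <- fix_y_null()
  f1 <- tempfile(fileext = ".stl")
  f2 <- tempfile(fileext = ".ply")
  write_stl(fx$mesh, f1)
  write_ply(fx$mesh, f2, scalar = rep(1.5, nrow(fx$mesh$vertices)))
  m1 <- read_stl(f1)
  m2 <- read_ply(f2)
  expect_equal(nrow(m1$faces), nrow(fx$mesh$faces))
  expect_equal(nrow(m2$vertices), nrow(fx$mesh$vertices))
  expect_equal(mesh_volume(m1), mesh_volume(fx$mesh), tolerance = 1e-6)
  expect_equal(sort(m2$vertices[, 1]), sort(fx$mesh$vertices[, 1]),
               tolerance = 1e-6)
  expect_equal(m2$scalars$quality, rep(1.5, nrow(fx$mesh$vertices)))
  expect_length(boundary_loops(m1), length(boundary_loops(fx$mesh)))
})

test_that("voxelization reproduces analytic volumes and connectivity", {
  sm <- sphere_mesh(r = 10)
  mk <- voxelize(sm, 0.5)
  expect_equal(mask_volume(mk), 4 / 3 * pi * 1000, tolerance = 0.02)
  expect_error(voxelize(surface_mesh(matrix(0, 0, 3),
                                     matrix(integer(0), 0, 3)), 0.5), "empty")
  fx <- fix_tube_straight()
  tube <- voxelize(fx$mesh, 0.5)
  lab <- pamorph:::cpp_connected_components26(as.logical(tube$grid),
                                              dim(tube$grid))
  expect_equal(max(lab), 1)         # single 26-connected component
})
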