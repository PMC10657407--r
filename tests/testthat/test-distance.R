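test_that("identical and concentric surfaces give exact distances", {
  sm <- sphere_mesh(10, n_lat = 12, n_lon = 24)
  expect_equal(vertex_to_surface_distance(sm, sm),
               rep(0, nrow(sm$vertices)))
  # concentric spheres: vertex-to-surface distance equals the radial gap,
  # up to the outer sphere's faceting (vertices lie exactly on radius 10.4)
  s2 <- sphere_mesh(10.4, n_lat = 48, n_lon = 96)
  d <- vertex_to_surface_distance(sm, s2)
  expect_equal(mean(d), 0.4, tolerance = 0.02)
  expect_lt(max(abs(d - 0.4)), 0.05)
})

test_that("point-to-triangle distances agree with a brute-force oracle", {
  # unit cube vs a copy translated by 0.1 along x
  cube_verts <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  hull <- rbind(
    c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
    c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
    c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  cube <- surface_mesh(cube_verts, hull)
  shifted <- surface_mesh(sweep(cube_verts, 2, c(0.1, 0, 0), "+"), hull)
  d <- vertex_to_surface_distance(cube, shifted)
  oracle <- brute_mesh_distance(cube$vertices, shifted)
  expect_lt(max(abs(d - oracle)), 0.05)   # oracle granularity: 1/25 sampling
  expect_true(all(abs(d[cube_verts[, 1] == 0] - 0.1) < 1e-9))
  expect_true(all(d[cube_verts[, 1] == 1] < 1e-9))

  # random probe points against a small closed mesh, vs the same oracle
  set.seed(42)
  probes <- cbind(runif(20, -20, 20), runif(20, -20, 20), runif(20, 20, 60))
  small <- sphere_mesh(8, n_lat = 8, n_lon = 12, center = c(0, 0, 40))
  probe_mesh <- surface_mesh(probes, matrix(c(1L, 2L, 3L), 1, 3))
  expect_equal(vertex_to_surface_distance(probe_mesh, small),
               brute_mesh_distance(probes, small), tolerance = 5e-3)
})

test_that("distance is asymmetric but both directions are available", {
  a <- sphere_mesh(10, n_lat = 10, n_lon = 16)
  b <- sphere_mesh(10, n_lat = 10, n_lon = 16, center = c(3, 0, 0))
  dab <- mean(vertex_to_surface_distance(a, b))
  dba <- mean(vertex_to_surface_distance(b, a))
  expect_equal(dab, dba, tolerance = 1e-6)   # symmetric shapes here
  c2 <- sphere_mesh(5, n_lat = 10, n_lon = 16, center = c(2, 0, 0))
  expect_false(isTRUE(all.equal(mean(vertex_to_surface_distance(a, c2)),
                                mean(vertex_to_surface_distance(c2, a)))))
})

test_that("trunk restriction keeps MPA/LPA/RPA and drops side-branch tubes", {
  fy <- fix_y_null()
  d0 <- vertex_to_surface_distance(fy$mesh, fy$mesh)
  res <- restrict_to_trunk(fy$mesh, fy$lt, d0)
  expect_true(all(res$region_mask))          # no side branches: all trunk
  expect_equal(res$mean, 0)
  expect_equal(res$sd, 0)

  fs <- fix_y_sides()
  d1 <- vertex_to_surface_distance(fs$mesh, fs$mesh)
  res1 <- restrict_to_trunk(fs$mesh, fs$lt, d1)
  # classify mesh vertices by the generating tubes: a vertex on a side tube
  # is within (radius + eps) of a side-branch axis
  side_br <- fs$tree$branches[grep("SIDE", names(fs$tree$branches))]
  sb <- lapply(side_br, function(b) list(points = b$points, radii = b$radii))
  f_side <- pamorph:::cpp_tree_field_points(fs$mesh$vertices, unname(sb))
  on_side <- f_side < 0.05
  # exclude the orifice neighbourhood (inside the daughter lumen)
  daughters <- fs$tree$branches[c("LPA", "RPA")]
  f_d <- pamorph:::cpp_tree_field_points(fs$mesh$vertices,
                                         unname(lapply(daughters, function(b)
                                           list(points = b$points, radii = b$radii))))
  pure_side <- on_side & f_d > 2
  expect_gt(sum(pure_side), 100)
  expect_lt(mean(res1$region_mask[pure_side]), 0.05)
})

test_that("perturbed reconstructions report noise-scale trunk distances", {
  fy <- fix_y_null()
  noisy <- perturb_mesh(fy$mesh, sd = 0.3, seed = 5)
  res <- compare_surfaces(fy$mesh, noisy, fy$lt, symmetric = TRUE)
  expect_gt(res$mean, 0.05)
  expect_lt(res$mean, 0.5)
  expect_true(is.finite(res$symmetric_mean))
})
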