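test_that("threshold masking labels voxels strictly above the threshold", {
  img <- array(100, c(5, 5, 5))
  expect_equal(sum(mask_from_threshold(img, 170)$grid), 0)
  img[3, 3, 3] <- 500
  expect_equal(sum(mask_from_threshold(img, 175)$grid), 1)
  expect_error(mask_from_threshold(matrix(0, 3, 3), 10), "3D")
  expect_error(mask_from_threshold(img, Inf), "finite")

  # a synthetic contrast image of a tube reproduces the tube mask exactly
  fx <- fix_tube_straight()
  tube <- voxelize(fx$mesh, 1)
  img2 <- array(0, dim(tube$grid))
  img2[tube$grid] <- 300
  mk <- mask_from_threshold(list(data = img2, spacing = tube$spacing,
                                 origin = tube$origin), 170)
  expect_identical(mk$grid, tube$grid)
})

test_that("surface extraction recovers analytic volumes", {
  mk <- sphere_mask(r = 10, spacing = 0.5)
  mesh <- extract_surface(mk)
  expect_length(boundary_loops(mesh), 0)      # closed
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * 1000, tolerance = 0.02)
  expect_equal(mesh_volume(mesh), mask_volume(mk), tolerance = 0.05)
})

test_that("surface extraction handles degenerate and disconnected masks", {
  g <- array(FALSE, c(3, 3, 3)); g[2, 2, 2] <- TRUE
  single <- extract_surface(voxel_mask(g, 1))
  expect_length(boundary_loops(single), 0)
  v <- mesh_volume(single)
  expect_gt(v, 0.1); expect_lt(v, 1.5)

  g2 <- array(FALSE, c(12, 6, 6))
  g2[2:7, 2:5, 2:5] <- TRUE       # large blob
  g2[10, 3, 3] <- TRUE            # small blob
  expect_message(m2 <- extract_surface(voxel_mask(g2, 1)), "discarding")
  expect_equal(mesh_volume(m2), mesh_volume(extract_surface(
    voxel_mask(array(g2[1:8, , ], c(8, 6, 6)), 1))), tolerance = 1e-6)

  expect_error(extract_surface(voxel_mask(array(FALSE, c(3, 3, 3)), 1)),
               "empty")
})

test_that("surface -> voxelize -> extract preserves enclosed volume", {
  fy <- fix_y_null()
  v0 <- mesh_volume(fy$mesh)
  v1 <- mesh_volume(extract_surface(voxelize(fy$mesh, 0.5)))
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("volume error of extract(voxelize(.)) decreases as spacing shrinks", {
  truth <- 4 / 3 * pi * 1000
  errs <- vapply(c(1, 0.5, 0.25), function(sp) {
    abs(mesh_volume(extract_surface(sphere_mask(10, sp))) - truth) / truth
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("smoothing preserves volume, removes staircase, and is gentle on smooth input", {
  expect_identical(smooth_volume_preserving(fix_tube_straight()$mesh, 0),
                   fix_tube_straight()$mesh)

  rough <- extract_surface(sphere_mask(10, 0.8))
  sm <- smooth_volume_preserving(rough, 20)
  expect_equal(nrow(sm$vertices), nrow(rough$vertices))
  expect_lt(abs(mesh_volume(sm) - mesh_volume(rough)) / mesh_volume(rough),
            0.001)
  rad_dev <- function(m) max(abs(sqrt(rowSums(m$vertices^2)) - 10))
  expect_lt(rad_dev(sm), rad_dev(rough))
  expect_lt(pamorph:::face_normal_variation(sm),
            pamorph:::face_normal_variation(rough))

  # already-smooth analytic tube barely moves
  tube <- fix_tube_straight()$mesh
  smt <- smooth_volume_preserving(tube, 20)
  expect_lt(max(sqrt(rowSums((smt$vertices - tube$vertices)^2))), 0.1)
  expect_lt(abs(mesh_volume(smt) - mesh_volume(tube)) / mesh_volume(tube),
            0.001)
})
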