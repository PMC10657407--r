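test_that("generator is seed-deterministic and seeds differ", {
  a <- make_tree("human", seed = 1)
  b <- make_tree("human", seed = 1)
  c2 <- make_tree("human", seed = 2)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$truth, c2$truth))
})

test_that("drawn subject parameters stay within the template envelope", {
  for (s in 1:8) {
    tr <- make_tree("human", seed = s)
    expect_gt(tr$params$D_MPA, 27.6 - 3 * 3.37)
    expect_lt(tr$params$D_MPA, 27.6 + 3 * 3.37)
    expect_true(tr$params$n_side_lpa >= 2 && tr$params$n_side_lpa <= 10)
  }
})

test_that("continuous-curve truth satisfies the parameter definitions", {
  # straight constant tube: no taper, straight centreline
  t1 <- make_tree("custom", seed = 1,
                  params = list(kind = "tube", length = 100, radius = 10))
  expect_equal(t1$truth$CI, 1.0)
  expect_equal(t1$truth$taper, 0.0)
  expect_equal(t1$truth$length, 100)
  expect_equal(t1$truth$diameter, 20)

  # half-circle arc: chord over arc = 2/pi
  th <- make_tree("custom", seed = 1,
                  params = list(kind = "tube", radius = 5, ring_radius = 30,
                                arc_deg = 180))
  expect_equal(th$truth$CI, 2 / pi, tolerance = 1e-4)
  expect_equal(th$truth$length, pi * 30, tolerance = 1e-5)

  # area-preserving symmetric split nulls the enlargement index
  ty <- fix_y_null()$tree
  expect_equal(ty$truth$EnI, 0, tolerance = 1e-10)
  expect_equal(ty$truth$alpha, 90, tolerance = 1e-6)

  # species trees: truth taper/CI consistent with the daughter curves
  tr <- make_tree("ovine", seed = 4)
  for (side in c("LPA", "RPA")) {
    b <- tr$branches[[side]]
    off <- 10
    st <- pamorph:::interp_along(b$points, off, b$radii)
    en_r <- b$radii[length(b$radii)]
    expect_equal(tr$truth[[paste0("T_", side)]],
                 (2 * st$value - 2 * en_r) / (b$length - off),
                 tolerance = 1e-8)
  }
})

test_that("branch_spec enforces its invariants", {
  cp <- rbind(c(0, 0, 0), c(0, 0, 50))
  expect_s3_class(branch_spec(cp, 10, 8), "branch_spec")
  expect_error(branch_spec(cp, -1, 8), "positive")
  expect_error(branch_spec(rbind(c(0, 0, 0), c(0, 0, 0)), 10, 8),
               "non-coincident")
  child <- branch_spec(rbind(c(0, 0, 0), c(10, 0, 0)), 4, 4)
  expect_error(branch_spec(cp, 10, 8,
                           children = list(list(at = 1.2, branch = child))),
               "inside")
})

test_that("surfaces have exact tube radii and one boundary loop per open end", {
  fx <- fix_tube_straight()
  r <- sqrt(fx$mesh$vertices[, 1]^2 + fx$mesh$vertices[, 2]^2)
  expect_lt(max(abs(r - 5)), 0.01)
  expect_length(boundary_loops(fx$mesh), 2)

  expect_length(boundary_loops(fix_y_null()$mesh), 3)     # inlet + 2 outlets
  expect_length(boundary_loops(fix_y_sides()$mesh), 1 + 2 + 7)
})

test_that("self-intersecting specifications are rejected with a diagnostic", {
  bad <- make_tree("custom", seed = 1,
                   params = list(kind = "y", trunk_length = 50,
                                 trunk_radius = 10, daughter_length = 40,
                                 daughter_radius = 8, angle = 10))
  expect_error(surface_from_tree(bad, axial_step = 1), "self-intersecting")
})

test_that("ground truth serializes as a JSON sidecar", {
  tr <- fix_y_sides()$tree
  f <- tempfile(fileext = ".json")
  write_ground_truth(tr, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$L_MPA, tr$truth$L_MPA)
  expect_equal(back$n_side_rpa, tr$truth$n_side_rpa)
})

test_that("masks round-trip through NIfTI in millimetre coordinates", {
  mk <- sphere_mask(r = 6, spacing = 1)
  f <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(mk, f)
  back <- read_mask_nifti(f)
  expect_equal(dim(back$grid), dim(mk$grid))
  expect_equal(back$spacing, mk$spacing, tolerance = 1e-6)
  expect_equal(back$origin, mk$origin, tolerance = 1e-6)
  expect_equal(sum(back$grid), sum(mk$grid))
})
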