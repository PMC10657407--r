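test_that("straight cylinder yields an axial polyline with inscribed radii", {
  fx <- fix_tube_straight()
  V <- fx$cl$vertices
  expect_lt(max(sqrt(V[, 1]^2 + V[, 2]^2)), 0.5)
  expect_true(all(abs(fx$cl$radius - 5) < 0.25))
  expect_equal(total_arc_length(fx$cl), 100, tolerance = 0.02)
  # constant-radius tube: radii nearly constant along the line
  expect_lt(sd(fx$cl$radius) / mean(fx$cl$radius), 0.05)
})

test_that("topology matches the outlets: one leaf per outlet loop", {
  fy <- fix_y_null()
  expect_length(fy$cl$leaves, 2)
  expect_length(fy$cl$bifurcations, 1)
  fs <- fix_y_sides()
  expect_length(fs$cl$leaves, length(boundary_loops(fs$mesh)) - 1)
})

test_that("curved tube recovers arc length and curvature index", {
  fx <- fix_half_torus()
  expect_equal(total_arc_length(fx$cl), pi * 30, tolerance = 0.02)
  pp <- fx$cl$vertices[fx$cl$paths[[1]], ]
  expect_equal(curvature_index(pp), 2 / pi, tolerance = 0.02)
})

test_that("closed meshes and single-loop meshes are rejected", {
  expect_error(extract_centerline(sphere_mesh(8)), "closed")
})

test_that("an explicit inlet hint overrides the largest-loop default", {
  fy <- fix_y_null()
  # hint at an outlet: that loop becomes the root, the old inlet a leaf
  cl2 <- extract_centerline(fy$mesh, inlet_hint = c(60 / sqrt(2), 0,
                                                    60 + 60 / sqrt(2)))
  root_pos <- cl2$vertices[cl2$root, ]
  expect_gt(root_pos[1], 30)
  expect_length(cl2$leaves, 2)
})

test_that("resampling gives the requested per-path counts and spacing", {
  fx <- fix_tube_straight()
  rs <- resample_centerline(fx$cl, 101)
  expect_equal(nrow(rs$vertices), 101)
  seg <- sqrt(rowSums((rs$vertices[-1, ] - rs$vertices[-101, ])^2))
  expect_equal(seg, rep(total_arc_length(rs) / 100, 100), tolerance = 0.02)
  # idempotence
  rs2 <- resample_centerline(rs, 101)
  expect_lt(max(abs(rs2$vertices - rs$vertices)), 1e-3)
  expect_error(resample_centerline(fx$cl, 5), ">= 10")
})

test_that("resampling interpolates radii linearly and keeps arc length", {
  ft <- fix_tube_tapered()
  rs <- resample_centerline(ft$cl, 51)
  mid <- rs$radius[26]
  expect_equal(mid, 7.5, tolerance = 0.25)
  expect_equal(total_arc_length(rs), total_arc_length(ft$cl),
               tolerance = 0.01 * total_arc_length(ft$cl))

  # branching tree: every root-to-leaf path has exactly n vertices and
  # bifurcation positions are preserved exactly
  fy <- fix_y_sides()
  rsy <- resample_centerline(fy$cl, 100)
  expect_true(all(lengths(rsy$paths) == 100))
  b_old <- fy$cl$vertices[fy$cl$bifurcations, , drop = FALSE]
  b_new <- rsy$vertices[rsy$bifurcations, , drop = FALSE]
  expect_equal(nrow(b_new), nrow(b_old))
  for (i in seq_len(nrow(b_old))) {
    d <- sqrt(rowSums(sweep(b_new, 2, b_old[i, ])^2))
    expect_lt(min(d), 1e-6)
  }
  expect_equal(total_arc_length(rsy), total_arc_length(fy$cl),
               tolerance = 0.01 * total_arc_length(fy$cl))
})

test_that("centreline trees round-trip through VTP and JSON", {
  fy <- fix_y_sides()
  cl <- resample_centerline(fy$cl, 40)
  fv <- tempfile(fileext = ".vtp")
  fj <- tempfile(fileext = ".json")
  write_centerline_vtp(fy$lt, fv)     # labeled variant writes branch_label
  write_centerline_vtp(cl, fv)
  write_centerline_json(cl, fj)
  bv <- read_centerline_vtp(fv)
  bj <- read_centerline_json(fj)
  for (back in list(bv, bj)) {
    expect_equal(nrow(back$vertices), nrow(cl$vertices))
    expect_equal(total_arc_length(back), total_arc_length(cl), tolerance = 1e-6)
    expect_length(back$leaves, length(cl$leaves))
    expect_equal(sort(back$radius), sort(cl$radius), tolerance = 1e-6)
  }
})
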