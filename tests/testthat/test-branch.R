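# hand-built centreline trees (no mesh needed) for the labeling rules

# trunk along +z to (0,0,10), daughters at +/-45 degrees in the x-z plane;
# the left (+x) daughter carries a downstream bifurcation whose children
# deviate by `a1` and `a2` degrees from the incoming direction
two_angle_tree <- function(a1 = 20, a2 = 70, r_kid = c(3, 3)) {
  step <- 2
  V <- rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10))
  parent <- c(NA, 1, 2)
  dirL <- c(sin(pi / 4), 0, cos(pi / 4))
  dirR <- c(-sin(pi / 4), 0, cos(pi / 4))
  add_chain <- function(from, start, dir, n) {
    for (k in seq_len(n)) {
      V <<- rbind(V, start + k * step * dir)
      parent <<- c(parent, from)
      from <- nrow(V)
    }
    nrow(V)
  }
  lpa_mid <- add_chain(3, V[3, ], dirL, 5)       # 10 mm of LPA
  rpa_end <- add_chain(3, V[3, ], dirR, 10)      # RPA straight to its end
  # two children at a1/a2 degrees from the incoming LPA direction, rotated
  # within the x-z plane
  rot <- function(d, ang) {
    a <- ang * pi / 180
    c(cos(a) * d[1] + sin(a) * d[3], 0, -sin(a) * d[1] + cos(a) * d[3])
  }
  c1_end <- add_chain(lpa_mid, V[lpa_mid, ], rot(dirL, a1), 6)
  c2_end <- add_chain(lpa_mid, V[lpa_mid, ], rot(dirL, -a2), 6)
  radius <- rep(4, nrow(V))
  radius[(lpa_mid + 1):c1_end] <- r_kid[1]
  radius[(c1_end + 1):c2_end] <- r_kid[2]
  centerline_tree(V, radius, parent)
}

test_that("daughters are assigned by projection onto the left axis", {
  tr <- two_angle_tree()
  lt <- label_edges(tr, left_axis = c(1, 0, 0))
  V <- tr$vertices
  end_l <- V[lt$lpa_path[length(lt$lpa_path)], ]
  expect_gt(end_l[1], 0)                         # LPA went toward +x
  # flipping the axis swaps the labels
  lt2 <- label_edges(tr, left_axis = c(-1, 0, 0))
  expect_equal(lt2$rpa_path[2], lt$lpa_path[2])
  expect_equal(lt2$lpa_path[2], lt$rpa_path[2])
})

test_that("the smallest-angle child continues the trunk; the rest are side branches", {
  tr <- two_angle_tree(20, 70)
  lt <- label_edges(tr)
  vl <- pamorph:::vertex_labels(lt)
  V <- tr$vertices
  # the 20-degree child's endpoint carries the LPA label, the 70-degree one SIDE
  lab_of_endpoint <- function(target) vl[which.min(rowSums(sweep(V, 2, target)^2))]
  expect_equal(unname(vl[lt$lpa_path[length(lt$lpa_path)]]), "LPA")
  side_ids <- which(vl == "SIDE")
  expect_gt(length(side_ids), 0)
  # side subtree is the a2 branch: its vertices lie on the -70 rotation side
  expect_equal(unname(lab_of_endpoint(V[lt$lpa_path[length(lt$lpa_path)], ])), "LPA")
})

test_that("angle ties fall to the larger-radius child", {
  tr <- two_angle_tree(30, 30, r_kid = c(2, 5))
  lt <- label_edges(tr)
  trunk_end <- lt$lpa_path[length(lt$lpa_path)]
  expect_equal(tr$radius[trunk_end], 5)
})

test_that("labels partition the edges and counts match the generator", {
  fs <- fix_y_sides()
  lt <- fs$lt
  expect_equal(length(lt$edge_labels), nrow(fs$cl$edges))
  expect_false(any(is.na(lt$edge_labels)))
  cnt <- count_side_branches(lt)
  expect_equal(unname(cnt), c(fs$tree$truth$n_side_lpa, fs$tree$truth$n_side_rpa))
  # label-symmetric quantities are invariant under a left-axis flip
  lt_f <- label_edges(fs$cl, left_axis = c(-1, 0, 0))
  r1 <- measure_subject(lt)
  r2 <- measure_subject(lt_f)
  expect_equal(r2$alpha, r1$alpha, tolerance = 1e-9)
  expect_equal(r2$EnI, r1$EnI, tolerance = 1e-9)
  expect_equal(r2$L_LPA, r1$L_RPA, tolerance = 1e-9)
  expect_equal(r2$n_side_lpa, r1$n_side_rpa)
})

test_that("trees without a bifurcation are rejected", {
  fx <- fix_tube_straight()
  expect_error(label_edges(fx$cl), "no bifurcation")
})

test_that("landmarks sit at the right arc distances", {
  fy <- fix_y_null()
  lt <- locate_landmarks(fy$lt)
  expect_equal(lt$landmarks$P2$arc, 10, tolerance = 1e-9)
  expect_equal(vnorm_test(lt$landmarks$Pb$position -
                          c(0, 0, 60)), 0, tolerance = 1)
  # on a curved daughter the offset is arc length, not Euclidean distance
  fs <- fix_species_subject()
  lts <- locate_landmarks(fs$lt)
  expect_equal(lts$landmarks$P2$arc, 10, tolerance = 0.1)
  expect_lt(vnorm_test(lts$landmarks$P2$position - lts$landmarks$Pb$position), 10.01)

  # a daughter shorter than the offset is flagged non-evaluable
  short <- two_angle_tree()
  lt_short <- label_edges(short)
  expect_error(locate_landmarks(lt_short, offset = 30),
               class = "pamorph_short_daughter")
})
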