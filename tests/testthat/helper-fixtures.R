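# Shared fixtures, built once per test run and cached. All geometry is
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

fix_tube_straight <- function() fixture("tube_straight", function() {
  tree <- make_tree("custom", seed = 1,
                    params = list(kind = "tube", length = 100, radius = 5))
  mesh <- surface_from_tree(tree, axial_step = 1)
  list(tree = tree, mesh = mesh, cl = extract_centerline(mesh))
})

fix_tube_tapered <- function() fixture("tube_tapered", function() {
  tree <- make_tree("custom", seed = 1,
                    params = list(kind = "tube", length = 100,
                                  radius_start = 10, radius_end = 5))
  mesh <- surface_from_tree(tree, axial_step = 1)
  list(tree = tree, mesh = mesh, cl = extract_centerline(mesh))
})

fix_half_torus <- function() fixture("half_torus", function() {
  tree <- make_tree("custom", seed = 1,
                    params = list(kind = "tube", radius = 5,
                                  ring_radius = 30, arc_deg = 180))
  mesh <- surface_from_tree(tree, axial_step = 1)
  list(tree = tree, mesh = mesh, cl = extract_centerline(mesh))
})

# straight, symmetric, area-preserving Y: every shape parameter at its null
fix_y_null <- function() fixture("y_null", function() {
  tree <- make_tree("custom", seed = 1,
                    params = list(kind = "y", trunk_length = 60,
                                  trunk_radius = 10, daughter_length = 60,
                                  daughter_radius = 10 / sqrt(2), angle = 90))
  mesh <- surface_from_tree(tree, axial_step = 1)
  cl <- extract_centerline(mesh)
  list(tree = tree, mesh = mesh, cl = cl, lt = label_edges(cl))
})

# Y with tapered daughters and side branches
fix_y_sides <- function() fixture("y_sides", function() {
  tree <- make_tree("custom", seed = 1,
                    params = list(kind = "y", trunk_length = 60,
                                  trunk_radius = 12, daughter_length = 90,
                                  daughter_radius = 9, daughter_radius_end = 6,
                                  angle = 100, n_side_lpa = 3, n_side_rpa = 4))
  mesh <- surface_from_tree(tree, axial_step = 1)
  cl <- extract_centerline(mesh)
  list(tree = tree, mesh = mesh, cl = cl, lt = label_edges(cl))
})

fix_species_subject <- function() fixture("species_subject", function() {
  tree <- make_tree("porcine", seed = 7)
  mesh <- surface_from_tree(tree)
  cl <- resample_centerline(extract_centerline(mesh), 100)
  list(tree = tree, mesh = mesh, cl = cl, lt = label_edges(cl))
})

# analytic binary sphere mask, radius r, isotropic spacing
sphere_mask <- function(r = 10, spacing = 0.5, margin = 2) {
  half <- r + margin * spacing
  ax <- seq(-half, half, by = spacing)
  g <- array(FALSE, c(length(ax), length(ax), length(ax)))
  for (k in seq_along(ax)) {
    d2 <- outer(ax^2, ax^2, "+") + ax[k]^2
    g[, , k] <- d2 < r^2
  }
  voxel_mask(g, spacing, origin = rep(-half, 3))
}

# latitude/longitude triangulated sphere mesh (closed, outward-oriented)
sphere_mesh <- function(r = 10, n_lat = 24, n_lon = 48, center = c(0, 0, 0)) {
  verts <- rbind(center + c(0, 0, r))
  for (i in seq_len(n_lat - 1)) {
    th <- pi * i / n_lat
    for (j in seq_len(n_lon)) {
      ph <- 2 * pi * j / n_lon
      verts <- rbind(verts, center + r * c(sin(th) * cos(ph),
                                           sin(th) * sin(ph), cos(th)))
    }
  }
  verts <- rbind(verts, center - c(0, 0, r))
  idx <- function(i, j) 1 + (i - 1) * n_lon + ((j - 1) %% n_lon) + 1
  south <- nrow(verts)
  F <- NULL
  for (j in seq_len(n_lon))
    F <- rbind(F, c(1, idx(1, j), idx(1, j + 1)))
  for (i in seq_len(n_lat - 2))
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1); c2 <- idx(i + 1, j); d <- idx(i + 1, j + 1)
      F <- rbind(F, c(a, c2, d), c(a, d, b))
    }
  for (j in seq_len(n_lon))
    F <- rbind(F, c(south, idx(n_lat - 1, j + 1), idx(n_lat - 1, j)))
  surface_mesh(verts, F)
}

# brute-force point-to-mesh distance oracle: dense barycentric sampling of
# every triangle (independent of the package's closest-point code path)
brute_mesh_distance <- function(points, mesh, n_sub = 25) {
  V <- mesh$vertices
  F <- mesh$faces
  bar <- NULL
  for (i in 0:n_sub) for (j in 0:(n_sub - i))
    bar <- rbind(bar, c(i, j, n_sub - i - j) / n_sub)
  samples <- NULL
  for (t in seq_len(nrow(F)))
    samples <- rbind(samples, bar %*% V[F[t, ], ])
  apply(points, 1, function(p)
    sqrt(min(colSums((t(samples) - p)^2))))
}

vnorm_test <- function(v) sqrt(sum(v^2))

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}
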