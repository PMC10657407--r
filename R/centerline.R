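# Centreline extraction from open-ended tubular surfaces.
#
# Strategy: rasterise the lumen, compute the Euclidean distance transform
# (distance to the wall), run Dijkstra from the inlet over foreground voxels
# with a medialness edge cost (step length weighted by the inverse squared
# wall distance, which pulls geodesics onto the medial axis), trace one path
# per outlet boundary loop, merge the shared prefixes into a rooted tree,
# then smooth each branch chain and recentre every sample in its normal plane
# by locally maximising the distance to the wall. Radii are the exact
# point-to-surface distances at the final sample positions, i.e. local
# maximal-inscribed-sphere radii.

#' Rooted centreline tree
#'
#' @param vertices n x 3 matrix of sample positions (mm).
#' @param radius inscribed-sphere radius (mm) per vertex.
#' @param parent integer vector: parent vertex index per vertex (NA at root).
#' @return A `centerline_tree` with derived `edges`, `paths` (canonical
#'   root-to-leaf index sequences), `root`, `leaves` and `bifurcations`.
#' @export
centerline_tree <- function(vertices, radius, parent) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  stopifnot(length(radius) == n, length(parent) == n)
  if (any(radius <= 0, na.rm = TRUE)) stop("all radii must be positive")
  root <- which(is.na(parent))
  if (length(root) != 1) stop("tree must have exactly one root")
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  nchild <- lengths(children)
  leaves <- which(nchild == 0)
  bifs <- which(nchild >= 2)
  edges <- cbind(parent[!is.na(parent)], which(!is.na(parent)))
  # downstream maximal arc length, for canonical child ordering
  elen <- sqrt(rowSums((vertices[edges[, 2], , drop = FALSE] -
                        vertices[edges[, 1], , drop = FALSE])^2))
  if (any(elen <= 0)) stop("zero-length centreline edge")
  maxdown <- numeric(n)
  ord <- order_topological(parent, children, root)
  for (i in rev(ord)) {
    ch <- children[[i]]
    if (length(ch) > 0) {
      seglen <- sqrt(rowSums((vertices[ch, , drop = FALSE] -
                              matrix(vertices[i, ], length(ch), 3, byrow = TRUE))^2))
      maxdown[i] <- max(maxdown[ch] + seglen)
    }
  }
  paths <- list()
  walk <- function(i, acc) {
    repeat {
      acc <- c(acc, i)
      ch <- children[[i]]
      if (length(ch) == 0) {
        paths[[length(paths) + 1]] <<- acc
        return(invisible())
      }
      if (length(ch) > 1) {
        o <- order(-maxdown[ch], -radius[ch])
        for (c2 in ch[o]) walk(c2, acc)
        return(invisible())
      }
      i <- ch
    }
  }
  walk(root, integer(0))
  structure(list(vertices = vertices, radius = as.numeric(radius),
                 parent = parent, children = children, edges = edges,
                 root = root, leaves = leaves, bifurcations = bifs,
                 paths = paths),
            class = "centerline_tree")
}

order_topological <- function(parent, children, root) {
  n <- length(parent)
  ord <- integer(n)
  k <- 0L
  stack <- root
  while (length(stack) > 0) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- i
    stack <- c(stack, children[[i]])
  }
  ord
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> %d vertices, %d path(s), %d bifurcation(s), total arc %.1f mm\n",
              nrow(x$vertices), length(x$paths), length(x$bifurcations),
              total_arc_length(x)))
  invisible(x)
}

#' Total arc length of all centreline edges
#' @param tree a `centerline_tree`.
#' @return Length in mm.
#' @export
total_arc_length <- function(tree) {
  e <- tree$edges
  sum(sqrt(rowSums((tree$vertices[e[, 2], , drop = FALSE] -
                    tree$vertices[e[, 1], , drop = FALSE])^2)))
}

path_points <- function(tree, path) tree$vertices[path, , drop = FALSE]

# chains of vertex indices between special nodes (root/bifurcations/leaves)
tree_segments <- function(tree) {
  special <- sort(unique(c(tree$root, tree$bifurcations, tree$leaves)))
  segs <- list()
  for (s in special) {
    for (ch in tree$children[[s]]) {
      seg <- c(s, ch)
      i <- ch
      while (!(i %in% special)) {
        nxt <- tree$children[[i]]
        i <- nxt[1]
        seg <- c(seg, i)
      }
      segs[[length(segs) + 1]] <- seg
    }
  }
  segs
}

smooth_chain <- function(pts, iters, w) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  for (it in seq_len(iters)) {
    mid <- 0.5 * (pts[1:(n - 2), , drop = FALSE] + pts[3:n, , drop = FALSE])
    pts[2:(n - 1), ] <- pts[2:(n - 1), , drop = FALSE] +
      w * (mid - pts[2:(n - 1), , drop = FALSE])
  }
  pts
}

chain_directions <- function(pts) {
  n <- nrow(pts)
  d <- rbind(pts[2, ] - pts[1, ],
             if (n > 2) pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
             pts[n, ] - pts[n - 1, ])
  d
}

# Bifurcation refinement. Least-cost paths through a junction diverge
# somewhat upstream of the anatomical bifurcation (inside the common lumen
# both daughters' paths hug the trunk axis), and stay biased toward the
# common-lumen centre for roughly one local radius beyond it. For each
# bifurcation: walk the two dominant child chains, find where they truly
# separate (> tol apart), fit both local axes on a clean window past the
# biased zone, place the bifurcation vertex at the closest approach of the
# two axes, and rebuild the near-junction geometry along them. Surgeries are
# applied one at a time (the structure is rebuilt in between) so refinements
# of nearby junctions cannot act on stale topology.
refine_junctions <- function(V, parent, radius, tol = 0.6, max_walk = 30,
                             fit_len = 12, step = 1.0) {
  processed <- matrix(numeric(0), 0, 3)
  for (guard in 1:100) {
    res <- refine_one_junction(V, parent, radius, processed, tol, max_walk,
                               fit_len, step)
    if (is.null(res)) break
    V <- res$V
    parent <- res$parent
    radius <- res$radius
    processed <- rbind(processed, res$apex)
  }
  list(V = V, parent = parent)
}

refine_one_junction <- function(V, parent, radius, processed, tol, max_walk,
                                fit_len, step) {
  n0 <- nrow(V)
  children <- vector("list", n0)
  for (i in seq_len(n0)) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  root <- which(is.na(parent))
  ord <- order_topological(parent, children, root)
  maxdown <- numeric(n0)
  for (i in rev(ord)) {
    ch <- children[[i]]
    if (length(ch) > 0) {
      seglen <- sqrt(rowSums((V[ch, , drop = FALSE] -
                              matrix(V[i, ], length(ch), 3, byrow = TRUE))^2))
      maxdown[i] <- max(maxdown[ch] + seglen)
    }
  }
  walk_chain <- function(start, maxlen) {
    ids <- integer(0)
    i <- start
    acc <- 0
    repeat {
      ids <- c(ids, i)
      ch <- children[[i]]
      if (length(ch) != 1 || acc >= maxlen) break
      acc <- acc + vnorm(V[ch, ] - V[i, ])
      i <- ch
    }
    ids
  }
  is_processed <- function(pos) {
    nrow(processed) > 0 &&
      any(rowSums(sweep(processed, 2, pos)^2) < 1e-10)
  }
  bifs <- intersect(ord, which(lengths(children) >= 2))  # root-first order
  for (B in bifs) {
    if (is_processed(V[B, ])) next
    ch <- children[[B]]
    edgelen <- sqrt(rowSums((V[ch, , drop = FALSE] -
                             matrix(V[B, ], length(ch), 3, byrow = TRUE))^2))
    o <- order(-(maxdown[ch] + edgelen))
    c1 <- ch[o[1]]; c2 <- ch[o[2]]
    ch1 <- walk_chain(c1, max_walk)
    ch2 <- walk_chain(c2, max_walk)
    P1 <- rbind(V[B, ], V[ch1, , drop = FALSE])
    P2 <- rbind(V[B, ], V[ch2, , drop = FALSE])
    a1 <- cum_arc(P1); a2 <- cum_arc(P2)
    lmax <- min(a1[length(a1)], a2[length(a2)])
    if (lmax < 2) next
    ds <- 0.2
    svals <- seq(ds, lmax, by = ds)
    sep <- vapply(svals, function(s)
      vnorm(interp_along(P1, s)$position - interp_along(P2, s)$position),
      numeric(1))
    div <- which(sep > tol)
    if (length(div) == 0) next
    sstar <- svals[div[1]]
    if (sstar <= ds + 1e-9) next               # already separated at B
    sclean <- min(sstar + 0.9 * radius[B], lmax - 1.5)
    if (sclean <= sstar) sclean <- sstar
    fl <- min(fit_len, lmax - sclean)
    if (fl < 1.5) next
    # fit each daughter axis on the clean window, quadratic in arc length
    # when the window is wide enough to estimate curvature stably (so curved
    # branches extrapolate backward along their own curvature), else linear
    use_quad <- fl >= 5
    fit_axis <- function(P, s0, s1) {
      sw <- seq(s0, s1, by = 0.5)
      Q <- t(vapply(sw, function(s) interp_along(P, s)$position, numeric(3)))
      if (use_quad) {
        X <- cbind(1, sw - s0, (sw - s0)^2 / 2)
        beta <- qr.solve(X, Q)               # value, tangent, curvature
        function(u) as.numeric(c(1, u, u^2 / 2) %*% beta)
      } else {
        X <- cbind(1, sw - s0)
        beta <- qr.solve(X, Q)
        function(u) as.numeric(c(1, u) %*% beta)
      }
    }
    f1 <- fit_axis(P1, sclean, sclean + fl)
    f2 <- fit_axis(P2, sclean, sclean + fl)
    # closest approach of the two extrapolated axes (u <= 0 is backward)
    usearch <- function(grid1, grid2) {
      Q1 <- t(vapply(grid1, f1, numeric(3)))
      Q2 <- t(vapply(grid2, f2, numeric(3)))
      d2m <- outer(rowSums(Q1^2), rep(1, length(grid2))) +
        outer(rep(1, length(grid1)), rowSums(Q2^2)) - 2 * Q1 %*% t(Q2)
      ij <- arrayInd(which.min(d2m), dim(d2m))
      c(grid1[ij[1]], grid2[ij[2]])
    }
    lo <- -(sclean + 4)
    uap <- usearch(seq(lo, 1, by = 0.5), seq(lo, 1, by = 0.5))
    uap <- usearch(seq(uap[1] - 0.5, uap[1] + 0.5, by = 0.1),
                   seq(uap[2] - 0.5, uap[2] + 0.5, by = 0.1))
    newPb <- 0.5 * (f1(uap[1]) + f2(uap[2]))
    q1a <- f1(0)
    q2a <- f2(0)
    if (vnorm(newPb - V[B, ]) > max_walk) {
      newPb <- 0.5 * (q1a + q2a)
      uap <- c(0, 0)
    }

    # the trunk path is biased toward the junction crotch for about one local
    # radius around the apex (and the divergence vertex B itself may even sit
    # downstream of it): excise the upstream stretch whose distance to the
    # apex is below that and rebuild it as a straight run into the apex
    up_ids <- integer(0)
    u <- B
    up_len <- 0
    while (up_len < max_walk) {
      pu <- parent[u]
      if (is.na(pu)) break
      up_ids <- c(up_ids, u)        # B first, then its ancestors
      up_len <- up_len + vnorm(V[pu, ] - V[u, ])
      u <- pu
      if (length(children[[u]]) >= 2) break
      if (vnorm(V[u, ] - newPb) > 0.9 * radius[B] + 0.5) break
    }
    U <- u                          # kept anchor vertex upstream of the apex
    keep <- rep(TRUE, n0)
    keep[up_ids] <- FALSE           # dropped: biased prefix incl. B
    newV <- list()
    newParent <- integer(0)
    add_run <- function(from_id, from_pos, to_pos) {
      m <- max(0L, floor(vnorm(to_pos - from_pos) / step) - 1L)
      prev_id <- from_id
      if (m > 0) for (j in seq_len(m)) {
        newV[[length(newV) + 1]] <<- from_pos + (j / (m + 1)) * (to_pos - from_pos)
        gid <- n0 + length(newV)
        newParent[length(newV)] <<- prev_id
        prev_id <- gid
      }
      newV[[length(newV) + 1]] <<- to_pos
      newParent[length(newV)] <<- prev_id
      n0 + length(newV)
    }
    pb_id <- add_run(U, V[U, ], newPb)
    for (chain in list(list(ids = ch1, a = a1, f = f1, u = uap[1]),
                       list(ids = ch2, a = a2, f = f2, u = uap[2]))) {
      drop_ids <- chain$ids[chain$a[-1] <= sclean + 1e-9]
      keepfirst <- setdiff(chain$ids, drop_ids)[1]
      keep[drop_ids] <- FALSE
      # rebuild the daughter along its fitted arc from the apex to the
      # clean-window start
      us <- seq(chain$u, 0, length.out = max(2, ceiling(-chain$u / step) + 1))
      last_id <- pb_id
      for (uu in us[-1]) {
        newV[[length(newV) + 1]] <- chain$f(uu)
        newParent[length(newV)] <- last_id
        last_id <- n0 + length(newV)
      }
      if (!is.na(keepfirst)) parent[keepfirst] <- last_id
      # children hanging off dropped vertices (e.g. side twigs) re-attach
      # at the rebuilt daughter start
      for (dv in drop_ids) {
        extra <- setdiff(children[[dv]], chain$ids)
        for (rp in extra) parent[rp] <- last_id
      }
    }
    # children of B or of the dropped upstream stretch that are neither of
    # the two refined chains re-attach at the apex
    for (dv in up_ids) {
      extra <- setdiff(children[[dv]], c(up_ids, c1, c2))
      for (rp in extra) if (keep[rp]) parent[rp] <- pb_id
    }
    Vnew <- do.call(rbind, newV)
    Vall <- rbind(V, Vnew)
    parent_all <- c(parent, newParent)
    radius_all <- c(radius, rep(radius[B], length(newV)))
    keep_all <- c(keep, rep(TRUE, length(newV)))
    idx <- which(keep_all)
    remap <- integer(length(keep_all))
    remap[idx] <- seq_along(idx)
    p2 <- parent_all[idx]
    p2[!is.na(p2)] <- remap[p2[!is.na(p2)]]
    return(list(V = Vall[idx, , drop = FALSE], parent = p2,
                radius = radius_all[idx], apex = newPb))
  }
  NULL
}

#' Extract a rooted centreline tree from an open-ended tubular surface
#'
#' One leaf is produced per outlet boundary loop; the root is snapped to the
#' inlet loop centroid and each leaf to its outlet loop centroid. Per-vertex
#' radii are local maximal-inscribed-sphere radii (exact distances from the
#' recentred samples to the wall).
#'
#' @param mesh a `surface_mesh` with at least two boundary loops.
#' @param inlet_hint either `"largest-boundary-loop"` (default: the loop with
#'   the largest mean radius is the inlet) or a length-3 point in mm, in which
#'   case the nearest loop is used.
#' @param spacing voxel spacing (mm) of the internal rasterisation; default is
#'   min(1, max(0.4, r_min / 3)) for the smallest loop radius r_min.
#' @return A `centerline_tree`.
#' @export
extract_centerline <- function(mesh, inlet_hint = "largest-boundary-loop",
                               spacing = NULL) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0)
    stop("mesh is closed: a centreline needs an inlet and at least one outlet loop")
  if (length(loops) == 1)
    stop("mesh has a single boundary loop: no outlet to trace to")
  infos <- lapply(loops, loop_info, mesh = mesh)
  radii_loops <- vapply(infos, `[[`, numeric(1), "radius")
  if (is.numeric(inlet_hint) && length(inlet_hint) == 3) {
    dists <- vapply(infos, function(li) vnorm(li$centroid - inlet_hint), numeric(1))
    inlet_i <- which.min(dists)
  } else {
    inlet_i <- which.max(radii_loops)
  }
  outlet_i <- setdiff(seq_along(infos), inlet_i)
  if (is.null(spacing)) spacing <- min(1, max(0.4, min(radii_loops) / 3))

  mask <- voxelize(mesh, spacing)
  mask <- suppressMessages(largest_component(mask))
  dims <- dim(mask$grid)
  sp <- mask$spacing
  dt <- cpp_edt3d(as.logical(mask$grid), dims, sp)

  fg <- which(as.logical(mask$grid))
  if (length(fg) == 0) stop("rasterised lumen is empty; decrease spacing")
  vox_center <- function(idx0) {  # 0-based full-grid index -> mm centre
    i <- idx0 %% dims[1]
    j <- (idx0 %/% dims[1]) %% dims[2]
    k <- idx0 %/% (dims[1] * dims[2])
    cbind(mask$origin[1] + i * sp[1], mask$origin[2] + j * sp[2],
          mask$origin[3] + k * sp[3])
  }
  fg0 <- fg - 1L
  fg_pts <- vox_center(fg0)
  nearest_fg <- function(p) {
    d2 <- (fg_pts[, 1] - p[1])^2 + (fg_pts[, 2] - p[2])^2 + (fg_pts[, 3] - p[3])^2
    fg0[which.min(d2)]
  }
  source <- nearest_fg(infos[[inlet_i]]$centroid)
  dj <- cpp_dijkstra_grid(dims, sp, dt, source)
  parent_vox <- dj$parent

  vox_paths <- list()
  for (oi in outlet_i) {
    # among candidates near the outlet centroid, prefer reachable voxels
    p <- infos[[oi]]$centroid
    d2 <- (fg_pts[, 1] - p[1])^2 + (fg_pts[, 2] - p[2])^2 + (fg_pts[, 3] - p[3])^2
    cand <- fg0[order(d2)[seq_len(min(50, length(fg0)))]]
    cand <- cand[dj$dist[cand + 1] < 1e29]
    if (length(cand) == 0)
      stop("outlet loop not reachable from the inlet through the lumen")
    tgt <- cand[1]
    path <- tgt
    while (parent_vox[path[1] + 1] >= 0) path <- c(parent_vox[path[1] + 1], path)
    if (path[1] != source)
      stop("internal error: Dijkstra path does not reach the source")
    vox_paths[[length(vox_paths) + 1]] <- path
  }

  # merge paths (they share Dijkstra-tree prefixes) into one rooted tree
  dict <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list()
  par <- integer(0)
  add_vertex <- function(vox, parent_id) {
    id <- length(verts) + 1L
    verts[[id]] <<- vox
    par[id] <<- parent_id
    assign(as.character(vox), id, envir = dict)
    id
  }
  for (path in vox_paths) {
    prev <- NA_integer_
    for (vox in path) {
      key <- as.character(vox)
      id <- dict[[key]]
      if (is.null(id)) id <- add_vertex(vox, prev)
      prev <- id
    }
  }
  P <- vox_center(unlist(verts))
  R <- rep(NA_real_, nrow(P))
  tree0 <- centerline_tree(P, rep(1, nrow(P)), par)

  # geometric refinement per chain: snap endpoints, smooth, recentre, smooth
  V <- tree0$vertices
  loop_of_leaf <- integer(0)
  # map leaves back to outlet loops (leaf vertex = last voxel of its path)
  for (k in seq_along(vox_paths)) {
    leaf_id <- dict[[as.character(vox_paths[[k]][length(vox_paths[[k]])])]]
    loop_of_leaf[leaf_id] <- outlet_i[k]
  }
  V[tree0$root, ] <- infos[[inlet_i]]$centroid
  for (lf in tree0$leaves) V[lf, ] <- infos[[loop_of_leaf[lf]]]$centroid

  segs <- tree_segments(tree0)
  for (seg in segs) {
    pts <- V[seg, , drop = FALSE]
    pts <- smooth_chain(pts, iters = 8, w = 0.5)
    interior <- seg[-c(1, length(seg))]
    if (length(interior) > 0) V[interior, ] <- pts[-c(1, nrow(pts)), , drop = FALSE]
  }
  # recentre everything except snapped endpoints
  move <- setdiff(seq_len(nrow(V)), c(tree0$root, tree0$leaves))
  if (length(move) > 0) {
    dirs <- matrix(0, length(move), 3)
    for (ii in seq_along(move)) {
      i <- move[ii]
      p <- tree0$parent[i]
      ch <- tree0$children[[i]]
      ref <- if (length(ch) > 0) V[ch[1], ] else V[i, ]
      base <- if (!is.na(p)) V[p, ] else V[i, ]
      dirs[ii, ] <- ref - base
    }
    rc <- cpp_recenter_points(V[move, , drop = FALSE], dirs, mesh$vertices,
                              mesh$faces - 1L, spacing * 0.75, 4L,
                              2.5 * spacing)
    V[move, ] <- rc$points
  }
  for (seg in segs) {
    pts <- smooth_chain(V[seg, , drop = FALSE], iters = 3, w = 0.3)
    interior <- seg[-c(1, length(seg))]
    if (length(interior) > 0) V[interior, ] <- pts[-c(1, nrow(pts)), , drop = FALSE]
  }
  R0 <- cpp_point_mesh_distance(V, mesh$vertices, mesh$faces - 1L)
  rj <- refine_junctions(V, tree0$parent, R0, tol = max(0.5, 0.6 * spacing))
  R <- cpp_point_mesh_distance(rj$V, mesh$vertices, mesh$faces - 1L)
  R <- pmax(R, 1e-6)
  centerline_tree(rj$V, R, rj$parent)
}

#' Resample a centreline tree to a consistent per-path vertex count
#'
#' Every root-to-leaf path ends up with exactly `n_per_path` vertices.
#' Bifurcation vertices are kept exactly (their positions do not move) and
#' receive the index closest to their relative arc position, so topologically
#' matching subjects get matching bifurcation indices; between consecutive
#' landmarks the vertices are equally spaced in arc length and radii are
#' linearly interpolated.
#'
#' @param tree a `centerline_tree`.
#' @param n_per_path vertices per root-to-leaf path (>= 10 and more than twice
#'   the number of bifurcations on any path).
#' @return A resampled `centerline_tree`.
#' @export
resample_centerline <- function(tree, n_per_path = 100) {
  if (n_per_path < 10) stop("n_per_path must be >= 10")
  for (p in tree$paths) {
    nb <- sum(p %in% tree$bifurcations)
    if (n_per_path <= 2 * nb)
      stop("n_per_path too small to preserve the bifurcation topology")
  }
  special_old <- sort(unique(c(tree$root, tree$bifurcations, tree$leaves)))
  newV <- list(); newR <- list(); newPar <- integer(0)
  id_map <- new.env(hash = TRUE, parent = emptyenv()) # old special id -> new id
  add <- function(pos, rad, parent_id) {
    id <- length(newV) + 1L
    newV[[id]] <<- pos
    newR[[id]] <<- rad
    newPar[id] <<- parent_id
    id
  }
  for (p in tree$paths) {
    pts <- path_points(tree, p)
    rad <- tree$radius[p]
    arc <- cum_arc(pts)
    L <- arc[length(arc)]
    sp_pos <- which(p %in% special_old)        # includes 1 and length(p)
    mapped <- vapply(p[sp_pos], function(i) !is.null(id_map[[as.character(i)]]),
                     logical(1))
    k0 <- max(c(which(mapped), 1L))            # deepest already-built landmark
    if (!any(mapped)) {
      # first path: start from the root
      start_new <- add(pts[1, ], rad[1], NA_integer_)
      assign(as.character(p[1]), start_new, envir = id_map)
      assign(paste0("idx_", p[1]), 0L, envir = id_map)
      start_index <- 0L
    } else {
      start_new <- id_map[[as.character(p[sp_pos[k0]])]]
      start_index <- id_map[[paste0("idx_", p[sp_pos[k0]])]]
    }
    s0 <- arc[sp_pos[k0]]
    remaining_idx <- (n_per_path - 1L) - start_index
    segs_pos <- sp_pos[seq(k0, length(sp_pos))]
    # target indices for the remaining landmarks, proportional in arc length
    s_land <- arc[segs_pos]
    idx_land <- start_index +
      round((s_land - s0) / max(L - s0, 1e-12) * remaining_idx)
    idx_land[1] <- start_index
    idx_land[length(idx_land)] <- n_per_path - 1L
    for (j in seq_along(idx_land)) {
      if (j > 1) idx_land[j] <- max(idx_land[j], idx_land[j - 1] + 1L)
      idx_land[j] <- min(idx_land[j], n_per_path - 1L - (length(idx_land) - j))
    }
    prev_id <- start_new
    for (j in seq_len(length(segs_pos) - 1)) {
      a <- segs_pos[j]; b <- segs_pos[j + 1]
      seg_pts <- pts[a:b, , drop = FALSE]
      seg_rad <- rad[a:b]
      nseg <- idx_land[j + 1] - idx_land[j]       # intervals in this segment
      seg_len <- arc[b] - arc[a]
      for (m in seq_len(nseg)) {
        s <- seg_len * m / nseg
        if (m == nseg) {
          pos <- seg_pts[nrow(seg_pts), ]
          rv <- seg_rad[length(seg_rad)]
        } else {
          ip <- interp_along(seg_pts, s, seg_rad)
          pos <- ip$position
          rv <- ip$value
        }
        prev_id <- add(pos, rv, prev_id)
      }
      old_land <- p[b]
      if (old_land %in% special_old && is.null(id_map[[as.character(old_land)]])) {
        assign(as.character(old_land), prev_id, envir = id_map)
        assign(paste0("idx_", old_land), idx_land[j + 1], envir = id_map)
      }
    }
  }
  centerline_tree(do.call(rbind, newV), unlist(newR), newPar)
}

# ---------------------------------------------------------------------------
# Centreline I/O: VTK XML PolyData (VTP) polylines with point arrays, and a
# JSON dialect {vertices, radius, parent, labels?}.

#' Write a centreline tree as VTK XML PolyData (VTP)
#'
#' Each canonical root-to-leaf path becomes one polyline; the inscribed-sphere
#' radius is stored as a `radius` point array, and branch labels (if the tree
#' is labeled) as an integer `branch_label` array (MPA=1, LPA=2, RPA=3,
#' SIDE=4, assigned per vertex from its incoming edge).
#'
#' @param tree a `centerline_tree` or `labeled_tree`.
#' @param path output file path.
#' @export
write_centerline_vtp <- function(tree, path) {
  lt <- if (inherits(tree, "labeled_tree")) tree else NULL
  if (!is.null(lt)) tree <- lt$tree
  V <- tree$vertices
  n <- nrow(V)
  conn <- unlist(lapply(tree$paths, function(p) p - 1L))
  offs <- cumsum(lengths(tree$paths))
  label_arr <- ""
  if (!is.null(lt)) {
    codes <- c(MPA = 1L, LPA = 2L, RPA = 3L, SIDE = 4L)
    vl <- vertex_labels(lt)
    label_arr <- paste0(
      '    <DataArray type="Int32" Name="branch_label" format="ascii">\n      ',
      paste(codes[vl], collapse = " "), "\n    </DataArray>\n")
  }
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    '<PolyData>\n',
    sprintf('<Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="0">\n',
            n, length(tree$paths)),
    '  <PointData Scalars="radius">\n',
    '    <DataArray type="Float64" Name="radius" format="ascii">\n      ',
    paste(sprintf("%.9g", tree$radius), collapse = " "), "\n    </DataArray>\n",
    label_arr,
    '  </PointData>\n',
    '  <Points>\n',
    '    <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n      ',
    paste(sprintf("%.9g", t(V)), collapse = " "), "\n    </DataArray>\n",
    '  </Points>\n',
    '  <Lines>\n',
    '    <DataArray type="Int64" Name="connectivity" format="ascii">\n      ',
    paste(conn, collapse = " "), "\n    </DataArray>\n",
    '    <DataArray type="Int64" Name="offsets" format="ascii">\n      ',
    paste(offs, collapse = " "), "\n    </DataArray>\n",
    '  </Lines>\n',
    '</Piece>\n</PolyData>\n</VTKFile>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Read a centreline tree from a VTP file written by [write_centerline_vtp()]
#' @param path file path.
#' @return A `centerline_tree`.
#' @export
read_centerline_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  get_arr <- function(name) {
    node <- xml2::xml_find_first(doc, sprintf(".//DataArray[@Name='%s']", name))
    as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  }
  pts_node <- xml2::xml_find_first(doc, ".//Points/DataArray")
  pts <- as.numeric(strsplit(trimws(xml2::xml_text(pts_node)), "\\s+")[[1]])
  V <- matrix(pts, ncol = 3, byrow = TRUE)
  radius <- get_arr("radius")
  conn <- as.integer(get_arr("connectivity")) + 1L
  offs <- as.integer(get_arr("offsets"))
  parent <- rep(NA_integer_, nrow(V))
  seen <- logical(nrow(V))
  start <- 1L
  for (o in offs) {
    line <- conn[start:o]
    for (k in seq_along(line)[-1]) {
      if (!seen[line[k]]) parent[line[k]] <- line[k - 1]
      seen[line[k]] <- TRUE
    }
    seen[line[1]] <- TRUE
    start <- o + 1L
  }
  centerline_tree(V, radius, parent)
}

#' Write a centreline tree as JSON
#' @param tree a `centerline_tree`.
#' @param path output file path.
#' @export
write_centerline_json <- function(tree, path) {
  jsonlite::write_json(list(vertices = tree$vertices, radius = tree$radius,
                            parent = tree$parent),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a centreline tree from JSON written by [write_centerline_json()]
#' @param path file path.
#' @return A `centerline_tree`.
#' @export
read_centerline_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  parent <- x$parent
  parent[vapply(parent, is.null, logical(1))] <- NA_integer_
  centerline_tree(as.matrix(x$vertices), as.numeric(x$radius),
                  as.integer(unlist(parent)))
}
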