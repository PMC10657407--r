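# Surface synthesis from a parametric tree.
#
# The tree is turned into an implicit tube union f(x) = min over branches of
# (distance to centreline - local radius), sampled on a regular grid,
# triangulated with marching tetrahedra, and the triangle vertices are then
# Newton-projected onto the exact zero level set, so vertex positions match
# the analytic tube surface to well below the grid resolution. Terminal
# branch ends are extended past their nominal end plane and clipped back
# exactly at it, leaving one clean boundary loop per open end (inlet, LPA and
# RPA ends, and each side-branch truncation plane).

truncate_branch <- function(branch, arc_max) {
  if (arc_max >= branch$length - 1e-9) return(branch)
  keep <- branch$arc < arc_max - 1e-9
  endp <- interp_along(branch$points, arc_max, branch$radii)
  pts <- rbind(branch$points[keep, , drop = FALSE], endp$position)
  b <- branch
  b$points <- pts
  b$arc <- cum_arc(pts)
  b$length <- b$arc[length(b$arc)]
  b$radii <- c(branch$radii[keep], endp$value)
  b
}

# apply the reconstruction truncation rules: daughters are cut where their
# diameter falls below d_min; side branches are cut ~10 mm beyond the parent
# wall (attachment radius + 10 mm along their own axis)
effective_branches <- function(tree, d_min = 8, side_beyond_wall = 10) {
  br <- tree$branches
  out <- list()
  for (nm in names(br)) {
    b <- br[[nm]]
    if (nm %in% c("LPA", "RPA")) {
      below <- which(2 * b$radii < d_min)
      if (length(below) > 0) {
        i <- below[1]
        if (i == 1) stop("daughter ", nm, " starts below the minimum reconstructable diameter")
        t <- (d_min - 2 * b$radii[i - 1]) / (2 * b$radii[i] - 2 * b$radii[i - 1])
        b <- truncate_branch(b, b$arc[i - 1] + t * (b$arc[i] - b$arc[i - 1]))
      }
    } else if (!is.null(b$parent) && !is.na(b$attach_arc %||% NA_real_)) {
      parent <- br[[b$parent]]
      if (!is.null(parent)) {
        r_att <- interp_along(parent$points, b$attach_arc, parent$radii)$value
        b <- truncate_branch(b, r_att + side_beyond_wall)
      }
    }
    out[[nm]] <- b
  }
  out
}

decimate_branch <- function(branch, step) {
  s <- unique(c(seq(0, branch$length, by = step), branch$length))
  pts <- t(vapply(s, function(si) interp_along(branch$points, si)$position,
                  numeric(3)))
  rad <- vapply(s, function(si) interp_along(branch$points, si, branch$radii)$value,
                numeric(1))
  list(points = pts, radii = rad)
}

# open ends of the effective branch set: the root inlet plus every branch end
# that has no child attached at it
open_ends <- function(branches) {
  ends <- list()
  child_end_attached <- function(nm, L) {
    for (b in branches) {
      if (identical(b$parent, nm)) {
        aa <- b$attach_arc %||% NA_real_
        if (is.na(aa) || aa >= L - 1e-6) return(TRUE)
      }
    }
    FALSE
  }
  for (nm in names(branches)) {
    b <- branches[[nm]]
    if (is.null(b$parent)) {
      ends[[length(ends) + 1]] <- list(
        label = paste0(nm, "_inlet"), branch = nm,
        point = b$points[1, ], normal = -branch_tangent(b, 0),
        radius = b$radii[1])
    }
    if (!child_end_attached(nm, b$length)) {
      ends[[length(ends) + 1]] <- list(
        label = paste0(nm, "_end"), branch = nm,
        point = b$points[nrow(b$points), ],
        normal = branch_tangent(b, b$length),
        radius = b$radii[length(b$radii)])
    }
  }
  ends
}

extend_branch_ends <- function(branches, ends, ext) {
  for (e in ends) {
    b <- branches[[e$branch]]
    if (endsWith(e$label, "_inlet")) {
      p0 <- b$points[1, ] + e$normal * ext
      b$points <- rbind(p0, b$points)
      b$radii <- c(b$radii[1], b$radii)
    } else {
      p1 <- b$points[nrow(b$points), ] + e$normal * ext
      b$points <- rbind(b$points, p1)
      b$radii <- c(b$radii, b$radii[length(b$radii)])
    }
    b$arc <- cum_arc(b$points)
    b$length <- b$arc[length(b$arc)]
    branches[[e$branch]] <- b
  }
  branches
}

# Sutherland-Hodgman clip of selected triangles against a plane, keeping the
# half-space dot(x - point, normal) <= 0; only faces with a vertex inside the
# vicinity sphere are touched, so distant geometry crossing the same infinite
# plane is preserved.
clip_mesh_at_plane <- function(V, F, point, normal, vicinity_radius) {
  normal <- unitize(normal)
  d <- as.vector(sweep(V, 2, point) %*% normal)
  invic <- rowSums(sweep(V, 2, point)^2) < vicinity_radius^2
  fd <- matrix(d[F], ncol = 3)
  fv <- matrix(invic[F], ncol = 3)
  affected <- fv[, 1] | fv[, 2] | fv[, 3]
  n_out <- rowSums(fd > 1e-9)
  keep <- !affected | n_out == 0
  crossing <- which(affected & n_out > 0 & n_out < 3)
  newV <- list()
  newF <- list()
  for (fi in crossing) {
    idx <- F[fi, ]
    poly <- list()   # entries: list(pos, id or NA)
    for (s in 1:3) {
      a <- idx[s]; b <- idx[if (s == 3) 1 else s + 1]
      da <- d[a]; db <- d[b]
      if (da <= 1e-9) poly[[length(poly) + 1]] <- list(pos = V[a, ], id = a)
      if ((da <= 1e-9) != (db <= 1e-9)) {
        t <- da / (da - db)
        poly[[length(poly) + 1]] <- list(pos = V[a, ] + t * (V[b, ] - V[a, ]),
                                         id = NA_integer_)
      }
    }
    if (length(poly) < 3) next
    ids <- integer(length(poly))
    for (k in seq_along(poly)) {
      if (is.na(poly[[k]]$id)) {
        newV[[length(newV) + 1]] <- poly[[k]]$pos
        ids[k] <- -length(newV)            # placeholder, resolved below
      } else ids[k] <- poly[[k]]$id
    }
    for (k in 2:(length(poly) - 1))
      newF[[length(newF) + 1]] <- c(ids[1], ids[k], ids[k + 1])
  }
  Vout <- V
  if (length(newV) > 0) Vout <- rbind(V, do.call(rbind, newV))
  Fkeep <- F[keep, , drop = FALSE]
  if (length(newF) > 0) {
    Fnew <- do.call(rbind, newF)
    Fnew[Fnew < 0] <- nrow(V) + (-Fnew[Fnew < 0])
    Fkeep <- rbind(Fkeep, Fnew)
  }
  list(V = Vout, F = Fkeep)
}

#' Triangulated surface of a synthetic vessel tree
#'
#' Builds the open-ended tube-union surface of a [make_tree()] result. The
#' daughters are clipped where their diameter falls below `d_min` (the
#' smallest reconstructable vessel calibre) and side branches are truncated
#' about 10 mm beyond the parent wall before surfacing, mirroring how vascular
#' reconstructions are cropped in practice.
#'
#' @param tree a `pa_tree`.
#' @param circumferential_samples target number of vertices around the
#'   circumference of the thinnest tube (>= 8); together with `axial_step` it
#'   sets the sampling resolution of the surfacing grid.
#' @param axial_step target axial vertex spacing in mm (must not exceed the
#'   smallest tube radius).
#' @param d_min minimum reconstructable diameter (mm) for the daughter trunks.
#' @return A `surface_mesh` with attributes `ends` (open-end metadata:
#'   label, centre, outward normal, radius) and `min_radius`.
#' @export
surface_from_tree <- function(tree, circumferential_samples = 32,
                              axial_step = 1.0, d_min = 8) {
  stopifnot(inherits(tree, "pa_tree"))
  if (circumferential_samples < 8) stop("circumferential_samples must be >= 8")
  branches <- effective_branches(tree, d_min = d_min)
  rmin <- min(vapply(branches, function(b) min(b$radii), numeric(1)))
  if (axial_step > rmin)
    stop(sprintf("axial_step (%.2f) exceeds the smallest tube radius (%.2f)",
                 axial_step, rmin))
  h <- min(axial_step, 2 * pi * rmin / circumferential_samples)
  h <- max(h, 0.3)

  ends <- open_ends(branches)
  # reject self-intersecting specifications: an open end cap buried inside
  # another branch's lumen cannot be surfaced consistently
  for (e in ends) {
    others <- branches[setdiff(names(branches), e$branch)]
    if (length(others) == 0) next
    others <- lapply(others, function(b) list(points = b$points, radii = b$radii))
    f <- cpp_tree_field_points(matrix(e$point, 1, 3), unname(others))
    if (f < 0.25 * e$radius)
      stop("self-intersecting tree specification: open end '", e$label,
           "' lies inside or grazes another branch (clearance ",
           sprintf("%.2f", f), " mm)")
  }

  ext <- 3 * h
  branches_ext <- extend_branch_ends(branches, ends, ext)
  dec <- lapply(unname(branches_ext), decimate_branch, step = max(h, 0.75))

  allpts <- do.call(rbind, lapply(dec, `[[`, "points"))
  rmax <- max(vapply(dec, function(b) max(b$radii), numeric(1)))
  margin <- max(2.5 * h, 1.5)
  lo <- apply(allpts, 2, min) - rmax - margin - h
  hi <- apply(allpts, 2, max) + rmax + margin + h
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  field <- cpp_tree_field_grid(dims, lo, rep(h, 3), dec, margin)
  mc <- cpp_marching_tets(field, dims, lo, rep(h, 3), 0)
  if (nrow(mc$vertices) == 0) stop("surfacing produced an empty mesh")
  V <- cpp_project_to_tree(mc$vertices, dec, 5L)
  F <- mc$faces + 1L
  for (e in ends) {
    vic <- sqrt((e$radius + 2 * h)^2 + (ext + h)^2) + h
    n0 <- nrow(V)
    cl <- clip_mesh_at_plane(V, F, e$point, e$normal, vic)
    V <- cl$V
    F <- cl$F
    if (nrow(V) > n0) {
      # rim vertices sit on clipped chords: push them back onto the tube
      # surface, then exactly onto the cut plane
      idx <- (n0 + 1):nrow(V)
      Vr <- cpp_project_to_tree(V[idx, , drop = FALSE], dec, 4L)
      d <- as.vector(sweep(Vr, 2, e$point) %*% e$normal)
      V[idx, ] <- Vr - outer(d, e$normal)
    }
  }
  mesh <- weld_mesh(surface_mesh(V, F), tol = 1e-6)
  mesh <- repair_tiny_loops(mesh, tol = min(1, h))
  attr(mesh, "ends") <- ends
  attr(mesh, "min_radius") <- rmin
  mesh
}

#' Perturb a mesh along vertex normals (synthetic reconstruction variability)
#'
#' Emulates operator variability by displacing interior vertices along their
#' area-weighted normals with a smooth zero-mean Gaussian random field
#' (a sum of random plane waves with the given correlation length), so
#' neighbouring vertices move coherently the way independent segmentations
#' disagree regionally. Independent per-vertex noise would make the surface
#' jagged and bias inscribed-sphere radii inward. Boundary-loop vertices stay
#' fixed so open ends are preserved.
#'
#' @param mesh a `surface_mesh`.
#' @param sd field standard deviation in mm.
#' @param seed integer seed.
#' @param correlation_length spatial scale of the field in mm.
#' @return A perturbed `surface_mesh`.
#' @export
perturb_mesh <- function(mesh, sd = 0.3, seed = 1L, correlation_length = 25) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  N <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  # accumulate face normals onto vertices
  VN <- matrix(0, nrow(V), 3)
  for (s in 1:3) for (cc in 1:3) {
    acc <- rowsum(N[, cc], F[, s])
    VN[as.integer(rownames(acc)), cc] <- VN[as.integer(rownames(acc)), cc] + acc
  }
  nn <- pmax(sqrt(rowSums(VN^2)), 1e-12)
  VN <- VN / nn
  bnd <- unique(as.vector(boundary_edges(mesh)))
  disp <- with_seed(seed, {
    k <- 24L
    dirs <- matrix(rnorm(3 * k), k, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    omega <- 2 * pi / correlation_length
    phase <- runif(k, 0, 2 * pi)
    amp <- rnorm(k)
    waves <- sin(V %*% t(dirs * omega) + matrix(phase, nrow(V), k, byrow = TRUE))
    as.vector(waves %*% amp) / sqrt(k / 2) * sd   # unit variance, scaled

  })
  if (length(bnd) > 0) disp[bnd] <- 0
  surface_mesh(V + VN * disp, F, scalars = mesh$scalars)
}
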