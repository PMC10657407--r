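#' Triangulated surface mesh
#'
#' Container for an open-ended tubular surface in millimetre coordinates:
#' vertices (n x 3 matrix) and faces (m x 3 integer matrix of 1-based vertex
#' indices). Faces are expected to be consistently oriented with outward
#' normals; meshes produced by this package satisfy that.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param scalars optional named list of per-vertex numeric vectors.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, scalars = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, scalars = scalars),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  nb <- tryCatch(length(boundary_loops(x)), error = function(e) NA_integer_)
  cat(sprintf("<surface_mesh> %d vertices, %d faces, %s boundary loop(s)\n",
              nrow(x$vertices), nrow(x$faces),
              ifelse(is.na(nb), "?", nb)))
  invisible(x)
}

# remove zero-area faces and unreferenced vertices
clean_mesh <- function(mesh, area_tol = 1e-10) {
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(F) == 0) return(mesh)
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  area2 <- sqrt(cx^2 + cy^2 + cz^2)
  degen <- area2 < area_tol | F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3]
  F <- F[!degen, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  surface_mesh(V[used, , drop = FALSE],
               matrix(remap[F], ncol = 3),
               scalars = lapply(mesh$scalars, function(s) s[used]))
}

# weld vertices closer than tol (used after clipping)
weld_mesh <- function(mesh, tol = 1e-6) {
  V <- mesh$vertices
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  Vn <- V[first, , drop = FALSE]
  Fn <- matrix(idx[mesh$faces], ncol = 3)
  clean_mesh(surface_mesh(Vn, Fn))
}

# close degenerate pinholes: boundary loops whose circumference is below tol
# (slivers collapsed by vertex projection) are welded into a single vertex
repair_tiny_loops <- function(mesh, tol) {
  repeat {
    loops <- boundary_loops(mesh)
    small <- Filter(function(l) {
      P <- mesh$vertices[l, , drop = FALSE]
      polyline_arc(rbind(P, P[1, ])) < tol
    }, loops)
    if (length(small) == 0) return(mesh)
    remap <- seq_len(nrow(mesh$vertices))
    for (l in small) remap[l] <- l[1]
    mesh <- clean_mesh(surface_mesh(mesh$vertices,
                                    matrix(remap[mesh$faces], ncol = 3),
                                    scalars = mesh$scalars))
  }
}

# directed boundary edges: edges incident to exactly one face, in face winding
boundary_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1], e[, 2])
  once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  e[once, , drop = FALSE]
}

#' Boundary loops of an open mesh
#'
#' Returns the closed vertex cycles bounding each open end (inlet, outlet and
#' side-branch truncation planes). A watertight mesh has none.
#'
#' @param mesh a `surface_mesh`.
#' @return List of integer vectors, each an ordered cycle of vertex indices.
#' @export
boundary_loops <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) return(list())
  nxt <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(be))) assign(as.character(be[i, 1]), be[i, 2], envir = nxt)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  loops <- list()
  for (i in seq_len(nrow(be))) {
    v0 <- be[i, 1]
    if (!is.null(visited[[as.character(v0)]])) next
    loop <- integer(0)
    v <- v0
    repeat {
      loop <- c(loop, v)
      assign(as.character(v), TRUE, envir = visited)
      nv <- nxt[[as.character(v)]]
      if (is.null(nv)) break       # non-closing chain: defect, return as-is
      v <- nv
      if (v == v0) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

# loop geometry: centroid, mean radius, best-fit plane normal (via the
# directed loop orientation) and circumference
loop_info <- function(mesh, loop) {
  P <- mesh$vertices[loop, , drop = FALSE]
  centroid <- colMeans(P)
  rel <- sweep(P, 2, centroid)
  radius <- mean(sqrt(rowSums(rel^2)))
  # Newell normal respects loop orientation
  nrm <- c(0, 0, 0)
  n <- nrow(P)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    nrm <- nrm + pracma_cross(P[i, ], P[j, ])
  }
  circ <- sum(sqrt(rowSums((P[c(2:n, 1), , drop = FALSE] - P)^2)))
  list(vertices = loop, centroid = centroid, radius = radius,
       normal = if (vnorm(nrm) > 0) unitize(nrm) else c(0, 0, 1),
       circumference = circ)
}

# fan-cap all boundary loops; returns list(mesh=closed mesh, cap_faces=matrix)
cap_mesh <- function(mesh) {
  loops <- boundary_loops(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  capF <- NULL
  for (loop in loops) {
    centroid <- colMeans(V[loop, , drop = FALSE])
    cid <- nrow(V) + 1L
    V <- rbind(V, centroid)
    n <- length(loop)
    # directed boundary edge a->b belongs to an interior face; the cap must
    # traverse it b->a for consistent outward orientation
    tri <- cbind(rep(cid, n), loop[c(2:n, 1)], loop)
    capF <- rbind(capF, tri)
  }
  list(mesh = surface_mesh(V, rbind(F, capF)),
       cap_faces = capF, n_loops = length(loops))
}

#' Enclosed volume of a surface mesh
#'
#' Open boundary loops are fan-capped before integrating the divergence
#' theorem, so open-ended tubes report their enclosed lumen volume.
#'
#' @param mesh a `surface_mesh`.
#' @return Volume in mm^3 (non-negative).
#' @export
mesh_volume <- function(mesh) {
  cm <- cap_mesh(mesh)
  V <- cm$mesh$vertices
  F <- cm$mesh$faces
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  det6 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  abs(sum(det6)) / 6
}

# mean per-face normal variation against neighbouring faces (staircase metric)
face_normal_variation <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  N <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  N <- N / pmax(sqrt(rowSums(N^2)), 1e-12)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  fid <- rep(seq_len(nrow(F)), 3)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ord <- order(key)
  key <- key[ord]; fid <- fid[ord]
  same <- key[-1] == key[-length(key)]
  f1 <- fid[-length(fid)][same]
  f2 <- fid[-1][same]
  dots <- rowSums(N[f1, , drop = FALSE] * N[f2, , drop = FALSE])
  mean(acos(pmin(1, pmax(-1, dots))))
}

#' Write a mesh as ASCII STL
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid pamorph", con)
  for (i in seq_len(nrow(F))) {
    p1 <- V[F[i, 1], ]; p2 <- V[F[i, 2], ]; p3 <- V[F[i, 3], ]
    n <- pracma_cross(p2 - p1, p3 - p1)
    nn <- vnorm(n)
    n <- if (nn > 0) n / nn else c(0, 0, 0)
    writeLines(c(
      sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "  outer loop",
      sprintf("    vertex %.9g %.9g %.9g", p1[1], p1[2], p1[3]),
      sprintf("    vertex %.9g %.9g %.9g", p2[1], p2[2], p2[3]),
      sprintf("    vertex %.9g %.9g %.9g", p3[1], p3[2], p3[3]),
      "  endloop",
      "endfacet"), con)
  }
  writeLines("endsolid pamorph", con)
  invisible(path)
}

#' Read an ASCII STL file
#' @param path file path.
#' @param weld_tol vertex welding tolerance in mm.
#' @return A `surface_mesh`.
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("not a valid ASCII STL file: ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  F <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  weld_mesh(surface_mesh(nums, F), tol = weld_tol)
}

#' Write a mesh as ASCII PLY (optionally with one per-vertex scalar)
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param scalar optional numeric vector (one value per vertex), stored as a
#'   `quality` property, e.g. a surface distance for visualisation.
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == nrow(V))
    hdr <- c(hdr, "property float quality")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(scalar)) {
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3], scalar), con)
  }
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file
#' @param path file path.
#' @return A `surface_mesh`; a `quality` vertex property is kept in `scalars`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("not a valid ASCII PLY file: ", path)
  hdr <- trimws(lines[1:endh])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  props <- sub("^property float ", "", grep("^property float", hdr, value = TRUE))
  vlines <- lines[(endh + 1):(endh + nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
  flines <- lines[(endh + nv + 1):(endh + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(x)
    as.integer(x[2:4]) + 1L))
  scal <- NULL
  qi <- match("quality", props)
  if (!is.na(qi)) scal <- list(quality = vm[, qi])
  surface_mesh(vm[, 1:3, drop = FALSE], fm, scalars = scal)
}
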