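# Image-to-surface stages: intensity thresholding, iso-surface extraction
# from a binary label field, and volume-preserving smoothing.

#' Candidate lumen mask from an intensity threshold
#'
#' Labels every voxel whose intensity lies strictly above the threshold.
#' On contrast CT this is the first, automatic step of lumen segmentation;
#' the result is a candidate mask only (manual correction is a separate,
#' interactive process and out of scope here).
#'
#' @param image 3D numeric array, or a list with elements `data` (3D array),
#'   `spacing` and `origin`.
#' @param threshold intensity threshold (e.g. a Hounsfield Unit value; typical
#'   contrast-CT lumen thresholds range from roughly 80 to 400 HU depending on
#'   contrast concentration).
#' @param spacing,origin used when `image` is a bare array.
#' @return A `voxel_mask`.
#' @export
mask_from_threshold <- function(image, threshold, spacing = c(1, 1, 1),
                                origin = c(0, 0, 0)) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (is.list(image) && !is.null(image$data)) {
    spacing <- image$spacing %||% spacing
    origin <- image$origin %||% origin
    image <- image$data
  }
  if (length(dim(image)) != 3) stop("image must be a 3D array")
  voxel_mask(image > threshold, spacing, origin)
}

#' Extract a triangulated surface from a binary mask
#'
#' Triangulates the 0.5 iso-level of the binary label field with a marching
#' tetrahedra scheme (each grid cell is split into six tetrahedra sharing the
#' main diagonal; crossing vertices are placed by linear interpolation, which
#' on a binary field is the midpoint of each inside/outside grid edge). Only
#' the largest 26-connected foreground component is surfaced; smaller blobs
#' are reported and discarded. The resulting mesh is closed and lives in the
#' mask's millimetre frame.
#'
#' @param mask a `voxel_mask` with at least one foreground voxel.
#' @return A closed `surface_mesh`.
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$grid)) stop("cannot extract a surface from an empty mask")
  mask <- largest_component(mask)
  g <- mask$grid
  d <- dim(g)
  # pad with background so the surface closes at the volume border
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- g
  field <- array(1, dim(padded))
  field[padded] <- 0
  origin <- mask$origin - mask$spacing
  mc <- cpp_marching_tets(as.numeric(field), dim(padded), origin,
                          mask$spacing, 0.5)
  clean_mesh(surface_mesh(mc$vertices, mc$faces + 1L))
}

#' Volume-preserving surface smoothing
#'
#' Removes the voxel staircase of an extracted surface with a Taubin
#' lambda/mu smoothing iteration followed, each iteration, by a volume
#' compensation step that displaces free vertices along their normals until
#' the enclosed volume matches the input (drift below 0.1 percent by
#' construction). Open boundary-loop vertices are frozen so truncation planes
#' keep their shape, and the vertex count never changes.
#'
#' @param mesh a `surface_mesh` with more than 4 vertices.
#' @param iterations number of smoothing iterations (>= 0; 0 returns the
#'   input unchanged).
#' @param strength Laplacian step size lambda in (0, 1).
#' @return The smoothed `surface_mesh`.
#' @export
smooth_volume_preserving <- function(mesh, iterations = 20, strength = 0.5) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$vertices) <= 4) stop("mesh too small to smooth")
  if (iterations < 0) stop("iterations must be >= 0")
  if (iterations == 0) return(mesh)
  # reject meshes that are non-manifold beyond their open boundaries
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- sort(pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1], e[, 2]))
  if (any(key[seq_len(length(key) - 2)] == key[-(1:2)]))
    stop("non-manifold mesh: an edge has more than two incident faces")
  cm <- cap_mesh(mesh)
  capF <- if (is.null(cm$cap_faces)) matrix(integer(0), 0, 3) else cm$cap_faces
  storage.mode(capF) <- "integer"
  # cap centroid vertices ride along (no open-mesh neighbours, so they stay put)
  Vs <- cpp_smooth_volpres(cm$mesh$vertices, mesh$faces - 1L, capF - 1L,
                           as.integer(iterations), strength)
  out <- surface_mesh(Vs[seq_len(nrow(mesh$vertices)), , drop = FALSE],
                      mesh$faces, scalars = mesh$scalars)
  for (at in c("ends", "min_radius")) attr(out, at) <- attr(mesh, at)
  out
}
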