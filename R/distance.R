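# Operator-bias surface comparison: per-vertex nearest-surface distances
# between two independent reconstructions of the same anatomy, summarised
# over the trunk region only (MPA + LPA + RPA), so differences in how far
# side branches were segmented do not contaminate the agreement metric.

#' Per-vertex distance from one surface to another
#'
#' For every vertex of mesh `a`, the unsigned Euclidean distance to the
#' closest point on any triangle of mesh `b` (point-to-triangle, not
#' vertex-to-vertex). No registration is performed: reconstructions of the
#' same scan already share a frame. Note the measure is asymmetric:
#' `d(a, b) != d(b, a)` in general; this function reports `a -> b`.
#'
#' @param a,b `surface_mesh` objects in the same millimetre frame.
#' @return Numeric vector, one distance (mm) per vertex of `a`.
#' @export
vertex_to_surface_distance <- function(a, b) {
  if (nrow(a$vertices) == 0 || nrow(b$faces) == 0)
    stop("cannot compare empty meshes")
  cpp_point_mesh_distance(a$vertices, b$vertices, b$faces - 1L)
}

#' Restrict a surface-distance field to the MPA/LPA/RPA trunk region
#'
#' A vertex of `a` belongs to the trunk region iff its nearest centreline
#' vertex carries a trunk label (MPA, LPA or RPA) and lies within
#' `radius_factor` times that vertex's local radius, which excludes vertices
#' sitting on side-branch tubes. Mean and SD are computed over the region.
#'
#' @param a the `surface_mesh` the distances live on.
#' @param lt a `labeled_tree` extracted from `a`.
#' @param distances per-vertex distances from [vertex_to_surface_distance()].
#' @param radius_factor region membership multiplier (default 1.5).
#' @param bins number of histogram bins.
#' @return A `distance_result`: `per_vertex_distance`, logical `region_mask`,
#'   `mean`, `sd`, and a `histogram`.
#' @export
restrict_to_trunk <- function(a, lt, distances, radius_factor = 1.5, bins = 30) {
  stopifnot(length(distances) == nrow(a$vertices))
  cl <- lt$tree$vertices
  rad <- lt$tree$radius
  vl <- vertex_labels(lt)
  n <- nrow(a$vertices)
  nearest <- integer(n)
  ndist <- numeric(n)
  chunk <- 4000L
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    A <- a$vertices[s:e, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rep(1, nrow(cl))) +
      outer(rep(1, nrow(A)), rowSums(cl^2)) - 2 * A %*% t(cl)
    j <- max.col(-d2, ties.method = "first")
    nearest[s:e] <- j
    ndist[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(A)), j)], 0))
  }
  region <- vl[nearest] %in% c("MPA", "LPA", "RPA") &
    ndist <= radius_factor * rad[nearest]
  if (!any(region)) stop("trunk region is empty")
  dr <- distances[region]
  h <- graphics::hist(dr, breaks = bins, plot = FALSE)
  structure(list(per_vertex_distance = distances, region_mask = region,
                 mean = mean(dr), sd = stats::sd(dr), histogram = h),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> trunk region: %d / %d vertices, distance %.3f +/- %.3f mm\n",
              sum(x$region_mask), length(x$region_mask), x$mean, x$sd))
  invisible(x)
}

#' Compare two reconstructions of one subject over the trunk region
#'
#' Convenience wrapper: distances `a -> b`, trunk restriction via the labeled
#' centreline of `a`, optional symmetric mean (average of both directions'
#' region means).
#'
#' @inheritParams restrict_to_trunk
#' @param b the second reconstruction.
#' @param symmetric also compute the `b -> a` region-unrestricted mean and
#'   report the average of the two directed means.
#' @return A `distance_result`, with `symmetric_mean` appended if requested.
#' @export
compare_surfaces <- function(a, b, lt, radius_factor = 1.5, symmetric = FALSE) {
  d <- vertex_to_surface_distance(a, b)
  res <- restrict_to_trunk(a, lt, d, radius_factor = radius_factor)
  if (symmetric) {
    dba <- vertex_to_surface_distance(b, a)
    res$symmetric_mean <- mean(c(res$mean, mean(dba)))
  }
  res
}
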