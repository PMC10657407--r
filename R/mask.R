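#' Binary voxel mask
#'
#' A 3D binary label field in millimetre coordinates. `origin` is the position
#' of the centre of voxel `[1, 1, 1]`; voxel centres lie on a regular grid
#' with the given per-axis spacing. The axis convention label is metadata only.
#'
#' @param grid logical or 0/1 3D array.
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @param axis_convention frame label, default "LPS".
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, spacing, origin = c(0, 0, 0),
                       axis_convention = "LPS") {
  if (length(dim(grid)) != 3) stop("grid must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be positive on every axis")
  structure(list(grid = array(as.logical(grid), dim = dim(grid)),
                 spacing = spacing, origin = as.numeric(origin),
                 axis_convention = axis_convention),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels @ %s mm, %d foreground (%.1f mm^3)\n",
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$grid), mask_volume(x)))
  invisible(x)
}

#' Foreground volume of a mask (voxel count x voxel volume)
#' @param mask a `voxel_mask`.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$grid) * prod(mask$spacing)
}

# largest 26-connected component; message when smaller blobs are discarded
largest_component <- function(mask) {
  lab <- cpp_connected_components26(as.logical(mask$grid), dim(mask$grid))
  if (max(lab) <= 1) return(mask)
  tab <- tabulate(lab)
  keep <- which.max(tab)
  message(sprintf("discarding %d disconnected foreground component(s); keeping the largest (%d voxels)",
                  length(tab) - 1L, tab[keep]))
  g <- array(lab == keep, dim = dim(mask$grid))
  voxel_mask(g, mask$spacing, mask$origin, mask$axis_convention)
}

#' Rasterise a surface mesh into a binary voxel mask
#'
#' Open boundary loops are fan-capped internally, then voxel centres are
#' classified by ray-crossing parity: a centre inside the capped solid is
#' foreground. Spacing and origin are carried so the mask stays in the mesh's
#' millimetre frame.
#'
#' @param mesh a `surface_mesh`.
#' @param spacing scalar or length-3 voxel spacing in mm.
#' @param margin extra empty border around the mesh, in voxels.
#' @return A `voxel_mask`.
#' @export
voxelize <- function(mesh, spacing, margin = 2L) {
  if (nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0)
    stop("cannot voxelize an empty mesh")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  rmin <- attr(mesh, "min_radius")
  if (!is.null(rmin) && max(spacing) > rmin)
    warning("voxel spacing exceeds the smallest tube radius; the mask may disconnect")
  closed <- cap_mesh(mesh)$mesh
  lo <- apply(closed$vertices, 2, min) - margin * spacing
  hi <- apply(closed$vertices, 2, max) + margin * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  g <- cpp_voxelize_mesh(closed$vertices, closed$faces - 1L, dims, lo, spacing)
  voxel_mask(array(g, dim = dims), spacing, lo)
}

#' Write a voxel mask as NIfTI
#'
#' The affine carries spacing and origin so that a round-trip stays in the
#' source millimetre frame.
#'
#' @param mask a `voxel_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(as.integer(mask$grid), dim = dim(mask$grid))
  img <- RNifti::asNifti(arr)
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(mask$spacing)
  aff[1:3, 4] <- mask$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask written by [write_mask_nifti()]
#' @param path file path.
#' @param threshold values strictly above this are foreground.
#' @return A `voxel_mask`.
#' @export
read_mask_nifti <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4]
  voxel_mask(array(as.array(img) > threshold, dim = dim(img)[1:3]),
             spacing, origin)
}
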