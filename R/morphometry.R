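# Geometric size and shape parameters of a labeled centreline tree.
#
# Conventions: the MPA is measured from the inlet to the bifurcation vertex
# Pb; the LPA and RPA from Pb to their end vertices. Taper and curvature use
# the segment from the 10 mm landmark (P2/P3) to the branch end, with the
# curved arc length as the segment length. Diameters are twice the
# inscribed-sphere radius, linearly interpolated at landmark positions.

trunk_path <- function(lt, label) {
  switch(label,
         MPA = lt$mpa_path,
         LPA = lt$lpa_path,
         RPA = lt$rpa_path,
         stop("unknown branch label: ", label, " (expected MPA, LPA or RPA)"))
}

#' Accumulated length of a labeled trunk path
#'
#' Sum of edge lengths along the MPA (root to bifurcation) or a daughter
#' (bifurcation to end vertex).
#'
#' @param lt a `labeled_tree`.
#' @param label one of `"MPA"`, `"LPA"`, `"RPA"`.
#' @return Length in mm.
#' @export
branch_length <- function(lt, label) {
  polyline_arc(lt$tree$vertices[trunk_path(lt, label), , drop = FALSE])
}

#' Length-weighted mean diameter of a labeled trunk path
#'
#' Each edge contributes its length times its mean diameter (average of the
#' two endpoint diameters); the total is normalised by the path length.
#'
#' @inheritParams branch_length
#' @return Diameter in mm.
#' @export
length_weighted_diameter <- function(lt, label) {
  p <- trunk_path(lt, label)
  V <- lt$tree$vertices[p, , drop = FALSE]
  r <- lt$tree$radius[p]
  seg <- sqrt(rowSums((V[-1, , drop = FALSE] - V[-nrow(V), , drop = FALSE])^2))
  dmean <- r[-1] + r[-length(r)]        # = 2 * mean endpoint radius
  sum(seg * dmean) / sum(seg)
}

#' Vessel taper
#'
#' `(d_in - d_out) / length`: the diameter decrease per unit segment length.
#' Negative values indicate a flaring segment and are allowed (flagged in QC).
#'
#' @param d_in,d_out diameters (mm) at the segment start and end.
#' @param length curved segment length (mm), positive.
#' @return Dimensionless taper.
#' @export
taper <- function(d_in, d_out, length) {
  if (length <= 0) stop("segment length must be positive")
  (d_in - d_out) / length
}

#' Curvature index of a centreline segment
#'
#' Ratio of the straight start-to-end distance to the curved arc length.
#' 1 means a straight segment; lower values mean stronger curvature.
#'
#' @param path ordered point matrix (n x 3) from segment start to end.
#' @return CI in (0, 1].
#' @export
curvature_index <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 2) stop("need at least two points")
  L <- polyline_arc(path)
  if (L <= 0) stop("zero arc length: coincident points")
  vnorm(path[nrow(path), ] - path[1, ]) / L
}

#' Enlargement index of the main bifurcation
#'
#' `(1 - (d_lpa^2 + d_rpa^2) / d_mpa^2)^2`: the squared relative mismatch of
#' summed daughter cross-sectional area against the trunk area. 0 for an
#' area-preserving split; larger values indicate a sudden cross-sectional
#' change that promotes flow separation.
#'
#' @param d_mpa trunk diameter (mm, positive).
#' @param d_lpa,d_rpa daughter diameters (mm) at the 10 mm landmarks.
#' @return Dimensionless EnI >= 0.
#' @export
enlargement_index <- function(d_mpa, d_lpa, d_rpa) {
  if (d_mpa <= 0) stop("d_mpa must be positive")
  (1 - (d_lpa^2 + d_rpa^2) / d_mpa^2)^2
}

#' Bifurcation angle
#'
#' Angle at `pb` between the vectors to the two daughter landmarks, in
#' degrees.
#'
#' @param pb bifurcation point (length-3).
#' @param p2,p3 daughter landmark points (length-3).
#' @return Angle in degrees, in (0, 180].
#' @export
bifurcation_angle <- function(pb, p2, p3) {
  if (vnorm(p2 - pb) < 1e-9 || vnorm(p3 - pb) < 1e-9)
    stop("landmarks coincide with the bifurcation point")
  angle_between_deg(p2 - pb, p3 - pb)
}

# sub-path from arc position s to the end, with the interpolated start point
subpath_from <- function(V, s) {
  arc <- cum_arc(V)
  st <- interp_along(V, s)$position
  rbind(st, V[arc > s + 1e-9, , drop = FALSE])
}

#' Measure all geometric parameters of one subject
#'
#' Assembles the full per-subject parameter record from a labeled centreline
#' tree: side-branch counts, trunk lengths and length-weighted diameters,
#' bifurcation angle, daughter taper and curvature indices (both measured
#' from the 10 mm landmark to the branch end), and the enlargement index.
#' If a daughter is shorter than the landmark offset the shape parameters are
#' reported as non-evaluable with a reason instead of failing the subject.
#'
#' @param lt a `labeled_tree` (landmarks are located on demand).
#' @param eni_mpa_at where the MPA diameter entering the enlargement index is
#'   read: `"P1"` (10 mm upstream of the bifurcation, the default: the
#'   inscribed-sphere radius at the bifurcation vertex itself is dominated by
#'   the daughter lumina) or `"Pb"`. Both variants are reported in `qc`.
#' @param offset landmark offset in mm.
#' @param subject_id,species metadata carried into the record.
#' @return A `morphometry_record`.
#' @export
measure_subject <- function(lt, eni_mpa_at = c("P1", "Pb"), offset = 10,
                            subject_id = NA_character_, species = NA_character_) {
  eni_mpa_at <- match.arg(eni_mpa_at)
  stopifnot(inherits(lt, "labeled_tree"))
  rec <- list(subject_id = subject_id, species = species)
  cnt <- count_side_branches(lt)
  rec$n_side_lpa <- unname(cnt[1])
  rec$n_side_rpa <- unname(cnt[2])
  for (lab in c("MPA", "LPA", "RPA")) {
    rec[[paste0("L_", lab)]] <- branch_length(lt, lab)
    rec[[paste0("D_", lab)]] <- length_weighted_diameter(lt, lab)
  }
  shape_fields <- c("alpha", "T_LPA", "T_RPA", "CI_LPA", "CI_RPA", "EnI")
  qc <- list()
  lmres <- tryCatch({
    if (is.null(lt$landmarks) || !identical(lt$landmark_offset, offset))
      lt <- locate_landmarks(lt, offset)
    lt
  }, pamorph_short_daughter = function(e) e)
  if (inherits(lmres, "condition")) {
    for (f in shape_fields) rec[[f]] <- NA_real_
    qc$non_evaluable <- conditionMessage(lmres)
  } else {
    lt <- lmres
    lm <- lt$landmarks
    rec$alpha <- bifurcation_angle(lm$Pb$position, lm$P2$position, lm$P3$position)
    for (side in c("LPA", "RPA")) {
      p <- trunk_path(lt, side)
      V <- lt$tree$vertices[p, , drop = FALSE]
      st <- if (side == "LPA") lm$P2 else lm$P3
      en <- lm[[paste0("End_", side)]]
      Lseg <- en$arc - st$arc
      rec[[paste0("T_", side)]] <- taper(2 * st$radius, 2 * en$radius, Lseg)
      rec[[paste0("CI_", side)]] <- curvature_index(subpath_from(V, st$arc))
    }
    d_mpa_pb <- 2 * lm$Pb$radius
    d_mpa_p1 <- if (!is.null(lm$P1)) 2 * lm$P1$radius else NA_real_
    qc$EnI_Pb <- enlargement_index(d_mpa_pb, 2 * lm$P2$radius, 2 * lm$P3$radius)
    qc$EnI_P1 <- if (is.na(d_mpa_p1)) NA_real_ else
      enlargement_index(d_mpa_p1, 2 * lm$P2$radius, 2 * lm$P3$radius)
    rec$EnI <- if (eni_mpa_at == "P1" && !is.na(d_mpa_p1)) qc$EnI_P1 else qc$EnI_Pb
    if (eni_mpa_at == "P1" && is.na(d_mpa_p1))
      qc$note <- "MPA shorter than the landmark offset: EnI falls back to the Pb diameter"
    qc$D_MPA_Pb <- d_mpa_pb
    qc$D_MPA_P1 <- d_mpa_p1
    qc$D_LPA_P2 <- 2 * lm$P2$radius
    qc$D_RPA_P3 <- 2 * lm$P3$radius
    if (any(c(rec$T_LPA, rec$T_RPA) < 0)) qc$flag_flaring_segment <- TRUE
    if (rec$alpha > 175) qc$flag_implausible_angle <- TRUE
  }
  rec$eni_mpa_at <- eni_mpa_at
  rec$qc <- qc
  structure(rec, class = "morphometry_record")
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat("<morphometry_record>\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  if (!is.null(x$qc$non_evaluable))
    cat("non-evaluable shape parameters:", x$qc$non_evaluable, "\n")
  invisible(x)
}

#' @export
as.data.frame.morphometry_record <- function(x, ...) {
  fields <- c("subject_id", "species", "n_side_lpa", "n_side_rpa",
              "L_MPA", "L_LPA", "L_RPA", "D_MPA", "D_LPA", "D_RPA",
              "alpha", "T_LPA", "T_RPA", "CI_LPA", "CI_RPA", "EnI")
  vals <- lapply(fields, function(f) x[[f]] %||% NA)
  names(vals) <- fields
  as.data.frame(vals, stringsAsFactors = FALSE)
}
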