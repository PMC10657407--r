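# Synthetic pulmonary-artery-like trees with analytically known morphometry.
#
# A tree is a main trunk (MPA) splitting into two daughters (LPA toward the
# subject-left +x axis, RPA opposite), each carrying truncated side branches.
# Branch centrelines are dense polylines sampled from parametric curves
# (straight lines and circular arcs), radii are linear in arc length, so every
# geometric parameter (length, length-weighted diameter, taper, curvature
# index, enlargement index, bifurcation angle) has a known target value that
# is stored in the `truth` mapping using the same landmark conventions the
# measurement pipeline applies (P1/P2/P3 at 10 mm from the bifurcation).

CURVE_STEP <- 0.25   # mm, dense sampling of parametric centrelines

# --- parametric curve builders ---------------------------------------------

# straight or circular-arc curve: start point, unit direction, bend normal m
# (unit, perpendicular to dir), total turn angle (rad) and arc length (mm)
curve_points <- function(start, dir, length, bend_normal = NULL,
                         turn_rad = 0, step = CURVE_STEP) {
  n <- max(2L, ceiling(length / step) + 1L)
  s <- seq(0, length, length.out = n)
  dir <- unitize(dir)
  if (turn_rad < 1e-9 || is.null(bend_normal)) {
    p <- cbind(start[1] + s * dir[1], start[2] + s * dir[2], start[3] + s * dir[3])
  } else {
    m <- unitize(bend_normal - sum(bend_normal * dir) * dir)
    Ra <- length / turn_rad
    phi <- s / Ra
    p <- cbind(
      start[1] + Ra * (sin(phi) * dir[1] + (1 - cos(phi)) * m[1]),
      start[2] + Ra * (sin(phi) * dir[2] + (1 - cos(phi)) * m[2]),
      start[3] + Ra * (sin(phi) * dir[3] + (1 - cos(phi)) * m[3]))
  }
  p
}

new_branch <- function(name, points, r_start, r_end, parent = NULL,
                       attach_arc = NA_real_, planned_angle = NA_real_) {
  arc <- cum_arc(points)
  L <- arc[length(arc)]
  radii <- r_start + (r_end - r_start) * arc / max(L, 1e-12)
  if (any(radii <= 0)) stop("branch radii must stay positive")
  list(name = name, points = points, radii = radii, arc = arc, length = L,
       parent = parent, attach_arc = attach_arc, planned_angle = planned_angle)
}

branch_tangent <- function(branch, arc_pos) {
  i <- findInterval(arc_pos, branch$arc, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(branch$points) - 1L)
  unitize(branch$points[i + 1, ] - branch$points[i, ])
}

branch_at <- function(branch, arc_pos) {
  ip <- interp_along(branch$points, arc_pos, branch$radii)
  list(position = ip$position, radius = ip$value,
       tangent = branch_tangent(branch, arc_pos))
}

# turn angle of a circular arc whose chord/arc ratio equals a target CI,
# solved on the sub-arc running from the 10 mm landmark to the branch end
turn_for_ci <- function(ci, length, offset = 10) {
  if (ci >= 0.99995) return(0)
  if (ci <= 0.2) stop("curvature index target too small for an arc model")
  f <- function(phi) 2 * sin(phi / 2) / phi - ci
  phi <- stats::uniroot(f, c(1e-6, 1.999 * pi))$root
  phi * length / max(length - offset, 1e-6)
}

# --- BranchSpec (parametric specification type) -----------------------------

#' Parametric branch specification
#'
#' Describes one vessel branch by its centreline control points, a linear
#' radius law between start and end radius, and children attached at interior
#' arc fractions with a planned takeoff angle.
#'
#' @param control_points numeric matrix (>= 2 x 3) of centreline points in mm.
#' @param start_radius,end_radius radii (mm) at the two ends; interpolation is
#'   linear in arc length.
#' @param children list of `list(at = fraction in (0,1), branch = branch_spec,
#'   angle = degrees)` entries.
#' @return An object of class `branch_spec`.
#' @export
branch_spec <- function(control_points, start_radius, end_radius,
                        children = list()) {
  control_points <- as.matrix(control_points)
  if (ncol(control_points) != 3 || nrow(control_points) < 2)
    stop("control_points must be an n x 3 matrix with n >= 2")
  steps <- sqrt(rowSums((control_points[-1, , drop = FALSE] -
                         control_points[-nrow(control_points), , drop = FALSE])^2))
  if (any(steps < 1e-9)) stop("control points must be pairwise non-coincident")
  if (start_radius <= 0 || end_radius <= 0) stop("radii must be positive")
  for (ch in children) {
    if (is.null(ch$at) || ch$at <= 0 || ch$at >= 1)
      stop("child arc fractions must lie strictly inside (0, 1)")
    if (!inherits(ch$branch, "branch_spec")) stop("children must carry branch_spec objects")
  }
  structure(list(control_points = control_points, start_radius = start_radius,
                 end_radius = end_radius, children = children),
            class = "branch_spec")
}

spec_to_branches <- function(spec, name, parent = NULL, attach_arc = NA_real_,
                             planned_angle = NA_real_, counter = new.env()) {
  pts <- spec$control_points
  # resample the control polyline densely so the radius law is in arc length
  arc <- cum_arc(pts)
  L <- arc[length(arc)]
  s <- seq(0, L, by = CURVE_STEP)
  if (s[length(s)] < L) s <- c(s, L)
  dense <- t(vapply(s, function(si) interp_along(pts, si)$position, numeric(3)))
  br <- new_branch(name, dense, spec$start_radius, spec$end_radius,
                   parent = parent, attach_arc = attach_arc,
                   planned_angle = planned_angle)
  out <- list(br)
  for (ch in spec$children) {
    counter$i <- (counter$i %||% 0L) + 1L
    child_name <- sprintf("%s_child%d", name, counter$i)
    out <- c(out, spec_to_branches(ch$branch, child_name, parent = name,
                                   attach_arc = ch$at * L,
                                   planned_angle = ch$angle %||% NA_real_,
                                   counter = counter))
  }
  out
}

# --- species templates ------------------------------------------------------

# cohort-level parameter distributions per species (mm, degrees); median[IQR]
# rows are mapped to mean ~ median, sd ~ IQR/1.35
species_templates <- function() {
  list(
    porcine = list(
      L_MPA = c(49.3, 9.83), L_RPA = c(100.9, 12.75), L_LPA = c(83.5, 8.15),
      D_MPA = c(23.4, 3.30), D_RPA = c(15.2, 2.18), D_LPA = c(14.8, 1.63),
      alpha = c(71, 6.1), T_RPA = c(0.113, 0.0221), T_LPA = c(0.150, 0.0367),
      CI_RPA = c(0.93, 0.020), CI_LPA = c(0.96, 0.014),
      n_side = c(4.7, 0.8)),
    ovine = list(
      L_MPA = c(51.5, 10.46), L_RPA = c(134.1, 22.76), L_LPA = c(112.2, 13.95),
      D_MPA = c(22.8, 6.09), D_RPA = c(12.4, 2.00), D_LPA = c(11.9, 1.97),
      alpha = c(69, 16.2), T_RPA = c(0.113, 0.0133), T_LPA = c(0.138, 0.0267),
      CI_RPA = c(0.86, 0.040), CI_LPA = c(0.96, 0.017),
      n_side = c(6.6, 1.6)),
    human = list(
      L_MPA = c(47.1, 8.77), L_RPA = c(116.9, 18.68), L_LPA = c(104.0, 14.14),
      D_MPA = c(27.6, 3.37), D_RPA = c(18.8, 2.45), D_LPA = c(18.1, 1.78),
      alpha = c(92, 11.4), T_RPA = c(0.169, 0.0334), T_LPA = c(0.195, 0.0402),
      CI_RPA = c(0.88, 0.053), CI_LPA = c(0.77, 0.062),
      n_side = c(5.0, 1.3))
  )
}

draw_subject_params <- function(tpl, overrides = list()) {
  d <- function(key, lower = -Inf, upper = Inf) {
    m <- tpl[[key]]
    rtnorm3(1, m[1], m[2], lower, upper)
  }
  # both daughter diameters of one subject scale together; a shared
  # subject-level component (rho = 0.95) gives within-subject diameter
  # orderings the pairing power they have in real cohorts
  rho <- 0.95
  z_shared <- rnorm(1)
  d_corr <- function(key, lower) {
    m <- tpl[[key]]
    x <- m[1] + m[2] * (rho * z_shared + sqrt(1 - rho^2) * rnorm(1))
    min(max(x, max(m[1] - 3 * m[2], lower)), m[1] + 3 * m[2])
  }
  p <- list(
    L_MPA = d("L_MPA", lower = 25),
    L_RPA = d("L_RPA", lower = 40),
    L_LPA = d("L_LPA", lower = 40),
    D_MPA = d("D_MPA", lower = 12),
    D_RPA = d_corr("D_RPA", lower = 9),
    D_LPA = d_corr("D_LPA", lower = 9),
    alpha = d("alpha", lower = 35, upper = 160),
    T_RPA = d("T_RPA", lower = 0.02),
    T_LPA = d("T_LPA", lower = 0.02),
    CI_RPA = d("CI_RPA", lower = 0.55, upper = 0.995),
    CI_LPA = d("CI_LPA", lower = 0.55, upper = 0.995),
    n_side_lpa = as.integer(round(rtnorm3(1, tpl$n_side[1], tpl$n_side[2], 2, 10))),
    n_side_rpa = as.integer(round(rtnorm3(1, tpl$n_side[1], tpl$n_side[2], 2, 10))),
    mpa_taper_frac = 0.05,
    side_radius_factor = 0.5,
    d_min = 8,
    landmark_offset = 10
  )
  utils::modifyList(p, overrides)
}

# --- anatomical tree construction ------------------------------------------

build_daughter <- function(name, origin, dir0, p, L, D_lw, Taper, CI, offset,
                           d_min) {
  D_start <- D_lw + Taper * L / 2
  D_end <- D_start - Taper * L
  if (D_end < d_min + 0.2) D_end <- d_min + 0.2  # reconstruction floor
  if (D_start <= 0 || D_end <= 0) stop("daughter radius law went non-positive")
  turn <- turn_for_ci(CI, L, offset)
  pts <- curve_points(origin, dir0, L, bend_normal = c(0, 1, 0), turn_rad = turn)
  new_branch(name, pts, D_start / 2, D_end / 2, parent = "MPA")
}

add_side_branches <- function(parent, n, prefix, factor, jitters, psis, zetas) {
  if (n == 0) return(list())
  out <- list()
  L <- parent$length
  for (i in seq_len(n)) {
    frac <- 0.18 + (0.92 - 0.18) * (i - 0.5 + jitters[i]) / n
    at <- frac * L
    loc <- branch_at(parent, at)
    t <- loc$tangent
    ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n1 <- unitize(pracma_cross(t, ref))
    n2 <- pracma_cross(t, n1)
    psi <- psis[i] * pi / 180
    zeta <- zetas[i]
    dir <- cos(psi) * t + sin(psi) * (cos(zeta) * n1 + sin(zeta) * n2)
    len <- 10 + loc$radius               # ~10 mm beyond the parent wall
    r <- factor * loc$radius
    pts <- curve_points(loc$position, dir, len)
    out[[length(out) + 1]] <-
      new_branch(sprintf("%s%d", prefix, i), pts, r, r, parent = parent$name,
                 attach_arc = at, planned_angle = psis[i])
  }
  out
}

# clearance (mm) between a candidate branch tube and a set of other branches:
# minimum over candidate samples of (distance to other tube surface - own
# radius); negative means the tubes overlap
# coarse polyline for clearance testing (cached per branch by the caller);
# `from` drops the proximal stretch that legitimately runs inside the parent
decimate_for_clearance <- function(b, step = 1.5, from = 0) {
  ss <- unique(c(seq(from, b$length, by = step), b$length))
  ss <- ss[ss <= b$length]
  list(points = t(vapply(ss, function(si) interp_along(b$points, si)$position,
                         numeric(3))),
       radii = vapply(ss, function(si)
         interp_along(b$points, si, b$radii)$value, numeric(1)))
}

branch_clearance <- function(candidate, others_dec, skip_arc = 0) {
  if (length(others_dec) == 0) return(Inf)
  s <- seq(0, candidate$length, by = 1)
  s <- s[s >= skip_arc]
  if (length(s) == 0) return(Inf)
  pts <- t(vapply(s, function(si) interp_along(candidate$points, si)$position,
                  numeric(3)))
  rad <- vapply(s, function(si)
    interp_along(candidate$points, si, candidate$radii)$value, numeric(1))
  f <- cpp_tree_field_points(pts, unname(others_dec))
  min(f - rad)
}

# side branches drawn with rejection: redraw position/orientation until the
# new tube keeps clearance from every branch except its parent
draw_side_branches <- function(parent, n, prefix, factor, existing,
                               min_clearance = 1.6, max_try = 60) {
  out <- list()
  L <- parent$length
  parent_dec <- list(decimate_for_clearance(parent))
  existing_dec <- lapply(
    existing[vapply(existing, function(b)
      !identical(b$name, parent$name), logical(1))],
    decimate_for_clearance)
  for (i in seq_len(n)) {
    got <- FALSE
    for (try in seq_len(max_try)) {
      jitter <- runif(1, -0.22, 0.22)
      psi <- runif(1, 45, 75)
      zeta <- runif(1, 0, 2 * pi)
      # early tries keep branches in their evenly spread slot; later tries
      # search the whole eligible stretch for a clear spot
      frac <- if (try <= max_try / 2)
        0.18 + (0.92 - 0.18) * (i - 0.5 + jitter) / n
      else runif(1, 0.18, 0.92)
      at <- frac * L
      loc <- branch_at(parent, at)
      t <- loc$tangent
      ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      n1 <- unitize(pracma_cross(t, ref))
      n2 <- pracma_cross(t, n1)
      psir <- psi * pi / 180
      dir <- cos(psir) * t + sin(psir) * (cos(zeta) * n1 + sin(zeta) * n2)
      len <- 10 + loc$radius             # ~10 mm beyond the parent wall
      r <- factor * loc$radius
      # attachments too close along the parent would fuse into one stem in
      # a rasterised extraction, so keep them apart
      prev_at <- vapply(out, `[[`, numeric(1), "attach_arc")
      if (length(prev_at) > 0 &&
          min(abs(prev_at - at)) < max(5, 0.8 * loc$radius)) next
      cand <- new_branch(sprintf("%s%d", prefix, i),
                         curve_points(loc$position, dir, len), r, r,
                         parent = parent$name, attach_arc = at,
                         planned_angle = psi)
      # the stretch inside and just outside the parent lumen legitimately
      # hugs it; only the distal end must keep clear of the parent so the
      # truncation cap cannot graze it (relevant for curved parents)
      exit_arc <- loc$radius / sin(psir) + 1
      ok <- branch_clearance(cand, existing_dec,
                             skip_arc = exit_arc) >= min_clearance &&
        branch_clearance(cand, parent_dec,
                         skip_arc = max(exit_arc, len - 5)) >= min_clearance
      if (ok) {
        out[[length(out) + 1]] <- cand
        existing_dec[[length(existing_dec) + 1]] <-
          decimate_for_clearance(cand, from = exit_arc)
        got <- TRUE
        break
      }
    }
    if (!got)
      message(sprintf("could not place side branch %s%d without overlap; dropping it",
                      prefix, i))
  }
  out
}

build_anatomical_tree <- function(p) {
  offset <- p$landmark_offset
  r_mpa_end <- p$D_MPA / 2
  r_mpa_start <- r_mpa_end * (1 + p$mpa_taper_frac)
  mpa <- new_branch("MPA", curve_points(c(0, 0, 0), c(0, 0, 1), p$L_MPA),
                    r_mpa_start, r_mpa_end)
  pb <- mpa$points[nrow(mpa$points), ]

  daughters_at <- function(thL, thR) {
    dirL <- c(sin(thL), 0, cos(thL))
    dirR <- c(-sin(thR), 0, cos(thR))
    list(
      lpa = build_daughter("LPA", pb, dirL, p, p$L_LPA, p$D_LPA, p$T_LPA,
                           p$CI_LPA, offset, p$d_min),
      rpa = build_daughter("RPA", pb, dirR, p, p$L_RPA, p$D_RPA, p$T_RPA,
                           p$CI_RPA, offset, p$d_min))
  }
  measured_alpha <- function(d) {
    p2 <- interp_along(d$lpa$points, offset)$position
    p3 <- interp_along(d$rpa$points, offset)$position
    angle_between_deg(p2 - pb, p3 - pb)
  }
  a <- p$alpha * pi / 180
  thL <- a * 0.55
  thR <- a * 0.45
  d <- daughters_at(thL, thR)
  corr <- (p$alpha - measured_alpha(d)) * pi / 180
  d <- daughters_at(thL + corr / 2, thR + corr / 2)   # one Newton-style fix

  # side-branch randomness drawn here so the daughter construction stays
  # deterministic given the subject parameters
  base <- list(mpa, d$lpa, d$rpa)
  sideL <- draw_side_branches(d$lpa, p$n_side_lpa, "SIDE_L",
                              p$side_radius_factor, base)
  sideR <- draw_side_branches(d$rpa, p$n_side_rpa, "SIDE_R",
                              p$side_radius_factor, c(base, sideL))
  branches <- c(base, sideL, sideR)
  names(branches) <- vapply(branches, `[[`, character(1), "name")
  branches
}

# --- ground-truth evaluation on the continuous curves -----------------------

lw_diameter_branch <- function(branch) {
  seg <- sqrt(rowSums((branch$points[-1, , drop = FALSE] -
                       branch$points[-nrow(branch$points), , drop = FALSE])^2))
  dmean <- (branch$radii[-1] + branch$radii[-length(branch$radii)])  # = 2 * mean radius
  sum(seg * dmean) / sum(seg)
}

compute_truth <- function(branches, offset = 10) {
  truth <- list()
  mpa <- branches$MPA
  truth$L_MPA <- mpa$length
  truth$D_MPA <- lw_diameter_branch(mpa)
  truth$D_MPA_Pb <- 2 * mpa$radii[length(mpa$radii)]
  if (mpa$length > offset) {
    truth$D_MPA_P1 <- 2 * interp_along(mpa$points, mpa$length - offset,
                                       mpa$radii)$value
  }
  if (!is.null(branches$LPA) && !is.null(branches$RPA)) {
    pb <- mpa$points[nrow(mpa$points), ]
    for (side in c("LPA", "RPA")) {
      b <- branches[[side]]
      truth[[paste0("L_", side)]] <- b$length
      truth[[paste0("D_", side)]] <- lw_diameter_branch(b)
      st <- interp_along(b$points, offset, b$radii)
      en <- list(position = b$points[nrow(b$points), ],
                 value = b$radii[length(b$radii)])
      Lseg <- b$length - offset
      truth[[paste0("T_", side)]] <- (2 * st$value - 2 * en$value) / Lseg
      truth[[paste0("CI_", side)]] <- vnorm(en$position - st$position) / Lseg
      truth[[paste0("D_", side, if (side == "LPA") "_P2" else "_P3")]] <- 2 * st$value
      truth[[paste0("D_", side, "_end")]] <- 2 * en$value
    }
    p2 <- interp_along(branches$LPA$points, offset)$position
    p3 <- interp_along(branches$RPA$points, offset)$position
    truth$alpha <- angle_between_deg(p2 - pb, p3 - pb)
    eni <- function(dm) (1 - (truth$D_LPA_P2^2 + truth$D_RPA_P3^2) / dm^2)^2
    truth$EnI_Pb <- eni(truth$D_MPA_Pb)
    if (!is.null(truth$D_MPA_P1)) truth$EnI <- eni(truth$D_MPA_P1)
    truth$n_side_lpa <- sum(vapply(branches, function(b)
      identical(b$parent, "LPA"), logical(1)))
    truth$n_side_rpa <- sum(vapply(branches, function(b)
      identical(b$parent, "RPA"), logical(1)))
  } else {
    # single-tube tree: report the path-level analogues (and plain aliases)
    b <- mpa
    truth$taper <- (2 * b$radii[1] - 2 * b$radii[length(b$radii)]) / b$length
    truth$CI <- vnorm(b$points[nrow(b$points), ] - b$points[1, ]) / b$length
    truth$length <- b$length
    truth$diameter <- lw_diameter_branch(b)
  }
  truth
}

# --- public generator -------------------------------------------------------

#' Generate a synthetic pulmonary-artery-like tree with known ground truth
#'
#' Draws subject-level geometric parameters from a species template (cohort
#' means and spreads of trunk/daughter lengths, diameters, tapers, curvature
#' indices, bifurcation angle and side-branch counts), builds a parametric
#' centreline tree realising them, and evaluates the target parameter values
#' analytically on the continuous curves. The same seed always reproduces the
#' same tree.
#'
#' @param template `"porcine"`, `"ovine"`, `"human"`, or `"custom"`.
#' @param seed integer seed; fully determines the subject.
#' @param params for named species templates, a list of overrides for the
#'   drawn subject parameters. For `"custom"`, a list describing the tree:
#'   either `kind = "tube"` (fields `length`, `radius` or
#'   `radius_start`/`radius_end`, optional `arc_deg` or `ring_radius`),
#'   `kind = "y"` (fields `trunk_length`, `trunk_radius`, `daughter_length`,
#'   `daughter_radius`, `angle`, optional `daughter_radius_end`,
#'   `n_side_lpa`, `n_side_rpa`, `side_angle`), or `kind = "spec"` with a
#'   `root` [branch_spec()].
#' @return A `pa_tree` with elements `branches`, `truth`, `seed`, `template`,
#'   and the realised subject `params`.
#' @export
make_tree <- function(template = c("porcine", "ovine", "human", "custom"),
                      seed = 1L, params = list()) {
  template <- match.arg(template)
  with_seed(seed, {
    if (template == "custom") {
      tree <- make_custom_tree(params)
    } else {
      tpl <- species_templates()[[template]]
      # template_params replaces cohort-level (mean, sd) entries; all other
      # params entries override the drawn subject-level scalars
      if (!is.null(params$template_params)) {
        tpl <- utils::modifyList(tpl, params$template_params)
        params$template_params <- NULL
      }
      p <- draw_subject_params(tpl, params)
      branches <- build_anatomical_tree(p)
      tree <- list(branches = branches,
                   truth = compute_truth(branches, p$landmark_offset),
                   params = p)
    }
    tree$template <- template
    tree$seed <- as.integer(seed)
    class(tree) <- "pa_tree"
    tree
  })
}

make_custom_tree <- function(params) {
  kind <- params$kind %||% "tube"
  if (kind == "tube") {
    arc_deg <- params$arc_deg %||% 0
    L <- params$length
    if (!is.null(params$ring_radius) && arc_deg > 0)
      L <- params$ring_radius * arc_deg * pi / 180
    if (is.null(L)) stop("custom tube needs a length (or ring_radius + arc_deg)")
    if (is.null(params$radius_start %||% params$radius))
      stop("custom tube needs a radius")
    r0 <- params$radius_start %||% params$radius
    r1 <- params$radius_end %||% params$radius %||% r0
    br <- new_branch("MPA",
                     curve_points(c(0, 0, 0), params$axis %||% c(0, 0, 1), L,
                                  bend_normal = params$bend_normal %||% c(1, 0, 0),
                                  turn_rad = arc_deg * pi / 180),
                     r0, r1)
    branches <- list(MPA = br)
  } else if (kind == "y") {
    tl <- params$trunk_length %||% 60
    tr <- params$trunk_radius %||% 10
    dl <- params$daughter_length %||% 60
    dr <- params$daughter_radius %||% (tr / sqrt(2))
    dre <- params$daughter_radius_end %||% dr
    ang <- (params$angle %||% 90) * pi / 180
    mpa <- new_branch("MPA", curve_points(c(0, 0, 0), c(0, 0, 1), tl), tr, tr)
    pb <- mpa$points[nrow(mpa$points), ]
    lpa <- new_branch("LPA", curve_points(pb, c(sin(ang / 2), 0, cos(ang / 2)), dl),
                      dr, dre, parent = "MPA")
    rpa <- new_branch("RPA", curve_points(pb, c(-sin(ang / 2), 0, cos(ang / 2)), dl),
                      dr, dre, parent = "MPA")
    branches <- list(MPA = mpa, LPA = lpa, RPA = rpa)
    nL <- params$n_side_lpa %||% 0
    nR <- params$n_side_rpa %||% 0
    sang <- params$side_angle %||% 60
    if (nL > 0) {
      s <- add_side_branches(lpa, nL, "SIDE_L", params$side_radius_factor %||% 0.5,
                             rep(0, nL), rep(sang, nL),
                             seq(0, by = 2.4, length.out = nL))
      branches <- c(branches, stats::setNames(s, vapply(s, `[[`, character(1), "name")))
    }
    if (nR > 0) {
      s <- add_side_branches(rpa, nR, "SIDE_R", params$side_radius_factor %||% 0.5,
                             rep(0, nR), rep(sang, nR),
                             seq(1.2, by = 2.4, length.out = nR))
      branches <- c(branches, stats::setNames(s, vapply(s, `[[`, character(1), "name")))
    }
  } else if (kind == "spec") {
    if (!inherits(params$root, "branch_spec")) stop("params$root must be a branch_spec")
    bl <- spec_to_branches(params$root, "MPA")
    branches <- stats::setNames(bl, vapply(bl, `[[`, character(1), "name"))
  } else {
    stop("unknown custom tree kind: ", kind)
  }
  list(branches = branches,
       truth = compute_truth(branches, params$landmark_offset %||% 10),
       params = params)
}

#' @export
print.pa_tree <- function(x, ...) {
  cat(sprintf("<pa_tree> template=%s seed=%d, %d branches\n",
              x$template, x$seed, length(x$branches)))
  tv <- unlist(x$truth)
  cat("truth:", paste(sprintf("%s=%.4g", names(tv), tv), collapse = ", "), "\n")
  invisible(x)
}

#' Write the ground-truth parameter mapping as a JSON sidecar
#' @param tree a `pa_tree`.
#' @param path output path.
#' @export
write_ground_truth <- function(tree, path) {
  jsonlite::write_json(tree$truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
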