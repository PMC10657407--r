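# Branch labeling: MPA up to the first bifurcation, LPA/RPA continued through
# downstream bifurcations along the smallest-angle child, all remaining edges
# are side branches. Landmarks Pb (bifurcation), P1/P2/P3 (10 mm offsets) and
# the daughter end vertices support the shape parameters.

#' Label centreline edges as MPA / LPA / RPA / side branch
#'
#' Edges from the root up to the first bifurcation form the MPA. The two
#' daughters there are told apart by projecting their initial directions onto
#' the subject-left axis (the daughter pointing left is the LPA). From each
#' daughter onwards, at every bifurcation the child edge with the smallest
#' angle to the incoming edge continues the trunk (ties within 1 degree go to
#' the larger-radius child); every other edge belongs to a side branch. At a
#' first "bifurcation" with more than two children, the two children with the
#' largest mean radius over their first 5 mm become the daughters.
#'
#' @param tree a `centerline_tree` with at least one bifurcation.
#' @param left_axis unit vector pointing to the subject's left (default `+x`
#'   in an LPS-like frame).
#' @return A `labeled_tree`: the tree plus `edge_labels` (one per edge, keyed
#'   by child vertex), the three trunk paths, and the first bifurcation.
#' @export
label_edges <- function(tree, left_axis = c(1, 0, 0)) {
  stopifnot(inherits(tree, "centerline_tree"))
  left_axis <- unitize(left_axis)
  V <- tree$vertices
  # first bifurcation: walk the single-child chain from the root
  i <- tree$root
  mpa_path <- i
  repeat {
    ch <- tree$children[[i]]
    if (length(ch) == 0) stop("tree has no bifurcation: cannot identify LPA/RPA")
    if (length(ch) >= 2) break
    i <- ch
    mpa_path <- c(mpa_path, i)
  }
  fb <- i
  ch <- tree$children[[fb]]
  if (length(ch) < 2) stop("first bifurcation has fewer than two children")

  # helper: walk downstream from a vertex up to `dist` mm, collecting vertices
  walk_down <- function(start, dist) {
    out <- start
    acc <- 0
    i <- start
    while (acc < dist) {
      nxt <- tree$children[[i]]
      if (length(nxt) == 0) break
      j <- nxt[which.max(tree$radius[nxt])]
      acc <- acc + vnorm(V[j, ] - V[i, ])
      out <- c(out, j)
      i <- j
    }
    out
  }
  daughters <- ch
  if (length(ch) > 2) {
    mr <- vapply(ch, function(c2) mean(tree$radius[walk_down(c2, 5)]), numeric(1))
    daughters <- ch[order(-mr)][1:2]
  }
  init_dir <- function(c2) {
    w <- walk_down(c2, 3)
    unitize(V[w[length(w)], ] - V[fb, ])
  }
  proj <- vapply(daughters, function(c2) sum(init_dir(c2) * left_axis), numeric(1))
  lpa_first <- daughters[which.max(proj)]
  rpa_first <- daughters[which.min(proj)]
  if (lpa_first == rpa_first) stop("cannot disambiguate LPA and RPA along the left axis")

  label_by_child <- rep(NA_character_, nrow(V))      # label of edge (parent->v)
  for (v in mpa_path[-1]) label_by_child[v] <- "MPA"

  follow_trunk <- function(first, lab) {
    path <- c(fb, first)
    label_by_child[first] <<- lab
    i <- first
    prev <- fb
    repeat {
      ch2 <- tree$children[[i]]
      if (length(ch2) == 0) break
      if (length(ch2) == 1) {
        nxt <- ch2
      } else {
        prev_dir <- V[i, ] - V[prev, ]
        ang <- vapply(ch2, function(c2)
          angle_between_deg(prev_dir, V[c2, ] - V[i, ]), numeric(1))
        best <- min(ang)
        cand <- ch2[ang <= best + 1]                 # 1-degree tie window
        nxt <- cand[which.max(tree$radius[cand])]
      }
      label_by_child[nxt] <<- lab
      path <- c(path, nxt)
      prev <- i
      i <- nxt
    }
    path
  }
  lpa_path <- follow_trunk(lpa_first, "LPA")
  rpa_path <- follow_trunk(rpa_first, "RPA")
  label_by_child[is.na(label_by_child)] <- "SIDE"
  label_by_child[tree$root] <- NA_character_          # root has no incoming edge

  edge_labels <- label_by_child[tree$edges[, 2]]
  structure(list(tree = tree, edge_labels = edge_labels,
                 label_by_child = label_by_child,
                 mpa_path = mpa_path, lpa_path = lpa_path, rpa_path = rpa_path,
                 first_bif = fb, left_axis = left_axis, landmarks = NULL),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  tab <- table(x$edge_labels)
  cnt <- count_side_branches(x)
  cat(sprintf("<labeled_tree> edges: %s; side branches LPA=%d RPA=%d\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              cnt[1], cnt[2]))
  invisible(x)
}

# label per vertex: the label of its incoming edge (root counts as MPA)
vertex_labels <- function(lt) {
  vl <- lt$label_by_child
  vl[lt$tree$root] <- "MPA"
  vl
}

#' Count side branches attached to the LPA and RPA trunks
#'
#' A side branch is one connected SIDE component; it is counted once at its
#' attachment vertex even if it bifurcates further downstream. Attachments at
#' the main bifurcation vertex itself are not assigned to either daughter.
#'
#' @param lt a `labeled_tree`.
#' @return Integer vector `c(n_lpa_side, n_rpa_side)`.
#' @export
count_side_branches <- function(lt) {
  tree <- lt$tree
  vl <- vertex_labels(lt)
  par <- tree$parent
  is_side <- !is.na(lt$label_by_child) & lt$label_by_child == "SIDE"
  par_trunk <- !is.na(par) & vl[ifelse(is.na(par), 1L, par)] %in% c("MPA", "LPA", "RPA")
  side_first <- which(is_side & par_trunk)
  att <- par[side_first]
  c(n_lpa_side = sum(att %in% setdiff(lt$lpa_path, lt$first_bif)),
    n_rpa_side = sum(att %in% setdiff(lt$rpa_path, lt$first_bif)))
}

path_arc_interp <- function(V, radii, s) {
  ip <- interp_along(V, s, radii)
  list(position = ip$position, radius = ip$value, arc = ip$arc)
}

#' Locate the bifurcation landmarks
#'
#' `Pb` is the first bifurcation vertex. `P2` and `P3` sit at `offset` mm of
#' arc length downstream of `Pb` on the LPA and RPA; `P1` sits `offset` mm
#' upstream on the MPA. The offset keeps the daughter landmarks clear of the
#' bifurcation apex, where cross-sections of the three vessels overlap.
#' Positions and radii are interpolated when the offset falls inside an edge.
#'
#' @param lt a `labeled_tree`.
#' @param offset landmark offset in mm (default 10).
#' @return The `labeled_tree` with a `landmarks` element (`Pb`, `P1`, `P2`,
#'   `P3`, `End_LPA`, `End_RPA`; each with `position`, `radius`, `arc`).
#'   A daughter shorter than `offset` raises an error of class
#'   `pamorph_short_daughter`.
#' @export
locate_landmarks <- function(lt, offset = 10) {
  stopifnot(inherits(lt, "labeled_tree"))
  tree <- lt$tree
  V <- tree$vertices
  lm <- list()
  lm$Pb <- list(position = V[lt$first_bif, ], radius = tree$radius[lt$first_bif],
                vertex = lt$first_bif)
  for (side in c("LPA", "RPA")) {
    p <- if (side == "LPA") lt$lpa_path else lt$rpa_path
    pts <- V[p, , drop = FALSE]
    rad <- tree$radius[p]
    L <- polyline_arc(pts)
    if (L < offset) {
      cond <- structure(
        class = c("pamorph_short_daughter", "error", "condition"),
        list(message = sprintf(
          "%s path is only %.1f mm long (< %.0f mm landmark offset): shape parameters are non-evaluable for this subject",
          side, L, offset), call = sys.call(-1)))
      stop(cond)
    }
    lm[[if (side == "LPA") "P2" else "P3"]] <- path_arc_interp(pts, rad, offset)
    lm[[paste0("End_", side)]] <- list(position = pts[nrow(pts), ],
                                       radius = rad[length(rad)], arc = L)
  }
  mp <- V[lt$mpa_path, , drop = FALSE]
  mr <- tree$radius[lt$mpa_path]
  Lm <- polyline_arc(mp)
  lm$P1 <- if (Lm >= offset) path_arc_interp(mp, mr, Lm - offset) else NULL
  lt$landmarks <- lm
  lt$landmark_offset <- offset
  lt
}
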