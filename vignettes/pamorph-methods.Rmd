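---
title: "Centreline-based pulmonary-artery morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centreline-based pulmonary-artery morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamorph)
```

## The problem

Implantable pulmonary-artery pressure sensors are anchored in the left or
right pulmonary artery (LPA/RPA). Whether a device holds, and how it disturbs
the flow around it, depends on a small set of geometric properties of the
landing zone: vessel calibre and length, how fast the vessel narrows (taper),
how strongly it curves, how abruptly the cross-section changes at the main
bifurcation, the bifurcation angle, and how many side branches could catch a
fixation wire. `pamorph` computes this parameter set automatically from an
open-ended triangulated surface of the pulmonary artery (or from a binary
segmentation mask), and provides the cohort-level statistics used to compare
species — for instance to judge how well a porcine or ovine animal model
matches human anatomy at a candidate implantation site.

Because real CT reconstructions demand manual segmentation, the package ships
a synthetic vessel-tree generator whose geometry is known in closed form.
Every stage of the pipeline is validated by recovering those known values.

## The parameter set

Measurements live on a centreline: a rooted tree of sample points inside the
lumen, each carrying the radius of the largest sphere centred there that fits
inside the vessel (the maximal-inscribed-sphere radius, whose doubling is the
local diameter). Let `Pb` be the first bifurcation vertex, and `P1`, `P2`,
`P3` the points 10 mm upstream on the main PA (MPA) and 10 mm downstream on
the LPA and RPA. The 10 mm offset keeps the daughter landmarks clear of the
bifurcation apex, where the three lumina still overlap; it is configurable
(`landmark_offset`).

* **Branch length** `L`: accumulated edge length of the labeled path — the
  MPA from inlet to `Pb`, each daughter from `Pb` to its end vertex.
* **Length-weighted diameter** `D`: sum over path edges of edge length times
  mean edge diameter, divided by total length.
* **Taper** `T = (D_in − D_out) / L`, with `D_in` at `P2` (resp. `P3`),
  `D_out` at the branch end, and `L` the curved arc length between them.
  Negative taper (a flaring segment) is allowed and flagged in QC.
* **Curvature index** `CI = L0 / L`: straight start-to-end distance over
  curved arc length of the same segment; 1 is a straight vessel, a
  half-circle arc gives `2/π ≈ 0.637`.
* **Enlargement index** `EnI = (1 − (D_LPA² + D_RPA²) / D_MPA²)²` with the
  daughter diameters read at `P2`/`P3`: the squared relative mismatch of
  summed daughter cross-sectional area against the trunk area, zero for an
  area-preserving split.
* **Bifurcation angle** `α`: angle at `Pb` between the vectors to `P2` and
  `P3`.
* **Side-branch counts**: connected components of side-branch edges attached
  to the LPA or RPA trunk path.

### Where the MPA diameter for EnI is read

The inscribed-sphere radius *at* the bifurcation vertex is not a trunk
diameter: inside the junction the sphere is bounded by the daughters' lumina,
so on a symmetric area-preserving Y it reports roughly 0.7 of the true trunk
diameter and would push EnI toward 1 where the geometry says 0. The default
therefore reads the MPA diameter at `P1`, 10 mm upstream, mirroring the
daughter convention; `eni_mpa_at = "Pb"` switches to the bifurcation vertex
itself, and both variants are always reported in the record's QC block.

## Pipeline stages

### Reconstruction from a mask

`mask_from_threshold()` labels voxels strictly above an intensity threshold
(on contrast CT, lumen thresholds of roughly 80–400 HU depending on contrast
concentration); it yields a candidate mask only — interactive correction of a
real segmentation is out of scope. `extract_surface()` triangulates the 0.5
iso-level of the binary field with marching tetrahedra: each grid cell is
split into six tetrahedra sharing the main diagonal, which makes the
triangulation consistent across cell faces (watertight) and free of the
ambiguous cases of cube-based contouring; on a binary field the crossing
vertices sit at grid-edge midpoints. Only the largest 26-connected component
is surfaced; smaller blobs are reported and dropped.

`smooth_volume_preserving()` removes the voxel staircase with a Taubin
lambda/mu iteration in which the Laplacian displacement is projected onto the
vertex normal (staircase is normal-direction oscillation; suppressing the
tangential component keeps vertices from sliding across an already-smooth
surface), followed each iteration by a volume-compensation step that
displaces free vertices along their normals until the enclosed volume matches
the input. Open boundary-loop vertices are frozen so truncation planes keep
their shape. The defining contract — volume drift below 0.1% — is asserted in
the tests rather than assumed.

### Centreline extraction

The extractor rasterises the lumen (fan-capping the open ends for the
inside/outside test), computes the Euclidean distance transform, and runs
Dijkstra from the inlet over foreground voxels with a medialness edge cost —
step length weighted by the inverse squared wall distance — which pulls
least-cost paths onto the medial axis. One path is traced per outlet boundary
loop, so the tree has exactly one leaf per outlet; shared prefixes merge into
a rooted tree. Each branch chain is then smoothed and every sample recentred
in its normal plane by maximising the distance to the wall (nearest-wall
direction plus a golden-section line search). Radii are exact point-to-mesh
distances at the final samples. The root and leaves are snapped to the
boundary-loop centroids.

Least-cost paths through a junction diverge upstream of the anatomical
bifurcation and stay biased toward the common-lumen centre for about one
local radius beyond it. A dedicated refinement therefore walks the two
dominant child chains of every bifurcation, finds where they genuinely
separate, fits each axis on a clean window past the biased zone (quadratic in
arc length when the window allows, so curved daughters extrapolate along
their own curvature), places the bifurcation vertex at the closest approach
of the two fitted axes, and rebuilds the near-junction geometry along them.
Surgeries are applied one at a time with the structure rebuilt in between, so
refinements of neighbouring junctions cannot act on stale topology.

`resample_centerline()` gives every root-to-leaf path exactly `n_per_path`
vertices (default 100): bifurcation vertices keep their exact positions and
receive the index nearest their relative arc position, and vertices between
landmarks are equally spaced in arc length with linearly interpolated radii —
so topologically matching subjects get matching bifurcation indices.

### Labeling

Edges from the root to the first bifurcation are the MPA. The two daughters
there are told apart by projecting their initial directions onto the
subject-left axis (`left_axis`, default `+x` in an LPS-like frame, matching
how left and right are defined by patient orientation in the scanner). From
each daughter onward, at every bifurcation the child edge with the smallest
angle to the incoming edge continues the trunk; ties within 1° go to the
larger-radius child; everything else is a side branch. Should the first
junction have more than two children, the two with the largest mean radius
over their first 5 mm become the daughters — radius being the least
arbitrary tiebreak for a malformed junction.

### Surface agreement (operator bias)

`vertex_to_surface_distance()` reports, for every vertex of one
reconstruction, the unsigned distance to the nearest point on any triangle of
the second (point-to-triangle via a uniform spatial grid over triangles,
validated against an exhaustive oracle). Reconstructions of the same scan
share a frame, so no registration is applied. Because segmentations disagree
most about how far side branches were followed, the summary statistics are
restricted to the trunk: a vertex belongs to the region iff its nearest
centreline vertex carries a trunk label and lies within 1.5× that vertex's
radius — the multiplier is this package's operational proxy for a "confined
trunk region" and is configurable. The measure is asymmetric
(`d(A→B) ≠ d(B→A)`); the directed A→B summary is reported, with an optional
symmetric mean.

### Cohort statistics

`describe()` reports mean ± SD when Shapiro–Wilk does not reject normality at
0.05, otherwise median [IQR] with quartiles by the linear-interpolation rule
(`quantile(type = 7)`; environments differ here, so the rule is fixed and
stated). `compare_groups()` selects the two-tailed Student's t-test (pooled
variance; paired where applicable, gated on the normality of the paired
differences) or the Mann–Whitney U / Wilcoxon signed-rank test. α = 0.05
throughout; a Bonferroni flag (off by default) scales α for families of
comparisons. Bland–Altman limits are mean ± 1.96 sample SD of the paired
differences, and ICC(1,1) is the one-way random-effects single-measurement
coefficient `(MSB − MSW) / (MSB + (k−1)·MSW)`.

The cross-species similarity table codes each parameter "+" when the
animal-vs-human comparison is *not* significant (agreement) and "−"
otherwise. Relational rows ("LPA diameter < RPA diameter") are coded "+" when
the animal reproduces the human within-species ordering: significant in
humans ⇒ significant in the animal with the same direction; not significant
in humans ⇒ not significant in the animal. The similarity score counts the
"+" entries.

## The synthetic generator

`make_tree()` draws one subject from a species template: trunk and daughter
lengths, length-weighted diameters, tapers, curvature indices, bifurcation
angle and side-branch counts, each drawn from cohort-level normal
distributions (truncated at ±3 SD; median[IQR] table rows are mapped to
mean ≈ median, SD ≈ IQR/1.35). The two daughter diameters share a
subject-level component (correlation 0.95): both daughters of one subject
scale together, which is what gives within-species diameter-ordering tests
their pairing power in real cohorts. Branch centrelines are straight lines and
circular arcs — the arc's turn angle is solved so the landmark-to-end segment
has exactly the drawn curvature index — and radii are linear in arc length,
which makes the drawn taper exact on the measurement segment. Side branches
take off at 45–75° with uniform azimuth, start at half the local parent
radius, and run ~10 mm beyond the parent wall; they are placed by rejection
sampling so every tube keeps ≥ 1.6 mm clearance from all non-parent branches
(overlapping tubes would merge lumina and silently change the topology that
the recovery tests assert). Daughter end diameters are floored just above the
8 mm reconstruction limit; when a drawn taper×length combination would dip
below it, the subject's stored truth is recomputed from the realised curve,
so the `truth` mapping always satisfies the parameter definitions on the
generated geometry exactly.

`surface_from_tree()` does not sweep and stitch tubes; it samples the
implicit union field (distance to the nearest branch axis minus local radius)
on a grid, triangulates its zero level with marching tetrahedra, and then
Newton-projects every vertex onto the exact implicit surface, so vertex
positions match the analytic tubes to ~10⁻⁴ mm. Terminal ends are extended
past their nominal planes and clipped back exactly, leaving one clean
boundary loop per open end — the inlet, both daughter ends (cut where the
diameter would fall below 8 mm), and each side-branch truncation plane.
Specifications whose open end caps would sit inside another branch's lumen
are rejected as self-intersecting. `voxelize()` rasterises any such surface
back into a mask by ray-crossing parity, which closes the loop needed to
exercise the reconstruction stages.

What the generator deliberately does *not* emulate: CT intensities and noise
(only binary masks), non-circular cross-sections, wall motion over the
cardiac cycle, anatomical naming of side branches, and any hemodynamics.
Passing recovery tests therefore demonstrate the geometry processing, not
robustness to segmentation artefacts of real scans; the optional
`perturb_mesh()` vertex-normal noise (default off) probes robustness to
surface-level reconstruction variability only.

## Numerical choices and degenerate inputs

* Surfacing grid: the spacing is the finer of the axial step and the
  circumference of the thinnest tube divided by `circumferential_samples`,
  floored at 0.3 mm.
* Centreline rasterisation: spacing `min(1, max(0.4, r_min/3))` for the
  smallest boundary-loop radius; recentring recovers sub-voxel accuracy, so
  the default favours speed.
* Junction refinement: separation tolerance `max(0.5, 0.6·spacing)`; axis
  windows start 0.9 local radii past the separation point; quadratic fits
  need ≥ 5 mm of window, otherwise the fit degrades gracefully to linear.
* Zero-variance samples: descriptives skip the W-test with a warning;
  paired comparisons of identical samples return the exact null (p = 1) and
  a constant nonzero offset returns certainty (p = 0); ICC of fully constant
  data is NA with a warning.
* Degenerate pinholes left by vertex projection (boundary loops of
  near-zero circumference) are welded shut before the loop census.
* Meshes that are closed, have a single boundary loop, or are non-manifold
  beyond their open boundaries are rejected with explicit errors; daughters
  shorter than the landmark offset mark the subject's shape parameters
  non-evaluable (with the reason in QC) instead of failing the batch.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on generated
geometry: single-tube and Y fixtures at 1 mm surfacing resolution, one
full-resolution species-template subject, four two-operator pairs, and
truth-level cohorts of 41/14/49 subjects for the species comparison — sizes
chosen so the whole suite exercises every stage end to end while staying
comfortably desk-scale.

## Worked example

```{r example, eval = FALSE}
tree <- make_tree("human", seed = 1)
mesh <- surface_from_tree(tree)
cl   <- resample_centerline(extract_centerline(mesh), n_per_path = 100)
lt   <- label_edges(cl, left_axis = c(1, 0, 0))
rec  <- measure_subject(lt)
print(rec)
unlist(tree$truth[c("L_MPA", "D_MPA", "alpha")])
```

## Known limitations

* The centreline contract is validated on tubular synthetic anatomy;
  pathologies that break tubularity (aneurysmal sacs, fused vessels) have no
  ground truth here and may defeat the junction refinement.
* Branch lengths follow the bifurcation-vertex convention (`Pb` to end);
  studies measuring from the bifurcation apex will differ by roughly one
  trunk radius on the daughters.
* The similarity table reproduces a coding convention, not a validated
  clinical score; its relational rows depend on within-species paired power.
* Thresholding is a helper for synthetic masks; real lumen segmentation
  needs manual editing that this package does not provide.
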