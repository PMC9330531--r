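---
title: "Methods: models, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, phantoms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the tunable parameters and their defaults,
what the synthetic phantoms do and do not emulate, and the numerical
choices made where the underlying literature leaves the method open.

## Coordinate and unit conventions

All volumes are 3D arrays in fixed `(z, y, x)` axis order with strictly
positive per-axis spacing in micrometres; the centre of voxel `(i, j, k)`
sits at `origin + (c(i, j, k) - 1) * spacing`. Everything downstream of the
readers — graph coordinates, distances, volumes, surface areas — is in
physical micrometres and respects anisotropic spacing; voxel indices never
appear in reports. The default spacing, `2 x 1.19 x 1.19` um, mirrors
high-resolution confocal acquisition of sinusoid-scale structure.

## Sinusoid network extraction

**Skeletonization.** Curve thinning deletes border voxels that are simple
points — their removal changes neither the number of foreground components
nor of tunnels, characterized locally by (a) one 26-component of
foreground neighbours and (b) one 6-component of background in the
18-neighbourhood touching the centre — in six directional subiterations
with re-checking at deletion time, protecting curve endpoints. Foreground
connectivity is 26 throughout. Because simple-point topology is defined on
an isotropic lattice, anisotropic volumes are first resampled (nearest
neighbour) to the finest pitch; skeleton coordinates map back to physical
units. Endpoint protection leaves spurs of roughly one tube radius at tube
ends and occasionally on closed loops; these are removed by spur pruning
(below), not by the thinning itself.

**Graph construction.** Skeleton voxels with three or more neighbours are
clustered (adjacent junction voxels merge into one node at their
centroid; ties in traversal are broken by linear voxel index, so graphs
are deterministic); single-neighbour voxels become end nodes; the chains
between nodes become edges carrying their centerline polyline. A component
with no junction or end voxel — a pure cycle — gets one anchor node with a
self-loop, satisfying Euler's identity `c = E - V + C`. Traced polylines
are smoothed by a few endpoint-preserving 1-2-1 passes: the half-voxel
staircase otherwise inflates arc lengths by several percent (a semicircle
measured without smoothing reads ~4% above `pi/2`; with it, within 2%).

**Junction consolidation.** Thinning a thick junction can split one branch
point into two or three junction nodes a few voxels apart, rarely with a
voxel-scale loop inside the cluster. `consolidate_graph()` contracts
junction-junction edges shorter than `merge_um` and collapses basis loops
with perimeter below `max_loop_perimeter_um`. Both default to off; the
validated recipe for tube networks scales them with the tube radius `r`
(`3 r` and `10 r`), which is far below the edge-length scale, so genuine
loops are untouched. With this recipe the rasterize-skeletonize-rebuild
round trip recovers `V`, `E`, the degree sequence and the cyclomatic
number of generated networks exactly (verified on twenty seeded phantoms).

**Spur pruning.** Terminal edges shorter than the threshold are removed
iteratively and the degree-2 nodes left behind are dissolved; loops are
never removed, so the cyclomatic number is invariant. Since
endpoint-protection spurs scale with tube radius, not voxel pitch, the
effective threshold for full spur removal is radius-scaled (`3 r` in the
round-trip recipe); the pipeline default of `1.5 x` the largest voxel
pitch only removes sub-voxel hairs and is deliberately conservative.

**Edge measurement.** Length is polyline arc length; tortuosity is
length over endpoint chord (undefined and reported missing for
self-loops); the radius is the mean over the centerline of the distance
transform of the vessel wall, minus half the finest pitch to correct the
centre-to-centre offset of the first background voxel. At fine isotropic
sampling this estimator is within 0.5 um of truth for a 3-um tube; at the
coarse anisotropic default spacing it underestimates sinusoid-scale radii
by a few tenths of a micrometre, which is reported as-is rather than
rescaled.

## Network statistics

The edge/node ratio counts multi-edges and self-loops. Loops are
formalized as the elements of a minimum cycle basis of the simple graph
(Horton's algorithm: candidate cycles through shortest-path trees, sorted
by weight, selected greedily by GF(2) elimination), with self-loops
counted as 1-edge and each extra parallel edge as a 2-edge loop; the
census total always equals the cyclomatic number. The minimum basis is the
canonical smallest-loop decomposition behind "4-7-edge loop" framing of
capillary networks; on every graph with at most 12 edges the
implementation matches a brute-force greedy over the full cycle space
(exact by the matroid property). Clustering and centralization are
computed on the simple graph (multi-edges collapsed, self-loops dropped),
nodes of degree below two contributing zero; centralization is Freeman's
`sum(deg_max - deg_i) / ((V-1)(V-2))`. Degree-law fits use the lognormal
maximum-likelihood estimates on raw degree values above zero — degrees are
discrete, so the KS statistic against the continuous fitted law is
approximate and flagged as such. Branch-angle directions are taken at a
configurable tangent arc distance (default 5 um) along each incident
centerline; since it is not obvious whether angle summaries should pool
over angles or over junctions, both poolings are reported
(`mean_angle_deg`, `node_mean_angle_deg`) along with the mean per-node
minimum angle.

## Lobule morphology

Lobule outlining from landmarks is an automated proxy for expert manual
segmentation: each parenchyma voxel joins the nearest central-vein
component (classical mode) or portal component (portal mode), with
anisotropy-respecting Euclidean distance and ties to the lower label. This
generalized-Voronoi rule is validated on phantoms (at least 95% voxel
agreement, exact on the default geometry); fidelity on real tissue, where
lobule boundaries follow sinusoid orientation rather than pure distance,
is not claimed. Ellipsoid semi-axes come from second moments
(`sqrt(5 * eigenvalues)` of the voxel-coordinate covariance — exact for
solid uniform ellipsoids, hence the 3% recovery tolerance covers only
discretization); regions with under 10 voxels or coplanar support are
rejected. The oblate / prolate call uses the axis-difference rule on
sorted semi-axes `a >= b >= c`: oblate if `a - b < b - c`, prolate if
greater, indeterminate within `tol * a` (default `tol = 0.01`). Published
"ellipticity" conventions vary between software packages; this rule is the
symmetric one and the tolerance is exposed. Sphericity uses the standard
`psi = pi^(1/3) (6V)^(2/3) / A`.

**Surface area.** Voxel-face counting overestimates curved surfaces by up
to 50%, so areas come from a crack-free marching-tetrahedra mesh (Kuhn
6-tet decomposition, outward-oriented triangles; enclosed volume by the
divergence theorem). The binary field is first smoothed by a separable
Gaussian of `0.7 x` the finest pitch: this sigma was calibrated against
the two analytic extremes — a sphere (mesh sphericity 0.978 at radius 10
voxels, versus 0.78 unsmoothed) and a cube (area within ~2% of `6 s^2` at
side 48; edge rounding scales as `1/s`). Heavier smoothing rounds cube
edges too far, lighter smoothing leaves staircase on spheres. For cells a
few voxels across, residual staircase biases sphericity low (a 3-um ball
at the default anisotropic spacing reads ~0.93); morphology comparisons
should therefore be made at fixed spacing.

## Cell spatial statistics

The distribution index is `rho = D2 / (D1 + D2)`, the unique simple ratio
that is 1 on the central vein (`D1 = 0`), 0 on the lobule boundary
(`D2 = 0`) and bounded by `[0, 1]`. `D1` is measured centroid-to-CV
surface and `D2` centroid-to-nearest-voxel-outside-the-label, both
interpolated from exact anisotropic distance transforms; a cell with both
distances zero has no defined position and errors. Cells whose centroid
lies outside every lobule are flagged and excluded from rho statistics;
cells spanning two labels follow their centroid. Cells at exactly
`rho = 0` count toward the boundary fraction (strictly-below threshold,
default 0.15) but are excluded from the lognormal fit, whose log is
undefined there; their count is reported. Because rho is bounded by 1, the
fitted `(mu, sigma)` are moments of the `(0, 1]`-truncated law, not of an
unbounded lognormal. Both the count of cells at exactly `rho = 1` and the
mass of the top histogram bin are reported, as the two defensible readings
of "cells surrounding the central vein". Histogram bin widths default to
0.04 (0.05 for coarser panels) and are configurable. The presinusoidal
"Area I" sub-compartment is not implemented: no operational definition of
the region is available, so any implementation would be a guess.

## Metastases and macrophage shells

Foci are 26-connected components; the 0.2-mm micrometastasis rule is
applied to the equivalent spherical diameter (the maximum Feret diameter
is available as an alternative reading, estimated from boundary voxels).
"Periportal" means the focus surface lies within 20 um of the portal
mask, "surrounded" means the macrophage-filled fraction of the 30-um
shell reaches 0.05; all three numbers are explicit configuration defaults
rather than published constants, and sensitivity sweeps only require
changing the config. The recruitment coefficient
`sigma = GFP volume / tumor volume` is dimensionless and invariant under
joint rescaling.

## The phantom generator

The phantom provides exact ground truth for every stage, at desk scale:

- **Lobules** are non-overlapping solid ellipsoids, oblate by default
  (`a = b = 2c`, volume-equivalent radius 80 um at the default grid of
  `96 x 192 x 192` voxels), each seeded by a central-vein cylinder along
  the short axis and six portal spheres on the equatorial boundary. Real
  lobule volumes (~0.17 mm^3) would need hundred-megavoxel grids; the
  phantom keeps the tissue-scale microstructure (sinusoid pitch, radii,
  voxel spacing) inside a smaller lobule, and all statistics that depend
  on absolute lobule size are reported per volume.
- **The sinusoid network** places nodes on a jittered cubic lattice at the
  24.91-um edge pitch, takes the Euclidean minimum spanning tree of the
  near-neighbour candidate graph (connected, zero loops) and adds exactly
  `loop_excess` shortest chords, preferring low-degree endpoints, so the
  cyclomatic number is hit exactly and interior degrees concentrate on
  3-4. The default `loop_excess = round(0.37 V)` puts the edge/node ratio
  at the loop-rich scale of healthy lobules (~1.37). Edge centerlines are
  quadratic arcs whose sagitta fraction (default 0.22) sets tortuosity
  near 1.13; tube radius defaults to 2.92 um.
- **Cells** realize a prescribed `(0, 1]`-truncated lognormal law for rho
  *by construction*: for each cell a target rho is drawn by inverse-CDF,
  a ray is cast from a random CV voxel of its lobule in a random
  direction, and the position solving `D2/(D1+D2) = rho` on the actual
  distance maps is found by bisection (rays whose achievable floor is
  above the target — e.g. exiting through the lobule cap next to the CV —
  are redrawn). Stored `D1`, `D2`, rho are therefore reproducible from
  the masks to within a voxel diagonal. The default law
  `(mu, sigma) = (-1.7, 0.8)` was chosen once so the truncated law puts
  40% of cells below `rho = 0.15`, the boundary-skewed regime of healthy
  liver; 322 cells per lobule is a realistic count for a healthy mouse
  lobule.
- **Metastases** are spheres with known diameters (default 30-90 um,
  micrometastasis scale), alternately placed touching a portal sphere and
  deep inside a lobule (kept 25 um clear of portal landmarks so the true
  location class is unambiguous, and mutually non-overlapping), with
  Bernoulli-filled shells of stated thickness and fill fraction; true
  volumes, flags and shell contents are recorded from the final masks.

Determinism: a spec plus seed fully determines every output byte; the
graph, lobule, cell and metastasis components draw from separate seed
streams, so adding one element never perturbs the others.

What the phantom does **not** emulate: optics (PSF blur, depth-dependent
attenuation, spectral bleed-through), segmentation noise, irregular
lobule packing, hemodynamics, or biologically realistic junction
geometry. Passing phantom tests therefore demonstrates the correctness of
the measurement pipeline on known geometry — not the fidelity of any
segmentation of real stacks, which enters this pipeline as an input mask.

## Problem sizes and runtime

The shipped tests and the acceptance script run on one CPU in a few
minutes total: phantoms of `96 x 192 x 192` voxels (one 80-um lobule,
~100-250 network nodes), twenty round-trip phantoms, 200 random graphs
for the cycle-space oracle, and 10,000-cell scatters for parameter
recovery. Larger grids scale linearly in voxels for the volume kernels;
the minimum cycle basis is the only super-linear stage
(O(V E) candidate cycles) and handles lobule-scale graphs (hundreds of
edges) in well under a second.

## Known limitations

- Radii at coarse anisotropic spacing are biased low by a few tenths of a
  micrometre (half-voxel surface localization).
- The KS statistic for discrete degree data is approximate.
- Nearest-landmark lobule segmentation is a stated proxy for expert
  outlining; agreement is proven on phantoms only.
- Whether measured sinusoid "length" should be per graph edge or per
  branch-free segment is convention; here it is per edge
  (branch-point-to-branch-point after chain dissolution), and generated
  chains keep their intermediate degree-2 nodes until `dissolve_chains()`
  is applied.
- Surfaces of objects only a few voxels across are under-resolved; their
  sphericity is comparable within, not across, voxel spacings.
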