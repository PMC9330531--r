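# hepatograph

Quantitative analysis of mesoscale liver architecture from cleared-tissue
3D microscopy: the sinusoid capillary network as a measured spatial graph,
hepatic lobules as classified ellipsoids, immune-cell positions as
distribution-index statistics, and micrometastases with their macrophage
shells. A deterministic phantom generator produces synthetic volumes with
exact ground truth, so the whole pipeline is testable without microscopy
data.

It is written for groups doing whole-mount imaging of cleared liver lobes
(CUBIC-style clearing, confocal or light-sheet acquisition) who want the
downstream quantification — skeletonization, loop census, lobule
morphology, cell spatial statistics — as scripted, reproducible R instead
of interactive commercial software.

## What it computes

**Sinusoid network.** A binary vessel volume is thinned to a one-voxel
centerline by topology-preserving simple-point deletion, converted to a
spatial graph (junction clusters become nodes, chains become edges with
polyline centerlines), spur-pruned, and measured: per-edge length,
tortuosity `arc/chord >= 1`, and radius from the Euclidean distance
transform of the vessel wall. Network statistics follow the field's
conventions:

- edge/node ratio `E/V` (1 + (c − C)/V by Euler's formula; close to 1 for
  tree-like, well above 1 for loop-rich networks),
- loop census by a minimum cycle basis — the canonical decomposition of
  the cycle space into `c = E − V + C` smallest loops, keyed by edge
  count,
- degree histogram, high-degree fraction (degree > 3), lognormal fit
  (`mu = mean(log x)`, `sigma = sd(log x)`, KS statistic),
- mean local clustering coefficient and Freeman degree centralization,
- branch angles from centerline tangents at a configurable arc distance.

**Lobules.** Segmented from central-vein / portal landmarks by
nearest-landmark (generalized Voronoi) assignment; each lobule gets a
second-moment ellipsoid fit (`semi-axes = sqrt(5 * eigenvalues)` of the
voxel covariance), an oblate / prolate class by the axis-difference rule,
sphericity `psi = pi^(1/3) (6V)^(2/3) / A` with the surface area from a
marching-tetrahedra mesh, and a sinusoid volume fraction.

**Cells.** Each cell's distribution index is `rho = D2 / (D1 + D2)`, with
`D1` the distance to the lobular central vein and `D2` the distance to the
lobule boundary: `rho = 1` on the central vein, `rho = 0` on the boundary.
The package reports the rho histogram, the boundary fraction
(`rho < 0.15` by default), a truncated-lognormal fit, per-lobule counts
and densities, CV-distance profiles, and cell sphericity morphology.

**Metastases.** Tumor foci are 26-connected components with equivalent
spherical diameter `(6V/pi)^(1/3)`; foci under 0.2 mm are flagged as
micrometastases, classified periportal vs intralobular by surface distance
to the portal tree, and their macrophage shell (default 30 um) is
quantified, including the recruitment coefficient
`sigma = GFP volume / tumor volume`.

## Worked example

```r
library(hepatograph)

spec  <- phantom_spec(seed = 42, edge_bow = 0.12)   # one oblate lobule
ph    <- generate_phantom(spec)

# ground-truth sinusoid network
print(ph$graph)
#> <vessel_graph> V=95 E=129 components=1 cyclomatic=35
#>   edge length 24.16 +/- 1.57 um; tortuosity 1.037 (mean)
edge_node_ratio(ph$graph)
#> 1.358

# recover the graph from the rasterized vessel channel
g <- skeletonize(ph$sinusoid_mask) |> build_graph() |>
  consolidate_graph(merge_um = 3 * spec$sinusoid_radius_um,
                    max_loop_perimeter_um = 10 * spec$sinusoid_radius_um) |>
  prune_spurs(3 * spec$sinusoid_radius_um) |>
  measure_edges(ph$sinusoid_mask)
print(g)
#> <vessel_graph> V=63 E=97 components=1 cyclomatic=35
#>   edge length 31.31 +/- 14.73 um; tortuosity 1.216 (mean)

topology_report(g, reference_volume_mm3 = 0.00217)
#> <topology_report> V=63 E=97 E/V=1.540 loops=35
#>   clustering 0.1032, centralization 0.01692, high-degree fraction 0.365
#>   loop census: 2-edge: 3, 3-edge: 8, 4-edge: 8, 5-edge: 7, 6-edge: 3, ...

measure_lobules(ph$lobule_labels, sinusoid_mask = ph$sinusoid_mask)
#> label volume_mm3  a_um  b_um  c_um shape_class sphericity sinusoid_fraction
#>     1    0.00217   101   101    51      oblate      0.851            0.0411

ct <- assign_cell_geometry(ph$cell_table[, c("cell_id","z_um","y_um","x_um")],
                           ph$cv_mask, ph$lobule_labels)
rho_statistics(ct)[c("n", "boundary_fraction")]
#> $n: 322      $boundary_fraction: 0.398
```

Reading the output: the generated network keeps 35 independent loops and
an edge/node ratio of 1.358 (decentralized, loop-rich — far from a binary
tree's ratio just under 1); the voxel pipeline recovers exactly the same
topology after chains are dissolved to branch-point-to-branch-point edges
(V = 63, E = 97, cyclomatic 35). The lobule is recovered as an oblate
ellipsoid (semi-axes 101 x 101 x 51 um), and 39.8% of the 322 cells sit
near the lobule boundary (rho < 0.15), matching the boundary-skewed
truncated-lognormal law the phantom scatters from.

A thin CLI over the same functions is in
`inst/scripts/hepatograph.R`
(`Rscript hepatograph.R run --config cfg.yaml --out DIR --seed 1`).

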