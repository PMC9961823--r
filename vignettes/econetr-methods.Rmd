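---
title: "Methods: ecological network construction and optimization in econetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecological network construction and optimization in econetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

econetr builds an ecological network from a categorical land-cover raster in
six stages: morphological segmentation of habitat (MSPA), graph-theoretic
source selection (IIC/PC/dPC), a weighted multi-factor resistance surface,
least-cost (minimum cumulative resistance) corridors, gravity-model corridor
ranking, and betweenness-centrality stepping-stone optimization scored by
planar network indices. This vignette records the model, its assumptions,
and every numerical choice the method family leaves open.

## Raster substrate and conventions

Rasters are plain matrices over a `grid_geometry` (rows x cols, square cell
size in metres, north-west origin). Row 1 is the northern edge; cell centres
sit at `(origin_x + (col - 0.5) s, origin_y - (row - 0.5) s)`. All distances
are metres between cell centres; areas are km² except the gravity model's
patch masses, which are hectares (labelled in its output). Raster I/O uses
the plain-text Esri ASCII grid; corridors are GeoJSON LineStrings; tables
are CSV; configuration is YAML. No GeoTIFF reader ships because no raster
binary format is needed for any computation.

## Synthetic landscape generator

The generator is first-class, tested code standing in for regional
land-cover products. Its defaults are the stated world of the test suite:

* **Grid**: 200 x 200 cells of 500 m (a 100 km window). The emulated region
  spans ~1.25 x 10^5 km², so a desk-scale raster of 4 x 10^4 cells
  corresponds to sub-km cells; 30 m native resolution would need 10^8 cells.
* **Grassland** (80 % of cells, the declared foreground share) arises by
  thresholding, at the quantile that delivers the target share exactly, the
  superposition of 12 radial habitat nuclei, smoothed Gaussian noise
  (smoothness scale `fragmentation` = 3 cells; weight 0.55), and — when the
  east–west gradient is on — a west-to-east suitability trend of amplitude
  0.6. The trend makes western grassland survive only as isolated noise
  peaks: the west is fragmented, the east contiguous, and the mean eastern
  patch exceeds the mean western patch. At any seed this world hosts
  roughly 50–130 core patches, so a 10-source / 10-stone configuration
  always exists.
* **Other classes**: non-grass cells are partitioned by a secondary smoothed
  field into fixed shares dominated by bare land (40 %) and water-linked
  classes, with marginal construction land — an alpine-basin mixture.
* **DEM**: a smooth surface near 4200–5300 m rising westward;
  **vegetation cover** is a clipped affine function of grassland presence
  plus smooth noise (hence positively correlated with habitat);
  **roads** are 8-connected random-walk polylines (2 main roads spanning
  the window east–west, 8 shorter branches).

What the generator does *not* emulate: real topographic drainage, road
network topology, spatial autocorrelation of class mosaics beyond a single
smoothing scale, or any geographic feature of a specific basin. A green
test therefore establishes that the algorithms are correct and the
pipeline's count laws and invariants hold — not that the package
reproduces any region-specific table.

Aspect is computed from the DEM by Horn's 3 x 3 finite differences; the
compass direction of steepest descent is binned into eight 45° sectors,
zero-gradient cells are `flat`, and border cells inherit the nearest
interior value. Any consistent convention works; this one is fixed and
documented because the factor table scores aspect classes.

## MSPA segmentation

The foreground (grassland by default) is segmented into seven exhaustive,
mutually exclusive classes on the 8-neighbourhood grid with edge width
`w = 1` cell (both configurable):

* **core** — foreground whose chessboard distance to the nearest background
  cell (cells beyond the raster count as background) exceeds `w`;
* **islet** — foreground components containing no core;
* **perforation / edge** — non-core cells within `w` of a core cell,
  split by whether a *hole* (a background component not connected to the
  raster border) lies within `w` (ties go to perforation);
* **bridge / loop / branch** — the remaining non-core cells, grouped into
  connector components and classed by their contact set: the core cells
  within chessboard distance `w + 1`. Contacts on two or more core
  components make a bridge; two or more spatially disjoint contact groups
  (8-components of the contact set) on one core component make a loop; a
  single group makes a branch; an empty contact set leaves the connector
  as edge.

The `w + 1` contact radius is the decidable grid rendering of "connector
attached to a core": connectors are by construction farther than `w` from
any core cell (an edge band always intervenes), so literal 8-adjacency
would never fire; one extra step reaches exactly the cores the connector
abuts through its band. This class semantics is an approximation of the
geodesic reconstruction/skeleton machinery of the reference MSPA software;
on convoluted shapes the two can differ, which is why the package's claims
are anchored to the class definitions, hand-enumerated fixtures, and a
brute-force erosion oracle rather than to that software's output.

## Connectivity indices and source selection

Core patches (8-connected components) form a habitat graph whose links
join patches with edge-to-edge (minimum boundary-cell-centre) distance
within 5000 m; the direct dispersal probability on a link is the negative
exponential `p_ij = exp(-k d_ij)` calibrated so `p(5000 m) = 0.5`
(`k = ln 2 / 5000` per metre) — the standard kernel consistent with the
stated threshold/probability pair. With `AL` the full raster area and
self-pairs included (required so a single landscape-filling patch scores
exactly 1):

* `IIC = Σ_ij a_i a_j / (1 + nl_ij) / AL²`, `nl_ij` the link count on the
  shortest topological path (unreachable pairs contribute 0);
* `PC = Σ_ij a_i a_j p*_ij / AL²`, `p*_ij` the maximum product of link
  probabilities over paths (computed as a shortest path on `-ln p`
  weights);
* `dX_i = 100 (X - X_{-i}) / X`, recomputed with patch i and its links
  removed and `AL` unchanged.

Sources are the top 10 patches by dPC, ties broken by larger area then
smaller id. Edge-to-edge distance (not centroid) is used because the
threshold is a dispersal gap; it is configurable via a precomputed distance
matrix.

## Resistance surface

Six factors — elevation, aspect, land use, vegetation cover, distance to
main roads, distance to branch roads — are each reclassified to ordinal
scores 1 (least resistance) to 5 on left-closed/right-open ascending
intervals, then combined as the weighted sum `R = Σ_f w_f score_f`, a
convex combination that keeps `R` in [1, 5]. The shipped weights are
elevation 0.16, aspect 0.08, land use 0.06, vegetation 0.21, main road
0.26, branch road 0.23. Boundary extensions the published break tables
leave open, fixed monotonically: road distances beyond the largest break
(and an entirely empty road layer, whose distance transform is infinite)
score 1; elevations below the lowest break score 1; full vegetation cover
scores 1; `flat` aspect scores 1 (level ground, like south-facing slopes,
is the easiest terrain); bare land scores 5 (the highest-resistance
surface type alongside ice). All rules are configurable.

`pca_weights()` reproduces the classical composite-score PCA weighting chain on a seeded
uniform sample of cells: eigendecompose the correlation matrix of the
standardized factor scores, keep the leading components, and derive
loadings (`eigenvector·√eigenvalue`), linear-combination coefficients
(`loading/√eigenvalue`), variance-share-weighted composite coefficients,
and sum-normalised weights. Eigenvector signs are fixed so each
component's loading sum is positive. The function exists for
methodological fidelity; the pipeline's default weights are the shipped
table, because a PCA on synthetic scores has no reason to reproduce
another landscape's weights (and composite coefficients can even be
negative on adversarial inputs — the report prints them so the
normalisation is auditable).

## Corridors and the gravity model

Cost distance is Dijkstra over the 8-connected cell graph with step cost
`s · m · (R_u + R_v)/2` (`m` = 1 rook, √2 diagonal) — the standard
average-resistance convention; the aggregation function the minimum
cumulative resistance formulation leaves unspecified is taken as the
identity. One corridor is traced per unordered source pair by multi-source
Dijkstra from the patch's cells and predecessor backtracking to the
minimising cell of the partner patch; corridors may pass through
intermediate sources, and no neighbour-limiting prunes pairs (10 sources
give exactly C(10,2) = 45 corridors).

Interaction strength is `G_ij = L_max² ln(S_i) ln(S_j) / (L_ij² P_i P_j)`
with `S` in hectares (areas must exceed 1 ha so `ln S > 0`; the function
refuses smaller patches with an explanatory error), `P` the mean cell
resistance of the patch ("overall resistance" is undefined in the source
method; mean is the default, sum is available), and `L_max` the largest
corridor cost. The top 15 corridors by `G` (ties: smaller cost, then id
order) are flagged important.

## Stepping stones and network quality

Betweenness is Freeman centrality on the same thresholded, unweighted
patch graph used for source selection, normalised by the unordered-pair
count `(N-1)(N-2)/2` so the middle node of a 3-path scores exactly 1.
Stones are the 10 top-scoring non-source patches (ties: area, then id)
subject to a 1 ha minimum — the gravity model's domain requirement, since
the planned network re-scores corridors with `ln S`. The planned network
joins all pairs of sources plus stones (C(20,2) = 190 corridors, 145 of
them new) and flags the top 8 by gravity.

Quality indices use the planar-network formulas
`alpha = (L - V + 1)/(2V - 5)`, `beta = L/V`, `gamma = L/(3(V - 2))`.
The pipeline reports them with `V` = network nodes and `L` = corridor
count (before: 10/45, after: 20/190). Because the corridor set is
complete rather than planar, alpha and gamma can exceed 1 under this
convention; `V` and `L` are printed alongside precisely so the convention
is auditable — the literature this index family comes from does not state
which links it counted.

## Numerical and degenerate-input choices

* Component labelling, erosion/dilation and the loop/branch contact-group
  test all use the chessboard (8-neighbour) metric to match the declared
  eight-neighbourhood analysis; 4-connectivity is available throughout.
* The Euclidean distance transform is the exact separable lower-envelope
  algorithm (squared distances in cell units; a large finite sentinel
  replaces infinity to keep envelope intersections finite).
* An empty foreground yields a valid all-background MSPA map; an empty
  patch list propagates as an empty report; an empty road layer scores
  minimum resistance; zero-resistance or infinite cells are rejected
  before corridor extraction; removal importances are refused when the
  global index is 0.
* Determinism: every stochastic step (landscape fields, road walks, PCA
  sampling) is governed by a single integer seed; identical configuration
  and seed reproduce bit-identical stacks and artifact hashes.

## Known limitations

The MSPA connector classes approximate, not replicate, the reference
implementation's skeleton-based semantics. The patch-distance step is
exact but quadratic in boundary size, appropriate at desk scale.
Equivalent-connectivity indices, dPC fraction decomposition, corridor
widths/swaths and circuit-theory current maps are out of scope. Region-
specific published values that depend on proprietary rasters (class area
tables, source rankings, interaction matrices) are not reproduction
targets; only the input-free count laws, the worked coefficient table,
and the analytic limits are.
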