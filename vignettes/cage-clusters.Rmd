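---
title: "Hierarchical cage clusters in hydrogen-bond networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical cage clusters in hydrogen-bond networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaclust)
```

## The model

Liquid water's hydrogen-bond network carries structure on several levels,
and `aquaclust` analyses it as a four-level hierarchy:

1. **Hydrogen bonds** (1st level). Two molecules are bonded when a hydrogen
   of one lies strictly closer than 2.5 &Aring; to the oxygen of the other,
   under the minimum-image convention. The criterion is purely geometric —
   no donor–hydrogen–acceptor angle term — so the bond graph is a function
   of coordinates alone. Bifurcated contacts (one hydrogen within the
   cutoff of two acceptors) contribute one edge per acceptor; multiple
   contacts between the same molecule pair collapse to a single undirected
   edge.

2. **Shortest-path rings** (2nd level). A cycle of the bond graph is a ring
   when, for *every* pair of its members, the shorter arc along the cycle
   equals the shortest-path distance in the whole graph. This rejects
   cycles that can be short-cut through a chord or an external detour. The
   maximum ring size is 8; rings of size 3 are admitted (only the upper
   bound is constrained).

3. **Cage fragments** (3rd level). A fragment is a minimal set of 3–5 rings
   in which every covered hydrogen-bond edge belongs to exactly two member
   rings — a closed 2-complex, the topological idealization of a
   three-dimensional cage. The simplest family is the *theta cage*: two
   degree-3 molecules joined by three internally disjoint paths of
   `p1, p2, p3` edges, whose cycles realize ring signatures such as
   (4,5,5) with 6 molecules and (6,7,7) or (4,8,8) with 9.

4. **Water clusters** (4th level). Fragments sharing rings form a network
   (edge weight = number of shared rings); its Louvain communities,
   materialized as the unions of their fragments' molecules, are the water
   clusters. Cluster size `S` is the molecule count; molecules in rings
   shared across community boundaries belong to both clusters, and
   coverage statistics always use the union.

On top of the hierarchy the package computes cluster morphology
(alpha-shape volume `V` and area `A` at alpha radius 3.5 &Aring;, maximum
diameter `L`, radius `r = L/2`), SPC/E interaction energies, local-structure
descriptors (LSI, probe-sphere density, RDFs), scaling fits, and
frame-to-frame transformation dynamics.

## Worked example

```{r example}
cage <- build_theta_cage(c(2, 2, 3))
graph <- detect_hbonds(cage$frame)
rings <- enumerate_sp_rings(graph)
frags <- detect_fragments(rings, graph)
frags[[1]]$signature
length(frags[[1]]$molecules)

report <- run_pipeline(cage$frame)
report
```

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `hb_cutoff` | 2.5 | &Aring; | O···H bond criterion (strict `<`) |
| `max_ring_size` | 8 | — | largest SP ring enumerated |
| `fragment_ring_counts` | {3,4,5} | — | rings per closed cage |
| `alpha_radius` | 3.5 | &Aring; | alpha-shape refinement of cluster shape |
| `probe_radius` | 4.6 | &Aring; | local-density probe sphere |
| `lsi_shell_cutoff` | 3.7 | &Aring; | first-shell boundary for the LSI |
| `energy_cutoff` | 10.0 | &Aring; | truncation of SPC/E pair energies |
| `frame_interval` | 10.0 | fs | time between consecutive frames |

All thresholds flow through one `trajectory_settings()` object recorded in
the run report; there are no hidden defaults. Lengths are &Aring;ngstr&ouml;m
throughout, times femtoseconds, energies kJ/mol (with `kjmol_per_ev` for
eV reporting).

## Numerical choices

**Periodic geometry.** Coordinates are stored as given; wrapping happens
only inside geometry kernels. Minimum-image displacements wrap
componentwise into `[-box/2, box/2)`. Only orthorhombic boxes are
supported; triclinic inputs are rejected with a clear error. Before any
shape computation a cluster is unwrapped by breadth-first traversal of its
bond graph, each molecule placed at its minimum-image position relative to
its parent, so clusters straddling the periodic wall are measured in
contiguous real space.

**Neighbor search.** A periodic cell list (cells at least one search
radius wide, 27-cell neighborhoods) backs bond detection, neighbor lists,
probe counting and RDFs. Boxes too small for three cells per dimension
fall back to a direct all-pairs scan, because the cell walk would
double-count wrapped neighbors there. Brute-force 27-image scans exist in
the test suite as oracles only.

**Delaunay triangulation.** The alpha-shape machinery needs a 3D Delaunay
tetrahedralization, which the package implements natively (incremental
Bowyer–Watson in C++). Robustness comes from normalizing coordinates to
unit scale and adding a deterministic symbolic jitter of about 1e-9, which
removes exact cosphericality and coplanarity; all metric quantities
(volumes, areas, circumradii) are then computed from the original,
unjittered coordinates. The alpha complex keeps tetrahedra with
circumradius at most `alpha * (1 + 1e-7)`: surface-sampled validation
solids are exactly cospherical point sets whose interior simplices sit
precisely at the alpha threshold, and the relative tolerance makes the
keep/drop decision well-posed there. `alpha = Inf` reduces to the convex
hull; boundary area is the total area of facets bordering exactly one kept
tetrahedron, so internal cavities contribute to `A` as real surface.

**Ring enumeration.** Cycles are enumerated by bounded depth-first search
rooted at each cycle's minimum-index vertex, pruned with BFS distances
(no vertex can sit farther from the root than half the size bound), then
filtered by the all-pairs shortest-path condition and canonicalized
(lowest member first, lexicographically smaller direction). The SP
condition is deliberately applied to **all** vertex pairs of the cycle
against the full graph — the strictest reading — and the brute-force test
oracle implements the same definition through an independent route
(exhaustive simple-cycle enumeration plus a distance filter).

**Theta cages and the closure condition.** For a theta graph with sorted
path lengths `p1 <= p2 <= p3`, the largest cycle (`p2 + p3`) is a
shortest-path ring only when `p1 = p2`; otherwise its two branch vertices
are closer through the shortest path than along the cycle, the cycle is
short-cut, and no three-ring closure exists. Every cage family quoted
above — (4,5,5), (6,7,7), (4,8,8) — satisfies `p1 = p2`. The synthetic
builder therefore reports a `closes` flag, and the validation loop asserts
one fragment with `2 + sum(p_i - 1)` molecules for closing specs and zero
fragments otherwise.

**Cage embedding.** The two poles sit on the z axis; each path lies on a
meridional circular arc (azimuths 120&deg; apart) whose center offset is
solved by bisection so that consecutive molecules are exactly one bond
length (2.8 &Aring;) apart. The pole separation is 2.8 &Aring; when a
single-edge path is present and 3.71 &Aring; otherwise — just above the
3.5 &Aring; non-bond floor while leaving the arcs room to clear each
other. Donors are oriented so no molecule donates more than twice (greedy
with local repair), donor hydrogens sit 1.0 &Aring; from their oxygen along
the bond, spare hydrogens point away from the cage, and the builder
verifies that geometric bond detection reconstructs the intended graph
exactly, failing loudly otherwise.

**Louvain runs.** Community detection uses the Louvain heuristic (igraph's
multilevel implementation), weighted by shared-ring counts at resolution 1
by default; both are configurable. The heuristic's randomness lies in the
node traversal order, so a run is seeded, and restarts diversify in three
faithful ways: permuted vertex orders for igraph, an independent in-package
multilevel implementation with randomized sweeps and random tie-breaking,
and a finishing phase-1 local-moving sweep on the original graph (the
aggregated levels cannot move single vertices, so a final fine sweep can
still improve the partition). The best partition by modularity wins.
Louvain carries no optimality guarantee: on small random graphs there
exist partitions that no sequence of strictly-improving Louvain moves can
reach, and the test suite documents this by comparing against exhaustive
set-partition search.

**Power-law fitting.** The size-distribution exponent is fitted by least
squares on logarithmically binned counts converted to densities (count /
linear bin width, geometric bin centers), using only bins holding at least
10 observations — sparse tail bins carry large multiplicative noise and
otherwise dominate the regression. A continuous-Pareto maximum-likelihood
estimator is available as `method = "mle"`. Recovery tests draw samples
from a seeded discrete power law and require bias below 0.05 at 1e5
samples.

**Energies.** SPC/E: `q_O = -0.8476 e`, `q_H = +0.4238 e`, O–O
Lennard-Jones sigma 3.166 &Aring;, epsilon 0.650 kJ/mol, Coulomb constant
1389.35458 kJ &Aring; mol⁻¹ e⁻². Pair energies are direct nine-site sums
truncated at the O–O cutoff with no Ewald or tail correction — cluster
energy is defined as a plain intra-cluster pair sum. Published energy-size
fit parameters of order −12 per molecule are quoted in eV, which is
physically implausible for pair-interaction magnitudes (−12 kJ/mol ≈
−0.13 eV is the natural scale); the package stores kJ/mol and leaves unit
conversion to the caller.

**Transformation bookkeeping.** Each frame decomposes into clusters,
isolated rings (rings in no fragment), and debris molecules (in no cluster
and no isolated ring). Entities of consecutive frames sharing molecules
form bipartite components; each component holding at least one cluster is
an event, classified as changeless (identical membership, the strict
reading), merge (single product cluster built from at least one cluster or
ring), split (the mirror), or complex. Lifetimes count strictly unchanged
membership chains with no grace for single-frame interruptions, in units
of the frame interval.

## What the synthetic generators emulate — and what they do not

The generators produce *topologically* faithful fixtures: theta cages
whose bond graph is known exactly, ice-Ih-like lattices (4-coordinated,
6-rings only, built from an orthorhombic 8-molecule cell with an Eulerian
orientation enforcing the two-donor ice rule), hard-core random packings,
ideal-solid surface samples, and seeded power-law size samples. They are
geometric constructions, not thermodynamic states: there is no force
field, no temperature, and no Boltzmann sampling behind them. Green tests
therefore certify that every stage computes what it claims on structures
with known answers; they do not certify the physical statistics of real
water (for example, reported exponents near τ ≈ 2.44 or coverage above
95% arise only from large equilibrated simulations, which are out of
scope here). Two lattice caveats: wrap-around cycles in small periodic
ice cells are genuine graph cycles, so the "6-rings only" guarantee needs
at least 3 unit cells per dimension; and probe spheres centered on lattice
sites see lattice shell counts, not the continuum density — the bulk value
is recovered by generic (off-site) probe positions.

## Degenerate inputs and edge cases

* Fewer than 4 points, or (nearly) coplanar clusters, raise a typed
  `aquaclust_degenerate_shape` error; the pipeline catches it and reports
  the cluster with missing `V`/`A` rather than aborting the frame.
* A hydrogen exactly equidistant (within 1e-6 &Aring;) between two oxygens
  is an assignment error on input, not a silent choice.
* Distances exactly at a cutoff are excluded everywhere (strict `<`),
  matching the bond criterion's wording.
* Identical distributions, or distributions differing by a constant
  factor, yield a "no crossing found" result rather than an error;
  crossings are located by linear interpolation between the nearest
  nonzero values of the (optionally smoothed, default 5-point moving
  average) difference, so an exact zero on the grid is handled.
* Empty networks produce empty partitions; singleton fragments become
  singleton communities.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes on one core: surface samples of
5000 points per solid and three sizes per solid for shape factors;
random boxes up to 500 molecules for neighbor-search and bond oracles;
100 random graphs of up to 12 nodes for the ring oracle; 42 random graphs
of up to 10 nodes for the exhaustive modularity oracle; 1e5 draws for
estimator recovery. The pipeline itself has no hard size limit, but the
all-pairs distance matrix used by ring enumeration makes frames beyond a
few thousand molecules memory-hungry; analysing production trajectories
frame-by-frame (they are processed independently) is the intended route.

## Known limitations

* Only orthorhombic periodic boxes.
* The SP-ring criterion is fixed to the all-pairs form; variants that test
  only opposite pairs would admit more rings.
* Fragment search enumerates connected ring subsets up to size 5; cages of
  more than 5 rings are out of scope by definition.
* Louvain communities are computed per frame with a fixed resolution of 1;
  no cross-frame smoothing is attempted, which makes lifetimes a strict
  lower bound under membership churn.
* Cluster energies ignore long-range electrostatics beyond 10 &Aring; by
  construction.
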