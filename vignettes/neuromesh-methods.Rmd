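---
title: "From point-and-diameter skeletons to watertight neuronal membranes"
author: "neuromesh developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From point-and-diameter skeletons to watertight neuronal membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromesh)
```

## The problem

Stochastic reaction-diffusion simulators (STEPS and kin) operate on
tetrahedral volume meshes, and tetrahedralizers such as TetGen demand a
*watertight* input surface: a two-manifold triangle mesh with zero
non-manifold edges and vertices, no boundary edges, no self-intersecting
facets, and a single connected component. Neuronal morphologies, however,
are archived (e.g. on NeuroMorpho.Org) as point-and-diameter skeletons:
acyclic graphs of digitized samples organized into segments, sections and
neurites around a soma. Bridging that gap robustly is hard; approaches that
assemble the membrane from analytic pieces or boolean unions fail precisely
at the places neurons are interesting - thin fibers, irregular branch
geometry, and spines.

`neuromesh` takes the voxel-welding route: build *proxy* meshes for every
component of the cell that are individually closed but freely overlapping,
rasterize their union into a solid occupancy lattice at a feature-derived
resolution, re-extract a surface from the lattice (which removes every
overlap and self-intersection by construction), and then optimize the
over-tessellated result under an iterative watertightness-verification
loop.

## Morphology model and preprocessing

SWC input is reduced to a soma centroid + mean radius (single-sample,
three-point and contour somata alike - the soma surface is regrown by
simulation, so only the aggregate matters) and a forest of sections.
Sections duplicate their branching samples as shared endpoints so each can
be resampled independently; root sections carry a leading auxiliary sample
at the soma centroid, recording the soma-arbor segment.

Preprocessing never changes this structure. It (i) flags neurites whose
root sample lies beyond `tolerance_factor` (default 2, a closed interval)
times the somatic radius; (ii) deletes leading arbor samples inside the
mean-radius soma sphere (each section keeps two samples); and (iii)
resamples every section at a step equal to the *local radius*. The adaptive
step is a deliberate choice: thin fibers need dense support for the voxel
stage while thick trunks do not, and the radius itself is the only local
length scale the skeleton offers. "Somatic spatial extent" is interpreted
as the mean-radius sphere; a reconstructed-profile alternative would need
the soma mesh before preprocessing, which inverts the pipeline order.

## Proxy arbors

Two interchangeable arbor generators exist (`arbor_algorithm`):

* **node-to-leaf** (default): at every branch point the child with the
  largest first-segment radius is labeled *primary* (ties to the smallest
  section index, for determinism); depth-first traversal yields one path
  per leaf, each following primary continuations, and the root path is
  prepended with a soma-centroid point so the tube pierces the soma and
  welds during voxelization.
* **articulated**: one independent path per section plus icosphere
  articulations at every branch point, sized by the largest sample meeting
  there, and one auxiliary icosphere at each neurite root.

Paths are resampled on a natural interpolating cubic spline (or piecewise
linearly) at step `min(local radius, 1 um)` and swept with
`ring_sides`-gon cross-sections oriented by rotation-minimizing frames
(double-reflection); naive Frenet frames twist at inflections and create
avoidable self-intersections. One numerical choice deserves emphasis: ring
radii are *area-compensated* by `sqrt((2*pi/n)/sin(2*pi/n))`, so an n-gon
cross-section has exactly the area `pi*r^2`. An inscribed 16-gon tube
otherwise underestimates volume by 2.55% - more than the 2% end-to-end
volume budget of the whole pipeline. With compensation a straight tube's
volume is exact to rounding for every `n`.

## Soft-body soma

The soma grows from a subdivision-3 icosphere (radius
`soma_initial_radius_factor x` somatic mean radius, default 0.5) under
damped explicit Euler mass-spring dynamics (`dt = 0.1`, velocity damping
0.9, unit masses). Three force systems act:

* edge springs (Hooke) with stiffness `k = soma_stiffness`;
* *goal* springs of the same `k` tying every non-pulled vertex to its rest
  position - the shape-memory mechanism of Blender-style soft bodies;
* pull springs of fixed strength 1.0 driving each connected arbor's vertex
  patch (the icosphere vertices inside the cone subtended by the arbor's
  initial cross-section, half-angle `atan(r/d)`) toward the arbor root.

Because the restoring forces scale with the one stiffness knob while the
pull does not, stiffness behaves as expected: higher values keep the soma
rounder, monotonically. (Making the pull scale with stiffness too would
cancel out of the equilibrium entirely.) Pulled vertices stay force-driven
rather than position-clamped; clamping would guarantee arrival but can
fold the surface at high step counts. The integrator is deterministic and
topology-preserving; `steps = 0` and pull-free networks return their input
bit-exactly.

## Spines

Circuit-derived spine meshes and synapse positions are proprietary, so the
package provides parametric stand-ins: surfaces of revolution composed of
a cylindrical neck and a spherical head in a canonical frame (base disc at
the origin, +Z axis, height = length), in three classes (stubby = head
equal to neck, mushroom, thin). Defaults live inside the biological
envelope - lengths 1-3 um, necks 0.06-0.8 um - and a hard floor of
0.06 um on neck diameter is enforced. Placements are Poisson in dendritic
arclength (`spine_density` per um, type-3/4 sections only), with uniform
azimuth about the local tangent, fully reproducible from `rng_seed`; users
with real synapse tables can supply a CSV instead. Each placed spine is
sunk 25% of the local dendrite radius below the surface: the algorithm
only requires overlap, and a fixed fraction guarantees a weld at any voxel
size up to half the neck diameter.

## Voxel remeshing

The joint proxy (pure concatenation - explicitly *not* a boolean union) is
voxelized at
`voxel_size = min(smallest sample diameter, thinnest spine neck) / voxel_feature_divisor`,
divisor 2 by default, i.e. at least two voxels across the finest feature.
A voxel is occupied iff its *center* lies inside the union of the member
solids: conservative triangle rasterization marks a surface shell, an
exterior flood fill (6-connectivity, 2+ voxels of padding) classifies the
bulk exactly, and shell voxels are resolved by per-member ray parity
(members are individually closed, so parity is well defined even though
the union self-intersects). Center semantics make occupancy volume
unbiased to first order and make `voxelize(A u B) = voxelize(A) OR
voxelize(B)` exact; marking every surface-touching voxel instead would
inflate a radius-5 um sphere by about `A*h/2 ~ 3%` at `h = 0.1`.

Polygonization runs marching tetrahedra on a parity-alternating
five-tetrahedra cube decomposition of the lattice (nodes at voxel
centers, field +1/-1, iso 0). Since no node equals the iso value, the
level set of the piecewise-linear interpolant is a closed embedded
2-manifold *by theorem*, not by case-table audit - zero boundary edges and
zero non-manifold edges on every input, including adversarial random
grids. The binary field is deliberately not pre-smoothed: a one-pass box
filter drags 2-voxel-wide features (exactly the divisor-2 operating point;
a 2x2 neck column averages 12/27 < 0.5) below the iso level and
re-introduces the fragmentation the resolution rule exists to prevent.
Smoothing is the mesh optimizer's job, where volume can be compensated.

One corner case needs explicit care at the divisor-2 operating point: a
feature exactly two voxels wide can digitize with occupied voxels that
touch only along a voxel edge or corner, which the piecewise-linear field
rightly treats as disconnected (a one-voxel octahedron satellite). The
solid genuinely continues through such gaps, so the voxelizer bridges every
diagonal-only contact by switching on one intermediate voxel (preferring
voxels the surface passes through; deterministic tie-break), iterated to a
fixed point. This adds a handful of voxels per cell - negligible volume
bias - and restores the 6-connectivity that guarantees a single extracted
manifold for a connected solid.

A fragmentation check follows: components are counted over triangle
adjacency, and a multi-component result aborts the pipeline with a
diagnostic (or keeps the largest component under `allow_fragments`) -
under-resolved spine necks are the canonical cause.

## Optimization and repair

The raw surface is heavily over-tessellated (~2 triangles per surface
voxel facet). `optimize_mesh` runs:

1. **Coarsening**: quadric-error edge collapse (area-weighted plane
   quadrics, optimal-point placement with endpoint/midpoint fallback,
   link-condition and normal-flip rejection) down to
   `optimization_target_ratio` (default 0.6) of the input triangles.
   Planar regions have zero quadric cost and collapse first, so
   tessellation concentrates at spines and branch points; genuinely planar
   geometry is preserved exactly.
2. **Smoothing** (`smoothing_iterations`, default 3): a uniform Laplacian
   half-step, a gentle normal-driven pass toward the area-weighted average
   plane of incident faces, then a global rescale about the centroid
   restoring the enclosed volume *exactly* - this is what makes the
   pipeline's 2% volume budget enforceable rather than aspirational.
3. **Repair loop**: check -> mark the vertices of every defect element
   (endpoints of boundary/non-manifold edges, pinch vertices, all six
   vertices of each self-intersecting pair, vertices of zero/thin faces)
   -> delete their faces -> close each boundary loop by ear-clipping
   against its best-fit plane (centroid-fan fallback for degenerate
   loops) -> one smoothing pass -> re-check, up to
   `repair_max_iterations` (default 20). Non-convergence raises an error
   carrying the trace; it is not silently tolerated.

A final drift gate rejects results whose enclosed volume moved more than
2% relative to the polygonized mesh.

Quality is reported with Verdict-style per-triangle metrics: radius ratio
`R/(2r)`, edge ratio, radius-to-edge ratio, and per-face min/max interior
dihedral angles (from outward normals, `acos(-n1.n2)`; a flat pair reads
180 degrees). Zero faces are `area < 1e-10 um^2` and thin faces
`radius ratio > 100` - standard defect classes without canonical
thresholds; these values sit far above the quality mass of remesher
output.

## What the synthetic generator emulates - and what it does not

`synthesize_morphology` produces seeded binary-branching neurites with
angular wander, per-section radius taper (floored at 0.05 um), a 3-6 um
soma, and one axon among the neurites. That covers what the meshing
algorithm actually consumes: branching topology, taper, thin distal
fibers, spiny dendrites, soma-arbor geometry. It does not emulate real
arbor statistics (branch-angle or Sholl distributions), axonal boutons,
myelination, or EM-grade spine shape variety, so a green test certifies
robust geometry processing, not biological realism of the fixtures.

The acceptance fixtures (ten seeded spiny neurons) use spatial extent
26 um, trunk radii ~0.85 um tapering to ~0.36 um, and spine necks of
0.24-0.5 um, giving feature-rule voxel sizes near 0.12 um. Full-scale
cortical neurons with 0.06 um necks obey the same rule at ~8x finer
grids; they are out of reach of a single-CPU test budget, which bounds
scale, not logic. Each fixture still has >= 20 sections and >= 50 spines,
meshed at divisor 2 with no overrides.

## Degenerate inputs and tie-breaks

* Equal-radius children at a branch: the smallest section index is
  primary.
* Coincident consecutive path points are dropped before sweeping.
* A singleton sample under the soma still yields a valid two-sample
  section via the auxiliary centroid sample.
* Degenerate triangles in metrics report infinite ratios instead of
  erroring; `enclosed_volume` refuses open meshes outright.
* The voxel memory budget errors with the required count and a workable
  voxel size rather than swapping.

## Known limitations

* Cyclic morphologies (vasculature) are rejected; HDF5/ASC readers are out
  of scope.
* The repair loop deletes geometry; pathological inputs could in principle
  oscillate. In 100-seed fuzzing it converges in <= 3 iterations, and the
  iteration bound plus trace make failures diagnosable.
* Coarsening quality (not validity) degrades below target ratios of ~0.1
  on organic surfaces; feature-edge preservation is intentionally absent.
* Spine placement is density-based, not synapse-driven; no attempt is made
  to classify spine types from imagery.
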