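---
title: "Scale-adaptive surface reconstruction of segmented vessels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-adaptive surface reconstruction of segmented vessels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A validated binary segmentation of a vascular tree (1 = vessel, 0 =
background, anisotropic voxel spacing allowed) is to be turned into a
smooth, watertight, consistently oriented two-manifold triangle mesh whose
triangle size adapts to the local curvature of the surface: small triangles
on thin, strongly curved branches, large triangles on flat stretches. Such
meshes feed computational fluid dynamics and interactive planning tools,
which tolerate neither the staircase artifacts of direct voxel contouring
nor needle-shaped triangles.

`vesselmesh` implements a model-free pipeline in four stages: boundary
point extraction, normal estimation, an implicit indicator function, and
curvature-adaptive polygonization (mesh expansion plus gap stitching).

# Pipeline stages

## Boundary point extraction

Every face shared by an object voxel and a 6-neighbour background voxel
generates one sample at the face centre (world coordinates; voxel centres
sit at integer index positions, `world = origin + index * spacing`).
Structures thinner than a 3x3x3 box are detected by the white top-hat
transform (the volume minus its morphological opening, computed in index
space); boundary faces whose outer (background) voxel touches such a thin
voxel are refined into their four subface-quadrant centres, quadrupling
the local sampling density so that one-voxel-wide branches remain
represented. The morphology is implemented with vectorized array shifts:
no installed package provides 3D binary morphology on plain arrays.

## Covariance normals

Each sample's normal is the eigenvector belonging to the smallest
eigenvalue of the covariance matrix of its `k = 10` nearest neighbours
about their centroid. The printed form of the covariance equation omits
the `1/k` in the centroid; the arithmetic mean is used, since covariance
analysis is undefined otherwise. Orientation is resolved locally and
deterministically: the sign is chosen so the normal points toward the
sample's source object-voxel centre (inward), with exact ties broken
toward the generating face's inward axis. No propagation scheme is needed
because every sample knows its source voxel.

## Poisson indicator function

The oriented cloud defines a vector field `V` (inward unit normals
splatted onto the eight nearest depth-`d` grid nodes with trilinear
weights), and the indicator `psi` solves `Delta psi = div V` in the
Galerkin sense over node basis functions: tensor-product quadratic
B-splines, the standard compactly supported surrogate for the unit-variance
Gaussian, centred on the nodes and scaled by their width so each has unit
integral. On the regular node grid the stiffness and divergence operators
are separable five-point stencils per axis; the system is applied
matrix-free and solved by conjugate gradients (relative residual `1e-8`,
iteration cap `10 sqrt(N) + 1000`). The iso-level is the mean of `psi`
over the sample positions.

A design deviation worth stating: the solver always uses the complete
depth-`d` node grid (the fully refined octree) rather than an adaptive
multi-depth basis. At the depths vessel volumes need (6-7), the dense grid
is at most a few million nodes, the matrix-free stencils keep it fast and
memory-light, and a single code path is easier to validate. The adaptive
octree structure is still built (`build_octree`) and serves point location
and the structural contracts; the Galerkin equations are identical.
The bounding cube is the sample bounding box scaled by 1.25 to keep the
level set clear of boundary truncation.

## Mesh expansion

A seed point (a sample near the cloud centroid; several candidates are
tried, because a sample on a flat rasterization plateau or in a concave
crease may not admit a regular tangent hexagon) is projected onto the
level set by Newton steps `x <- x - (psi - iso) grad psi / |grad psi|^2`
(tolerance `1e-6` of the field's value span, step capped at two node
widths). A regular hexagon in the tangent plane probes the local radius of
curvature by the chord formula `r = min_i d_i / (2 sin(theta_i / 2))`
over the projected vertices (`d_i` chord length, `theta_i` normal
deviation; deviations under `1e-4` rad count as flat), is rebuilt with
circumradius `rho * r` (`rho = 0.15`), reprojected, and installed as six
triangles. If the projected ring is irregular (flat spots send `r` to its
clamp and the hexagon overshoots), the radius is halved geometrically, but
never below one basis-node width.

Expansion pops boundary edges from a FIFO queue. Two adjacent boundary
edges meeting at less than 70 degrees are closed with an "ear" from
existing vertices. Otherwise a candidate vertex is placed opposite the
owning triangle at distance `rho * r` (probes: the projected candidate
against the edge endpoints' stored normals), projected, and accepted when
the base angles of the constructed triangle lie in [50, 70] degrees and
the triangle keeps a clearance of one third of the longest edge involved
from every other triangle not sharing its vertices. Rejected edges return
to the queue at most twice (their surroundings keep changing) and are
otherwise left for stitching.

Numerical choices that stabilise this stage on rasterized data, where the
reconstructed level set carries voxel-scale ripples:

* the angle window is tested on the constructed in-plane triangle, so
  acceptance depends on the edge-length ratio rather than projection
  jitter;
* when `rho * r` exceeds what the window admits, the largest admissible
  edge (1.44 times the base) is used, so the mesh recovers toward
  `rho * r` at the fastest rate the rule allows instead of stalling;
* edges never shrink below one node width (`edge_min = w`): finer
  triangles carry no surface information and ripple noise in the
  curvature probes would otherwise drive a shrink spiral;
* a candidate must not leave a residual wedge under 20 degrees at either
  endpoint (such a wedge forces a needle on whoever closes it; deferring
  lets a relaxed ear close the whole wedge well-shaped);
* the proximity test checks all nearby faces, not only those still
  carrying a boundary edge: a front can otherwise corkscrew through
  regions whose faces have already become interior and never terminate.

After the queue empties, cleanup passes sweep the remaining boundary with
the ear rule relaxed to 90 and then 110 degrees (ears with a minimal angle
under 20 degrees are still refused). Thresholds beyond 110 degrees were
found to coarsen the seam into large skewed triangles whose stitched fill
sags; at 110 the seam stays near the local edge scale.

## Gap stitching

The remaining boundary partitions into simple closed loops. Each loop is
closed by the minimum-weight triangulation under the lexicographic weight
`(alpha, beta, A)`: `alpha` the triangle's minimal interior angle
(maximized first), `beta` the largest dihedral deviation against the
already fixed neighbours (the mesh triangle across each loop edge and the
sub-patch triangles across diagonals), `A` the area; weights accumulate as
`(min alpha, max beta, sum A)`. The printed accumulation rule in the
source formula carries a typo (`min(beta_1, beta_2)` where the prose and
field order require the minimal angle); the prose semantics are
implemented.

Two implementation points:

* *Exactness.* Plain interval memoization is not exact for this weight: a
  triangle's dihedral depends on its sub-polygons' top triangles, and the
  min/max/sum accumulation is not monotone under the lexicographic order
  (a skinny triangle upstream caps `alpha` for every continuation, so a
  sub-solution with worse `alpha` but better dihedrals can win globally).
  The programme therefore runs over states (interval, top triangle) and
  keeps the Pareto front over (`alpha` up, `beta` down, `A` down) per
  state, which is exact; a dedicated enumeration oracle in the test suite
  confirms equality with the brute-force minimum over all triangulations.
  To keep the cubic-and-worse cost bounded, loops longer than 12 vertices
  are pre-split along their shortest admissible chord and the halves
  solved recursively; the localization also keeps patches on the surface
  (a global solve on a winding seam happily spans fat chords through empty
  space).
* *Diagonal legality.* A patch triangle must not reuse an edge that
  already carries two faces; such diagonals are excluded outright.

### Topology budget

Closing every loop with a disk yields Euler characteristic
`chi(open mesh) + #loops`. The target is known exactly from the input:
the segmentation's boundary surface has `chi = 2 chi(voxel complex)`
(vertices minus edges plus faces minus cubes of the object voxels,
computed by array shifts; `volume_surface_euler()`). When disk-filling
would exceed the target by `2h`, the stitcher realises `h` handles: the
two mutually nearest rims are closed with an annulus ladder (the classical
two-contour merge, solved as a monotone-path dynamic programme over rung
choices with illegal rungs excluded), and a single loop that winds a
handle is first split along a short antiparallel chord into two cycles
sharing that chord. This is the one deliberately genus-creating move and
it happens exactly as often as the voxel data demands; for genus-0 inputs
stitching reduces to pure disk fills. The advancing front necessarily
terminates as a topological disk (fronts stop a clearance short of
touching), so without this budget a torus-like vessel loop would always
close into a sphere with a membrane across its lumen.

### Patch subdivision

Stitched patches are refined so their density matches the surroundings:
patch-interior edges longer than 1.5 times the mean original boundary-edge
length of their loop are split at the midpoint, red-green style (three
marked edges split a triangle 1-to-4, shape-preserving; one or two marked
edges use the conforming 1-to-2 / 1-to-3 patterns), and the midpoints are
projected onto the level set. Two rounds are performed: near rippled
regions the projected midpoints can stretch child edges back over the
threshold, so further rounds chase noise rather than converge (runs with
more rounds multiplied sliver triangles without improving accuracy).
An edge is also never split when the resulting children would be
needle-shaped (edge ratio under 0.3 at the plain midpoint): the method's
purpose is a mesh free of thin elongated triangles, and a density split
that manufactures one defeats it.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `rho` | 0.15 | triangle edge length as a fraction of the local curvature radius |
| `knn_k` | 10 | neighbourhood size for covariance normals |
| `depth` | 7 | node-grid depth of the Poisson solve (6 for the desk-scale phantom studies here; memory grows as `8^depth`) |
| `r_min`, `r_max` | 0.5 min spacing, 100 max spacing | curvature-radius clamps; flat regions report infinite radius and are clamped |
| `max_triangles` | 200000 | expansion cap; exceeding it signals a mis-tuned `rho` or a degenerate field |

`rho` and `k` are the method's standard settings; the iso-level and grid
depth are not fixed by the method and are configuration with the defaults
above.

# The phantom generator

Test volumes are rasterized from analytic solids with exact signed
distances: sphere, tube (capsule), torus, Y-bifurcation (two radius-6
tubes meeting at 60 degrees by default), and a dumbbell (spheres of radii
15 and 5 joined by a radius-3 neck) for curvature-adaptivity checks.
A voxel is set when its centre lies strictly inside the solid, matching
the binary-segmentation input model. The phantoms reproduce the features
the pipeline must handle - curved tubes, branch creases, thin structures,
a handle - at desk scale (volumes of roughly 40-60 voxels per side,
reconstructed at depth 6 in seconds to a couple of minutes each; these
sizes are the package's study conditions throughout the tests).

What they do not emulate: segmentation noise (isolated voxels, rough
surfaces beyond rasterization staircase), anisotropic clinical spacing in
the test defaults (supported by the code, exercised only lightly), contact
between distinct branches, and clinical-scale trees with hundreds of
branch points. Passing the phantom suite therefore demonstrates the
machinery is correct and well-behaved on clean geometry of the right
local structure; it does not certify accuracy figures on clinical CT/MRA
segmentations.

# Known limitations

* Triangle quality inside stitched patches is below the expansion-stage
  quality, most visibly on the torus phantom where the handle ladder
  closes a long corridor; the edge-ratio tail reported by the quality
  report makes this measurable.
* The expansion's curvature probes read the reconstructed field, so at
  structures close to one node width the radius estimate is
  noise-dominated; the node-width edge floor keeps the mesh sane there at
  the cost of curvature adaptivity below that scale.
* Islands (holes containing separate interior components) are not filled,
  and multi-label volumes are out of scope.
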