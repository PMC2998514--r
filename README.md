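# vesselmesh

Model-free surface reconstruction of segmented vascular structures.
Given a binary segmentation volume (1 = vessel, 0 = background, possibly
anisotropic voxel spacing), `vesselmesh` produces a smooth, watertight,
consistently oriented two-manifold triangle mesh whose triangle size
adapts to the local curvature of the surface — small triangles on thin,
strongly curved branches, large triangles on flat stretches. Meshes of
this kind are the required input for blood-flow (CFD) simulation and
interactive surgical planning, which tolerate neither voxel staircase
artifacts nor needle-shaped triangles.

## Method

1. **Point extraction** — every object/background voxel face contributes a
   sample at its centre; faces adjacent to thin structures (detected by a
   white top-hat transform with a 3×3×3 box) are refined into four subface
   samples.
2. **Covariance normals** — each sample's normal is the
   smallest-eigenvalue eigenvector of the covariance matrix of its
   *k* = 10 nearest neighbours, oriented toward the sample's source voxel
   (inward).
3. **Poisson indicator function** — the inward normal field V is splatted
   onto a depth-*d* node grid (trilinear weights) and the indicator ψ
   solves Δψ = ∇·V over unit-integral tri-quadratic B-spline node bases;
   the level set at the mean of ψ over the samples is the surface.
4. **Curvature-adaptive polygonization** — a seed hexagon in the tangent
   plane is sized by the chord estimate r(p) = min dᵢ / (2 sin(θᵢ/2)) and
   grown edge-by-edge: new triangles have edge length ρ·r (ρ = 0.15),
   base angles constrained to [50°, 70°], ears close wedges under 70°, and
   a one-third-longest-edge clearance rule stops colliding fronts.
5. **Gap stitching** — the remaining boundary loops are closed by an exact
   minimum-weight triangulation under the lexicographic weight (α, β, A)
   (maximal minimal angle first, then smallest worst dihedral, then area),
   with an Euler-characteristic budget computed from the voxel data so the
   segmentation's genus is preserved; patches are then subdivided to match
   the surrounding density.

Everything downstream of the volume reader operates in world coordinates,
so anisotropic spacing is handled throughout. Analytic phantoms (sphere,
tube, torus, Y-bifurcation, dumbbell) with exact signed distances are
built in, so the whole pipeline is testable without any data downloads.

## Worked example

```r
library(vesselmesh)

# reconstruct a Y-bifurcation phantom: two radius-6 tubes meeting at 60 deg
shape <- shape_bifurcation(r = 6, angle_deg = 60, length = 25)
vol   <- rasterize(shape, spacing = c(1, 1, 1))
res   <- reconstruct_surface(vol, pipeline_config(depth = 6))

quality_report(res$mesh, reference = shape)
#> quality_report: 3724 triangles, 48.1% tau>=0.8, 0.91% tau<0.3
#>   topology: euler 2, 1 component(s), 0 boundary edges, manifold TRUE
#>   distance: mean 0.1461, max 0.6362, rms 0.1928

save_mesh(res$mesh, "bifurcation.ply")
```

About half of the triangles are close to equilateral (edge ratio
τ = min/max edge length ≥ 0.8), under one percent are the low-ratio
triangles introduced by gap stitching (τ < 0.3), the mesh is a closed
two-manifold of the correct genus, and the maximum deviation from the
analytic surface is below one voxel.

The same pipeline is available from the shell:

```sh
vesselmesh reconstruct --in seg.nii.gz --out mesh.ply --report report.json \
                       --rho 0.15 --knn 10 --depth 7
vesselmesh reconstruct --phantom sphere:R=20 --out sphere.ply --depth 6
vesselmesh evaluate    --mesh mesh.ply --phantom bifurcation:r=6,angle=60,len=25
vesselmesh phantom     --kind torus:R=10,r=4 --out torus.mha
```

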