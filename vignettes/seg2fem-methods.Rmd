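---
title: "From labeled spine MRI volumes to finite-element models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From labeled spine MRI volumes to finite-element models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

seg2fem turns integer label volumes — segmentation masks of vertebrae and
intervertebral discs (IVDs) as produced by modern spine MRI segmentation
networks — into simulation-ready tetrahedral finite-element models. This
vignette explains the procedure stage by stage, the assumptions behind it,
the tunable parameters and their defaults, and the numerical choices made
where the design was genuinely open. Nothing here states an empirical result
that the package's test suite or `scripts/acceptance.R` does not itself
compute.

## The problem

Spine MRI is acquired slice-wise: typical scans have about 1 × 1 mm in-plane
resolution but 2.5–3.5 mm slice thickness. A labeled mask voxelized on such
an anisotropic grid produces, after iso-surfacing, terraced "stair-step"
surfaces. Two further properties of segmentation masks matter downstream:

* **Adjacent bodies touch.** A vertebra and its neighbouring disc share a
  voxel face, so their extracted surfaces coincide along the endplate
  region. For finite-element analysis this is an opportunity: if the two
  meshes can be made to *share node coordinates exactly* along the contact
  patch, no contact or penalty formulation is needed at all — displacements
  and loads transfer through common nodes.
* **Masks carry defects.** Partial-volume islands of a few voxels,
  disconnected label components, and enclosed cavities all occur, and each
  breaks a different stage of the chain. A cohort pipeline must detect,
  classify and survive them.

The pipeline is: mask cleanup → surface extraction → anatomically
constrained smoothing (vertebrae first, then discs adaptively) → constrained
tetrahedral filling → quadratic elements → node sets, coupling, loads →
static linear-elastic solve → cohort quality statistics.

## Label conventions

Vertebra labels occupy 4..25, matching the label range of multi-class spine
segmentation networks. A disc between vertebrae `v` and `v + 1` carries the
integer label `100 v + (v + 1)` in the grid (1011 for the 10/11 disc); the
NIfTI sidecar JSON spells these as `vert_10`, `ivd_10_11`. Segmented
endplates, where present as separate labels, are merged into the disc label
(`merge_ivd_endplates()`) before surfacing so that each disc forms one body.

## Mask cleanup

`remove_small_components()` deletes connected components with fewer than 4
linked voxels (the partial-volume artifacts that otherwise produce sharp
spikes during smoothing). Two readings of "fewer than" are possible; the
package keeps components of exactly the threshold size (strict `<` removal),
the minimal-destruction reading, and the threshold is a parameter.
Connectivity is 26-neighbourhood by default — the permissive reading of
"linked" — and configurable; defect injection and detection share the same
setting so the two cannot disagree.

## Surface extraction

`extract_surface()` binarizes one label and extracts the iso-level-0.5
surface on the voxel-center grid, sampling every voxel layer, then maps
vertices to world millimetres through the volume affine. The exact
marching-cubes variant is open in principle; the package uses **marching
tetrahedra** (each grid cube split into six tetrahedra around a fixed
diagonal, crossings interpolated on tetrahedron edges, with a shared-edge
vertex cache). This variant needs no disambiguation table and is watertight
and manifold *by construction*, which the diagnostics confirm on every
phantom body. Orientation is fixed geometrically (normals point from inside
to outside), so enclosed volumes computed by the divergence theorem are
positive.

`repair_mesh()` merges duplicate vertices within 10⁻⁶ mm (well below voxel
scale, so only numerically coincident nodes are touched), drops degenerate
faces, and closes boundary loops by ear-clipping the loop projected onto its
best-fit plane, with a fan fallback for degenerate polygons. Repair never
moves a vertex by more than the merge tolerance. What cannot be repaired
(residual non-manifold edges) raises an error carrying the diagnostics
report, which the pipeline converts into a failure category.

## Smoothing: selective for vertebrae, adaptive for discs

The smoothing stage is the scientific heart of the pipeline. It must remove
stair steps on the *contact* surfaces (where they would corrupt load
transfer), avoid over-smoothing anatomical detail elsewhere, and leave the
disc and vertebra meshes sharing nodes bitwise.

**Interface detection.** Contact is decided vertex-to-vertex: a vertex of
one mesh is an interface vertex if its nearest vertex on the other mesh lies
strictly below a distance threshold. The vertex-to-vertex definition (rather
than vertex-to-surface) is deliberate: the snapping step that follows is
defined on vertices, so detection and snapping use the same metric.
Anatomical thresholds range 0.6–0.8 mm by spinal level; in the original
setting they were tuned by visual inspection, so no closed rule exists. The
package ships a two-value default table (0.6 mm for cervical-range labels
4–7, 0.8 mm otherwise — smaller cervical anatomy warrants the tighter bound)
and treats it as configuration.

**Vertebrae** are processed first: repair, detect the interface sets against
each adjacent (raw) disc mesh — both discs jointly for mid-stack vertebrae —
then Laplacian-smooth *only the interface subsets* (umbrella operator,
`p ← p + w(mean(neighbours) − p)`), reinsert, and finally Taubin-smooth the
whole mesh. Laplacian parameters default to 10 iterations at weight 0.5;
Taubin to λ = 0.5, μ = −0.53, 10 pairs — the classic pass-band choice. Only
positions change; vertex and face counts are invariants of this stage.

**Discs** are smoothed adaptively against the *already smoothed* vertebrae:

1. *Preprocess*: Taubin, then Laplacian over the whole mesh, repair, then a
   dilation along area-weighted vertex normals that compensates the
   Laplacian volume loss. The offset is calibrated per body by bisection so
   the preprocessed volume matches the raw enclosed volume within 1%,
   bounded by 0.5 mm; the bound keeps a pathological mesh from ballooning.
2. *Snap*: every interface vertex is replaced by the coordinates of the
   nearest vertex of the adjacent smoothed vertebra — bitwise, not within a
   tolerance. Two disc vertices may legitimately snap onto the same
   vertebra vertex; they are merged afterwards and the face set is cleaned,
   which keeps the mesh manifold.
3. *Postprocess*: the border ring (vertices within two edge hops of the
   snapped set, excluding it) is Taubin-smoothed to relax the crease where
   the snapped patch meets the free surface, then the mesh is repaired at a
   tolerance (10⁻⁹ mm) that cannot renumber the snapped vertices. Snapped
   vertices are *frozen* throughout postprocessing. Freezing is the design
   choice that preserves the shared-node property; smoothing the border
   without freezing would silently destroy it.

If snapping produces flipped or intersecting faces beyond repair, the body
fails with the `self_intersecting_faces` category rather than propagating a
broken mesh.

Stair steps on circumferential (non-contact) surfaces are deliberately only
softened by the global Taubin pass, never targeted: the contact surfaces are
what the shared-node construction needs, and preserving lateral detail
(osteophytes, edges) is the point of selective smoothing.

## Constrained tetrahedral filling

`fill_volume()` fills a watertight surface with tetrahedra while keeping
every input surface vertex at its exact coordinates (the contract the later
rounded-coordinate node matching relies on):

1. The boundary triangulation is refined by exact midpoint edge splits until
   no edge exceeds 1.5 × the target edge length. Splits are planar, so the
   geometry and enclosed volume are unchanged to the last bit; this is what
   keeps long stair-step edges (up to a slice thickness) from forcing
   high-aspect-ratio boundary tetrahedra.
2. Interior points are seeded on a body-centred-cubic lattice at the target
   spacing (1 mm default, matching a 1 mm global seed), keeping points at
   least 0.7 × the target edge from the nearest boundary vertex, with a
   small (5%) deterministic jitter that breaks the cospherical degeneracies
   a regular lattice would pose for Delaunay.
3. The combined point set is Delaunay-tetrahedralized. The Delaunay kernel
   is SciPy's Qhull binding, called through the Python interpreter on the
   PATH (declared in `SystemRequirements`); the package ships the small
   kernel script and authors everything around it.
4. Tetrahedra are classified by the generalized winding number of their
   centroid; outside ones are discarded. Tetrahedra built purely from
   interior seeds are inside by construction and skip the test. The winding
   number is evaluated with a two-level scheme (exact solid angles for
   nearby face patches, dipole approximation beyond 2.5 patch radii) whose
   classification agreed with the exact evaluation everywhere it was
   compared in the test fixtures.
5. Elements are oriented positively and unused points dropped. The original
   surface vertices are, by construction, the first nodes.

Because the kept boundary facets coincide with the (refined) input
triangulation, the summed element volume matches the surface's enclosed
volume essentially exactly; the acceptance suite requires 0.5% per body.
A "deviation factor"-style curvature refinement knob is unnecessary here
since the boundary is fixed; interior sizing is uniform and isotropic.

`to_quadratic()` converts to 10-node tetrahedra (corners plus one midpoint
per unique edge, edge order 1-2, 2-3, 3-1, 1-4, 2-4, 3-4, the C3D10
layout). Midpoints are exact edge midpoints, so the barycentric-to-physical
map stays affine and corner-based aspect ratios equal full-edge ones.

**Quality metric.** The aspect ratio of an element is max/min over its six
edge lengths; ratios above 5 mark poor elements, and meshes are
conventionally aimed at under 10% poor elements. Cohort statistics
(`summarize_cohort()`) average the poor-element percentage label-wise over
successfully meshed models, excluding failed ones.

## FE model assembly

Volume meshing renumbers nodes, so interface node sets are recovered by
matching coordinates rounded to 3 decimals (micrometres) — far below element
size, far above double-precision noise. An unmatched vertex means the
vertex-retention contract broke and raises a mapping error naming the
vertex. Each body gets superior and inferior node sets, reference nodes
(set member nearest the set centroid, ties to the lowest id), a kinematic
coupling that makes the superior surface rigid, full fixation of every
inferior-set node (solid-element nodes carry three translations each; fixing
all of them also restrains the surface's rigid rotations, which is the
solver-level meaning of a six-degree-of-freedom restraint on a surface), and
a flexion moment, 7.5 N·m by default, applied to the superior reference
node. Model space is millimetres, so the moment is stored as 7500 N·mm and
stresses emerge in MPa. The flexion axis defaults to the world x axis —
orthogonal to the stacking direction and the phantom's anterior–posterior
axis — and is configurable, since "flexion" is anatomical rather than
numeric. The inferior reference node is emitted in the model for downstream
use but not loaded by default.

Materials are linear elastic and isotropic, deliberately simple: vertebra
E = 10 000 MPa, ν = 0.3; disc E = 10 MPa, ν = 0.45. These are configurable
placeholders informed by the literature, not calibrated ground truth, and
the package treats them as configuration. The `material()` domain admits
ν = 0 so the closed-form elasticity oracles (which are exact at ν = 0) can
run through the public type.

Models are exchanged in the ABAQUS/CalculiX `.inp` keyword dialect: node and
element blocks (C3D4/C3D10), named node sets encoding the body name
(`VERT_10_SUP`, …), `*COUPLING`/`*KINEMATIC`, `*ELASTIC`, a static step with
`*BOUNDARY` and a `*CLOAD` on rotational components 4–6. Data lines wrap at
16 entries. The reader inverts the writer exactly on its own output.

## The static solver

The in-package solver replaces an external commercial step with standard
small-strain isoparametric elasticity: constant-strain integration for
4-node tetrahedra, a 4-point interior rule for 10-node ones. The kinematic
coupling is realized by degree-of-freedom elimination through the
small-rotation rigid map `u_i = u_ref + θ × (x_i − x_ref)` — a
transformation matrix rather than Lagrange multipliers, which keeps the
reduced operator symmetric positive definite and small. The linear analysis
justifies the linearized coupling; coupled-set rigidity therefore holds in
the first-order sense (the constraint equation is satisfied to solver
precision; finite vertex-to-vertex distances change at second order in the
rotation). Factorization uses CHOLMOD's supernodal Cholesky; a failed or
ill-conditioned factorization (or a residual above 10⁻⁶ relative) yields a
`converged = FALSE` result instead of an exception, which the pipeline
counts as a `non_convergence` failure — the bookkeeping analogue of failed
solver runs in cohort statistics, not a reproduction of any particular
solver's heuristics. Per-element stresses are quadrature averages; von Mises
values feed the result export (VTU + JSON summary).

Verification relies on closed forms: a patch test (linear displacement
field reproduced to 10⁻⁸ relative, both element orders), a bar under axial
load via the coupling (`FL/EA`, within 1%), a beam under an end moment
(`ML/EI`, within 5% at 1 mm sizing; exact for quadratic elements at ν = 0
since pure bending is a quadratic field), equilibrium of reactions against
the applied 7.5 N·m to 10⁻⁸ relative, and monotone mesh convergence of the
linear-element beam.

## The synthetic phantom: what it emulates and what it does not

Patient data cannot ship with a package, so all cohort-level claims are
exercised on synthetic label volumes. `generate_phantom()` builds a stack of
vertebra bodies (superellipse cross-section, exponent 2.5, lateral semi-axis
ratio 0.8, a mild sinusoidal waist, and an optional posterior lobe standing
in for the posterior processes) and flatter, slightly bulging discs, stacked
in direct voxel contact and voxelized at 1 × 1 × 3 mm by default. `jitter`
perturbs per-body scale, height and center reproducibly from the seed.
Defects are injectable: a 3-voxel island, a disconnecting slice cut, an
enclosed cavity.

Default dimensions (body radius 8 mm, height 12 mm, disc height 4.5 mm,
3 levels) are compact — cervical-scale — so that a 30-subject cohort meshes
at the 1 mm seed in minutes; they were chosen once as the package's study
conditions. At this scale a strongly jittered disc can fall to a single
slice and fewer than 200 voxels, in which case the pipeline screens it as a
small segmentation volume — the same class of event as real thin-structure
segmentation failures, and it is counted as such in cohort summaries.

The phantom reproduces the geometric features the pipeline actually
stresses: stair-step anisotropy, coincident contact surfaces, mixed
convex/concave regions, label conventions, and defect classes. It does not
reproduce vertebral anatomy (processes are a single lobe), MR intensities
(only labels), segmentation noise along boundaries, or pathology. Passing
the cohort tests therefore demonstrates the pipeline's robustness and mesh
quality on anisotropically voxelized multi-body stacks — not segmentation
accuracy on clinical images.

The pipeline's per-subject processing scale is set by the phantom defaults;
the cohort quality statistics in the acceptance script run 30 subjects of
3 vertebrae + 2 discs and 50 single-vertebra subjects, with per-body meshes
of roughly 20 000–50 000 nodes.

## Failure taxonomy

`classify_failure()` maps defects to categories with a deterministic
priority: `disconnected_volumes` > `small_segmentation_volume` > `hole` >
`non_manifold_edges` > `self_intersecting_faces` > `mapping_error` >
`non_convergence`. Voxel-level screens (component count, body size, enclosed
cavity) run before surfacing; mesh-level diagnostics (boundary edges, extra
shells, non-manifold edges, exact triangle–triangle intersection tests
excluding adjacency) cover the smoothing entry; mapping and convergence
categories cover the model stages. One body's failure never touches another
body's results — each body is processed in isolation and the cohort run
continues.

## Known limitations

* Uniform isotropic tetrahedra and a single material per body: no
  cortical/trabecular split, no anisotropic, biphasic or fiber-reinforced
  disc models, no structured annulus meshes. These are modelling choices
  downstream tools can revisit via the `.inp` interface.
* The smoothing threshold table is a stand-in for per-level tuning that was
  originally done by eye; it is exposed as configuration.
* The solver is linear static only; the soft default disc material under the
  default 7.5 N·m moment produces displacements outside the small-strain
  regime, which is acceptable for pipeline verification but not for
  biomechanical interpretation.
* The Delaunay kernel requires a Python interpreter with SciPy on the PATH;
  without one, volume meshing fails with a clean meshing error while all
  voxel, surface and smoothing stages remain fully functional.
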