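---
title: "Recovering 3D cell surface tractions under finite strain: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering 3D cell surface tractions under finite strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tfm3d)
```

# The problem

A cell embedded in a three-dimensional extracellular matrix (ECM) pulls on
its surroundings. Traction force microscopy (TFM) infers those surface
tractions from the motion of fluorescent fiducial beads dispersed in the
matrix: one confocal stack is acquired with the cell contracted (the
*deformed* state), a second after pharmacological relaxation of the
cytoskeleton (the *relaxed*, force-free state). The displacement field that
carries the matrix from the deformed to the relaxed state is measured by
tracking beads between the stacks; the inverse mechanical problem then asks
which traction distribution on the cell surface produces it.

`tfm3d` implements the full chain — bead tracking, segmentation, meshing,
and the inverse solve — under *finite-strain* kinematics with a nonlinear
(Neo-Hookean) material. Matrix deformations around contractile cells easily
exceed the linear regime; linearized reconstructions are known to misstate
tractions by tens of percent at strains of order 50%, which is the regime
this package targets.

# Constitutive model

Both the cell body and the ECM are modelled as the same compressible
Neo-Hookean solid with the volumetric/isochoric split

$$\Psi = C_{10}\,(\bar I_1 - 3) + \frac{1}{D_1}\,(J-1)^2, \qquad
\bar I_1 = \mathrm{tr}\,\bar b,\quad \bar b = J^{-2/3} b,\quad
b = F F^{\mathsf T},\quad J = \det F,$$

with defaults $C_{10} = 20$ kPa and $D_1 = 0.005$ kPa$^{-1}$, i.e. an
initial shear modulus $\mu = 2C_{10} = 40$ kPa and bulk modulus
$\kappa = 2/D_1 = 400$ kPa — a soft, nearly incompressible collagen-scale
medium. The Cauchy stress is the push-forward of $2\,\partial\Psi/\partial C$:

$$\sigma = \frac{2C_{10}}{J}\left(\bar b - \frac{\bar I_1}{3} I\right)
  + \frac{2}{D_1}(J-1)\,I .$$

The test suite verifies this pair against a central-difference derivative of
the energy over random deformation states (relative error $<10^{-5}$), plus
closed forms (pure dilation, simple shear) and objectivity under superposed
rotations.

The choice of a single material for cell and matrix follows the observation
that, within the parameter range of interest, differentiating the two has a
minor effect on recovered tractions. The penalty-form volumetric term
handles near-incompressibility without mixed elements; with $\kappa/\mu = 10$
volumetric locking of linear tetrahedra is mild, and the volumetric/isochoric
energy ratio can be monitored per solve. Fibrillar (strain-stiffening,
compression-softening) collagen models are deliberately out of scope.

# The iterative three-analysis inverse scheme

Let $u_{\mathrm{real}}$ be the measured nodal displacement field on the
imaged (deformed) configuration $\Omega_t$, with the deformed-to-relaxed
sign convention. Each outer iteration runs three mechanical analyses on the
current configuration $\Omega_i$:

1. **Reaction estimate.** The residual displacement target is prescribed on
   all ECM nodes while the cell surface $\Gamma_s$ and cell body are held
   fixed. The reaction forces arising on $\Gamma_s$, flipped in sign and
   divided by tributary areas, give an intermediate traction field $t'$.
2. **Scaling.** $t'$ is applied as a surface load; the response $u'$
   calibrates the scalar $k = \sum_i\|u_{\mathrm{real},i}\| / \sum_i\|u'_i\|$
   and the traction estimate becomes $t = k\,t'$.
3. **Verification.** $t$ is applied; the response $u_{\mathrm{computed}}$ is
   compared to the measurement through the per-node relative error
   $\mathrm{err}_i = \|u_{\mathrm{measured},i}-u_{\mathrm{computed},i}\|
   \,/\, \max_j \|u_{\mathrm{measured},j}\|$.

If fewer than `node_fraction` (default 90%) of the evaluated nodes are below
`delta` (default 0.15), the configuration is updated — nodes move by
$u_{\mathrm{computed}}$, the mesh is quality-restored, the residual target
becomes $u_{\mathrm{real}} - \sum u_{\mathrm{computed}}$ carried per node —
and the loop repeats. This updated-Lagrangian walk drives the geometry from
the imaged deformed state toward the relaxed state; the logarithmic strain
$\ln V$ of each iteration's deformation is recorded with its source mesh.

## Interpretive choices (and why)

The scheme leaves several details open; `tfm3d` resolves them as follows,
each behind an explicit argument:

* **Error target (`err_mode`).** The default compares the *measured field*
  against the *accumulated* computed deformation (the literal reading of the
  error measure: $u_{\mathrm{measured}}$ is the fixed experimental field).
  The alternative — each iteration judged against its own residual target —
  is available (`err_mode = "residual"`), but its normalization degenerates
  as the residual shrinks: a perfectly contracting walk can then never meet
  a fixed threshold.
* **Evaluation node set (`eval_set`).** The criterion is evaluated on the
  cell-surface nodes by default. Far-field nodes carry displacements
  orders of magnitude below the normalizing maximum, so including them
  makes the criterion pass essentially immediately without any fidelity
  where tractions act; the surface is both the hard set and the place where
  error maps are drawn. `"signal"` (all nodes above a relative displacement
  floor) and `"all"` are available, and the final error *distributions* are
  reported both for the surface and for the whole discretization.
* **Clamp distortion in Analysis 1 (`alpha`).** Prescribing the full
  measured field while the surface is clamped shears the one-element
  boundary layer next to $\Gamma_s$; at finite strain this inverts elements
  outright. Analysis 1 therefore applies the largest fraction $\alpha$ of
  the target that keeps every element volume ratio above 0.25. Only the
  spatial pattern of $t'$ matters — the scaling step exists precisely to fix
  its magnitude — so $\alpha$-scaling changes nothing in the linear regime
  and is a mild estimator change beyond it. $\alpha$ is recorded per
  iteration in the convergence trace.
* **Partial loads in Analyses 2–3.** The unscaled reaction field $t'$ is
  often far too strong to apply in full (that is *why* $k \ll 1$ typically).
  If load continuation stalls, Analysis 2 linearly extrapolates the response
  from the largest reached load fraction (it only needs a magnitude), while
  Analysis 3 records the traction actually applied so that the strain
  history and the error check stay consistent.
* **Cell interior.** Interior cell nodes are clamped with the surface in
  Analysis 1 and free elsewhere; tractions are external nodal loads on
  $\Gamma_s$ with both domains elastically active.

# Finite elements, meshing, remeshing

The FE core uses linear 4-node tetrahedra with single-point quadrature
(constant $F$ per element) in a total-Lagrangian formulation per solve,
assembled in C++ with the analytic material tangent
$\mathfrak C = 2\,\partial S/\partial C$. Newton's method uses a backtracking
line search on the residual norm and automatic bisection load stepping;
the default relative residual tolerance is $10^{-8}$ with at most 25
iterations per load step. Linear systems are solved by sparse supernodal
Cholesky (CHOLMOD via the Matrix package) with the symbolic factorization
cached across iterations, and an LU fallback for indefinite tangents met
mid-continuation. Surface tractions are *true* (Cauchy) tractions:
consistent nodal loads are re-assembled on the current deformed interface
at every Newton iteration using one-third-rule tributary areas; the
corresponding load-stiffness term is omitted from the tangent, which the
line search absorbs.

Image-derived geometry is discretized one element per voxel via the
deterministic Kuhn (Freudenthal) 6-tetrahedron subdivision — exactly
volume-conserving and face-conforming, with radius-edge ratio
$\sqrt3/2$ everywhere. There is no external mesh generator: quality
restoration after each configuration update is a constrained smart-Laplacian
smoother that moves only interior nodes (never interface or boundary
nodes), accepting moves that improve the local worst radius-edge ratio.
Connectivity is therefore preserved across the whole inverse run, which
makes per-node residual bookkeeping exact (a Lagrangian identification of
nodes) and reduces inter-mesh field transfer to the identity in the common
case; the general barycentric transfer (with per-element fields first
projected to nodes by volume-weighted averaging) is used for everything
else and is exact for affine fields. Severely deformed configurations near
traction patches can exceed the quality bound even after smoothing; the
remesher then returns its best effort with a warning and a quality report,
and the solver's load stepping carries the burden.

# Imaging pipeline

* **Detection** finds strict 26-neighbourhood local maxima above a
  threshold; **refinement** iterates the squared-intensity centroid of the
  surrounding 7×7×7-voxel subvolume (re-centred each pass, trilinear
  sampling) to subpixel convergence. The subvolume is 7×7×7 *voxels*
  at the 0.63 µm acquisition spacing.
* **Matching** minimizes the sum of squared intensity differences between
  the two stacks over the shift, by integer grid search followed by
  continuous Nelder–Mead refinement. Both subvolumes are sampled at half
  the candidate shift (symmetric sampling), so trilinear interpolation blur
  affects both stacks equally and the first-order bias of the SSD minimum
  cancels; on noise-free synthetic pairs sub-0.1-voxel accuracy follows.
  Shifts whose integer minimum lies on the search boundary are flagged
  unreliable and excluded downstream.
* **Segmentation** is Otsu (or fixed) thresholding, largest 6-connected
  component, 3D interior hole filling.
* **Field building** interpolates the sparse bead displacements to grid
  nodes by k-nearest-neighbour inverse-distance weighting (exact at
  anchors, k = 8, power 2), with no extrapolation: nodes farther than a
  support radius from every anchor stay zero. A Delaunay-based linear
  interpolant would be the natural alternative; no 3D Delaunay backend is
  available to this package, and for the smooth, densely sampled fields of
  interest IDW differs from it well below the tracking noise. The
  *action area* assumption then zeroes node displacements beyond
  `action_radius` (default 10 µm) of the cell surface, tapering with the
  decreasing quadratic weight $w(d) = 1-(d/R)^2$ — 1 at the surface,
  continuously 0 at the frontier. Distances come from an exact Euclidean
  distance transform of the cell mask (Felzenszwalb–Huttenlocher, voxel
  resolution, error ~half a voxel). Voxel $(i,j,k)$ (1-based) is centred at
  $((i-\tfrac12)\,dx, \ldots)$ throughout.

# Final traction recovery

Because each iteration deforms a different configuration, the total
deformation is assembled by transferring the per-iteration $\ln V$ fields
onto the final mesh and summing them component-wise. This additive
treatment is exact for coaxial stretch sequences and first-order accurate
otherwise; `log_strain_additivity_gap()` quantifies the commutator gap for
any two steps, and the tests exercise both the exact (coaxial) and the
flagged (non-coaxial) case. From the accumulated $\ln V$, the kinematics
are rebuilt ($b = e^{2\ln V}$, $J = \sqrt{\det b}$) and the Cauchy stress
follows from the constitutive law; the surface traction is $\sigma\cdot n$
with area-weighted nodal normals.

Two refinements matter at desk-scale resolution:

* The per-iteration tractions act as *surface loads* on $\Gamma_s$, so the
  stress is discontinuous across it. `recover_tractions()` therefore
  projects element stresses to surface nodes separately per side and takes
  the jump, $t = -(\sigma_{\mathrm{cell}} - \sigma_{\mathrm{ECM}})\cdot n$
  (the leading sign reverses the deformed-to-relaxed walk back into the
  cell-exerted traction).
* Single-point linear tetrahedra make pointwise surface stress the least
  accurate quantity in the computation. `recover_tractions_consistent()`
  bypasses it: taking the recovered relaxed configuration as reference and
  reversing the walk, the internal nodal forces of that deformation vanish
  at interior nodes by equilibrium and equal the applied surface load on
  $\Gamma_s$ *exactly*, so dividing by tributary areas yields a traction
  estimate whose only error is the walk's own convergence error. The
  round-trip closure tests use this estimator; the two agree increasingly
  with mesh refinement.

# The synthetic benchmark

`make_sphere_benchmark()` builds the validation problem: a spherical
pseudo-cell of radius 40 µm centred in a rectangular ECM prism
(default 200 µm cube) whose outer surfaces are encastred. Traction patches
are geodesic caps (default 6 caps of 15° angular radius) at seeded-random
surface directions; each carries a constant traction obtained by spreading
a pseudo-random force vector of magnitude `force_scale` over the patch's
reference area (nN over µm² giving kPa directly). The direct finite-strain
problem is solved with load stepping; the deformed mesh and the reversed
displacement field are exactly what the imaging pipeline would hand the
inverse solver, with known tractions for comparison.

The mesh is a structured "spherified cube-shell" grid: concentric cube
shells of the Kuhn lattice are mapped onto spheres near the interface
(exactly spherical at the cell surface) and blend to identity at the fixed
boundary. A stair-stepped voxel sphere would make surface normals — and
hence every $\sigma\cdot n$ comparison — meaningless at practical
resolutions, and its re-entrant corners generate spurious stress
singularities; the smooth structured mesh keeps the voxel pipeline's
determinism while giving the benchmark a well-defined surface. The voxel
path remains the production route for image-derived geometries.

Default conditions: `element_size = 10` µm grid pitch (six tetrahedra per
voxel, ~9.3k nodes — a desk-scale problem that one inverse run completes in
minutes on a single core; the real-data regime of ~400k nodes is reached
only by changing this one number) and `force_scale = 60000` nN per patch,
calibrated once to drive the matrix well into the finite-deformation
regime: local principal stretches exceed 2.5 near the patches and the peak
displacement reaches about a third of the sphere radius. Displacements of
order the radius are reachable at about 2.5x this load, but every doubling
multiplies the continuation steps the follower-load solves need, pushing a
complete round trip far beyond what a single-core validation run should
cost; the default is the largest load whose full direct-plus-inverse cycle
stays in the minutes range. Follower tractions at these strains admit multiple
equilibria at full load, so the traction-driven solves always ramp the load
quasi-statically (initial quarter step) rather than attempting one Newton
solve at full load — a full-load solve can converge cleanly onto a
non-physical branch. The same generator with `force_scale` reduced 100×
provides the near-linear round trip used for closure tests.

`make_bead_stack_pair()` generates deformed/relaxed bead-image pairs with a
known warp: uniformly placed Gaussian blobs with a minimum separation,
optional additive Gaussian noise, and recorded ground-truth per-bead
displacements. It emulates bead density and blob scale, not confocal optics
(no anisotropic PSF, bleaching, or drift) — passing tracking tests bound
algorithmic error, not microscope artifacts.

## What desk-scale validation does and does not show

With the surface criterion ($\delta = 0.15$ at 90% of surface nodes) the
benchmark converges in a handful of outer iterations, mirroring the
published workflow's behaviour on its sphere test. The error that remains
at convergence concentrates at patch edges: constant-strain tetrahedra at
10 µm pitch resolve a 15°-cap traction discontinuity marginally, and the
global scalar $k$ corrects smooth displacement modes much faster than
patch-localized ones (the effective step for a mode of wavelength
$\ell$ scales like $h/\ell$ relative to the smooth content). Refining the
mesh both sharpens the attainable error floor and accelerates the sharp-mode
convergence; the package defaults trade that fidelity for single-core
runtimes. Consequently the benchmark's value at desk scale is the
*round-trip closure* — recovered tractions and displacements against known
ground truth on the same discretization — rather than mesh-converged
absolute accuracy.

# Degenerate inputs and numerical edge cases

Element inversion during assembly signals load stepping rather than
failure; fully-prescribed solves are recognized and evaluated directly
(no Newton); a zero measured field converges in one iteration with zero
tractions; a zero traction estimate aborts the scaling step with a
diagnostic rather than dividing by zero; beads too close to stack borders
are dropped with a logged count; matching minima on the search boundary are
excluded from field building; segmentation failing to find any
above-threshold voxel is an error, as is an anchor set that is coplanar
(the interpolation would be rank-deficient along one axis).

# Known limitations

* One material for cell and ECM; no fibrillar nonlinearity, viscoelasticity
  or active contractility models.
* No regularization of the recovered traction field: the method returns the
  force distribution the iteration converges to, with no sparsity or
  smoothness prior (focal-adhesion masks can be emulated by restricting the
  traction-carrying node set, but none is applied by default).
* The additive log-strain merge is first-order in the non-coaxiality of the
  per-iteration stretches; the gap diagnostic quantifies, but does not
  correct, it.
* Smoothing-based remeshing preserves connectivity; extremely large
  configuration updates that would require topological remeshing instead
  rely on sub-stepping of the update.
* Tracking assumes an isotropic Gaussian-ish bead image and no drift
  between stacks.
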