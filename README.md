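# tfm3d

Three-dimensional traction force microscopy (TFM) under finite strain:
recover the tractions a cell exerts on the extracellular matrix (ECM) it is
embedded in, starting from paired confocal bead-image stacks — one with the
cell contracted, one after pharmacological relaxation — or from fully
synthetic benchmark problems with known ground truth.

The package is aimed at cell-mechanics labs and methods developers who need
a self-contained, scriptable 3D TFM chain that does **not** assume small
strains or linear elasticity: matrix deformations around contractile cells
routinely reach strains of order 1, where linearized reconstructions
misstate tractions badly.

## What it computes

Both the cell and the collagen-scale ECM are modelled as a compressible
Neo-Hookean solid,

$$\Psi = C_{10}(\bar I_1 - 3) + \tfrac{1}{D_1}(J-1)^2,\qquad
\sigma = \tfrac{2C_{10}}{J}\bigl(\bar b - \tfrac{\bar I_1}{3}I\bigr)
 + \tfrac{2}{D_1}(J-1)I,$$

with defaults $C_{10}=20$ kPa, $D_1=0.005$ kPa⁻¹. Given the measured
displacement field $u_{\mathrm{real}}$ on the imaged (deformed)
configuration, an iterative three-analysis loop recovers the surface
tractions:

1. prescribe the residual displacement target on the ECM with the cell
   surface $\Gamma_s$ encastred → interface reaction tractions $t'$;
2. apply $t'$, compare response magnitudes,
   $k=\sum\|u_{\mathrm{real}}\|/\sum\|u'\|$ → scaled estimate $t = k\,t'$;
3. apply $t$, measure the per-node relative error
   $\mathrm{err}_i=\|u_{\mathrm{meas},i}-u_{\mathrm{comp},i}\|/\max_j\|u_{\mathrm{meas},j}\|$.

Until 90% of the evaluated (cell-surface) nodes are below $\delta = 0.15$,
the configuration is updated by the computed displacement
(updated-Lagrangian walk from the deformed toward the relaxed geometry) and
the loop repeats. Logarithmic strains are accumulated across the
per-iteration configurations; the final tractions follow from the
Neo-Hookean stress of the accumulated strain as $t=\sigma\cdot n$
(interface stress jump), with a discretely-consistent reaction-based
estimator available for round-trip validation.

Supporting stages: 3D bead detection with iterative squared-intensity
subpixel refinement (7×7×7-voxel subvolumes), SSD bead matching with
symmetric subvoxel interpolation, Otsu 3D segmentation, voxel→tetrahedron
Kuhn meshing with cell/ECM labelling, action-area masking (quadratic taper
over a 10 µm shell), a finite-strain Newton/load-stepping FE engine
(linear tets, sparse supernodal Cholesky), and VTU/VTP/CSV export for
ParaView.

## Worked example

A synthetic sphere benchmark — a 40 µm-radius pseudo-cell in a constrained
200 µm ECM prism, six seeded-random traction patches — solved forward and
then inverted:

```r
library(tfm3d)

bp <- make_sphere_benchmark(seed = 1)     # direct problem, ~30 s
bp
#> sphere benchmark: radius 40 um in 200x200x200 um box, 6 patches, 9261 nodes
#>   direct solve: max |u| = 14.90 um (0.37 x radius)

st <- run_inverse(bp$deformed_mesh, bp$u_real, bp$material)
convergence_trace(st)[, c("iteration", "k", "err_p90", "frac_below_delta")]
#>   iteration         k   err_p90 frac_below_delta
#> 1         1 0.5493964 0.2798485        0.5388601
#> 2         2 0.3241599 0.2303655        0.7953368
#> 3         3 0.2933887 0.1749602        0.8626943
#> 4         4 0.3404352 0.1576057        0.8937824
#> 5         5 0.3134665 0.1324623        0.9248705

err <- nodal_error_summary(st, "all")
round(c(max = max(err), p95 = unname(quantile(err, 0.95)),
        below1 = mean(err < 0.01)), 4)
#>    max    p95 below1
#> 0.3179 0.0466 0.6953
```

The direct problem is genuinely finite-strain (local principal stretches
beyond 2.5 near the patches) and the run converges in five outer
iterations: the displacement mismatch is below 15% of the peak displacement
at 92% of the surface nodes, and over the whole discretization about 70% of
the nodes are reconstructed to better than 1%. The remaining residual
concentrates at the traction-patch edges,
where the 10 µm elements resolve the traction discontinuity marginally —
see the methods vignette for why this is the governing error source at desk
scale. `recover_tractions(st, bp$material)` returns the recovered surface
traction field (kPa) and `export_results()` writes ParaView-ready VTU/VTP
files.

For real data, the same pipeline is driven from TIFF stacks:

```r
cfg    <- tfm_config()
sparse <- cmd_track(cfg, "deformed.tif", "relaxed.tif")   # bead tracking
mask   <- segment_cell(read_image_stack("cell.tif", channel = "cell"))
vm     <- voxelize(mask, box_dims = c(102, 102, 30))
mesh   <- tetrahedralize(vm)
u      <- build_displacement_field(sparse, mask, vm, action_radius = 10)
state  <- cmd_solve(cfg, mesh, u, "runs/cell01")
```

A thin CLI wrapper with `track`, `solve` and `benchmark` commands lives at
`inst/cli/tfm3d.R` (`Rscript inst/cli/tfm3d.R benchmark --seed 1 --small`).

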