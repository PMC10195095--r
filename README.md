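# myoconduct

Image-based estimation of the anisotropic **intracellular electrical
conductivity tensor** of cardiac tissue — the three bidomain components
σ<sub>myo,l</sub> (longitudinal, along the myocyte long axis),
σ<sub>myo,t</sub> (transverse, within the laminar sheet) and
σ<sub>myo,n</sub> (normal to the interlaminar cleft planes) — from 3D
labeled voxel reconstructions: a myocyte instance segmentation, tissue-class
masks (vessels, fibroblasts, myofibroblasts, clefts) and a connexin43
(Cx43) fluorescence channel.

It is aimed at cardiac modellers and microscopists who want
microstructure-resolved conductivities (e.g. to parameterise bidomain or
monodomain simulations of the normal heart and the infarct border zone)
rather than homogenised literature values.

## Method in brief

1. **Gap junctions.** Threshold the Cx43 channel at the image mode +
   4.5 SD; isolate myocytes with a one-voxel separating membrane layer;
   project each supra-threshold voxel within 1 µm onto its nearest membrane
   voxel; membrane voxels shared by two myocytes become gap-junction voxels
   attributed to that pair.
2. **Calibration.** A gap-junction voxel of edge *l* and face area *A*
   receives σ<sub>gj</sub> = G<sub>pair</sub>/N<sub>gj,control</sub> · *l/A*,
   with G<sub>pair</sub> = 1.24 µS the reference conductance of a normal
   myocyte pair and N<sub>gj,control</sub> the mean coupled-voxel count per
   pair in control stacks.
3. **Conductivity model.** Myocyte voxels → σ<sub>cyto</sub> (0.86 S/m
   default), gap-junction voxels → σ<sub>gj</sub>, everything else 0 S/m.
4. **Poisson solve.** For each axis, ±1 V plate electrodes and
   ∇·(σ∇φ) = 0 on a flux-conservative 7-point stencil (harmonic-mean face
   conductances, residual < 1e-10, multigrid-preconditioned conjugate
   gradients); the directional conductivity is
   σ<sub>dir</sub> = mean(J<sub>dir</sub>)/E<sub>dir</sub>, the mean axial
   current density over full cross-sections divided by the applied field.

A synthetic brick-myocyte tissue generator (with exact per-pair junction
ground truth, staggered/truncated myocytes, cleft planes, inclusions, and
control / infarct border-zone presets) provides the fully characterised
test bed, including a closed-form conductivity reference that the solver
matches to better than 1e-10 S/m in its exact regime.

## Worked example

```r
library(myoconduct)

# synthetic control-preset stack: 63 x 120 x 63 voxels at 1 um
tis <- generate_brick_tissue(brick_preset("control", seed = 1))

# Cx43 -> gap-junction map, and sigma_gj calibration from the pair counts
gjp <- derive_gap_junctions(tis$segments, tis$cx43)
cal <- calibrate_sigma_gj(gjp$gj$pair_counts, grid = tis$segments$grid)
cal
#> <gj_conductivity> sigma_gj 0.09912 S/m (pair conductance 1.24 uS, N_gj 12.51, l 1000 nm)

model  <- build_model(gjp$isolated_segments, gjp$gj,
                      sigma_cyto = 0.86, sigma_gj = cal)
tensor <- estimate_tensor(model)
tensor
#> Intracellular conductivity tensor estimate (S/m)
#>   longitudinal (y): 0.310376
#>   transverse   (z): 0.0315751
#>   normal       (x): -3.52519e-13

quantify_stack(tis$segments, tis$labels, gjp$gj)
#> <tissue_features> Vmyo 64.59% Vvessels 4.83% Vfibro 2.93% Vmyofibro 0.10% Ve 27.55%
#>   Vgj 0.1287%  dl 0.1 deg  dn 0.0 deg
```

Reading the output: current flows easily along the myocyte chains
(0.31 S/m), an order of magnitude less across them through sparse lateral
junctions (0.032 S/m), and not at all across the interlaminar cleft planes
(σ<sub>myo,n</sub> ≈ 0: the clefts interrupt every sheet-normal path, a
configuration this tissue preset shares with most real stacks). The
feature line gives the volume fractions entering the closure identity
Ve = 100 − (Vmyo + Vfibro + Vmyofibro + Vvessels) and the orientation
checks (myocyte axis within 10° of y, cleft normal within 30° of x) used
to exclude poorly aligned stacks.

A thin CLI over the same functions is installed at
`inst/exec/myoconduct` (subcommands `synth`, `substacks`, `gj`,
`features`, `solve`, `stats`; volumes travel as multi-page TIFF with a
YAML sidecar).

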