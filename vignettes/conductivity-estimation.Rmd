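---
title: "Estimating intracellular conductivity tensors from labeled tissue volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intracellular conductivity tensors from labeled tissue volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Cardiac tissue conducts intracellular current through the cytoplasm of
myocytes and through gap junctions — connexin43 (Cx43) channel clusters —
that couple neighbouring cells. In the bidomain description of cardiac
electrophysiology, this intracellular pathway is summarised by an
anisotropic conductivity tensor with three principal components tied to the
tissue microstructure: longitudinal (along the myocyte long axis, the y
image axis here), transverse (across the myocytes but within a laminar
sheet, z), and sheet-normal (across the interlaminar cleft planes, x).

`myoconduct` estimates these three components from 3D labeled voxel
reconstructions of tissue. The chain is:

1. **Gap-junction derivation.** The Cx43 fluorescence channel is
   thresholded at the image mode plus 4.5 standard deviations. Myocyte
   labels are dilated three times (26-neighbourhood) so that adjacent cells
   come into contact, then isolated again so that exactly one voxel of
   separation remains; the one-voxel shell around the isolated myocytes is
   the candidate membrane. Each supra-threshold Cx43 voxel within 1 µm of
   that shell is projected onto its nearest shell voxel; shell voxels that
   receive signal *and* touch two distinct myocytes become gap-junction
   voxels, attributed to that myocyte pair.
2. **Conductivity calibration.** A single gap-junction voxel of edge `l`
   and face area `A` receives the conductivity
   `sigma_gj = G_pair / N_gj * l / A`, where `G_pair = 1.24 µS` is the
   reference whole-pair conductance of normal ventricular myocyte pairs and
   `N_gj` is the mean number of coupled voxels per coupled pair in control
   stacks. This makes the *average* junction between two cells carry the
   measured pair conductance regardless of voxel size.
3. **Conductivity model.** Myocyte voxels get the cytoplasmic conductivity
   (0.86 S/m by default), gap-junction voxels get `sigma_gj`, everything
   else (extracellular space, vessels, fibroblasts, myofibroblasts,
   clefts, uncoupled membrane) is non-conducting.
4. **Poisson solve.** For each axis, ±1 V plate electrodes are applied to
   the opposite domain faces and `div(sigma grad phi) = 0` is solved;
   the directional conductivity is the mean axial current density over full
   cross-sectional planes divided by the applied field
   `E = 2 V / length`. Averaging over the *full* plane (non-conducting
   area contributes zero current) makes the result an effective
   tissue-scale conductivity rather than an intra-myocyte one.

## Numerical scheme

The discretization is a flux-conservative 7-point finite-volume stencil on
the voxel grid. Face conductances are harmonic means of the two adjacent
voxel conductivities — the standard well-posed choice for piecewise-constant
coefficients, and the one that reproduces series-resistor compositions
exactly on axis-aligned interfaces. Electrode potentials act on ghost faces
at half-cell distance, so a homogeneous bar returns its own conductivity
exactly and the electrode-plane current equals every interior plane current
(Kirchhoff conservation, asserted plane-by-plane in the tests).

Voxels that no path connects to either electrode would make the linear
system singular; a 6-connected region growing seeded at both electrode
planes removes them first. Face (6-) connectivity is used rather than
26-connectivity because current only flows through stencil faces — a
diagonally-touching voxel carries no current.

The system is symmetric positive definite. Small systems (up to 150 000
unknowns by default) are solved by sparse Cholesky factorization; larger
ones by conjugate gradients preconditioned with one V(1,1)-cycle of an
aggregation multigrid hierarchy (2×2×2 voxel aggregates, Galerkin coarse
operators, symmetric Gauss–Seidel smoothing). The convergence contract is
the residual norm below `tol` (default 1e-10, in conductance-scaled units
where face conductances are `sigma`-valued and the common geometric factor
`A/l` is divided out); the preconditioner never affects the answer, only
the iteration count, and the residual is always re-verified against the
plain stencil operator. Potentials on non-conducting voxels are stored as
`NA` and excluded from every reduction.

Two values for the cytoplasmic conductivity circulate in the experimental
literature for this preparation (0.86 and 0.89 S/m); the package defaults
to 0.86 S/m and exposes `sigma_cyto` everywhere, so either convention is a
one-argument change.

## The synthetic test bed

Real microscopy reconstructions are not distributable with the package, so
all end-to-end validation runs on `generate_brick_tissue()`: densely packed
axis-aligned brick myocytes separated by thin extracellular walls, with

* end-to-end and side-to-side Cx43 patches of exactly `n_gj_end` /
  `n_gj_side` voxels per realized junction face (positions sampled
  uniformly without replacement; the truth record keeps the per-pair
  counts);
* optional staggering of the longitudinal brick phase between columns, with
  bricks truncated at the stack borders (they keep their IDs);
* interlaminar cleft planes carved along selected x walls;
* vessel / fibroblast / myofibroblast blocks placed randomly without
  overlap until target volume fractions are met within one percentage
  point;
* an optional in-plane rotation of the long axis for testing the
  orientation features.

The `control` and `mi` presets encode the two study conditions: the MI
(infarct border zone) preset has wider walls (lower myocyte fraction),
junction counts scaled by 0.4 (reproducing the roughly 0.03 % vs 0.07 %
gap-junction volume fractions), denser and thicker clefts, and added
fibroblast/myofibroblast inclusions.

What the generator deliberately does **not** emulate: realistic myocyte
shapes, the t-tubular system, image noise and point-spread blur, or
segmentation errors. Tests passing on this geometry therefore validate the
measurement pipeline — thresholding, projection, calibration,
discretization, solving, statistics — not the upstream segmentation of real
images.

## Closed-form reference and its exact regime

For an untruncated, unstaggered lattice the effective conductivity has a
series/parallel closed form: along a direction, one period is the myocyte
span at `sigma_cyto` in series with a one-voxel junction layer whose
conducting area is the junction voxel count at `sigma_gj`, the whole scaled
by the conducting cross-sectional area fraction
(`analytic_conductivity()`). Two points deserve care:

* **Exactness.** When the junction patch covers the *full* shared face,
  every voxel column between the electrodes carries the same series
  profile, no lateral currents flow, and the discrete solution equals the
  closed form to solver precision — the ghost-face electrode convention
  makes the per-column discrete resistance telescope to the plain sum
  `sum(l / sigma_i)`. This is the regime used for the analytic-agreement
  validation (observed agreement ~5e-14 S/m on a 64×127×64 lattice, well
  inside the 1e-10 S/m target). For *partial* face coverage the closed
  form smears the junction over the face and neglects constriction
  (current-spreading) resistance, making it an upper bound; the solver is
  validated in that regime against an independent dense Kirchhoff solve on
  small fixtures instead.
* **Finite stacks.** The closed form is evaluated for the finite generated
  domain (which must start and end with a full myocyte along each axis),
  counting `n_bricks - 1` junction layers — this is the configuration the
  electrode solve actually sees.

## The stack-length study

To quantify how stack length affects the longitudinal conductivity when
myocytes bridge the whole stack or are truncated at its borders, the
package re-runs the size study on synthetic tissue: 80×20×20 µm myocytes at
1 µm voxel spacing, one-voxel walls, stagger fraction 0.4 (which spreads
five distinct longitudinal phases over the 3×3 myocyte columns of a
63×63 µm cross-section), 60-voxel end patches and 40-voxel side patches,
`sigma_gj` calibrated once from the 400 µm reference stack, stack lengths
100–400 µm with three seeds each. The five staggered phases keep each
column's junction count close to `length / period` at every stack length —
a resistor-chain argument made before running the study — so the 100 µm
stacks are expected to stay within the 10 % band around the 400 µm mean;
the measured maximum deviation is ~9.8 %.

Problem sizes throughout (about half a million voxels for the analytic
lattice, up to 1.6 million for the 400 µm stacks, ≤ 10³ voxels for the
dense-oracle fixtures) were chosen so that a complete validation run takes
a few minutes on a single CPU; all statistics of interest are well
converged at these sizes.

## Tissue features and exclusion

Volume fractions divide class voxel counts by stack voxels; the
extracellular fraction closes the identity
`Ve = 100 - (Vmyo + Vfibro + Vmyofibro + Vvessels)`, with clefts counted
inside `Ve` but reported separately. Fibrosis is defined *relative to the
control group*: `Vfibrosis = (Ve + Vfibro + Vmyofibro) - control mean of
the same sum`, which forces a control-group mean of exactly zero and allows
negative control values.

Myocyte orientation takes the ten largest myocytes by volume, computes each
principal axis from the second-order central moments, flips all axes into
the non-negative-y hemisphere (axes are directionless, so averaging needs a
consistent hemisphere), averages the unit vectors, and reports the angle to
y. Averaging vectors rather than angles is well-defined for the small
spreads that matter here. The cleft-plane normal is the
smallest-eigenvalue eigenvector of the largest 26-connected cleft
component's moments ("largest cleft plane" is not operationally defined
otherwise; the largest connected component by voxel count is the recorded
choice, noted in the output). Stacks with `delta_l > 10°` or
`delta_n > 30°` (strict inequalities) are flagged as excluded.

Degenerate cases are pinned down deterministically: eigenvector order
follows the LAPACK convention (eigenvalues descending), sign ambiguity is
resolved toward +y (then +x, then +z), and a spherically symmetric segment
yields a repeatable, documented value rather than a random one.

## Isolation: why one voxel, and why one-sided

The gap-junction definition requires membrane voxels *shared* by two
myocytes in a 26-neighbourhood, which is only satisfiable if adjacent
myocytes are separated by exactly one voxel. Clearing every voxel adjacent
to a different label — the naive reading of the isolation step — removes a
layer from *both* sides of a contact and leaves a two-voxel gap in which no
voxel touches both cells, making the gap-junction volume identically zero.
The package therefore (a) dilates with a conflict barrier, so a background
voxel adopts the unique adjacent label and voxels reached by two labels
stay background (an existing one-voxel wall survives dilation unchanged),
and (b) carves only the larger-ID side of any remaining direct contact.
Both passes are order-independent and deterministic, and the pipeline then
reproduces the generator's wall geometry exactly, which is what makes
exact truth-recovery tests possible.

## Statistics

Feature–conductivity relationships use ordinary least squares with the
F-test against the intercept-only model; effect sizes are weak
(R² < 0.3), moderate (0.3 ≤ R² ≤ 0.5, boundaries inclusive as printed) and
strong (R² > 0.5). Control and MI are reported separately when
significance holds in exactly one group but not combined, or when the two
R² values differ by more than 0.1. Group comparisons use Student's
pooled-variance two-sample t-test (the specific two-sample variant is
recorded in the output), with `mean ± SD` summaries; no multiple-testing
correction is applied, matching per-test reporting at p < 0.05.

## Known limitations

* No myocyte–non-myocyte electrical coupling: fibroblasts and
  myofibroblasts are insulators here, although coupling is reported in
  diseased tissue.
* The pair-conductance calibration assumes one reference value for all
  pairs; plaque-size-dependent conductance is not modeled.
* HDF5 container I/O is not available in this build; volumes travel as
  multi-page TIFFs with a YAML sidecar for spacing and kind.
* The closed-form reference is exact only for full-face junction layers;
  partial-face geometries are validated numerically, not analytically.
* Real-image effects (noise, blur, segmentation error) are outside the
  synthetic test bed, as noted above.
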