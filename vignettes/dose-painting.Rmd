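---
title: "Voxel-wise dose painting by numbers: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise dose painting by numbers: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, and the
numerical decisions taken where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The planning model

Dose painting by numbers (DPBN) replaces the uniform dose of a contoured
target with a per-voxel prescription driven by the PET standardized
uptake value (SUV). `paintbox` uses the linear min–max relation

$$D_i \;=\; D_{\mathrm{low}} + \frac{\mathrm{SUV}_i - \mathrm{SUV}_{\min}}
{\mathrm{SUV}_{\max} - \mathrm{SUV}_{\min}}\,
(D_{\mathrm{high}} - D_{\mathrm{low}}),$$

normalized over the segmented target mask, with defaults
$D_{\mathrm{low}} = 70$ Gy and $D_{\mathrm{high}} = 82$ Gy over a
30-fraction course. The exact functional form of the SUV-to-dose relation
is a modelling choice; min–max normalization is adopted because it pins
both endpoints exactly (the minimum-SUV voxel receives the baseline
prescription, the maximum-SUV voxel the full escalation) and because it
is invariant to affine rescalings of the SUV map. A constant-SUV target
degenerates to the uniform baseline dose — the conventional plan is the
special case. For tracers whose biology is not monotone in uptake (e.g.
hypoxia imaging) the linear relation would have to be replaced; the rest
of the chain is agnostic to it.

The plan itself is the solution of a linear program over aperture
weights $\omega_j \ge 0$:

$$\min \; P_{T,\max}\textstyle\sum_i x_i + P_{T,\min}\sum_i y_i +
P_{\mathrm{OAR},\max}\sum_i x_i$$

subject to, for every target voxel $i$ and every prescription map $m$
stacked on it,

$$\textstyle\sum_j \omega_j d_{ij} - x_{i,m} \le D^m_{i,\max}\Delta^m_{\max},
\qquad
\sum_j \omega_j d_{ij} + y_{i,m} \ge D^m_{i,\min}\Delta^m_{\min},$$

and $\sum_j \omega_j d_{ij} - x_i \le D_{\mathrm{OAR},\max}$ for
organ-at-risk voxels, all slacks non-negative. Three properties matter:

* **Feasibility is unconditional.** The slacks absorb any conflict, so
  stacking contradictory maps (the "robust" mode) is well-posed: the
  optimizer returns the compromise that minimizes the penalty-weighted
  violation, voxel by voxel.
* **The similarity factors are the robustness dial.** With
  $\Delta_{\min}/\Delta_{\max} = 0.97/1.03$ each voxel owns a ±3% band
  rather than an equality; the optimizer is free inside the band. The
  defaults equal the tightest quality-index tolerance reported for such
  plans; they are per-map configurable.
* **Degenerate stacks are allowed.** After stacking, a voxel may end up
  with a floor above its ceiling; the LP simply pays for the gap. This
  is intended behaviour, not an error.

Default penalties are $P_{T,\max} = P_{T,\min} = 1$,
$P_{\mathrm{OAR},\max} = 0.5$: target fidelity is the primary objective
and the OAR term is a soft guard (the caps themselves do the clinical
work). No published penalty values exist for this formulation; these are
package defaults and all three are exposed in `lpConfig()`.

## The LP solver

No linear-programming engine is available in the package's dependency
envelope, and the problem has a structure worth exploiting anyway: with
$R$ constraint rows and $M$ apertures ($M \ll R$), the standard-form
system is $[G, -I, I]$ with $G$ the signed dose rows. The package
implements a Mehrotra predictor–corrector interior-point method in which
the normal-equations matrix $G D_\omega G^\top + E$ is inverted through
the Woodbury identity, so every Newton step costs one $M\times M$
Cholesky plus $O(R)$ diagonal work; problems with tens of thousands of
rows and ~100 apertures solve in seconds.

Numerical choices, in the order they bite:

* **Convergence** is declared at relative duality gap and scaled
  primal/dual residuals below `tol` (default $10^{-9}$), iteration cap
  200.
* **Ill-conditioning near the optimum** (diagonal ratios up to the cap
  $10^{10}$) is handled with iterative refinement of every Woodbury
  solve against the exact operator, a best-iterate safeguard, and a
  blow-up guard that stops the iteration when a step destroys more than
  it gains.
* **Polish.** The returned weights are refined by an active-set weighted
  least-squares step, accepted only when the *exact* piecewise-linear
  objective decreases. On feasible instances (objective zero) this takes
  the weights from interior-point accuracy (~$10^{-5}$) to near machine
  precision, which is what makes the zero-objective certificate sharp.
* **Reported slacks** are the analytic optimum given the weights
  ($x = \max(0, d^\top\omega - U)$ etc.), so the reported objective is
  exact for the reported $\omega$. `recoverSlacks()` recomputes the same
  quantities through an independent code path and is used as the
  solver's oracle in the tests, alongside a vertex-enumeration brute
  force on tiny random instances.
* **Apertures with no influence on any constrained voxel** are free
  variables of the LP; they are fixed at weight zero before the solve.
* **Ties/degeneracy.** Weights on a degenerate optimal face are not
  unique; determinism is asserted on the objective and the dose, never
  on individual weights.

## What the phantoms emulate — and what they do not

The synthetic module defines the study conditions; its defaults are
fixed and the tests run against them.

**Geometry.** Two phantoms: a *tube phantom* (0.3 ml sphere, plus a
0.3 ml sphere nested in a 2.0 ml vial to mimic heterogeneous uptake;
activity concentrations in the ratio of 0.116 MBq/0.3 ml to
0.1 MBq/2 ml, zero background) used for the interpolation-chain study,
and a *head-and-neck-like phantom* (three separate lesions of 4, 2, and
1.4 ml at SUV 8, 6 and 10, the largest carrying a 0.5 ml hot core at
SUV 12; an elliptic tissue outline; a spinal-cord-like cylinder with a
50 Gy cap) used for planning. Ground truth lives on a 1.5 mm isotropic
grid (89×89×61 voxels).

**Reconstruction emulation.** A protocol is emulated as Gaussian blur of
fwhm $\sqrt{\mathrm{psf}^2 + \mathrm{filter}^2}$ in world units,
linear resampling onto the protocol grid, then multiplicative Gaussian
voxel noise. The two built-in protocols are the EARL-harmonized one
(3.2×3.2×5 mm voxels, 6 mm post-filter) and the high-resolution
PSF-reconstruction one (1.6×1.6×1.5 mm voxels, 3 mm post-filter). The
intrinsic psf fwhm is not a published quantity; the defaults — 4.5 mm
for the harmonized protocol, 2.0 mm for the resolution-modelled one —
encode that PSF reconstruction recovers part of the scanner blur while
the harmonized protocol deliberately does not. Noise is voxel-wise at
CV 0.05 by default. This emulation reproduces the *effects* that matter
to planning — partial-volume peak depression, resolution-dependent
segmentation, non-scalable differences between protocols — and nothing
of scanner physics: no sinograms, no attenuation or scatter, no
iterative-reconstruction texture (real OSEM noise is spatially
correlated; the voxel-wise noise here is white, which is the harsher
condition for voxel-wise planning). Passing tests therefore certify the
planning chain under controlled conditions, not PET quantification
itself.

**Follow-up imaging** applies per-lesion multiplicative activity changes
and zeroed sub-regions on the same grid. No morphological change is
modelled, which is exactly the assumption that makes voxel-wise dose
accumulation across phases a plain weighted sum.

## Grids, resampling and the interpolation chain

Grids are axis-aligned lattices; the world coordinate of voxel index
$(i,j,k)$ (0-based) is $\mathrm{origin} + (i,j,k)\cdot\mathrm{spacing}$.
Resampling samples the source at target voxel centres with nearest,
trilinear, or tricubic B-spline interpolation (tridiagonal prefilter,
mirror boundary); all three reproduce node values exactly on the
identity grid, and points outside the source extent take fill value 0.
Interpolated physical fields are clipped at 0 to keep SUV/dose/density
volumes valid.

The interpolation-chain study crosses first-stage (PET→CT) and
second-stage (CT→dose-grid) methods and reports measured lesion volumes
and percent deviations at both stages. Lesions are measured by
thresholding at 50% of the observed local peak (capped at the nominal
fill level) and keeping the 26-connected component at the lesion centre;
an empty segmentation is reported as −100%, not an error. The planning
pipelines follow the chain this study favours: cubic-spline fusion onto
the CT grid, nearest-neighbour onto the dose grid. The fusion stage
matters: prescriptions carried to the dose grid directly from the
coarse-voxel protocol arrive as staircases that no smooth deliverable
dose can track.

## Beams, apertures and the dose engine

Seven equispaced coplanar beams by default (the beam count is not a
published quantity). Aperture generation is image-driven: the prescribed
dose over the union target is quantized into `nBands = 4` nested bands
(equally spaced thresholds between the target's dose extremes), each
band is projected onto each beam's fluence plane by parallel-ray
tracing, and each projection row becomes one open MLC leaf interval
(convex hull of its open pixels; leaf width 5 mm, fluence pixel 2 mm).
Per beam, the pool holds the conformal silhouette, dilated copies
(+3/+6 mm, to own the penumbra at the target edge), eroded copies
(−2/−4/−6 mm), and each band with the same erosion ladder; dilation and
erosion act in both fluence-plane directions. Fully closed shapes are
dropped. This yields ~90–130 apertures for the default phantom. Banding
exists only to *generate shapes*; the LP always optimizes against the
per-voxel prescription.

The dose engine is a three-parameter pencil-beam model: dose =
outputFactor · exp(−μ·radiological depth) · (aperture fluence ⊗ lateral
Gaussian), with μ = 0.005/mm and σ = 4 mm by default — clinically shaped
megavoltage depth and penumbra curves with an analytic oracle
(exponential depth dose in water, flat in air). Radiological depth is
the density-weighted path length computed by resampling the CT onto a
beam-aligned lattice and accumulating along the beam direction.
Influence-matrix entries below $10^{-6}$ of their column maximum are
truncated to preserve sparsity. Monte Carlo transport, leaf-end effects
and delivery-time modelling are out of scope by design; the engine's
job is to make the optimization problem realistic, sparse and exactly
linear.

## Evaluation and adaptation

Q is planned/prescribed dose per target voxel; QF = 100·mean|Q−1|;
tolerance fractions use strict inequalities (0.97 < Q < 1.03 and the
4%/5% analogues). The conformity index is read as *coverage*: the
fraction of the structure receiving at least 95% of its own per-voxel
prescription — the literal isodose-to-volume ratio can exceed 100%,
whereas all reported values of the index are percentages of the target,
so coverage is the consistent interpretation. QVH bins are 0.01 in Q,
DVH bins 0.1 Gy.

Replanning builds apertures from the follow-up prescription, discards
those geometrically identical to a pool member, and re-solves the LP
over prior-plus-new apertures with the prior weights as a warm start —
so replanning against an unchanged prescription provably cannot worsen
the objective, and a shrinking target yields few new apertures. Phase
doses (each planned as a total-course dose) accumulate per voxel with
fraction weights (e.g. 17/30 and 13/30); the accumulated dose is
evaluated against the identically weighted blend of the phase
prescriptions, over voxels prescribed in every phase. How to anchor Q
for voxels that leave the target between phases is genuinely open; the
intersection convention is the conservative choice and is confined to
`accumulatePhases()`.

## Problem sizes and runtimes

The default study conditions were chosen once: truth grid 1.5 mm
(89×89×61), dose grid 3 mm isotropic (45×45×31, ~63k voxels), ~180–200
target voxels on the dose grid, 7 beams, ~85 apertures after drops. One
default plan takes about a minute on one core; the full test suite a few
minutes. These sizes are the package's reference configuration — large
enough to exhibit partial-volume and co-registration effects, small
enough to iterate on.

## Known limitations

* The pencil-beam engine has no build-up region and parallel-ray
  geometry by default; absolute dose scale is arbitrary (weights absorb
  it).
* Threshold segmentation stands in for clustering-based PET
  segmentation; multifocality is handled, diffuse-boundary modelling is
  not.
* White voxel noise overstates the high-frequency content of
  reconstructed PET; plan-quality figures under correlated noise would
  be slightly more favourable.
* OAR toxicity caps are package placeholders (50 Gy for the cord
  surrogate), not clinical values.
* No DICOM-RT I/O; NIfTI and the native container are the interchange
  formats.
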