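---
title: "Measuring force and motion in confined cell islands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring force and motion in confined cell islands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandmech)
```

# The measurement chain

`islandmech` analyses time-lapse microscopy of epithelial monolayers
confined to circular micropatterned islands (the reference assay uses 1 mm
islands of MDCK cells on 6 kPa polyacrylamide). Three quantities are
extracted, each feeding the next:

1. **Motion** — subset-based digital image correlation (DIC) of consecutive
   phase-contrast frames gives cell velocity fields; correlating each
   fluorescent-particle frame against the traction-free reference image
   (taken after trypsin release) gives substrate displacement fields.
2. **Traction** — the substrate is an elastic half-space of known Young's
   modulus $E$, so per Fourier mode the tangential surface displacement
   $\hat u$ and traction $\hat T$ are related by the Boussinesq kernel
   $\hat u = G(\mathbf k)\hat T$ with
   $$G(\mathbf k) = \frac{2(1+\nu)}{E k^3}
     \begin{pmatrix}(1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y\\
                    -\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2\end{pmatrix},$$
   inverted mode by mode (Fourier-transform traction microscopy).
3. **Stress** — monolayer stress microscopy: in-plane force balance of the
   sheet of height $h$,
   $$\partial_x \sigma_{xx} + \partial_y \sigma_{xy} = T_x/h,\qquad
     \partial_x \sigma_{xy} + \partial_y \sigma_{yy} = T_y/h,$$
   closed by compatibility of the strain rates and the linear constitutive
   law
   $$\sigma_{ij} = (K_1 - \tfrac23 K_2)\,\dot\varepsilon_{kk}\,\delta_{ij}
     + 2K_2\,\dot\varepsilon_{ij},$$
   solved with plane-stress bilinear finite elements on the island mask.

The same linear system covers the elastic reading (strains, moduli) and the
viscous reading (strain rates, viscosities): the stresses are obtained by
applying $K^{-1}$ and then $K$, so the magnitude and units of the
constitutive constants cancel, and by the viscoelastic correspondence
principle the result applies to any linear viscoelastic sheet. Only the
dimensionless ratio
$$\nu_m = \frac{K_1 - 2K_2/3}{K_1 + 4K_2/3}$$
(the Poisson ratio, for an elastic material) enters, and its influence on
the recovered tension is modest; `k_to_nu()` documents the mapping and
`solve_stress(..., ratio_nu_m = )` exposes the ratio directly.

# Sign conventions

Conventions are fixed once, here, and enforced by tests:

* Grids are image-style: x right, y **down**, pixel centers at
  $0, 1, \dots$ times the pixel size. Radial/tangential decompositions are
  taken from the mask centroid.
* $T$ is the traction the **cells exert on the substrate**. The force
  balance above then reads $\nabla\cdot\sigma = T/h$, and the finite
  element load vector is assembled from $-T/h$. With this choice an island
  under tension (positive $\sigma$, decaying outward) pulls **radially
  inward** at its edge, which is what contractile monolayers do; the
  equivalent statement is that edge cells pull themselves toward the free
  space.
* Contractile tension is $(\sigma_1+\sigma_2)/2 = (\sigma_{xx} +
  \sigma_{yy})/2$, positive in tension.

# The synthetic generator

Every inverse stage is validated against `synthesize_island()`, which runs
the forward model: velocity field → strain rate → stress → traction →
substrate displacement → rendered speckle images.

* **Random mode** low-pass filters white noise (Gaussian kernel of the
  requested correlation length), tapers it to zero with a cosine ramp that
  ends three pixels *inside* the mask edge, and normalizes the RMS speed
  inside the island. Because the stress is built from an actual velocity
  field through the constitutive law, it satisfies compatibility exactly —
  on the generating grid the discrete compatibility residual is zero to
  machine precision because centered-difference operators commute — which
  makes it the reference input for the stress-recovery test. The taper
  margin matters: ending the taper exactly at the mask edge leaves a ring
  of stress divergence straddling the boundary, which clips to an O(1%)
  inconsistency that stalls grid convergence of the recovery.
* **Contractile mode** emulates a real island: a slow radially inward
  drift velocity (the kinematic observable) together with a prescribed
  active isotropic tension $p(r) = \sigma_0 \tfrac12(1 + \cos(\pi r/R_e))$.
  The tension is *not* derived from the drift through the constitutive
  law: active stress is set by actomyosin contractility, not by the slow
  passive flow, and any stress derived from a velocity field that vanishes
  at the island edge necessarily integrates to zero mean tension (its
  trace integral reduces to a boundary flux of velocity), which would
  contradict the tensile state of real islands.

Defaults emulate the experimental conditions at desk scale: 256×256 grids,
a circular island filling ~62% of the image width, pixel size 0.65 µm (the
experiments resolve 12 px = 7.9 µm and 8 px = 5.2 µm grid spacings at this
magnification), $E$ = 6000 Pa, frame interval 10 min, peak active tension
200 Pa and drift speeds of ~0.1–0.3 µm/min. Speckle images use 0.03–0.08
particles/px² with Gaussian spots of σ ≈ 1.2 px, rendered analytically so
image pairs carry no resampling artifacts; the experimental particle
density after centrifugation is not documented, so the density is a free
parameter.

What the generator does **not** emulate: phase-contrast cell texture,
nuclei, image noise and illumination drift, discrete cell shapes, and
out-of-plane displacements. Passing tests therefore demonstrate the
correctness of the operators and conventions, not robustness to every
experimental artifact.

# Numerical choices

* **DIC.** Normalized cross-correlation per subset (FFT numerator,
  integral-image normalization), 3-point Gaussian subpixel fit per axis,
  quality = peak correlation with a 0.5 threshold; flagged nodes are
  filled by iterated neighbor averaging before the Fourier inverse, which
  needs complete fields. Defaults mirror the experimental analysis (48
  px/12 px subsets for cells, 32 px/8 px for particles). An optional
  warp-and-recorrelate second pass (`refine = TRUE`, bicubic image
  warping) removes the subset-averaging bias of strongly curved fields;
  the default is a single pass. Whether the original analysis dropped or
  filled low-quality subsets is not documented; the threshold-and-inpaint
  behavior here is this package's stated default. Stage-drift
  pre-alignment is available but off by default.
* **FTTC.** The zero mode (rigid translation) is set to zero in both
  directions; displacements are therefore defined up to a constant, and
  comparisons against the free-space Green's function are made modulo that
  offset. The odd shear coupling $-\nu k_x k_y$ is zeroed on the unpaired
  Nyquist row/column so that real fields map to real fields exactly, which
  makes `fttc_inverse(fttc_forward(T))` an identity at $\lambda = 0$.
  Tikhonov regularization $(G^TG+\lambda^2 I)^{-1}G^T$ is available but
  the default is $\lambda = 0$. Zero-padding and a cosine border window
  are options (recorded in the output metadata) and default off: synthetic
  islands carry a built-in zero margin, and the reference datasets' exact
  windowing is not documented. The half-space assumption is justified by
  the 100–120 µm gel thickness, large compared to the displacement decay
  length at island traction wavelengths; the substrate Poisson ratio is
  not stated for the reference data, so a configurable ν = 0.45
  (nearly incompressible polyacrylamide) is the default — results depend
  only weakly on it.
* **Equilibrium.** Before the stress solve, the net force and net moment
  of the traction field must vanish (tolerance 10⁻⁶ of the RMS traction).
  `enforce_equilibrium()` applies the minimal least-squares correction —
  the projection onto the two uniform translations and the solid rotation
  about the mask centroid — which zeroes both exactly. The original
  "minor correction" script is not described; this correction is a stated
  design of this package.
* **FEM.** One square bilinear element per mask pixel (2×2 Gauss
  stiffness), tractions taken element-wise constant so each element's load
  goes one quarter to each corner — this preserves net force and moment
  exactly, which is what makes the solution independent of where the
  three Dirichlet constraints are placed (default: vertical at the
  leftmost node, both components at the rightmost, as in the original
  analysis; `bc_nodes` overrides them and the stresses change only at the
  solver-roundoff level). The sparse symmetric system is solved by direct
  factorization; element stresses are evaluated at element centers via
  the constitutive matrix, which puts them on the same grid as the input
  tractions (node-averaged extrapolation is deliberately not used).
  Disconnected masks keep their largest 4-connected component with a
  warning. Monolayer height is unstated in the reference protocol;
  h = 5 µm is the default, and since $T \propto h\,\nabla\cdot\sigma$ the
  product $\sigma h$ (line tension) is h-independent.
* **Trajectories.** Forward Euler with one step per frame and bilinear
  velocity interpolation, piecewise constant in time between frames. The
  10-minute sampling does not support sub-frame information, so
  higher-order schemes would only pretend accuracy. Seeds default to every
  4th grid node inside the mask; trajectories leaving the mask are
  truncated and flagged.

# Validation metrics

`rms_traction_ratio()` (RMS traction outside/inside the island, excluding
a 2-node boundary margin — the margin the reference analysis used is
unstated, so it is configurable) quantifies localization: noise-free
synthetic islands give < 0.01; good experimental data give ≈ 0.03.
`edge_traction_sign()` averages the radial traction over the outer 20%
annulus (negative = inward = contractile). `normalize_tension()` rescales
a tension time series by its pre-treatment mean, so drug responses read as
fold changes (a treatment that removes 80% of contractility plateaus near
0.2; one that triples it plateaus near 3).

# Problem sizes and verification

The test suite and the acceptance script verify, among others: exact FTTC
roundtrip (relative RMS < 10⁻⁸ at 256², measured ~10⁻¹⁴); stress recovery
of the random-flow island within 2% at 256² (measured ~0.6%, and the error
falls with refinement); invariance of the stresses to a 10³ scaling of
(K₁, K₂) and to relocating the pinned nodes (both < 10⁻¹⁰ and < 10⁻⁸,
measured ~10⁻¹³); DIC recovery of integer shifts to < 0.05 px and of a
2 px amplitude sinusoidal warp to ≤ 0.1 px RMS with 32 px subsets (with
the refinement pass); exact cancellation of net force and moment by the
equilibrium correction; and the sign conventions of the contractile
island. Unit tests run on 64–192 px grids; the acceptance checks use the
full 256² scale.

# Known limitations

* Half-space substrate only: no finite-thickness or layered kernels, no
  out-of-plane traction component.
* The constitutive closure is linear and homogeneous; heterogeneous or
  nonlinear monolayer rheology is outside the model (though the recovered
  mean tension is closure-independent, being fixed by the tractions
  through the force balance).
* No automatic regularization selection (L-curve/Bayesian) for noisy
  displacement data; λ is a user choice.
* The MAT-file interface covers numeric arrays (the deposited layouts) but
  is not a general MAT parser, and the variable naming of external files
  is discovered defensively rather than assumed.
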