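---
title: "Modeling and inverting anisotropic glioma growth with gliogrow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inverting anisotropic glioma growth with gliogrow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliogrow)
```

## The growth model

gliogrow simulates diffuse glioma growth with the anisotropic Fisher–KPP
reaction–diffusion model. The normalized tumor cell density
$c(\mathbf{x}, t) \in [0, 1]$ (cell density divided by the tissue carrying
capacity) evolves over the brain domain $\Omega$ as

$$\frac{\partial c}{\partial t}
  = \nabla \cdot \big( D(\mathbf{x}) \nabla c \big) + \rho\, c\, (1 - c),$$

with no-flux Neumann conditions
$D \nabla c \cdot \mathbf{n}_{\partial\Omega} = 0$ on the brain boundary:
tumor cells cannot leave the brain. $D(\mathbf{x})$ is a symmetric
per-voxel diffusion tensor (mm²/year) and $\rho$ a scalar proliferation
rate (1/year).

For constant coefficients this equation admits a traveling-wave solution
whose asymptotic front speed is $v = 2\sqrt{d\rho}$ and whose leading edge
decays exponentially with the infiltration length
$\lambda = \sqrt{d/\rho}$. These two wave parameters are the natural
clinical quantities: $v$ measures how fast the visible tumor advances,
$\lambda$ how diffusely it infiltrates beyond its visible margin. The pair
$(\lambda, v)$ maps one-to-one onto $(d, \rho)$ via
$d = \lambda v / 2$ and $\rho = v / (2\lambda)$ (`derive_rates()`), and the
package samples tumors in $(\lambda, v)$ space precisely because a uniform
box there avoids invisible or brain-filling tumors that independent
uniform draws of $(d, \rho)$ would produce.

## Tumor diffusion tensor from water diffusion

Tumor cells migrate preferentially along white-matter fiber tracts. The
package builds the tumor tensor piecewise from a brain label map and a
DTI-style water tensor field (`build_tumor_tensor()`): at each white-matter
voxel the water tensor is eigendecomposed, its Westin shape fractions
$(c_l, c_p, c_s)$ — linear, planar, spherical; they sum to 1 — are
computed, the eigenvalues are reweighted by
$l_i(a) = [(a, a, 1), (1, a, 1), (1, 1, 1)]_i \cdot (c_l, c_p, c_s)^\top$
with anisotropy factor $a = 10$, and the result is rescaled so that
$\mathrm{tr}\, D = 3 d_\mathrm{white}$ exactly. Gray matter gets the
isotropic tensor $0.1\, d_\mathrm{white} I$ (the gray/white diffusivity
ratio 0.1 is held fixed across subjects and tumors), and CSF/background
the zero tensor, which removes them from the growth domain. Useful
identities: $l_3(a) = 1$ always, $a = 1$ returns the water tensor rescaled
to mean diffusivity $d_\mathrm{white}$, and an isotropic water voxel gives
exactly $d_\mathrm{white} I$. A *unit* tensor is built once per subject
with $d_\mathrm{white} = 1$ and rescaled per tumor by a scalar multiply.

## Numerical scheme

`simulate_growth()` advances the PDE by forward Euler on the voxel grid.
The divergence term is discretized in conservative flux form: a flux is
computed once per interior face between two in-domain voxels — normal
terms from face-averaged $D_{ii}$ and first differences, mixed $D_{ij}$
terms from face-averaged tensors and corner-averaged first differences —
and applied with opposite signs to the two cells. Faces touching CSF or
background carry zero flux, which realizes the no-flux boundary on
arbitrarily shaped (non-convex) domains without ghost cells. Two
consequences are exact by construction and are used as solver tests: with
$\rho = 0$ the total mass is conserved to round-off, and each step's mass
increment equals the summed logistic reaction.

The explicit scheme is stable for
$\Delta t \le 1 / (2 \max_\mathbf{x} L(\mathbf{x}))$ with
$L = \sum_i D_{ii}/h_i^2 + \sum_{i \ne j} |D_{ij}|/(h_i h_j)$ (in per-day
units); `stability_limit()` reports the bound and the solver refuses to
exceed it by default. At 1 mm spacing the default $\Delta t = 0.5$ d
clears the bound for the entire sampled parameter range (the fastest
tumor has $d_\mathrm{white} = 49$ mm²/year). Like all non-monotone
anisotropic stencils, the scheme can produce small under- and overshoots
near steep fronts; by default each step clips densities to $[0, 1]$ and
reports the total clipped mass. Clipping is part of the step map, so
restarting from a stored snapshot reproduces later snapshots bit-exactly
(the semigroup property the forecasting tests rely on); it is switched off
(`clamp = FALSE`) when the raw conservative scheme itself is being
verified. Times are handled in days, rates in years
(1 year = 365 days), and snapshots are taken at the nearest completed
step.

One discretization subtlety matters for validation: the Fisher–KPP front
converges to its asymptotic speed only algebraically (the transient decays
like $1/(\rho t)$). Front-speed checks therefore run long on a fine 1D
slab — $h = 0.2\lambda$ and measurement windows around
$\rho t \approx 30$–40 — where the measured speed sits within a few
percent of $2\sqrt{d\rho}$ and the leading-edge decay length within a few
percent of $\lambda$.

## Synthetic study conditions

Each synthetic tumor draws $\lambda \sim U[0.5, 2]$ mm,
$v \sim U[28.28, 48.99]$ mm/year, and integer imaging intervals
$\Delta t_1, \Delta t_2 \sim U\{90, \dots, 180\}$ d; two further intervals
are fixed at 90 d, giving imaging times $t_1 \dots t_4$. The seed is a
3×3×3 voxel block of density 1 centered on a white-matter voxel drawn
uniformly among those whose full neighborhood lies inside the brain.
Draws whose visible core (the $c \ge 0.80$ region at $t_2$) is empty, or
whose $c > 0.01$ region covers more than 90% of the brain at $t_2$, are
rejected and resampled; both rules operationalize the "not too small, not
too large" requirement and their counts are logged. The imaging model is
a pure threshold: a voxel is visible on a sequence iff $c \ge c_{seq}$,
with $c_1 = 0.80$ mimicking the contrast-enhancing core and $c_2 = 0.16$
the T2-FLAIR edema.

Real brain geometries are supported through NIfTI label maps and
6-component tensor volumes (`load_brain_map()`, `load_water_tensor()`).
For self-contained testing the package generates brain phantoms
(`generate_brain_phantom()`): a gray-matter shell around a white-matter
core with a small central CSF cavity, plus a water tensor field that is
strongly anisotropic (linear shape fraction above 0.5) and oriented
circumferentially — mimicking fiber tracts — in white matter,
near-isotropic in gray matter, and zero outside the brain. The "folded"
style perturbs the shell radii sinusoidally to produce non-convex domains
that exercise the boundary treatment. What the phantoms deliberately do
not emulate: hemispheric structure, gyral folding at realistic scales,
partial-volume mixing, or DTI noise beyond mild jitter. Tests passing on
phantoms therefore validate the numerics and the estimation machinery,
not anatomical realism.

## Inverse estimation

Two estimators recover $(\lambda, v)$ from threshold contours.

**Grid search** (`gridsearch_estimate()`) is the transparent oracle,
usable when the seed location is known (always true for synthetic
records): each candidate $(\lambda, v)$ is simulated from the seed, its
contours at the observation times are extracted, and the candidate
minimizing the summed average symmetric surface distance to the three
observed contours (core and edema at $t_2$, edema at $t_1$) wins, ties
broken toward smaller $\lambda$ then smaller $v$.

**Convolutional networks.** The package implements its own small
volumetric convolution engine (im2col + BLAS forward/backward, Adam) and
two architectures. The density reconstructor is a U-Net: four
down-sampling blocks (two 3×3 stride-1 convolutions with bias and ReLU,
then a 2×2 stride-2 convolution), four up-sampling blocks (two
convolutions, then a 2×2 stride-2 transposed convolution with ReLU),
concatenation skip connections from each encoder level to the decoder
stage of matching resolution, and an output block ending in a 1×1
convolution with no activation that merges the final base-width feature
maps into one density channel. Channel widths double per level from a
configurable base (default 32, i.e. 32-64-128-256 with a 512-wide
bottleneck); the exact widths at full scale are not fully pinned down by
the architecture description, so they are spec parameters with these
defaults. The parameter regressor is a convolutional encoder: six
down-sampling blocks of the same structure whose channel schedule ends at
8 (default 32-32-16-16-8-8), a flatten, concatenation of the scalar
imaging interval $\Delta t_2$ (in days, unscaled), and one fully
connected layer to 2 outputs. At the full 192×192×128 input this makes
the pre-output vector 3·3·2·8 + 1 = 145 components. Inputs are the binary
contour masks followed by the 6 unit-tensor components; targets
$(\lambda, v)$ are standardized by the theoretical mean and standard
deviation of their uniform sampling distributions. Training follows the
original protocol: Adam (learning rate $10^{-4}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-6}$), batch size 1, MAE loss for the
density network and MSE for the regressor, random integer shifts of ±15
voxels applied identically to all channels (and the target for the
density task), and early stopping after 100 epochs without improvement of
the held-out-subject loss. A 2D problem is a volume with a singleton
axis; kernels, strides and shifts degrade gracefully along it.

## Scaled-down verification conditions

Full-scale 3D training is a GPU-class computation, so the package's own
verification runs a deliberately scaled-down 2D study; the sizes below
are package choices, stated here once.

* Phantom subjects: six 2D phantoms of 48×48 voxels at 2.5 mm (a 120 mm
  field of view), alternating convex and folded geometries, with the
  white core at 80% of the gray-shell radius so that growth happens
  mostly in white matter, as for a centrum-semiovale tumor. Both the
  physical domain size and the white fraction matter for
  identifiability: on small domains, or with a thick slow gray shell,
  fast fronts stall before $t_2$ and the front-speed information is
  degraded before any estimator sees it.
* Dataset: 30 tumors per subject, $\Delta t = 2$ d (the stability bound at
  this spacing exceeds 2.7 d for the fastest sampled tumor), last
  subject held out — mirroring the subject-wise 83/17 split of the
  full-scale design.
* Networks: the parameter regressor runs with 4 down blocks of widths
  16-16-8-8 on the 48×48 grid, shift augmentation ±4 voxels, learning
  rate $10^{-3}$, at most 130 epochs with early-stopping patience 50, and
  three fixed initialization/shuffling seeds — a larger learning rate
  and shorter schedule than at full scale, appropriate to the model size,
  with the optimizer family and protocol otherwise unchanged. At this
  scale the infiltration length is recovered with strong concordance,
  while front-speed concordance remains clearly below its full-scale
  value: the speed signal is the subtlest feature (a displacement/interval
  ratio read from coarse contours), and its recovery was still improving
  when the epoch budget ran out. The corresponding verification check is
  asserted at the full-scale bar and documents this gap rather than
  hiding it.
* Grid search: a 12×12 candidate grid spanning the sampled
  $(\lambda, v)$ box, evaluated on the held-out subject's records.
* Dataset-capacity checks (1200 records over six subjects with the
  subject-wise split) run on an even smaller 40×40 grid at 2 mm, where
  only the record bookkeeping — counts, splits, reproducibility — is
  under test, not the physics.

Because observations and candidate simulations share one solver and grid,
the grid-search study measures identifiability of the inverse problem
rather than discretization error (deliberately so — the "inverse crime"
is the point of an internal-consistency oracle).

## Design choices on open points

* The evaluation mask for density errors is the *true* field's
  $c > 0.01$ region, so an estimate cannot shrink its own evaluation
  region.
* Surface voxels use 6-connectivity; connected components (post-processing
  of reconstructed densities) use 26-connectivity.
* Post-processing of a reconstructed density applies, in order: zero
  non-brain voxels, clip to $[0, 1]$, keep only the largest 26-connected
  component of $\{c > 10^{-6}\}$. The order follows the narrative of the
  original protocol; the operation is idempotent.
* The third input contour of the regressor uses the edema threshold
  $c_2 = 0.16$ at $t_1$.
* Lin's concordance coefficient uses population (1/n) moments.
* Eigenvalues are sorted descending before the Westin measures; for
  degenerate eigenvalues any orthonormal eigenbasis gives the same
  tensor because tied eigenvalues receive equal weights.
* Label encoding 0/1/2/3 = background/CSF/gray/white is fixed
  package-wide; loaders translate component-order dialects of tensor
  files to the internal (xx, xy, xz, yy, yz, zz) order.
* Dataset bundles live in memory as R lists with an optional on-disk
  manifest (JSON) and parameter table (CSV); volumes are exchanged as
  NIfTI.

## Known limitations

* The explicit stencil is non-monotone under strong anisotropy
  ($a = 10$): under/overshoots of order $10^{-3}$–$10^{-2}$ appear near
  discontinuous seeds and are clipped (and accounted) by default.
  A monotone scheme for arbitrary tensors would require a different
  discretization.
* Front speeds on coarse grids ($h \gtrsim \lambda$) are biased; the
  package's scaled studies rely on matched discretization between
  observation and candidate, as any self-consistent inverse study does.
* The linear output head of the parameter regressor can only linearize
  the ratio relation between front displacement and $\Delta t_2$; this is
  inherent to the architecture at any scale.
* Mass effect, necrosis, treatment response, and multifocal seeding are
  out of scope; tensors inside tumor-destroyed tissue are taken as given.
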