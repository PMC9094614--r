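---
title: "Rotation-invariant survival prediction from tumor shape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-invariant survival prediction from tumor shape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphsurv)
```

# The problem

Given a CT volume and a binary segmentation of a tumor, we want a scalar risk
score that ranks patients by expected survival and does not depend on how the
tumor happens to be oriented in the scanner. Orientation is prognostically
meaningless, but features extracted by Cartesian convolutional networks are
not orientation-stable. `sphsurv` implements the alternative: project the
segmented tumor onto signals on the unit sphere, process them with a
spherical-harmonic convolutional network whose layers are rotation
equivariant, and read out rotation-invariant features that feed a Cox-type
survival objective.

# The survival model

Each subject contributes an observation time $T > 0$ (months) and an event
indicator $E \in \{0, 1\}$; $E = 0$ means the survival time is right-censored
at $T$. The hazard is modeled proportionally,
$$\lambda(t \mid x) = \lambda_0(t)\, e^{h(x)},$$
with an unspecified baseline $\lambda_0$ and a log-risk function $h$. The
classical linear choice $h(x) = \beta^\top x$ is the Cox proportional hazards
model; here $h$ is the spherical network $h_\theta$ applied to the tumor's
spherical maps, trained by minimizing the average negative log partial
likelihood
$$L(\theta) = -\frac{1}{N_E} \sum_{i : E_i = 1}
  \Big[ h_i - \log \!\!\sum_{j : T_j \ge T_i}\!\! e^{h_j} \Big],$$
with Breslow handling of tied event times and each subject included in its
own risk set (Efron's correction is available via `ties = "efron"`). The
partial likelihood eliminates $\lambda_0$, so only score *differences*
matter; $h_\theta$ is identified up to an additive constant. Both the loss
and its gradient shift each risk set's scores by their maximum before
exponentiating, so arbitrarily spread scores cannot overflow or underflow
into `0/0` softmax terms.

Model quality is measured by Harrell's concordance index: the fraction of
comparable pairs whose predicted risk ordering matches the observed survival
ordering. Pair $(i, j)$ is comparable with $i$ earlier iff $E_i = 1$ and
$T_i < T_j$, or $T_i = T_j$ with $E_i = 1, E_j = 0$; tied scores count half.
These conventions differ between software packages, so they are fixed here
and enforced against a brute-force pair enumeration in the tests. Risk
stratification splits a cohort at the *median* predicted score (ties go to
the low-risk group — deterministic and documented), and each group gets a
Kaplan-Meier survivor-function estimate.

# Spherical projections

All projections are computed in physical millimetres; voxel $(i,j,k)$
(1-based) has center $\mathrm{origin} + (i-\tfrac12, j-\tfrac12,
k-\tfrac12) \cdot \mathrm{spacing}$. An enclosing sphere is placed at the
mask's center of mass with radius $R$ equal to the largest center-to-voxel
distance plus one voxel diagonal, so the whole tumor is strictly inside.

* **Depth projection** (`depthProjection`): for each grid direction a ray
  marches from the sphere surface toward the centroid in steps of half the
  minimum voxel spacing, interpolating the mask trilinearly; the first
  sample at or above 0.5 (refined by linear interpolation between the
  bracketing samples) defines the tumor's radial extent along that
  direction, in mm. Rays that never hit the mask record 0. Values are kept
  in mm by default because tumor size is prognostic; `normalize = TRUE`
  divides by $R$ when a scale-free map is wanted.
* **Intensity projection** (`intensityProjection`): the same rays accumulate
  the image intensity inside the mask as a line integral (sample sum times
  step length). Intensities are first windowed affinely from
  $[-1000, 400]$ HU to $[0, 1]$ — a soft-tissue window; configurable.
* **Extended Gaussian image** (`egi`): the orientation distribution of the
  tumor's outward surface normals. The 0.5 isosurface of the mask (smoothed
  by a Gaussian of $\sigma = 1$ voxel; $\sigma = 0$ keeps the raw voxel
  surface, whose normals collapse onto few directions) is triangulated by
  marching tetrahedra; each triangle adds its area to the grid cell
  containing its outward normal, and cell masses are divided by the exact
  cell solid angle. Total integrated mass therefore equals the triangulated
  surface area *identically*, which the tests exploit. Normals are oriented
  by the negative smoothed-mask gradient, which is correct for non-convex
  shapes where "away from the centroid" is not.

The network consumes either the depth channel alone (`sphcnn1`) or the EGI
plus intensity channels (`sphcnn2`); the two configurations separate what
the segmentation alone contributes from what the image content adds.
Channels are standardized by mean and standard deviation computed on the
*training split only*; the statistics travel inside the model object, so
external cohorts are mapped into the training frame and no statistic of the
evaluation data leaks into the model.

# The grid and the transforms

Spherical signals live on the equiangular $2B \times 2B$ grid
$\theta_j = \pi(2j+1)/(4B)$, $\phi_k = \pi k / B$ with Driscoll-Healy
quadrature weights, which integrate signals band-limited below $B$ exactly.
This convention oversamples the polar caps relative to the equator; the
weights make integrals unbiased, but cells are not equal-area, and binned
densities (the EGI) are noisier near the poles. A uniform-area sampling
would remove that anisotropy at the cost of losing the fast separable
transform; we keep the equiangular convention and document it.

The forward/inverse spherical harmonic transform uses orthonormal complex
harmonics with the Condon-Shortley phase; real signals are represented
through the conjugate symmetry $\hat f_{l,-m} = (-1)^m \overline{\hat
f_{lm}}$. Rotations act by Wigner-D matrices with ZYZ Euler angles and
$D^l_{mn}(\alpha,\beta,\gamma) = e^{-im\alpha} d^l_{mn}(\beta)
e^{-in\gamma}$; $d^l(\beta) = e^{\beta K}$ is evaluated through the
eigendecomposition of the tridiagonal angular-momentum generator, which is
exact and stable for the degrees used here (below 64). Any consistent
convention would work; this one is pinned down by round-trip, Parseval,
rotation-action and brute-force integration tests, all at $10^{-8}$ or
tighter.

Correlating a spherical signal with a filter produces a function on the
rotation group SO(3), with Wigner spectrum
$\hat g^l_{mn} = \hat f_{lm} \overline{\hat\psi_{ln}}$; a second correlation
stage acts on SO(3) itself by per-degree block products
$\tfrac{8\pi^2}{2l+1} \hat g^l (\hat\chi^l)^H$. SO(3) signals are sampled on
a $2L \times 2L \times 2L$ Euler grid whose $\beta$ axis reuses the
equiangular colatitudes and weights. Both correlations are verified against
direct numerical integration of their definitions on coarse grids.

# Network architecture

Three layers, deliberately shallow — deeper stacks did not help this
problem class and small cohorts argue for few parameters:

1. spherical correlation lifting the input channels onto SO(3)
   (`channelsIn` to `c1` channels), bias, pointwise ReLU on the grid;
2. spherical pooling: spectral truncation to half the bandwidth plus
   resampling on the coarser grid (constants pass through unchanged, energy
   never increases);
3. SO(3) correlation (`c1` to `c2`), bias, ReLU, pooling;
4. invariant readout: per channel the integral over SO(3) *and* the
   weighted L2 norm (the second statistic captures spectral energy that the
   mean discards; `useL2Stat = FALSE` disables it);
5. a dense layer with exactly 40 features, ReLU (flag `reluDense`), and a
   linear scalar output $h_\theta$.

Defaults: bandwidths $B \to B/2 \to B/4$ across layers ($32 \to 16 \to 8$
at the default $B = 32$; the experiments in this package run at $B = 16$,
i.e. $16 \to 8 \to 4$, which preserves every structural property at a
quarter of the cost), channel widths `c1 = 8`/`c2 = 16` by default with
`c1 = 4`/`c2 = 8` used in the phantom experiments. Filters are
parameterized directly by their spectral coefficients — there is no reason
to sample filters on the grid when the convolutions are spectral — and are
projected onto the real-signal subspace in the forward pass, so the
optimizer works on unconstrained complex arrays. Initialization scales
coefficient variance by fan-in, seed-controlled.

The ReLU between convolutions is pointwise on grid samples. It mildly
leaks energy above the band limit (the following analysis step truncates
it), which is standard practice for spherical networks; the alternative of
spectral nonlinearities was not pursued.

## What invariance means here, exactly

Every layer before the readout is rotation *equivariant* and the readout
integrates over the group, so the composition is rotation *invariant*. On a
discrete grid the statement needs care:

* Polar rotations that correspond to longitude shifts by multiples of
  $B/l_2$ input columns survive every internal activation grid (the ReLU
  commutes with exact grid permutations), and $h_\theta$ is invariant to
  float precision ($\sim 10^{-15}$).
* Finer longitude shifts land between nodes of the coarser internal grids
  and leave a small residual ($\sim 10^{-4}$ at $B = 16$).
* Arbitrary rotations require resampling the voxel volume, which perturbs
  the input itself: the re-voxelized rotated tumor is not a rotated copy of
  the original signal but differs by boundary discretization noise. The
  measured score change therefore has a floor set by voxel size, not by the
  architecture; empirically it scales roughly linearly with voxel size. The
  acceptance experiment runs this probe on 0.4 mm phantoms so that the
  discretization term does not swamp the architecture property, and
  normalizes the score change by the standard deviation of scores across
  phantoms — the only meaningful scale, since Cox log-risks are defined up
  to an additive constant. Across model draws the typical change is
  around 1% of the score spread at that resolution; unlucky draws with a
  flat score distribution can roughly double it.

# Training

Adam (default learning rate $10^{-3}$; the phantom experiments use
$3 \times 10^{-3}$, which converges in 60 epochs on those cohorts) with
decoupled weight decay $10^{-4}$ on filter and dense weights (not biases).
Mini-batches of 64 subjects form their own Cox risk sets — the standard
stochastic compromise; batches are reshuffled until each contains at least
one event, and `batchSize >= n` recovers exact full-cohort risk sets. An
event-stratified validation split (20% by default) drives model selection
on validation loss — smoother than the validation C-index, which is logged
alongside for transparency. Gradients are hand-derived adjoints of every
layer and checked against central differences in the test suite; the check
excludes coordinates whose perturbation flips a ReLU state, where the loss
is genuinely non-differentiable and central differences are meaningless.
Fixed seeds make runs bit-reproducible.

Cross-validation (`crossValidate`) uses subject-level, event-stratified
folds fixed by the seed, serialized so the same splits can be reused across
methods. External evaluation (`evaluateExternal`) applies the stored
training normalization without re-fitting, stratifies at the median of the
*external* predicted scores, and returns per-group Kaplan-Meier curves.

# The phantom generator

Real cohorts of segmented lung tumors with survival outcomes cannot ship
with a package; the generator provides a stand-in with known ground truth.

* **Shape**: star-shaped solids $r(\omega) = r_0 (1 + \sum_{l \le 4, m}
  a_{lm} S_{lm}(\omega))$ with real spherical harmonics, $r_0 \sim
  U(6, 12)$ mm, coefficient scale 0.12 decaying with degree, clamped so
  $r(\omega) > 0$. Star-shape is not incidental: it makes the depth
  projection analytic ($r(\omega)$ itself), giving the mapping module an
  exact oracle. The band limit 4 sits far below the mapping bandwidth, so
  phantoms are representable without aliasing.
* **Texture**: soft tissue around 40 HU with smooth random blobs
  (amplitude sd 25 HU) and i.i.d. noise (sd 20 HU) inside the mask, air at
  $-1000$ HU outside. Roughly CT-like numbers at 1 mm voxels.
* **Survival**: constant baseline hazard $\lambda_0 = 0.05$ events/month
  (mean 20 months at baseline risk), true log-risk $\beta^\top x$ on
  standardized shape covariates (log tumor volume and the perturbation
  magnitude, an "asphericity" score), event times drawn exactly by inverse
  transform $T^* = -\log(U) / (\lambda_0 e^{h})$, and censoring uniform on
  $[0, 60]$ months independent of everything — the usual non-informative
  censoring assumption. These settings yield roughly one third censored
  records, comparable to public lung-cancer cohorts.

What the phantoms do *not* emulate: CT acquisition physics, lung anatomy,
pleural attachment, multi-lesion disease, segmentation error, or any
dependence of risk on texture (risk is a pure function of shape by
construction, which is what makes the recovery experiment interpretable).
Passing the phantom experiments shows the pipeline recovers shape-driven
risk through the spherical representation; it says nothing about how much
prognostic signal real CT tumors carry.

# Numerical choices and degenerate inputs

* Ray marching: step = half the minimum spacing, trilinear interpolation,
  0.5 threshold, sub-step linear refinement; misses map to 0.
* Masks touching the volume border are zero-padded by 2 voxels before
  surface extraction; an empty mask is an error everywhere (never a silent
  origin).
* Marching tetrahedra (6-tetrahedra Kuhn decomposition) rather than
  marching cubes: no ambiguous cases, watertight across shared faces, and
  triangle areas bin exactly.
* A solid smaller than half a voxel voxelizes to the single central voxel;
  solids that would overflow the grid raise an error naming the required
  grid size.
* Degenerate Newton steps in the linear Cox fit raise errors (singular
  information, divergence, monotone likelihood via $|\beta| > 15$ at
  convergence).
* The validation C-index is reported as `NA` when the split has no
  comparable pairs.

# Problem sizes used by the checks

The spherical-transform and convolution checks run at bandwidths 8 and 16
against brute-force integration. The mapping oracle uses 20 phantoms at
1 mm voxels; the rotation-invariance probe uses 12 phantoms at 0.4 mm. The
end-to-end recovery experiment trains on 120 phantoms at $B = 16$
(`c1 = 4`, `c2 = 8`, 60 epochs) and evaluates on an independent cohort of
200 — large enough that the null band of the C-index is a few points wide —
with the true-log-risk concordance reported as the ceiling. The linear Cox
oracle recovers $\beta = 1$ on 500 subjects. All of these run on one CPU
core in a few minutes total.

# Known limitations

* Bandwidths above 64 are out of scope (dense Wigner algebra; the intended
  tumor maps live comfortably below that).
* The equiangular grid's polar oversampling is inherited by every map;
  uniform-area sampling is future work.
* Multi-lesion masks are not split; the projections treat the full
  foreground as one object relative to one centroid.
* Mini-batch risk sets bias the partial likelihood slightly for small
  batches; use full-batch mode when exactness matters more than speed.
* Training runs on CPU only and is sized for cohorts of hundreds, not
  thousands.
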