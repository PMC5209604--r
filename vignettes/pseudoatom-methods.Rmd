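---
title: "Pseudoatom coarse-graining of density maps: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoatom coarse-graining of density maps: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudem)
```

## The representation

A cryo-EM density map is a scalar field $f(\mathbf r)$ sampled on a voxel
grid. `pseudem` approximates it by a weighted sum of isotropic Gaussian
radial basis functions of a *single, fixed* standard deviation $\sigma$:

$$\hat f_N(\mathbf r) = \sum_{i=1}^{N} \omega_i\,
K_\sigma(\lVert\mathbf r - \mathbf r_i\rVert), \qquad
K_\sigma(d) = e^{-d^2/2\sigma^2},$$

with centers $\mathbf r_i$ (Angstrom, varying continuously — they are not
snapped to voxels), weights $\omega_i > 0$, and amplitude-1 kernels. Each
term is called a *pseudoatom*: a control point carrying local density, not
a chemical atom. $\sigma$ is specified in voxel units (typical values 1-2
voxels) and converted to Angstrom through the voxel size.

The quality of the approximation is measured over an evaluation mask of
$V$ voxels as

$$e_N = \frac{100}{V} \sum_{j=1}^{V}
\frac{|f(\mathbf r_j) - \hat f_N(\mathbf r_j)|}{\Delta f} \; [\%],$$

where $\Delta f$ is the effective range of the map over the mask. The user
sets a target $\varepsilon$; the algorithm chooses $N$, the positions and
the weights so that $e_N < \varepsilon$.

Two conventions are fixed once and used everywhere: voxel $(i,j,k)$
(0-based) has its **center** at `origin + voxel_size * (i,j,k)`, and all
physical coordinates are in Angstrom.

## The approximation algorithm

`approximate_map()` is an alternation of four steps:

1. **Seed** (`seed_model`): visit masked voxels in decreasing density
   order, accepting a voxel as a center when it is at least
   `min_separation` voxels from every accepted center, up to `n_seed`
   grains. Seeding is deterministic — no random initialization — so a run
   is exactly reproducible.
2. **Refine** (`refine_step`): gradient descent with backtracking line
   search on the smooth objective $J = \sum_{\text{mask}} (f - \hat
   f_N)^2$, with analytic gradients in all $3N$ coordinates and $N$
   weights. The descent direction is the gradient scaled per block
   (positions vs. weights) so a unit step moves the farthest-moving center
   by one voxel and the most-changing weight by one mean weight; the step
   size is halved until $J$ decreases and re-inflated after acceptance.
   Weights are clipped at $10^{-12}$ (pruning removes them later); centers
   are clamped to the grid extent. $J$ never increases across accepted
   steps.
3. **Prune** (`prune_step`): remove grains below `weight_floor` times the
   mean weight (the heaviest grain always survives), then repeatedly merge
   any pair closer than `min_separation` into its weight-weighted centroid
   with summed weight. Merging lets neighboring grains absorb removed
   density without a second refinement pass.
4. **Grow** (`grow_step`): if $e_N \ge \varepsilon$, add up to
   `grow_fraction * N` grains (at least one) at the voxels of largest
   positive residual $f - \hat f_N$, again respecting the minimum
   separation, each initialized with the residual value as weight. Adding
   grains where the error is large is what lets the optimization escape
   local minima of a fixed-$N$ fit.

The loop stops as soon as the measured $e_N$ (not $J$) drops below
$\varepsilon$, or after `max_outer_iters` iterations with
`converged = FALSE` — non-convergence is a flagged outcome, not an error.

### Why descend an L2 surrogate but stop on e_N?

$e_N$ is a mean of absolute values, non-differentiable wherever a residual
crosses zero. The refinement therefore descends the everywhere-smooth sum
of squares $J$, while convergence is always judged on the quantity the
user actually bounds, $e_N$. On the matched-kernel phantoms used in the
tests the two are minimized at the same configurations.

### Numerical choices

* **Kernel truncation.** Kernels are evaluated within $4\sigma$ of their
  center and are exactly zero beyond (`kernel_eval`). The kernel value at
  the cutoff is $e^{-8} \approx 3.4\times10^{-4}$, which bounds the
  pointwise truncation error at $\sum_i \omega_i e^{-8}$; rendering within
  the cutoff matches an independent brute-force sum to rounding error. The
  gradient code uses the same cutoff so $J$ and $\nabla J$ are consistent.
* **Effective range.** $\Delta f$ is `max - min` over the mask. A robust
  percentile range would also be defensible; max - min is the simplest
  reading of "effective range" and is what the error reports use.
* **Mask.** Default: voxels strictly above `mask_threshold * max(f)` with
  threshold 0, i.e. all positive voxels. An explicit logical array can be
  supplied instead.
* **Defaults.** `n_seed = min(300, V/1000)`, `grow_fraction = 0.1`,
  `min_separation = 1` voxel, `weight_floor = 1%` of the mean weight,
  50 inner descent steps per outer iteration, inner stop at relative
  decrease $10^{-4}$. These are concrete values for the qualitative
  "remove grains with small weights or distances" rule; all are exposed in
  `approx_config()`.
* **Growth cap.** `max_pseudoatoms` (default 5000) stops growth — but not
  refinement — when a target is unattainable for the chosen $\sigma$
  (e.g. a very noisy map with a small $\varepsilon$); without it, a
  non-convergent run would grow $N$ geometrically for up to
  `max_outer_iters` iterations.

### A property of the mean-absolute error worth knowing

Because $e_N$ averages over the whole mask, a *small, low-weight* feature
in a *large, mostly empty* grid contributes little to it: on a sparse test
grid a 1%-target run can legitimately converge without placing any grain
on a minor blob. Tightening $\varepsilon$ (or masking to the molecular
region) forces such features to be represented. This is inherent to the
error definition, not an implementation artifact, and it is why the
denoising examples on small phantoms use tight targets.

## Elastic network and normal modes

The pseudoatom centers are the nodes of an elastic network
(`build_network`): every pair within the interaction cutoff (closed ball)
is joined by a harmonic spring with a uniform force constant. The
`assemble_hessian` routine builds the standard $3N \times 3N$
anisotropic-network Hessian ($-k\,\mathbf u\mathbf u^T$ off-diagonal
blocks, negated row sums on the diagonal); `compute_modes` performs a full
dense symmetric eigendecomposition. Frequencies are the square roots of
the eigenvalues; eigenvalues within $10^{-8}\lambda_{max}$ of zero are
clamped to zero and counted — a connected network has exactly six such
rigid-body modes (three translations, three rotations), which are flagged
and normally excluded from deformations.

Choices made here: **unit masses and a uniform force constant** (the
pseudoatom weights are *not* used as masses), a **default cutoff of three
times the mean nearest-neighbor distance** (keeps typical grain clouds
connected; a disconnected network warns and yields $6c$ zero modes for
$c$ components), and **dense eigendecomposition** (models here are at most
a few thousand grains, where `eigen()` is unproblematic; block/RTB
speedups belong to large-scale NMA codes and are out of scope).

Mode vectors are normalized to unit Euclidean norm over all $3N$
coordinates, so a displacement amplitude $a$ on one mode
(`displace_model`) moves the model by RMSD $a/\sqrt N$; amplitudes are
unitless, coordinates stay in Angstrom. Mode indices in R are 1-based:
the first non-rigid mode of a connected network is index 7.
`make_trajectory` samples amplitudes uniformly in $[-a_{max}, a_{max}]$
for animation export as a multi-model PDB.

## Elastic fitting and the conformational distance space

`fit_pair` deforms a model along its lowest non-rigid modes and maximizes
the Pearson correlation between the rendered deformed model and a
reference map. The optimizer is a derivative-free Nelder-Mead simplex
started at zero amplitudes (the undeformed model), keeping the best point
seen — so the result is never worse than the starting correlation —
with each amplitude bounded by $10\sqrt N$ and a relative tolerance of
$10^{-3}$ or 500 evaluations. The correlation is computed over the union
of the voxels above 5% of the maximum in the reference and in the
undisplaced render; restricting to this support keeps empty background
from diluting the comparison. Five fitted modes is the default, exposed
as configuration.

`distance_matrix` converts every map of a set, fits each model to every
other map, records $d_{ij} = 1 - \max\mathrm{CC}$, and symmetrizes by the
arithmetic mean of $d_{ij}$ and $d_{ji}$ (the raw quantity is mildly
asymmetric because modes of model $i$ are used for the ordered pair). The
diagonal is zero. `embed_space` maps the matrix into 1-3 dimensions by
classical metric multidimensional scaling (`stats::cmdscale`); axes with
non-positive eigenvalues are zero-filled with a warning.

`fit_image` is the single-image analogue: amplitudes are optimized per
orientation of an explicit user-supplied grid, with the in-plane
translation solved at every objective evaluation by the FFT
cross-correlation peak (integer pixels). Projections are analytic — a
grain contributes $\omega\sqrt{2\pi}\sigma\,e^{-\rho^2/2\sigma^2}$ at
in-plane distance $\rho$, the exact line integral of the 3D kernel — so
no voxel rotation/interpolation error enters. Processing of large image
series, off-grid orientation refinement and CTF handling are deliberately
out of scope.

## Denoising

`denoise_map` is approximate-then-render: the fixed-width smooth kernels
cannot follow voxel-scale noise, so rendering the fitted model back onto
the input grid suppresses it. The default regime, $\sigma = 1.5$ voxels
with $\varepsilon = 1\%$, suits higher-resolution maps; for
lower-resolution maps larger targets ($\varepsilon = 5$-$15\%$) are the
usual choice. No intensity rescaling is applied to the rendered map; the
fitted result rides along as an attribute for inspection.

## The phantom generator

All tests and examples run on synthetic maps from `phantom_spec()` /
`make_phantom()`: sums of isotropic Gaussian blobs evaluated *exactly*
(no truncation) at voxel centers, with optional $C_n$ symmetrization
about the z axis and additive white Gaussian noise applied in a separate,
seeded step (`add_noise`). `make_conformation_series` interpolates blob
centers linearly between two specs, so every frame has a known
ground-truth displacement field. Three reference phantoms are exported:
`phantom_five_blob()` (five separated blobs, 48^3 voxels at 2 A/voxel,
blob width matched to a 1.5-voxel kernel — the accuracy-control
benchmark), `phantom_c4()` (C4-symmetric, for symmetry preservation) and
`phantom_hinge_pair()` (a two-domain molecule whose arm rotates 30 degrees
about a hinge — a minimal continuous conformational change).

What the phantoms emulate: multi-domain globular density, point-group
symmetry, additive noise, continuous hinge motion sampled as discrete
unordered maps. What they do **not** emulate: CTF and envelope effects,
colored cryo-EM noise spectra, reconstruction artifacts, compositional
heterogeneity, and molecular surfaces more intricate than Gaussian blobs.
Passing tests therefore demonstrate correctness of the algorithms under
the stated model, not end-to-end performance on experimental
reconstructions.

Problem sizes were chosen so the whole suite runs in well under a minute
of compute: 48^3 benchmark grids, 40^3 conformational series, models of
tens to a few hundred grains, five-frame series, four-orientation image
grids. These sizes exercise every code path at tolerances far tighter
than the sizes' cost would suggest, because the phantoms admit exact
ground truth.

## Known limitations

* Fixed, shared $\sigma$ by design; per-grain or anisotropic widths are a
  different representation with different trade-offs.
* The grow/prune schedule is one concrete realization of the
  qualitative add-where-error-is-large / remove-small rule; other
  schedules reach the same $\varepsilon$ with different $N$.
* `fit_image` searches orientations only on the supplied grid.
* Collinear node arrangements give an elastic network extra spurious zero
  modes (rotation about the line costs no energy with central springs) — a
  well-known property of this network class. The six-zero-mode statement
  assumes generic, non-degenerate geometry.
* MRC I/O is deliberately narrow: MRC2014, little-endian, axis order
  1,2,3, isotropic voxels; mode 2 on write.
* Maps so simple that a single grain is exact cannot be given an elastic
  network (a 2-node minimum applies, and meaningful modes need more).
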