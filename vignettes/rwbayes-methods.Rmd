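---
title: "Knowledge-based Bayes random-walker segmentation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based Bayes random-walker segmentation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwbayes)
```

## The problem

Segmenting an organ (the motivating case is the liver in abdominal CT) from
a 3D volume with a classical seeded random walker requires solving one
sparse linear system over *every* voxel, and its result depends entirely on
where the operator happens to place seeds: the walker knows nothing about
the organ's characteristic intensity or shape. `rwbayes` implements the
knowledge-based alternative: segment one interactively seeded start slice,
then propagate slice-by-slice, letting each segmented slice supply the
*intensity knowledge* (a per-class Gaussian model), the *shape knowledge*
(a dilated-mask prior and automatically generated seeds) and a small
restricted subgraph for its neighbour.

## The random walker and its Bayes extension

An image slice is a 4-connected lattice graph; edge weights are the
Gaussian similarity

$$w_{ij} = \exp\!\big(-\beta\,(\hat I_i - \hat I_j)^2\big) + \varepsilon,$$

with $\hat I$ the slice min–max rescaled to $[0,1]$ (so $\beta$ is
scale-free; default $\beta = 90$) and $\varepsilon = 10^{-6}$ a floor that
keeps the graph numerically connected when $\beta$ is large. With the
graph Laplacian $L$ partitioned by marked/unmarked nodes into $L_M$, $B$,
$L_U$, the classical walker solves

$$L_U\, x_U^s = -B^\top x_M^s,$$

giving each unmarked pixel the probability that a random walk starting
there reaches an object seed before a background seed. For two labels only
$s = 1$ is solved; $x^2 = 1 - x^1$.

The Bayes extension adds a unary energy pulling $x^s$ toward a posterior
$p(s \mid I_i)$, built from the intensity likelihood and the shape prior:

$$\big(L_U + \gamma \textstyle\sum_q \Lambda^q\big)\, x_U^s
  = \gamma\, p(s \mid I_U) - B^\top x_M^s,$$

where $\Lambda^q$ is diagonal with the label-$q$ posterior on the
diagonal, and $\gamma = 0.01$ by default. Because the posteriors sum to
one per pixel, summing the system over $s$ shows that
$\sum_s x_i^s = 1$ must hold for **any** $\gamma \ge 0$ — the package
asserts this as a derived property rather than imposing it. At
$\gamma = 0$ the classical walker is recovered exactly; as
$\gamma \to \infty$ (seedless, unreduced form) the solution converges to
the posterior. Both limits are tested.

Solves use sparse Cholesky factorisation (`Matrix`); the contract is a
relative residual $\le 10^{-8}$, not a named algorithm.

## Priors

**Intensity.** Each class gets a single Gaussian $N(\mu_s, \sigma_s^2)$
fitted by maximum likelihood (population variance, floored at $10^{-4}$ on
normalised intensities so constant regions stay proper). On the start
slice the samples are the operator's seed pixels; during propagation the
object model is fitted from the current slice's pixels under the previous
mask and the background model from the pixels of the background annulus
(see below). Fitting both classes from the *current* slice keeps the
model synchronous with the slice being solved; the adjacent-slice
correlation assumption makes the sampling regions valid either way.

**Candidate pixels.** The two-class normalised likelihood
$p(I\mid s)/\sum_q p(I\mid q)$ is thresholded at $0.5$ on the object side
(values *at* the threshold are kept; background likelihoods pass through
untouched). Pixels below threshold cannot be object: they are excluded
from the unknown set and treated as marked background.

**Shape.** The previous mask dilated by a disk of radius 10 px carries
object prior $1-\epsilon$ inside and $\epsilon = 0.01$ outside. The
crisp-with-$\epsilon$ form is the literal reading of "dilating the
previous organ region"; $\epsilon$ keeps the linear system well posed
everywhere. On the start slice, where no previous mask exists, equal
priors are used and the posterior reduces to the normalised likelihood.

## Automatic seeding

For each connected component of the previous mask:

* rough object seeds **FS** = component eroded by a disk of radius 8;
* background seeds **BS** = (component ⊕ disk 10) \\ (component ⊕ disk 8),
  an annulus 8–10 px *outside* the boundary.

Disks are discrete Euclidean disks (a pixel belongs iff its centre
distance is ≤ r); structuring-element offsets falling outside the image
are ignored, so erosion does not eat masks at the image frame. Components
whose erosion is empty are too thin to propagate and are dropped — this is
also the pipeline's natural termination: when the organ tapers below the
erosion radius, propagation in that direction stops. A secondary guard
stops a direction when the new mask falls below `min_mask_area`
(default 20 px), since an organ that has vanished leaves nothing
trustworthy to propagate.

Object seeds are then refined with the narrow-band threshold
$[\mu - \beta_{\mathrm{NBT}}\sigma,\ \mu + \beta_{\mathrm{NBT}}\sigma]$
(default $\beta_{\mathrm{NBT}} = 0.2$, useful range $[0.05, 0.3]$ from
low- to high-contrast data), which removes bright non-organ structures
such as vessels from FS. If the band removes every seed it is deemed too
narrow for the data and the unrefined FS is kept with a warning.
Background seeds are never intensity-refined: the annulus is outside the
organ by construction.

The solved subgraph is restricted to the previous mask dilated by 10 px;
everything outside is marked background (the annulus already declares that
region background, so farther pixels are so a fortiori). This is what
keeps per-slice systems small — on the bundled phantom the unknown count
is roughly 40 % of a slice rather than 100 %, and the saving grows with
image size.

## Boundary smoothing

The final per-slice boundaries are low-pass filtered with truncated
Fourier descriptors: each coordinate sequence of a traced closed boundary
is transformed, only the 15 lowest frequencies are kept — the DC term plus
14 harmonics, each with its conjugate partner so the inverse transform is
real — and the curve is rasterized back. Keeping conjugate pairs is the
real-curve reading of a one-sided 15-component truncation, which would
otherwise produce complex coordinates. The DC term is always retained, so
the centroid is exact; smoothing is idempotent on the retained band.

Two geometric conventions matter and are easy to get subtly wrong:

* the traced contour connects boundary-pixel *centres*, while the true
  region boundary runs half a pixel outside them — so the contour is
  offset outward by 0.5 px along its normals before smoothing;
* rasterization includes a pixel iff its centre is strictly inside the
  smoothed curve or exactly on it. Rounding curve samples to pixels
  instead would recruit pixels up to half a pixel beyond the curve, and a
  sub-pixel Gibbs ripple at a boundary shared with an adjacent bright
  structure can then annex single voxels of that structure.

With both conventions, `rasterize_contour(trace_boundary(mask))`
round-trips exactly, and filling the smoothed closed boundary also closes
interior holes left by candidate thresholding. Contours shorter than
$2 \times$ `keep` points are returned unchanged (boundaries are normally
well over 100 points).

## What the phantom emulates — and what it does not

`generate_phantom()` builds volumes in the regime the method assumes: an
elliptical organ cross-section whose centre drifts smoothly (default
≈ 1.4 px/slice, well under the ≤ 4 px adjacency assumption) and whose
radii taper toward the volume ends; object and background intensities from
two Gaussians (defaults 150 ± 15 vs 70 ± 15, i.e. > 4σ separation);
optionally a brighter confounder ellipse (230 ± 15) touching the organ on
the superior third of the volume — the adjacent-heart failure mode, placed
away from the mid-volume start slice just as the heart sits away from a
mid-liver start slice. `phantom_start_seeds()` emulates the operator's
interior/exterior strokes with 25 evenly spaced pixels per class by
default; isolated single clicks make 5-sample variance estimates unstable,
which is a property of any Gaussian fit, not of this method.

The phantom deliberately omits: anatomical shape variation and lesions,
partial-volume effects, CT physics (beam hardening, HU calibration),
textured backgrounds with multiple tissue classes, and inter-slice
artefacts. Passing phantom tests therefore demonstrates correctness of
the machinery and robustness in the assumed regime — not clinical
performance.

Sizes used in the test-suite and acceptance runs (a package choice):
20 slices of 64 × 64 for end-to-end runs, 6 × 6 to 8 × 8 lattices for the
dense and Monte-Carlo solver oracles, and z-resampling factors
{0.5, 0.75, 1, 1.5, 2} for the resolution sweep.

## Numerical and design choices

* **Connectivity** 4-neighbour in 2D, 6-neighbour for the 3D baseline —
  the minimal standard lattice.
* **Node indexing** is R's own column-major linearisation, 1-based;
  seed files use 1-based `(y, x)` with `y` the row. Stated prominently
  because seed files depend on it.
* **Single start slice, bidirectional propagation**: one seeded slice
  propagated both up and down subsumes multi-start variants and is the
  minimal consistent design.
* **Tie-break**: a pixel with object probability exactly 0.5 is labelled
  object.
* **Degenerate inputs**: images need ≥ 2 pixels; a marked set is required
  for the reduced system (the seedless unreduced Bayes form is available
  for the large-γ limit); empty previous masks terminate propagation;
  degenerate zero-area contours rasterize to empty masks with a warning;
  zero posterior denominators fall back to 0.5/0.5 with a warning.
* **Determinism**: the segmentation pipeline contains no randomness; the
  phantom generator is deterministic given its seed.

## Known limitations

Binary (object/background) labelling only. A single Gaussian per class —
strongly bimodal organs (large lesions) would need a mixture. The shape
prior is crisp rather than distance-weighted. Smoothing is per-slice, not
a 3D surface fairing. The classical RW3D baseline solves the full-volume
system and is memory-bound for large volumes — which is one of the
motivations for the slice-propagated method in the first place.
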