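# rwbayes

Knowledge-based Bayes random-walker segmentation of volumetric images.

Seeded random-walker (RW) segmentation assigns each unlabelled pixel the
probability that a random walk started there reaches an object seed before
a background seed, computed by solving the graph-Laplacian system
`L_U x_U = -Bᵀ x_M` on a weighted pixel lattice with edge weights
`w_ij = exp(-β (Î_i - Î_j)²)`. Applied to a whole CT volume this requires
one enormous sparse solve and knows nothing about the organ being
segmented. `rwbayes` implements the knowledge-based alternative for
organs such as the liver in abdominal CT:

1. **Start slice** — the operator seeds one slice; a two-class Gaussian
   intensity model fitted from the seeds is thresholded into candidate
   pixels and the classical RW solves only the candidate subgraph.
2. **Slice-by-slice propagation** — each segmented slice hands its
   neighbour the intensity model (refitted Gaussians), automatic seeds
   (erosion of the mask for object seeds, a dilation annulus for
   background seeds, narrow-band intensity refinement
   `[μ - βσ, μ + βσ]` to strip vessels), a dilated-mask shape prior, and
   a restricted subgraph. The slice is solved with the Bayes-extended
   walker `(L_U + γ ΣΛ) x_U = γ p(s|I_U) - Bᵀ x_M` (default γ = 0.01),
   whose unary term pulls probabilities toward the posterior
   `p(s|I) ∝ p(I|s) p(s)`.
3. **Boundary smoothing** — every slice boundary is low-pass filtered
   with truncated Fourier descriptors (15 components per coordinate).

The package also provides the classical full-volume RW3D baseline,
Dice/Jaccard overlap metrics, a synthetic phantom generator with analytic
ground truth (including an adjacent bright "heart-like" confounder), and
NIfTI / PNG / TIFF / seed-file I/O. Intended users are medical-image
analysis researchers who want a transparent, fully testable reference
implementation of prior-guided random-walker segmentation.

## Worked example

Generate a 64×64×20 phantom (bright drifting elliptical organ, Gaussian
intensities 150±15 over a 70±15 background), seed the middle slice with
operator-like strokes, and segment the volume:

```r
library(rwbayes)

ph    <- generate_phantom(phantom_spec(noise_seed = 1))
seeds <- phantom_start_seeds(ph$truth, slice = 10)
head(seeds, 3)
#>   label  y  x
#> 1     1 28 17
#> 2     1 37 18
#> 3     1 41 19

seg <- segment_volume(ph$volume, start_slice = 10, seeds = seeds)
seg
#> rw_segmentation: 64x64x20 volume, start slice 10, 20 segmented slice(s) [1-20], 12082 object voxels

overlap_report(ph$truth, seg$masks)
#> Dice 99.78%  |  Jaccard overlap 99.57% (error 0.43%)
#> voxels: manual 12044, auto 12082, intersection 12037, union 12089
```

Dice is `2|A∩B|/(|A|+|B|)` in percent; the Jaccard overlap is
`|A∩B|/|A∪B|` in percent (its complement is exposed as `voe_error()`).
Every segmented slice records full provenance — seed counts, fitted
Gaussian parameters (on volume-normalised intensities), γ, solver
residual, and the size of the restricted system actually solved:

```r
seg$provenance[[11]][c("mu", "sigma", "residual", "n_unmarked")]
#> $mu
#>     object background
#>  0.6678064  0.3024653
#> $sigma
#>     object background
#> 0.11558973 0.06893535
#> $residual
#> [1] 9.892531e-16
#> $n_unmarked
#> [1] 1680
```

The restricted solve has 1680 unknowns on a 4096-pixel slice — the
graph-size reduction that makes slice propagation fast. Seed coordinates
are 1-based `(y, x)` with `y` the matrix row (R convention); seed files
(`label y x` text or JSON) use the same convention.

A thin command-line front end is installed under `exec/`:

```sh
rwbayes segment --input vol.nii.gz --seeds seeds.json --start-slice 42 \
        --out mask.nii.gz --provenance prov.json
rwbayes eval --pred mask.nii.gz --truth truth.nii.gz
```

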