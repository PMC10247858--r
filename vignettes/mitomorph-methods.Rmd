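---
title: "Quantifying mitochondrial morphology with mitomorph: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial morphology with mitomorph: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The problem

Mitochondria continuously remodel between two phenotypic extremes: a
*fragmented* state of small, roundish puncta and a *fused* state of large,
irregular, interconnected networks. The balance between the two shifts under
chemical stress — for example, inhibition of OXPHOS complex V pushes
HepG2 cells toward fragmentation, while complex I/III inhibition largely does
not — so the fragmented fraction of the mitochondrial population is a useful
high-content imaging readout for mechanism-based toxicology.

`mitomorph` implements an unsupervised pipeline for that readout on confocal
fluorescence images (nominally 1024 x 1024 px at 0.1 um/px, 5--30 cells per
field):

1. **Pixel classification**: a filter bank (Laplacian of Gaussian and
   Difference of Gaussians, both at sigma = 3.5 px) feeds a random forest
   trained on sparse foreground/background annotations, producing a binary
   mitochondrial mask per image.
2. **Feature quantification**: connected components of the mask become
   objects; each object is described by area, perimeter, formfactor and
   solidity (pixel units).
3. **Mixture classification**: a two-component full-covariance Gaussian
   mixture is fitted to the pooled four-feature table by multi-restart EM;
   each object is assigned to the maximum-posterior component, and
   components are named by mean object area (smaller = "fragmented").
4. **Summaries and statistics**: per condition and replicate, the fragmented
   fraction is computed by object count and by object mass (area-weighted);
   treated conditions are compared with the vehicle control by one-way ANOVA
   plus Dunnett's many-to-one test.

Companion readouts quantify mitochondrial membrane potential (cytoplasmic
rhodamine-123 intensity in a 10-px ring around each nucleus), cell death
(fraction of nuclear pixels positive for propidium iodide, with a cell
flagged dead at >= 10%), ATP (FRET biosensor emission ratio at 408/488 nm
under 408-nm excitation), nuclear-count normalization for plate assays, and
the OPA1 cleavage ratio L/(L+S) from integrated western-blot band
intensities.

## The mixture model

Let $x_i \in \mathbb{R}^4$ be the feature vector (area, perimeter,
formfactor, solidity) of object $i$. The model is

$$p(x) = \sum_{k=1}^{2} \pi_k \, \mathcal{N}(x;\, \mu_k, \Sigma_k),$$

with full covariances $\Sigma_k$ (the feature clouds are elongated and
tilted, so diagonal covariances would misrepresent them). Fitting minimizes
the negative log-likelihood by EM from 100 random starts by default; the
restart with the lowest value wins. Numerical choices:

* **Initialization** (per restart): means drawn uniformly from data rows,
  covariances set to the pooled data covariance, uniform weights. The
  number of restarts matters mainly for poorly separated data; recovery
  experiments on well-separated mixtures in this package use 10 restarts.
* **Regularization**: every M-step covariance receives a ridge of
  `1e-6 * mean(diag(Sigma))` on the diagonal, so near-duplicate subsamples
  (as arise in aggressive subsampling experiments) cannot produce singular
  covariances.
* **Convergence**: relative change of the negative log-likelihood below
  `1e-6`, or 500 iterations. The per-iteration log-likelihood trace of the
  selected restart is stored and is non-decreasing by construction of EM;
  the tests assert this to within 1e-8.
* **Restart seeds** form a nested stream derived from the master seed: the
  first $m$ restarts of any run are the same restarts for every larger run,
  which makes "best of 100 is at least as good as best of 1" a testable
  invariant rather than a statistical statement.
* **No feature standardization** by default; the mixture is fitted in raw
  pixel units. A `standardize` flag exists for sensitivity analysis (the
  likelihood is then reported on the standardized scale).
* **Class naming** is a post-hoc convention: the unsupervised components
  carry no identity, so the component with the smaller mean area is called
  "fragmented". Exactly equal mean areas (a measure-zero event) raise an
  error demanding manual assignment rather than guessing.
* **Ties in the posterior argmax** break toward the lower component index;
  this affects only measure-zero inputs and is asserted in the tests.

Objects are classified once with a model fitted on the pooled table of all
conditions (vehicle and treatments, all timepoints), then summarized per
condition — refitting per condition would let the class definition drift
with treatment.

## Shape features and their pixel-level definitions

All four features are computed on pixel sets, not polygonal outlines:

* **area** = number of object pixels.
* **perimeter** = number of boundary pixels, i.e. object pixels with at
  least one 4-connected neighbour outside the object. Pixels adjacent to
  interior holes count, so the perimeter of a holed object is the sum of its
  inner and outer boundaries.
* **formfactor** = $4\pi\,\mathrm{area}/\mathrm{perimeter}^2$ by default —
  the standard circularity, 1 for an ideal disk. A `"literal"` variant
  computing $4\pi\,\mathrm{area}/\mathrm{perimeter}$ is retained behind a
  switch for strict fidelity to pipelines that used that formula; it is
  dimensionally a length, not a shape descriptor, and is not the default.
* **solidity** = area / convex-hull area, both in pixels: the hull is taken
  over pixel centres and its area is the count of grid points inside or on
  the hull. Convex pixel sets score exactly 1.

Two rasterization effects are worth knowing. First, boundary-pixel counting
undercounts diagonal runs relative to geometric arc length, so rasterized
disks have a standard formfactor slightly *above* 1 (about 1.26--1.35 for
radii 5--50, computed directly in the tests) rather than exactly 1. Second,
nearest-neighbour upscaling of a smooth shape doubles the boundary count
only approximately — stair-step corners add a few extra boundary pixels.
Both are properties of the definition, not bugs; the mixture model is
scale-consistent because every object in a dataset is measured the same way.
Features are reported in pixels, with the physical pixel size carried in
metadata: the mixture is scale-sensitive, so units must simply be fixed, and
pixels avoid a spurious air of physical calibration.

## Segmentation

The pixel classifier mirrors an interactive "pixel classification" workflow
run headlessly. The default filter bank is exactly the two filters the
original assay selected (LoG and DoG at sigma = 3.5 px); the DoG secondary
sigma is 0.66 x sigma, the documented convention of the interactive software
this emulates, and the DoG sign convention is
$G(0.66\sigma) * I - G(\sigma) * I$ (positive on thin bright structures).
The raw intensity plane can be added as a third feature with a flag but is
off by default. The forest (100 trees by default) is trained on sparse
annotations; in synthetic benchmarks the annotations are sampled from the
generator's ground truth, standing in for a human's scribbles. Predictions
are per-pixel class votes with a fixed tie-break (an exact 50/50 vote goes
to background) so masks are bit-reproducible.

Connected components are labelled under 8-connectivity by default (thin
diagonal tubes stay single objects); 4-connectivity is available. Labels are
deterministic (numbered by first raster occurrence) and verified against an
independent flood-fill oracle. No minimum object size is applied at the
labelling level by default. The *pipeline* config, however, defaults to a
4-px floor: at realistic noise the classifier produces occasional isolated
false-positive pixels, and a cloud of 1-px specks otherwise forms a
degenerate point-mass cluster that captures one mixture component. Four
pixels is 0.04 um^2 at 0.1 um/px — far below any resolvable organelle — and
the floor is configurable down to 1 px.

Nuclei are segmented by Gaussian equalization, Otsu thresholding and a
watershed on the Euclidean distance transform; touching nuclei are split
with an h-maxima-style tolerance. These details (threshold method, seed
detection, tolerance) are this package's choices: the original in-house
module is not published in detail.

## The synthetic-data generator

No public image set accompanies the assay this package models, so every
stage is exercised on seeded synthetic scenes with known ground truth:

* **Geometry**: cells on a jittered grid; one elliptical nucleus per cell
  (default radius 40 px at the full 1024 px field, scaled for smaller test
  fields); mitochondrial objects placed in a perinuclear annulus that widens
  if the neighbourhood is saturated, with a minimum 4-px gap between objects
  so PSF blur cannot merge neighbours. Packing that cannot be satisfied
  within bounded retries is an error, not a silent degradation.
* **Classes**: fragmented objects are filled ellipses (area 20--80 px^2,
  eccentricity 0--0.7); fused objects are persistent random-walk tubes
  (length 30--120 px, width 4 px, branch probability 0.3) — at 0.1 um/px
  these correspond to ~0.5 um puncta and 3--12 um tubules, the scales a
  confocal image of HepG2 mitochondria shows. The assay itself publishes no
  numeric shape ranges; these are generator assumptions chosen once to
  produce the clearly bimodal feature clouds the original scatter plots
  display, and they are deliberately *not* tuned further.
* **Class assignment is stratified**: exactly `round(f * N)` of the N
  objects are fragmented. The planted fraction is therefore realized up to
  rounding, and fraction-recovery benchmarks measure the pipeline rather
  than the generator's binomial noise.
* **Optics and noise**: Gaussian PSF (sigma 1 px), then Poisson shot noise
  and additive Gaussian read noise (default sd 50 at foreground amplitude
  500 over background 100 — roughly SNR 10), clipped to the 16-bit range.
  Single z-plane only; no photobleaching; no spectral bleed-through.
* **Functional truth**: time-lapses plant per-cell rho123 trajectories and
  death events (a fixed fraction of nuclear pixels turns PI-positive from
  an onset frame); FRET pairs plant a per-pixel 488/408 ratio on a base
  408-nm intensity.

What passing tests on this generator do and do not show: they demonstrate
that the algorithms are implemented correctly and recover planted truth
under a realistic noise model; they do not demonstrate robustness to
out-of-focus light, staining heterogeneity, mitochondria overlapping in the
z-projection, or cell crowding beyond the packing model. Results on real
images depend on annotation quality in a way the truth-derived annotations
cannot emulate.

## Statistics

Fragmented fractions are summarized per biological replicate first, and the
replicate values enter a one-way fixed-effects ANOVA followed by Dunnett's
many-to-one comparisons against the vehicle control, two-sided, with the
classical equal-variance pooled error. Adjusted p-values come from the joint
multivariate-t distribution of the comparison statistics (correlation
$\rho_{ij} = \lambda_i\lambda_j$, $\lambda_i = \sqrt{n_i/(n_i+n_0)}$),
evaluated by deterministic-seeded quadrature; with one treatment the
procedure collapses exactly to the pooled two-sample t-test. Simulation
tests verify a type-I error of 0.05 +/- 0.01 for the ANOVA and a familywise
error of 0.05 +/- 0.01 for Dunnett under the null (5,000 simulated
experiments each), and the critical value for the balanced 4-treatment,
df = 20 design reproduces the published Dunnett table value (2.65). Both
count- and mass-based fractions are tested and reported, since either can be
the readout of interest.

## Robustness analyses

`robustnessAnalysis()` refits the mixture on subsamples and reports the
distribution of per-component means and variances under three schemes:
leave-one-compound-out, random halves of the images (100 by default), and
random object fractions (1/2, 1/10, 1/500). On 10,000-object tables the 1/2
and 1/10 fractions reproduce the full-fit means within a few percent, while
1/500 (20 objects) visibly destabilizes the variance estimates — the
qualitative pattern that justifies trusting fits on full datasets.
Subsamples too small to fit are reported as unfitted rather than failing the
analysis.

## Problem sizes used in tests and benchmarks

The packaged tests and the acceptance script run on desk-scale problems
chosen as the package's own benchmark sizes: 192--256 px synthetic fields
with 3--9 cells for imaging stages, 20 scenes for the segmentation IoU
benchmark (mean IoU >= 0.7 against ground truth at default SNR), mixtures of
n = 10,000 over 10 seeds for parameter recovery (means within 5% relative,
weights within 0.03), and 5,000 simulated experiments for the error-rate
calibrations. The statistics are intensive quantities, so field size does
not change their meaning.

## Known limitations

* Per-image (not per-cell) morphology aggregation; objects are not assigned
  to cells after segmentation.
* K is fixed at 2; intermediate morphologies are forced into one of the two
  classes, and swollen-but-round organelles will be called "fragmented" by
  shape even when large.
* No cell tracking across time-lapse frames; death fractions are per-frame
  population measures.
* Western-blot densitometry (lane finding, background subtraction) is out
  of scope; the cleavage ratio consumes already-integrated band
  intensities.
* The "object mass" weighting uses binary-object area, not integrated
  intensity — the objects are binary at that stage of the pipeline.

## A worked example

```{r example, eval = FALSE}
library(mitomorph)

cfg <- list(
  seed = 8L,
  outDir = "run1",
  nReplicates = 3L,
  conditions = list(
    list(name = "vehicle",  fragmentedFraction = 0.3),
    list(name = "compound", fragmentedFraction = 0.6)
  )
)
res <- runPipeline(cfg)
res$fractions$summary
res$stats[, c("comparison", "method", "estimate", "p_adjusted")]
```

The run writes `features.csv`, `assignments.csv`, fraction tables, the
fitted mixture as JSON and a deterministic run log into `outDir`; rerunning
with the same config produces byte-identical files.
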