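# mitomorph

Unsupervised quantification of mitochondrial morphology from high-content
fluorescence microscopy, for toxicologists and cell biologists screening
compounds that perturb mitochondrial dynamics.

Mitochondria shift between *fragmented* (small, roundish puncta) and *fused*
(large, irregular networks) states under chemical stress, and the fragmented
fraction of the organelle population is a sensitive imaging biomarker —
OXPHOS complex V inhibitors drive fragmentation while complex I/III
inhibitors largely do not. `mitomorph` turns confocal images into that
readout without hand-drawn class boundaries:

1. **Segmentation** — a filter bank (Laplacian of Gaussian and Difference of
   Gaussians, σ = 3.5 px) feeds a random-forest pixel classifier trained on
   sparse fore/background annotations; connected components of the resulting
   binary mask are the mitochondrial objects. Nuclei are segmented by a
   distance-transform watershed.
2. **Features** — each object is measured in pixel units: area, perimeter
   (boundary-pixel count, inner + outer boundaries), formfactor
   (4πA/P², circularity) and solidity (A / convex-hull area).
3. **Classification** — a two-component full-covariance Gaussian mixture

   p(x) = π₁ N(x; μ₁, Σ₁) + π₂ N(x; μ₂, Σ₂),  x = (area, perimeter, formfactor, solidity)

   is fitted to the pooled feature table by EM from 100 random restarts,
   keeping the restart with the lowest negative log-likelihood. Objects get
   the maximum-posterior component; the smaller-mean-area component is named
   "fragmented".
4. **Summaries + statistics** — fragmented fraction per condition and
   replicate, by object count and by object mass (area-weighted), compared
   against the vehicle control with one-way ANOVA plus Dunnett's
   many-to-one test.

Companion functional readouts: cytoplasmic rhodamine-123 intensity in a
10-px ring around each nucleus (membrane-potential proxy), propidium-iodide
death calls (≥ 10% of nuclear pixels PI-positive), FRET ATP-biosensor
ratios (488/408 nm emission), nuclear-count normalization, and the OPA1
cleavage ratio L/(L+S).

Because no public image set accompanies the assay, the package ships a
seeded synthetic-scene generator (`generateMitoScene`, `generateMmpTimelapse`,
`generateFretPair`, `sampleFeatureTable`) that renders fields of cells with
known ground truth — every pipeline stage is benchmarked against planted
truth, fully offline.

## Worked example

Simulate a vehicle condition (planted fragmented fraction 0.3) against a
compound (0.6), three replicates each, and run the full pipeline:

```r
library(mitomorph)

res <- runPipeline(list(
  seed = 8L, outDir = "run1", nReplicates = 3L,
  conditions = list(list(name = "vehicle",  fragmentedFraction = 0.3),
                    list(name = "compound", fragmentedFraction = 0.6))))

res$fractions$summary[, c("condition", "n_objects",
                          "mean_fraction_by_count", "se_fraction_by_count")]
#>   condition n_objects mean_fraction_by_count se_fraction_by_count
#> 1  compound        93                  0.614              0.01309
#> 2   vehicle        80                  0.287              0.00477

res$stats[, c("comparison", "method", "estimate", "p_adjusted", "significant")]
#>           comparison            method estimate p_adjusted significant
#> 1 compound - vehicle fraction_by_count    0.327   1.96e-05        TRUE
#> 2 compound - vehicle  fraction_by_mass    0.193   1.62e-04        TRUE

res$model
#> GmmModel: 2 components over area_px, perimeter_px, formfactor, solidity
#>   weights: 0.4624 0.5376
#>   -logLik: 785.8326 (best of 20 restarts)
#>   classes: 1=fragmented, 2=fused
```

The planted fractions (0.3 / 0.6) come back as 0.287 / 0.614 from the fully
segmented and classified images; the planted 0.3 shift is estimated at 0.327
and flagged significant against the vehicle by both fraction definitions.
`runPipeline` writes the feature table, per-object assignments, fraction
summaries, the mixture model (JSON) and a deterministic run log to `outDir`;
the same config and seed reproduce every file byte for byte.

A thin command-line wrapper for the two entry points lives at
`inst/scripts/mitomorph.R` (`simulate` renders a scene from a YAML parameter
file; `run` executes a pipeline config).

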