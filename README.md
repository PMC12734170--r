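# vesseltex

Texture-based preprocessing and topology-aware evaluation for
time-sequential digital subtraction angiography (DSA), in R.

Automated segmentation of intracranial arteries from DSA sequences fails
most often where it matters most: thin, low-contrast distal branches get
lost against smooth background shading and bone-edge subtraction
residues, and the resulting masks are *fragmented* even when their pixel
overlap looks acceptable. `vesseltex` is for image-analysis researchers
and methodologists who want (a) a vessel-focused preprocessing front end
for segmentation models, (b) an evaluation suite that measures vascular
*topology* as well as overlap, and (c) a fully synthetic, exactly
ground-truthed phantom generator to validate both.

## What it computes

**Per-frame texture descriptors** (vessel-bright frames, 5 x 5 window,
reflective padding):

- local contrast — the windowed variance
  `C(x,y) = (1/N) Σ_{(i,j)∈N(x,y)} (I_ij − μ(x,y))²`;
- local entropy — `H(x,y) = −Σ_k p_k log₂(p_k + ε)` over the window's
  256-level histogram, `ε = 2⁻⁵²`;
- brightness threshold — `T = inf{t : P(I ≤ t) ≥ 0.85}` from the frame's
  empirical CDF, with bright mask `B = 1 ⇔ I > T`.

These fuse into the combined vessel evidence
`F = (Ĉ + Ĥ + B)/3` (normalized maps, configurable weights), binarised at
Otsu's threshold of `F`. Sequences become a two-channel model input: `F`
of the inverted minimum intensity projection, plus the renormalized sum
of per-frame scores. A CLAHE baseline
(`(cdf − cdf_min)/(n_tile − cdf_min)·(G−1)` per tile, clipped histograms,
bilinear tile interpolation) is included for comparison.

**Evaluation**: the seven confusion metrics (DICE, IoU, accuracy,
sensitivity, specificity, precision, F1) with batch mean/sd/95% CI
reports, and **Vessel Connectivity (VC)** — skeletonize both masks,
decompose the ground-truth centerline into segments between junctions and
endpoints, and average per-segment connectivity errors
`CE = mean matched distance + Σ arc lengths of unmatched runs`
(`r_match = 2` px). Lower VC means better-preserved continuity; gaps in
thin branches raise VC sharply while barely moving DICE.

**Phantoms**: seeded bifurcating vessel trees with per-node bolus arrival
times, rasterized with projected-cylinder intensity profiles over smooth
backgrounds with bone-like band artifacts, plus controlled degradations
(gaps, branch deletion, dilation, shift, speckle). Deterministic per
(config, seed).

**Protocol arithmetic**: 256/20 patch tiling with exact stitch-back, a
verifiable U-Net specification (4 levels from 32 channels + bottleneck,
~7.8 M parameters, counted analytically), the five-operator augmentation
policy, and sequence-level 70/10/20 splits.

## Worked example

```r
library(vesseltex)

cfg  <- phantomConfig(size = 256, noiseSd = 10/255)
tree <- generateTree(cfg, 7)
sim  <- simulateSequence(tree, cfg, 7)
sim$sequence
#> DSASequence: 13 frame(s) of 256 x 256, integer mode (G = 256), vessel_dark, 4 fps

input    <- buildModelInput(sim$sequence)        # two-channel fused input
pred     <- thresholdSegmenter(input)            # texture pipeline
baseline <- segmentRawOtsu(sim$sequence)         # no preprocessing

round(segmentationMetrics(pred, sim$fullMask), 3)
#>        dice         iou    accuracy sensitivity specificity   precision          f1
#>       0.716       0.558       0.920       0.741       0.948       0.693       0.716
round(segmentationMetrics(baseline, sim$fullMask), 3)
#>        dice         iou    accuracy sensitivity specificity   precision          f1
#>       0.347       0.210       0.522       0.933       0.457       0.213       0.347

vesselConnectivity(sim$fullMask, pred)
#> Vessel Connectivity: VC = 0.8272 over 189 segment(s), matched fraction 0.895 (r_match = 2 px)
vesselConnectivity(sim$fullMask, baseline)
#> Vessel Connectivity: VC = 1.5661 over 189 segment(s), matched fraction 0.815 (r_match = 2 px)
```

On this noisy phantom the texture-fused input roughly doubles DICE over
raw-intensity Otsu (0.72 vs 0.35 — the baseline floods the bright
background, see its 0.21 precision) and cuts the connectivity error
nearly in half (VC 0.83 vs 1.57): the same qualitative pattern on both
the overlap and the topology axis.

A command-line interface wraps the same functions
(`inst/cli/vesseltex simulate | preprocess | segment | evaluate | vc |
unet-spec | split`), writing masks as PNG, sequences and scores as TIFF,
and a YAML provenance sidecar per run.

## Package layout

- `R/`, `src/` — S4 classes and pipeline (texture, fusion, CLAHE, VC,
  phantoms, backend, CLI); windowed descriptors in Rcpp.
- `tests/testthat/` — unit and property tests with independent
  brute-force oracles; `test-acceptance.R` holds the end-to-end checks.
- `vignettes/vesseltex-methods.Rmd` — the methods vignette: model
  details, design decisions, phantom realism limits, numerical choices.
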