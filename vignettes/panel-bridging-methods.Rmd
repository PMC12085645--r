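---
title: "Methods: panel-bridging integration by virtual labelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-bridging integration by virtual labelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Standard immunofluorescence resolves ~4 molecular markers per sample. When an
experiment needs more — say, eight epithelial–mesenchymal (EM) state markers on
top of structural stains — one can run several 4-plex panels in parallel wells,
each carrying the same *anchoring* channels (label-free relief image, DNA,
F-actin, a junctional β-catenin-like marker) plus one *variable* marker unique
to the panel. `plexbridge` integrates such panels into a single high-plexity
single-cell dataset: for each variable marker an image-to-image model is
trained on the wells where that marker was experimentally labelled (anchors in,
marker out), then applied to **all** wells. Because the anchors recur
everywhere, the per-marker models bridge the otherwise disjoint cell
populations, yielding one matrix of all markers × all cells. This is a
designed-anchor form of mosaic integration: the anchors are chosen at
experiment time precisely so that they support the bridging models.

Two model families are implemented on an in-package convolutional engine
(there is no deep-learning framework dependency):

* **U-Net regression** — encoder of 4×4/stride-2 convolutions (leaky-ReLU 0.2),
  widths doubling from `base_filters` and capped at 8× (64…512 at paper
  scale over 8 layers), a mirrored transposed-convolution decoder with skip
  concatenation, tanh output, L1 loss. Batch normalisation
  (ε = 1e-5, momentum 0.1) after the activation on all but the first and final
  convolutions; dropout 0.5 on the three deepest decoder blocks.
* **Conditional GAN** — the same U-Net as generator plus a patch
  discriminator (4×4 stride-2 convolutions doubling 64→512, a stride-1
  512-wide layer, then a stride-1 1-channel classifier; no batch norm on the
  first layer). Objective `100·L1 + 1·LSGAN`, where the LSGAN term is the mean
  squared error of the discriminator score against its target label.

Training uses ADAM (β₁ = 0.5, β₂ = 0.999), learning rate 2e-4 held constant
for 50 epochs then decayed linearly to zero over 50 more, with ×4 flip
augmentation. Inputs and targets are normalised to [−0.5, 0.5]
(`x/255 − 0.5`); since the generator's tanh can emit values in [−1, 1], the
inverse mapping clips to [−0.5, 0.5] before returning to 8-bit. Backpropagated
gradients are verified against finite differences in the test suite.

## Preprocessing chain

Fixed order: label-free background subtraction (rolling 40 px median, or a
σ = 0.5 Gaussian alternative) → label-free contrast enhancement allowing 35%
of pixels to saturate (17.5% per tail, the Fiji convention) → per-image
min–max 8-bit conversion of the label-free channel → dataset-level 8-bit
conversion of fluorescence channels, treating the bottom and top 10% of pooled
pixels as outliers and mapping the remaining range to 0–255 — computed **per
channel**, because different markers have incommensurate dynamic ranges and
models are trained per marker → bilinear half-resize → non-overlapping
256-px patches (`floor` tile counts, remainders dropped) → ×4 flips →
model-range normalisation. A denoiser slot (`preprocess_config(denoiser =
...)`) accepts a plugin applied to resized 8-bit images; none is bundled.

## The synthetic benchmark and what it plants

`sim_config()` describes a three-condition EM-modulation experiment: control,
a weak inducer (EGF-like) and a strong inducer (TGF-β-like), with per-cell
latent state *s* ∈ [0,1] drawn from condition-specific Beta distributions
(defaults Beta(2,6), Beta(4,4), Beta(6,2): ordered means 0.25 < 0.5 < 0.75,
with deliberate overlap — treatments shift a continuum, they do not split it).
Geometry: nuclei as random ellipses on a jittered grid; star-convex cell
bodies tiling by nearest-normalised-radius, with radius (+30% over the state
range) and protrusion lobes growing in *s*. Channels, on [0,1] before 16-bit
quantisation:

* **DNA** — uniform nuclear signal; **F-actin** — cytoplasmic with a cortical
  rim; **junctional anchor** — membrane-bound weight `w(s)` interpolating
  0.75 → 0.35 from epithelial to mesenchymal (the relocalisation magnitude is
  the package's "anchor informativeness" control; the corresponding biological
  quantity is not characterised, so it is a parameter, not an assertion).
* **variable markers** — monotone logistic responses `f_m(·)` (direction ±1,
  marker-specific midpoint/slope, range 0.10–0.85 of the dynamic range) of a
  marker-specific *effective sub-state*: the shared morphological state *s*
  plus a condition-dependent advance of the molecular EM program
  (`(c − 2) · marker_condition_shift`, default 0.16 — inducers regulate
  marker expression before morphology follows) and independent cell-level
  sub-state noise (sd 0.05). Real labels therefore carry condition
  information that the anchors — and hence any virtual label — cannot
  reveal; this is what keeps experimental multiplexing the gold standard in
  the benchmark. Rendering applies the configured localisation, cell-level
  lognormal noise (σ = 0.12) and pixel noise (Gaussian σ = 1% of range plus
  Poisson-like variance 0.2%·intensity). With noise off, the primary
  compartment carries exactly the expected response — the recovery oracle
  used throughout the tests.
* **label-free relief** — shaded-relief transform of the cell height map. The
  relief amplitude and intracellular granularity scale with *s*
  (`dic_state_gain`): mesenchymal cells image with stronger texture. This is
  the benchmark's planted "latent anchor information": it is visible to the
  virtual-labelling models (which consume the label-free channel) but is
  **not** summarised by the single-cell feature set (no features are extracted
  from the label-free channel, as in CellProfiler practice). The planted
  effect mirrors the premise being tested — that virtual labelling surfaces
  information the fixed feature summary of the anchors does not expose, which
  is exactly why integrated virtual markers can improve downstream analyses
  over the anchor features alone while never exceeding truly independent
  experimental labels.

One RNG stream is derived per well from `(seed, well)`, so any well
regenerates independently and whole datasets are byte-identical given
`(config, seed)`. The generator does not attempt photorealism: no
illumination/vignetting artefacts, no 3-D structure, no spatial correlation in
pixel noise. Passing tests on it therefore demonstrate correctness of the
machinery and directional behaviours under a controlled planted effect — not
performance on real microscopy.

## Segmentation and features

Nuclei: Otsu threshold on DNA + connected components (< 5 px discarded).
Cells: seeded propagation on the actin channel restricted to an
actin-or-nucleus foreground (the secondary-object convention). Objects
touching the image border are excluded; neighbourhood features are computed
*before* exclusion so border cells still count as neighbours. The feature
table is frozen by `feature_schema()`: 17 morphology/neighbourhood features
(area, perimeter, form factor, eccentricity, solidity, extent, major/minor
axis, aspect ratio, convex area, equivalent diameter, orientation, neighbour
count, percent touching, nearest-neighbour and mean-neighbour distance,
nucleus/cell area ratio — the published feature list is in a supplementary
table we do not have, so this enumeration is a documented stand-in of the
stated cardinality and categories), and per marker 142 features: 15
object-intensity features, 75 radial-distribution features (fraction-at-
distance, mean fraction, radial CV × 25 concentric annuli, with the radial CV
over 8 angular wedges), 52 texture features (13 Haralick statistics × 4
directions on 8-level globally quantised intensities), plus pairwise in-cell
colocalisation PCC. Cells under 9 px or with non-finite core features are
dropped with a message. The schema is convention-compatible with
CellProfiler, not bit-compatible.

## Integration, cross-validation and the leakage rule

Folds partition *fields* (all tiles of a field share a fold) stratified by
condition — tile-level folds would leak overlapping spatial context. For each
marker × fold, a model trains on the marker's training wells outside the fold
and predicts every field inside the fold, across all wells. Consequently every
cell's virtual value comes from a model that never saw that field as a
training target, including cells in the marker's own training wells (held-out
rule; the alternative — in-sample predictions for training wells — is
optimistic and was rejected). Downstream analyses use virtual values for all
cells uniformly; real variable-marker values are reserved for evaluation.
A ground-truth pass-through stub model exercises the whole orchestration path
and must reproduce the ground truth bit-exactly.

## Fidelity metrics and statistics

SSIM uses uniform (not Gaussian) 7×7 windows — only the window size is
specified upstream, and the uniform choice keeps the brute-force oracle
trivial; constants C1 = (0.01·255)², C2 = (0.03·255)². Pixel-PCC is computed
per field/tile and aggregated by median (per fold, then across folds), not on
pooled pixels. Feature-PCC correlates a feature across cells between real and
virtual labels. Significance uses Welch's two-sided t-test; raw p-values are
reported without multiple-testing correction. Distribution recapitulation is
summarised by density-normalised histograms and the Kolmogorov–Smirnov
distance.

## Classification, embedding, pseudotime

Classification: per fold, features are standard-scaled and PCA-reduced with
training-set parameters, then an RBF-kernel SVM (default cost) predicts
condition; macro-F1 averaged over folds. Component selection by Minka's MLE is
not available in the installed stack, so the documented fallback — the
smallest number of components explaining 95% of training variance — is used
and logged. Morphology/neighbourhood features are included in every
classification recipe (so that spatial information potentially encoded by the
models is equally available to all recipes) and excluded from every manifold
recipe (morphology is EM-state-linked and would confound state-sensitive
manifolds). The deterministic `pca2` backend underlies all tested properties;
nonlinear embeddings are pluggable functions.

Pseudotime is a k-node polygonal principal curve (default k = 25; an 8-node
variant suits smaller embeddings): nodes initialised from PC1 quantile-bin
means, refined ≤ 50 iterations by projection/averaging with light neighbour
smoothing, converged when maximal node movement < 1e-4 of the data diameter.
Pseudotime is normalised arc length from the root, the endpoint whose 50
nearest cells are most control-enriched. The curve is fitted in the embedding
space used for the manifold (a flag could expose PCA-space fitting; embedding
space matches how the manifolds are read). Marker dynamics z-score each mean-
intensity feature across cells and average within equal-count pseudotime bins
(deciles), so endpoint bins are never dominated by a few extreme cells; real
series are restricted to each marker's experimentally labelled wells.

## Desk-scale problem sizes

The `desk` preset exercises every code path at interactive scale, and is the
configuration used by the package's own acceptance analyses: 3 conditions ×
4 marker panels × 1 well, 12 fields of 128 px per well (≈ 1 500 profiled
cells), half-resized to one 64-px patch per field; depth-6 U-Net with 16 base
filters, batch 8, 5 + 5 epochs; 2 field-level folds (with one well per
condition per marker and 12 fields per well, 5 folds would leave fewer than
three fields per condition in training splits; k = 5 remains the default for
dataset-scale use). The desk marker subset is factorial — EpCAM (−, membrane),
N-cadherin (+, membrane), PTEN (−, cytoplasmic), vimentin (+, cytoplasmic) —
covering both response directions at both localisations. The paper-scale preset (256-px patches, depth 8, 64
filters, 50 + 50 epochs, 5 folds) is retained for larger runs.

## Known limitations

* The conv-net engine is CPU-bound R/BLAS; paper-scale training is feasible
  but slow — the architecture is faithful, the throughput is not.
* A transformer bottleneck (`arch = "custom"`) is an interface slot only;
  pretrained-weight loading is out of scope.
* The generator's planted effect is one-dimensional; real EM biology is not.
* Radial/texture feature values are convention-compatible with CellProfiler
  but not numerically identical to it.
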