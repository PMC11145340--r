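---
title: "Nuclei-constrained attention MIL: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclei-constrained attention MIL: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmil)
```

## The problem and the model

Whole-slide images (WSIs) are gigapixel scans with a label per slide but
none per region — the classic multiple-instance setting: a slide (bag) is
cancerous iff at least one of its tiles (instances) is. `nucmil`
implements an attention-based MIL classifier in which the slide-level
decision is *constrained* by two finer levels of evidence:

1. **Slide level.** Each 512×512 tile is embedded to a 1024-d feature
   vector by a pluggable extractor. Gated multi-head attention assigns a
   weight $s_i$ to each tile,
   $$s_i = \mathrm{softmax}_i\!\big(\tau(\mathrm{SA}_a(p_i))\odot
   \xi(\mathrm{SA}_b(p_i))\big),$$
   with a sigmoid branch $\tau$ and a tanh branch $\xi$, each branch a
   multi-head self-attention transform of the bag followed by a per-tile
   scalar projection. The slide feature is the convex combination
   $f_{slide} = \sum_i s_i p_i$, classified by a linear head with
   cross-entropy loss.
2. **Patch level.** The $c = 8$ tiles with the highest attention inherit
   the slide label (optionally the $c$ lowest-attention tiles are
   supervised as normal); a linear instance head is trained with a
   noise-robust loss (below).
3. **Nuclei level.** Within each selected tile, segmented nuclei become
   nodes of a K-nearest-neighbour graph (an edge joins a nucleus to each
   of its $K=5$ nearest neighbours closer than $d_{min}=50$ px,
   symmetrised by union). Nodes carry a 16-dimensional handcrafted
   feature vector; two rounds of degree-scaled multi-aggregator message
   passing and mean pooling feed a graph-level class head supervised by
   the slide label, again with the noise-robust loss.

The total training objective is the exact weighted sum
$$L_{total} = w_1 L_{slide} + w_2 L_{patch} + w_3 L_{nuclei},
\qquad (w_1, w_2, w_3) = (0.7, 0.2, 0.1),$$
minimised with Adam. Setting $w_2 = w_3 = 0$ is the slide-only ablation;
restoring each term separately reproduces the ablation structure of the
method's evaluation.

## The 16 handcrafted nucleus features

Geometric features come from image moments of the binary nucleus mask
$H$ (coordinates 0-based, $x$ = column, $y$ = row):
$M_{pq} = \sum_x\sum_y x^p y^q H(x,y)$, centralised to $\mu_{pq}$ and
normalised as $\bar\mu_{pq} = \mu_{pq}/M_{00}$. The equivalent-ellipse
axes are
$Major = \sqrt{8(\bar\mu_{20}+\bar\mu_{02}+R)}$,
$Minor = \sqrt{8(\bar\mu_{20}+\bar\mu_{02}-R)}$ with
$R = \sqrt{4\bar\mu_{11}^2 + (\bar\mu_{20}-\bar\mu_{02})^2}$ — the
enclosing square root is required for pixel units (a solid disk of radius
$r$ then reports $Major = 2r$) and matches the standard region-properties
convention. Orientation is
$\theta = \tfrac12\arctan\big(2\bar\mu_{11}/(\bar\mu_{20}-\bar\mu_{02})\big)$,
which the plain arctangent confines to $(-\pi/4, \pi/4]$; vertical and
horizontal elongations both map into this branch. The remaining
features: $Area = M_{00}$; $Ecc = \sqrt{1 - Minor^2/Major^2}$;
$Ell = Minor/Major$; $Dia = \sqrt{4\,Area/\pi}$; the perimeter
$Per = N_v + N_h + w_d (N_{d1} + N_{d2})$ counts adjacencies between
contour pixels (foreground pixels with a 4-connected background
neighbour) along the four directions, with diagonal weight $w_d = 2$ as
the primary form and $w_d = \sqrt 2$ available
(`perimeter diagonal_weight`); and $AreaHull$ counts the lattice points
inside or on the convex hull polygon of the pixel set — a pixel count,
so $AreaHull \ge Area$ always holds, with the polygon's shoelace area
exposed separately as `poly_area`.

Texture features are computed on the gray-level co-occurrence matrix of
the nucleus patch quantised to $l = 8$ bins, counting only pixel pairs
that lie entirely inside the mask, for the four offsets
$(1,0), (1,1), (0,1), (-1,1)$. Each direction's matrix is normalised to
sum to 1 before the statistics (contrast, dissimilarity, homogeneity,
entropy with $\log_2$ and $0\log 0 = 0$, angular second moment,
dispersion $\sum (P - \epsilon)^2$ with $\epsilon = 1/l^2$), and the four
directions are averaged; per-direction output is available via
`texture_features(average = FALSE)`. Roughness is $Per / P_n$ with $P_n$
the hull-polygon perimeter. The choice $l = 8$ keeps the co-occurrence
matrices of small nuclei well populated; the quantisation bin width,
not the raw 8-bit range, sets the texture resolution.

## Degree-scaled message passing

Neighbour messages $M(h_u)$ are summarised by four statistics (mean,
population standard deviation, max, min), each taken under three degree
scalings $S(D,\alpha) = (\log(D+1)/\delta)^\alpha$ for
$\alpha \in \{0, +1, -1\}$ — twelve blocks concatenated in the fixed
order `[identity, amplify, attenuate] × [mean, sd, max, min]`. The
normaliser $\delta$ is the mean of $\log(\mathrm{degree}+1)$ over all
nodes of the *training* graphs, computed once and frozen in the
checkpoint. Isolated nodes aggregate to an all-zero message row (the
statistics are undefined on empty neighbourhoods and zero keeps the
update map well defined); an empty graph is represented by a learned
null embedding and flagged. Ties at the K-th neighbour distance break
toward the lower node index, making graph construction deterministic.

## The noise-robust instance loss

Instance supervision inherited from the slide label is noisy — a
high-attention tile of a cancerous slide need not be cancerous. The
patch and nuclei branches therefore use an active-passive pair:
$$\mathrm{NCE} = \frac{\log p(y|x)}{\sum_k \log p(k|x)} \in [0,1],
\qquad
\mathrm{RCE} = -\sum_k p(k|x)\log q(k|x),\; \log 0 := A = -4 ,$$
so for one-hot truth $\mathrm{RCE} = -A(1 - p(y|x))$. Closed forms used
as test anchors: a uniform binary prediction against one-hot truth gives
NCE $= \log(1/2)/\log(1/4) = 0.5$ and RCE $= -0.5A = 2$. A plain-CE
active term is available (`apl_active = "ce"`) for ablation.

## What the synthetic generator emulates — and what it does not

Clinical cohorts, trained backbone weights and nucleus segmentations
cannot ship with a package, so every stage is exercised on synthetic
slides: grids of gray tiles with dark elliptical nuclei on a light
background. Nuclei are filled rotated ellipses (analytic truth for the
geometric features) with additive Gaussian texture noise;
non-overlap is enforced by rejection sampling of centres so each
instance label is a single 4-connected component. The class contrast
defaults mirror the empirical cancer/normal morphometry ratios reported
for breast tissue: mean nucleus area ratio 1.3726 (the primary
calibrated contrast), darker chromatin (higher contrast), noisier
texture (homogeneity and angular-second-moment ratios below 1, entropy
above 1), slightly rounder shape. A positive slide draws a random
witness subset of its tiles (fraction `witness_rate`, default 0.75, never
fewer than one) from the cancer-like morphology — the MIL bag
assumption made literal.

Defaults: 30 slides per class, 8 tiles of 512 px per slide, 15–30
nuclei per tile, background 230 ± 4. The nucleus density is far below
real breast tissue (where a 512-px field at 0.25 µm/px holds hundreds of
nuclei); it is a deliberate desk-scale subsampling that leaves the
morphometric contrasts intact. No magnification is fixed: all sizes are
in pixels and scale with `area_mean`. The generator does **not** emulate
H&E colour (features are gray-level by design — colour features are
excluded from the handcrafted set), stain variation, scanner
heterogeneity, lesion subtypes, or spatially structured tissue
architecture. Passing tests therefore demonstrate the pipeline's
mechanics and its recovery of configured morphological contrasts, not
clinical performance.

## The stub extractor and feature standardisation

The default extractor is a deterministic stand-in for a pretrained
convolutional backbone: the tile is block-averaged to 16×16, centred by
a fixed constant, and mapped through a seeded random projection to 1024
dimensions. Fixed centering (rather than per-tile standardisation)
matters: per-tile normalisation would erase exactly the between-tile
intensity contrast that distinguishes witness tiles. Random projections
preserve linear separability, but the projected features carry a large
common-mode component (the shared background), so the trainer fits a
per-dimension standardiser on the training split's patch features and
freezes it into the checkpoint — the same pattern as the z-scaler for
the 16 handcrafted features, and the analogue of the fixed input
normalisation a real backbone would apply.

## Numerical and optimisation choices

* Exact gradients come from a small reverse-mode tape; the
  test suite checks every operation and the full composite training
  step against central finite differences (~1e-11 relative error).
* Optimiser: Adam with decoupled weight decay (AdamW). Defaults
  lr $10^{-3}$, decay $10^{-2}$, 20 epochs, early stopping on
  validation total loss with patience 10, best-validation checkpoint.
  The 1024-wide linear heads have far more parameters than a desk-scale
  dataset has slides; without decay they memorise the training bags
  instead of the class direction.
* Attention: 4 heads, key width 64 per head, key scaling
  $1/\sqrt{d_K}$; the simpler `gated_plain` variant (no self-attention
  transforms) is available for ablation.
* Message passing: 2 layers, hidden width 64, ReLU; population (not
  sample) standard deviation in the aggregator, clamped-at-zero square
  root so identical neighbours give exactly zero spread.
* Degenerate inputs: empty masks raise errors; collinear/singleton
  masks clamp `Minor` to 1 px and fall back to `AreaHull = Area`
  (flagged); single-pixel nuclei raise "degenerate GLCM"; probability
  floors at $10^{-12}$ guard the logs; `0.5`-probability ties in
  `PreCls` resolve to class 0 via `which.max`.
* Determinism: one master seed drives the generator, splits, parameter
  initialisation and epoch shuffles; two runs with the same seed produce
  identical loss histories, and the generator is bit-reproducible.

## Problem sizes used by the tests and the acceptance script

Unit tests run on tiny fixtures (tiles of 48–128 px, bags of ≤ 8
patches, graphs of ≤ 60 nodes, 100-fold oracle sweeps on masks ≤ 32×32).
The Monte-Carlo recovery of the configured area ratio uses 10,000
standalone nuclei per class. The end-to-end demonstration trains the
default 60-slide synthetic dataset (42/6/12 stratified 7:1:2 split) for
20 epochs and evaluates the 12 held-out slides; the acceptance variant
repeats this over three seeds and requires at least two to reach 90%
test accuracy, reflecting the stochastic nature of a small test set.

## Known limitations

* The stub extractor is linear; it demonstrates the pipeline, not
  representation learning. A real backbone can be plugged in through
  the `feature_extractor` interface (`width`, `deterministic`, `fun`).
* One nucleus graph spans one selected tile (the method text leaves the
  graph's spatial extent open; per-tile is the implemented reading), so
  cross-tile nucleus interactions are not modelled.
* Whether `dmin = 50` is in level-0 pixels or micrometres is not
  derivable from the method text; the package treats it as pixels and
  exposes it (`dmin`).
* Pyramidal WSI formats are out of scope; the pipeline consumes plain
  images and manifests, with masking level and downsample factor
  configurable (`tissue_mask(level = )`).
* Multi-class subtyping, colour/contour features, stain normalisation
  and AUC-style evaluation are out of scope.
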