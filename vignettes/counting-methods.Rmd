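---
title: "Semi-supervised density-map counting of conifer new shoots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised density-map counting of conifer new shoots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shootcount)
```

## The problem

The number of current-season new shoots on a slash pine (*Pinus
elliottii*) crown is a phenotyping trait: it proxies shoot density and
hence growth and photosynthetic capacity. Counting shoots in top-down
RGB images of single trees is a dense small-object counting problem —
tens to hundreds of bright, irregular spots per crown — and exhaustive
point annotation is the bottleneck. `shootcount` implements a
semi-supervised density-estimation approach: a small labeled subset of
images supervises a counting network directly, while a large unlabeled
remainder contributes through teacher-student consistency.

## Density-map supervision

Each annotated image carries one point per shoot. The regression target
is a density map: every point is spread into a unit-mass 2-D Gaussian,
so the map's integral equals the count. Bandwidths follow the geometric
adaptive rule used throughout the crowd-counting literature,

$$\sigma_i = \beta \cdot \bar d_i^{(k)},$$

the mean distance from point $i$ to its $k$ nearest annotated
neighbours, scaled by $\beta$. Defaults are $k = 3$, $\beta = 0.3$, the
convention of the CSRNet line of work. Kernels are truncated at
$\pm 4\sigma$, clipped to the canvas, and renormalized to unit mass, so
shoots at image borders still contribute exactly one count; conservation
of mass is the property the evaluation metrics depend on, and the test
suite checks it on random point sets. Single-point images fall back to a
fixed $\sigma = 4$ px (no neighbour distance exists), and bandwidths are
floored at 0.25 px so coincident points stay well defined.

The regression head operates at 1/8 of the input resolution, so the
full-resolution target is reduced by $8 \times 8$ block sums, which
preserve the integral exactly.

## The network

The extractor is a VGG19-style convolutional stack in which the last
three stages all sit at 1/8 resolution: pooling is retained through
stage 3 and stages 4–5 use dilation-2 convolutions instead of further
pooling. This is forced by the published feature geometry (three maps of
$H/8 \times W/8$ with 256, 512 and 512 channels). The two deepest maps
are blended by attentional feature fusion (AFF): a gate
$M = \sigma(L(X) + G(X))$ with $X$ the sum of the inputs, $L$ a
pointwise-conv bottleneck applied per location, and $G$ the same
structure applied to the globally average-pooled channel vector,
broadcast spatially (the multiscale channel attention module, MS-CAM).
The fused map is

$$W = M \otimes L_f + (1 - M) \otimes H_f,$$

with $M$ strictly inside $(0, 1)$ under the sigmoid. Because the second
fusion pairs a 512-channel map with the 256-channel stage-3 map, a
$1 \times 1$ projection reconciles the widths first; the published
description is silent on this mismatch, so the projection is our
declared convention.

The fused features pass a multiscale dilated convolution (MDC) block:
three parallel $3 \times 3$ columns with dilations 1, 2 and 3,
concatenated, projected back, and added to an identity shortcut.
Dilations (1, 2, 3) are the smallest set whose union of sampling taps
covers a contiguous window — no gridding holes, which matters when a
single lost pixel can hide several shoots. The regression head
($3\times3$ then $1\times1$ convolutions, ReLU output so densities are
nonnegative) emits the density map; the classification head (two
$1\times1$ convolutions, global average pooling, softmax) emits a
density-class distribution.

Density classes discretize the per-image count into $C = 5$ right-open
bins. How the class target is constructed is not pinned down by the
published description; this package uses per-image classification with
bin edges at the quintiles of the labeled training counts, which keeps
every class populated on any dataset. The choice of 5 classes and the
binning policy are configurable.

## The loss stack

Labeled images contribute a regression and a classification term. The
regression term masks both maps to the dense region (the ground-truth
density thresholded at $\varepsilon = 10^{-3}$) and averages
$1 - \mathrm{SSIM}$ over a $K = 3$ level average-pooling pyramid, with
SSIM stabilizers $Z_1 = 0.01$, $Z_2 = 0.03$; to this a total-variation
term — the L1 distance between the count-normalized maps, weighted by
the ground-truth count — is added with weight $\lambda_1 = 0.01$. SSIM
local statistics use the reference convention of the measure: an
$11 \times 11$ Gaussian window with $\sigma = 1.5$, shrunk to the grid
when the grid is smaller, evaluated over valid window positions.
(The printed source formula carries a spurious leading "1 −" inside the
SSIM symbol; we treat SSIM as the standard similarity — so
$\mathrm{SSIM}(X, X) = 1$ — and apply $1 - \mathrm{SSIM}$ in the
pyramid loss, which is the only reading consistent with a loss that
vanishes at the optimum.) The classification term is cross-entropy with
the probability floored at $10^{-12}$.

Unlabeled images are patch-masked (below) for the student while the
teacher sees the clean crop. The consistency loss compares the two
predictions only inside the masked-patch footprint, with a smooth-L1
($\beta = 1$) per masked patch, summed over the masked set and averaged
over the unlabeled batch; the class distributions are compared the same
way. Teacher outputs are constants — no gradient reaches the teacher.
Whether the class-consistency should compare distributions or hard
pseudo-labels is unspecified in the source; distributions are used.

The totals satisfy $L_L = L_{RL} + L_{CL}$, $L_U = L_{RU} + L_{CU}$ and
$L = L_L + L_U$, with any non-finite component aborting training by
name. All gradients are hand-derived (the package trains without an
autograd framework) and the test suite pins every one of them to
central finite differences.

## Masking and augmentation

Masking is patch-aligned: the canvas is divided into squares of 16 px
(configurable over {8, 16, 32, 64}) and exactly
`round(ratio * n_patches)` of them — half-up rounding keeps the
realized ratio nearest the nominal one — are filled with a constant
(default 0.5, an approximate mean intensity, so no spurious dark
"objects" appear). Masks are redrawn every iteration rather than fixed
per image. Only unlabeled images are masked. Photometric and geometric
augmentation (brightness ±20%, horizontal flip with probability 0.5,
optional rescale, random crop) transforms point coordinates together
with the pixels, and the labeled density target is re-rendered from the
transformed points so labels never drift from their image.

## Training

The student minimizes $L$ by Adam; after every step the teacher is
updated as $\theta_T \leftarrow \alpha \theta_T + (1-\alpha) \theta_S$,
with the warmup $\alpha_t = \min(\alpha, 1 - 1/(t+1))$ so the teacher
tracks the student closely at the start. Evaluation and inference use
the teacher — the usual mean-teacher convention, switchable to the
student. The full profile mirrors the reference settings: crop
$256 \times 256$, batch 16, 500 epochs, Adam at $10^{-5}$ with weight
decay $10^{-4}$, $\alpha = 0.99$.

The reduced profile is a first-class desk-scale configuration (thin
channels, stage depths 1/1/2/2/2, 64-px crops, batch 4, Adam at
$10^{-3}$) used by the tests and the acceptance script. Two of its
settings deserve justification. First, the learning rate: $10^{-5}$
cannot move a freshly initialized network within tens of steps, so the
reduced profile uses the largest conventionally stable Adam rate.
Second, the EMA decay: a run of a few hundred steps is *shorter* than
the averaging horizon $1/(1-\alpha) = 100$ of $\alpha = 0.99$, so the
teacher would lag the student for the whole run and the consistency
term would drag the student toward stale predictions; the reduced
profile therefore uses $\alpha = 0.9$ (horizon 10 steps), keeping the
horizon-to-budget ratio comparable to the full-scale regime.

## Synthetic scenes

The generator renders procedural road/soil/grass backgrounds (smooth
low-frequency color fields plus fine noise, with horizontal streaks for
road) and scatters anisotropic bright Gaussian bumps as shoots —
new shoots photograph as small bright irregular spots, and Gaussian
bumps are the simplest shape that makes density regression non-trivial.
Per-image counts are drawn uniformly from a configurable range. The
default range is 80–246 (the range observed in the real single-tree
imagery at $1024 \times 768$) scaled linearly by canvas area for
smaller canvases; at $64 \times 64$ that area scaling degenerates to
fewer than two shoots per image, so desk-scale experiments pass an
explicit range of 5–25, keeping local shoot density in a realistic
regime while counts stay informative. Everything is reproducible
bit-for-bit from `(spec, seed)`.

What the generator deliberately does **not** reproduce matters for
interpreting results: blob positions are a uniform, spatially
independent point process. Real shoots cluster along branches, so in
real imagery the content of a hidden patch is partially predictable
from its context — which is precisely the premise of masked-image
consistency. In our synthetic scenes that premise is false by
construction: a masked patch's content is statistically independent of
its surroundings, the consistency target is irreducibly unpredictable,
and the unsupervised branch contributes regularization noise rather
than contextual signal. Desk-scale comparisons between semi-supervised
and supervised-only training on these scenes therefore measure the
machinery (losses, masking, EMA, gradients — all separately verified),
not the contextual benefit the method is designed to exploit, and the
semi-supervised arm is not expected to dominate here the way it does on
real data. We report the comparison as measured rather than adapting
the generator after the fact.

## Numerical choices and degenerate inputs

* Split sizes: `floor(n * ratio)` for train and validation, remainder
  to test — deterministic, so the "10 labeled images at 5% of a
  313-image dataset" bookkeeping is exactly reproducible.
* Labeled selection samples the training split only; validation and
  test always keep labels (metrics need ground truth).
* Empty point sets are valid zero-count images everywhere (I/O, density
  construction, augmentation).
* Zero-sum density pairs define the total-variation loss as 0; an
  all-zero segmentation mask gives a structural loss of 0.
* The pyramid depth must be feasible for the grid
  (dims divisible by $2^{K-1}$), otherwise an error is raised rather
  than silently shrinking the pyramid.
* Density-class bin edges must be strictly increasing; quantile ties
  are collapsed, reducing the class count rather than producing empty
  bins.
* Problem sizes in the tests and acceptance script — $64 \times 64$
  scenes, 79-image datasets (55 train / 15 val / 9 test), 100 epochs,
  3 seeds — were chosen once as the smallest sizes at which every
  mechanism is exercised meaningfully.

## Known limitations

* The backbone trains from scaled random initialization; no pretrained
  weights are bundled, while the full-scale method initializes from
  ImageNet-pretrained VGG19.
* Per-patch density classification (an alternative reading of the
  class-target construction) is not implemented; per-image
  classification is the default and only mode.
* The comparison baselines (MCNN, CSRNet, DM-Count, and the
  semi-supervised lines) are consumed as published table values only;
  none are re-trained here.
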