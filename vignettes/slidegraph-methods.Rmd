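---
title: "Two-step whole-slide classification of gastric biopsies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step whole-slide classification of gastric biopsies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Endoscopic gastric biopsies are graded on the WHO (5th edition) four-tier
scale — negative for dysplasia (NED), low-grade dysplasia (LGD), high-grade
dysplasia (HGD) and intramucosal invasive neoplasia (IIN) — from whole-slide
images (WSIs) of H&E-stained tissue. Two practical outputs matter to a
pathology service: a *screening* mode that removes clearly benign slides
from the review queue without ever discarding a dysplastic one, and a
*four-tier* mode that proposes a grade for the slides that remain.

`slidegraph` implements a two-step classifier for this task at desk scale:
a convolutional patch segmenter locates abnormal tissue and extracts patch
features, and a graph convolutional network (GCN) over the most abnormal
patches produces the slide-level call. Because real WSIs are gigapixel
images under restrictive data-use agreements, the package ships a synthetic
slide generator so that the full pipeline is trainable, testable and
reproducible on a laptop.

## The model

### Stain normalization

Color varies between centers with staining chemistry and scanner response.
Tissue is first separated from the near-white background by Otsu
thresholding of the saturation channel (with small connected components
removed). Each channel of the whole image is then linearly mapped so that
the tissue-pixel statistics match a target:

$$Z = \frac{X - \mu}{\sigma}\,\sigma_T + \mu_T$$

where $(\mu, \sigma)$ are the slide's own tissue mean and standard
deviation for that channel and $(\mu_T, \sigma_T)$ the targets, obtained by
averaging the per-slide tissue statistics over the training set. The
statistics are computed over tissue pixels only, but the affine map is
applied to every pixel, and the result is clipped to 0..255. The transform
is exactly linear before clipping, which the test suite exploits.

### Patch segmentation

Slides are tiled into a non-overlapping grid of $P \times P$ patches
(desk-scale default $P = 128$); patches with less than 5% tissue are
dropped. A small V-Net-style 2-D encoder–decoder (3 levels, base width 8,
skip connections, bottleneck width 32) predicts, per pixel, the probability
that tissue is abnormal (LGD $\cup$ HGD $\cup$ IIN — the head is binary;
grade discrimination is delegated to the GCN). Training minimizes the soft
dice loss

$$L_\mathrm{dice} = 1 - \frac{2\sum_i p_i g_i}{\sum_i p_i^2 + \sum_i g_i^2 + \varepsilon},
\qquad \varepsilon = 10^{-6},$$

with Adam at learning rate $10^{-3}$. Per-patch probability maps are
stitched back onto the padded slide canvas pixel-exactly (dropped patches
contribute probability 0). The same network doubles as the feature
extractor: the global average of the bottleneck activation gives a
32-dimensional feature vector per patch.

Two numerical points deserve note. First, the dice loss has *zero* gradient
on a patch whose mask is empty, so all-background patches carry no training
signal; the training-set sampler therefore draws lesion-bearing patches
plus surrounding tissue, and false-positive suppression is learned from the
normal tissue inside those patches. Second, the segmentation head is
initialized small with bias $-2$, so the untrained network leans toward
background — the sensible prior when abnormal pixels are the minority.

### The slide graph

Each patch receives an abnormality grade: the mean of its probability map.
Only the top-$n$ patches in the abnormality ranking become graph nodes
(default $n = 64$), which removes interference from purely negative
regions; ties break toward row-major patch order. An undirected, unweighted
edge connects nodes $m$ and $n$ exactly when the Chebyshev ($L_\infty$)
distance of their features is strictly below a threshold $\gamma$:

$$E_{mn} = \begin{cases} 1 & d_\infty(x_m, x_n) < \gamma \\ 0 & d_\infty(x_m, x_n) \ge \gamma \end{cases}$$

so $\gamma = 0$ gives an edgeless graph and $\gamma = \infty$ a complete
one, and the edge set grows monotonically in $\gamma$. Since no single
$\gamma$ suits every feature scale, the default resolves $\gamma$
per slide as the 20th percentile of the slide's pairwise node distances
("auto"); a fixed global $\gamma$ is equally supported, and neither mode is
claimed to be canonical. Self-loops are on by default so isolated nodes
still propagate their own features through the GCN.

### Slide-level GCN

Node inputs are the 32-dimensional patch features with the abnormality
grade appended (the grade is cheap, already computed, and sharpens the
NED-versus-rest decision when lesions are small). Two message-passing
layers (row-normalized adjacency, ReLU, hidden width 32) are followed by
mean pooling over nodes — making the prediction invariant to node order —
and a 4-way softmax head, so every slide receives a probability simplex
$(p_\mathrm{NED}, p_\mathrm{LGD}, p_\mathrm{HGD}, p_\mathrm{IIN})$ summing
to 1. Training minimizes the focal loss

$$L_\mathrm{focal} = -\alpha_c\,(1 - p_t)^{\gamma_f} \log p_t,
\qquad \gamma_f = 2,$$

with $p_t$ the probability of the true class (floored at $10^{-12}$ before
the log) and $\alpha_c$ inversely proportional to class frequency
(normalized to mean 1). Adam again runs at $10^{-3}$.

### Output modes

The four-tier call is the argmax of the simplex; an exact tie resolves
toward the more severe category (IIN > HGD > LGD > NED) to avoid
under-calling malignancy. The screening mode uses $p_\mathrm{NED}$ as its
score: the threshold is calibrated as

$$t = \max_{\text{positive slides}} p_\mathrm{NED}$$

over a calibration set, and a slide is screened out as benign exactly when
$p_\mathrm{NED} > t$ (strict). By construction no calibration positive can
be screened out, so sensitivity for positives and the negative predictive
value are exactly 100% on the calibration set *for any model quality* —
this is a structural property of the rule, not a learned one — and among
all thresholds with that guarantee, $t$ screens out the most benign slides.
Applied unchanged to new data the guarantee is empirical, not structural;
the package reports it and does not assert it.

## The synthetic generator

The generator emulates the aspects of gastric-biopsy WSIs this pipeline
actually consumes, at a scale where training is a matter of minutes:

* slides are 1024 × 1024 RGB rasters (configurable), not gigapixel
  pyramids;
* tissue appears as 2–4 small wavy fragments covering roughly 20% of the
  slide, as pinch biopsies do, on a near-white background (every channel
  at 240 or above, so automatic thresholding is well-posed);
* tissue is eosin-pink with small dark nuclei-like spots and Gaussian
  pixel noise (sd 6);
* non-NED slides carry lesion blobs whose texture grows monotonically more
  disordered with severity — higher spot density, larger spots, darker and
  more purple chroma — with the blob radius iterated so the lesion/tissue
  area ratio lands within about 20% of the requested fraction;
* the paired mask stores per-pixel labels 0 (background), 1 (NED tissue),
  2–4 (LGD/HGD/IIN);
* each center applies a channel-affine stain style (gain, offset, noise)
  after synthesis, emulating between-center stain and scanner variation.

Adjacent categories differ in mean lesion chroma by at least three
synthetic-noise standard deviations, so recovery tests downstream are
meaningful rather than vacuous. Generation is bit-reproducible from the
spec seed.

What the generator deliberately does *not* model: nuclear morphology and
glandular architecture, H&E stain physics, scanner artifacts (blur, tiling
seams, text annotations) and pyramidal file formats. A model that passes
the recovery tests here has demonstrated that the pipeline's machinery —
normalization, segmentation, ranking, graph construction, classification
and calibration — works end to end on separable signal; it has demonstrated
nothing about histology itself.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `patch_size` | 128 px | tile side; any multiple of 4 works with the default 3-level net |
| `min_tissue_fraction` | 0.05 | tiles below this tissue share are dropped |
| seg levels / width / d | 3 / 8 / 32 | encoder depth, base channels, feature dimension |
| seg `epochs`, `lr`, `batch_size` | 5, 1e-3, 8 | dice training schedule (Adam) |
| `n` | 64 | top patches kept as graph nodes |
| `gamma` | "auto" (q = 20) | edge threshold; per-slide 20th percentile of pairwise distances, or a fixed number, or `Inf` |
| GCN `epochs`, `hidden` | 800, 32 | focal training schedule; the GCN is tiny, so epochs are cheap |
| `gamma_f`, `alpha` | 2, "balanced" | focal focusing exponent and class weights |

## Problem sizes

The package's desk-scale study conditions, used by the test suite and the
acceptance script: 120 training slides (15 per category from each of two
centers with different stain styles) and 40 held-out slides at 1024 × 1024
with 128-px patches; a segmenter training set capped at 320 sampled
patches; and a 200-slide calibration set (50 per category) for the
screening threshold. On one CPU core the full cycle — generate, train both
stages, predict, calibrate — completes in well under half an hour.

## Evaluation battery

`evaluate_predictions()` reports the confusion matrix under the four-tier
grouping or either two-tier grouping (NED vs rest; NED+LGD vs HGD+IIN),
one-vs-rest sensitivity/specificity/accuracy/NPV (undefined margins are
reported as `NA`, never as 0), percent agreement, ROC/AUC (threshold sweep
with trapezoidal area, identical to the Mann–Whitney statistic with ties
counted ½; computed via pROC), and Cohen's κ. κ is computed both unweighted
and quadratically weighted with agreement weights
$w_{ij} = 1 - ((i-j)/(K-1))^2$ on the severity ordering, and is always
labeled with its weighting, since agreement numbers of both kinds circulate
in this literature. Descriptive bands follow the conventional cut-points
(poor < 0.20 ≤ fair < 0.40 ≤ moderate < 0.60 ≤ good < 0.80 ≤ very good),
boundaries belonging to the upper band. Per-center breakdowns pool the
centers for the overall row.

## Known limitations

* The segmenter's pixel head is binary; a four-class pixel head is a
  natural extension the current design deliberately leaves out.
* The screening guarantee binds only on the calibration set; deployment
  monitoring is out of scope.
* The feature extraction layer (global-average bottleneck) and the graph
  defaults ($n$, the auto-$\gamma$ percentile) are pragmatic choices, not
  tuned optima; both are exposed as configuration.
* Everything here runs single-threaded; the package trades the scale of
  production systems (multi-GPU, hundreds of thousands of patches) for
  reproducibility on commodity hardware.
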