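---
title: "Example-driven region-of-interest scoring for virtual slides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Example-driven region-of-interest scoring for virtual slides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slideroi)
```

## The problem

A digitized histology slide (virtual slide) is far too large for a
pathologist to inspect exhaustively, and far too large to transmit or cache
naively. If the diagnostically relevant regions (RoIs) can be ranked ahead
of time, a viewer can prefetch, compress and navigate intelligently. Fully
automatic bottom-up saliency does poorly on histology — tissue is full of
high-contrast structure with no diagnostic meaning — so `slideroi` takes a
semi-automatic, example-driven approach: the user points at **one typical
relevant block** (the *target*) and **one typical irrelevant block** (the
*distractor*), and the package ranks every other block of the slide by how
much it resembles the former and not the latter.

## The pipeline

### 1. Block grid

The slide is tiled by square, non-overlapping blocks (default 70 × 70
pixels). Trailing partial strips are dropped rather than padded: every block
then contains exactly the same number of pixels, so raw histogram counts are
directly comparable and no per-block renormalization artifacts enter the
metrics. Pixel coordinates are 0-based, top-left origin; block rectangles
are half-open. Overlapping or strided grids are deliberately out of scope.

### 2. Five low-level histograms per block

Each block is projected into five feature spaces chosen to cover color,
intensity, orientation and texture without any tuning to a particular stain
or organ:

* **gray** (256 bins): intensity distribution, one bin per 8-bit level.
* **color** (512 bins): the RGB cube split 8 × 8 × 8; bin index
  `64⌊R/32⌋ + 8⌊G/32⌋ + ⌊B/32⌋`.
* **lbp** (256 bins): local binary patterns — for each interior pixel an
  8-bit code over its 8 neighbors, clockwise from the top-left neighbor, bit
  set iff the neighbor is *strictly* brighter than the center. The strict
  comparison makes a constant block map to code 0; the 1-pixel border is
  excluded rather than padded, because padding would invent intensities.
* **tamura** (512 bins): the three Tamura texture measures most correlated
  with human perception, computed per pixel and jointly quantized 8 × 8 × 8:
  coarseness (dominant texel scale `2^k`, `k ∈ 1..5` maximizing the
  nearest-neighbor average-difference `E_k`), contrast
  (`σ / kurtosis^{1/4}` over a 13 × 13 window), and directionality (Prewitt
  gradient angle in `[0, π)`, defined only where the gradient magnitude
  exceeds 12 — flat pixels carry no orientation and contribute no triple).
  Quantization ranges are fixed a priori (coarseness on a log2 scale over
  2..32, contrast clipped to [0, 128], directionality over [0, π)): fixed
  ranges keep histograms comparable across blocks, which per-block min-max
  scaling would destroy. Windows near the block border use replicate
  padding so every pixel has defined coarseness and contrast.
* **sobel** (512 bins): gradient magnitude of the 3 × 3 Sobel pair at each
  interior pixel, normalized by the analytic maximum `4 · 255 · √2` and
  quantized uniformly; an edge-density signature.

Color images are converted to luminance with the ITU-R BT.601 weights
`round(0.299R + 0.587G + 0.114B)` for the four intensity-based features. For
grayscale slides the color histogram degenerates to the gray histogram
zero-padded to 512 bins so the data model is unchanged; since its maps would
exactly duplicate the gray maps, the color feature is skipped at integration
(20 rather than 25 maps per example) and `n_maps` reflects that.

### 3. Five histogram metrics

Histograms are L1-normalized and compared with Euclidean distance, histogram
intersection (`1 − Σ min`), Jensen–Shannon divergence (natural log, bounded
by `2 ln 2`), relative bin deviation (a χ²-type per-bin form,
`Σ (H−G)²/((H+G)/2 + ε)`), and relative histogram deviation
(`‖H−G‖₂ / ((‖H‖₂+‖G‖₂)/2 + ε)`), with `ε = 10⁻¹²`. These are the
conventional content-based-retrieval definitions of the five names; all are
symmetric, non-negative and exactly zero at equality, which is everything
the downstream map algebra relies on. "Relative bin deviation" and "relative
histogram deviation" have more than one form in the retrieval literature;
both chosen forms are implemented and the metric set is configurable, so a
user who prefers another variant can restrict or extend the set. A zero-mass
histogram (possible for Tamura on a perfectly flat block) is kept as the
zero vector rather than rejected, so a uniform image degenerates to all-zero
maps instead of an error.

### 4. Map normalization and integration

Every feature × metric pair yields a distance map to the target and one to
the distractor (5 × 5 × 2 = 50 maps by default). Each map passes through:

1. **Zero reassignment** — the example block is itself part of the grid and
   sits at distance 0; every cell at the global minimum is raised to the
   second-smallest value so the example cannot dominate the normalized map.
2. **Similarity inversion** — affine rescale so the largest distance maps to
   0 and the smallest to `N_scale`; `N_scale = 1` by default since any
   positive constant rescales all maps identically before the quadratic
   weighting, and 1 keeps weights in [0, 1]. A constant map maps to all
   zeros.
3. **Peak promotion** — the map's weight is `(M − m̄)²`, with `M` the global
   maximum and `m̄` the mean of the other local maxima (3 × 3 neighborhood;
   positive cells only; cells equal to `M` excluded; `m̄ = 0` when there are
   none). A map with one strong activity peak keeps weight ≈ `M²`; a map
   whose peaks are many and comparable is quenched toward 0. Local maxima at
   the grid border compare only against their existing neighbors; requiring
   positivity excludes flat zero plateaus, and excluding cells equal to `M`
   makes the single-peak map the maximal-weight case.
4. **Weighted sum** — maps are added cellwise with their weights (these
   scalars are the per-map weight factors of the final combination). The
   "each element is weighted" operation is implemented as a uniform scalar
   per map, i.e. the classic saliency-style map-promotion operator.

The relevance map is `R = (T − D) / N_maps`, then min-max rescaled to
[0, 1]. The rescale gives the downstream "relevance larger than 90%" rule a
concrete scale; a degenerate constant difference rescales to all zeros.
RoIs are the top `ceil(fraction · n_blocks)` blocks (default fraction 0.1),
with ties broken in row-major order so results are bit-reproducible.

### 5. Evaluation against navigation logs

A viewing session is a sequence of window-of-interest (WoI) requests
(`time_ms, x, y, w, h, level` in CSV). A block is *visited* by a request
when their rectangles intersect; dwell time is not weighted — the protocol
counts visits. Blocks with visit counts strictly above 50% of the most
visited block form the *interesting* set **I**; blocks with relevance
strictly above 0.9 on the rescaled map form the *estimated* set **E**.
Both rules use strict inequality. Precision is `|E ∩ I| / |E|`, recall
`|E ∩ I| / |I|` (0 for empty sets). The in-package comparator is uniform
random block selection without replacement, whose expected precision is
`|I| / N` (hypergeometric); the test suite verifies the Monte-Carlo mean to
within three standard errors over 10,000 draws. An alternative reading of
the 90% rule — the 90th percentile of scores rather than the absolute 0.9
level — is exposed as `percentile_rule` and off by default. Logs from
several observers can simply be concatenated (times per observer
non-decreasing) before visit counting if pooled marking is wanted.

## The synthetic slide generator

Real annotated virtual slides with recorded expert navigations are not
publicly available, so the package ships a generator that emulates the
relevant statistics of an H&E slide at desk scale:

* background: pale pink (≈ RGB 240, 200, 210) with Gaussian intensity noise
  (sd 8) — eosin-like stroma;
* target regions: rectangles (side 1.5–2.5 blocks) densely filled with dark
  purple elliptical blobs (≈ RGB 80, 50, 120, radii 3–7 px, ~40% areal
  density) — nuclei-cluster-like texture;
* distractor regions: a visually distinct texture (default a smooth pale
  blue-gray tint; stripes are also available);
* ground truth: a block is labeled target/distractor when ≥ 50% of its
  pixels lie in such a region — regions are placed with a 2-px disjointness
  margin so labels are unambiguous;
* navigation: synthetic sessions aim most WoI requests (default 50) at
  random target blocks and a few (default 5) elsewhere, with windows sized
  to stay inside the aimed block so a request visits exactly the block it
  was aimed at, and strictly increasing synthetic timestamps.

Defaults are 700 × 700 pixels, 70-px blocks (100 blocks), 3 target and 2
distractor regions, chosen as the smallest configuration that leaves a
clear majority of background blocks around several separated regions. The
whole slide is a deterministic function of the spec, including its seed.

What the generator does *not* emulate: stain variability and deconvolution
physics, tissue morphology (gland/vessel shapes), multi-resolution pyramids,
compression artifacts, or the spatial autocorrelation of real navigation
(real experts pan smoothly; the synthetic log jumps). Passing the synthetic
recovery tests therefore shows that the pipeline separates texture classes
it was designed to separate and that its plumbing is correct — not that the
method attains any particular accuracy on clinical material.

## Numerical and degenerate-input choices

* All map algebra is double precision; feature histograms are exact integer
  counts, so oracle tests compare them with `==`.
* Constant (degenerate-range) maps normalize to all zeros at every stage; a
  uniform image yields an all-zero relevance map and no error.
* `ceiling(fraction · n)` is evaluated with a 10⁻⁹ slack so that e.g. a 10%
  fraction of 100 blocks is exactly 10 despite floating-point representation
  of the fraction.
* Coarseness argmax ties keep the smaller scale; thresholding ties
  (`> 0.5 · max`, `> 0.9`) are strict everywhere.
* All randomness (generator, navigation, baseline) flows through local RNG
  scopes seeded from explicit arguments; the caller's RNG state is never
  disturbed, and reruns are bitwise identical.

## Problem sizes used by the shipped tests

The test suite and the reproduction script run entirely on synthetic data:
oracle equivalence on 10 × 10-pixel blocks and ≤ 10 × 10-block grids;
baseline calibration with 10,000 draws on a 100-block grid; and a 20-seed
sweep of 700 × 700 slides for end-to-end recovery. These sizes were chosen
so the full suite exercises every stage, including the complete method on
100-block slides, in about a minute of CPU.

## Known limitations

* Single target and single distractor example; multi-example queries and
  learning the per-map weights from recorded navigations are out of scope.
* No multiresolution pyramid: WoI coordinates must be expressed at the
  grid's reference resolution.
* The Tamura per-pixel definitions and the two "relative deviation" metric
  forms follow the standard texture/retrieval literature; other variants
  exist and would change absolute distances (though rarely the ranking).
* Block size is a free parameter; 70 px is the default, but whether a fixed
  block fully captures an RoI depends on magnification and lesion size.
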