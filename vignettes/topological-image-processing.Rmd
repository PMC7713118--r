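---
title: "Topological image modification and processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological image modification and processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topimg)
```

## The model

A grayscale image is a scalar field $f$ on the pixel grid. Joining each
pixel to its eight neighbours and sweeping a threshold $t$ upwards defines
the *sublevel filtration* $\{f \le t\}$: dark objects appear first as
separate connected components and are progressively absorbed into lighter
surroundings. Zero-dimensional persistent homology summarizes this sweep
as a multiset of points $(b, d)$ — a component born at intensity $b$ that
merged into an older component at intensity $d$ — and its *lifetime*
$L = d - b$ measures how strongly the object is separated from its
surroundings. When two components merge, the elder rule kills the one with
the larger birth value; exactly one component, born at the global minimum,
never dies.

This package implements the whole detection pipeline built on that
summary:

1. **Modification** (`tim_modify()`): box smoothing with a $k \times k$
   window destroys small-scale topological noise (isolated dark pixels,
   thin hair-like curves), and *border modification* overwrites an
   $l$-pixel frame with (global minimum $- \delta$) so that the single
   infinite component is the frame itself and every object touching the
   border is born through it. After this step all real interior objects
   have finite lifetimes.
2. **Threshold selection** (`select_threshold()`): lifetimes are sorted
   decreasingly and the threshold $\tau$ is the midpoint of the largest
   gap between consecutive lifetimes; everything above $\tau$ is a
   detected object.
3. **Marking** (`mark_objects()`): each selected diagram point is realized
   as the 8-connected component of the strict sublevel set
   $\{f < \min_i d_i\}$ (the state of the filtration right before the
   lowest selected death) containing the point's birth pixel. By the elder
   rule the component that kills a significant component is itself at
   least as significant, so these masks are well defined and pairwise
   disjoint.
4. **Background fill** (`idw_fill()`): marked pixels keep their values;
   every background pixel takes the inverse-distance-weighted combination
   (default exponent 2) of the values of its nearest pixel in each marked
   component. The result is a processed image with a homogeneous
   background and strongly contrasted objects, on which generic
   unsupervised segmenters (Chan-Vese, ISODATA, isocontours, superpixels,
   Roberts edges, snakes) work far better than on the raw image.

The pipeline assumes dark objects on a lighter background that touches the
image border; `polarity = "light"` negates the image first (the superlevel
filtration) for bright objects.

## Parameters

* `k` (odd, pixels) — smoothing window; the default is the diagonal
  heuristic $k \sim \Delta(I)/25$ rounded to an odd integer, floored at 3.
  Larger $k$ destroys larger structures.
* `l` (pixels) — border band width, default $l \sim \Delta(I)/100$,
  floored at 1; it must only be wide enough that the frame is connected
  through every border-touching object.
* `sigma` — standard deviation of the tie-breaking noise on the $[0,1]$
  intensity scale, default 0.1 (variance 0.01). Its purpose is to make
  all pixel values distinct so every birth maps to one pixel; by diagram
  stability (bottleneck distance is bounded by the sup-norm perturbation,
  a property the test suite checks) it does not move lifetimes by more
  than a few hundredths. Noise is injected before smoothing and is not
  clamped: intermediate values may leave $[0,1]$ and are only quantized
  on file write.
* `power` — IDW exponent, default 2 (the customary inverse-square
  weighting; with a single detected component any exponent reduces to a
  nearest-value fill).
* `resolution` — intensity resolution used by the stability diagnostic
  (below), default one 8-bit level ($1/255$).

## The stability ratio

The largest-gap rule is reliable only when the largest empty band in the
diagram clearly dominates the others. The ratio of the largest gap to the
mean gap diagnoses this, with ratios below 4 flagging low-contrast images
where no trustworthy threshold exists. Computed naively over all raw
consecutive gaps this ratio is scale-degenerate: a modified image carries
hundreds of near-diagonal points (shallow noise minima), the mean raw gap
collapses towards zero, and the ratio grows like the diagram size no
matter what the image shows — even pure noise scores far above 4. The
package therefore measures empty regions at the intensity resolution of
the data: lifetimes are quantized to the 8-bit grid, repeated values are
separated by no region at all, and the ratio is taken over the gaps
between consecutive *distinct* quantized lifetimes. On the synthetic
scenes this separates cleanly (low-contrast scenes score 1–3, clearly
contrasted ones 7–10). With `resolution = 0` the raw-gap definition is
used unchanged. The threshold $\tau$ itself and the number of selected
objects never depend on this choice.

## The synthetic scenes

`lesion_scene()` emulates, at desk scale, the situations the method is
designed for: a dark elliptical lesion (intensity 0.3) off the border on
a textured background (base 0.75, Gaussian texture sd 0.02), thin dark
hair-like Bezier curves (intensity 0.2), a dark half-disk distractor
clipped by the border (intensity 0.35), optionally an illumination
gradient and an inflammation-like rim, and a two-lobe variant emulating a
lesion split by scarring. The ground truth marks the lesion only.

The default canvas is 256×256. This is deliberate: the diagonal heuristic
then gives $k = 15$, and a 1-pixel hair is destroyed by smoothing to a
depth of $\approx 0.04$ — the same hair-to-window and gradient-to-contrast
regime as high-resolution dermoscopy under $k \approx 25$. At 128×128
($k = 7$) hairs survive with depth $\approx 0.16$, bridge the lesion to
the border frame and break the isocontour segmenter; the behaviour being
emulated is resolution-dependent and the default states the regime the
method targets.

`digits_scene()` renders a '1' (bar with serif foot) and an '8' (two
overlapping annuli) dark on light — two components, two loops — entirely
procedurally (no fonts, for reproducibility). `low_contrast_scene()` sets
the lesion within one texture standard deviation of the background.

What a green test does **not** establish: the scenes have no real skin
texture, no specular highlights, no color, no rulers or markers, and
their hairs never overdraw the lesion; real-data performance (the
package's batch evaluator supports it) is not implied by fixture-scale
results.

## Numerical and design choices

* **Ties.** Pixels are processed in increasing (value, row, col) order
  and the elder rule breaks ties on the same key, so diagrams are
  deterministic even without noise; with noise, ties are measure-zero.
* **Border band value.** "Lowest value" is implemented as global minimum
  $- 10^{-6}$, guaranteeing the frame is strictly the earliest birth
  without relying on tie-breaking.
* **Smoothing at edges.** The window is clipped to the image and the
  divisor is the number of valid pixels (no padding), so constants are
  exactly preserved.
* **H1 by duality.** Loops of the 8-connected sublevel set are computed
  as H0 of the negated image under 4-connectivity with a virtual node
  joining the border pixels (the standard digital-topology pairing). An
  explicit flag-complex reduction would have to decide whether 4-cliques
  are filled; the duality avoids that ambiguity and reproduces the glyph
  and annulus examples. Only H0 drives detection; H1 exists for the
  demonstration and the oracle tests.
* **Digit-scene component counting.** On the raw scene the light
  background cedes the infinite point to one of the glyphs, so only one
  finite outlier exists; the count "2 components" is obtained after
  border modification — the method's own device for making every real
  object finite. The loop count is computed on the unmodified scene,
  since the modified frame is itself a giant loop.
* **Extraction level.** All selected components are extracted at the
  common strict sublevel of the minimum selected death. A component
  degenerately born at or above that level falls back to its own death
  level, with a warning.
* **Marking over-covers.** Death occurs when a component meets the frame
  component, typically well above the object's boundary intensity, so
  masks include a halo around the object; the marking is a region that
  *includes* the object (inclusion of the truth is asserted at 0.95 in
  the acceptance tests), not a tight segmentation — that is exactly why
  the processed image is handed to a downstream segmenter.
* **Chan-Vese.** Implemented as morphological active contours without
  edges with interface-local updates; initialization is a mean-threshold
  level set, because a plain checkerboard deadlocks on symmetric images
  (both phase means coincide exactly and no pixel moves).
* **MCC.** Uses the standard square-root denominator — the product form
  sometimes printed contradicts the stated $[-1, 1]$ range; the unrooted
  value is available via `mcc(..., rooted = FALSE)`.
* **Degenerate metrics.** Zero denominators return 0 carrying a
  `degenerate` attribute rather than `NaN`, so batch averages stay
  defined.
* **File formats.** Native raster I/O is PGM/PPM (the environment offers
  no PNG codec package); PNG/JPEG paths are converted through the system
  Python's Pillow when present.

## Limitations

* Objects lighter *and* darker than the background in the same image need
  two passes with opposite polarity.
* A prominent dark object separated from the border but irrelevant to the
  user (e.g. a surgical marker) is indistinguishable from a relevant one.
* Death times after full object inclusion prevent using the diagram as a
  direct segmentation; the marking deliberately over-covers.
* The homology engine is exact but 2D-only; no dimension-2 features
  exist on an image grid.
* The bottleneck distance is exact but intended for the small diagrams
  produced here (binary search over candidate costs with an augmenting
  path matching).
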