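# topimg

Unsupervised object detection and contrast enhancement for raster images
via cubical persistent homology, with a case focus on skin-lesion
photographs: a dark lesion on lighter skin, contaminated by hairs, border
artifacts and illumination gradients. The package is for image-analysis
practitioners who want a fully unsupervised front end that finds the
relevant object(s), suppresses everything else, and hands a cleaned-up
image to any generic segmenter.

## The method

The grayscale image is treated as a scalar field `f` on the 8-connected
pixel grid and swept by the sublevel filtration `{f ≤ t}`. Each connected
component appears at its minimum (birth `b`) and is absorbed into an older
component at a merge value (death `d`, elder rule); its lifetime `L = d − b`
measures object salience. The pipeline:

1. **Topological image modification** — box smoothing (window
   `k ~ Δ(I)/25`, `Δ(I)` the pixel diagonal) destroys noise components and
   hair-like curves; **border modification** sets an `l ~ Δ(I)/100` frame
   to the lowest value, so the one infinitely-persisting component is the
   frame and every border-touching object is born through it. Normal
   noise (σ² = 0.01) makes pixel values unique so births map to pixels;
   by stability, `d_b(Dgm(I), Dgm(J)) ≤ ‖f − g‖∞`, it cannot distort the
   diagram.
2. **Threshold selection** — sort finite lifetimes decreasingly; `τ` is
   the midpoint of the largest consecutive gap; components above `τ` are
   the detected objects. A largest-gap/mean-gap ratio below 4 flags
   low-contrast images with no trustworthy threshold.
3. **Object marking** — each selected component is extracted as the
   8-connected component of `{f < min selected death}` containing its
   birth pixel.
4. **Background fill** — unmarked pixels get the inverse-distance-weighted
   value of the nearest pixel of each marked component, yielding a
   homogeneous background and high object contrast.

Downstream, six generic unsupervised segmenters are included (Chan–Vese
morphological active contours, ISODATA thresholding, isocontour polygon
fill, k-means superpixels, Roberts edges, hull-initialized snakes), plus
confusion-matrix metrics (accuracy, Dice, MCC, inclusion/recall) and
procedural scene generators with ground truth.

## Worked example

```r
library(topimg)

scene  <- lesion_scene(scene_spec(seed = 1))   # 256x256: lesion + hairs + border distractor
params <- default_params(scene$image, seed = 1) # k = 15, l = 4 from the diagonal heuristic
res    <- tip_process(scene$image, params)
res
#> topologically processed image (256 x 256): status ok
#> lifetime threshold tau = 0.257261 (largest gap 0.361708, ratio 11.6)
#> 1 component(s) selected

evaluate_mask(chan_vese(res$values)$mask, scene$truth)  # segment the processed image
#>   accuracy      dice       mcc inclusion
#> 1 0.997818 0.9854601 0.9843514 0.9746581

evaluate_mask(chan_vese(scene$image)$mask, scene$truth) # same segmenter, raw image
#>    accuracy      dice       mcc inclusion
#> 1 0.9577789 0.7821774 0.7827568 0.9991955
```

The threshold diagnostics say one object was selected with a gap ratio of
11.6 (well above the low-contrast cutoff of 4); Chan–Vese on the processed
image reaches Dice 0.985 against the ground truth, versus 0.782 on the raw
grayscale — the raw segmentation also swallows the hairs and the
border-touching distractor.

A command-line wrapper ships in `inst/cli/tip.R`:

```sh
Rscript inst/cli/tip.R demo --scene lesion --seed 0 --out demo-out
Rscript inst/cli/tip.R process scene.pgm --out processed.pgm --auto --seed 3
Rscript inst/cli/tip.R segment processed.pgm --method isodata --out mask.pgm
Rscript inst/cli/tip.R evaluate mask.pgm truth.pgm
```

## Acceptance script

`scripts/acceptance.R` re-runs the installed package's whole pipeline from
scratch at a given seed — scene synthesis, modification, persistence,
threshold selection, marking, IDW fill, the three binary segmenters and
their evaluation, plus the digit-scene component/loop counts — and writes
a JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
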