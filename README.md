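# nedsem

Unsupervised segmentation of pigmented skin-lesion (dermoscopy) images,
built for the *banded edge* problem: melanoma lesions do not end at a crisp
contour but fade into healthy skin across an annular transition zone whose
colour changes gradually and nonlinearly. That band bounds the clinical
resection margin, so it should be segmented as a region of its own — not
collapsed into a boundary curve. `nedsem` is aimed at researchers in
medical image analysis who want an interpretable, training-free baseline
for this three-region (background / banded edge / lesion core) problem.

## Method

1. **Neutrosophic conversion.** Each RGB channel `P′` becomes a triple
   `(T, I, F)`: truth `T` is the morphologically *closed* channel min–max
   rescaled to [0, 1] (closing erases hairs and specks first), falsity is
   `F = 1 − T`, and indeterminacy `I` is the rescaled absolute
   *morphological gradient*, peaking on edges.
2. **Single-valued neutrosophic entropy.** Each pixel's triple collapses to

   `E = 1 − (2/√3) · sqrt( (t − f)²/2 + ((1 − 2i)/2)² )`,

   i.e. one minus the normalised distance to the maximal-uncertainty axis
   `{t = f, i = ½}` of the membership cube. Points equidistant from the
   axis form an *isentropic cylinder* and share one entropy; `E = 1` on the
   axis, `E = 0` at crisp corners such as `(1, 0, 0)`.
3. **Edge feature.** `R_b = E_R − E_B` keeps the band (where the red
   channel is maximally uncertain while blue is still dark) and cancels
   core and background; grayscale dilation then fills pinholes.
4. **Clustering.** An MRF-regularised hierarchical Gaussian mixture
   (`K` categories, each an `r`-component Gaussian mixture, per-pixel
   priors coupled to the 3×3 neighbourhood by smoothness `β`) is fitted by
   EM; the highest-feature cluster is the banded edge and the region it
   encloses is the lesion core.

Evaluation helpers compute accuracy, specificity, Jaccard and Dice from
pixel confusion counts, and a seeded phantom generator produces
dermoscopy-like images with exact ground truth, so the whole pipeline is
testable without any external data. K-means and fuzzy C-means comparator
clusterers and a morphology-ordering ablation are included.

## Worked example

```r
library(nedsem)

fx  <- synth_lesion(lesion_spec())   # 128x128 phantom, exact truth mask
seg <- nedsem(fx$image, seed = 1)    # full pipeline with defaults
print(seg)
#> nedsem segmentation (hgmm, k = 3, order = rb_then_dilate)
#>   128 x 128 mask: background 11901, banded edge 2558, lesion core 1925

evaluate_mask(seg$mask, fx$truth)                 # lesion vs background
#>    Acc     SP     JA   Dice
#> 0.9669 1.0000 0.8920 0.9429
evaluate_mask(seg$mask, fx$truth, positive = 1)   # banded edge only
#>    Acc     SP     JA   Dice
#> 0.9593 0.9935 0.7875 0.8811
```

The lesion (core + band) is recovered with Dice 0.94 against the generator
truth, and the banded edge itself with Dice 0.88; specificity 1.00 means no
background skin was swept into the lesion. The fitted mixture behind the
mask is a first-class model object:

```r
summary(seg$model)$table
#>   category   mean     sd pixels weight
#> 1        1 0.0442 0.0128   8447  0.453
#> 2        2 0.0535 0.0348   5379  0.382
#> 3        3 0.4428 0.2232   2558  0.164
```

— two near-zero categories (background and core, indistinguishable in the
feature by design) and one high-feature category: the band.

A thin CLI wraps the same functions
(`inst/cli/nedsem segment|synth|eval|ablate`), e.g.
`Rscript inst/cli/nedsem segment image.png --out mask.png --seed 1`.

See `vignettes/nedsem-methods.Rmd` for the model, its assumptions, the
phantom generator's scope, and all numerical choices.

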