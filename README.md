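# powerseg

Robust two-phase segmentation of noisy grayscale images, built around a
power-mean (generalized mean) data term.

## The problem and who this is for

Region-based segmentation models summarize foreground and background by
representative intensities (c1, c2) and pick the partition that best fits
them. The classical models fit by least squares, so the representatives are
plain region means — and a minority of outlying pixels (speckle in
ultrasound or coherent imaging, salt-and-pepper corruption, acquisition
artifacts) drags the means and ruins the partition. `powerseg` is for
anyone segmenting binary-ish scenes in noisy 2-D images — biological and
medical imaging in particular — who needs the segmentation to be robust to
such outliers and independent of where the initial contour was drawn.

## The model

The fitting energy couples a fuzzy membership z ∈ [0,1] with a robust data
term and a boundary-length penalty:

    F(z, c1, c2) = mu ∫ |∇z|
                 + ∫ alpha (u − c1)² z^m
                 + ∫ beta  (u − c2)² (1 − z)^m,

where the weights alpha = (d1² + eps)^(p−1), beta = (d2² + eps)^(p−1) come
from a power-mean M-estimator: residuals enter effectively as (d²)^p with
0 < p ≤ 1, so for p < 1 outliers are down-weighted instead of dominating.
Centers are updated as weighted fuzzy means (iteratively reweighted / MM),
the membership has a closed-form update — for m = 2 simply
z = d2^(2p) / (d1^(2p) + d2^(2p)) — and a Gaussian filter of width sigma
regularizes z each iteration. With weights and centers frozen the energy is
convex in z, so the result does not depend on the initialization. The final
mask is z > 0.5.

Defaults: `p = 0.5`, `mu = 0.7`, `sigma = 3`, `m = 2`.

Also included: the classical Chan–Vese model (`cv_segment()`, relaxed
membership form with its own curvature regularization) and the
least-squares fuzzy energy model (`febm_segment()`, which is exactly the
power-mean model at p = 1); Jaccard/Dice metrics; a seeded phantom
generator with speckle/Gaussian/salt-and-pepper noise and bias fields;
PNG/TIFF/JPEG readers and writers; and a `powerseg` CLI
(segment / simulate / evaluate).

## A worked example

```r
library(powerseg)

ph  <- three_object_phantom()                      # 128x128, 3 bright objects
img <- add_noise(ph$image, "speckle", level = 0.2, seed = 1)
fit <- pm_segment(img)                             # defaults p=0.5, mu=0.7, sigma=3
print(fit)
#> Power-mean fuzzy segmentation
#>   image: 128 x 128   init: disk
#>   centers: c1 = 0.8035 (foreground), c2 = 0.1041 (background)
#>   iterations: 56 (converged), final energy 1523.7719
#>   foreground pixels: 3462 of 16384 (21.1%)
jaccard(fit$mask, ph$truth)
#> [1] 0.8288245
dice(fit$mask, ph$truth)
#> [1] 0.9064014
```

The printed centers sit on the true object/background intensities (the
phantom's objects are 0.80–0.90 on a 0.10 background) despite 20% of pixels
being heavily corrupted; the Jaccard/Dice values quantify mask overlap with
the known ground truth. `plot(fit)` shows the image with the recovered
contour, the fuzzy membership, and the energy trace; `coef()`, `fitted()`,
`residuals()` and `predict()` work as for any fitted model.

From the shell:

```sh
powerseg simulate --spec spec.yaml --seed 1 --out-image img.png --out-truth gt.png
powerseg segment  --input img.png --out mask.png --p 0.5 --mu 0.7 --sigma 3
powerseg evaluate --pred mask.png --truth gt.png --report report.yaml
```

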