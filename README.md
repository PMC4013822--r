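# enameloct

Automatic measurement of tooth enamel thickness from dental OCT volumes,
across the stages of orthodontic treatment with fixed braces.

Orthodontic work — polishing, acid etching, adhesive application, bracket
bonding, debonding and clean-up — removes or adds material on the enamel
surface. Quantifying those changes requires comparing OCT volumes of the
same tooth acquired at different treatment stages. `enameloct` implements a
fully automatic pipeline for that comparison, aimed at image-analysis
researchers and dental-imaging groups who have B-scan stacks (multi-page
TIFF) and want per-stage thickness statistics without manual boundary
tracing.

## Method core

For a filtered volume `L_M(m, n, i)` (depth row, lateral column, B-scan):

* **Outer boundary** `L_en(n, i)`: the first row whose intensity exceeds a
  global Otsu threshold `p_r`.
* **Inner boundary** `L_in(n, i)`: each A-scan below the surface is a linear
  brightness decay (enamel) over a constant plateau (dentine). The plateau's
  histogram mode `p_r2` and the plateau mean + one standard deviation
  `p_r3` bracket the working threshold; the volume is binarized,
  median-filtered, closed (3 x 3), hole-filled, and per B-scan the largest
  8-connected component's bottom edge is smoothed by a least-squares cubic
  in `n`.
* **Thickness** `L_d = L_in − L_en`, in axial pixels, times the axial pixel
  size (default 5 µm/px; 70 px → 350 µm).
* **Stage registration**: the depth-summed, min–max-normalized C-scan
  projection `L_T(n, i)` of each stage is aligned to the first stage by
  exhaustive search over shifts `Δn, Δi ∈ [−40, 40]` px and zoom
  `Δz ∈ {−20, −10, 0, 10, 20}` %, minimising the mean absolute difference
  `J = (1/(I·N)) Σ |L_Ta(n,i) − L_Tb(n+Δn, i+Δi)|` (zero written outside
  the moving image).
* **ROI**: a greedy active contour (±20 px moves, 6 x 6 grey-level patches)
  shrinks a frame-inset polygon onto the tooth outline of the smoothed
  reference projection; statistics are computed inside it.
* **Report**: per-stage mean/std/min/max thickness and the antisymmetric
  7 x 7 matrix of mean differences between stages `a`..`g`.

A synthetic phantom generator (`phantom_params()`, `generate_volume()`,
`generate_stage_series()`) produces volumes with known boundaries, planted
stage transforms and Rayleigh-like speckle, so the whole pipeline is
testable without proprietary scanner data.

## Worked example

Seven treatment stages of a phantom tooth (constant 730 µm enamel in the
footprint), with per-stage thickness offsets mimicking a published
treatment course and small planted shifts, run end to end:

```r
library(enameloct)

deltas <- c(0, -80, -435, -170, -650, -275, -125)   # µm vs. stage a
p <- phantom_params(shape = c(360, 128, 48), seed = 2,
                    speckle = list(model = "rayleigh", strength = 0),
                    thickness_fun = function(n, i, shape) {
                      e2 <- ((n - 64.5) / 55)^2 + ((i - 24.5) / 21)^2
                      ifelse(e2 <= 1, 146, 0)       # 146 px = 730 µm
                    })
series <- generate_stage_series(p, deltas,
  list(c(0,0,0), c(2,1,0), c(-3,2,0), c(1,-2,0), c(0,3,0), c(-2,-1,0), c(3,0,0)))

cfg <- pipeline_config(h3 = c(5, 5),                 # small-volume override
                       contour = contour_params(init_margin = 2))
res <- run_pipeline(lapply(series, `[[`, "volume"), cfg)

round(sapply(res$stats, `[[`, "mean"), 1)
#> [1] 729.4 649.4 294.4 559.4  79.4 454.4 604.4
res$diff_matrix[1, ]
#> L_ROIa L_ROIb L_ROIc L_ROId L_ROIe L_ROIf L_ROIg
#>      0    -80   -435   -170   -650   -275   -125
res$registrations[[2]][c("dn", "di", "dz")]
#> $dn [1] 2   $di [1] 1   $dz [1] 0
```

The stage means recover the planted thickness course to within a fraction
of an axial pixel (the small shared offset comes from the cubic boundary
fit and cancels exactly in differences), the first row of the difference
matrix reproduces the planted stage deltas exactly, and the planted
stage-b shift (2, 1, 0 %) is recovered exactly.

The command-line interface wraps the same pipeline:

```sh
exec/enamel-oct phantom --shape 360,128,48 --stages 7 --seed 2 --out stages/
exec/enamel-oct run --stages stages/stage_a.tiff,...,stages/stage_g.tiff \
                    --config cfg.yaml --out report/
exec/enamel-oct register --ref stages/stage_a.tiff --moving stages/stage_b.tiff \
                    --out reg.json
exec/enamel-oct validate --auto report/thickness_a.csv --expert expert.csv --ncols 128
```

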