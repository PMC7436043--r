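# detrusor

Fully automated measurement of bladder (detrusor) wall thickness from
transabdominal 2D B-mode ultrasound images.

Bladder wall thickness (BWT) is a noninvasive biomarker for bladder outlet
obstruction, detrusor overactivity and voiding dysfunction, and an input
required by bladder elastography. Reading it by hand is slow and
observer-dependent. `detrusor` automates the two steps a sonographer
performs:

1. **Segment the bladder sac.** A rough centre is found from the axial
   intensity profile (two interior maxima of a fitted 4th-degree
   polynomial mark the anterior and posterior walls). The image gradient
   is resampled along 360 rays around that centre and inverted, turning
   the closed inner boundary into the minimal-cost path of a dynamic
   program

   `C^(w,h) = min_δ [ C^(w−1,h−δ) + C(w,h)·(1+|δ|/γ) ]`, `|δ| ≤ 3`, `γ = 20`,

   solved exactly with 360-degree closure and projected back to image
   coordinates as a contour plus filled lumen mask.

2. **Track the anterior wall.** In a 14 × 6 mm search box at the mid-top
   of the sac contour, a multidimensional DP tracks the outer and inner
   wall boundaries jointly: node cost `g_inv(x,y1) + g(x,y2)` (inverted /
   signed depth gradient), transition factor
   `(1+α1)^|δ1| (1+α2)^|δ2| (1+α3|Δd|)` with `α = 0.2`, and the separation
   `d` constrained to the adult BWT range 1 mm < d < 7 mm. The mean
   separation is the reported thickness.

A compact U-Net-style convolutional segmenter (weighted categorical
cross-entropy, Glorot init, Adam, subject-level cross-validation, elastic
augmentation) is included as a fast alternative for step 1, together with
a synthetic sector-phantom generator with exact ground truth and the
evaluation toolkit (Dice, Hausdorff distance, RMSE, Bland–Altman).

## Worked example

```r
library(detrusor)

# a speckled phantom with known 2.6 mm wall at 0.2 mm/px
ph  <- generate_phantom(phantom_spec(wall_thickness_mm = 2.6), seed = 3)

seg <- segment_bladder_dp(ph$image)          # polar DP sac segmentation
dice(seg$mask, ph$lumen_mask)
#> [1] 0.998805

th  <- measure_wall_from_image(ph$image, seg$contour)
th
#> <thickness_result> mean wall thickness 2.53 mm over 30 columns
glance(th)
#> # A tibble: 1 x 3
#>   mean_thickness_mm n_columns total_cost
#>               <dbl>     <int>      <dbl>
#> 1              2.53        30       246.
```

The Dice index close to 1 says the segmented lumen overlaps the true mask
almost perfectly; the estimated thickness 2.53 mm is the true 2.6 mm
recovered to within half a pixel (0.1 mm) under speckle. `autoplot(seg)`
overlays the contour on the image, `tidy(th)` returns the per-column
thickness profile, and `bland_altman()` / `observer_table()` reproduce the
standard agreement analyses.

A thin command-line front end ships in `inst/cli/detrusor.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/detrusor.R", package="detrusor"))')" \
  segment-dp --image bladder.png --spacing 0.2 --out-mask m.png --out-contour c.csv
```

with subcommands `phantom`, `segment-dp`, `wall`, `eval`, `run`, `batch`.

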