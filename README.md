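# iriscal

Absolute (millimetre) facial measurements from frontal photographs with
**unknown magnification**, using the iris as an in-image ruler.

Clinical frontal photography rarely includes a physical scale, so pixel
distances between facial landmarks (inter-canthal span, subnasale–submental
height, …) cannot be converted to millimetres. The horizontal visible iris
diameter (HVID) is one of the most size-stable structures of the adult
face: population means cluster near 12.2 mm with an SD of about 0.49 mm.
`iriscal` implements *iris-dependent calibration*: segment the iris,
measure its horizontal diameter in pixels, assign it a constant anatomical
value, and scale every pixel measurement by

```
ratio (mm/px) = assigned HVID (mm) / measured HVID (px)
estimate (mm) = distance (px) × ratio
```

The package is aimed at researchers in facial anthropometry, orthodontics
and plastic/maxillofacial surgery who need absolute measurements from
archival or heterogeneous photograph collections, and at image-analysis
developers who want a complete, testable evaluation harness around their
own detectors/segmenters.

## What's inside

* **Calibration core** — `hvid_pixels()` (maximal horizontal chord, robust
  to eyelid occlusion), `magnification_ratio()`, `estimate_mm()`,
  `sweep_assigned_hvid()` (error as a function of the assigned value).
* **Classical reference pipeline** — CLAHE preprocessing, a deterministic
  eye detector and iris segmenter, with plug-in interfaces so trained
  models can be dropped in without touching the evaluation code.
* **Evaluation apparatus** — detection AP50/AP75/mAP against a greedy
  matcher; Dice/IoU/precision/recall with a five-fold cross-validation
  harness; MAE/MSE/RMSE/MAPE; Bland–Altman bias and limits of agreement;
  consistency validators for published tables.
* **Synthetic-scene generator** — schematic frontal faces with exhaustively
  known ground truth (true HVID, magnification, landmark positions, iris
  masks, eye boxes), LabelMe-dialect annotation export, population
  simulation with realistic HVID variability.
* **Tidy surface** — tabular results are tibbles; fitted objects support
  `tidy()`, `glance()` and `autoplot()`.

## Worked example

Generate one synthetic subject (true HVID 12.0 mm, rendered at 5 px/mm,
true inter-canthal distance 95 mm, subnasale–submental 70 mm), run the
full measurement pipeline, and calibrate with the standard assigned value
of 12.2 mm:

```r
library(iriscal)

sc <- make_scene(scene_params(hvid_mm = 12.0, magnification = 5,
                              canthal_distance_mm = 95,
                              subnasale_submental_mm = 70))
m <- measure_scene_reference(sc)   # detect -> segment -> chord
m$hvid_px
#>     left    right
#> 59.23438 59.23438

cal <- magnification_ratio(m$hvid_px[["left"]], m$hvid_px[["right"]],
                           assigned_mm = 12.2)
cal
#> <calibration: HVID (59.23, 59.23) px, assigned 12.20 mm, ratio 0.20596 mm/px>

estimate_mm(m$distances_px, cal)
#>      lateral_canthi subnasale_submental
#>            97.83171            72.08652
```

The true distances are 95 and 70 mm; the ~3% overshoot is exactly the
`12.2 / 12.0` assignment error — the intrinsic cost of assuming a
population-mean iris, which dominates the (sub-percent) measurement error.
A population-level validation quantifies it:

```r
cfg <- default_config()
cfg$synthetic$n <- 40
cfg$seed <- 2024
v <- run_validation(cfg)
glance(v$report)
#> # A tibble: 1 × 9
#>       n   mae   mse  rmse  mape  bias sd_diff loa_lower loa_upper
#>   <int> <dbl> <dbl> <dbl> <dbl> <dbl>   <dbl>     <dbl>     <dbl>
#> 1    80  3.29  19.6  4.43  3.94 -1.48    4.20     -9.71      6.75

autoplot(bland_altman(v$pairs))      # agreement plot
autoplot(run_sweep(cfg))             # MAPE vs assigned HVID
```

A thin command-line wrapper (`exec/iriscal`) exposes the same runs as
`iriscal {simulate|estimate|validate|sweep} --config cfg.yaml --out-dir out/`.

## Documentation

The methods vignette (`vignettes/iris-calibration.Rmd`) describes the
measurement model and its error floor, every pipeline tunable with its
default and rationale, what the synthetic scenes do and do not emulate,
and the package's numerical conventions.
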