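---
title: "Iris-dependent calibration: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iris-dependent calibration: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iriscal)
```

## The measurement model

A frontal facial photograph taken without a ruler has an unknown
magnification: the same face photographed at a different distance or focal
length yields a different pixel-per-millimetre scale, so pixel distances
between facial landmarks carry no absolute meaning. Iris-dependent
calibration exploits the remarkably tight population distribution of the
horizontal visible iris diameter (HVID). Across adult populations the HVID
mean is close to 12.2 mm with a standard deviation of roughly 0.49 mm —
about 4% of the mean — and it is essentially fixed after early childhood.
Treating the iris as an in-image ruler, the calibration is

$$ r = \frac{\mathrm{HVID}_{\mathrm{assigned}}\ (\mathrm{mm})}
           {\mathrm{HVID}_{\mathrm{measured}}\ (\mathrm{px})}
   \qquad\text{(mm per px)}, \qquad
   \hat d_{\mathrm{mm}} = r \cdot d_{\mathrm{px}} $$

for any pixel-space landmark distance $d_{\mathrm{px}}$ in the iris plane.
The package measures HVID automatically (eye detection, then iris
segmentation, then the widest horizontal chord of the mask) and ships the
statistical apparatus used to validate the approach: MAE/MSE/RMSE/MAPE,
Bland–Altman agreement, detection AP and segmentation overlap metrics with
a five-fold cross-validation harness, and a sweep of the assigned HVID
value.

The error of the method is dominated by biology, not by image analysis: if
a subject's true HVID is $H$ and the assigned value is $a$, every estimated
distance is off by the factor $a/H$. With $H \sim N(\mu, \sigma)$ and
$a = \mu$, the expected absolute percentage error tends to the folded-normal
mean

$$ \mathrm{MAPE} \;\to\; 100\,\frac{\sigma}{\mu}\sqrt{2/\pi}
   \;\approx\; 3.2\% \quad (\sigma = 0.49,\ \mu = 12.2), $$

which the test suite verifies by simulation. This is an intrinsic floor of
iris-dependent calibration; detector and segmenter quality only add to it.

## Pipeline stages and their tunables

1. **CLAHE** (`clahe()`): contrast-limited adaptive histogram equalization,
   tile grid 8×8, clip limit 2.0 expressed relative to the uniform bin
   height. The method is standard; because this package pins an exactly
   testable contract (per-tile mass conservation, single-tile/∞-clip
   reducing to plain histogram equalization with
   $m(g) = \mathrm{round}(255\,\mathrm{cdf}(g)/N)$, exact idempotence on
   constant images via an identity mapping for single-level tiles), the
   implementation lives in the package rather than behind a third-party
   call. Whether equalization helps more before detection or before
   segmentation is an open practical question; the pipeline applies it
   before both, each switchable in the config.
2. **Eye detection** (`detect_eyes()`): Otsu thresholding isolates dark
   compact blobs; candidates in the upper 65% of the image are ranked by
   circularity $4\pi A/P^2$ (also the confidence score) and the best blob
   on each side of the midline is kept. The reported box is the bright
   palpebral-fissure component surrounding the blob — matching the
   annotation convention in which the eyelids bound the rectangle above and
   below and the canthi laterally. Any learned detector can be slotted in:
   the contract is `image -> tibble(eye, corners, score)`.
3. **Iris segmentation** (`segment_iris()`): each eye box (15% margin) is
   cropped, resized bilinearly to the 256×256 model frame, equalized and
   thresholded (Otsu); morphological opening and closing (disc radius 2)
   clean the foreground, the largest connected component is kept and holes
   (the pupil) are filled. Again a plug-in interface, so trained-network
   masks can be evaluated with the same harness.
4. **Calibration** (`hvid_pixels()`, `magnification_ratio()`): HVID is the
   *maximal horizontal chord* of the mask, not the width of a fitted circle
   or bounding box. This matches the "horizontal visible" semantics and is
   invariant to upper-eyelid occlusion of up to 40% of the iris height (the
   equator stays visible); the tests pin this invariance. Chords measured
   in the model frame are mapped back through the recorded
   `frame_transform` before the ratio is formed — landmark distances are
   annotated on the original image, and mixing frames would silently
   corrupt the ratio. The two eyes are combined as the mean of their pixel
   diameters (one magnification per photograph); `left`, `right` and
   `per_eye_mean_of_ratios` are available in the config because the
   reporting conventions in this literature do not settle the question.
5. **Error analysis** (`error_metrics()`, `bland_altman()`,
   `stratified_report()`): differences are taken as actual − predicted,
   SDs use the sample (n−1) denominator, MAPE is reported in percent, and
   the limits of agreement are bias ± 1.96·SD. Published tables of this
   kind sometimes print the upper limit annotated with the "− 1.96·SD"
   formula and vice versa; the implementation follows the standard
   definition (upper = bias + 1.96·SD). `validate_error_summary()` and
   `validate_segmentation_summary()` check printed tables for the internal
   identities RMSE² = MSE and Jaccard distance = 1 − IoU at the rounding
   tolerance of the printed figures.

## The synthetic-scene generator

Real clinical photographs cannot ship with a package, so every stage is
exercised on schematic frontal scenes with exhaustively known ground truth:
a light background, a skin-tone face ellipse, bright palpebral fissures,
dark circular irises with darker pupils, optional upper-eyelid occlusion
drawn as an arc clipping the iris top, and the four landmarks (lateral
canthi, subnasale, submental). The population defaults *are* the study
conditions: true HVID ~ Normal(12.2, 0.49) mm, both landmark distances
uniform over their clinical ranges (lateral canthi 88–110.7 mm, subnasale–
submental 47.25–86 mm), occlusion uniform up to 20% of the iris height and
no pixel noise, so renders are bit-reproducible under a seed. The
magnification range, 3–8 px/mm, is an artifact choice (source photographs
in this field are typically a few thousand pixels across a ~200 mm face,
but the true camera scale is never reported); it is wide enough that the
scale-invariance claim is tested across nearly a factor of three.

Geometric conventions are pinned so rasterization oracles are unambiguous:
0-based (row, col) pixel indices, a disk of diameter $d = \mathrm{HVID}
\times \mathrm{magnification}$ rasterized by pixel-centre inclusion
(boundary included), landmark coordinates stored unrounded, and the
pre-rasterization diameter stored exactly. A scene's ground truth therefore
recovers its true distances exactly through the calibration formula, and
the rasterized mask's chord agrees with the stored diameter to within one
pixel.

What the generator deliberately does **not** emulate: skin texture,
specular highlights, eyelashes, iris ellipticity under gaze deviation,
perspective, glasses or contact lenses, and depth-plane differences between
the iris plane and landmarks in deeper planes (a known systematic of the
method that would require a depth correction; out of scope here).
Consequently, passing tests demonstrate the *correctness of the
computational chain* and the *statistical behaviour of the calibration*,
not detector/segmenter robustness on clinical photographs — the
plug-in interfaces exist precisely so trained models can replace the
classical references without touching the harness.

## Numerical choices and degenerate inputs

* Polygon rasterization uses the pixel-centre even-odd rule with a
  scanline implementation; centres lying exactly on an edge are included
  (deterministic tie-break). Zero-area polygons yield an empty mask plus a
  warning.
* AP uses greedy score-ordered one-to-one matching with score ties broken
  by larger IoU then input order, and 101-point interpolated precision by
  default; all-point interpolation is a config flag, since detection
  papers rarely state their convention. An empty truth set is an
  undefined-metric error, not 0 or 100.
* Metrics with zero denominators are `NaN` (flagged undefined, never
  silently 0, so averages cannot be inflated); all-zero confusion counts
  are an error.
* Failure policy in the pipeline is skip-and-log per subject — the
  clinical analogue of exclusion criteria — with a hard error if nothing
  survives (or if more than 20% of a sweep population fails).
* Cross-validation folds are disjoint, differ in size by at most one, and
  are deterministic under a seed.

## Problem sizes

The shipped simulation studies use 500 subjects for the assigned-HVID
sweep (measurement-level, unrendered scenes), 200 rendered subjects for
the full-pipeline error bound, 50 noiseless scenes for detector AP, and
4000 unrendered subjects for the folded-normal comparison; at these sizes
the sweep's minimizing value is stable to the 0.1 mm grid and the MAPE
estimates to well under half a percentage point. These are the package's
own choices of simulation size, balancing Monte-Carlo stability against a
laptop-friendly runtime.

## Known limitations

* The classical detector and segmenter are references for the harness, not
  clinical-grade models; on real photographs a trained detector/segmenter
  should be plugged in.
* Landmarks are taken from annotations, not detected; automating landmark
  localization is a separate problem.
* All measurements assume the landmark lies in the iris plane; distances to
  deeper structures inherit a systematic scale error that this package does
  not correct.
* The assigned 12.2 mm is a population mean; per-subject deviation from it
  sets the ~3.2% error floor derived above, and no amount of additional
  data removes it.
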