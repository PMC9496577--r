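---
title: "Methods: from plate photograph to concentration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plate photograph to concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platequant)
```

## The measurement problem

A colorimetric assay develops a dye whose colour intensity tracks the
analyte concentration: the Jaffe reaction turns creatinine plus picric
acid red (peak absorbance 490 nm); a glucose oxidase/peroxidase reagent
turns glucose pink (560 nm). In a laboratory the plate is read in a
microplate reader; a portable alternative photographs a white opaque
96-well plate from above with a fixed camera, four white corner LEDs, and
four dark reference squares around the well area. `platequant` is the
software half of such a reader: it converts one test photograph plus one
white-block calibration photograph into per-well optical densities and
dilution-corrected concentrations via a standard curve.

The pipeline is: **register** (find the four fiducial squares, fit the
pixel-to-plate homography, resample into plate millimetres) →
**flat-field** (divide out the illumination pattern recorded by the white
image) → **readout** (per well, per RGB channel, the histogram-mode
intensity; then one scalar by camera-sensitivity weighting) →
**photometry** (estimate per-well incident light from nearby empty wells,
form the optical density) → **quantify** (fit the log-linear standard
curve, predict, dilution-correct, replicate statistics).

## Registration

The camera views a plane, so a 3x3 projective homography relates pixel
and plate coordinates, and the four fiducials determine it exactly
(8 constraints, 8 degrees of freedom; normalized DLT). Detection is
Otsu thresholding followed by connected-component filtering. Three
filters identify the markers among other dark blobs:

* area between 64 px and 5% of the image (and, when an expected marker
  area is supplied, within 0.25x--4x of it);
* solidity > 0.8 and a 99th-percentile/mean radial-distance ratio
  >= 1.62 — about 1.72 for a square and 1.49 for a disc, which is what
  separates square markers from equally dark *circular* dye wells,
  rotation-invariantly and robustly to boundary noise;
* mean RGB channel spread <= 40 intensity units — markers are neutral
  gray, dye spots are strongly chromatic, and this also rejects wells
  whose shape was distorted by glare or bubbles.

Exactly one candidate must survive per image quadrant, otherwise the
detector refuses with a diagnostic rather than guessing.

Centroids are computed by *normalized coverage*: local background and
dark levels are fitted as planes around each marker, each pixel is scored
by `(background - I) / (background - dark)`, and the centroid is taken
over these coverage weights. Interior pixels score exactly 1 regardless
of the illumination gradient, and anti-aliased edge pixels score by their
true coverage fraction, giving centroids good to a few hundredths of a
pixel. Plain intensity-weighted centroids carry an
illumination-gradient bias an order of magnitude larger, which is
measurable in the recovered homography.

Registration cannot (and should not) disambiguate a 180-degree plate
rotation when the markers are placed symmetrically: orientation is fixed
by how the plate is inserted into the device, not by software.

## Flat-field calibration

Illumination is not homogeneous: the four corner LEDs differ in output,
their light falls off toward the plate centre, and the sensor response
varies across the field. All of these are multiplicative, so one white
image determines a per-pixel, per-channel gain:

    gain(p, ch) = median_ch / white_smoothed(p, ch)

The white image is Gaussian-smoothed (sigma = 2% of image width) to
suppress target texture and shot noise without disturbing the smooth
illumination field; the reference level is the *median* of the smoothed
image (robust to specular highlights, unlike the maximum), so the median
gain is exactly 1. There is no dark-frame term — a single white image
only supports a multiplicative model, and dark offset is negligible for a
well-exposed camera. A gain spread above 10x aborts loudly, as does >1%
saturation in any channel.

Because the reference is the plate-median level, two different
illumination fields produce corrected images on slightly different
absolute scales; optical density is a ratio and cancels the scale
exactly. The residual field-to-field disagreement is set by 8-bit
quantization: one intensity step at weighted intensity y is about
`0.434 / y` OD, i.e. 0.009 OD at y = 50 but 0.025 OD at y = 17. OD-level
invariance claims therefore apply to wells above the dark floor, while
concentration-level invariance (< 2% for paired test/white renders under
LED intensities matched within about +-10%, the usual LED binning
envelope) holds for the sample range.

## Well readout

Well positions are known in plate coordinates (ANSI/SLAS: 9 mm pitch, A1
centre at 14.38, 11.24 mm), so segmentation after registration is purely
geometric. The ROI is a disc at 70% of the well radius: large enough for
a stable histogram, small enough to exclude the well wall and rim shadow.

Each channel is reduced to the intensity with the **highest histogram
frequency** (256 integer bins, ties to the lower bin). The mode, unlike
the mean, is unmoved by glare, bubbles, reflections, or any artifact
occupying less than half the ROI — a saturated disc covering 20% of the
pixels changes nothing. The three channel modes are then combined into
one scalar

    y = a I_R + b I_G + c I_B,   a = RS/(RS+GS+BS), etc.

with RS, GS, BS the camera sensitivities at the assay's peak absorbance
wavelength (Sony IMX219: RS = 0.07, GS = 0.82, BS = 0.66 at 490 nm for
creatinine; RS = 0.13, GS = 0.83, BS = 0.11 at 560 nm for glucose;
arbitrary wavelengths by linear interpolation of a user-supplied
sensitivity curve). Mode first, then weighting — so artifact robustness
acts per channel.

## Incident light and optical density

The incident light for a well is estimated from *empty wells near it*,
which compensates the residual centre-to-edge intensity trend:

1. Round the 96 weighted intensities to integers and histogram them; the
   most frequent level `w` is the empty-well intensity (dye wells vary,
   empty wells agree; ties go to the brighter level since empty wells are
   the brightest repeated value).
2. For each well take all wells in the 5x5 grid window centred on it
   (truncated at plate edges; the centre well is included — if it holds
   dye it fails the next cut anyway), keep those with `y >= 0.95 w`, and
   average them to get the local incident estimate `wL`. If none
   qualifies, fall back to `w` and flag the well.
3. `OD = -log10(wL / y)`.

This sign convention makes an absorbing solution's OD *negative* (it is
the negative of conventional absorbance); the standard-curve slope
absorbs the sign, and `conventional_od = TRUE` flips it for
interoperability with absorbance-based instruments. A well with `y = 0`
is flagged saturated and excluded rather than producing an infinite OD.

## Standard curve and quantification

Empirically, camera-based white-plate readouts of these assays show a
saturating OD-concentration relationship that is well described by a
log-linear law, so the curve is fitted as

    ln(Cd) = x * OD + z        (OLS on the nonzero standards)

and inverted as `Cd = exp(x OD + z)`. The zero standard cannot enter a
log fit; it is retained as a quality-control point whose OD should be
near 0. Fewer than three nonzero standards, or standards with no OD
variance, abort the fit. The final concentration applies the dilution
factor, `C = Cd * df`, exactly.

Flags are advisory: `above_range`/`below_range` compare the *diluted*
concentration (the quantity actually on the curve) with the standards'
span; `extrapolated` marks ODs outside the standards' OD span. An
above-range sample should be diluted further and re-tested. Replicate
groups get the arithmetic mean and the sample (n-1) SD — for duplicates,
`|x1 - x2| / sqrt(2)`. `dilution_series_report()` recommends, among
dilution levels whose diluted concentration stayed in range, the one
minimising the replicate SD (ties to the lowest dilution): stronger
dilution helps because on an exponential curve a fixed intensity
uncertainty produces a concentration error that grows with the
concentration — `|dC/dy| = |x| C / (y ln 10)` increases along the curve —
until over-dilution pushes the sample below the detection limit.

The fitted curve is a classed model object with `print`, `summary`,
`coef`, `predict`, `residuals` and `plot` methods; the pipeline wrapper
`plate_analyze()` returns a `plate_assay` bundling readings, OD table,
curve, sample results and QC counters, with CSV/JSON writers that format
numerics at fixed 6 decimals so identical inputs give byte-identical
outputs.

## The synthetic plate generator

Every stage above is validated against rendered scenes with exact ground
truth (`plate_scene()`, `render_plate()`, `render_white_block()`). The
generator emulates:

* SLAS plate geometry (127.76 x 85.48 mm) with four 5 mm gray fiducial
  squares inset 5.5 mm from the corners;
* four corner LEDs at 70 mm height with per-source relative intensities
  `c(1, 0.95, 1.05, 0.9)` (LED binning tolerance) and falloff exponent 3
  — the physical Lambertian-times-inverse-square law for a
  downward-pointing source. This yields a 7% well-to-well intensity CV
  uncorrected, the gradient flat-fielding exists to remove;
* a projective camera (default 5 px/mm fronto-parallel; tilt/rotation
  configurable), 8-bit quantization with round-half-to-even;
* Gaussian sensor noise (sigma 2 intensity units), saturated glare discs
  (3 per plate, radius 0.5--1.2 mm, at most ~12% of a well's area) and
  dark bubbles (2 per plate, 0.3--0.7 mm) — the artifacts the
  histogram-mode readout is designed to shrug off;
* analytic anti-aliasing of the fiducial edges (exact pixel-footprint
  coverage): the sub-pixel edge information a real camera's optical blur
  provides, without which sub-pixel marker localisation would be
  meaningless.

Everything is driven by one integer seed; identical scenes render
bit-identical images.

### Dye response models

The forward colour model fixes the weighted transmittance
`T(c) = y(c) / y_blank` and then distributes the attenuation over the RGB
channels with relative absorptivities (absorbance channel 1, red weakest
for a red complex), solving a one-dimensional root per concentration so
the *weighted* intensity matches `T(c)` exactly. Two response laws are
available:

* `"log_linear"` (default): `T(c) = (c / c_ref)^(-gamma)` above a small
  threshold `c_lo` below the lowest nonzero standard, with a strictly
  decreasing linear ramp to `T(0) = 1`. This is the saturating response
  regime in which the exponential standard curve is *exact*, matching
  the empirically log-linear behaviour of the physical readout, and
  giving an analytic oracle for the fitting stage: rendered standards
  recover the generating `(x, z)` and a held-out standard to well under
  a percent (noise-limited).
* `"beer_lambert"`: `T(c) = 10^(-k c)` — ideal Beer–Lambert attenuation
  of the weighted intensity. Useful for testing the photometry layer
  (OD is then exactly proportional to concentration), but note that an
  exponential standard curve is a biased approximation in this regime:
  the two laws cannot hold simultaneously, and the package deliberately
  ships both so the distinction stays visible.

Creatinine defaults: gamma 0.64, c_ref 0.0413 mmol/L, c_lo 0.045 mmol/L,
alpha (0.12, 1, 0.85) — the top 1.77 mmol/L standard transmits ~9%,
keeping the darkest well above the 8-bit noise floor. The standard
series is a doubling ladder 0, 0.625, 1.25, 2.5, 5, 10, 20 mg/dL
(0--1.77 mmol/L; 1 mg/dL creatinine = 0.0884 mmol/L), the usual design
for a log-spaced curve; glucose uses 0, 1, 2, 4, 8, 16, 32 mg/dL over
its 0--32 mg/dL range.

### What the generator does not emulate

No lens PSF or Bayer demosaic (only the markers are anti-aliased), no
meniscus optics, no vignetting beyond the LED falloff, no urine
background colour, no reagent kinetics (incubation time is metadata),
and no inter-device variation. Passing tests therefore demonstrate the
*algorithmic* correctness and noise/artifact robustness of the pipeline
on images whose physics is known exactly — not the clinical accuracy of
any physical device, which additionally depends on chemistry, optics and
sample matrix effects outside this model.

## Problem sizes and numerical choices

Unit fixtures render at 3 px/mm (about 404 x 277 px) for speed; the
study condition used by the end-to-end recovery experiment is the
default 5 px/mm (about 669 x 458 px), 20 seeded replicates, full noise
and artifact model, with the 0.221 mmol/L standard held out of the fit
and assayed as an unknown duplicate. Tie-breaks are fixed (channel mode:
lower bin; empty-well level: higher bin; dilution recommendation: lower
factor), degenerate inputs error with named wells, and all RNG flows
from explicit seeds. The oracle for the incident-light stage is an
independent brute-force enumeration of the 5x5 window, compared exactly
on 1000 random intensity configurations.

## Known limitations

* 8-bit mode readout quantizes OD; precision degrades below y ~ 30.
* Fiducial shape/colour filters assume gray square markers and coloured
  dye; a gray-black assay would need a different marker discriminator.
* The homography model ignores lens distortion; strongly distorted
  optics would need a prior undistortion step.
* The log-linear curve is fitted unweighted; replicate-weighted or
  4PL/5PL fits are out of scope.
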