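---
title: "Methods: how berrymorph measures fruit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how berrymorph measures fruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrymorph)
```

# The measurement problem

Breeding programs for berry crops select on fruit size, shape, colour and
their uniformity, but hand measurement (calipers, colour bins,
anthocyanin assays) is slow, destructive or subjective. Photographing the
fruit separated on a uniform stage under controlled light turns all of
those traits into an image-analysis problem: find every berry and every
circular scale marker, measure each berry from its segmentation mask, and
report the results per berry in physical units.

`berrymorph` implements that pipeline with a deliberately classical,
fully deterministic computer-vision path. Each stage is exposed as an
ordinary function on tibbles and matrices, so any stage can be replaced —
in particular the segmenter: `process_image()` only needs *some* source of
labelled masks, and a neural instance-segmentation backend can be slotted
in where `hsv_threshold_segment()` + `classify_components()` sit today.

# Segmentation

The stage background is assumed uniform and either lighter or darker than
every object. In the default `auto` mode the value channel (HSV) is
thresholded with Otsu's method; the polarity is chosen from the median
border-pixel value, and saturated pixels are kept as foreground so that
bright-but-coloured fruit on a light background are not lost. Users with
unusual scenes can switch to fully static hue/saturation/value windows in
`threshold_config()`. The foreground is cleaned by morphological opening
and closing (disk radius `morph_radius`, default 2 px — large enough to
remove speckle, small enough not to blunt a berry tip), holes are filled
(specular highlights can punch holes in otherwise solid fruit, and the
area metric is defined on the filled region), and components smaller than
`min_object_area` (default 200 px) are dropped. Components touching the
image border are dropped and reported: a partially visible berry cannot be
measured honestly.

A component is called a **marker** only if it is simultaneously circular
(circularity $4\pi A/P^2 \ge 0.85$), dark (mean value channel $\le 0.35$)
and of plausible size (within $[0.25\times, 4\times]$ the median area of
the circular-dark candidates). Everything else — including any ambiguous
object — defaults to berry, which errs on the side of flagging rather than
silently discarding fruit.

These thresholds were tuned on the package's synthetic fixtures only; the
classical path is intended for clean, consistently laid-out stages.

# Size and shape

All coordinates are 1-based with pixel centers at integer positions,
x = column, y = row.

**Orientation.** The major-axis direction is taken from the second central
moments of the foreground pixels,
$\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11},\ \mu_{20}-\mu_{02})$,
mapped to $[0, \pi)$. Near-isotropic masks (relative moment anisotropy
below $10^{-6}$) get $\theta = 0$ for determinism; all downstream metrics
are rotation-invariant for such masks anyway.

**Length and width** are the extents of the boundary, rotated by
$-\theta$ about the centroid, under the pixel-extent convention
$\max - \min + 1$: an axis-aligned $w \times h$ rectangle reports exactly
$w$ and $h$. If the moment axis disagrees with the longest extent the two
are swapped so length ≥ width always holds (the swap is recorded on the
result).

**Perimeter.** The outer boundary is traced through boundary-pixel
centers with 8-connectivity. The raw chain systematically overestimates
smooth boundaries — averaged over edge directions a digital straight
segment measures ≈ 5.5% long under the (1, √2) step metric — so the
perimeter is measured on the Douglas–Peucker simplification of the chain
at a 0.8 px tolerance. Vertices remain boundary-pixel centers (no
sub-pixel smoothing); a 10 × 10 square measures exactly 36 and a digital
disk of radius 100 is within ~1% of $2\pi r$. The tolerance trades
corner fidelity against staircase noise; 0.8 px keeps true right angles
(sagitta of a 90° corner ≈ 0.71 px > would be cut at lower tolerance)
while absorbing one-pixel jitter.

**Width profile, volume and surface area.** The berry is modelled as a
solid of revolution about its major axis. The boundary polygon is rotated
so the major axis is vertical and sliced at unit steps; slice $i$ gets the
extent $w_i$ between the outermost boundary crossings (+1, same extent
convention). Slicing the rotated *polygon* analytically, instead of
resampling the rotated *mask*, keeps the profile free of nearest-neighbor
jitter: the frustum sum below is first-order sensitive to slice-to-slice
noise, and with mask resampling its rotation spread was several times
larger. For axis-aligned masks the polygon slices equal the per-row mask
extents exactly. Widths are extents rather than pixel counts so interior
holes can never deflate them.

$$V = \pi \sum_{i=1}^{h} (w_i/2)^2, \qquad
S = \pi\Big[(w_1/2)^2 + (w_h/2)^2 +
\sum_{i=1}^{h-1} \big(\tfrac{w_i}{2}+\tfrac{w_{i+1}}{2}\big)
\sqrt{\big(\tfrac{w_i}{2}-\tfrac{w_{i+1}}{2}\big)^2+1}\Big]$$

Each slice is a 1-px-high cylinder; the surface sum uses the lateral
areas of 1-px frustums plus the two end caps. Note the $\pi$ in the
volume sum: a cylinder slab of radius $w_i/2$ and unit height has volume
$\pi (w_i/2)^2$, and without it no accuracy statement against true
volumes could hold.

**Reference solids.** The estimators are validated against the prolate
spheroid obtained by revolving an ellipse (semi-axes $a \ge b$) about its
major axis: $V = \tfrac43\pi b^2 a$ and
$S = 2\pi b^2(1 + \tfrac{a}{be}\arcsin e)$, $e = \sqrt{1-b^2/a^2}$. These
closed forms are exact for the solid the width profile of an ideal
ellipse mask describes; general tri-axial ellipsoids have no closed-form
surface area, but a mask-derived solid of revolution is not tri-axial.

## Discretization accuracy, honestly

On ideal ellipse masks rasterized by pixel-center inclusion, the
estimators carry a resolution-dependent bias. The dominant term is
*flat-top quantization*: near the equator the true half-chord
$b\sqrt{1-y^2/a^2}$ drifts by less than one pixel across
$\mathcal{O}(a/\sqrt{b})$ consecutive slices, all of which quantize to
the same integer extent, so their errors do not average out. The test
battery used by `scripts/acceptance.R` (semi-axes 50×30, 100×60, 150×150,
200×80, 120×40 px) measures a worst-case volume error of **0.88%**
(at 50×30; 0.27% at 100×60, 0.04% for the sphere) and a worst-case
surface-area error of **4.6%**. The volume bias falls roughly linearly
with resolution — at semi-axes 500×300 px it is 0.03%, and the unit tests
pin that convergence — so claims of ~0.05% volume accuracy apply to
high-resolution masks (berries several hundred pixels across), not to the
small end of this battery. No extent convention does better: exact
(sub-pixel) chords on the same slice grid reach 0.01% at 50×30, but a
binary mask simply does not carry that information at that scale.

**Roundness** is $r_\text{inscribed}/r_\text{enclosing}$ with the
inscribed radius from the Euclidean distance transform and the enclosing
radius from the minimum enclosing circle of the boundary (Welzl's
algorithm on a deterministic point order — no RNG is consumed).
**Solidity** divides the pixel count by the number of pixel centers
inside or on the convex hull of the boundary, so both numerator and
denominator are in the same currency and convex shapes score 1.0 up to
rasterization error (a filled square scores exactly 1).

# Colour

Waxy fruit mirror the stage along their rim, so a 10-px border (the
`erosion_radius` default; appropriate for berries ≳ 60 px across) is
eroded off before any colour statistic. If erosion would empty a small
mask, the un-eroded mask is used and the berry is flagged
`EROSION_FALLBACK`.

Per-channel RGB means, medians and population variances are computed over
the remaining pixels. Medians use the lower-median tie rule so they stay
integers on 8-bit images. Grayscale is the Rec.601 luma of the channel
medians, $0.299R + 0.587G + 0.114B$ (coefficients sum to 1, so gray is a
fixed point); the per-pixel gray variance is reported alongside the
channel variances as the colour-variation measure. HSV means treat hue
circularly (resultant-vector direction, degrees), so hues straddling
0°/360° — exactly where red fruit live — average correctly.

CIELAB values are computed per pixel by the standard path: sRGB gamma
decoding → linear RGB → XYZ → Lab under the **D65** reference white (the
native white point of sRGB; configurable). Means and population SDs are
taken after conversion — converting the mean RGB instead would make the
dispersion statistics meaningless. $L^*$ falls monotonically as a colour
darkens at fixed chromaticity, which is what makes it a ripeness proxy;
$a^*$ separates green from red fruit by sign.

# Calibration, grids and matching

Marker diameters come from the minimum enclosing circle of each marker's
boundary — robust to small segmentation nicks, unlike area-equivalent
diameters. The scale is the median diameter divided by the known physical
diameter (2.54 cm default), after excluding markers deviating more than
20% from the median (a mis-classified berry would otherwise poison the
scale). The median (rather than the mean) was chosen for the same
robustness reason. With no markers, metrics stay in px and the cm columns
are NA — both column sets are always present so downstream tooling never
re-measures.

Grid assignment sorts centroids by y and opens a new row when the y-gap
exceeds half the median mask height — a threshold that separates typical
5 × 6 stage layouts with realistic jitter; pathological layouts surface
as obviously wrong row counts rather than silent misassignment. Within
rows, columns follow x. Berries measured twice (two platforms, two runs)
are matched by **reciprocal nearest centroids**: a pair is kept only if
each is the other's nearest neighbour. No distance cutoff is applied, but
distances are reported so callers can filter.

# Quality control

Two runtime checks mirror how segmentation failures actually look:
`LOW_SOLIDITY` (solidity < 0.95) catches ragged or leaked masks, and
`AREA_OUTLIER` (area more than 3 within-image SDs from the image mean)
catches merged or fragmented detections. `EROSION_FALLBACK` and border
contact extend the vocabulary because both silently bias metrics; they
are additions of this implementation and named accordingly.

# The synthetic scene generator

`make_grid_spec()` / `render_scene()` emulate the validation conditions
of a stage photograph: a jittered grid of shaded elliptical berries
(default 5 rows × 6 columns, semi-axes drawn from 38–50 × 30–40 px, a
dark-red palette, ±4 px jitter) with near-black circular markers
(100 px ↔ 2.54 cm, i.e. ≈ 39.4 px/cm — the scale of a typical DSLR stage
setup) in the side margins. Rasterization uses pixel-center inclusion
with no anti-aliasing, so ground truth (axes, colours, areas, grid
positions) is exact and scenes are bit-reproducible from their seed.
Radial shading (linear darkening toward the rim) mimics the shadow/specular
structure that motivates border erosion; a triangular notch of
caller-chosen depth lowers solidity for QC tests. Berry colours default
to uniform (`shading = 0`) so colour recovery can be asserted exactly;
shaded variants exercise the variance paths.

What the generator does **not** emulate — and what green tests therefore
do not establish about camera data: lens distortion and perspective,
sensor noise and demosaicing, JPG artefacts (PNG is the default; a
quality-95 JPG path exists for robustness checks), touching or
overlapping fruit, non-elliptical berry silhouettes, stems and debris,
and illumination gradients. The classical segmenter's thresholds are
fixture-tuned; on real images they are starting points, not a validated
reproduction of any production configuration.

# Problem sizes and determinism

The shipped tests validate estimator accuracy on ellipse masks up to
semi-axes 500 × 300 px, run the full pipeline on ten seeded 5 × 6 scenes
(~1340 × 910 px), check matching against a brute-force oracle on 100
random point sets (n ≤ 100), and the statistic identities on 1000 random
vectors — sizes chosen so the whole suite exercises every claim at
meaningful scale while remaining quick to run. Everything outside the
seeded generators is deterministic: segmentation and measurement consume
no random numbers, and the generator restores the caller's RNG state.

# Platform-comparison statistics

For matched berries measured by two platforms, `compare_traits()` reports
per-trait means with t-based 95% confidence intervals, pooled minima and
maxima, the mean difference $\bar d = \overline{x - y}$ (implementation
minus reference), the **range-normalised mean difference**

$$\mathrm{rmd} = \frac{\bar d}{\min\big(x_{(n)}-x_{(1)},\; y_{(n)}-y_{(1)}\big)}$$

— the shift between platforms expressed against the smaller
within-platform spread, comparable across traits of different scales —
plus the Pearson correlation and a paired t-test. Degenerate inputs are
handled explicitly: identical platforms give $t = 0, p = 1$; zero-range
traits make rmd an error rather than an Inf. p-values are unadjusted; on
thousands of berries nearly everything is "significant", so rmd and $r$
are the quantities to read.

# Known limitations

* The classical segmenter needs clean backgrounds and separated fruit; it
  has no notion of object classes beyond berry/marker and will happily
  segment debris (which QC flags only sometimes catch).
* Volume and surface area inherit the resolution-dependent bias analysed
  above; compare absolute values between datasets only at similar
  image scales.
* Colour statistics are only as good as the illumination; no colour
  correction is applied (colour-card workflows are out of scope), so
  cross-dataset colour comparisons need identical capture conditions.
* Solidity and roundness are 2-D silhouette properties; lobed or
  flattened fruit resting on different faces will score differently.
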