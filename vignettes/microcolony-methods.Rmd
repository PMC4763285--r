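---
title: "Methods: simulating and counting microcolonies on a lensless on-chip microscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and counting microcolonies on a lensless on-chip microscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcolony)
```

## The measurement this package models

In contact-mode (shadow) on-chip microscopy a bacterial culture grows
directly on a CMOS pixel array: each pixel records the transmission shadow of
whatever sits above it, giving a field of view equal to the whole chip
(5.7 mm × 4.3 mm at 2.2-µm pitch, about 25 mm²) but a raw resolution limited
by the Nyquist criterion to roughly twice the pixel pitch. Sub-pixel sweeping
recovers resolution: a light source is stepped through a grid of lateral
offsets, each offset tilting the illumination and translating every shadow by
a sub-pixel amount. The low-resolution (LR) frames are then fused into one
high-resolution (HR) image per timepoint. Segmenting, sizing and tracking the
colonies in the HR time-lapse turns the chip into an automated
microcolony counter: colonies become countable at ~20 µm equivalent diameter,
hours before they are visible to the naked eye on a plate.

This package implements the full software side of that instrument —
geometry, forward simulation, reconstruction, segmentation, tracking and
enumeration statistics — so the pipeline can be exercised and validated
end-to-end on synthetic ground truth.

## Shadow-shift geometry

A point source at lateral offset $L = (L_x, L_y)$ and height $H$ above the
sensor displaces the shadow of an object at height $z$ by

$$\Delta = -\frac{z}{H - z}\,L$$

(similar triangles; positive source offset moves the shadow the other way).
We use the exact $z/(H-z)$ form rather than the small-$z$ approximation
$z/H$ — it costs nothing and removes an ambiguity. The shift is treated as
global across the field of view; the neglected field-position dependence is
of order FOV$/H \approx 10^{-4}$ of the shift and is quantified against a
brute-force ray-tracing oracle in the tests, which agrees with the model to
$10^{-9}$ relative error.

`design_scan()` inverts the relation: for enhancement factor $E$ the source
spacing that advances the shadow by exactly $1/E$ LR pixel per step is
$\text{pitch}\cdot(H-z)/(zE)$. The default acquisition is an 8 × 8 grid at
$H = 80$ mm in serpentine order (consecutive frames always differ by one
grid step), giving 64 frames that cover the $E^2 = 16$ sub-pixel phases
four times over. Neither the LED grid geometry nor its height is prescribed
by the measurement principle; both are configurable, and all results state
the geometry used.

## The phantom generator

The generator is the package's definition of the study conditions, not a
tuning knob:

* **Seeding.** Colony centres are uniform over the FOV. Surface density is
  the controlled primitive (default 80 CFU/cm², below the 100 CFU/cm²
  working limit for microcolony counting), or an explicit count can be
  given. An optional hard-core minimum separation emulates a well-dispersed
  inoculum; with it at 0 (default), neighbouring colonies may merge as they
  grow, which is exactly what limits plate-count densities.
* **Growth law.** Linear radial expansion after a normally distributed lag:
  $d(t) = d_0 + 2v\,\max(0, t - t_0)$, with per-colony
  $t_0 \sim N(240, 40^2)$ min and $v \sim N(0.10, 0.02^2)$ µm/min truncated
  positive, $d_0 = 1$ µm. Only monotone growth is essential; the linear-radial
  form with these defaults puts the simulated size statistics in the range
  observed for *S. epidermidis* microcolonies (mean diameter in the
  mid-20s of µm near 6 h, roughly doubling every further 2 h). The model is
  pluggable.
* **Optics.** Each colony is an absorbing disk, centre transmission 0.35,
  with a logistic edge 2 µm wide (the boundary is the feature segmentation
  keys on, so its profile matters more than interior texture). Overlapping
  colonies multiply transmissions, so merged colonies form one connected
  dark region. Diffraction of the shadow across the sample–sensor gap is
  modelled crudely as a Gaussian blur with σ = 0.3 µm per 10 µm of height;
  exact Fresnel propagation is out of scope, but the blur reproduces the
  qualitative resolution loss with height that digital refocusing must cope
  with.
* **Sensor.** The scene is rendered on a grid `supersample_S` (default 8)
  times finer than the pixel pitch, translated by the exact shadow shift,
  box-integrated over each pixel footprint, multiplied by a fixed low-order
  polynomial flat-field (±5% by default, so background correction is
  genuinely exercised), then corrupted by Poisson shot noise (5000 photons
  per pixel at full scale) and Gaussian read noise (σ = 2 DN) and quantized
  to 16 bits.

What the generator does **not** emulate: lobed or filamentous colony
morphology, 3-D thickness profiles, motility, nutrient depletion, sensor
fixed-pattern noise, and coherent diffraction fringes. Passing tests
therefore demonstrate that the algorithms are correct for compact absorbing
colonies under realistic shot noise — not that they are robust to every
morphology a real culture can produce.

## Shift-and-add reconstruction and digital refocusing

Each LR pixel value is deposited at its de-shifted position on the $E\times$
finer grid, rounded to the nearest HR bin; a hit-count grid normalizes the
accumulation, and the few bins never visited (only possible for undesigned
scans) are filled by separable linear interpolation. This
nearest-bin shift-and-add is the standard reading of "interpolate the LR
frames onto a larger matrix according to their shifts"; with $E = 1$ and
zero shifts it reduces *exactly* to frame averaging, which the tests pin
down. Accumulation is in double precision; HR images serialize as 32-bit
float TIFF. A deconvolution post-step to undo the pixel-aperture box blur
would be a natural extension but is deliberately absent: the counting
pipeline does not need it.

Because the de-shifts depend on the assumed height $z$, reconstructing the
same stack at several candidate depths and scoring each ("digital
refocusing") recovers the sample plane after acquisition. The score is the
Tenengrad measure — mean squared 3 × 3 Sobel gradient magnitude — after a
Gaussian pre-smoothing of 1.5 HR px. The pre-smoothing is a deliberate
numerical choice: reconstructing at a wrong depth misregisters frames by
fractions of a pixel, producing bin-to-bin speckle whose raw gradients can
outscore a genuinely focused edge; smoothing at the HR point-spread scale
suppresses the speckle while preserving the ordering of true edge
sharpness. Ties break toward the smaller depth, and a maximum at an
endpoint of the scanned range raises a warning. Focus recovery was
validated on single-colony phantoms at random depths in 15–85 µm with
candidates every 10 µm: the argmax lands within one candidate step in ≥ 90%
of runs.

## Segmentation and sizing

The counting algorithm is deliberately simple (load → segment → enumerate):

1. **Background correction.** Block medians on cells of about half the
   background scale (default scale 200 µm) are fitted with a quadratic
   surface; cells flagged as dark outliers by a first fit (colony-dominated
   cells) are dropped and the surface refitted. Dividing by the surface
   removes low-order illumination essentially exactly (< 0.5% residual for a
   5% polynomial flat-field) without denting colony contrast, which plain
   large-kernel smoothing does.
2. **Edge detection.** Sobel gradient magnitude, thresholded by Otsu's
   method on the gradient image, floored at median + 5 MAD so a featureless
   frame yields no regions (Otsu alone would bisect the noise
   distribution).
3. **Absorption mask.** Pixels darker than 0.8 of the corrected background
   are unioned in. This exists for one geometric reason: a colony clipped by
   the FOV border has an open edge contour, so hole-filling cannot recover
   its interior from edges alone and the region would fragment.
4. **Morphology.** Closing with a 2-µm disk, hole filling, removal of
   components below 20 µm², 8-connected labelling.
5. **Sizing refinement.** The gradient band straddles the colony rim, so
   its filled outline overestimates the diameter by roughly the edge width.
   Each region is re-measured at the intensity half-depth contour inside
   its padded bounding box (threshold midway between the region's dark
   decile and the local background median, keeping only components that
   intersect the original label). For a logistic edge the half-depth radius
   is the mid-edge radius, which is what the equivalent diameter
   $d = 2\sqrt{A/\pi}$ should measure; validated accuracy is a mean
   absolute error well under 2 HR pixels across 20–80 µm disks at default
   noise.

All thresholds are physical (µm), converted by the image's pixel pitch, so
results do not depend on the enhancement factor. Regions touching the FOV
border are flagged but counted by default — excluding them would bias
counts low on a 25 mm² chip; an `exclude` policy exists. The counted flag
applies the ≥ 20 µm reliability cutoff. Merged colonies are counted as one
region — no watershed splitting, matching how a boundary-based counter
actually behaves; merge frequency is instead surfaced by the tracker.

## Tracking and enumeration statistics

Linking is greedy nearest-centroid between consecutive timepoints
(closest pairs first, one match per track and per region, gate 15 µm —
colony centroids barely move between 20-min frames). A track left
unmatched may have been absorbed by a neighbour: merge candidates are
regions within the *sum of equivalent radii* (a merged region's centroid
can jump by up to the colony separation, so a fixed gate cannot attribute
merges). The largest-area contender keeps the region; displaced tracks
re-enter the queue until each is matched, merged (recording `merged_into`
and the merge time), or ended. This keeps the bookkeeping identity
*active tracks + cumulative merges = cumulative births* on noiseless
phantoms.

Downstream statistics follow the assay's conventions: per-timepoint count
of regions at or above the cutoff; mean and sample SD (n − 1) of
equivalent diameters; saturation time as the earliest timepoint reaching
95% of the final count; density as final count over FOV area; titer as
count × dilution / volume, with volume and dilution always explicit inputs
(the mapping from an inoculated droplet to the counted area is an
instrument calibration, not something software should assume). Per-track
radial growth rates come from least-squares regression of diameter on time
over the counted observations (slope/2); on 32-colony phantoms at default
noise the median relative error is well under 15%.

The two-assay comparison uses an exact Mann–Whitney U test:
$U = \sum_{a,b} [a > b] + \tfrac12 [a = b]$, with the two-sided p-value
computed by full enumeration of all $\binom{n_A+n_B}{n_A}$ group
assignments of the pooled values, counting assignments whose $U$ deviates
from $n_A n_B/2$ by at least the observed deviation. At the $n = 5$ group
sizes typical of assay validation the exact enumeration is instant and
sidesteps the normal approximation entirely; ties are handled exactly by
the half-count convention. An independent rank-sum enumeration oracle
reproduces both $U$ and $p$ on 200 random tied instances in the tests.

## Numerical and design choices worth knowing about

* Degenerate inputs: `z = 0` cannot be designed for (any spacing gives zero
  shift) and is rejected by `design_scan()`; empty segmentations return
  empty tibbles, not errors; an all-zero count series has an undefined
  saturation time and warns; `n = 1` size distributions report SD 0 with an
  explicit flag.
* Determinism: every stochastic stage is driven by an explicit seed; a
  pipeline run with the same configuration twice produces byte-identical
  artifacts (hashes recorded in the run manifest).
* Colonies become visible at their lag time; before it they are absent from
  the rendered scene (not drawn at seed size).
* Problem sizes used in the validation suite were chosen to keep a full
  run modest on one CPU: the count-recovery check uses the full
  2591 × 1954 sensor at enhancement 1 (counting fully grown colonies does
  not need super-resolution; the phantom uses a 200-µm hard-core
  separation so the ground-truth count is unambiguous), while
  resolution, refocusing and sizing checks use 64–160 px crops at
  enhancement 4 with the designed 8 × 8 sweep.

## Known limitations

* The forward model is incoherent and purely absorptive; coherent fringing,
  phase objects and thick-colony lensing are not simulated, so refocusing
  performance on real data will differ quantitatively.
* One global shift per frame: strong field-position dependence (very low
  source heights) would require per-tile shifts.
* The tracker assumes colonies do not move; it is not a general cell
  tracker.
* Merged colonies stay merged: counts after heavy merging underestimate
  true CFU, as they do for any boundary-based counter; the density bound
  helper quantifies the density at which this matters.
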