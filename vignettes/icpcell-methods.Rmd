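---
title: "Methods: quantifying element mass in single cells with icpcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying element mass in single cells with icpcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpcell)
```

# The measurement problem

Metal content of individual cells — for example platinum taken up from
cisplatin exposure — can be measured by two orthogonal ICP-TOFMS routes:

* **Suspension (SC-ICP-MS).** Cells are nebulised one at a time into the
  plasma. Each cell produces a sub-millisecond burst of ions recorded as a
  count spike in one dwell of a time-resolved trace (3 ms dwell, ~10 uL/min
  uptake are typical). The instrument background is Poisson counting noise.
* **Imaging (LA-ICP-TOFMS).** Cells deposited as a monolayer (cytospin) are
  rastered with a laser; each ablated spot yields a full elemental spectrum,
  giving one intensity map per isotope on a regular pixel grid (2.5 x 2.5 um
  here). A bright-field image taken before ablation drives segmentation.

`icpcell` implements both arms, their calibrations, QC and population
statistics, and a ground-truth generator used to validate the whole chain.

# Suspension arm

## Event detection

`detect_events()` separates cell events from background iteratively: compute
the mean `Av` and standard deviation `Stdv` of all currently unmarked
dwells, set a threshold

$$T = \mathrm{Av} + k \cdot \mathrm{disp},$$

mark dwells strictly above `T` as events, remove them, and repeat until an
iteration marks nothing new. Two dispersion choices are available:
`mode = "gaussian"` uses `Stdv`; `mode = "poisson"` uses
`max(Stdv, sqrt(Av))`, which never under-states the spread of a Poisson
background whose realised sample happens to be narrow — at the low count
rates of trace-metal channels the noise is Poisson, not normal.

Numerical conventions, fixed for determinism:

* ties with the threshold count as background (strict `>`), so a
  zero-variance trace yields no events;
* the iteration cap (default 100) guarantees termination; hitting it flags
  the result and warns rather than erroring;
* the background intensity used for subtraction is the mean of the
  *converged* non-event dwells of the same channel;
* runs of adjacent above-threshold dwells are merged into one event with
  summed background-subtracted intensity (`merge_adjacent = TRUE`), so a
  transient split across a dwell boundary is not double-counted.

`k = 3` is the package default, the common choice for *detecting* events.
For *quantitative population recovery* on long traces the validation suite
uses `k = 5` with `mode = "poisson"` and `merge_adjacent = FALSE`, for two
reasons. First, a 3-sigma threshold applied to tens of thousands of Poisson
background dwells admits hundreds of tail false positives whose near-zero
masses drag the population median down; a 5-sigma event criterion (standard
in single-particle ICP-MS) suppresses them by construction. Second, at a
3 ms dwell a 300-400 us transient never spans two dwells, so adjacent-dwell
merging can only fuse distinct cells that happen to arrive in neighbouring
dwells, inflating the mean. Both remain ordinary arguments; nothing in the
detector depends on the generator. Same-dwell coincidences (true doublets)
cannot be resolved by either setting and remain a known bias of suspension
analysis at high event rates.

## Mass calibration

With a liquid-standard calibration slope $b$ (counts per ug/L, OLS via
`fit_liquid_calibration()`), the mass of the element in one cell is

$$m_c = \eta \, F \, t \, \frac{I}{b},$$

where $I$ is the background-subtracted event intensity (counts), $F$ the
sample flow, $t$ the dwell time and $\eta$ the transport efficiency of the
liquid standards. Units are handled explicitly in `event_mass()`: $I/b$ is
a concentration in ug/L, $F t$ the litres of sample nebulised during one
dwell, and the product is reported in femtograms. $\eta = 1$ is the default
— the standard assumption for a full-consumption introduction system at
~10 uL/min. Cell transport efficiency (typically ~20%, estimated from bead
standards by `transport_efficiency()`) reports the *number* bias of
suspension introduction; it is not applied to masses, because each detected
cell's mass is calibrated through the liquid-standard route.

The per-event detection limit (`sc_lod()`) is three background standard
deviations pushed through the same equation.

# Imaging arm

## Geometry

`compute_pixel_pitch()` encodes the raster geometry: a square spot of edge
$s$ at dosage $d$ (shots per spot length) with line overlap $o$ gives
pixels of $s/d \times (s - o)$; the 5 um spot, dosage 2, 2.5 um overlap
configuration yields the 2.5 x 2.5 um grid used throughout. Cell size is
reported as the equivalent diameter $2\sqrt{A \, dx \, dy / \pi}$ of the
$A$-pixel footprint.

## Segmentation and transfer

`segment_cells()` works on the bright-field image (cells dark on light):
Otsu threshold on the inverted image, hole filling, connected components,
and an optional distance-transform watershed for touching cells (EBImage
primitives). Each segment is scored by equivalent diameter, circularity
$4\pi A / P^2$ (clamped to 1 — discrete perimeters make compact shapes
overshoot) and convexity, computed as solidity on the pixel grid: pixel
area over the pixel count of the rasterised convex hull, so a discrete disc
scores exactly 1. Default filters are diameter 8-30 um (monocytes and
macrophages run ~15-20 um), circularity >= 0.4, convexity >= 0.85; the
proprietary software used for the original measurements does not publish
its cutoffs, so these are explicit, configurable defaults. Rejected
segments are returned with a fail reason instead of being dropped, keeping
the exclusion of debris, doublets and clusters auditable.

Registration (`register_brightfield()`) is translation plus the isotropic
scale implied by the two pixel sizes — cytospin slides are scanned in a
fixed orientation, so rotation is out of the default model. Both frames
are binarised (Otsu), the bright-field mask is resampled to the map pitch,
and the translation maximising the FFT cross-correlation is taken; the
reported score is the Dice overlap after alignment. Coordinates are
0-based, row-major pixel centres; `transfer_and_integrate()` maps each
bright-field pixel centre into its containing map pixel, de-duplicates,
and sums each channel over the footprint. Segments reaching outside the
map are clipped and flagged `edge_touching`.

## Droplet calibration and LOD

Microdroplet standards (gelatin droplets of ~400 pL spiked with known
element amounts, fully ablated) give a line of summed intensity against
absolute amount (fg); `droplet_amount_fg()` converts concentration x
volume. Per-cell mass is the background-subtracted summed intensity over
the segment divided by the slope, floored at zero. The calibration is
fitted with a free intercept, but quantification uses the slope only: the
instrument background is a per-pixel quantity, so it is subtracted per
pixel (mean of cell-free pixels, `background_pixels()`) before summation
rather than as a per-cell intercept — this keeps blank segments at zero
mass regardless of footprint size.

The per-cell detection limit (`la_lod()`) follows the Longerich
formulation: $3\sigma$ of cell-free background pixels divided by the
per-pixel sensitivity, times the mean pixel footprint of a cell. Because
summed intensities are additive in the contained amount, a slope fitted on
droplet *sums* is already the per-pixel sensitivity — a pixel holding $m$
fg reads $b\,m$ counts regardless of how many pixels its droplet spanned.
The `droplet_pixels` rescaling argument exists only for calibrations whose
response is the *mean per-pixel* droplet intensity.

# QC and population statistics

Dead cells carry a high Rh-intercalator sum. `flag_dead_cells()` offers
three thresholds: 1-D Otsu on the log scale (Rh sums span decades; maximal
between-class variance plateaus across the empty gap between modes, so the
plateau midpoint is taken), `median + 5 * mad` (robust when few or no
cells are stained; a constant channel flags nothing), and a fixed value.
Otsu is the method of choice for a clear live/dead split but always
bisects the sample, so the image pipeline defaults to `mad` for unlabelled
populations.

`population_summary()` reports n, mean, median and the 25-75 percentile
band using linear interpolation between order statistics
(`stats::quantile()` type 7) — percentile ranges depend on the convention,
so it is fixed and documented. `welch_test()` wraps
`stats::t.test(var.equal = FALSE)` (Welch statistic, Welch-Satterthwaite
df); dead, morphology-failing and edge-touching cells are excluded before
summaries by default, with `include_flagged` to keep them.
`normalize_by_size()` removes the trivial size dependence of per-cell
content, per diameter (fg/um, default) or per spherical volume (fg/um^3) —
the appropriate choice depends on whether uptake scales with membrane or
cytoplasm, so both are explicit and unit-labelled.

# The synthetic generator

`simulate_trace()` draws Poisson background per dwell, introduces cells as
a Poisson process thinned by the transport efficiency, assigns lognormal
masses, and adds Poisson-distributed event counts obtained by inverting the
mass equation. `simulate_image()` renders non-overlapping discs (cytospun
cells are near circular; an optional boundary-perturbation mode stresses
segmentation) that are dark in the bright-field, carry uniform endogenous
31P/23Na signal, a total 195Pt signal proportional to the true mass, Rh
only on dead-flagged cells, and Poisson pixel noise.
`simulate_droplet_array()` produces calibration sums with multiplicative
noise. All generators are deterministic under a fixed seed and restore the
caller's RNG state.

Default conditions echo the instrument settings above: 3 ms dwell,
10 uL/min flow, 2.5 um pitch, diameters normal around 15 um, lognormal
masses around 2 fg (four-population comparisons use medians ~0.8 / 1.8 /
2.8 / 8 fg — fixture choices in the reported range, not claims about
biology).

What the generator deliberately does *not* model: aerosol/plasma transport
physics, size-dependent transport efficiency, subcellular structure,
flat-field or drift artefacts of real ablation, and chamber-slide cell
contours beyond the boundary-perturbation mode. Passing the closed-loop
tests therefore demonstrates correctness of the algorithms under the
stated statistical model, not instrument-level accuracy on real samples.

# Validation study sizes

The test suite and `scripts/acceptance.R` run, on one CPU in a few
minutes: detector/brute-force equivalence on 200 spiked 1000-dwell traces;
suspension recovery on ~500 events (50 s at 10 events/s, median 2 fg,
geometric SD 1.6); imaging recovery on 400 cells in a 1200 x 1200 px frame
(3 x 3 mm at 2.5 um) with droplet calibration at 1% noise, including exact
segment counting and <1% mass-conservation bookkeeping; cross-arm
agreement (~500 + ~300 cells) checked by median difference and a Welch
test; Welch size under the null over 2000 simulated pairs; and
calibration-slope recovery at zero and 1% noise. These sizes were chosen
as the smallest that make the 10% / 1% / 3% recovery checks statistically
meaningful.

# Known limitations

* Suspension doublets sharing one dwell are indistinguishable from a
  single large cell; the coincidence warning in `simulate_trace()` flags
  the regime, mirroring the acquisition-side caveat.
* Registration recovers integer map-pixel translations (adequate because
  the criterion is half a pixel); no rotation or shear.
* Watershed splitting of genuinely merged cells depends on the distance
  map and is best-effort; rejected-segment reasons make the failures
  visible.
* Equivalent diameter assumes the pixel footprint is a filled section of
  a sphere-like cell; flattened or irregular cells bias per-volume
  normalisation.
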