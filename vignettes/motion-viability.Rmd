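---
title: "Label-free viability from membrane motion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free viability from membrane motion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellmotion)
```

## The measurement problem

Primary leukemia blasts in a collagen/stroma co-culture cannot be assayed
repeatedly with dye-based viability readouts: the dyes are toxic, interfere
with drug metabolism, and destroy the kinetic information a time-lapse
provides. `wellmotion` implements a label-free alternative. Non-adherent
blasts imaged in bright field/phase contrast at low magnification render as
bright discs outlined by a dark membrane ring. A live cell's membrane
wobbles on the half-hour timescale while the collagen matrix keeps its
position essentially fixed; a dead cell is completely still. Motion of the
membrane is therefore a direct, reagent-free proxy for viability.

## The motion statistic

For every well the pipeline computes, per frame $t$ (0-based, frames every
30 min by default):

1. **Registration.** Translational drift is estimated by Fourier
   cross-correlation with local upsampled-DFT refinement and removed, so
   that stage drift and vibration are not mistaken for membrane motion.
2. **Background subtraction.** A grayscale morphological opening with a
   disc (radius 50 px at the reference 5x scale, i.e. well above a cell
   diameter) estimates the smooth illumination envelope, which is
   subtracted; cells become bright objects on a dark background. By
   default one envelope is computed for the whole registered stack, from
   the opening of the temporal median frame: a per-frame envelope would
   follow the dark membrane rings as they move and leak background
   fluctuation into the motion signal (`background_mode = "frame"`
   restores per-frame estimation, which instead tracks slow illumination
   drift).
3. **Running maximum projection.** The per-pixel maximum over the trailing
   window of $W = 6$ frames (3 h). Everywhere a bright membrane passed
   during the window stays bright in the projection.
4. **Difference.** The current frame is subtracted from the projection and
   clipped at zero. Static structure cancels exactly; moving membranes
   leave bright rings.
5. **Rings to spots.** A Gaussian blur (sigma = half the cell radius)
   merges the rings, a threshold binarizes them, and holes are filled so
   each moving cell becomes one solid spot.
6. **Area.** The viability signal is the total spot area in pixels —
   deliberately an area, not an object count, so partially overlapping and
   clumped cells still contribute proportionally.

The first defined value falls at frame index $W$ (3 h), the first frame
with a complete trailing window.

### Thresholding

The binarization threshold is
$\max(k_{abs},\; k_{rel} \cdot q_{99.9})$, with $k_{rel} = 0.25$ of the
99.9th percentile of the blurred difference image and an absolute floor
$k_{abs}$ estimated from an 8-px border strip of the same blurred images
(median + 5 MAD, pooled over frames). The relative term makes the mask
invariant to global intensity rescaling (verified to within 5% for gains
between 0.5x and 10x); the absolute floor keeps empty and all-dead wells
at zero instead of amplifying noise. A robust location/scale estimate is
used for the floor because the border strip is only *mostly* cell-free: a
motile stromal cell occasionally crosses it, and a quantile-based floor
would inherit that signal.

Within `viability_trace()` the relative term is evaluated once per well,
on the baseline window (the first three defined frames), and the
resulting threshold is held fixed for the whole movie. Re-evaluating it
frame by frame would progressively relax the cut as cells die — the
percentile tracks the shrinking signal — and inflate late-frame live area
exactly in the strongly responding wells where accuracy matters most.
The single-image operation `rings_to_spots()` retains the per-image rule.

### Registration regularization

Chain-mode registration (each frame against its predecessor, steps
accumulated) is the default because well content changes slowly over a
four-day acquisition. Membrane wobble, however, leaks a small random
component (typically under 0.1 px, occasionally several tenths) into every
pairwise estimate. Integrated naively over 192 frames this random walk
blurs a perfectly drift-free stack and corrupts the 3-h baseline. Three
regularizations address this, all exposed in `acq_config()`:

* the per-step series is filtered with a running median (window 5):
  genuine drift is smooth, misestimates are isolated;
* steps below `reg_deadband` (0.3 px) are zeroed;
* cumulative shifts within 0.2 px of an integer are snapped, so drift-free
  wells are never resampled (bilinear interpolation attenuates exactly the
  1-px crescents the signal is built from).

A constant drift of 0.5 px/frame — the scale the deadband must not mask —
is recovered to within a few percent, while a drift-free live well gets an
identically zero shift table.

## Normalization and quality control

Raw area is normalized twice. First to the same well's value at frame $W$
(defined as 100% viability), absorbing the considerable well-to-well
variation in how many cells are actually in the field; a well whose
baseline is zero, below the noise floor, or under 5% of the median
vehicle-control baseline is flagged `static_start` and excluded. Second to
the mean of the vehicle-control wells of the same sample at the same time
point, removing drug-independent death or proliferation. By construction
the mean of the normalized controls is exactly 100% at every time point —
a property the test suite checks at machine precision.

Assay validity is judged on the control curve at 60 h: mean control
baseline viability at or above 60% is valid, at or below 50% invalid, and
the open interval is conditionally valid only if an appropriate
dose-response pattern is observed. That pattern check is operationalized
(the choice is ours; the criterion is qualitative in standard practice) as:
among drugs with endpoint top-dose viability below 75%, at least half must
show endpoint viability non-increasing in dose with Spearman rho <= -0.8
across the five doses. Positive-control wells (a sensitive cell line at the
top dose) are traced and normalized like treatment wells but never enter
dose-response fitting; endpoint viability below 50% marks the drug
active/stable, and a failure annotates rather than invalidates the plate.

## Dose-response summaries

Per (sample, drug), replicate traces are averaged into a
concentration-by-time viability surface. Two summaries are computed:

* **LD50** at the evaluation time (default: last frame): linear
  interpolation in log10 dose between the doses bracketing the 50%
  crossing. Five doses in a 1:5 geometric series and duplicate wells do
  not support a four-parameter logistic fit, so none is attempted. If
  viability at the top dose exceeds 50% the LD50 is censored at twice the
  top dose (the screen's standard encoding, which censored values also
  carry into downstream correlations); below 50% at the lowest dose it is
  reported at the lowest dose with a `below_range` flag rather than
  extrapolated; multiple crossings use the lowest-dose crossing and flag
  the curve non-monotone.
* **AUC** in [0, 1]: per dose, the trapezoidal time-integral of
  viability/100 normalized by the integrated duration, then averaged over
  doses. The integration order (time within dose, then dose average) is a
  package decision — bounded, interpretable and comparable across runs of
  different lengths — and is stated here because conventions differ.

## The synthetic-data generator

`simulate_well()` renders the phenomenology the pipeline must detect or
resist, with per-cell ground truth: bright-disc/dark-ring blasts; live
membranes wobbling as fresh low-order Fourier boundary modes each frame
(modes $k = 2..4$ only — mode 1 would translate the whole cell, but the
matrix pins positions and only membranes move); death as instantaneous
freezing of the boundary, with exponential death times whose hazard follows
a Hill function of dose; sparse large elongated stromal cells random-walking
through the scene and dragging any blast inside their dilated elliptical
footprint (every contact logged); linear stage drift; an illumination gradient; Gaussian sensor
noise. A seed fully determines the stack.

Default study conditions, chosen once:

* Reduced geometry 256x256 px, 48 frames at 30 min (the full 2,048x1,536,
  192-frame scale is available through the same config). All simulator
  tests state their scene sizes; plates for recovery experiments use
  192x192 with 60 blasts/well so a ten-seed experiment stays inside a
  desktop compute budget.
* 100 blasts and 2 stromal cells per default scene — the reference
  co-culture seeds 100 stromal cells against 4,000 blasts per well, a 1:40
  ratio.
* Membrane jitter amplitude 1 px/frame. The true amplitude at this
  magnification is not established; this value makes live/dead separation
  neither trivial nor marginal, and is documented as synthetic.
* Ring depth 0.25 against background 0.35. Markedly darker rings would
  drag the morphological background envelope along with every membrane
  fluctuation — an artifact bright-field data does not show.
* Kill model: hazard $h(c) = h_{max} c / (c + c_{50})$ per hour with
  $h_{max} = 2\ln 2 / 20.5$, so a cell at $c_{50}$ has even odds of dying
  across the 20.5 h between the default scene's baseline frame (3 h) and
  its endpoint (23.5 h); the measured 50% crossing then sits at $c_{50}$
  by construction. Detection trails death by up to one window length
  (3 h), because a cell is only classified dead once it has been still for
  a full window; the calibration above accounts for the symmetric lag at
  baseline and endpoint.

What the generator does **not** emulate: optics (point-spread function,
phase halo), morphological death transitions (blebbing, fragmentation),
cell division, focus drift, and non-rigid deformation of the field. Tests
passing on these scenes therefore demonstrate the pipeline's arithmetic
and its robustness to the modelled confounders — dead cells, drift,
stromal motion, illumination and gain changes — not performance on real
microscopy, which additionally depends on focus quality and optical
artifacts.

## Numerical choices and degenerate inputs

* Motion differences are clipped at zero (bright-in-projection semantics);
  signed or absolute differences would double-count appearing vs
  disappearing intensity.
* The trailing window means values exist only from frame $W$; death within
  the first 3 h is invisible by construction (the well simply baselines
  lower), which is also why wells starting mostly dead must be caught by
  the `static_start` flag, not the curve.
* A constant (zero-variance) frame yields shift (0, 0) with a flag; a
  control mean of zero leaves the normalized value undefined (`NA`) and
  flagged rather than infinite.
* Exact 50% viability at a tested dose returns that dose, uncensored.
* Ties and boundaries in QC resolve permissively at the top (>= 60 valid)
  and conservatively at the bottom (<= 50 invalid).
* Overcrowded scenes (over 60% of the frame requested as cell area) and
  unplaceable non-overlap constraints raise errors instead of silently
  overlapping cells.

## Worked example

```{r example, eval = FALSE}
library(wellmotion)
library(dplyr)

# a 12-well plate: 2 vehicle wells + 5 doses (1:5 from 8 nM) in duplicate
doses <- 8 * 5^(0:4)
layout <- plate_layout(tibble::tibble(
  well = c("A01", "A02", sprintf("B%02d", 1:5), sprintf("C%02d", 1:5)),
  role = c(rep("vehicle_control", 2), rep("treatment", 10)),
  drug = c(NA, NA, rep("drugX", 10)),
  concentration_nM = c(NA, NA, doses, doses),
  replicate = c(1L, 2L, rep(1L, 5), rep(2L, 5)),
  sample = "S1"))

plate <- simulate_plate(layout, scene_config(n_live = 60, width = 192,
                                             height = 192),
                        c50_true = 20, seed = 1)
cfg <- acq_config(frame_height = 192, frame_width = 192,
                  total_duration = 23.5, cell_radius = 6,
                  background_radius = 40)
res <- run_plate_analysis(plate$stacks, layout, cfg)
tidy(res)           # per-drug LD50 / AUC
tidy(res$qc)        # per-sample verdict
autoplot(res$surface)
```

## Known limitations

* Translational registration only; rotation and non-rigid motion are out
  of scope.
* No single-cell tracking or per-cell death-time calling; the readout is a
  well-level area.
* The stromal-motion confounder is mitigated experimentally (few stromal
  cells) and can be bounded with the optional `max_object_area` filter,
  but wells where blasts die very fast while stroma keep moving remain the
  hardest case — flagged by QC, not fixed.
* The AUC and the conditional-QC pattern check are explicit package
  conventions; comparing against numbers produced under other conventions
  requires matching definitions first.
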