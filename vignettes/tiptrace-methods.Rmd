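---
title: "Tracking moving specimens with tiptrace: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking moving specimens with tiptrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiptrace)
```

## The tracking model

`tiptrace` keeps a moving specimen — typically a growing root tip — centred
in the field of view of a motorized-stage microscope by a purely image-based
feedback loop. No assumption is made about the shape or brightness of the
specimen; the same loop tracks a root tip and a migrating cell cluster.

Per specimen and time point *t*:

1. **Projection.** The acquired z-stack is reduced to a 2-D maximum
   intensity projection on the tracking channel.
2. **Tracking window.** A centred square window of side
   `floor(roi_fraction × min(frame dims))` is cropped; `roi_fraction`
   defaults to 1/3. The window is centred, not tip-anchored, because the
   control loop itself keeps the specimen near the frame centre.
3. **Filter variants.** The window is used raw, mean-filtered and
   median-filtered (3×3 kernels by default; borders replicate edge values
   so that no artificial dark frame biases the correlation).
4. **Shift estimation.** Each variant of the previous window is correlated
   directly (no amplitude normalisation, mean-subtracted) against the
   matching variant of the current frame, and the correlation maximum gives
   a lateral shift Δ in pixels. The previous window acts as a *template*
   searched within the full current frame: this keeps the template fully
   overlapped for any displacement up to the window size. With two
   equal-size crops instead, a displacement of *d* pixels leaves only
   `(side − d)` rows of genuine overlap, and for fast specimens (a 300 µm/h
   root at 30-min intervals moves 150 µm, ~70 % of a 213 µm window) the
   overlap-area taper of the zero-padded correlation buries the true peak
   under partial self-matches of the cell-wall lattice. Template search is
   what makes the "window = maximum per-interval displacement" rule hold.
5. **Median fusion.** The component-wise median of the three variant shifts
   is the estimate. A single outlying variant — e.g. a raw-image peak
   hijacked by impulse noise — is discarded; this is the robustness
   mechanism, not an average.
6. **Displacement update and prediction.**
   δ(t) = δ(t−1) + Δ·s (pixel size s, µm/px), and the next position list is
   P(t+1) = P(t) + δ(t). Because every frame is acquired *after* the stage
   applied the previous prediction, Δ is the residual prediction error, and
   the recurrence makes δ(t) exactly the specimen's measured motion during
   (t−1, t] — a constant-velocity predictor with correction. δ(0) = 0, so
   the first interval is uncompensated by design.
7. **Safety limit.** If the per-step move norm ‖δ‖ exceeds `max_step_um`
   (inclusive comparison), that specimen is stopped — keeping a lost track
   from driving the stage into the objective — while the others continue. A
   window with zero intensity variance likewise stops the specimen
   (`zero_variance`) rather than guessing a shift. The limit is per-step,
   not cumulative: a healthy specimen legitimately accumulates millimetres
   over a session.

### Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `roi_fraction` | 1/3 | — | tracking-window side as a fraction of the frame; 1/3 of a 20x field (1400 px × 0.457 µm/px) is ≈213 µm, which bounds the per-interval displacement the tracker accepts |
| `mean_kernel_px`, `median_kernel_px` | 3 | px | filter variant kernels; sizes are a configuration choice, not dictated by the method |
| `max_step_um` | 200 | µm | per-step stage-move safety limit |
| `subpixel` | off | — | parabolic refinement of the correlation peak; prediction does not need it, and stages are typically commanded in integer-ish steps anyway |
| `axis_map` | identity | — | sign/swap between image axes (col → x, row-down → y) and stage axes; hardware-dependent, so explicit configuration |

Interval choice follows from geometry: the specimen must stay within the
tracking window between acquisitions, so `speed × interval` must not exceed
the window size — for 300 µm/h in a 213 µm window, intervals of at most
30 min.

## Growth kinetics

Rates are derived from the recorded position history. For a closed-loop
track log the per-record displacement δ(t) *is* the measured motion during
(t−1, t], so the rate for that interval is ‖δ(t)‖ divided by the interval,
stamped at the interval midpoint. This attributes each rate to the interval
it measures; computing chords between recorded stage positions instead
would shift every rate one interval late (the stage applies δ(t) only on
the *next* move), which mislabels one interval at every light transition
and visibly biases phase-resolved means. For plain position histories
without displacement columns, chord length over elapsed time is used.
Records after a specimen stopped are excluded. Light annotation uses the
schedule state at the interval midpoint on half-open [start, end)
intervals.

The tip angle is measured from the gravity axis (+y, image-down), clockwise
positive, in (−180°, 180°]; 0° grows straight down. This matches the
rotation module's convention, under which a +90° (clockwise) chamber
rotation takes a straight-down root to −90° — the angle conventions of the
two modules are deliberately coupled and tested together.

## Rotation of the sample chamber

Gravistimulation rotates the chamber by θ about a mechanical centre **C**
calibrated once by imaging a small drilled hole on the rotation axis
(intensity centroid after Otsu thresholding and connected-component
labelling; exactly one disk-like component is required). Positions are
remapped as P′ = C + R(θ)(P − C). Positive θ is clockwise in the displayed
image; with row-down image axes this is the mathematically positive
rotation in (x, y-down) coordinates. The transform is an exact isometry
(tested to 1e−9), so tips that were centred before the rotation are centred
after it; mechanical imperfection of a real stage is emulated in the
simulator by a Gaussian perturbation of the true rotation axis (σ = 5 µm by
default in those tests), after which the tracker's next cycles absorb the
few-µm residual.

## The synthetic scene

The simulated microscope exists so that every closed-loop claim is testable
without hardware, against known ground truth.

The **root world** is a continuous-coordinate model: a tube of radius
~50 µm whose apex advances along the integral of a piecewise-constant speed
profile (day/night modulation is a profile with two alternating speeds).
The visible tip region — apex cap plus meristematic cell files — translates
rigidly with the tip, as the meristem of a real root does. Appearance
follows a plasma-membrane marker: bright cell walls on a near-background
interior. Realism details that turned out to be *load-bearing* for the
correlator, and are therefore worth stating:

* **Aperiodic cell lengths** (seeded, ±40 % around `cell_length_um` = 20 µm):
  a perfectly periodic lattice makes large shifts ambiguous.
* **Several parallel cell files** (`cell_width_um` ≈ 18 µm) with staggered
  cross-walls and per-cell wall-segment and interior brightness variation:
  uniform axis-parallel lines carry no information about motion along the
  axis (the aperture problem).
* **A tapered apex** (rounded elliptic profile over ~2.5 radii): near the
  tip, walls converge obliquely and constrain the axial lag. The tracking
  window is tip-centred, so this is most of what the correlator sees.
* **Synchronized divisions**: every cell inserts a midpoint wall each
  `division_period_h`; after k rounds every pair of adjacent
  first-generation walls brackets 2^k − 1 new walls, giving an exact
  bookkeeping oracle.

The **cluster world** (a prechordal-plate-like blob of overlapping
soft-edged disks jittering about a moving centroid path) checks that
nothing in the tracker is root-specific.

Rendering evaluates the world on the pixel grid of a stage-centred window;
z-plane *i* is blurred with σ = `psf_sigma_px`·i (defocus growing linearly
with depth — simple, and sufficient because tracking uses the MIP), then
Gaussian read noise and salt-and-pepper pixels are applied and intensities
quantized to 16 bits. All randomness derives from the world seed plus the
render arguments, so identical calls are bit-identical, and the stage
repositioning error of the simulated microscope is an independent seeded
stream.

What the synthetic scenes do *not* emulate: optically realistic PSFs,
depth-dependent scattering, elongation-zone cell stretching (tissue moves
rigidly), root waving/circumnutation, neighbouring roots crossing the
window, or photobleaching. Passing the closed-loop tests therefore
demonstrates correctness of the control loop and estimator under the stated
image model, not performance on every real-world pathology.

## Numerical choices

* Correlation is computed with zero-padded FFTs over all integer lags;
  surfaces match direct summation to 1e−6 relative tolerance (tested).
  Images are mean-subtracted first; there is no amplitude normalisation.
* Peak ties are broken toward the smaller shift magnitude, then toward
  non-negative dx, then dy — relevant only for pathological flat surfaces.
* Template/search size differences must be even so centre-aligned lags stay
  integer; the session crops the search window accordingly.
* Subpixel refinement fits a parabola through the peak and its axial
  neighbours, clamped to ±0.5 px, and is skipped at the lag-range boundary.
* Filters use edge replication; the C++ implementations are exact
  (`nth_element` median), not histogram approximations.
* CSV round trips print doubles with `%.17g`, which reproduces IEEE doubles
  exactly.
* TIFF I/O is 16-bit, page order position→channel→z (time→channel→z for
  per-position hyperstacks), with acquisition metadata in a JSON sidecar —
  baseline TIFF has no portable hyperstack tags.

## Problem sizes used in the tests

Unit tests run on 48–320 px frames. The full closed-loop characterisation
(two roots programmed at 250/50 µm/h over 24 h at 20-min intervals) uses
640×640 px frames at 1 µm/px with 3 z planes — a 640 µm field of view
matching the 20x geometry at reduced sampling, chosen so the whole suite
runs comfortably on a laptop-class machine while keeping the 213 µm window
and ≥80 px per-interval displacements fully representative. Recovered
phase means land within a few tenths of a µm/h of the programmed speeds;
the residual quantization error of integer-pixel shifts averages out over a
phase (bounded per interval by pixel_size/interval).

## Known limitations

* Tracking is lateral only; z is passed through unchanged. (Correlating
  orthogonal projections would extend the same machinery to 3-D, but the
  specimens stay in the coverslip–agar plane.)
* The predictor is zero-order (constant velocity). Kalman or autoregressive
  prediction would smooth the first interval after abrupt speed changes but
  adds nothing at realistic root accelerations.
* The first interval of a session is always uncompensated (δ(0) = 0); for
  specimens near the window-size speed limit this makes the first
  measurement the hardest one — the template search exists for exactly that
  case.
* A specimen stopped by the safety limit stays stopped; there is no
  automatic re-acquisition of lost tracks.
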