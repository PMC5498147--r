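# tiptrace

Closed-loop tracking of autonomously moving microscopy specimens — growing
*Arabidopsis* root tips, migrating cell clusters — on a motorized stage,
with growth-kinetics analysis and a built-in simulated microscope.

## The problem

An *Arabidopsis* primary root tip can grow at up to 300 µm/h, crossing the
field of view of a 20x objective within one or two hours. Long-term
time-lapse imaging of many roots in parallel therefore requires the stage
position of every specimen to be updated between acquisitions. `tiptrace`
implements the image-based feedback loop that makes this possible, plus the
downstream analyses (growth rates, day/night annotation, tip angle,
side-intensity ratios) and the coordinate transform needed to re-find all
specimens after the sample chamber is rotated for gravistimulation.

## The method

At each time point *t*, for each tracked specimen:

1. A **maximum intensity projection** (MIP) of the acquired z-stack is
   computed.
2. A centred **tracking window** — by default ⅓ of the field of view — is
   cropped from the projection.
3. The window is compared to the previous time point three ways: raw,
   **mean-filtered** and **median-filtered** (3×3 each by default). Each
   pair yields a lateral shift **Δ** (pixels) as the maximum of the direct
   cross-correlation of the mean-subtracted images, the previous window
   acting as a template searched within the current frame.
4. The **component-wise median of the three shifts** is taken, making the
   estimate robust to a single outlying variant.
5. The cumulative displacement is updated, **δ(t) = δ(t−1) + Δ·s** (with
   *s* the pixel size in µm/px), and the next position list is predicted as
   **P(t+1) = P(t) + δ(t)**. Because each frame is acquired after the stage
   already applied the previous prediction, Δ is the residual prediction
   error and δ converges to the specimen's per-interval motion — a
   constant-velocity predictor with correction.
6. A **safety limit** on the per-step stage move (Euclidean norm ≤
   `max_step_um`) stops tracking of any specimen whose predicted move is
   implausible, while the other specimens continue.

After a gravistimulation rotation by angle θ about the calibrated centre
**C**, every position is remapped as **P′ = C + R(θ)(P − C)** (positive θ =
clockwise in the displayed image). Growth kinetics are derived from the
recorded position history: the rate over each interval is the measured
displacement norm divided by the interval, optionally annotated with a
day/night light schedule.

Everything is exercised against a **simulated microscope**: synthetic
growing roots (tapered bright-walled tip, parallel cell files with
staggered cross-walls and synchronized division rounds) and migrating cell
clusters, rendered at any stage window and time with defocus, noise and
configurable stage repositioning error.

## Worked example

Track two simulated roots growing at 150 µm/h for eight 20-min cycles:

```r
library(tiptrace)

profile <- data.frame(start_h = 0, end_h = Inf, speed_um_per_h = 150)
worlds <- list(
  r1 = make_root_world(synthetic_root_spec(speed_profile = profile,
                                           noise_sigma = 10, seed = 1)),
  r2 = make_root_world(synthetic_root_spec(start_xy_um = c(2000, 0),
                                           speed_profile = profile,
                                           noise_sigma = 10, seed = 2)))
mic <- simulated_microscope(worlds, frame_px = c(320, 320), pixel_size = 1,
                            n_z = 2)
log <- run_session(mic, stage_positions(c("r1", "r2"), c(0, 2000), c(0, 0)),
                   tracker_config(max_step_um = 300),
                   n_timepoints = 8, interval_h = 1 / 3)
print(subset(log, specimen_id == "r1",
             select = c(time_index, y_um, dy_px, delta_y_um)),
      row.names = FALSE)
#>  time_index y_um dy_px delta_y_um
#>           0    0    NA         NA
#>           1    0    50         50
#>           2   50     0         50
#>           3  100     0         50
#>           4  150     0         50
#>           5  200     0         50
#>           6  250     0         50
#>           7  300     0         50
```

The first interval is uncompensated (δ starts at zero), so the full 50 µm
step appears as the first measured shift; from then on the prediction is
exact and the residual shift is 0 px while the stage advances 50 µm per
cycle. Growth rates recover the programmed speed:

```r
head(growth_rates(log), 3)
#>  specimen_id    time_h rate_um_per_h
#>           r1 0.1666667           150
#>           r1 0.5000000           150
#>           r1 0.8333333           150
```

A command-line interface wrapping the same functions is provided at
`inst/scripts/tiptrace.R`, with subcommands `simulate`, `track`,
`rotate-positions`, `kinetics` and `split`; every run writes a
`manifest.json` with the seed and configuration needed to reproduce it.

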