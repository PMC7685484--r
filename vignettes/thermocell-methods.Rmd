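---
title: "thermocell: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermocell: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocell)
```

`thermocell` is a software twin of a low-cost, Peltier-based stage-top
temperature controller for live-cell microscopy, together with the
single-cell image-analysis chain used to quantify how rod-shaped
bacteria respond to temperature shifts. This vignette explains the
models behind each component, the parameters that matter (with units and
defaults), the numerical choices, and what the synthetic benchmarks do
and do not demonstrate.

## Thermistor calibration

The temperature sensor is a 100-kΩ NTC thermistor. Over the working
range its resistance follows the linearized beta model

$$\frac{1}{T} = A + \frac{\ln R}{B},$$

with $T$ in Kelvin, $R$ in kΩ, $B$ (Kelvin) the beta parameter and $A$
(1/K) the intercept. `beta_from_pair()` implements the classical
two-point estimator $B = \ln(R_1/R_2) / (1/T_1 - 1/T_2)$;
`fit_thermistor()` averages it over all unordered pairs of calibration
points (6 pairs for the bundled four-point bench table) and estimates
$A$ as the mean of $1/T - \ln(R)/B$ over the points. All arithmetic is
in Kelvin: the pairwise estimator evaluated on the bench table is only
dimensionally and numerically consistent with Kelvin temperatures.

For the bundled table (274, 114, 81, 60 kΩ at 4, 22, 30, 37 °C) the
fit gives $B \approx 3942$ K and a nominal 25 °C resistance of
$\approx 100$ kΩ, matching the sensor's catalogue rating. The model is
exactly invertible (`temperature_to_resistance()`), and the round trip
is tested to $10^{-9}$ °C. Three-coefficient Steinhart–Hart fitting and
sensor self-heating are out of scope.

## Thermal plant

The heater/slide/coverslip assembly is modelled as a single thermal
compartment with first-order dynamics:

$$T_{ss}(u) = T_{amb} + g\,u, \qquad
  T(t + \Delta t) = T_{ss} + (T(t) - T_{ss})\,e^{-\Delta t/\tau},$$

where $u$ is the integer PWM command. `step_plant()` uses the exact
discrete solution, so the integration step size has no effect on
accuracy (a property tested against a brute-force Euler oracle).

Defaults are anchored to two observed facts about the device: the PWM
cap of 50 heats a 25 °C ambient to a stable 89 °C, fixing the gain
$g = (89-25)/50 = 1.28$ °C per PWM unit, and passive cooling relaxes
with $\tau = 1.9$ min. A single compartment is defensible because the
device's recorded transitions are well fit by single exponentials.
Heating and cooling symmetry is an assumption of the linear plant — the
open-loop heating constant is not separately observable in the
published traces. Sensor readings add Gaussian noise
(`sensor_noise_sd`, default 0.05 °C) and can optionally be
round-tripped through the calibrated resistance relation to exercise
the ADC path. Process noise is available but defaults to zero. The
device self-heats only: there is no heatsink and no sub-ambient
capability.

## PID controller

The control loop mirrors a microcontroller implementation: every 500 ms
the sensor is read, the error $e = T_{set} - T_{meas}$ is formed, and an
integer PWM command in $[0, 50]$ (out of a hardware-possible 255) is
issued. The control law is PID with three implementation details that
matter:

* **Measurement filtering.** The reading is first passed through a
  first-order low-pass with `filter_s` = 10 s, the software analogue of
  firmware ADC averaging. Beyond noise rejection this is load-bearing
  for the loop shape: with a first-order plant and any
  linear-time-invariant controller, a single-pole closed loop cannot
  simultaneously show a ~0.6-min fitted heating constant on a 7 °C
  upshift *and* pull a 20 °C step into a ±0.3 °C band within 2 min
  (the band entry of a first-order response takes
  $\tau \ln(\Delta T/0.3) \approx 4.2\,\tau$). The filter pole shapes
  the loop toward a near-critically-damped second-order response, which
  satisfies both observed behaviours.
* **Anti-windup.** Conditional integration: the rectangular integral is
  frozen whenever the output saturates in the direction of the error.
  Overshoot after a fully saturated ramp stays below 0.3 °C.
* **Error-feedback quantization.** The integer PWM is produced by
  carrying each rounding remainder into the next sample (a first-order
  sigma–delta quantizer). With plain rounding, one PWM unit is worth
  1.28 °C at steady state and holds develop slow quantization limit
  cycles of a few tenths of a degree; remainder carry makes the
  time-averaged drive equal the controller's continuous demand and
  removes the limit cycle. The derivative term acts on the (filtered)
  measurement, not the error, to avoid setpoint kick; with the
  measurement filter in place the tuned derivative gain is 0.

The default gains (`pid_gains()`: kp = 2.0 PWM/°C, ki = 0.019
PWM/(°C·s), kd = 0, filter 10 s) are repository-tuned constants: the
device's published firmware constants are not available, so the
defaults were calibrated once, by scripted grid search against the
device's documented closed-loop behaviour — equilibration of every
25 → 27..45 °C step into a ±0.3 °C band within 2 min, hold standard
deviation below 0.2 °C, heating constant ≈ 0.6 min on a 30 → 37 °C
upshift, overshoot below 0.5 °C — and then frozen as regression
targets.

Setpoint programs (`setpoint_program()`, `parse_program()`) cover the
published waveforms: holds, steps, staircases (e.g. 28 → 46 °C in 2 °C
/ 5 min increments) and square-wave oscillations (upshift first, e.g.
3 × 20-min cycles between 30 and 37 °C). Downshifts need no special
mode: the lower PWM clamp at 0 *is* passive cooling. `run_closed_loop()`
can start "warm" (integrator preloaded with the steady-state drive),
representing a controller that was already holding temperature when
logging began — the movie recipes use this, since the corresponding
experiments start from steady state.

## Trace analytics

`temperature_trace` objects are plain data frames
(`time_s, temp_C, setpoint_C, pwm`) matching the CSV the device logs.
Statistics follow the conventions of the device's characterization:
1-min binning (`bin_trace()`), hold statistics with a tiled 3-min
windowed standard deviation (`stability_stats()`; tiled rather than
sliding windows — the cheaper, more common convention), and
equilibration time (`equilibration_time()`) defined as the first time
after which the reading stays within a band (default ±0.3 °C, the
documented control error at the hottest targets) of the target. The
band test uses a 3-sample rolling median: at 2 Hz sampling against a
~2-min plant time constant a single out-of-band sample is a readout
spike, not a thermal excursion.

Heating and cooling constants are fitted the way the device's step
responses were analysed: the segment is normalized to $[0, 1]$ using the
pre-shift baseline (mean of the preceding 1 min) and the post-shift
plateau (mean of the final 1 min), then least-squares fitted with
$1 - e^{-t/\tau_h}$ or $e^{-t/\tau_c}$. Two refinements remove known
small-sample artefacts of this normalize-then-fit recipe:

* the plateau window of a short segment still contains residual
  relaxation, so after an initial fit the asymptote is solved from the
  window mean and the fit repeated (this makes the fitter exact on
  noise-free exponentials even for 5-τ segments);
* the 95% CI combines the regression standard error with the
  sensitivity of τ to the estimated baseline and plateau (numerically
  propagated), without which Monte-Carlo coverage of the interval is
  far below nominal.

The fits are invariant to affine transformations of the temperature
scale, and the nonlinear least squares is started from the observed 63%
crossing time.

## Synthetic time-lapse generator

The generator produces ground-truthed phase-contrast-like movies of
rod-shaped cells whose growth responds to a temperature trace.

**Growth.** Each cell elongates exponentially,
$L(t+\Delta t) = L(t)\,e^{\lambda \Delta t}$, at an instantaneous rate
$\lambda$ that relaxes first-order toward a temperature-dependent
steady-state rate. The default rate map anchors 1.4 h⁻¹ at 30 °C and
1.98 h⁻¹ at 37 °C, linearly interpolated; an Arrhenius form is not used
because only the 37 °C rate is directly documented. The 30 °C value is
a generator parameter chosen, together with the adaptation time
constants, to reproduce the documented adaptation phenomenology: on the
*first* upshift of a 30↔37 °C oscillation the population rate rises
only ~14% in 10 min (`adaptation_tau_first_min` = 24 min), whereas on
later shifts steady state is regained within 7–8 min
(`adaptation_tau_later_min` = 2.5 min). Upshift and downshift
adaptation are counted separately, so the first downshift is also slow.
Growth responds to the trace's *measured* temperature (what the device
knows); the difference from the true plate temperature is below the
sensor noise.

**Division and mechanics.** Wildtype cells divide symmetrically (±3%
noise, length conserved) when they exceed a per-cell threshold drawn
from N(5 µm, 8%). Cells descended from one founder remain collinear
and push each other apart as they elongate: the chain is re-laid out
each step with a constant 0.25-µm pole gap, preserving its center of
mass — which is what growing rod chains do on an agarose pad, and what
keeps daughters resolvable to the segmenter. Temperature-sensitive
phenotypes activate above `nonpermissive_C` (default 40 °C):
*filamentous* cells stop dividing but keep elongating (≈4-fold mean
length in 75 min at 1.1 h⁻¹), *rounding* cells divert elongation into
width until the aspect ratio approaches 1, and *shrinking* cells lose
cross-sectional area exponentially (the high-temperature
shrinkage/blebbing phenotype, rendered without explicit blebs).

**Rendering.** Cells are spherocylinders drawn dark (0.28) on a
mid-gray background (0.5) with a bright halo ring (0.62) — the phase
contrast signature — with ~1-px smoothstepped edges, cumulative stage
drift, and per-pixel Gaussian noise (default 0.02). The default pixel
size (0.11 µm) corresponds to a 40X objective with a 1.5X tube lens on
a 6.5-µm camera; frames default to 30-s intervals. Ground truth records
every cell's lineage, geometry and instantaneous rate per frame, and an
`analyzable` flag that switches off once the population covers more
than 30% of the frame (crowding-induced growth inhibition). Movies are
bit-reproducible under a seed.

What the generator does *not* emulate: optical point-spread detail,
uneven illumination, focus drift, cell curvature and buckling,
agarose-pad mechanics, fluorescence. Pipeline results on these movies
demonstrate internal consistency of segmentation, tracking and rate
estimation under known ground truth — not performance on real
micrographs.

## Quantification pipeline

`quantify_stack()` chains the stages; each is exported separately.

* **Registration** (`register_stack()`): integer-pixel FFT
  cross-correlation against a template frame refreshed every 10 frames.
  A fixed first-frame template decorrelates as cells grow and divide;
  the keyframe chain keeps the correlation sharp while accumulating
  absolute drift. Exact for rigid scenes; on growing colonies the
  accumulated error stays well under a pixel per frame.
* **Segmentation** (`segment_frame()`): background-relative contrast
  (cells are dark), Gaussian smoothing (σ = 1 px), Otsu threshold with
  an absolute contrast floor of 0.08 (prevents segmenting shot noise on
  blank frames), morphological opening, hole filling, and distance-map
  watershed with a 2-px tolerance — deep enough never to split a
  flat-ridged rod, shallow enough to separate side-by-side contacts.
  This classical segmenter replaces the neural-network segmentation
  used with real micrographs; against ground-truthed synthetic frames
  it reaches IoU ≥ 0.9 per cell and ±5% label counts, which is the
  contract the downstream stages need.
* **Geometry** (`extract_contour()`, `centerline_and_dims()`): closed
  0.5-level contours of the Gaussian-smoothed label support give
  subpixel boundaries; the centerline is the smoothed midline between
  the two contour flanks in the principal-axis frame, extended to the
  poles by the axial extent beyond the flank region (for a
  spherocylinder, exactly the cap radius). Length is the centerline arc
  length; width is twice the median flank half-distance over the
  central 60%. Round objects degenerate gracefully to
  length ≈ width ≈ diameter, which is how the rounding phenotype is
  flagged. Coordinates are R-native 1-based (row, column).
* **Tracking** (`track_cells()`): maximal mask overlap between
  consecutive frames (≥30% of the region's area), falling back to
  nearest centroid within a 10-px gate (30-s frames; cells are
  sessile). One-to-two assignments end the mother track and open two
  daughter tracks — a division event; many-to-many assignments
  terminate tracks as ambiguous rather than guessing.
* **Rates** (`growth_rates()`): $\lambda = d\,\ln L/dt$ by central
  differences on a 5-frame (2.5-min) moving average of log length —
  linear smoothing is exact for exponential growth, and the window is a
  package default since no canonical value exists. Tracks end at
  divisions, so no sample spans one; frame-to-frame length ratios
  outside $[0.8, 1.3]$ are masked as segmentation glitches.
  `bin_population()` and `count_divisions()` produce the
  population-mean curve (±sd, n per bin) and the 5-min division
  histogram.

End-to-end on the standard benchmark movie (100 cells, 70 simulated
minutes at a held 37 °C, ~700 cells at the end), the pipeline recovers
the population mean rate within ~1% of the generator's truth and ≥90%
of ground-truth divisions within one frame.

## Reproducibility and problem sizes

Every stochastic entry point takes an explicit seed (the command layer
refuses to run without one) and writes a provenance record. The test
suite and the acceptance script use fixed problem sizes chosen to
exercise the published protocols at full temporal resolution: 0.5-s
control sampling throughout, a full 24-h hold (172,800 steps), the
3-cycle oscillation, a 70-min 100-cell maintenance movie and a 45-min
60-cell filamentation movie at 30-s frames. The movies dominate the
runtime (a few minutes each); everything else is seconds.

## Known limitations

* The plant is lumped and linear: no spatial gradients across the pad,
  no agarose melting, no multi-sensor arrays.
* Controller gains are tuned constants reproducing documented
  closed-loop behaviour, not transcribed firmware values; absolute PWM
  traces should not be compared against hardware logs.
* The segmenter assumes dark cells on a brighter background with
  modest noise; it is a stand-in for learned segmentation, not a
  general phase-contrast tool.
* Tracking assumes sessile cells and small frame-to-frame motion after
  registration; it has no appearance model and will not resolve
  crossing or motile cells.
* The 30 °C steady-state growth rate and the adaptation time constants
  are constrained only indirectly by published population responses;
  treat them as generator conventions, not measurements.
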