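# thermocell

Single-cell microbiology increasingly needs *dynamic* temperature
control: shifting cells between temperatures on the microscope while
tracking each cell's growth, division and shape. Low-cost stage-top
Peltier controllers make this practical — a thermistor at the coverslip,
a PID loop on a microcontroller, PWM drive to the heater, and a
time-lapse pipeline that turns phase-contrast movies into single-cell
growth-rate and division statistics.

`thermocell` is a software twin of that whole chain, for people who
design, tune or analyze such experiments without wanting hardware on the
bench: control engineers prototyping setpoint programs, and image-analysis
developers who need ground-truthed bacterial time-lapse data to validate a
pipeline against.

The package provides, as composable R functions:

* **Thermistor calibration** — the NTC beta model
  `1/T = A + ln(R)/B` (T in Kelvin), with the pairwise estimator
  `B = ln(R1/R2)/(1/T1 − 1/T2)` averaged over all calibration pairs,
  and exact temperature↔resistance conversion.
* **Thermal plant** — a lumped first-order model of the
  heater/slide assembly: steady state `T_amb + g·u` for PWM command
  `u ∈ [0, 50]`, exact exponential stepping with time constant τ
  (defaults: g = 1.28 °C/unit so full drive reaches 89 °C from 25 °C;
  τ = 1.9 min), plus a noisy simulated sensor.
* **Discrete PID control** — 500-ms sampling, measurement low-pass,
  conditional-integration anti-windup, error-feedback (sigma–delta)
  integer PWM quantization, one-sided clamping (PWM = 0 *is* passive
  cooling), and a setpoint-program engine for holds, steps, staircases
  and oscillations.
* **Trace analytics** — CSV trace I/O, time binning, hold-stability
  statistics, band equilibration times, and normalized exponential fits
  of heating/cooling constants `1 − exp(−t/τ_h)` / `exp(−t/τ_c)` with
  calibrated confidence intervals.
* **A synthetic time-lapse generator** — ground-truthed phase-contrast
  movies of exponentially growing, dividing rod-shaped cells whose
  instantaneous rate λ follows the temperature trace with slow
  first-shift adaptation, including temperature-sensitive phenotypes
  (filamentation, rounding, shrinkage).
* **A quantification pipeline** — drift registration, classical
  segmentation (threshold + watershed), subpixel contours, centerline
  length/width, overlap-based lineage tracking with division detection,
  growth rates as `d log L / dt`, binned population curves and
  division histograms.

## Worked example

Calibrate the bundled thermistor bench table, hold a virtual sample at
37 °C, then generate and quantify a synthetic movie:

```r
library(thermocell)

# 1. thermistor calibration (274/114/81/60 kOhm at 4/22/30/37 C)
model <- fit_thermistor(default_calibration_points())
model
#> Thermistor beta model (1/T = A + ln(R)/B)
#>   B (beta): 3941.6 K
#>   A (intercept): 0.00218498 1/K
#>   nominal R at 25 C: 100.3 kOhm
#>   calibration points: 4
```

The beta parameter lands within 0.3% of the sensor's rated 3950 K and
the implied 25 °C resistance within 0.3% of its 100-kΩ rating: the
four bench points are internally consistent with the catalogue part.

```r
# 2. closed-loop hold at 37 C for 30 min (0.5-s sampling)
trace <- run_closed_loop(plant_params(ambient_C = 25),
                         program = setpoint_program(seg_hold(37, 30)),
                         seed = 7)
stability_stats(trace, after_s = 600)[c("mean_C", "sd_C", "max_abs_error_C")]
#> $mean_C
#> [1] 37.00042
#> $sd_C
#> [1] 0.05029506
#> $max_abs_error_C
#> [1] 0.1783799
```

After equilibration the controller holds 37 °C to within ±0.05 °C
standard deviation — the readings are sensor-noise limited — with no
excursion beyond 0.18 °C in half an hour.

```r
# 3. a 3-cycle 30<->37 C oscillation, with per-transition fits
osc <- run_closed_loop(plant_params(ambient_C = 30),
                       program = parse_program("hold:30:2m,osc:30:37:10m:3"),
                       seed = 7)
fit_heating_constant(osc, 120, 720)     # first upshift
#> tau = 0.561 min (95% CI 0.5566-0.5654), rmse 0.0141, n = 1201
fit_cooling_constant(osc, 720, 1320)    # first passive cooling
#> tau = 1.9 min (95% CI 1.892-1.909), rmse 0.00719, n = 1201
```

Heating is loop-limited (τ_h ≈ 0.56 min, an emergent property of the
tuned gains); cooling is plant-limited and recovers the open-loop
τ = 1.9 min, because the controller simply switches off below setpoint.

```r
# 4. synthetic movie at 37 C and full quantification
cfg <- movie_config(trace, duration_min = 20, dim_px = c(300, 760),
                    seed = 7)
set.seed(7)
cells <- cell_population(12, growth_model(), frame_um(cfg), temp_C = 37,
                         col_spacing_um = 20, lane_spacing_um = 5)
movie <- simulate_movie(cfg, growth_model(), cells)
q <- quantify_stack(movie)
q
#> quantification: 41 frames, 34 tracks, 461 rate samples, 11 divisions
#>   population mean rate: 2.054 1/h
recovery_report(q, movie$truth, 30)[c("mean_rate_true", "division_recall")]
#> $mean_rate_true
#> [1] 2.024098
#> $division_recall
#> [1] 1
```

The pipeline re-measures this 12-cell movie's ground-truth mean rate
(2.024 h⁻¹ — a small-sample draw around the 1.98 h⁻¹ nominal rate at
37 °C) to within 1.5%, and finds every division event. `write_movie()` / `read_stack()` move movies through
multi-page TIFF plus a ground-truth CSV.

## Command-line interface

A thin dispatcher wraps the same functions:

```sh
Rscript inst/cli/thermocell.R calibrate inst/extdata/thermistor_calibration.csv
Rscript inst/cli/thermocell.R simulate-device --program "stair:28:2:5m:46" \
        --out out/stair --seed 1
Rscript inst/cli/thermocell.R simulate-movie --program "hold:37:75m" \
        --out out/movie --seed 1
Rscript inst/cli/thermocell.R quantify out/movie/stack.tiff --out out/movie \
        --truth out/movie/truth.csv
Rscript inst/cli/thermocell.R demo --out out/demo --seed 1
```

Stochastic commands require `--seed` and every run writes a
`provenance.json` (package version, seed, config hash). Configuration
is a validated YAML file (unknown keys are rejected); see
`?load_config`.

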