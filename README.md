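# pupiltrack

Simulation and analysis toolkit for **pupil-tracked lateral motion
correction in anterior segment OCT (ASOCT)**.

ASOCT needs seconds to acquire a volume, and involuntary fixational eye
movements (micro-saccades, drift, tremor) corrupt the data during that time.
A practical remedy is video-oculography: a fast camera images the dark pupil
on the bright IR-illuminated iris, a threshold/centroid algorithm reads out
the lateral eye position every frame, and a proportional correction —
gain

```
g = (Δmm/Δpix) · (Δθ/Δmm) · (volts/Δθ) · β
```

— is summed onto the OCT scanner waveforms so the scan follows the eye.
The loop's bandwidth is set almost entirely by its latency Δt: modelling the
tracker output as an inverted, delayed copy of sinusoidal subject motion,
the uncorrected residual is

```
x(t) + y(t) = −2A·sin(πfΔt)·cos(πf(2t + Δt)),
```

with envelope `2A·sin(πfΔt)`. The residual reaches 50% of the input at
`f = asin(0.25)/(πΔt)` (≈20 Hz for Δt = 4 ms) and *exceeds* the input above
`1/(6Δt)` — with enough latency, tracking amplifies motion instead of
removing it.

`pupiltrack` implements, on purely synthetic data:

* **synthetic scenes and motion** — bimodal pupil-camera frames, step /
  sinusoid / fixational (1/f-type with microsaccades) trajectories, and OCT
  M-scan volumes with speckle;
* **the tracker** — session threshold (histogram valley or Otsu), 7×7
  morphological closing, 8-connected largest component, sub-pixel centroid
  deviation;
* **the correction loop** — discrete-time proportional loop at the camera
  rate with calibrated gain, transport latency, ±2.5 mm tracking-range
  clamp and lost-pupil hold;
* **bench characterization** — step → impulse → frequency response,
  cross-correlation latency, SVP edge tracing (3×3 Gaussian → threshold →
  Sobel), motion-correction transfer functions, β optimization at 0.5 Hz;
* **the analytic latency model** — residual amplitude, half-amplitude
  frequency, latency × frequency residual surface;
* **OCT motion analytics** — summed-voxel projections, sequential B-scan
  cross-correlation traces, axial vs full registration and averaging.

## Worked example

```r
library(pupiltrack)

# analytic latency model: half-residual frequency for a 4 ms loop
half_amplitude_frequency(0.004)
#> [1] 20.10766

# one tracked frame: pupil displaced 0.5 mm right, 0.3 mm up
scene <- scene_params()                      # 320 x 256 px, 42 um pixels
frame <- generate_pupil_frame(scene, center = c(0.5, -0.3), seed = 1)
th <- select_threshold(frame)
th
#> [1] 151
track_frame(frame, th)$deviation             # pixels; truth is (11.90, -7.14)
#> [1] 11.923211 -7.125851

# closed-loop simulation: 1 mm, 10 Hz sinusoid, 500 Hz camera, 4 ms latency
traj <- generate_trajectory("sinusoid", amplitude = 1, frequency = 10,
                            duration = 1.2, rate = 1000)
sim <- simulate_closed_loop(traj, scene, gain_calibration(), loop_config(),
                            seed = 2)
ratio <- trace_amplitude(sim$corrected, 10, skip = 0.2) /
  trace_amplitude(sim$uncorrected, 10, skip = 0.2)
c(simulated = ratio, analytic = residual_amplitude(1, 10, 0.004))
#> simulated  analytic
#> 0.2506837 0.2506665
```

The tracker recovers the painted pupil center to a few hundredths of a
pixel despite sensor noise, and the simulated loop leaves a 10 Hz residual
of 25.1% of the input amplitude — within 0.01 percentage points of the
analytic `2·sin(π·10·0.004)` prediction.

Full experiments (β optimization, frequency sweeps, M-scan generation and
trace extraction, CSV/JSON outputs) are driven by `run_characterize()` with
an `experiment_config()` or YAML config; a thin command-line front end with
`simulate` / `track` / `characterize` / `latency-model` / `mscan`
subcommands is installed at `inst/scripts/pupiltrack`.

## Layout

```
R/                 implementation
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R
vignettes/         methods vignette (model, assumptions, design choices)
inst/scripts/      command-line front end
```
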