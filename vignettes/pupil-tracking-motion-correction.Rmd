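---
title: "Simulating pupil-tracked motion correction for anterior segment OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pupil-tracked motion correction for anterior segment OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupiltrack)
```

## The problem

Anterior segment OCT (ASOCT) acquires volumes over seconds, during which
involuntary fixational eye movements — micro-saccades, drift, tremor —
displace the eye laterally by tens to hundreds of microns. A low-cost remedy
is video-oculography: a fast camera images the dark pupil on the bright,
IR-illuminated iris, a threshold/centroid algorithm reads out the lateral eye
position at the camera frame rate, and a proportional correction is summed
onto the OCT scanner drive waveforms so the scan follows the eye.

`pupiltrack` implements that system as software: a synthetic scene and
eye-motion generator, the segmentation/centroid tracker, a discrete-time
correction loop with calibrated gain and transport latency, the bench
pipelines used to characterize such a loop, and the closed-form
latency-residual model that explains its bandwidth. Everything runs on
synthetic data; no camera, scanner, or subject is involved.

## The tracker

Frames are modelled as a dark disk (gray level ~20) on a bright background
(~200) with additive Gaussian sensor noise, i.e. a bimodal gray-level
histogram. The per-frame pipeline is:

1. **Threshold** (`select_threshold()`): the 256-bin histogram is smoothed
   with a small Gaussian kernel (sigma 2 gray levels) and the threshold is
   placed at the valley between the two dominant modes. The threshold is
   chosen once per session, not per frame, mirroring the stability of
   IR-illuminated scenes; Otsu's criterion is available as an alternative.
2. **Binarize and close** (`binarize_and_close()`): pixels at or below the
   threshold are foreground; morphological closing with a 7 x 7 square
   kernel removes small concavities and holes (eyelash shadows, specular
   artifacts) from the pupil blob.
3. **Largest component** (`largest_component_centroid()`): 8-connected
   labelling, largest blob wins; area ties break toward the blob nearest the
   designated reference position, where the pupil is expected.
4. **Centroid deviation** (`track_frame()`): the unweighted center of mass
   of the blob, minus the reference position, in camera pixels.

Coordinates are 0-based with the origin at the top-left pixel center, x
rightward and y downward; physical displacements convert through the pixel
pitch (42 um at default scene settings, giving a 13.4 x 10.8 mm field over
320 x 256 pixels). Disk edges are rendered with area-weighted anti-aliasing
so sub-pixel centroid recovery is meaningful; on noiseless frames the
tracker recovers painted centers to well under half a pixel, and to about a
pixel RMS at a sensor noise of 10 gray levels.

A lost pupil (empty foreground, e.g. a blink or an off-frame excursion) is
reported as an invalid detection, never an exception. The loop holds the
last deviation for a configurable number of frames (`hold_max`, default 25,
i.e. 50 ms at 500 Hz) and then resets the correction to neutral — recentring
the scan is the benign failure mode when the pupil is gone for good.

## The correction loop

The proportional gain is assembled from bench calibrations,

g = (mm/pixel) x (deg/mm) x (volts/deg) x beta,

camera pixel pitch, scanner angle per millimeter, mirror volts per degree,
and a unitless tuning factor beta. The scanner constants cancel when the
voltage is converted back to object-space millimeters, so the loop's
behavior depends on the product `mm_per_pixel x beta` against the true pixel
pitch: beta compensates calibration error, and its optimum is 1 when the
calibration is exact. `simulate_closed_loop()` runs the loop tick by tick at
the camera rate (500 Hz by default):

* the scene is rendered at the current true pupil position and tracked;
* the correction target `beta * mm_per_pixel * deviation` is scheduled;
* the applied correction is the target sequence delayed by the loop latency
  `dt` (default 4 ms, everything from exposure to output lumped together),
  evaluated at each tick by linear interpolation between updates and held
  between ticks, and clamped to the +/-2.5 mm tracking range;
* the residual seen by the OCT is `x(t) - c(t)`.

The camera images the eye directly — corrections feed the OCT scanners, not
the camera path — so the measured deviation is the absolute displacement and
the loop is feedforward. (A `camera_in_loop = TRUE` variant renders frames
at the corrected position and updates incrementally, for systems whose
tracking camera looks through the corrected optics; note that in that
topology the residual at any single frequency decreases monotonically with
beta up to the stability limit at beta = 2, so gain optimization must weigh
broadband noise amplification rather than a single spectral line.)

The delayed correction waveform is interpolated between update samples
rather than quantized to whole ticks so that the loop's effective transport
delay equals the configured `dt` exactly; quantizing would add up to half a
camera period of hidden latency and bias every bandwidth figure computed
downstream.

## The latency model

With subject motion `x(t) = A sin(2 pi f t)` and tracking output
`y(t) = -A sin(2 pi f (t + dt))`, the uncorrected residual factors as

x(t) + y(t) = -2 A sin(pi f dt) cos(pi f (2 t + dt)),

an oscillation with envelope `2 A |sin(pi f dt)|` (`residual_amplitude()`).
Three consequences drive the package's predictions:

* the residual reaches half the input amplitude at
  `f = asin(0.25) / (pi dt)` (`half_amplitude_frequency()`), about 20 Hz for
  a 4 ms loop;
* above `f = 1/(6 dt)` (about 41.7 Hz at 4 ms) the residual exceeds the
  input: latency turns tracking into amplification;
* the full surface over latency and frequency is tabulated by
  `residual_surface()`.

The simulated loop reproduces this model to better than 1% across latencies
of 2-8 ms and frequencies up to 30 Hz, which is the package's primary
internal consistency check.

## Bench characterization pipelines

`step_to_frequency_response()` differentiates a recorded step response into
an impulse-response estimate and takes its DFT magnitude, normalized to
DC = 1, locating the -3 dB crossing by linear interpolation; it is validated
against closed forms (a pure transport delay gives a flat response; a
first-order lag of time constant tau rolls off at `1/(2 pi tau)`). An
optional first-order pre-fit of the raw step suppresses measurement noise
before differencing.

`estimate_latency()` reads the loop latency from the lag maximizing the
cross-correlation between the drive waveform and the negated correction
waveform, at one-sample resolution.

`extract_edge_trace()` reproduces the OCT-side measurement: a synthetic
M-scan (repeated B-scans at one lateral line) is collapsed axially into a
summed-voxel projection (SVP), smoothed with a 3 x 3 Gaussian, thresholded
(Otsu by default on the smoothed image), and Sobel edge detection locates
the imaged pupil edge per B-scan row. Rows without a detectable edge are
filled by interpolation and flagged.

`measure_correction_response()` sweeps constant-amplitude sinusoidal phantom
motion across frequencies through the simulated loop and estimates
uncorrected/corrected amplitudes as the DFT component at the drive frequency
over an integer number of periods after a 0.2 s transient — robust to
broadband tracker noise; half the peak-to-peak excursion is available as an
alternative. `correction_transfer_function()` turns the per-frequency
amplitude ratios into the motion-correction transfer function. Its roll-off
is reported where the residual ratio reaches 0.5 by default: the
half-residual point is what the latency model ties to `dt`, and is how the
measured bandwidth of such systems is quoted; the strict amplitude
-3 dB criterion (ratio 0.708) is available behind a flag and sits higher
(about 29 Hz for a 4 ms loop).

`optimize_beta()` tunes the gain factor by minimizing the residual amplitude
at a 0.5 Hz probe — deep inside the correction band, where the residual is
dominated by gain error rather than latency — using a coarse grid followed
by golden-section refinement, every evaluation reusing the same seed so the
objective is deterministic. With an exact calibration the optimum lands at
beta = 1 to within a few parts in 10^4 and leaves a residual near the
analytic floor `2 sin(pi 0.5 dt)` (about 1.3% at 4 ms).

## OCT motion analytics

`svp()` collapses an M-scan axially (rows = time, columns = lateral).
`bscan_xcorr_trace()` estimates the lateral shift between consecutive
B-scans from the argmax of the normalized cross-correlation of their
depth-summed profiles and integrates the shifts into a motion trace;
integer-sample by default (correlation ties resolve to the smallest
displacement). With `refine = TRUE`, each pair is correlated over a lightly
smoothed window (half-width 8 samples) centered on the strongest intensity
edge and maximized over a continuous lag; windowing keeps the featureless
plateaus of the profile from diluting the edge information under speckle,
and the refinement recovers sinusoidal trajectories to a few tenths of a
lateral sample RMS at speckle contrasts up to 0.3. Because the trace is a
cumulative sum it is not detrended; estimator noise largely telescopes
(each frame's apparent-position error enters consecutive shifts with
opposite signs).

`register_average()` aligns repeated B-scans to the first by integer-sample
cross-correlation shifts — axial-only (what post-hoc B-scan registration can
always do) or axial plus lateral — and averages the stack. On laterally
jittered stacks full registration yields sharper averages than axial-only
registration, the synthetic analog of why real-time tracking helps even
when frames are registered afterwards: registration from the B-scans alone
cannot see motion orthogonal to the scan.

`trace_std()` reports the sample standard deviation of a trace, the summary
used to compare tracked and untracked acquisitions.

## The synthetic data generator

`generate_pupil_frame()` renders the bimodal scene described above with
optional dark-blob artifacts. `generate_trajectory()` provides steps,
sinusoids and constants for bench-style experiments.

`generate_fixational_trajectory()` emulates fixational eye motion: a 2D
drift/tremor component synthesized in the frequency domain with power
spectral density proportional to `1/f^a` (exponent `a` in [1, 2]; default 1,
with reported values spanning 1 to 2 and most power below 10 Hz), plus
Poisson-timed microsaccades modelled as instantaneous steps (typical rates
1-2 per second; step durations of ~20 ms are below the resolution of
interest for a 500 Hz loop). The combined displacement is scaled to a target
RMS of 0.1 mm, the scale of lateral fixational excursions relevant to
anterior-segment imaging. Above `drift_bandwidth` (50 Hz) the drift spectrum
rolls off as `f^-4` in power: physiological tremor beyond a few tens of Hz
carries sub-micron amplitude, and extending the `1/f` law to the sampling
Nyquist would place drift-scale power at frequencies where no eye moves —
and where a latency-limited loop amplifies. The band limit is piecewise so
the nominal spectral slope over 0.5-50 Hz is preserved.

`generate_mscan()` builds M-scan volumes in which each B-scan images a
bright-to-dark lateral edge at `edge_position - x(t_k)`, with a smooth axial
reflectivity profile and multiplicative unit-mean log-normal speckle of
configurable contrast (0.2 by default). Defaults follow a characterization
acquisition: 1000 B-scans of 240 A-lines over 8 mm at 416.7 Hz (2.4 s,
33.3 um lateral pitch).

What the generator does *not* emulate: corneal reflections and glints, pupil
dilation, eyelids and blinks (lost frames must be injected explicitly),
realistic OCT speckle statistics and shadowing, axial eye motion. Passing
tests therefore demonstrate the algorithms' correctness and the loop's
latency behavior, not robustness to every artifact of clinical video.

## Numerical choices and scales

* Amplitude estimation uses the DFT component at the known drive frequency
  over an integer number of periods, after discarding a 0.2 s transient.
* The histogram valley search smooths with sigma = 2 gray levels and
  requires modes at least 16 gray levels apart; closer secondary peaks are
  treated as part of the main mode.
* Sweeps use analysis windows of at least two drive periods (at least 0.6 s
  at high frequency); the gain optimization probes 0.5 Hz with one period.
  These window lengths keep a full characterization run — gain optimization
  plus a nine-frequency sweep at the native 320 x 256 / 500 Hz scene — at
  about five minutes on one core, with amplitude estimates stable to well
  under a percent; the package's own test suite uses a quarter-size scene
  for loop properties where only the loop dynamics matter.
* All randomness (sensor noise, speckle, fixational motion) is seeded;
  identical seeds give bit-identical frames, volumes and simulation runs.

## Known limitations

* The tracker is centroid-based: it does not fit an ellipse, so strongly
  elliptical or half-occluded pupils bias the center estimate.
* Scanner dynamics are ideal; a real fast-steering mirror contributes its
  own (here negligible, ~560 Hz) bandwidth, and the measured step-response
  bandwidth of a physical loop is hardware-coupled in ways this simulator
  only qualitatively approximates.
* The sequential cross-correlation trace accumulates estimator bias over
  very long acquisitions; for absolute positions over long windows the SVP
  edge trace is the better instrument.
* Microsaccades are instantaneous steps; their ~20 ms dynamics and the
  saccadic suppression of drift are not modelled.
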