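---
title: "Methods: localizing the vena contracta from tracked Doppler ICE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing the vena contracta from tracked Doppler ICE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vclocate)
```

## The problem and the model

Tricuspid regurgitation leaks blood backward through a coaptation gap between
valve leaflets; in color Doppler the narrowest section of the leaking jet —
the vena contracta (VC) — marks that gap and is the target for edge-to-edge
clip positioning. A forward-looking intracardiac echo (ICE) probe carrying an
electromagnetic pose sensor lets the VC be mapped once, in tracker
coordinates, and then used as a navigation landmark.

The estimator in `locate_vc()` is a deterministic image-processing chain.
Its modelling assumptions, stage by stage:

* **Gating.** The regurgitant jet is periodic with the heart rate; the frames
  of interest are a fixed-length window at peak regurgitation in each cycle.
  The cycle period in frames is `fps * 60 / bpm`. Non-integer periods are
  handled by rounding each cycle's start index (`round(first_peak + k * P)`),
  so gating cannot drift across a clip; incomplete trailing cycles are
  dropped because a partial peak window would bias the compound.
* **Color separation.** The console renders Doppler on a warm/cool (BART)
  map over grayscale B-mode. A pixel is treated as B-mode when its channel
  spread `max(R,G,B) - min(R,G,B)` is at most `gray_tol`; spread is used
  because it is invariant to brightness, unlike a saturation ratio. Cool
  (away) flow is identified by blue dominance, `B > R`; `R >= B` pixels are
  kept. `R == B` purple edges are retained — they are ambiguous, and the
  later threshold decides.
* **Compounding.** A maximum intensity projection across the gated frames
  scores each pixel by Rec.601 luminance (`0.299 R + 0.587 G + 0.114 B`)
  and copies the full RGB triple from the argmax frame (ties to the earliest
  frame). On warm Doppler maps higher velocity renders more yellow, and
  yellow has high luminance, so luminance is a velocity proxy. A per-channel
  maximum was rejected because it can fabricate colors present in no frame.
* **Segmentation.** The grayscale compound is thresholded strictly above an
  8-bit intensity (default 150; a documented preset of 130 for small
  infant-valve flows, where velocities render dimmer). Only the largest
  8-connected island is kept; 8-connectivity is required so a one-pixel
  diagonal neck does not split the jet.
* **VC detection.** Principal component analysis of the island's pixel
  coordinates (population covariance, divisor *n*) gives the jet axis. The
  mask is mapped rigidly to axis coordinates, pixels are binned by rounded
  major-axis coordinate *u*, and the jet height is the minor extent
  `max(v) - min(v) + 1` per bin — extent, not pixel count, so interior holes
  do not fake a neck. The VC is the interior minimum of this profile; its
  width is the VCW and its minor-extent midpoint, mapped back through the
  inverse PCA transform, is the VC pixel.
* **3D geometry.** The display is an orthographic projection of the conical
  imaging surface along the probe axis, so displayed offsets from the cone
  apex are true in-plane millimetres and depth is `z = rho / tan(theta)`
  with `theta` the imaging half-angle. Conventions: image row maps to +y,
  column to +x, origin at `center_px`, right-handed z away from the probe
  face. If a console reports the full opening angle, the user must pass half
  of it. The calibration (image to sensor) and tracked pose (sensor to
  tracker) are rigid 4x4 inputs, validated to `R'R = I` and `det R = +1`
  within 1e-6.
* **Validation.** The detection error is the closest Euclidean distance to a
  ground-truth VC point model. A detection is flagged as an outlier when it
  is strictly closer to the annulus model than to the VC model; the rule is
  comparative rather than an absolute millimetre cut because it is then
  scale-free and invariant under any rigid motion of the whole scene (a
  property the tests verify). A flagged run advises re-acquisition.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold` | 150 (130 preset) | 8-bit intensity | separates high-velocity jet core from dim flow |
| `gray_tol` | 20 | 8-bit counts | channel spread below which a pixel is B-mode |
| `frames_per_cycle` | user | frames | peak window length; small (2-4) keeps the probe-still assumption |
| `interior_fraction` | 0.1 | fraction | excludes jet tips from the width search (see below) |
| `imaging_angle_deg` | input | degrees | cone half-angle from the console |
| `mm_per_px`, `center_px` | input | mm/px, px | display scaling; console-specific |

## Numerical choices and edge cases

* **Tip exclusion.** The raw height profile is always minimal at the jet
  tips, where the mask tapers, while the physical VC is the interior neck of
  the converging-diverging jet. The search therefore excludes
  `interior_fraction` (10%) of the occupied u-range at each end. The value
  is configurable; 10% removes the taper on every fixture shape we generate
  while never reaching a centrally placed neck. No smoothing is applied to
  the profile.
* **Tie-breaks.** Equal minimum heights resolve to the bin nearest the
  centroid (u = 0), then the smaller u — deterministic, and central necks
  are the physically likely ones. Equal island areas resolve to the smallest
  top-left bounding-box corner. MIP ties resolve to the earliest frame.
* **Subpixel policy.** u-bins are integers; the reported VC is the bin
  center and the minor-extent midpoint (half-integer precision). PCA axis
  signs are fixed (column component >= 0, then row >= 0) so results are
  reproducible across runs.
* **Degenerate inputs.** Masks with fewer than 2 pixels raise a degenerate
  error; isotropic masks (equal principal moments) are processed but flagged
  `degenerate`; an empty segmentation raises a *no-jet* condition and a jet
  whose interior search range is empty raises *jet-too-short* — both carry a
  `vclocate_retake` class that `run_pipeline()` converts to a
  `"retake_advised"` status rather than a hard error, because they indicate
  the acquisition (not the software) failed.
* **Pose selection.** The compound spans a few frames during which the probe
  is held still; the pose of the first selected peak frame transforms the
  result, with a config override (`pose_frame`).
* **Dispersion.** `error_stats()` reports the sample SD (divisor n - 1),
  the usual choice for small validation sets; a single retained value
  reports SD 0.

## What the synthetic generator does and does not emulate

`generate_dataset()` renders the features the algorithm consumes: a warm
hourglass jet (two opposed triangles joined at the neck — no fluid
simulation) with red-to-yellow luminance ramp peaking above the threshold,
exact neck width at a known pixel (even widths get a half-pixel axis offset
so the rasterized extent is exact), cool blue-dominant inflow blobs,
grayscale speckle, cardiac-phase pulsation (full jet at the peak frame, half
amplitude — below threshold — for two frames, absent in diastole), and
per-frame poses with bounded jitter (defaults 0.5 mm / 0.5 degrees,
a hand-held but steady probe). All randomness sits behind one seed;
identical seeds give bit-identical datasets.

It does **not** emulate realistic speckle statistics, acoustic shadowing,
leaflet anatomy, color-map aliasing, console UI overlays, or tracking
latency. Passing tests therefore demonstrate the correctness of the
geometry, filtering and detection logic under known truth — not clinical
performance on console captures. Two further cautions: the synthetic ground
truth is constructed through the same cone and transform chain the pipeline
uses, so pose jitter cancels exactly (truth and estimate share the pose of
the peak frame) and the tracker-space error reduces to the propagated 2D
detection error; and the rendered jet segments almost perfectly, so errors
here are a floor, not a forecast. A real acquisition adds calibration error,
tracking noise relative to an independently traced truth, and imperfect
color separation.

The generator also reproduces the known failure mode: `drop_frames()`
deletes frames the way a slow frame grabber misses them, shifting all later
frames earlier. Deleting the peak frame of three of five cycles breaks the
gating alignment so that no full-amplitude frame is selected, which the
pipeline reports as no-jet/retake (or, when a weak jet survives, can surface
as an annulus-proximity outlier) — the acceptance suite exercises this
fixture.

## Problem sizes

The test and evaluation runs use 200 x 200 px frames, 5-second clips at
15 fps / 60 bpm (75 frames, 5 cycles), 20 seeded datasets with neck widths
cycling 3-8 px at 0.2 mm/px, and a 30-degree imaging half-angle — enough
cycles for the MIP to matter and enough datasets to estimate the error mean
and spread stably.

## Known limitations

* Single-jet assumption: largest-island selection discards secondary jets.
* The VC is reported as a point plus a width, not an orifice contour or area.
* The annulus model is a given input; no automatic annulus detection.
* Calibration is consumed, not estimated.
* Threshold and gray tolerance are global constants per run; console color
  maps that differ strongly from a BART warm ramp would need re-tuning.
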