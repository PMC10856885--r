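---
title: "Methods: stereo tracking of a climbing plant's tip"
author: "stereonut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo tracking of a climbing plant's tip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Circumnutation — the slow, roughly circular sweep a climbing shoot performs
while searching for support — unfolds over hours, so it is recorded as
time-lapse imagery (one frame per minute, several days per experiment).
A single overhead camera gives only the (x, y) component of the motion. This
package reconstructs the full 3D trajectory of the shoot tip from a pair of
synchronized views: a zenithal camera above the plant and a lateral camera at
the side of the growth booth, roughly 90° apart. The pipeline is:
single-camera and stereo calibration from chessboard images, background
subtraction of the plant against the booth, per-frame tip localization in
each view, temporal tracking with interpolation and operator corrections,
photoperiod-based synchronization of the two cameras' clocks, and two-view
triangulation with per-frame reprojection-error auditing.

## Camera model and calibration

Each camera is a pinhole with radial (k1, k2, k3) and tangential (p1, p2)
distortion acting on normalized coordinates. Pixel coordinates have their
origin at the top-left corner, u rightward, v downward, pixel centers on
integers; world units are centimeters throughout (board squares and booth
geometry are naturally measured in cm, and the accuracy of interest is
sub-centimeter).

Single-camera calibration is the classic planar-target procedure: per-view
homographies give a closed-form estimate of the intrinsic matrix, extrinsics
follow per view, and a joint Levenberg–Marquardt refinement (via
`minpack.lm`) minimizes the total squared reprojection error over
intrinsics, distortion and all board poses. k3 stays fixed at zero unless 15
or more views are supplied: with a wide-angle lens (112° field of view) and
few boards the sixth-order radial term is poorly constrained and tends to
soak up noise, which then corrupts undistortion at the image periphery.

Stereo calibration estimates each camera's pose per simultaneously captured
board pair (fixed-intrinsics PnP), forms per-pair relative poses
(R₂ = R·R₁, t₂ = R·t₁ + t), and fuses pairs by quaternion chordal averaging
of the rotations and plain averaging of the translations. A per-pair
rotation more than 5° from the fused rotation aborts the calibration as
inconsistent. The essential matrix is E = [t]ₓR and the fundamental matrix
F = A_side⁻ᵀ E A_top⁻¹, oriented so that F·p_top is the epipolar **line in
the side view** of a top-view pixel. The rig's world frame is anchored at
the first stereo board's origin; the pot base is a reported landmark, not
the origin.

Distortion inversion (needed to normalize observed pixels before
triangulation) is a fixed-point iteration with tolerance 1e-10 and at most
50 iterations; non-convergence raises an error with the residual rather than
returning an extrapolated guess — important because a distortion polynomial
fitted from narrow board coverage can diverge outside that coverage (see
"Known limitations").

### Chessboard detection

Inner chessboard corners are intensity saddle points. The detector scores
pixels by the negated Hessian determinant of the Gaussian-blurred image
(positive at saddles, ≈0 on edges, negative at single-square corners), takes
non-maximum-suppressed peaks, and snaps them onto a projective grid: the
four extreme corners initialize a homography, all candidates are mapped to
lattice coordinates, and only a complete cols × rows cover is accepted — a
partial grid yields no observation rather than a truncated one. Two
ambiguities are resolved deterministically: mirror interpretations are
rejected by the orientation sign of the grid-to-image homography (facing the
front of a right-handed board, the mapping reverses orientation because
image v runs downward), and the 180° rotation is resolved by sampling the
checker color of the square diagonally up-left of the origin corner (black
by convention). Corners are refined to sub-pixel accuracy by iterated Newton
steps on a local quadratic fit of the blurred intensity with bilinear
resampling; on rendered noiseless boards this lands within 0.1–0.2 px of
ground truth.

## Background segmentation

Each pixel carries up to 5 Gaussian intensity modes updated online
(Zivkovic-style recursion: weights decay by (1−α), the matched mode moves
toward the sample, an unmatched sample spawns a new mode replacing the
weakest). A pixel is background when it matches one of the highest-weight
modes whose cumulative weight stays within `background_threshold` (0.9); the
crossing mode is *excluded* (the top mode is always eligible) — including it
would absorb any moving object after a single frame. Matching uses a squared
Mahalanobis cutoff of 16 (≈4σ) with a variance floor of 1 on the 0–255
scale.

The photoperiod's light↔dark steps flood the foreground. When the total
retained contour area exceeds `lighting_change_area` (default 25% of the
image) a lighting change is declared, the model is reset to a single mode
seeded from the current frame, and re-detection is suppressed for
`lighting_change_est_time` frames so the freshly reset model is not
re-triggered every frame. The mask is lightly closed morphologically before
contour extraction (8-connected components; sub-threshold components are
discarded as noise) to bridge 1–2 px gaps in the segmented plant.

## Tip detection

**Top view.** For each retained contour the candidate is the pixel at
maximal geodesic (within-mask shortest-path) distance from the contour pixel
nearest the plant-base anchor, on the 8-connected pixel graph with step
costs 1 and √2. The base anchor (pot position per view) is a configuration
input. Ties break toward larger v then larger u, for determinism.

**Side view.** The epipolar line of the top-view tip selects the contour
fragment(s) that can contain the tip (fragments whose minimum distance to
the line is within a threshold; if none qualify the single closest is kept
so a candidate always exists while the plant is segmented), then the same
minimum-path rule localizes the candidate inside each fragment. When no
top-view tip exists for a frame, all fragments are considered.

This geodesic rule has a documented failure mode: when the tip bends over
and visually overlaps the stem, the geodesically farthest point is the
elevated stem, not the tip — the same behavior that manual corrections are
for in real recordings.

## Tracking, corrections, synchronization

Per frame: a single candidate is taken as-is (label `automatic`); among
several, the Euclidean-nearest to the previous selection wins (`estimated`);
frames with no candidate are filled afterwards by per-coordinate linear
interpolation between bounding observations (`interpolated`), with
leading/trailing gaps held at the nearest observation. Manual corrections
replace frames (label `manual`, even when the value is unchanged, so the
accounting reflects operator effort) and all interpolated frames are then
recomputed so gaps bounded by a corrected point stay consistent.

The two cameras free-run on their own clocks; their offset is recovered from
the photoperiod: light/dark steps are located in each camera's mean-luminance
series (first differences above half the dynamic range), and the offset is
chosen as the shift aligning the most transitions (ties toward the smallest
magnitude), since either sequence may open mid-phase with unmatched boundary
transitions. The side track is then aligned by frame-index shift; frames
without a partner at the sequence edges are dropped from reconstruction.

## Triangulation and error auditing

Both observations are undistorted to normalized coordinates; the 3D point is
the least-squares solution of the two-ray DLT system, refined by one
Gauss–Newton step on the summed squared pixel reprojection error. Rays
within 0.5° of parallel are rejected as ill-conditioned. Per frame the
pipeline records the reprojection error in each view and flags frames whose
mean exceeds 10 px. Study-level roll-ups report the unweighted mean of the
per-video per-view mean errors (the convention used in the bundled example
tables; point-weighted averaging differs in the second decimal), the
percentage of high-error points, and the percentage of manually corrected
frames.

## The synthetic scene generator

Ground truth for every stage comes from a rendered booth: a cylinder 100 cm
tall and 93 cm in radius, the zenithal camera at 130 cm looking down and the
lateral camera on the wall at 55 cm looking at the plant axis, 1280×720
frames through 112°-FOV optics (focal length follows from the field of
view). The plant is a stem polyline from the pot to a helically nutating tip
with a darker tip blob: nutation radius 6 cm and period 200 frames
(≈3.3 h at one frame per minute — within the range reported for beans) with
0.03 cm/frame of vertical growth; tip blob 0.45 cm, stem 0.35 cm wide. The
side view carries the booth's dark lower band, the top view the dark pot
disk; an optional support pole (90 × 1.8 cm at 30 cm) renders in both views.
Illumination follows a light:dark photoperiod scaled to 40:20 frames so test
sequences of a few hundred frames cover several cycles (a real day at one
frame per minute would be 960:480); the dark phase keeps 20% illumination,
emulating the dim safelight that real recordings use at night. Gaussian
pixel noise and all stochastic choices flow through one seeded generator, so
a fixed seed reproduces sequences bit-exactly.

Calibration sets place the board at varied distances, offsets, tilts and
rolls chosen so the corner cloud covers more than half of each image — the
coverage lesson is real: the test suite includes an experiment where boards
confined to the image center make the fitted distortion extrapolate badly,
reproducing the spatial error pattern in which localization degrades for
points near the lateral camera (which project peripherally). Notably, with
*correct* calibration the pure noise-propagation error is smallest there;
the degradation is a calibration-coverage effect, not a ray-geometry one.
Every generated pose is checked for full-grid visibility and the lateral
offset is shrunk until the board projects inside the frame with margin.

What the renderer does **not** emulate: leaves and canopy self-occlusion,
wind or vibration, photorealistic shading, sensor artifacts beyond additive
Gaussian noise, and irregular (elliptical, drifting) nutation. Passing the
closure tests therefore demonstrates the geometric and algorithmic chain is
correct under controlled conditions, not that segmentation is robust to
every greenhouse scene.

## Parameters on the scaled timebase

The module-level defaults follow per-minute recordings: MOG learning rate
0.01, lighting-change cooldown 30 frames, epipolar fragment threshold 20 px.
The pipeline defaults in `track_options()` are calibrated to the generator's
24×-compressed photoperiod, where background dynamics must scale
accordingly: learning rate 0.18, new-mode variance 4 (the renderer's noise
is sub-intensity-level), minimum contour area 6 px, closing radius 3,
cooldown 8 frames, epipolar threshold 8 px (the synthetic epipolar geometry
is near-exact, so a tight gate removes ghost fragments without risk). On
real day-scale recordings the module defaults are the right starting point.

Two behaviors of the compressed timebase are worth knowing. First, every
photoperiod step costs one interpolated frame per view (the reset frame has
no usable mask), so with ~10 steps per 300 frames the automatic-detection
ceiling is ≈96.7%. Second, when the tip's projected motion stalls (the side
camera sees the nutation circle edge-on at its extremes), a stationary tip
is absorbed into the background within a few frames and re-detected as soon
as it moves; the intervening frames are interpolated, which is harmless for
accuracy precisely because the tip is nearly still.

## Problem sizes used in validation

The test suite uses 10-view calibration sets, 8 stereo pairs, 90-frame
half-resolution pipeline runs, and one full-scale closure: a 300-frame
1280×720 sequence at 0.5 intensity-noise with a 7-frame stereo offset,
calibrated from rendered chessboard images. The acceptance script repeats
that closure and additionally recomputes the bundled example-study
roll-ups. Monte-Carlo error statements use 300–500 trials.

## Known limitations

- The geodesic tip rule detects the leading rim of the moving tip region, a
  systematic offset of roughly the blob radius (~3 px here); it also fails
  under tip–stem overlap, by design matching the behavior the
  correction workflow exists for.
- Distortion fitted from boards that do not cover the tracked volume
  extrapolates poorly; undistortion then fails loudly. Calibration coverage
  should span the image area traversed by the plant.
- The background model is grayscale; color-based cues are out of scope.
- Offset recovery assumes at least one shared photoperiod transition and is
  ambiguous for shifts that are exact multiples of the photoperiod.
- The interactive correction GUI of the original workflow is replaced by a
  corrections CSV merged at tracking time.
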