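---
title: "Measuring distal radius fracture parameters from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring distal radius fracture parameters from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drfparams)
```

## The measurement problem

Distal radius fractures are graded, and reduction is planned, from four
radiographic parameters measured on a biplane wrist study:

* **Radial angle (RA, degrees)** — the inclination of the distal radial
  articular line, from the styloid tip (ST) to the ulnar border of the
  radius (UBR), relative to the perpendicular of the shaft baseline in the
  AP (frontal) view. Normal is roughly 20–25°.
* **Radial length (RL, mm)** — the axial distance between the
  perpendiculars through ST and UBR; normally 8–14 mm.
* **Ulnar variance (UV, mm, signed)** — the axial offset between the flat
  distal ulnar surface (its centre, UH) and the sigmoid-notch level of the
  radius (UBR). Positive means the ulna is relatively long.
* **Palmar tilt (PT, degrees, signed)** — the tilt of the articular rim
  line joining the dorsal (DJ) and volar (VJB) rims relative to the
  perpendicular of the radial shaft in the lateral view. Positive is volar
  tilt (normal ~11°); dorsal tilt is the hallmark of a Colles pattern.

`drfparams` implements the *geometric* half of an automated measurement
system: its input is a pair of semantic label masks (one per view) such as
a segmentation network produces, and its output is the four parameters
with landmark and axis provenance. Segmentation itself is a pluggable
boundary — any upstream model (or a human annotator) that emits
VOC-style masks can feed the pipeline.

## Pipeline

For each view the pipeline runs four stages.

### 1. Contour extraction

Each bone part is binarized from its label code, enclosed holes are closed
by the classic flood-fill-and-invert trick (a one-pixel background ring
guarantees the fill starts outside), the mask is smoothed with a
normalised 3×3 sampled Gaussian (σ = 1 px by default) and re-thresholded
at 0.5 — which deletes single-pixel speckle — and the outer boundary of
the largest connected region is traced (Moore neighbour tracing, pixel
centres as vertices, shoelace area). Sobel gradients (the standard 3×3
kernels) are computed for validation overlays; tracing runs on the filled
binary mask because linking thin edge ridges is fragile while region
boundaries are unambiguous. Contours can be compacted by a
Visvalingam-style triangle eliminator: the vertex forming the smallest
triangle with its neighbours is deleted while its deviation from the
resulting chord stays below `simplify_tolerance` (1 px) and the enclosed
area has moved by less than 2%. Landmark detection always uses the dense
traced contour; simplification exists for serialisation and downstream
consumers.

### 2. Central axis fitting

The baseline axis is the fitted centre line of the shaft least affected by
the fracture: the **ulnar diaphysis** in the AP view and the **proximal
radial diaphysis** in the lateral view. `n_points` (500) random points are
drawn uniformly inside the shaft contour by seeded rejection sampling, and
a line is fitted by minimising

$$\mathrm{AxisLoss}(m,b)=\sum_i f\!\big(w_i - (m\,u_i+b)\big),\qquad
f(d) = 2\left(\sqrt{1+d^2/2}-1\right).$$

$f$ is a pseudo-Huber-style penalty: quadratic near zero (Euclidean
smoothness), linear with slope $\sqrt2$ in the tails (Manhattan
robustness), so stray points — residual segmentation bleed, head
asymmetry — are down-weighted. Minimisation is plain gradient descent
from $(m_0,b_0)=(0,\ \text{centroid})$ with backtracking line search, so
the loss sequence is non-increasing; a fixed-step variant is available.
Two numerical choices matter:

* **Fitting frame.** Bones are near-vertical, so $y=mx+b$ is
  ill-conditioned. When the cloud's vertical extent dominates we fit
  $x = m y + b$ instead and convert to a direction angle
  $\theta\in[0°,180°)$; the residual definition is unchanged, only the
  frame swaps.
* **Standardisation.** The abscissa is centred and scaled to unit
  variance inside the optimiser; without it the $(m,b)$ gradients differ
  by two orders of magnitude and descent stalls short of the optimum. The
  reported $(m,b)$ are mapped back to image coordinates.

A brute-force grid oracle (0.1° angle steps, 0.5 px offset steps across
the cloud's intercept range, same frame) verifies in the test suite that
the descent reaches the global minimum of this convex objective to better
than 0.1% relative.

### 3. Rotating-line landmark detection

All detections happen in a canonical right-wrist frame: distal is up, the
radius is on the left of the AP image (radial = smaller x), volar is the
left (−x) side of the lateral image. Left wrists are mirrored at read
time.

* **ST** — the topmost vertex of the AP distal-radius contour, ties
  toward the radial side.
* **UBR** — a line anchored at ST starts horizontal and rotates clockwise
  in 0.01° steps; the first contour intersection at a distance of at least
  `min_dist_frac` (25%) of the contour width is UBR. The distance rule
  skips the articular surface points adjacent to ST.
* **UH / ul_UBR** — from the topmost ulna vertex a counterclockwise sweep
  finds the far end of the flat distal surface; the fitted ulna axis is
  intersected with the distal contour, the flat-surface endpoint farther
  from that intersection is named ul_UBR (the corner facing the radius),
  and UH is the vertex-index midpoint of the shorter contour arc between
  the axis intersection and ul_UBR — the centre of the flat surface. When
  global rotation puts the far corner on the clockwise side the sweep is
  retried clockwise (with a warning).
* **DJ / VJB** — the topmost vertex of the lateral distal-radius contour
  is one articular rim; the fragment is classified volar/dorsal by which
  side of the shaft axis its centroid falls on; the line through the top
  rim rotates counterclockwise (volar displacement) or clockwise (dorsal)
  until the first qualifying intersection, the opposite rim. Final names
  are assigned by canonical side — the volar-most of the two points is
  VJB — because under dorsal tilt the anatomically highest point is the
  volar rim.

Two implementation details depart from the naive reading and are worth
recording. First, the **touch-point estimate**: at the angle where the
rotating line first meets the far corner it is tangent to the contour, so
on a pixelated contour the discretised line clips one or two staircase
pixels on its way in; taking the intersection nearest the centre lands up
to several pixels short of the corner on a shallow articular concavity,
while the farthest qualifying vertex within the current sweep step is a
stable estimator of the tangential touch point (the two coincide in the
continuum limit). Second, **sweep caps**: the UBR/VJB sweeps are capped at
60° and the UH sweep at 45° from the starting perpendicular — the
anatomical sector in which an articular surface can lie. Without the cap a
globally rotated case lets the sweep wrap around and qualify a point on
the far diaphysis, and an over-strict distance threshold would "find"
the distal cortex instead of failing cleanly.

### 4. Parameter assembly

With $\hat u$ the axis unit direction pointing distally (row decreasing)
and $\hat v$ its perpendicular,

$$\mathrm{RA} = \operatorname{atan2}\big((\mathrm{ST}-\mathrm{UBR})\cdot\hat u,\ |(\mathrm{ST}-\mathrm{UBR})\cdot\hat v|\big),\quad
\mathrm{RL} = |(\mathrm{ST}-\mathrm{UBR})\cdot\hat u|\, s,$$
$$\mathrm{UV} = (\mathrm{UH}-\mathrm{UBR})\cdot\hat u\, s,\quad
\mathrm{PT} = \operatorname{atan2}\big(-( \mathrm{VJB}-\mathrm{DJ})\cdot\hat u,\ (\mathrm{VJB}-\mathrm{DJ})\cdot\hat v_{volar}\big),$$

with $s$ the pixel spacing in mm/px. The two-argument arctangent handles
quadrants that a raw slope ratio would not; all angles are wrapped to
(−90°, 90°]. Angles are calibration-free; lengths are reported in px when
no spacing is supplied (spacing is an *input*: it cannot be estimated
from a mask) and in mm otherwise.

## Tunable parameters

| Parameter | Default | Unit | Why this value |
|---|---|---|---|
| `gaussian_sigma` | 1.0 | px | One-pixel-scale segmentation noise; kernel stays 3×3 |
| `min_area_px` | 50 | px² | Below this a region is speckle, not bone |
| `simplify_tolerance` | 1.0 | px | Sub-pixel fidelity is meaningless on a pixel contour |
| `n_points` | 500 | – | Direction noise ≈ 0.3–0.6° on a 40 px-wide shaft; doubling changes θ̂ by <0.5° |
| `alpha` | 1e-3 | – | Initial step; backtracking adapts it |
| `max_iter` / `tol` | 5000 / 1e-8 | – | Convex objective; convergence verified against the grid oracle |
| `step_deg` | 0.01 | deg | Sub-pixel angular resolution at typical bone radii |
| `min_dist_frac` | 0.25 | – | "Significantly distant": a quarter of the bone width separates surface-adjacent hits from the far corner |
| `max_sweep_deg` | 180 (capped 45–60 per landmark) | deg | Termination bound; per-landmark anatomical sector |
| `spacing` | 1.0 | mm/px | No calibration → px units, with a warning |

## The synthetic phantom: a stated world

Real, labelled biplane studies cannot ship with a package, so every stage
is exercised against a synthetic wrist phantom with exact ground truth.
The generator builds, in an upright frame and then under a global
rotation:

* an AP **distal radius** whose styloid apex is ST and whose articular
  edge bows proximally (a concave fossa, sagging ~15% of the chord) down
  to the UBR corner, placed so RA and RL are exact by construction;
* an AP **ulna** whose head is a knob roughly mass-balanced about the
  shaft axis, with a gently sagging distal surface spanning from the axis
  to its radial corner (ul_UBR); the surface centre is UH and sits at the
  prescribed ulnar variance relative to UBR;
* an AP **proximal radius** shaft (present so masks are label-complete);
* a LAT **proximal radius** shaft and a LAT **distal fragment** whose rim
  chord joins DJ and VJB at the prescribed palmar tilt, its centroid
  offset 8 px volarly or dorsally off the shaft axis;
* optional boundary jitter: the silhouette polygon is resampled every
  2 px and each vertex displaced along its outward normal by
  U(−noise, +noise).

Default parameter ranges mirror the clinically sensible window: RA
10–30°, RL 8–14 px (the normal mm range read at 1 mm/px), UV −3…3 px, PT
−20…20°, shaft vertical. Displacement is coupled to the tilt sign (volar
displacement with volar tilt, dorsal with dorsal — the Smith/Colles
pairing) because the sweep-direction rule only finds the opposite rim when
the highest rim and the displacement side agree. Reconstructing the
parameters analytically from the truth landmarks reproduces the spec to
1e-9, so the generator and the measurement definitions cannot drift
apart.

What the phantom does **not** emulate — and therefore what a green test
does not establish: real cortical texture and segmentation-model failure
modes (under/over-segmentation, bridges between bones), comminuted or
intra-articular fragments, radio-ulnar overlap in the lateral view,
anisotropic spacing, and anatomical shape variation beyond the
parameterised geometry. Tests green on the phantom certify the *geometry
engine*, not any segmentation model.

## Numerical choices and degenerate inputs

* "Highest point" means smallest row index; ties break toward a declared
  side per landmark (radial for ST, dorsal for DJ under volar
  displacement, volar under dorsal displacement).
* The Gaussian output is re-binarized at 0.5 before edge detection and
  tracing; the threshold is the neutral choice for a [0, 1] mask.
* A centroid within 0.5 px of the lateral axis is an ambiguous
  displacement; the classifier returns dorsal with a warning rather than
  guessing silently.
* Degenerate requests fail loudly: empty parts, contours below the area
  floor, sweeps that exhaust their cap, coincident landmark pairs.
* Rotation invariance holds exactly for the parameter formulas (rotating
  landmarks and axes together changes nothing beyond float error). The
  full raster pipeline is rotation-robust only at pixel scale: re-drawing
  a phantom at a new global angle re-quantises every corner by up to a
  pixel and perturbs the axis fit by a few tenths of a degree, so
  end-to-end parameter shifts of 1–2 px / 1–2.5° across ±10° rotations
  are expected and tested at those bounds.
* A 2% area budget and the deviation bound together keep simplification
  conservative; with boundary jitter comparable to the tolerance a
  deviation-bounded simplifier must retain roughly a third of the
  vertices — stronger compression claims are not honest at that noise
  level.

## Worked example

```{r example}
ph <- generate_phantom(phantom_spec(RA_true = 22, RL_true = 11,
                                    UV_true = 0, PT_true = 11))
res <- run_case(ph$ap, ph$lat)
res$params
unlist(ph$truth$params[c("RA", "RL", "UV", "PT")])
```

The recovered values sit within a pixel / a degree or two of the truth;
the residual is rasterisation and smoothing erosion at the landmark
corners, quantified across 50-phantom batches in the acceptance suite
(`tests/testthat/test-acceptance.R`, reproducible via
`scripts/acceptance.R`).

## Known limitations

* One dominant region per part: comminuted fragments are out of scope.
* Sub-pixel landmark refinement is deliberately absent; accuracy is
  bounded by the mask raster (±1–2 px per landmark).
* The segmentation losses module is a verification-grade reference
  (means over elements, no gradients); it is not a training harness, and
  the weighting of composite cross-entropy/Dice objectives is left to the
  trainer.
* Pixel spacing must be supplied; there is no calibration-object
  detection.
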