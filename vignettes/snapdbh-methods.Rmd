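---
title: "Single-shot DBH estimation: model, estimators and design choices"
author: "snapdbh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot DBH estimation: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Diameter at breast height (DBH) — the trunk diameter 1.4 m above the ground,
measured along the trunk's growth direction — is the standard size metric in
forest inventory. `snapdbh` estimates it from a single smartphone snapshot:
one RGB image (1440×1920 in the reference capture geometry), one
low-resolution LiDAR depth map (192×256, valid between 0.25 m and 5 m),
pinhole intrinsics and the gravity direction vector.

A single camera sees only part of the trunk's circular cross-section: the
arc between the two points where sight lines are tangent to the circle (the
apparent trunk edges in the image). Two observable quantities summarize that
arc:

* `N_BH` — the trunk's width in pixels at breast height, and
* `p̃` — the mean depth of the 3-D points on the visible arc.

With focal length `f`, the chord between the tangent points has length
`l = p N_BH / f`, where `p` is the perpendicular distance from the optical
center to that chord, and the diameter follows from tangent-circle geometry:

    d = l / (2p) * sqrt(l² + 4p²),  equivalently  sqrt(d² − l²) = l² / (2p).

The catch is that `p` itself is not measurable robustly from sparse depth;
the measurable quantity is the arc-average depth `p̃`, which is *always
smaller* than `p` because the visible arc bulges toward the camera.
Substituting `p̃` for `p` gives an underestimated chord `l̃ = l p̃ / p` and an
underestimated diameter `d̃`. The package's core is the exact forward model
of this bias and its inversion.

# The bias model

For a circle of diameter `d` with chord depth `p` (camera outside the trunk,
`p > d/2`):

* chord length: `l² = 2p(√(p²+d²) − p)` — implemented in the cancellation-free
  form `l = d·√(2p/(√(p²+d²)+p))`;
* arc-average depth (closed form, verified against adaptive quadrature of its
  integral form to 1e-9 relative):

      p̃ = p + ½√(d²−l²) − d²/(4l)·[asin(l/d) + (l/d)√(1−l²/d²)]

  with limits `p̃ → p` as `l → 0` and `p̃ → p − πd/8` as `l → d`;
* underestimated chord and diameter: `l̃ = l·p̃/p`,
  `d̃ = l̃/(2p̃)·√(l̃²+4p̃²)`.

The map `(d, p) → (d̃, p̃)` is exactly scale-invariant: scaling both inputs
scales all outputs. `solve_exact()` exploits this: the inversion reduces to a
*one-dimensional* bracketed root-find on the ratio `d/p` (the observed ratio
`d̃/p̃` is monotone in it), followed by a rescale. This is more robust than a
2-D Newton iteration — it cannot diverge on the attainable region — and it
doubles as the oracle against which the lookup table is validated.

## The correction lookup table

`build_lut()` sweeps `m1 × n1` forward samples of true `(d, p)` (defaults
`d ∈ [0.5, 100]` cm, `p ∈ [25, 500]` cm, `m1 = 996`, `n1 = 4996`), records
the observed ranges of `(d̃, p̃)`, and fills an `(m2+1) × (n2+1)` node grid
(defaults `m2 = 500`, `n2 = 1000`, about 0.1 cm node spacing in `d̃`) with
the true diameter. The sweep is a structured curvilinear grid in `(d̃, p̃)`
space, so the scattered-data interpolation is piecewise linear along the
grid lines: linear in `p̃` along each constant-`d` curve, then linear in `d̃`
across curves. (A general Delaunay triangulation would offer the same
piecewise-linear accuracy on these points at far higher cost.) Nodes outside
the attainable region are marked invalid. `lut_lookup()` indexes the cell
containing a query with the ceiling rule and refines with bilinear
interpolation over the four surrounding nodes; queries outside the observed
ranges are errors (no extrapolation), and a query next to invalid nodes
falls back to the nearest valid node with a warning.

Note that the `d` sweep range is for *diameters* and the `p` range for
*chord depths*; the depth range mirrors the LiDAR working range (0.25–5 m).
Validation tests hold the lookup to within 0.15 cm of `solve_exact()` over
the attainable region.

# From pixels to observables

The pipeline (in `estimate_dbh()` order):

1. **Depth upsampling.** Bilinear interpolation of the 192×256 depth grid to
   RGB resolution, grid corners aligned; any output pixel whose 2×2 stencil
   touches an invalid sample is invalid.
2. **Back-projection.** Per-pixel solution of the pinhole relation
   `s[u,v,1]ᵀ = P[x,y,z,1]ᵀ`, world frame = camera frame. Pixel convention:
   `(u,v)` = (column, row), 0-based, centers on integers; `s` is distance
   along the optical axis.
3. **Normals.** Tangent vectors by first differences of the point map along
   the pixel grid (central in the interior, one-sided at borders — a
   second-order stencil cannot produce tangent vectors), normal = normalized
   cross product.
4. **Seeds and segmentation.** A near-vertical trunk has `|n_g·n| < ε_t`
   (default 0.3); ground has `|n_g·n| > 1−ε_g` (default 0.1). The trunk seed
   is the nearest such pixel in a centered 500-px window; the ground seed is
   the pixel whose depth is closest to the mean depth of the ground set.
   Ties break to the smaller row, then column. The default segmenter grows
   4-connected regions from the seeds: eligibility is the seed's normal
   condition, with RGB color continuity as the gate and takeover inside the
   silhouette band where the coarse depth leaves normals undefined or
   blended; growth across valid depth requires `|Δs| ≤ 5 cm` between
   neighbors. The segmenter is pluggable (`segmenter` argument), and
   precomputed masks bypass it entirely.
5. **Ground plane.** Total least squares (smallest principal component) on
   the segmented ground points, normal oriented away from gravity.
6. **Stripes and orientation.** Every image row crossing the trunk
   contributes one center pixel (the trunk pixel nearest the row's mean
   trunk column); rows are assigned to four equal bands over ground-referenced
   heights (1.0, 1.8] m by the *center pixel's* height (half-open bands, as
   in `h_k < h ≤ h_{k+1}`). Each band's centers are fit with a total
   least-squares 3-D line, directions sign-aligned upward, and the growth
   orientation `o` is their renormalized mean. Row centers use the full
   trunk-mask row rather than per-pixel band membership because pixel height
   varies with depth across the visible arc — a thin band cuts each row in an
   off-center arc sliver, which at close range destroys the line fit.
7. **Breast height.** Heights along `o` (`h = plane distance / |n·o|`); the
   anchor `c0` is the center pixel with `h` closest to 1.4 m.
8. **Alignment.** The rotation mapping `o` to the y axis (about z to zero
   the x component, then about x to zero the z component; the recorded
   angles are the precession `θx = acos(a/√(a²+b²))` and nutation
   `θz = −asin(c)`), applied as `x → R(x − c0) + c0`. The rotation is tested
   by its contract `R·o = ŷ` rather than matrix entries.
9. **Slab measurement.** Slab rows are those whose center height falls in
   `1.4 ± 0.01` m. `N_BH` is the mean trunk-mask pixel count over those rows
   (kept at sub-pixel precision internally; an integer is displayed), scaled
   by `cos ψ` of the image-projected axis tilt — a horizontal image row cuts
   a tilted silhouette wider than the true chord. `p̃` is an average of
   aligned-frame z over slab-row trunk pixels, referenced to the
   *transformed camera position* (the alignment moves the camera; omitting
   the offset mixes an arbitrary translation into the depth).
10. **Correction.** `d̃` from the chord formulas, then the LUT (or
    `solve_exact`) gives `d`.

## Estimator choices that depart from the naive reading

Three measurement details matter at the accuracy level the synthetic tests
hold the pipeline to (0.2 cm noiseless), and each is a case of *estimating
the quantity the model actually defines*:

* **Chord-abscissa weighting of `p̃`.** Pixels sample the visible arc
  uniformly in image `u`; the bias model defines `p̃` uniformly over the
  chord abscissa. A plain pixel mean over-weights the near part of the arc
  and reads low by up to ~3% of `p` for thick trunks. Each slab point
  therefore carries a trapezoidal weight in its aligned x coordinate.
* **Trusted depth support and limb-truncation compensation.** Bilinear
  upsampling blends trunk and background depths within one low-resolution
  cell of the silhouette; those pixels are excluded via a trust mask (all
  four stencil samples inside the trunk). The excluded band holds the
  deepest part of the arc, so the measured average misses the tails near the
  tangent points. `refine_chord()` compensates with the model itself: solve
  for the implied `(d, p)`, evaluate the closed-form truncated-arc average
  over the observed chord half-span, add the deficit, recompute; two or
  three fixed-point passes converge. No circle is ever fit to the points.
* **Optical limb depth for the pixel-width conversion.** `l = p·N_BH/f`
  converts pixel width through the pinhole scale at the *optical* depth of
  the apparent trunk edges, while the circle relations use depths in the
  axis-perpendicular plane. The two coincide only for a vertical trunk.
  `refine_chord()` reconstructs the implied limb points in the aligned frame
  and maps them back through the inverse alignment to get the correct depth
  scale. Without this, a 20° lean biases a 22-cm trunk by ~2.5 cm.

`estimate_dbh(align = FALSE)` deliberately implements the *naive* estimator —
plain pixel-mean of raw (untransformed) depths, literal chord formulas, no
refinements — as the comparison case for the effect of trunk-axis alignment.
On cylinders leaning toward or away from the camera the naive estimate is
systematically lower: the horizontal slice of a tilted cylinder is an
ellipse, deeper than the circle the model assumes.

# The synthetic scene generator

`render_scene()` ray-casts a cylinder of known diameter standing on a plane,
per RGB pixel: nearest hit among the (ground-clipped) cylinder and the
plane; depth is the z component of the hit; the LiDAR grid is point-sampled
at ray positions whose grid corners align with the RGB grid, with optional
additive Gaussian depth noise (σ configurable; 3 mm in the replicated
experiments — the sensor's noise magnitude is not published, so this is a
fixture parameter reported with every experiment). The camera emulates the
reference capture: f = 1451.99 px, RGB 1440×1920, depth 192×256, y up,
gravity (0,−1,0). Ground truth (masks, axis, true chord depth, analytic
observables) accompanies every frame so each stage can be tested against
known geometry, and segmentation can be bypassed to isolate the measurement
model.

What the renderer deliberately does *not* emulate: bark texture and
non-circular cross-sections, occluding vegetation, illumination, lens
distortion, rolling shutter, or correlated sensor noise. Passing tests on
these scenes validate the geometry and the bias correction under the
method's own assumptions (circular cylindrical trunk, single plane ground);
they do not certify segmentation robustness on real imagery — the original
pipeline delegates that to a learned RGB model, and this package keeps that
boundary as a pluggable interface.

Placement in experiments follows the capture protocol: a cylinder of
diameter `d` is admissible at axis distances from
`max(0.35, 2.2·r + 0.25)` m (camera outside the trunk, sensor near limit) to
`min(4.5, f·d/(0.1·W))` m (trunk occupies ≥10% of the image width). Captures
closer than 0.95 m use the short-subject configuration (single stripe over
(4, 8] cm, measurement slab at 6 cm, camera at 0.25 m) — the tabletop
cylinder protocol; farther captures use the tree defaults (camera at 1.5 m).

## Problem sizes in the test suite

The packaged checks use: the full default LUT (996×4996 forward sweep,
500×1000 grid; ~3 s to build); 1000 random LUT-vs-solver queries; a
noiseless recovery sweep of 5 diameters ∈ {8, 15, 22, 40, 95} cm × 5
distances each at full capture resolution; and a replicated noisy
experiment — 100 replicates per diameter for d ∈ {8, 15, 22} cm (the
physical-cylinder protocol), σ = 3 mm, random orientation up to 20° from
vertical — rendered at half resolution with the focal length scaled
accordingly, which leaves the geometry unchanged and keeps 300 full
pipeline runs around two minutes.

# Numerical details and degenerate inputs

* Depth dialects: 16-bit PNG in millimeters (0 = invalid; round trip exact
  to 0.5 mm) and plain-text float matrices in meters (non-finite = invalid).
  Values outside 0.25–5 m are marked invalid on load; negative depths are a
  validation error.
* Plane and line fits refuse degenerate inputs (collinear or coincident
  points) by the spectrum of the centered scatter.
* `alignment_from_orientation()` flips a downward orientation and rejects an
  axis with no component in the x–y plane (trunk along the optical axis).
* Ties (seed selection, breast-height anchor) break deterministically to the
  smaller row, then column; the whole pipeline is deterministic for fixed
  inputs, and all synthetic-noise randomness flows from one recorded seed.
* `p̃` is constrained by construction to the LUT's observed ranges; queries
  outside them fall back to the uncorrected `d̃` with a warning rather than
  extrapolating.

# Known limitations

* The circular-cross-section assumption is inherited from the model;
  fluting, tapering within the slab, or strongly elliptical trunks are not
  corrected.
* The reference segmenter's RGB gate assumes the trunk is color-separable
  from its background near the silhouette; on real bark a learned segmenter
  should be plugged in.
* Trunks leaning more than ~20° from vertical leave the validated envelope
  (the seed conditions and the small-angle geometry corrections both degrade).
* A single ground plane is fit; sloped or stepped terrain is out of scope.
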