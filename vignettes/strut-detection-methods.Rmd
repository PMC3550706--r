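---
title: "Detecting stent struts in polar IVOCT pullbacks: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stent struts in polar IVOCT pullbacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octstrut)
```

## The problem

Intravascular optical coherence tomography (IVOCT) images coronary
arteries from inside the vessel at roughly 10–20 µm resolution. After a
stent is implanted, each metal strut appears in the polar (A-line ×
depth) representation as a small, very bright blob — struts are specular
reflectors — followed by a *trailing shadow*: a dark stripe extending
behind the strut to the far edge of the image, because almost no light
passes the metal. A pullback run contains hundreds of frames and
thousands of struts, so strut-level analysis (apposition/coverage
measurement, 3D stent reconstruction) is only practical when detection
is automatic.

`octstrut` implements a fully automatic detector that needs neither
lumen/vessel contours nor prior knowledge of the strut status (apposed,
malapposed, or tissue-covered). It works directly on the 16-bit polar
frames, which preserve the acquisition geometry: every image row is one
A-line, the row axis is angular and wraps (row 1 neighbours row
`n_alines`), and the column axis is depth with the catheter on the left.
Trailing shadows are therefore *almost horizontal* structures, which the
whole pipeline exploits.

## Pipeline

The detector runs five fixed stages per pullback.

**1. Preprocessing.** The lowest `noise_percentile` (default 5%) of the
global intensity histogram is treated as noise and zeroed. The
percentile is a rank-based order statistic (rank `ceiling(p*N)` of the
sorted pixel multiset, no interpolation), which is exact on integer
16-bit data. Catheter ring artifacts — bright vertical lines near the
left edge, constant across frames after z-offset calibration — are found
on the z-minimum projection of the pullback: moving tissue is suppressed
by the minimum, constant artifacts survive. A depth column within the
leftmost `catheter_search_fraction` of the image whose z-minimum exceeds
the noise floor in more than `line_row_fraction` of rows is an artifact
line; the region of interest (ROI) starts right of the last such line.

**2. Candidate pixels.** Struts cannot be segmented by a global
brightness threshold (image quality varies widely), but they fall off to
their shadow much faster than tissue attenuates. Per A-line, the
intensity peak is located (ties toward the smallest depth — the strut
front edge is the quantity of interest), the start of the potential
trailing shadow is the first window of `sliding_shadow_size` consecutive
pixels at or below the *maximum shadow intensity threshold* (the
`shadow_intensity_percentile`, default 89th, of the ROI histogram over
the whole pullback), and the two-point slope
`(I(shadow_start) − peak) / dist` must be at or below `slope_threshold`
(default −48 intensity units/pixel on 16-bit data; the threshold scales
with intensity units and is exposed in the configuration). One candidate
per A-line at most; overlapping stents are out of scope. At the far
image edge a truncated shadow window is accepted when at least half of
it remains, so deep struts near the border still qualify.

**3. Shadow edges.** After Gaussian smoothing (`gaussian_sigma`,
default 1.5 px; wrap boundary on the angular axis, reflection on the
depth axis), two 3×3 horizontal Prewitt compass kernels measure the
bright→dark (top) and dark→bright (bottom) transitions across rows.
Supra-threshold response pixels are grouped into per-row runs along the
depth axis; runs on adjacent rows with overlapping spans merge (shadows
may be slightly tilted), each edge is positioned on its
strongest-response run, and only edges at least `edge_length_threshold`
(default 100 px) long survive. The length filter is what rejects the
short false edges of an eccentric lumen boundary: a lumen crossing is
locally horizontal only over a few depth columns, whereas a true shadow
edge runs to the far edge of the image.

*Edge-strength threshold.* No usable auto-threshold emerged from
histogram bimodality here: edge responses scale with the local tissue
brightness, which decays exponentially with depth, so the edge class
itself spans orders of magnitude and Otsu's method splits it rather than
separating it from noise. The default is instead 3× the robust
(MAD-based) noise scale of the response image, with a floor of 5% of the
peak response for near-noiseless frames. A low threshold is safe by
construction: spurious exceedances form short runs that the length
filter removes, while a high threshold can break the continuity of a
deep, dim edge. An absolute override (`edge_response_threshold`) is
available.

**4. Edge-guided clustering.** Candidates agglomerate by single linkage:
clusters merge while their minimal inter-member distance is strictly
below `clustering_distance_threshold` (default 4 px), using Euclidean
pixel distance with wrap-aware row differences so that a strut split by
the frame seam reassembles. The result is the connected-component
partition of the proximity graph, hence independent of input order.
Because every strut sits directly below its shadow's top edge and above
the bottom edge, the first cluster below each top edge and the first
cluster above each bottom edge (in wrap-aware angular order) are kept;
all other clusters — speckle flukes in tissue, seam artifacts — are
discarded. Edges pair into intervals (each top edge claims the nearest
unclaimed bottom edge at a greater angular position, modulo the wrap);
an interval with both edges but no selected cluster triggers *non-bright
recovery*: within the interval's rows and a depth window anchored at the
edges' start columns (`non_bright_depth_back`/`_fwd`), the per-row
maximum pixels above the shadow threshold form a cluster flagged
`non_bright`. This recovers struts too dim for the slope test — deep
struts or struts under thick neointima — that still cast a clear shadow.
A strut position is the average of its cluster members (circular mean
over rows, arithmetic mean over depths, rounded half-to-even).

**5. 3D false-positive removal.** A guide wire reflects and shadows like
a strut, but it is closer to the catheter than anything else and its
position is continuous along the entire pullback — no strut has that
property, because which strut is closest changes as vessel geometry
rotates along the artery. Per frame the minimal-depth detection is
taken; entries at most `guide_wire_max_gap` frames apart and within
`guide_wire_distance_threshold` (default 40 px) chain together, and the
longest chain is accepted as the wire only when it covers at least
`min_track_fraction` (default 80%) of the frames. The gap tolerance
exists because a single frame in which the wire is missed (or a strut is
momentarily closest) must not sever an otherwise continuous track; with
strict adjacent-frame linking one missed frame splits a full-pullback
track into two sub-threshold halves. When no chain qualifies, nothing is
removed — pullbacks acquired without a wire are left untouched. Finally,
the per-frame counts of remaining detections are smoothed with a
`segment_smooth_window`-frame moving average and the longest run of
frames with at least `segment_min_count` struts becomes the stented
segment; detections outside it are flagged. Removed detections are
flagged (`guide_wire_removed`, `outside_segment_removed`), never
deleted, so results files carry the full audit trail.

## Parameters

All tunables live in one `detection_parameters()` object, serializable
to YAML. The defaults are the published operating point for clinical
504×960 polar frames (pixel size ≈ 0.005 mm in depth, so 10 px ≈
0.05 mm). `scale_parameters()` rescales the pixel-valued thresholds by
the depth ratio for other geometries (e.g. at 256 depth samples the
edge-length threshold becomes 27 px and the matching tolerance 3 px),
with small floors keeping discrete windows usable. The slope threshold
is intensity-scale-bound, not geometry-bound, and is left unscaled.

## The synthetic phantom

No clinical data ships with the package; every end-to-end claim is made
on synthetic polar phantoms with known ground truth
(`phantom_spec()` / `generate_phantom()`). The phantom emulates the
image formation features the detector relies on:

* tissue beyond an eccentric lumen (sinusoidal radius modulation) with
  exponential depth attenuation and multiplicative gamma speckle, the
  standard stand-in for coherent imaging noise;
* the eccentric lumen rotates slowly along the pullback
  (`lumen_phase_drift`), as real vessel geometry does — without this a
  static near-catheter strut would mimic a guide wire's frame-to-frame
  continuity, a degeneracy clinical pullbacks do not exhibit;
* struts as bright blobs with a front-edge intensity maximum (slight
  depth taper, weak speckle: struts reflect specularly) and full-depth
  trailing shadows; apposed, malapposed (floating in the lumen), covered
  (under a tissue layer) and non-bright (deep and dim, detectable only
  via recovery) variants;
* an optional guide wire near the catheter whose angular position
  oscillates smoothly across frames;
* constant catheter-artifact columns and uniform low-level background
  noise; strut-free margin frames at both pullback ends.

Default desk-scale geometry is 64 frames of 128×256 — scaled down from
clinical 504×960 so that a full pullback processes in seconds and the
entire suite (including a 15-run parameter sweep) stays within a few
minutes on one CPU. Generation is deterministic given the spec seed.
`standard_phantom_suite()` provides canned scenarios: high-quality
apposed, covered, malapposed, low-quality (3× speckle, half brightness),
non-bright, and matched pullbacks with and without a guide wire plus
12-frame strut-free margins.

Photometry was chosen once, from the physics the method assumes: tissue
peak 2500 with attenuation 0.005/px and speckle CV 0.12 keeps the
tissue peak-to-shadow slope well above the −48 threshold (typically −20
to −35, since speckle pushes the detected shadow start deep), while
strut slopes are steeper than −1000; the 89th-percentile shadow
threshold lands around 2000–2100 on these phantoms, between the shadow
floor (~80) and the dim-strut brightness (2800).

**What passing these tests does and does not show.** The phantoms
reproduce the geometry and contrast structure of IVOCT struts, not the
full phenomenology of clinical data: no sunflower or seam artifacts, no
residual blood, no motion — and clinical-scale validation figures (on
the order of 94% sensitivity over ~18,000 expert-marked struts) cannot
be reproduced without clinical pullbacks and expert annotations. Phantom results demonstrate correctness of the
implementation and qualitative robustness (sensitivity stays within ~10
percentage points under ±20% parameter perturbation, mirroring the
published sensitivity analysis), not clinical performance.

## Evaluation protocol

`match_detections()` pairs detections with reference struts per frame by
*optimal* one-to-one assignment (an O(n³) Hungarian solver) minimizing
total wrap-aware distance; only pairs within `acceptance_distance`
(default 10 px ≈ 0.05 mm) count. Optimal assignment is
order-independent and reproducible, where greedy matching depends on
record order. Sensitivity is TP / n_reference; the false-positive ratio
is FP / n_reference; distance statistics are over matched pairs. The
same matcher provides inter-observer agreement (matches divided by the
mean of the two observers' counts). `parameter_sweep()` reruns the whole
pipeline with each of the five main parameters at −20%/0/+20% of its
value; the shadow-intensity threshold is perturbed by scaling the
computed threshold value, since the 89th percentile itself cannot
meaningfully exceed 100%.

## Numerical choices and degenerate inputs

* Percentiles: rank-based order statistics (`type = 1`), exact on
  integers; a constant image returns that constant.
* Peak ties: smallest depth. Strut position rounding: half-to-even.
* Circular means guard the seam against floating-point drift (a mean
  infinitesimally below row 1 snaps to row 1, not `n_alines`).
* Cluster merging is strict (`distance < threshold`), matching the
  "shorter than" merge rule; Euclidean metric, with the Chebyshev
  alternative intentionally not offered — the difference is immaterial
  at a 4 px threshold and one metric keeps results comparable.
* All-zero A-lines yield no peak; frames without positive edge response
  yield no edges; a pullback with no qualifying frames yields an empty
  segment and everything flagged `outside_segment_removed`.
* The pipeline contains no randomness: identical input and configuration
  give byte-identical results files.

## Known limitations

* Overlapping stents (two struts in one A-line) are out of scope, as is
  z-offset correction (assumed already applied) and Cartesian rendering.
* Struts whose shadow is entirely blurred away (severe restenosis) are
  invisible to the edge-guided selection, and bioabsorbable struts —
  dark boxes rather than bright reflectors — violate the detector's
  contrast model.
* Touching struts can merge into one cluster; the package does not
  attempt to split them using stent-design patterns.
* The guide-wire filter assumes at most one wire; multi-wire procedures
  would require running the track search iteratively.
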