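---
title: "The epmap HDEAM analysis workflow: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The epmap HDEAM analysis workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the
electrophysiological quantities it computes, the assumptions behind each
algorithm, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the numerical
conventions that affect reported values. It states no empirical result
that the test suite does not itself compute.

## 1. The measurement model

A high-density electro-anatomical mapping (HDEAM) study of the right
ventricle (RV) consists of a triangulated chamber surface (vertices in
mm), a set of electro-anatomical points — each with a catheter position,
its projection onto the surface, a unipolar electrogram in mV at a fixed
sampling rate, and a contact force in grams — plus a 12-lead surface ECG
and two timing fields: the *reference annotation* (a fiducial time on the
recording, typically 2000 ms) and the *window of interest* (woi,
typically −100..+100 ms around it) within which activation fiducials are
searched.

The unipolar electrogram morphology encodes local electrophysiology: the
steepest negative deflection marks local depolarization; the steepest
positive slope of the following T wave marks local repolarization (the
Wyatt convention); and the amplitude at the surface-ECG J-point relative
to baseline (Uni-JEl) reflects the local transmural voltage gradient that
is believed to underlie the Brugada type-1 ECG pattern. In
Brugada-syndrome studies these quantities are mapped over the RV surface
and compared before and after an ajmaline challenge.

## 2. Feature extraction: algorithms and parameters

All parameters live in `feature_config()`; defaults below.

**J-point (QRS offset) detection.** The literature behind this workflow
does not specify its J-point algorithm, so the package uses a standard,
fully deterministic derivative-threshold detector behind a simple
interface (any function with the same signature can replace it): locate
the dominant QRS deflection, measure the peak smoothed absolute
derivative within ±60 ms of it, and return the first sample after the
deflection where the absolute derivative stays below
`jpoint_deriv_frac = 0.02` of that peak for `jpoint_hold_ms = 20` ms. The
study-level J-point is the *median* of the per-point detections, with the
lower of the two middle values for even counts, so it is always an
observed sample. V2 is the default lead (`lead_for_jpoint`); any standard
lead may be substituted when V2 quality is poor.

**Uni-JEl.** `U(t_J) − baseline`, where the baseline is the median of a
`baseline_window_ms = 40` ms segment ending at the QRS onset. The QRS
onset is detected on the surface lead by the mirror-image of the offset
detector and shared across points; when a caller provides none, the
window is anchored `qrs_pre_ms = 80` ms (a generous QRS duration) before
the J-point. The median baseline makes the measure robust to residual
noise in the segment.

**Activation time.** `AT = t(argmin dU/dt) − t(fiducial(V2))`, both
searched inside `[ref + woi[1], ref + woi[2]]`. The surface-lead fiducial
is read literally as the *amplitude minimum* of V2 (`v2_fiducial =
"min"`); because some laboratories instead use the steepest negative V2
slope, a `"dvdt_min"` switch is provided, and the default will not change
silently between versions. Derivatives are local linear-regression
(Savitzky–Golay order 1) slopes over
`derivative_smoothing_window_ms = 5` ms — at 1 kHz and the minimum window
this reduces to plain central differences. All argmin/argmax ties break
to the earliest sample.

**ARI (Wyatt).** Depolarization fiducial = argmin dU/dt within the woi;
repolarization fiducial = argmax dU/dt within
`[dep + t_search_min_ms, dep + t_search_max_ms]` (defaults 120 and
450 ms, a physiological bracket for RV action-potential durations; the
source workflow does not state its bounds). T-wave slopes are an order of
magnitude gentler than QRS slopes, so this search uses a wider derivative
window, `t_smoothing_window_ms = 25` ms; the window is symmetric, so it
cannot shift a symmetric slope maximum, and 25 ms is narrow relative to
T-wave rise times. `ARIc = ARI / sqrt(RR/1 s)` (Bazett); RR is supplied
explicitly or estimated as the median R-peak spacing of the surface lead
(the estimation is logged).

**Quality rejection.** A trace is discarded — never silently — with one
of three reason codes, tested in this order: `noise` when the detrended
pre-woi baseline RMS exceeds `noise_rms_max_mv = 0.15` mV;
`premature_beat` when a second cluster of samples with dU/dt below half
the main downstroke minimum appears inside the woi more than 40 ms from
the first; `abnormal_t_morphology` when the repolarization fiducial lands
on a search-window boundary or the two largest local maxima of the
T-window derivative are within 10% of each other and more than 30 ms
apart (an ambiguous repolarization time).

## 3. Maps, ROIs, areas

**Interpolation.** Vertex fields are built by nearest-neighbour
assignment from the points' *surface projections* (the coordinates the
map geometry is built from): each vertex takes the value of its closest
sample, ties to the lowest point index. Nearest-neighbour is the default
because it introduces no new extrema and was found the most accurate
choice for this class of map; an inverse-distance-weighted `"idw"` method
is the smooth fallback. A `"linear"` (Delaunay-barycentric) method is
part of the interface contract but requires a 3-D Delaunay backend that
is not among the package's dependencies; requesting it is an explicit
error rather than a silent substitution. `max_distance` (default `NULL`
= fill the whole surface, matching clinical practice; ~10 mm is a
sensible value for sparse maps) leaves far vertices missing.

**ROI selection.** A region is specified reproducibly — no interactive
picking — by an ordered list of mesh vertex IDs. Consecutive picks are
joined by shortest edge paths (geodesics over the mesh graph), because a
planar point-in-polygon test is ill-defined on a curved closed surface.
The closed contour must split the surface into two components; the
interior is chosen by an explicit `interior_hint` vertex or, by default,
as the smaller-area component, which makes the definition independent of
the clockwise/anticlockwise picking direction that a GUI would impose.
Contour vertices count as interior (boundary-inclusive), and boundary
triangles belong to the interior when ≥ 2 of 3 vertices are interior, so
interior and exterior areas partition the total exactly. A point is
inside the ROI iff its nearest mesh vertex is interior; this is a
deliberate strengthening of the original tool's 2-D test, chosen because
it is well-defined on any surface, and it is documented rather than
hidden. ROI re-interpolation uses only interior points, so exterior
samples cannot bleed into the region.

**Threshold areas.** `area_where()` sums triangles whose vertices satisfy
a condition; the conservative default counts a triangle only when *all
three* vertices satisfy it (the discretization is not defined by the
source workflow; a `"majority"` rule is available by flag, and the choice
is reported). Missing vertices never satisfy a condition. Joint
conditions AND two per-vertex predicates. The example voltage presets
(unipolar peak-to-peak ≤ 4.4 mV and ≤ 5.3 mV) ship as named conditions.
The published 0.85 mV two-colour threshold for delta-Uni-JEl maps is a
*recipe* — the median of the paired differences inside a ROI — not a
constant, and is implemented as such (`roi_median_condition()`).

## 4. Pre/post pairing

For each post-challenge point the Euclidean-nearest pre point is
identified on surface coordinates (raw positions by flag); pairs whose
distance *strictly exceeds* 5 mm are excluded, so a pair exactly at the
threshold is kept. The phrase "only the pair of points within the minimum
distance" in the source description is ambiguous between many-to-one and
one-to-one matching: the default keeps the literal per-post-point reading
(many-to-one allowed); `unique = TRUE` gives the one-to-one
interpretation via greedy global-minimum selection with deterministic tie
rules (selection distances are then non-decreasing by construction).
Neither is presented as the original authors' intent. Differential
features are post − pre per pair; pairs with a quality-rejected side are
dropped with a logged count, and delta maps are interpolated on the
post-phase geometry (the acquisition the drug effect lives on).

## 5. The synthetic generator: what a green test establishes

`make_rv_mesh()` builds a closed genus-0 surface (icosphere deformed to a
30 × 25 × 45 mm ellipsoid, roughly RV-sized) with a labelled outward
bulge standing in for the RVOT and a seeded ~2% smooth radial
irregularity. `make_study()` samples points area-uniformly, evaluates
user-supplied AT/ARI/Uni-JEl spatial fields, and builds each electrogram
from analytically placed components: a logistic downstroke (width
2.5 ms) whose steepest negative slope sits *exactly* at the prescribed
activation time; a fast logistic recovery (centre +14 ms, width 4 ms); a
T wave whose rising edge is a logistic of width 8 ms — its slope maximum
is exactly at activation + ARI, and being symmetric it cannot be shifted
by the symmetric derivative smoothing — with a compact cos² decay; and a
compactly supported ST ramp solved so the value at the study J-point
equals the prescribed Uni-JEl exactly. Compact supports keep the pre-QRS
baseline identically zero, which is what makes 10⁻⁶-mV-level Uni-JEl
recovery a meaningful test. Timing fields are snapped to the sampling
grid, so "recovery within ±1 sample" is well-defined. The synthetic V2
lead has its amplitude minimum exactly at the reference annotation, a
terminal-delay wave that places the detected J-point ≈ 58 ms after it,
and a second beat 1000 ms earlier for RR estimation. The template is
valid when activation precedes the study J-point by ≥ 12 ms; the
generator enforces this.

Stated-world defaults: sampling 1000 Hz, reference annotation 2000 ms,
woi (−100, 100) ms, QRS amplitude 2 mV, T amplitude 1 mV, white noise SD
0.05 mV in the noisy acceptance scenario, contact forces uniform on
2–30 g (straddling the 5–25 g filter on purpose), post-phase dropout
probability 0.36 (the published average map point loss), isotropic
positional jitter 0.5–1 mm.

What the generator does *not* emulate — and hence what a green suite does
not establish: biophysical electrogram genesis (no monodomain/bidomain
model), fractionated or multi-component electrograms, respiratory/cardiac
motion artefacts, beat-to-beat variability, far-field ventricular
components, or real CARTO export quirks. Green tests establish that the
*algorithms* implement their stated definitions exactly and behave
sensibly under additive white noise — not that the pipeline is validated
on clinical data.

## 6. Containers and formats

The native container is HDF5 with a fixed layout (`?save_study`): all
units mm/ms/mV/grams, indices 0-based on disk (1-based in R), trace
matrices point-major as seen by C-order readers, conventions recorded as
root attributes, and a `format_version` attribute checked on load.
Triangle indices are stored as 32-bit integers (sufficient for any
clinical mesh). OpenEP-style `userdata` import supports MAT v7.3 files —
which are HDF5 underneath, with MATLAB's transposed array layout behind a
512-byte header — locating the standard field names (`egmX`, `egmSurfX`,
`egm`, `ecg`, `referenceAnnotation`, `woi`, `triRep/X`,
`Triangulation`) at any nesting depth; older v5/v7 MAT files have no
parser among the dependencies and are rejected with instructions to
re-save with `-v7.3`. Points with entirely non-finite traces are flagged
invalid, not dropped, since the upstream representation of invalid points
is unspecified. Maps export as legacy ASCII VTK PolyData with one
point-data array per feature and NaN for missing; values are printed with
17 significant digits so read-back is bit-identical.

## 7. Numerical conventions worth knowing

* Argmin/argmax ties: earliest sample (signals), lowest index (points).
* Quartiles for the IQR: linear interpolation (R type 7); IQR values
  depend on this choice, so it is fixed and stated.
* SD uses the n−1 denominator and is reported missing for n = 1.
* Contact-force bounds are inclusive: the clinical rule discards strictly
  below 5 g or strictly above 25 g, so 5 g and 25 g survive. Missing
  forces are retained with a `force_unknown` flag (the rule is silent on
  them; discarding data silently seemed worse).
* The optional band-pass preprocessing (unipolar 1–240 Hz, bipolar
  30–500 Hz) replicates acquisition-side settings, is zero-phase (FFT
  brick wall, so fiducial timings do not shift), and is off by default:
  clinical exports are already band-limited.
* Degenerate (zero-area) triangles get area 0 with a warning rather than
  an error; point-to-triangle projection falls back to the nearest vertex
  for them.

## 8. Known limitations

Interpolation method `"linear"` is unavailable (above). The OpenEP
importer is tested against fixtures that mirror the documented v7.3
field layout, not against files produced by OpenEP itself (no clinical
data ship with the package). The J-point detector is a single-lead,
single-beat method; heavily fragmented or low-SNR surface leads should
use a different lead via `lead_for_jpoint`. Cohort-level statistics and
risk stratification are out of scope: the package produces per-study
reports that downstream analyses can aggregate.
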