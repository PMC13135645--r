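---
title: "Anatomy and wall-shear haemodynamics of arteriovenous fistulas with avfflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy and wall-shear haemodynamics of arteriovenous fistulas with avfflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avfflow)
```

## The problem

An arteriovenous fistula (AVF) — the surgical connection of a vein onto an
artery that provides vascular access for haemodialysis — matures only if the
vein remodels and dilates, and a large fraction of fistulas never do.
Remodelling is driven by local haemodynamics: wall shear stress (WSS) and its
temporal and spatial structure over the cardiac cycle. Those quantities are
not measurable directly in patients; they are obtained by segmenting the
lumen from angiographic imaging, reducing it to a centreline description
(diameters, curvatures, the anastomosis angle), simulating pulsatile flow,
and post-processing wall shear into summary metrics on short vessel
segments. `avfflow` implements that downstream analysis chain as reusable,
tested components, together with a synthetic geometry and flow generator so
that every stage can be validated without patient data, and a small cohort
statistics layer (group summaries and Mann–Whitney ROC analysis of
anatomical predictors of high venous outflow, at or above 1000 ml/min).

The package ships a 17-fistula cohort table (10 radio-cephalic, 6
brachio-cephalic, 1 brachio-basilic; 13 matured successfully) as
`load_avf_cohort()`; it is both the reference dataset for the statistics
layer and the source of realistic parameter ranges for the synthetic
generator.

## Synthetic fistula geometry

`build_end_to_side_avf()` models an end-to-side AVF as the union of two
swept circular capsules: a through-running artery (feeding and distal limbs)
and a vein leaving the junction at the design angle. The union is
polygonised by marching tetrahedra on a regular grid (Kuhn 6-tetrahedron
subdivision, which is translation-consistent and therefore yields a closed,
watertight, outward-oriented triangle mesh by construction). Choices a user
should know about:

* **Straight takeoff (default 20 mm).** Each limb leaves the junction
  straight before its constant curvature begins. This makes the designed
  anastomosis angle an unambiguous property of the geometry — measured
  tangent directions near the junction do not depend on how far from the
  junction they are fitted — and mimics the surgically handled
  juxta-anastomotic segment.
* **Helical tortuosity.** Real arm vessels with printed curvatures up to
  0.075 per mm cannot be planar arcs over a 100 mm window (the arc would
  close on itself once curvature times length reaches pi). Limbs whose arc
  would exceed that bound default to a helical path of the same constant
  curvature with torsion equal to the curvature; curvature summaries are
  unaffected, and the tube never self-intersects.
* **Tapered (spatulated) ostium.** Draining veins are usually wider than the
  artery they join. The vein enters through an ostium capped at 1.5 times
  the artery diameter (about the largest chord a side opening can offer) and
  expands linearly to its nominal diameter over the takeoff; explicitly
  requesting a wider ostium is rejected as geometrically impossible.
* **Anastomosis patch.** Faces are first attributed to artery or vein by
  nearest capsule; the weld seam is the set of edges where that attribution
  flips, and faces within one vein diameter of the seam are labelled
  `anastomosis`. The patch is excluded from all distance-indexed segments
  and from diameter sampling, and limb arclength starts (s = 0) at its
  boundary.
* **Round-trip truth.** The builder returns the analytic centrelines and the
  windowed summary implied by its own profiles over the same measurement
  windows. Validation compares pipeline output against that truth, so the
  ostium taper and takeoff are part of the reference, not error.

## Centrelines, diameters, curvature, angle

`extract_centreline()` marches cross-section centroids: cut the mesh with a
plane normal to the current direction, move to the area centroid of the
intersection polygon containing the current point, step forward, update the
direction. A first rough pass learns the local tangent at the seed (the
initial chord direction can be far from it on curved limbs); the second pass
is kept. Marching stops at an open section (end cap), at the anastomosis
patch, or at the far seed.

Equivalent diameter at a station is `2 * sqrt(A / pi)` from the cut-polygon
area. Because the polygon is inscribed in the smooth section, its area
carries a known deficit of order `1/n^2` in the vertex count n; the area is
multiplied by the regular-polygon factor `2 pi / (n sin(2 pi / n))`, which
removes the leading bias for near-circular sections and is what lets small
(2–3 mm) vessels be measured at the default 0.5 mm mesh resolution.

Pointwise curvature comes from local quadratic least-squares fits of the
coordinates against arclength over a sliding window (default 10 mm,
one-sided at the ends), i.e. the standard `|r' x r''| / |r'|^3` evaluated on
a locally smoothed curve. The window default is a compromise: long enough to
suppress extraction jitter (the noise test uses 0.1 mm point noise), short
enough not to flatten curvature radii around 15 mm.

The anastomosis angle is the angle between total-least-squares lines fitted
over 5 mm windows adjacent to the junction: the feeding-artery line directed
downstream (towards the junction) and the vein line directed away. Larger
values mean a more obtuse junction. Summaries average diameters (sampled
every 1 mm) and curvature over 0–100 mm of the feeding artery and draining
vein and 0–50 mm of the distal artery, truncated to the available length;
missing stations are excluded.

## Pulsatile wall shear and metric maps

`womersley_wall_shear()` produces the rigid-tube, axisymmetric pulsatile
flow solution for a waveform given as a steady component plus complex
harmonics (`flow_waveform()`, flows in ml/min at the interface, SI
internally). The steady part is Poiseuille shear `4 mu Q / (pi R^3)`; each
harmonic scales the classical oscillatory solution so its flow matches the
waveform, using Bessel functions of complex argument evaluated by power
series. Above a Womersley number of 40 (far beyond arm vessels at cardiac
frequencies) the harmonic switches, with a warning, to a finite-difference
solve of the radial momentum equation. Default blood properties are
viscosity 3.5e-3 Pa s and density 1050 kg/m^3 — conventional values for
blood, configurable everywhere they appear. The default cardiac period is
1 s and the default waveform preset is steady flow plus two harmonics (45%
fundamental with a quarter-cycle lag, 15% second harmonic), spanning the
physiologic unidirectional regime; a zero-mean `"oscillatory"` preset covers
the other end.

Metric maps over one cycle use periodic trapezoidal quadrature (the last
sample closes back to the first; a gap above a quarter period is an error):

* TAWSS, the time-averaged shear magnitude;
* OSI, `0.5 (1 - |mean vector| / mean magnitude)`, 0 for unidirectional and
  0.5 for zero-mean oscillation;
* transverse WSS, the time-averaged shear component perpendicular to the
  mean-shear direction. Faces with no mean direction are reported missing
  rather than zero — a purely oscillating face has no defined transverse
  axis, and conflating that with "no transverse shear" would bias segment
  means;
* WSSG, the magnitude of the intrinsic surface gradient of the TAWSS field,
  estimated per face by a least-squares fit over edge-connected neighbour
  centroids in the tangent plane (a time-averaged instantaneous-gradient
  variant is available via `time_average = TRUE`);
* LNH, the cosine of the angle between velocity and vorticity on a
  volumetric snapshot, conventionally taken at peak systole — defined as the
  sample of maximum reconstructed inflow, earliest sample on ties.

Segment means are area-weighted (face-count weighting would bias towards
finely meshed regions); the anastomosis segment is reported separately, and
partial trailing segments are kept but flagged.

## Lumped pressure network

The Ohm/Hagen–Poiseuille analogy for the fistula circuit is a three-node
nodal analysis (inlet, anastomosis, distal artery; venous outlet as the zero
reference) with Poiseuille limb resistances `8 mu L / (pi R^4)`, an
anastomotic resistance in series with the vein (reference: a 10 mm
juxta-anastomotic segment at half the vein radius, scaled by
`anastomosis_scale`), a collateral arterial path (20 times the feeding
resistance) and a peripheral runoff (9 times). The collateral/runoff ratio
places the distal flow-reversal threshold between the nominal configuration
(antegrade distal flow, maturation ordering
`P_inlet > P_distal ~ P_anastomosis > P_vein`) and the very-large-anastomosis
regime, where the anastomotic pressure collapses below the distal pressure
and the model flags reversal (arterial steal). The network is an ordering
model, not a calibrated physiological circuit; only pressure orderings and
the reversal flag should be interpreted.

## Cohort statistics

Group summaries use the population-SD convention (divisor n), which is the
convention that reproduces the shipped table's printed dispersions (e.g.
1.45 mm for the successful-group feeding-artery diameter, where divisor
n - 1 gives 1.51). ROC analysis is exhaustive Mann–Whitney pair counting
with ties counted 0.5 — the standard convention — cross-checked internally
against the trapezoidal area under the empirical ROC curve; orientation is
chosen so reported AUCs are at least 0.5, with the sign recorded. Under this
convention the feeding-artery-curvature AUC on the shipped table is 0.8125;
an AUC of 0.8194 is obtained only if the single tied pair is counted
concordant or if unrounded source measurements are used, so small
differences at the fourth decimal against externally reported values are
expected and documented rather than chased. The combined score is an
in-sample logistic regression on standardised predictors (ridge-penalised
fallback under separation, flagged); its AUC is reported as an in-sample
quantity and is guaranteed only to dominate its constituent single-variable
AUCs, not to estimate out-of-sample discrimination. Group-comparison
p-values default to the rank-sum test (small, non-normal samples; Welch
available) and are reported descriptively.

The cohort generator draws each anatomical variable per outflow group from
truncated normals (rejection sampling, bounded attempts), defaults taken
from the shipped table's High/Low group statistics, and assigns outflow
through a monotone flow link plus noise; the `outflow_category` column is
re-derived from the sampled outflow with the inclusive 1000 ml/min rule, so
it can disagree with the generating group exactly as measured categories
disagree with latent status. One integer seeds the whole table.

## What the synthetic data do and do not show

The generator emulates controllable lumen geometry in the observed
anatomical ranges and wall-shear time series spanning unidirectional to
fully oscillatory regimes. It does not emulate segmentation noise or imaging
artefacts, non-circular (diseased) cross-sections, wall compliance, or the
three-dimensional junction flow field — wall shear fields are analytic tube
solutions mapped onto the surface, not a Navier–Stokes solve. Passing
round-trip tests therefore demonstrates the correctness of the measurement
chain, not the fidelity of any flow prediction at a real anastomosis.

## Numerical choices and problem sizes

Grid spacing for polygonisation equals `mesh_edge_target` (default 0.5 mm;
the validation sweep uses the default, the shared unit-test fixture a
coarser 0.8–1 mm). Geometry validation runs the full pipeline on twelve
designs taken from rows of the shipped table (`avf_cohort_designs()`), checking
recovered diameters within 2%, curvatures within 10% and angles within 3
degrees against the builder's analytic truth; the finite-difference
wall-shear oracle uses at least 200 radial nodes and 20 periods. Centreline
marching steps 1 mm; degenerate inputs (repeated points, seeds outside the
lumen, disconnected cuts) raise errors rather than producing silent
results. All angles are degrees, lengths mm, shear Pa, flow ml/min at every
user-facing interface.

## Limitations

Equivalent-circle diameter is one of several defensible diameter measures
(maximum inscribed sphere is another); it was chosen because it is the
measure the cross-section area defines directly. Curvature is averaged
pointwise over the window, not taken from a global per-limb fit. The
supplementary formulas behind some published metric suites are not always
reproduced in print; the definitions here are the standard literature forms
stated above, and the WSSG variant switch exists precisely because that
definition varies between groups. The combined-ROC method behind published
multi-variable AUCs is typically unspecified; in-sample logistic scoring is
the reproducible choice made here.
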