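---
title: "Benchmarking lung SBRT plans prescribed to the mean ITV dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking lung SBRT plans prescribed to the mean ITV dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbrtbench)
```

## The problem

Pulmonary stereotactic body radiotherapy (SBRT) delivers a few very large
fractions to a small peripheral lung target. Institutions differ widely in
how they prescribe and normalize dose — to a covering isodose, to the
maximum, to the PTV median — and in the delivery platform (robotic
radiosurgery with cones, modulated beams or arcs, 3D-conformal fields) and
the dose-calculation algorithm. As a consequence, the dose the tumor
actually receives is hard to compare across centers even when the nominal
prescription is identical.

`sbrtbench` implements the analysis side of a multi-institutional planning
benchmark built around a *multiparameter* prescription: the dose (3 x
21.5 Gy, a biologically effective dose of about 203 Gy~10~) is normalized
to the **mean dose of the internal target volume (ITV)**, and a tiered set
of DVH-based objectives constrains PTV and ITV coverage, conformity and
hot spots, with protocol-defined "minor deviation" fallbacks. The package
normalizes voxelized dose distributions, computes the dosimetric metrics,
classifies plans against the protocol, and compares plan cohorts between
techniques and algorithms. A synthetic plan generator stands in for the
clinical submission pool so that every stage is testable end to end.

## The prescription and BED

A `prescription()` is `n` fractions of `d` Gy anchored to the mean ITV
dose; the default is 3 x 21.5 Gy = 64.5 Gy. Normalization multiplies the
whole dose array by `64.5 / mean ITV dose`, which makes the mean ITV dose
exactly 64.5 Gy, is idempotent, and scales every Gy-denominated DVH metric
linearly. Because the anchor is the *voxel-exact* occupancy-weighted mean
(never a binned-DVH readout), the normalization target is not quantized by
the DVH bin width.

Biologically effective dose uses the standard linear-quadratic form

$$\mathrm{BED} = D\left(1 + \frac{D/n}{\alpha/\beta}\right),$$

with $\alpha/\beta = 10$ Gy for tumor. The protocol's printed anchors are
reproduced under half-up display rounding (`display_round()`): 64.5 Gy in
3 fractions gives 203.175, printed 203 Gy~10~; the 90% level 58.05 Gy
gives 170.4, printed 170 Gy~10~; the 107%/110% hot-spot levels give
228/239 Gy~10~. One printed anchor is internally inconsistent in the
protocol literature: 112 Gy~10~ is quoted for the 70% threshold (45.2 Gy),
but the LQ form gives 113.3 for 45.2 Gy in 3 fractions; 112 is consistent
with 3 x 15 Gy = 45 Gy (BED 112.5, apparently truncated rather than
rounded). The package computes 112.5 for 3 x 15 and documents rather than
"fixes" the discrepancy.

Downstream objective thresholds default to the printed, rounded values
(45.2, 58.1, 69, 71 Gy), because that is what a protocol document
distributes to institutions; `default_objectives(basis = "percent")`
switches to the exact percent-derived thresholds
(45.15/58.05/69.015/70.95 Gy).

## DVH engine

The cumulative DVH is an occupancy-weighted histogram on a fixed 0.1 Gy
bin grid: the volume at level $e$ is the summed fractional voxel volume
with dose $\ge e$. Point metrics follow the conventions most planning
systems use:

* `D_x%` — dose received by at least x% of the structure, read from the
  curve with linear interpolation between bin edges. Interpolation is a
  choice, not a given: systems disagree, so a `strict` mode that snaps to
  the highest qualifying bin edge is provided for sensitivity checks.
  Interpolated values are capped at the maximum observed dose so a
  uniform structure reports its exact dose.
* `D 0.1 ml` — dose to the hottest 0.1 ml, same lookup with an absolute
  volume; ties resolve toward the higher dose, which is conservative for
  hot-spot objectives.
* `Dmean`, `Dmedian` — voxel-exact (weighted), never read from the binned
  curve. The weighted median equals `D_pct(50)` within one bin width; the
  voxel-exact form is used so that the normalization anchor and the
  reported means are exact.
* `V_d` — volume at dose d, as % of structure volume or absolute cm^3;
  percent-denominated outputs always state their denominator in the
  column name (`..._pct` of structure volume vs `..._gy` thresholds from
  the prescription).

No interpolation of dose *between voxels* is performed anywhere: the
curve is exact for the voxelized structure, and isodose volumes for the
conformity indices are occupancy-weighted voxel counts (no surface
meshing). That is the volume convention of the whole package.

## Conformity, gradient and the protocol

With $V(d)$ the total volume receiving at least $d$, $TV$ the PTV volume
and $TV_{PIV}$ the PTV volume covered by the prescription isodose
(45.2 Gy, the printed 70% level; the half level is the printed 22.6 Gy,
not a recomputed 45.15/2):

* $CI_{RTOG} = V(45.2)/TV$ — spillage-sensitive conformity;
* $CI_{Paddick} = TV_{PIV}^2 / (V(45.2)\cdot TV)$ — joint
  coverage/spillage, in [0, 1];
* $GI = V(22.6)/V(45.2)$ — low-dose-bath steepness, always $\ge 1$.

These satisfy $CI_{Paddick} \times CI_{RTOG} = (TV_{PIV}/TV)^2$ exactly
under the shared volume convention, which the tests assert to 1e-12.

The objective checker applies the tiered protocol in its printed order
(PTV coverage, ITV coverage, conformity, hot spot), each with its minor
tier (relaxed metric D90% for the coverage rows, relaxed limits for CI
and D0.1 ml), plus hard organ-at-risk rules (spinal canal D0.1 ml < 18 Gy,
chest wall V30Gy < 30 ml) and a report-only ALARA entry for the lungs.
Comparisons are strict inequalities as printed; boundary equality fails
the main tier, a deliberate reading since the protocol does not address
exact-boundary cases. A plan is excluded from cohort analysis when any
objective reaches VIOLATION, or — regardless of dosimetry — when it was
calculated with a pencil-beam algorithm, which is non-compliant for lung
SBRT. Plans with minor deviations (even several) remain included and the
report flags the count.

## The synthetic cohort generator

No clinical plan data are distributable, so the generator emulates the
benchmark's two phantom patients and the statistical structure of a
submission pool. It is first-class, tested code — the study conditions,
not a tuning knob.

**Phantoms.** Each patient is an ellipsoidal ITV; the PTV is the exact
morphological dilation by the 5 mm margin, computed from the analytic
signed distance to the ellipsoid surface with a one-voxel partial-volume
ramp. The ITV semi-axes are iterated so the rasterized PTV volume lands
within 1% of the requested target (23.8 cm^3 for patient 1, 19.4 cm^3 for
patient 2). Patient 1 sits against the chest-wall slab; patient 2 is
distant from it. Lungs are boxes, the spinal canal and esophagus are
cylinders, all on a 2.5 mm lattice of 64 x 54 x 54 voxels — small enough
that a 57-plan cohort simulates in seconds, fine enough that DVH metrics
are stable to well under one bin width.

**Dose model.** Dose is a function of the signed distance to the PTV
surface: a plateau with a central hotspot inside the ITV, a logistic drop
across the PTV shell, an exponential falloff outside (halving every
`falloff_scale_mm`, steepening in the far bath), a flat ~0.8 Gy scatter
floor, and clipped Gaussian noise. No beam transport is simulated — the
analytics only ever see the dose field, so a falloff model suffices and
keeps the generator desk-scale. Two mechanisms beyond a radial profile
proved necessary to reproduce the joint behaviour of real cohorts:

* the *shell drop position* separates the techniques: robotic cone plans
  drop the dose early in the shell (lowest mean PTV dose, steepest
  gradient), 3D-conformal plans keep the shell hot (highest mean PTV
  dose, largest spillage), modulated plans sit between — giving the
  characteristic RRS < MOD < 3D ordering of the mean PTV dose after
  normalization;
* a smooth random *directional wobble* of the isodose radii (first- plus
  second-order directional harmonics, ~1 mm amplitude) emulates imperfect
  conformity. A perfectly conformal radial model cannot simultaneously
  show PTV coverage below 100% and a conformity index above 1; the wobble
  decouples the two exactly as real plans do.

Per-institution variation comes from uniform jitter on the falloff scale,
surface level, hotspot and wobble amplitude of the group profile, with
algorithm labels apportioned per technique (robotic units Monte Carlo
only; modulated mostly Boltzmann-transport/AAA; 3D mostly collapsed cone;
a small pencil-beam share that downstream analysis excludes). One master
seed expands to per-plan substreams by a counter scheme, so cohorts are
reproducible and order-independent.

**Calibration.** The default profiles were calibrated once against the
benchmark's published distribution bands — conformity index within
[1.05, 1.2], gradient index within [3.4, 6.7], mean PTV dose medians near
56/57/57.5 Gy in the RRS/MOD/3D order, D2% and D0.1 ml around 67.5–69 Gy,
ITV V90% around 98–100% — and frozen; `scripts/calibrate_profiles.R`
reproduces the survey. Every default-profile plan passes the full
protocol after normalization, on both phantoms, which is the generator's
self-consistency invariant.

**What the generator does not emulate.** Beam/arc geometry, MLC
sequences, tissue heterogeneity, breathing traces, and TPS-specific
partial-volume handling are all out of scope. Two visible consequences:
the flat chest-wall slab cannot wrap around the lesion, so patient 1's
chest-wall V30Gy comes out around 2–5 ml where a wrapped anatomy yields
~7 ml (the <30 ml constraint behaviour is unaffected); and OAR doses are
only order-of-magnitude realistic. Passing tests therefore demonstrate
the correctness of the *analysis pipeline* under realistic dose
statistics, not the realism of any individual synthetic plan.

## Cohort statistics

Group summaries report median (midpoint convention), mean and sample
standard deviation (n−1; reported absent for single-plan groups) per
metric per group. Group differences use a from-scratch tie-corrected
Kruskal–Wallis test on midranks,

$$H = \frac{12}{N(N+1)} \sum_i n_i\left(\bar r_i - \frac{N+1}{2}\right)^2
  \Big/ \left(1 - \frac{\sum_t (t^3-t)}{N^3-N}\right),$$

with the p-value from the $\chi^2_{k-1}$ upper tail, the standard
large-sample treatment; an exact permutation p-value is available for
total $N \le 12$ where enumeration is feasible. All values identical is
handled as $H = 0$, $p = 1$ by convention. The implementation is
cross-checked in the tests against `stats::kruskal.test` and against full
permutation enumeration; its empirical type-I error at $\alpha = 0.05$
is verified to sit in [0.04, 0.06] over 10,000 null simulations.

The multiplicity policy is selective, mirroring a study design with one
primary endpoint: the primary metric (mean PTV dose) is tested
uncorrected, every other tested metric is Holm–Bonferroni adjusted within
the family, significance at 0.05. The protocol literature does not name
its correction; Holm was chosen because it uniformly dominates Bonferroni
without distributional assumptions, and the policy is recorded in every
statistics report. Which metrics form the family is configurable
(`multiplicity_family`) and reported, since reasonable analysts could
correct over all metrics or targets only. Patients are analyzed
separately by default (each patient is its own cohort), matching how
per-patient summary tables are reported.

## Numerical choices and degenerate inputs

* DVH bin width 0.1 Gy throughout; metrics derived from the curve are
  therefore accurate to one bin width, which the oracle tests assert.
* The 3D Euclidean distance transform (for mask-derived distances and
  any non-ellipsoidal dilation) is the exact two-pass lower-envelope
  algorithm, implemented in C++ with anisotropic spacing.
* Point-to-ellipsoid distance solves the foot-point equation by
  vectorized bisection (48 iterations); deep interior points beyond the
  evolute on an axis plane fall back harmlessly inside the dose plateau.
* A uniform dose field has no prescription isodose surface: conformity
  indices error out ("prescription-isodose volume is zero") rather than
  return 0/0.
* `D_absvol` beyond the structure volume, percentiles outside (0, 100],
  zero-volume masks, mismatched lattices, non-normalized plans entering
  the objective checker: all are explicit errors, never silent NA.
* Internal container files store float64 little-endian arrays after a
  text header; round-trips are exact. DICOM ingestion supports
  explicit-VR little-endian RT Dose / RT Structure Set pairs with
  axis-aligned grids, rescales by the dose-grid scaling attribute, and
  rasterizes planar contours with 3x3 in-plane supersampling (fractional
  mode) or voxel-centre membership (binary mode) — both offered because
  planning systems disagree on partial-volume handling, and that
  disagreement is itself a finding of multi-institution benchmarks.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run cohorts of 57 plans per
phantom on the 64 x 54 x 54 default lattice, 100 random 8–16³ grids for
the DVH oracle comparison, 1,680-assignment exact permutation nulls, and
10,000 null simulations for the type-I-error check — sizes chosen so the
whole suite completes in about a minute on a laptop-class single core
while leaving every statistical check well-powered.

## Limitations

The generator's realism claims are distributional, not per-plan; its
parameters emulate, they are not inferred from data. The DICOM reader is
an ingestion convenience for the common export syntax, not a general
DICOM implementation (no compressed transfer syntaxes, oblique grids, or
holes in contours). OAR dosimetry other than the constrained structures
is indicative only. Cross-patient pooling is provided but the per-patient
analysis is the defended default.
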