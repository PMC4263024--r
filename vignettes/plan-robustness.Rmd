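---
title: "Assessing setup-error robustness of scanned ion-beam plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing setup-error robustness of scanned ion-beam plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pbsrobust studies a question that matters clinically in scanned carbon-ion
and proton therapy of skull-base tumours: how much does a treatment plan's
delivered dose deteriorate when the patient is set up a millimetre or two
away from the planned position? Charged-particle dose distributions are
shaped by the water-equivalent path length (WEPL) traversed by each pencil
beam; where the entrance channel crosses strong density interfaces
(bone/air), a small transverse displacement turns into a range error and
can carve cold spots into the target even when the displacement is smaller
than the planning margin. The package provides the whole pipeline needed to
quantify this: seeded heterogeneous phantoms, a pencil-beam dose engine,
inverse spot-weight optimization, a complete enumerated battery of rigid
setup shifts recomputed at frozen weights, dose-volume metrics and
population statistics.

This vignette is the package's account of its models and the choices made
where the design was genuinely open. All quantitative statements about
package behaviour are reproduced by the test suite
(`tests/testthat/`) and by `scripts/acceptance.R`; nothing here is claimed
beyond what those compute.

## The dose model

The engine is a deliberately simplified scanned-pencil-beam model, chosen
so that every one of its properties is testable against closed forms or
brute-force evaluation:

* **Parallel-beam geometry.** Pencils travel along the beam direction with
  no divergence. This is the standard pencil-beam simplification and makes
  the model's key identity exact: a rigid shift of the irradiation fields
  along a beam's axis changes neither any ray's WEPL nor any lateral
  offset, so the dose to the anatomy is bit-identical. Transverse shift
  components simply translate the spot lattice relative to the anatomy.
* **WEPL ray tracing.** The WEPL to a voxel is the line integral of
  relative water-equivalent density from the grid boundary (plus any bolus
  water-equivalent thickness) along the direction, by midpoint sampling.
  The pointwise tracer uses a 0.5 mm step. The per-beam voxel maps use an
  exact cumulative-sum integral for axis-aligned beams and, for oblique
  beams, the same midpoint rule with the step set to
  `max(0.5, min(spacing)/2)` so that coarse study grids trace in
  proportionate time; on the fine unit-test grids this reduces to 0.5 mm.
* **Depth dose.** An analytic Bragg curve: a power-law entrance plateau
  `p0 + p1 (z/R)^2` smoothly cut off at the range by a Gaussian CDF, plus a
  Gaussian peak of width `sigma_z` centred at the range, normalized to 1 at
  `z = R`. `sigma_z` plays the role of a ripple filter: it is matched to
  the in-depth peak step (3 mm carbon with `sigma_z` = 2 mm; 2 mm proton
  with 3 mm, protons being intrinsically broader) so that layers stacked at
  the step produce a flat spread-out peak with sub-percent ripple. The
  entrance plateau is about 0.25 of the peak with the defaults; an optional
  exponential fragmentation tail is off by default so the distal falloff
  contract (below 1% of the peak at five falloff widths) holds.
* **Lateral profile.** A separable Gaussian with the in-air FWHM used at
  all depths (no depth broadening by default; the machine data behind a
  depth-dependent widening are machine-specific and not part of this
  model). FWHM varies linearly between the species' endpoints over the
  machine range span, 7.5-5.0 mm for carbon and 11.0-5.5 mm for protons
  over 20-300 mm WEPL; the interpolation *shape* between the endpoints is
  not physically constrained, and linear is the declared choice.
* **RBE.** Protons use the fixed clinical factor 1.1. Carbon uses a
  monotone piecewise-linear surrogate factor in residual range (3.0 at the
  end of range falling to 1.3 in the plateau). This is explicitly *not* a
  microdosimetric model: it preserves the qualitative structure that
  matters here (higher weighting near end of range, plan-level
  prescriptions in Gy(RBE)) while staying configuration-level. The factor
  field of a plan is frozen during optimization and during shift
  recomputation, so robustness deltas are not confounded by RBE model
  feedback.

The engine evaluates axis-aligned beams by exact separable superposition
(it agrees with an independent brute-force per-voxel triple sum to machine
precision); oblique beams use a 1 mm lateral fluence map with bilinear
interpolation and agree with brute force to a few percent.

## Phantoms

No patient images ship with the package; the generator emulates the
planning situation instead. A `phantom_spec` fixes grid shape and spacing,
the admissible CTV volume range (default the clinical range 15.6-90.7
cm^3), and the heterogeneity archetype: a lateral bone slab whose
posterior/superior edges cut through the target's beam's-eye footprint, an
air cavity in the mediolateral entrance channel, a skull shell, and
soft-tissue density noise. The brainstem is built abutting the PTV (the
overlap of a posterior cylinder with the PTV is carved away, guaranteeing
zero surface distance), with paired optic nerves and chiasm anterior of the
target. The CTV-to-PTV expansion applies 2 mm margins mediolaterally and
anteroposteriorly and 2.5-3 mm superoinferiorly following the slice
spacing, with voxel-centre-in-ellipsoid inclusion so an exhaustive
anisotropic-distance oracle can check it. Generation is a pure function of
(spec, seed).

What the phantoms do *not* emulate: real anatomical texture, immobilization
devices, contouring variability, and CT calibration uncertainty. Passing
the package's tests therefore demonstrates the *mechanism* (interface-driven
robustness loss and its mitigation by beam choice), not clinical effect
sizes; the quantitative deltas depend on the archetype's geometry, which
is configurable because no canonical quantification of "severe
heterogeneity" exists.

## Inverse planning

`optimize_plan()` minimizes a convex quadratic over non-negative spot
weights: the mean squared deviation of the RBE-weighted PTV dose from the
prescription (normalized by the prescription squared) plus one-sided
quadratic overdose penalties for each constrained OAR (normalized by the
limit squared, relative weight 50 by default). The brainstem constraint is
a near-maximum pair: the strict limit applies away from the PTV, and
voxels within 3 mm of the PTV may reach the relaxed surface limit (54 and
60 Gy(RBE) for carbon, 60 and 63 for protons).

The solver is a spectral projected-gradient method on the non-negative
orthant (Barzilai-Borwein steps, non-monotone line search); weights are
non-negative by projection at every iterate, never by clipping afterwards.
It starts from the uniform weight that sets the mean PTV dose to the
prescription, and stops on a relative objective change below 1e-6, an
absolute objective below 1e-7 (an RMS target deviation well under 0.1%),
or an iteration cap (default 500). Everything is deterministic.

Modes mirror clinical practice. `uc` drops the OAR terms. `mc` optimizes
all fields jointly. `sc` optimizes each field separately to a uniform
`1/n_fields` share of the prescription with the OAR limits scaled by the
same factor, then sums the fields — whether single-field clinical plans
share the target dose equally is not standardized, and the equal split is
the declared reading; it guarantees that fields summing to the
prescription individually respect the scaled limits. Where target coverage
and OAR sparing conflict, the penalties trade them off and the plan
reports the compromised coverage rather than failing.

Raster parameters follow the species: pitch 2 mm (carbon) / 3 mm
(proton), peak steps 3 / 2 mm, and a lattice dilation of
`tolerance * FWHM` beyond the per-layer target projection. The machine
"tolerance" parameter is interpreted as this transversal dilation radius
(the alternative reading — optimizer freedom at the border — is not
modelled); the default 0.7 sits mid-way in the 0.4-1.0 clinical band.
Targets shallower than the 20 mm minimum machine range raise an error
that names the remedy (a bolus), mirroring how such cases are planned.

## Metrics

All indices are functions of the dose multiset within a mask. V95 is exact
counting. D2%, D98% and D1% interpolate the empirical quantile function
linearly (`stats::quantile` type 7), which is stable across DVH bin widths;
the binned cumulative curve (0.1% of prescription per bin) is kept for
export and plotting only. HI = D2% - D98% is reported in percentage points
of the prescription. The conformity index is the van't Riet conformation
number `(TV_PIV/TV) x (TV_PIV/PIV)` at the 95% isodose — the published CI
variants differ, and the conformation number is adopted because it is
bounded in [0, 1] like the values this package is compared against.

## The robustness procedure

`enumerate_shifts()` builds the complete set of rigid shifts whose
components are each `0` or `±c` with equal magnitudes where non-zero and
whose 3-D length lies in the requested set: 26 vectors per magnitude, 52
for the canonical {1, 2} mm battery. `predict(plan, shift)` recomputes the
dose with frozen weights by translating every field's spot lattice by the
shift's transverse component in that beam's frame; the anatomy, the WEPL
maps, and the structure masks stay fixed, and indices are always evaluated
against the unshifted masks (the field-shift formulation implies this
reading, which is the one adopted). The zero shift is bit-exact by
construction, and a shift along a beam's axis leaves that beam's dose
bit-identical.

Deltas are signed `shifted - initial`, so a coverage loss is negative.
Population summaries report median, quartiles and extremes per index plus
the fraction of records with `|delta|` below the conventional thresholds
(1 pp for V95 and HI, 2 Gy(RBE) for OAR doses). Paired comparisons use the
exact two-sided binomial sign test at 0.05 with ties dropped — the
classical convention.

## Beam-setup selection

Clinically, robust beam directions are chosen by looking for entrance
channels free of density interfaces. `heterogeneity_score()`
operationalizes that visual judgement: the mean over target voxels of the
spread (max - min by default; standard deviation per option) of the WEPL
under small transverse probe shifts (the transverse projections of the
1 mm shift set by default). The score is zero in laterally homogeneous
media and grows with exactly the lateral WEPL gradients that convert setup
errors into range errors. OAR geometry is deliberately ignored — sparing is
the optimizer's job downstream. `select_robust_setup()` ranks feasible
candidate directions (a cranial-yaw x inclination grid on both patient
sides) and returns the lowest-scoring pair subject to a minimum angular
separation, with exhaustive search for two beams and deterministic
enumeration-order tie-breaks. No numeric score threshold separates
"robust" from "non-robust": selection is purely rank-based.

## Problem sizes and numerical choices

The shipped studies run on sizes chosen to make the full pipeline
convenient on a laptop-class machine: unit tests use 20-32 voxel grids at
1-2 mm; the identity checks use a 60^3 phantom at 2 x 2 x 2.5 mm; and the
beam-setup comparison uses ten seeded phantoms on 44^3 grids at 3 mm with
CTV volumes from the lower part of the clinical range (16-26 cm^3), probed
with the eight magnitude-2 shifts orthogonal to the lateral axis. Those
battery plans cap the optimizer at 120 iterations — comfortably past the
point where coverage objectives are met. Dense-matrix work is fastest with
a single BLAS thread at these sizes, which the test setup configures
explicitly.

Degenerate inputs are rejected rather than repaired: empty masks, empty
targets, non-positive magnitudes, shifts that move every spot off the grid
support, constraints referencing missing structures, and phantom specs
whose target cannot fit the grid all raise errors with the offending
quantity named.

## Known limitations

The dose engine has no nuclear fragmentation build-up, no scatter kernels,
no measured base data and no Monte Carlo reference; the carbon RBE factor
is a surrogate; rotational setup errors, fractionation-averaged cumulative
dose, range uncertainty and anatomical change are out of scope. The
package's conclusions are therefore about the *relative* robustness of
optimization modes, beam setups and species under rigid translational
errors in phantoms engineered to contain the interface failure mode — the
regime its design targets.
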