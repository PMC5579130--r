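---
title: "Methods: direct-controlled calibration of annulus fibrosus mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct-controlled calibration of annulus fibrosus mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteodisc)
```

## What the package models

`osteodisc` implements a complete characterisation-and-calibration chain for
the mechanics of the intervertebral disc's annulus fibrosus, built around
three experimental stages and their in-silico counterparts:

1. **Pre-strain (hoop strain) characterisation.** A radial cut through the
   annulus of an excised disc releases the circumferential residual strain;
   the disc opens by an angle $\varphi$. Assuming the disc stays circular
   with unchanged diameter, the hoop strain needed to close the opened ring
   is $\varepsilon_h = \varphi/(2\pi - \varphi)$. The circularity assumption
   itself is quantified by the *circularity deviation*: the sample standard
   deviation of six caliper diameters divided by their mean (0 for a
   circle, 0.592 in the infinitely elongated limit).

2. **Functional extrafibrillar-matrix modulus.** Single-lamella tension
   curves perpendicular to the fibres are restricted to the *functional*
   strain range $[\varepsilon_h, \varepsilon_{fail}]$ — the range the
   matrix actually works in, given its in-situ pre-strain — and the
   ordinary least-squares slope there defines the functional modulus
   $E_{f}$. Pearson's correlation over the same range quantifies how linear
   the tissue is in that window. Through incompressible neo-Hookean
   small-strain equivalence, $C_{10} = E_f/6$ (1.5 MPa $\to$ 0.25 MPa).

3. **Inverse calibration of the fibre parameters.** Osteodiscs (disc plus
   two half-vertebrae potted in PMMA) are compressed to 2100 N, with
   displacements re-zeroed at a 10 N preload. A reduced-order axisymmetric
   finite-deformation model of the specimen is driven to the same
   displacement, and the two parameters of the exponential fibre term of a
   Gasser–Ogden–Holzapfel (GOH) annulus model, $k_1$ (MPa) and $k_2$ (–),
   are found by bounded quasi-Newton (L-BFGS-B) minimisation of the RMS
   load difference between the measured and simulated curves.

## Constitutive models

The annulus uses the GOH form with isochoric invariants:
$$\Psi = C_{10}(\bar I_1 - 3) + \frac{1}{D}\Big(\frac{J^2-1}{2} - \ln J\Big)
 + \frac{k_1}{2k_2}\sum_{i=1,2}\Big[e^{k_2 \langle \bar E_i\rangle^2} - 1\Big],
 \qquad \bar E_i = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_{4i} - 1).$$

The two fibre families lie at $\pm\alpha$ (default 20°) to the transverse
plane in the circumferential–axial plane, with perfect alignment
($\kappa = 0$) by default. A family contributes only in tension: the switch
is applied per family on the isochoric invariant, $\bar I_{4i} > 1$. The
volumetric convention $U = (1/D)\,((J^2-1)/2 - \ln J)$ implies $D = 2/K$;
water's bulk modulus $K = 2200$ MPa gives the printed
$D = 9.09\times10^{-4}$ MPa$^{-1}$, which fixed this convention choice.

The nucleus pulposus is an incompressible Mooney–Rivlin solid. Full
incompressibility is realised as a volumetric penalty of $10^4$ times the
small-strain shear modulus $2(C_{10n}+C_{01n})$ rather than a
Lagrange-multiplier pressure field: an almost-incompressible (water-bulk)
nucleus was indistinguishable from an incompressible one in the sensitivity
study, so the simpler penalty is adequate. The nucleus coefficient defaults
($C_{10n} = 0.12$, $C_{01n} = 0.03$ MPa) are a modelling choice constrained
only by the requirement that the nucleus be noticeably softer than the
annulus; the nucleus-modulus sensitivity study shows the response is
insensitive to them in the downward direction. Bone is homogenised to a
single linear-elastic modulus (409 MPa, the volume average of the
image-based per-element mapping it replaces) and PMMA to 1.5 GPa, both with
$\nu = 0.3$, realised as compressible neo-Hookean solids that coincide with
linear elasticity at the small strains these regions see.

All stresses are analytic derivatives of the energies; the test suite
checks them against central finite differences of the energy over seeded
random deformations to $10^{-6}$ relative error.

## The reduced-order forward model

The specimen is modelled axisymmetrically: a stack of PMMA endcap, bone,
disc (nucleus core + annulus ring), bone, endcap on the $(r, z)$
half-plane. This is the decisive desk-scale reduction relative to
image-based 3D meshes, and rests on the measured near-circularity of bovine
caudal discs (circularity deviation below 0.06) and the purely axial load
case. Under axisymmetry the experiment's free transverse translations are
automatic (the net transverse force vanishes identically), and torsion,
flexion and endplate concavity are out of scope.

Discretisation uses bilinear quadrilaterals with 2×2 Gauss quadrature for
the isochoric response and a single centroid point for the volumetric
pressure (selective reduced integration), which avoids volumetric locking
in the nearly incompressible nucleus and annulus. Element tangents are
numerical (forward differences of the analytic internal force), assembled
sparsely and solved with `Matrix`; load is applied as prescribed axial
displacement of the proximal face in increments, with Newton iteration and
adaptive bisection of increments on non-convergence. Because the materials
are hyperelastic and the problem quasi-static, the solution is
path-independent: halving the increment count changes the final force by
less than 0.5 %.

Two discretisation facts matter for interpretation:

* On a homogeneous specimen the element converges fast (halving the
  element size changes the final force by ≈ 0.1 %). On the real layered
  specimen the perfectly bonded junction between the very soft annulus
  (≈ 0.5 MPa shear) and much stiffer bone (409 MPa) forms a classical
  bi-material free-edge singularity at the outer rim, which slows global
  force convergence to roughly first order: successive mesh halvings move
  the 2100 N force by ≈ 2 %. The working resolutions therefore carry a
  few-percent discretisation offset — smaller than the inter-specimen
  variation the pipeline is designed to resolve, and irrelevant to the
  calibration studies, which use the same mesh for data generation and
  fitting.
* The experiment is load-limited (2100 N) while the model is
  displacement-driven; `displacement_for_target_load()` finds the matching
  displacement by stepping with secant refinement to within 1 %.

Default problem sizes: the package-wide default mesh
(`mesh_resolution()`: 3+3 radial, 4/3/2 axial elements per region,
≈ 100 nodes) solves a full compression curve in well under a second; the
test and acceptance runs use this scale or slightly coarser so that entire
calibration studies complete in seconds to a few minutes.

## Response characterisation and the calibration cost

Force–displacement curves are summarised by a continuous tri-linear fit:
three slopes (initial, transition, linear stiffness) and two breakpoints,
found by exhaustive search over sample-pair breakpoints (at least two
samples per segment, ties to the smallest pair) followed by Nelder–Mead
refinement, so the fitted SSE is never worse than the best grid pair. On a
smoothly curving response the segmented fit's optimum depends on how the
curve is sampled; wherever model and experiment stiffnesses are compared,
the model curve is therefore resampled onto the experimental displacement
grid first.

The calibration cost is the RMS *difference* in newtons — not a relative
error — interpolated onto the experimental grid over the common
displacement range. The absolute form deliberately under-weights the small
toe-region forces, where boundary-condition artefacts live, relative to the
linear zone. Within the cost the simulated curve is sampled at twice the
protocol's step count so interpolation onto the experimental grid does not
bias the minimiser.

Calibration stops when either experimental rule fires: RMS below
`rms_frac` (default 5 %) of the maximum experimental force (105 N at
2100 N), or both parameters changing by less than `param_change_frac`
(default 5 %) between successive optimizer iterations; a forward-solve
budget backstops both. Gradients are central finite differences with a
relative step of $10^{-3}$ — one-sided differences proved too noisy deep in
the cost valley. These 5 % rules are convergence shortcuts of the
experimental protocol, not precision devices: recovery studies that need
the true optimum disable them (tiny `rms_frac`, negligible
`param_change_frac`) and let the search run to stationarity.

## Identifiability: what calibration can and cannot recover

Noise-free self-consistency experiments (pseudo-data generated by the same
forward model) recover the fibre pair accurately: over seeded truths drawn
log-uniformly in $[0.5,3]\times[1,3]$, median recovery errors are below
0.5 % for $k_1$ and about 2 % for $k_2$, and the central case
(truth 1.43/1.63, literature start 2.45/2.17) recovers both to well under
1 %/2 % in a few dozen forward solves.

With realistic force noise (≈ 2 % of the maximum load) the picture changes
qualitatively: the cost surface has a flat curved valley along which a
lower $k_1$ trades off against a higher $k_2$, and single-curve calibration
then identifies the pair only up to that valley — parameter errors of tens
of percent coexist with fits at the noise floor. This mirrors the large
per-specimen scatter of calibrated values in the source experiments and the
caveat that the optimisation solution need not be unique. Consumers of
calibrated pairs should compare predicted responses, not raw parameter
values. Truths with weak fibres (low $k_1$) are the worst-identified, since
$k_2$ then barely influences the response at all.

## Agreement statistics

Agreement between stiffness triples (model vs experiment, or sensitivity
variant vs baseline) uses Lin's concordance correlation coefficient with
population (1/n) moments,
$\mathrm{CCC} = 2 s_{xy}/(s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, pooling
the three stiffness values of every specimen into one comparison (a
per-stiffness breakdown is available from the stiffness tables). The 95 %
interval uses the Fisher $z$ transform with Lin's asymptotic variance; the
interval method is reported with the outputs because the source protocol
does not state one. The slope and intercept accompanying the CCC are plain
least squares of the computational on the experimental values, matching the
orientation of the agreement plots. Shapiro–Wilk plus two-sided paired $t$
tests (via `stats`) compare the repeat-measurement states in the opening
study, and Pearson's correlation quantifies lamella linearity.

## The synthetic cohort

Because the original specimens are not redistributable, every input the
pipeline consumes has a seeded generator whose defaults *are* the reported
study conditions: 5 opening-study discs (10-min opening angle
49.6° ± 9.2°, nucleus-to-annulus ratio 0.51 ± 0.05, six repeat measurements
per quantity), 16 lamellae (functional modulus 1.5 ± 0.7 MPa, toe ending
near the hoop strain, failure drawn in (0.4, 3.0)), and 12 osteodiscs
(diameter 30 ± 2 mm, height 9 ± 1 mm — typical bovine caudal dimensions,
chosen once as defaults since the source reports none — compressed to
2100 N with a 10 N preload). Per-specimen true fibre pairs are log-normal
around (1.43, 1.63) with spreads implied by the reported per-specimen
ranges (0.60–2.69 and 1.10–2.63). Distributions are truncated to physical
validity; repeat-measurement noise defaults to 2 % of the measured quantity
(assumed — the within-disc repeat spread was not reported); the
20–25-minute opening angle adds a non-negative increment
(13° ± 5°, consistent with the reported rise of mean hoop strain from 17 %
to 21 %). Pseudo-experimental compression curves are forward-model output
plus a random seating offset (the structure the preload zeroing removes)
and i.i.d. Gaussian force noise (default 20 N ≈ 1 % of maximum load).

What the generators deliberately do **not** emulate: image-based geometry
(endplate concavity, non-circular sections), inter-lamellar structure,
time-dependent relaxation between the two opening states, hydration, or
model discrepancy between generating and fitting model. Noise-free
calibration tests on this cohort are therefore self-consistency
("inverse-crime") checks: they validate the inverse machinery, not the
physical fidelity of the forward model. A configurable multiplicative
perturbation of generated curves is not included; robustness beyond the
self-consistent setting is probed through the additive-noise path.

## Sensitivity studies

Four studies re-solve each specimen at its baseline 2100 N displacement and
compare stiffness triples against the baseline via CCC/slope/intercept:

* **Nucleus compressibility** — incompressible (baseline), $\nu = 0.4999$
  (water-like bulk; indistinguishable from incompressible), $\nu = 0.49$
  (bulk four orders of magnitude lower; clearly softer).
* **Nucleus modulus** — both Mooney–Rivlin coefficients ×0.1 / ×10 with the
  volumetric penalty pinned at the baseline shear scale (the nucleus stays
  incompressible while its deviatoric stiffness is scaled). ×0.1 leaves the
  linear-zone stiffness within 2 %; ×10 stiffens the specimen.
* **Disc size** — the central disc diameter changed by ±5/10/15 % as a
  barrel morph: full change at mid-height, none at the endplates, whose
  diameter stays consistent with the bone; the nucleus scales
  proportionally so the NP:AF ratio is preserved. Its stiffness effect is
  secondary to the inter-specimen variation.
* **NP:AF ratio** — nucleus diameter 0.4/0.5 (baseline)/0.6 of the disc
  diameter: a larger nucleus softens the specimen, a smaller one stiffens
  it, most visibly in the transition and linear zones.

The fibre parameters for all sensitivity runs default to the literature
pair (2.45, 2.17).

## Numerical choices and degenerate inputs

* Angles are radians internally; CSV interfaces carry degrees explicitly.
* The six repeat measurements are averaged before derived quantities; the
  per-repeat values remain in the records for repeatability analysis.
* Failure-strain detection (when not supplied): first sample after the
  global stress maximum with a ≥ 5 % drop, else the last sample.
* The functional-modulus fit is ordinary least squares (strain is the
  controlled variable), and constant-stress windows return a zero modulus
  with an `NA` correlation and a degenerate flag rather than an error.
* Perfectly linear force–displacement data yield a tri-linear fit with
  three equal slopes, interior breakpoints, and a degenerate flag.
* Newton convergence is an absolute residual criterion scaled by the
  current internal force (relative $10^{-9}$); element inversion or
  non-finite residuals trigger increment bisection (down to 1/256 of the
  increment) before a solver error carrying the last converged
  displacement is raised.
* The calibration objective penalises (rather than aborts on) forward
  failures at trial points, and errors out after ten consecutive failures.

## Known limitations

* The axisymmetric reduction cannot represent endplate concavity or any
  non-axial load; the model is for quasi-static axial compression only.
* The bonded soft/stiff free edge makes pointwise fields near the annulus
  rim mesh-sensitive; reported forces carry a few-percent discretisation
  offset at the working resolutions (see above).
* Fibre dispersion $\kappa > 0$ is accepted by the parameter container and
  the energy, but all studies here use $\kappa = 0$.
* Viscoelasticity, osmotic swelling and hydration control are out of
  scope; the 1 mm/min experimental rate is not modelled (rate-independent
  hyperelasticity).
* The real-cohort statistics of the source experiments depend on specimen
  data that are not shipped; the pipeline reproduces their *structure*
  (specimen-specific < group < literature in RMS; validation improves on
  literature) on synthetic cohorts, not their numerical values.

## A small worked run

```{r study, eval = FALSE}
cfg <- default_study_config(
  seed = 1,
  cohort = cohort_spec(n_osteodiscs = 4, n_lamellae = 8),
  protocol = load_protocol(n_steps = 15),
  resolution = mesh_resolution(2, 3, 3, 2, 1),
  calibration = calibration_settings(max_forward_solves = 60))
report <- run_full_study(cfg)
report
```

The report object carries the hoop-strain table with its paired tests, the
functional-modulus summary and derived $C_{10}$, the seed-controlled
calibration/validation split, per-specimen and group calibration results,
the literature comparison, and the validation agreement — every number in
it regenerates from the configuration and seed.
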