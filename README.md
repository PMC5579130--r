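# osteodisc

Direct-controlled calibration of annulus fibrosus mechanics in R.

`osteodisc` is for spine biomechanics researchers who need to go from raw
disc measurements — opening-angle photographs of radially cut discs,
single-lamella tension curves, and osteodisc compression tests — to
calibrated, validated constitutive parameters for the annulus fibrosus,
with every step reproducible from a seed. "Direct-controlled" means the
specimen-specific model replicates exactly the boundary conditions of the
experiment performed on the same specimen, and the same quantities are
compared between the two.

## The science in brief

**Pre-strain.** A radial cut releases the circumferential residual strain
of the annulus; the disc opens by an angle φ. Under the (measured)
circularity of bovine caudal discs, the hoop strain that would close the
ring is

&nbsp;&nbsp;&nbsp;&nbsp;ε_h = φ / (2π − φ).

**Functional matrix modulus.** Single-lamella tension curves perpendicular
to the fibres are fitted by least squares over the *functional* range
[ε_h, ε_fail] — the strains the extrafibrillar matrix actually works in.
The slope is the functional modulus E_f; an incompressible neo-Hookean
ground matrix then has C10 = E_f / 6 (1.5 MPa → 0.25 MPa).

**Fibre calibration.** The annulus is a Gasser–Ogden–Holzapfel solid with
two perfectly aligned (κ = 0) tension-only fibre families at ±20° to the
transverse plane:

&nbsp;&nbsp;&nbsp;&nbsp;Ψ = C10 (Ī₁ − 3) + (1/D)((J² − 1)/2 − ln J)
+ (k₁ / 2k₂) Σᵢ [exp(k₂ ⟨Ēᵢ⟩²) − 1].

With C10 fixed by the tissue study and D by water's bulk modulus
(D = 2/K = 9.09·10⁻⁴ MPa⁻¹), only the fibre pair (k₁, k₂) remains. It is
reverse-engineered per specimen (or for a group) by L-BFGS-B minimisation
of the RMS load difference (in newtons, on the experimental displacement
grid) between the measured compression curve — 2100 N maximum load,
displacements zeroed at the 10 N preload — and a reduced-order
axisymmetric finite-deformation model of the osteodisc (nucleus:
incompressible Mooney–Rivlin; bone: homogenised 409 MPa; PMMA endcaps:
1.5 GPa). Curves are characterised by a continuous tri-linear fit
(initial / transition / linear stiffness), and agreement between model and
experiment is quantified with Lin's concordance correlation coefficient.

Because the original specimens cannot be shipped, the package includes
seeded generators for all three data types whose defaults are the reported
cohort statistics (opening angle 49.6° ± 9.2°, NP:AF diameter ratio
0.51 ± 0.05, functional modulus 1.5 ± 0.7 MPa, twelve osteodiscs split
6/6 into calibration and validation groups).

## Worked example

```r
library(osteodisc)

# 1. Pre-strain: a disc that opened by 50 degrees after the radial cut
hoop_strain(50 * pi / 180)

# 2. Functional modulus of a lamella curve above that hoop strain
strain <- seq(0, 0.8, by = 0.01)
stress <- ifelse(strain <= 0.17, 1.5 * strain^3 / (3 * 0.17^2),
                 1.5 * 0.17 / 3 + 1.5 * (strain - 0.17))
functional_modulus(lamella_curve(strain, stress), eps_h = 0.17)

# 3. Inverse calibration against a synthetic osteodisc experiment
geo   <- osteodisc_geometry()         # 30 mm disc, 9 mm high, NP:AF 0.5
truth <- goh_params(k1 = 1.43, k2 = 1.63)
proto <- load_protocol(n_steps = 20)  # compress to 2100 N, zero at 10 N
curve <- gen_pseudo_experiment(geo, truth, proto, force_noise_sd = 0,
                               seed = 7,
                               resolution = mesh_resolution(2, 3, 3, 2, 1))
calibrate_specimen(curve, geo,
                   settings = calibration_settings(init = c(2.45, 2.17),
                                                   rms_frac = 0.001,
                                                   param_change_frac = 0.005),
                   protocol = proto,
                   resolution = mesh_resolution(2, 3, 3, 2, 1))
```

which prints

```
[1] 0.1612903
Functional modulus: 1.500 MPa over strain [0.170, 0.800] (n = 64, r = 1.000)
specimen calibration: k1 = 1.423 MPa, k2 = 1.633, RMS = 1.13 N (rms_threshold, 56 forward solves)
```

Reading the output: a 50° opening corresponds to 16.1 % hoop strain; the
lamella's functional modulus is recovered exactly (Pearson r = 1 confirms
linearity above the toe); and starting from the literature pair
(2.45, 2.17), the calibration recovers the generating fibre parameters
(1.43, 1.63) to well under 1 % with a 1.1 N residual in 56 forward solves —
a noise-free self-consistency check of the whole inverse machinery. The
`run_full_study()` / `run_sensitivity()` functions compose these stages
into the complete characterise → calibrate → validate → sensitivity
pipeline; see the methods vignette (`vignettes/osteodisc-methods.Rmd`) for
the model, its assumptions, and what the synthetic cohorts do and do not
emulate.

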