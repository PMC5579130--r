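# Constitutive models: Gasser-Ogden-Holzapfel (GOH) annulus with two
# tension-only fibre families, Mooney-Rivlin nucleus, and a compressible
# neo-Hookean parameterisation for bone and PMMA. Energies and Cauchy
# stresses are evaluated by the compiled core; this file holds the parameter
# containers, unit conversions and the uniaxial fibre-direction response.

#' GOH annulus fibrosus material parameters
#'
#' Isotropic ground matrix `C10*(I1bar - 3)`, volumetric energy
#' `(1/D)*((J^2-1)/2 - ln J)`, and two exponential fibre families
#' `(k1/(2*k2))*(exp(k2*Ebar^2) - 1)` with
#' `Ebar = kappa*(I1bar-3) + (1-3*kappa)*(I4bar-1)`, active in tension only
#' (a family contributes only when its isochoric squared stretch `I4bar`
#' exceeds one). Fibres lie in the circumferential-axial plane at `+/-alpha`
#' to the transverse plane; `kappa = 0` means perfectly aligned fibres.
#'
#' Defaults: `C10 = 0.25` MPa (from a functional matrix modulus of 1.5 MPa,
#' see [matrix_modulus_to_C10()]), water-like compressibility
#' `D = 9.09e-4` MPa^-1, fibre angle 20 degrees, and the group-average
#' calibrated fibre pair `k1 = 1.43` MPa, `k2 = 1.63`.
#'
#' @param C10 Ground-matrix stiffness (MPa), > 0.
#' @param D Volumetric compliance (MPa^-1), > 0; `D = 2/K` with bulk
#'   modulus `K`.
#' @param k1 Fibre stiffness (MPa), >= 0.
#' @param k2 Dimensionless fibre nonlinearity, > 0.
#' @param kappa Fibre dispersion in `[0, 1/3]`.
#' @param alpha Fibre angle to the transverse plane (degrees).
#' @return Object of class `goh_params`.
#' @export
goh_params <- function(C10 = 0.25, D = 9.09e-4, k1 = 1.43, k2 = 1.63,
                       kappa = 0, alpha = 20) {
  stopifnot(C10 > 0, D > 0, k1 >= 0, k2 > 0,
            kappa >= 0, kappa <= 1 / 3, alpha >= 0, alpha < 90)
  structure(list(C10 = C10, D = D, k1 = k1, k2 = k2, kappa = kappa,
                 alpha = alpha),
            class = "goh_params")
}

#' Mooney-Rivlin nucleus pulposus material parameters
#'
#' Isochoric energy `C10n*(I1bar-3) + C01n*(I2bar-3)` with the same
#' volumetric convention as [goh_params()]. `Dn = 0` encodes full
#' incompressibility, realised numerically as a penalty bulk modulus of
#' `1e4` times the small-strain shear modulus `2*(C10n + C01n)`.
#' `poisson_override` replaces the compressibility by the bulk modulus
#' implied by a Poisson's ratio (used by the nucleus sensitivity study).
#'
#' The coefficient defaults are a modelling choice constrained only by the
#' requirement that the nucleus be noticeably softer than the annulus; they
#' are not measured values.
#'
#' @param C10n,C01n Mooney-Rivlin coefficients (MPa), `C10n + C01n > 0`.
#' @param Dn Volumetric compliance (MPa^-1); 0 means incompressible.
#' @param poisson_override Optional Poisson's ratio in (0, 0.5) from which
#'   the bulk modulus is derived instead of `Dn`.
#' @return Object of class `mooney_rivlin_params`.
#' @export
mooney_rivlin_params <- function(C10n = 0.12, C01n = 0.03, Dn = 0,
                                 poisson_override = NULL) {
  stopifnot(C10n + C01n > 0, Dn >= 0)
  if (!is.null(poisson_override))
    stopifnot(poisson_override > 0, poisson_override < 0.5)
  structure(list(C10n = C10n, C01n = C01n, Dn = Dn,
                 poisson_override = poisson_override),
            class = "mooney_rivlin_params")
}

#' Linear-elastic parameters for bone and PMMA
#'
#' Young's modulus and Poisson's ratio; realised in the finite-deformation
#' solver as a compressible neo-Hookean solid with the equivalent Lame
#' constants (the two coincide at small strains, which is the regime of the
#' bone and cement here).
#'
#' @param E Young's modulus (MPa), > 0.
#' @param nu Poisson's ratio in (0, 0.5).
#' @return Object of class `linear_elastic_params`.
#' @export
linear_elastic_params <- function(E, nu = 0.3) {
  stopifnot(E > 0, nu > 0, nu < 0.5)
  structure(list(E = E, nu = nu), class = "linear_elastic_params")
}

#' Unit fibre directions of the two GOH families
#'
#' In the local (radial, circumferential, axial) frame the families are
#' `(0, cos(alpha), +/- sin(alpha))`: oblique/counter-oblique at `alpha`
#' degrees to the transverse plane.
#'
#' @param alpha Fibre angle in degrees, `0 <= alpha < 90`.
#' @return 2 x 3 matrix; rows are the two unit direction vectors.
#' @export
fibre_directions <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha < 90)
  a <- alpha * pi / 180
  rbind(c(0, cos(a), sin(a)), c(0, cos(a), -sin(a)))
}

#' Deformation state from a deformation gradient
#'
#' Computes `J = det(F)`, the first isochoric invariant `I1bar` and the
#' squared isochoric fibre stretches `I4bar_a`, `I4bar_b` of the two fibre
#' families at angle `alpha`.
#'
#' @param F 3 x 3 deformation gradient in the (r, theta, z) frame.
#' @param alpha Fibre angle (degrees) used for the fibre invariants.
#' @return Object of class `deformation_state` with fields `F`, `J`,
#'   `I1bar`, `I4bar_a`, `I4bar_b`.
#' @export
deformation_state <- function(F, alpha = 20) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)), all(is.finite(F)))
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det(F) <= 0")
  Fbar <- J^(-1 / 3) * F
  bbar <- Fbar %*% t(Fbar)
  dirs <- fibre_directions(alpha)
  g1 <- Fbar %*% dirs[1, ]
  g2 <- Fbar %*% dirs[2, ]
  structure(list(F = F, J = J, I1bar = sum(diag(bbar)),
                 I4bar_a = sum(g1^2), I4bar_b = sum(g2^2)),
            class = "deformation_state")
}

# internal: encode a parameter object as the numeric row the compiled core
# expects (see src/fe_core.cpp for the layout)
.mat_row <- function(p) {
  if (inherits(p, "goh_params")) {
    c(0, p$C10, p$D, p$k1, p$k2, p$kappa, p$alpha * pi / 180, 0)
  } else if (inherits(p, "mooney_rivlin_params")) {
    mu <- 2 * (p$C10n + p$C01n)
    D <- if (!is.null(p$poisson_override)) {
      nu <- p$poisson_override
      2 / (2 * mu * (1 + nu) / (3 * (1 - 2 * nu)))
    } else if (p$Dn == 0) {
      2 / (1e4 * mu)  # incompressibility as a stiff volumetric penalty
    } else {
      p$Dn
    }
    c(1, p$C10n, p$C01n, D, 0, 0, 0, 0)
  } else if (inherits(p, "linear_elastic_params")) {
    mu <- p$E / (2 * (1 + p$nu))
    la <- p$E * p$nu / ((1 + p$nu) * (1 - 2 * p$nu))
    c(2, mu, la, 0, 0, 0, 0, 0)
  } else {
    stop("unknown material parameter object")
  }
}

#' Strain-energy density of a material at a deformation state
#'
#' @param state A [deformation_state()] (or a 3 x 3 deformation gradient).
#' @param params A [goh_params()], [mooney_rivlin_params()] or
#'   [linear_elastic_params()] object.
#' @return Energy density (MPa); zero at the reference configuration.
#' @export
strain_energy <- function(state, params) {
  F <- if (inherits(state, "deformation_state")) state$F else as.matrix(state)
  .mat_energy_cpp(F, .mat_row(params))
}

#' GOH strain-energy density
#'
#' Convenience wrapper of [strain_energy()] asserting GOH parameters.
#'
#' @inheritParams strain_energy
#' @param params A [goh_params()] object.
#' @export
goh_energy <- function(state, params) {
  stopifnot(inherits(params, "goh_params"))
  strain_energy(state, params)
}

#' Cauchy stress of a material at a deformation state
#'
#' Analytic derivative of the strain energy, pushed forward to the current
#' configuration. Symmetric; zero at the identity; fibre families under
#' compression (`I4bar <= 1`) contribute exactly nothing.
#'
#' @inheritParams strain_energy
#' @return 3 x 3 Cauchy stress tensor (MPa).
#' @export
cauchy_stress <- function(state, params) {
  F <- if (inherits(state, "deformation_state")) state$F else as.matrix(state)
  .mat_cauchy_cpp(F, .mat_row(params))
}

#' Ground-matrix C10 from the functional extrafibrillar-matrix modulus
#'
#' Small-strain equivalence of an incompressible neo-Hookean solid:
#' `E = 6 * C10`, so `C10 = E/6`. A functional modulus of 1.5 MPa gives
#' `C10 = 0.25` MPa.
#'
#' @param E_functional Functional modulus (MPa), > 0.
#' @return `C10` in MPa.
#' @export
matrix_modulus_to_C10 <- function(E_functional) {
  if (any(!is.finite(E_functional)) || any(E_functional <= 0))
    stop("`E_functional` must be positive")
  E_functional / 6
}

#' Volumetric compliance D from a bulk modulus
#'
#' `D = 2/K` under the volumetric energy `(1/D)*((J^2-1)/2 - ln J)`.
#' Water's bulk modulus of 2200 MPa gives `D = 9.09e-4` MPa^-1.
#'
#' @param K Bulk modulus (MPa), > 0.
#' @return `D` in MPa^-1.
#' @export
bulk_to_D <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("`K` must be positive")
  2 / K
}

#' Uniaxial stress-strain response in the fibre direction
#'
#' Engineering stress for an isochoric uniaxial stretch `lambda = 1 + eps`
#' along one fibre family with lateral stretches `lambda^(-1/2)`. The
#' engineering stress is the derivative of the energy along this kinematic
#' path, `P(lambda) = P : dF/dlambda`, evaluated from the analytic Cauchy
#' stress. Strictly increasing and convex for `k1 > 0`.
#'
#' @param strain_grid Non-negative engineering strains.
#' @param params A [goh_params()] object.
#' @return Engineering stresses (MPa) at the grid points.
#' @export
fibre_direction_stress_curve <- function(strain_grid, params) {
  stopifnot(inherits(params, "goh_params"))
  if (any(strain_grid < 0)) stop("strains must be >= 0")
  n <- fibre_directions(params$alpha)[1, ]
  Pn <- outer(n, n)
  Q <- diag(3) - Pn
  m <- .mat_row(params)
  vapply(strain_grid, function(eps) {
    lam <- 1 + eps
    F <- lam * Pn + lam^(-1 / 2) * Q
    sig <- .mat_cauchy_cpp(F, m)
    P <- det(F) * sig %*% t(solve(F))
    dF <- Pn - 0.5 * lam^(-3 / 2) * Q
    sum(P * dF)
  }, numeric(1))
}
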