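# GOH / Mooney-Rivlin / neo-Hookean energies and stresses.

test_that("fibre directions are unit vectors at +/- alpha in the (theta,z) plane", {
  d0 <- fibre_directions(0)
  expect_equal(d0[1, ], c(0, 1, 0))
  expect_equal(d0[2, ], c(0, 1, 0))
  d20 <- fibre_directions(20)
  expect_equal(d20[, 3], c(sin(20 * pi / 180), -sin(20 * pi / 180)))
  expect_equal(rowSums(d20^2), c(1, 1))
  expect_error(fibre_directions(90))
})

test_that("energy and stress vanish at the reference configuration", {
  mats <- list(goh_params(k1 = 1.43, k2 = 1.63), mooney_rivlin_params(),
               linear_elastic_params(409, 0.3))
  for (p in mats) {
    expect_equal(strain_energy(diag(3), p), 0)
    expect_equal(max(abs(cauchy_stress(diag(3), p))), 0, tolerance = 1e-12)
  }
  expect_error(strain_energy(diag(c(-1, 1, 1)), mats[[1]]), "det")
})

test_that("GOH with k1 = 0 coincides with Mooney-Rivlin with C01n = 0", {
  g <- goh_params(C10 = 0.4, D = 0.002, k1 = 0, k2 = 1)
  m <- mooney_rivlin_params(C10n = 0.4, C01n = 0, Dn = 0.002)
  set.seed(7)
  for (rep in 1:20) {
    F <- random_F()
    expect_equal(strain_energy(F, g), strain_energy(F, m),
                 tolerance = 1e-12)
    expect_equal(cauchy_stress(F, g), cauchy_stress(F, m),
                 tolerance = 1e-12)
  }
})

test_that("fibre term is exactly inactive when both families are compressed", {
  g <- goh_params(k1 = 1.43, k2 = 1.63, alpha = 20)
  g0 <- goh_params(k1 = 0, k2 = 1.63, alpha = 20)
  # equibiaxial compression in (theta, z): both I4bar < 1
  F <- diag(c(1.21, 0.95, 0.95))
  st <- deformation_state(F, alpha = 20)
  expect_lt(st$I4bar_a, 1)
  expect_lt(st$I4bar_b, 1)
  expect_equal(strain_energy(F, g), strain_energy(F, g0))
  expect_equal(cauchy_stress(F, g), cauchy_stress(F, g0))
})

test_that("uniaxial stretch along one family matches the closed-form fibre energy", {
  # alpha = 45: the two families are orthogonal, so stretching along one
  # leaves the other compressed (inactive)
  p <- goh_params(k1 = 1.43, k2 = 1.63, alpha = 45)
  lam <- 1.1
  n <- fibre_directions(45)[1, ]
  F <- lam * outer(n, n) + lam^(-1 / 2) * (diag(3) - outer(n, n))
  st <- deformation_state(F, alpha = 45)
  expect_equal(st$J, 1, tolerance = 1e-12)
  expect_equal(st$I4bar_a, lam^2, tolerance = 1e-12)
  expect_lt(st$I4bar_b, 1)
  fib <- strain_energy(F, p) - p$C10 * (st$I1bar - 3)
  expect_equal(fib, 1.43 / (2 * 1.63) * (exp(1.63 * (lam^2 - 1)^2) - 1),
               tolerance = 1e-10)
  expect_gt(fib, 0)
})

test_that("analytic stress matches finite differences of the energy", {
  set.seed(11)
  mats <- list(goh_params(k1 = 1.43, k2 = 1.63),
               mooney_rivlin_params(C10n = 0.12, C01n = 0.03, Dn = 1e-3),
               linear_elastic_params(409, 0.3))
  for (rep in 1:15) {
    F <- random_F()
    for (p in mats) {
      Pfd <- fd_piola(F, p)
      Pan <- piola_from_cauchy(F, p)
      expect_equal(Pan, Pfd, tolerance = 1e-6)
    }
  }
})

test_that("energy is frame-indifferent under seeded random rotations", {
  set.seed(3)
  p <- goh_params(k1 = 1.43, k2 = 1.63)
  m <- mooney_rivlin_params()
  for (rep in 1:20) {
    F <- random_F()
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_equal(strain_energy(Q %*% F, p), strain_energy(F, p),
                 tolerance = 1e-10)
    expect_equal(strain_energy(Q %*% F, m), strain_energy(F, m),
                 tolerance = 1e-10)
  }
})

test_that("parameter conversions reproduce the printed material constants", {
  expect_equal(matrix_modulus_to_C10(1.5), 0.25)
  expect_equal(matrix_modulus_to_C10(6), 1)
  expect_equal(matrix_modulus_to_C10(0.9), 0.15)
  expect_error(matrix_modulus_to_C10(0), "positive")
  expect_equal(bulk_to_D(2200), 9.09e-4, tolerance = 1e-3)
  expect_equal(bulk_to_D(2), 1)
  expect_lt(bulk_to_D(1e12), 1e-11)  # incompressible limit
  expect_error(bulk_to_D(-2), "positive")
})

test_that("fibre-direction stress curve is zero at rest, monotone, and
           consistent with differentiating the energy", {
  p <- goh_params(k1 = 2.45, k2 = 2.17)
  eps <- seq(0, 0.15, by = 0.01)
  s <- fibre_direction_stress_curve(eps, p)
  expect_equal(s[1], 0, tolerance = 1e-10)
  expect_true(all(diff(s) > 0))
  expect_gt(s[16], s[11])  # stress(0.15) > stress(0.10)

  # independent oracle: central differences of the energy along the path
  n <- fibre_directions(p$alpha)[1, ]
  Pn <- outer(n, n); Q <- diag(3) - Pn
  psi_of <- function(lam)
    strain_energy(lam * Pn + lam^(-1 / 2) * Q, p)
  h <- 1e-6
  for (e in c(0.03, 0.08, 0.14)) {
    lam <- 1 + e
    expect_equal(fibre_direction_stress_curve(e, p),
                 (psi_of(lam + h) - psi_of(lam - h)) / (2 * h),
                 tolerance = 1e-6)
  }
})
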