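# Forward compression solver: trivial limits, linearity in the single
# modulus, preload re-zeroing and load targeting.

test_that("zero applied displacement gives zero force", {
  mesh <- build_mesh(baseline_geometry(), tiny_res())
  cv <- solve_axial_compression(mesh, osteodisc_materials(),
                                load_protocol(applied_displacement = 0))
  expect_equal(cv$force, 0)
})

test_that("doubling the single modulus of a homogeneous model doubles the force", {
  C10 <- 0.25; K <- 1e4 * 2 * C10
  m1 <- goh_params(C10 = C10, D = 2 / K, k1 = 0)
  m2 <- goh_params(C10 = 2 * C10, D = 2 / (2 * K), k1 = 0)
  mesh <- build_mesh(baseline_geometry(), tiny_res())
  proto <- load_protocol(applied_displacement = 2, n_steps = 8)
  f1 <- solve_axial_compression(mesh, homogeneous_materials(m1), proto,
                                bc = "frictionless")$force
  f2 <- solve_axial_compression(mesh, homogeneous_materials(m2), proto,
                                bc = "frictionless")$force
  expect_equal(f2[-1] / f1[-1], rep(2, length(f1) - 1), tolerance = 1e-6)
})

test_that("reaction force is non-negative and non-decreasing in compression", {
  mesh <- build_mesh(baseline_geometry(), tiny_res())
  cv <- solve_axial_compression(mesh, osteodisc_materials(k1 = 1.43, k2 = 1.63),
                                load_protocol(applied_displacement = 2,
                                              n_steps = 12))
  expect_true(all(cv$force >= 0))
  expect_true(all(diff(cv$force) > -1e-8))
})

test_that("fully incompressible and nu = 0.4999 nuclei give near-identical forces", {
  geo <- baseline_geometry()
  mesh <- build_mesh(geo, tiny_res())
  proto <- load_protocol(applied_displacement = 2, n_steps = 10)
  m_inc <- osteodisc_materials(k1 = 1.43, k2 = 1.63)
  m_near <- m_inc
  m_near$nucleus <- mooney_rivlin_params(poisson_override = 0.4999)
  f_inc <- solve_axial_compression(mesh, m_inc, proto)$force
  f_near <- solve_axial_compression(mesh, m_near, proto)$force
  expect_lt(abs(tail(f_inc, 1) - tail(f_near, 1)) / tail(f_inc, 1), 0.01)
})

test_that("re-zeroing shifts the origin to the interpolated preload crossing", {
  # curve already starting at the preload: only the flag changes
  c0 <- force_displacement_curve(c(0, 1, 2), c(10, 110, 210))
  z0 <- rezero_at_preload(c0, 10)
  expect_true(z0$zeroed)
  expect_equal(z0$displacement, c(0, 1, 2))
  expect_equal(z0$force, c(10, 110, 210))

  # F = 100 d: crossing at d = 0.1, every displacement shifts by 0.1 mm
  d <- seq(0, 1, by = 0.05)
  c1 <- force_displacement_curve(d, 100 * d)
  z1 <- rezero_at_preload(c1, 10)
  expect_equal(z1$displacement[1], 0)
  expect_equal(z1$force[1], 10)
  expect_equal(max(z1$displacement), 0.9, tolerance = 1e-12)

  # preload strictly between samples: linear interpolation of the crossing
  # at d = 0.25; the crossing becomes the new origin sample
  c2 <- force_displacement_curve(c(0, 1, 2), c(0, 40, 120))
  z2 <- rezero_at_preload(c2, 10)
  expect_equal(z2$displacement, c(0, 0.75, 1.75), tolerance = 1e-12)
  expect_equal(z2$force, c(10, 40, 120))

  expect_error(rezero_at_preload(force_displacement_curve(0:1, c(0, 5)), 10),
               "never reaches")
})

test_that("load targeting reaches the requested load within 1 % and is
           monotone in the target", {
  mesh <- build_mesh(baseline_geometry(), tiny_res())
  mats <- osteodisc_materials(k1 = 1.43, k2 = 1.63)
  d1 <- displacement_for_target_load(mesh, mats, 800)
  d2 <- displacement_for_target_load(mesh, mats, 2100)
  expect_lt(as.numeric(d1), as.numeric(d2))
  # baseline specimen reaches 2100 N well before 30 % of the disc height
  expect_lt(as.numeric(d2), 0.3 * baseline_geometry()$disc_height)
  cv <- solve_axial_compression(mesh, mats,
          load_protocol(applied_displacement = as.numeric(d2), n_steps = 15))
  expect_equal(tail(cv$force, 1), 2100, tolerance = 0.01)
  expect_error(displacement_for_target_load(mesh, mats, 1e7),
               "unreachable")
})

test_that("solution is insensitive to the number of displacement steps", {
  mesh <- build_mesh(baseline_geometry(), tiny_res())
  mats <- osteodisc_materials(k1 = 1.43, k2 = 1.63)
  f20 <- tail(solve_axial_compression(mesh, mats,
          load_protocol(applied_displacement = 2, n_steps = 20))$force, 1)
  f40 <- tail(solve_axial_compression(mesh, mats,
          load_protocol(applied_displacement = 2, n_steps = 40))$force, 1)
  expect_lt(abs(f20 - f40) / f40, 0.005)
})

test_that("curve container validates lengths and monotonicity", {
  expect_error(force_displacement_curve(c(0, 1), 0), "same length")
  expect_error(force_displacement_curve(c(0, 1, 0.5), c(0, 1, 2)),
               "monotone")
  path <- withr::local_tempfile(fileext = ".csv")
  cv <- force_displacement_curve(c(0, 1, 2), c(0, 100, 250))
  write_fd_curve(cv, path)
  expect_equal(read_fd_curve(path)$force, cv$force)
})
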