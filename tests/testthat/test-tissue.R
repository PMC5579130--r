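# Hoop strain, circularity deviation, disc summaries and the functional
# extrafibrillar-matrix modulus.

test_that("hoop strain follows phi/(2pi - phi) and round-trips its inverse", {
  expect_identical(hoop_strain(0), 0)
  expect_equal(hoop_strain(pi), 1)
  expect_equal(hoop_strain(49.6 * pi / 180), 0.1597938, tolerance = 1e-6)
  expect_equal(hoop_strain(pi / 2), 1 / 3)

  phi <- seq(0, 2 * pi - 1e-6, length.out = 200)
  eps <- hoop_strain(phi)
  expect_true(all(diff(eps) > 0))  # strictly increasing
  expect_equal(opening_angle_from_hoop_strain(eps), phi, tolerance = 1e-12)

  expect_error(hoop_strain(-0.1), "0 <= phi")
  expect_error(hoop_strain(2 * pi), "0 <= phi")
})

test_that("circularity deviation reproduces its analytic limits", {
  expect_equal(circularity_deviation(rep(30, 6)), 0)
  # caliper widths of a 1:2 ellipse at 0, 30, ..., 150 degrees
  expect_equal(circularity_deviation(ellipse_caliper_diameters(2)),
               0.2487565, tolerance = 1e-6)
  # degenerate limit as the aspect ratio tends to infinity
  expect_equal(circularity_deviation(ellipse_caliper_diameters(1e6)),
               0.592, tolerance = 1e-3)
})

test_that("circularity deviation is scale- and permutation-invariant", {
  set.seed(1)
  for (rep in 1:10) {
    d <- runif(6, 20, 40)
    v <- circularity_deviation(d)
    expect_equal(circularity_deviation(3.7 * d), v)
    expect_equal(circularity_deviation(sample(d)), v)
  }
  expect_error(circularity_deviation(c(30, 31)), "at least 3")
  expect_error(circularity_deviation(c(30, 31, -1)), "positive")
})

test_that("disc summary averages repeats and derives ratio and strain", {
  rec <- opening_study_record(
    disc_id = "d1",
    diameters_intact = rep(30, 6),
    diameters_relaxed_10min = rep(30, 6),
    opening_angle_10min = pi / 2,
    opening_angle_late = pi / 2 + 0.1,
    nucleus_diameter = 15.3)
  s <- summarise_disc(rec)
  expect_equal(s$mean_diameter, 30)
  expect_equal(s$np_af_ratio, 0.51)
  expect_equal(s$circularity_dev, 0)
  expect_equal(s$hoop_strain, 1 / 3)

  expect_error(opening_study_record("x", rep(30, 5), rep(30, 6),
                                    0.5, 0.6, 15), "exactly 6")
  expect_error(opening_study_record("x", rep(30, 6), rep(30, 6),
                                    7, 0.6, 15), "2\\*pi")
})

test_that("engineering conversion divides by reference length and area", {
  cv <- engineering_curve(load = c(0, 10), disp = c(0, 1),
                          length0 = 4, area0 = 2)
  expect_equal(cv$strain, c(0, 0.25))
  expect_equal(cv$stress, c(0, 5))
  expect_error(engineering_curve(1, 1, length0 = 0, area0 = 2), "positive")
  expect_error(engineering_curve(1, 1, length0 = 1, area0 = -1), "positive")
})

test_that("failure strain is the first >=5% drop after the stress peak", {
  strain <- seq(0, 1, by = 0.1)
  stress <- c(0, 1, 2, 3, 4, 5, 4.9, 4.0, 3.5, 3.0, 2.0)
  expect_equal(detect_failure_strain(strain, stress), 0.7)
  # monotone curve: failure at the last sample
  expect_equal(detect_failure_strain(strain, seq(0, 2, length.out = 11)), 1)
})

test_that("functional modulus recovers a linear law and flags degeneracy", {
  strain <- seq(0.17, 0.60, length.out = 30)
  cv <- lamella_curve(strain, 1.5 * (strain - 0.05))
  fm <- functional_modulus(cv, 0.17)
  expect_equal(fm$modulus, 1.5, tolerance = 1e-10)
  expect_equal(fm$pearson_r, 1, tolerance = 1e-10)
  expect_equal(fm$strain_lo, 0.17)

  # toe below the hoop strain, slope 2 above it
  s2 <- seq(0, 0.8, length.out = 100)
  toe <- 0.17
  y <- ifelse(s2 <= toe, 2 * s2^3 / (3 * toe^2),
              2 * toe / 3 + 2 * (s2 - toe))
  fm2 <- functional_modulus(lamella_curve(s2, y), toe)
  expect_equal(fm2$modulus, 2.0, tolerance = 1e-6)

  # constant stress: zero slope, undefined correlation, flagged
  fm3 <- functional_modulus(lamella_curve(strain, rep(2, 30)), 0.17)
  expect_equal(fm3$modulus, 0)
  expect_true(is.na(fm3$pearson_r))
  expect_true(fm3$degenerate)

  expect_error(functional_modulus(lamella_curve(c(0, 0.1, 0.2, 0.3),
                                                c(0, 1, 2, 3)), 0.25),
               "fewer than 3")
})

test_that("opening-study and lamella CSV round-trips preserve the data", {
  rec <- opening_study_record("discA", rnorm(6, 30, 0.2), rnorm(6, 30, 0.2),
                              0.8, 0.95, 15.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_opening_study(list(rec), path)
  back <- read_opening_study(path)[[1]]
  expect_equal(back$diameters_intact, rec$diameters_intact)
  expect_equal(back$opening_angle_10min, rec$opening_angle_10min)
  expect_equal(back$nucleus_diameter, rec$nucleus_diameter)

  cv <- lamella_curve(seq(0, 1, 0.1), seq(0, 2, 0.2))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_lamella_curve(cv, path2)
  back2 <- read_lamella_curve(path2)
  expect_equal(back2$strain, cv$strain)
  expect_equal(back2$stress, cv$stress)
})
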