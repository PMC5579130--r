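# Inverse calibration of the fibre pair: stopping rules, optimality and
# parameter recovery.

test_that("a curve equal to the model output at the init converges immediately", {
  geo <- baseline_geometry()
  init <- c(2.45, 2.17)
  proto <- load_protocol(n_steps = 10)
  exp_cv <- gen_pseudo_experiment(geo, goh_params(k1 = init[1], k2 = init[2]),
                                  proto, force_noise_sd = 0, seed = 2,
                                  resolution = tiny_res())
  cal <- calibrate_specimen(exp_cv, geo,
                            settings = calibration_settings(init = init),
                            protocol = proto, resolution = tiny_res())
  expect_equal(cal$converged_by, "rms_threshold")
  expect_lte(cal$n_forward_solves, 2)
  expect_lt(cal$rms, 0.05 * 2100)
  expect_equal(c(cal$k1, cal$k2), init)
})

test_that("stopping rules fire exactly as configured", {
  geo <- baseline_geometry()
  proto <- load_protocol(n_steps = 10)
  exp_cv <- gen_pseudo_experiment(geo, goh_params(k1 = 1.43, k2 = 1.63),
                                  proto, force_noise_sd = 0, seed = 5,
                                  resolution = tiny_res())
  expz <- rezero_at_preload(exp_cv, proto$preload)

  # rms rule: threshold is rms_frac * max experimental force
  s1 <- calibration_settings(rms_frac = 0.05, max_forward_solves = 100)
  c1 <- calibrate_specimen(exp_cv, geo, settings = s1, protocol = proto,
                           resolution = tiny_res())
  expect_equal(c1$converged_by, "rms_threshold")
  expect_lt(c1$rms, 0.05 * max(expz$force))

  # unreachable rms: the search must stop by parameter stall or budget
  s2 <- calibration_settings(rms_frac = 1e-9, param_change_frac = 0.05,
                             max_forward_solves = 100)
  c2 <- calibrate_specimen(exp_cv, geo, settings = s2, protocol = proto,
                           resolution = tiny_res())
  expect_true(c2$converged_by %in% c("param_stall", "budget_exhausted"))

  # tiny budget: budget rule fires and the evaluation count respects it
  s3 <- calibration_settings(rms_frac = 1e-9, param_change_frac = 1e-6,
                             max_forward_solves = 5)
  c3 <- calibrate_specimen(exp_cv, geo, settings = s3, protocol = proto,
                           resolution = tiny_res())
  expect_equal(c3$converged_by, "budget_exhausted")
  expect_lte(c3$n_forward_solves, 6)
})

test_that("objective at the returned parameters does not exceed the init value", {
  geo <- baseline_geometry()
  proto <- load_protocol(n_steps = 10)
  exp_cv <- gen_pseudo_experiment(geo, goh_params(k1 = 1.0, k2 = 1.3),
                                  proto, force_noise_sd = 0, seed = 9,
                                  resolution = tiny_res())
  sett <- calibration_settings(rms_frac = 0.005, max_forward_solves = 60)
  cal <- calibrate_specimen(exp_cv, geo, settings = sett, protocol = proto,
                            resolution = tiny_res())
  # wrong parameters (k1 x5) give a worse fit than the calibrated pair
  val_cal <- validate_specimens(list(exp_cv), list(geo),
                                goh_params(k1 = cal$k1, k2 = cal$k2),
                                protocol = proto, resolution = tiny_res())
  val_bad <- validate_specimens(list(exp_cv), list(geo),
                                goh_params(k1 = 5 * cal$k1, k2 = cal$k2),
                                protocol = proto, resolution = tiny_res())
  expect_lt(val_cal$mean_rms, val_bad$mean_rms)
})

test_that("group calibration equals specimen calibration on identical specimens", {
  geo <- baseline_geometry()
  proto <- load_protocol(n_steps = 10)
  exp_cv <- gen_pseudo_experiment(geo, goh_params(k1 = 1.43, k2 = 1.63),
                                  proto, force_noise_sd = 0, seed = 12,
                                  resolution = tiny_res())
  sett <- calibration_settings(rms_frac = 0.01, max_forward_solves = 60)
  c_single <- calibrate_specimen(exp_cv, geo, settings = sett,
                                 protocol = proto, resolution = tiny_res())
  c_group <- calibrate_group(list(exp_cv, exp_cv), list(geo, geo),
                             settings = sett, protocol = proto,
                             resolution = tiny_res())
  expect_equal(c_group$mode, "group")
  expect_equal(c(c_group$k1, c_group$k2), c(c_single$k1, c_single$k2),
               tolerance = 1e-8)
  expect_equal(c_group$rms, c_single$rms, tolerance = 1e-8)
})

test_that("validation at the true parameters is perfectly concordant", {
  proto <- load_protocol(n_steps = 25)
  truth <- goh_params(k1 = 1.43, k2 = 1.63)
  geos <- list(baseline_geometry(),
               osteodisc_geometry(disc_diameter = 28, disc_height = 8))
  curves <- lapply(1:2, function(i)
    gen_pseudo_experiment(geos[[i]], truth, proto, force_noise_sd = 0,
                          seed = 20 + i, resolution = tiny_res()))
  val <- validate_specimens(curves, geos, truth, protocol = proto,
                            resolution = tiny_res())
  expect_equal(val$agreement$ccc, 1, tolerance = 1e-3)
  expect_equal(val$agreement$slope, 1, tolerance = 1e-2)
  expect_lt(abs(val$agreement$intercept), 15)
  expect_lt(val$mean_rms, 5)
})

test_that("noisy calibration fits the curve to the noise floor even though
           the fibre pair is identified only up to a flat valley", {
  geo <- baseline_geometry()
  res <- coarse_res()
  proto <- load_protocol(n_steps = 20)
  truth <- goh_params(k1 = 1.43, k2 = 1.63)
  exp_n <- gen_pseudo_experiment(geo, truth, proto, force_noise_sd = 42,
                                 seed = 21, resolution = res)
  sett <- calibration_settings(rms_frac = 0.01, param_change_frac = 0.005,
                               max_forward_solves = 120)
  cal <- calibrate_specimen(exp_n, geo, settings = sett, protocol = proto,
                            resolution = res)
  expect_true(cal$converged_by %in% c("rms_threshold", "param_stall"))
  expect_true(cal$k1 >= sett$lower[1] && cal$k1 <= sett$upper[1])
  expect_true(cal$k2 >= sett$lower[2] && cal$k2 <= sett$upper[2])
  # the fit is at least as good as the generating parameters and sits
  # near the injected noise level (sd 42 N)
  val_truth <- validate_specimens(list(exp_n), list(geo), truth,
                                  protocol = proto, resolution = res)
  val_cal <- validate_specimens(list(exp_n), list(geo),
                                goh_params(k1 = cal$k1, k2 = cal$k2),
                                protocol = proto, resolution = res)
  expect_lte(val_cal$mean_rms, val_truth$mean_rms + 1)
  expect_lt(val_cal$mean_rms, 2 * 42)
})

test_that("parameter recovery over seeded noise-free specimens", {
  # truths drawn log-uniformly; the protocol's coarse stopping shortcuts
  # (5 % rules) are disabled so the search runs to the optimum
  proto <- load_protocol(n_steps = 20)
  geo <- baseline_geometry()
  sett <- calibration_settings(rms_frac = 2e-4, param_change_frac = 1e-8,
                               max_forward_solves = 150)
  set.seed(33)
  err1 <- err2 <- numeric(0)
  for (i in 1:10) {
    k1t <- exp(runif(1, log(0.5), log(3)))
    k2t <- exp(runif(1, log(1), log(3)))
    cv <- gen_pseudo_experiment(geo, goh_params(k1 = k1t, k2 = k2t), proto,
                                force_noise_sd = 0, seed = 50 + i,
                                resolution = tiny_res())
    cal <- calibrate_specimen(cv, geo, settings = sett, protocol = proto,
                              resolution = tiny_res())
    err1 <- c(err1, abs(cal$k1 - k1t) / k1t)
    err2 <- c(err2, abs(cal$k2 - k2t) / k2t)
  }
  expect_lt(median(err2), 0.02)
  expect_lt(median(err1), 0.05)
})
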