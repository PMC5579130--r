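# Study orchestration: the four sensitivity studies (nucleus
# compressibility, nucleus modulus, disc size, nucleus-to-annulus ratio)
# and the end-to-end pipeline (characterise -> calibrate -> validate).

#' Sensitivity study specification
#'
#' The four studies with their levels: compressibility (incompressible,
#' Poisson 0.4999, Poisson 0.49), nucleus modulus (x0.1, baseline, x10),
#' disc size (-15 % to +15 % in 5 % steps) and nucleus-to-annulus diameter
#' ratio (0.4, 0.5 baseline, 0.6).
#'
#' @param study One of `"nucleus_compressibility"`, `"nucleus_modulus"`,
#'   `"disc_size"`, `"np_af_ratio"`.
#' @param levels Optional subset of the study's levels (character for the
#'   material studies, numeric for the geometric ones).
#' @return Object of class `sensitivity_study_spec` with fields `study`,
#'   `levels`, `baseline_level`.
#' @export
sensitivity_study_spec <- function(study = c("nucleus_compressibility",
                                             "nucleus_modulus", "disc_size",
                                             "np_af_ratio"),
                                   levels = NULL) {
  study <- match.arg(study)
  all_levels <- switch(study,
    nucleus_compressibility = c("incompressible", "nu_0.4999", "nu_0.49"),
    nucleus_modulus = c("x0.1", "baseline", "x10"),
    disc_size = c(-0.15, -0.10, -0.05, 0, 0.05, 0.10, 0.15),
    np_af_ratio = c(0.4, 0.5, 0.6))
  baseline <- switch(study,
    nucleus_compressibility = "incompressible",
    nucleus_modulus = "baseline",
    disc_size = 0,
    np_af_ratio = 0.5)
  if (is.null(levels)) levels <- all_levels
  if (!all(levels %in% all_levels))
    stop("invalid level(s) for study ", study, ": allowed levels are ",
         paste(all_levels, collapse = ", "))
  if (!(baseline %in% levels)) levels <- c(baseline, levels)
  structure(list(study = study, levels = levels,
                 baseline_level = baseline),
            class = "sensitivity_study_spec")
}

# internal: (geometry, materials) of one specimen under one study level
.apply_level <- function(study, level, geometry, materials) {
  if (study == "nucleus_compressibility") {
    nu <- switch(as.character(level),
                 incompressible = NULL,
                 "nu_0.4999" = 0.4999, "nu_0.49" = 0.49)
    materials$nucleus <- mooney_rivlin_params(
      C10n = materials$nucleus$C10n, C01n = materials$nucleus$C01n,
      poisson_override = nu)
  } else if (study == "nucleus_modulus") {
    fac <- switch(as.character(level), "x0.1" = 0.1, baseline = 1, "x10" = 10)
    # the nucleus stays incompressible while its coefficients are scaled:
    # keep the volumetric penalty at the baseline shear scale
    mu_base <- 2 * (materials$nucleus$C10n + materials$nucleus$C01n)
    materials$nucleus <- mooney_rivlin_params(
      C10n = fac * materials$nucleus$C10n,
      C01n = fac * materials$nucleus$C01n,
      Dn = 2 / (1e4 * mu_base))
  } else if (study == "disc_size") {
    # central disc diameter changed while the endplate diameter stays
    # anatomically consistent with the bone; NP:AF ratio preserved
    geometry$size_scale <- 1 + as.numeric(level)
  } else if (study == "np_af_ratio") {
    geometry$np_af_ratio <- as.numeric(level)
  }
  list(geometry = geometry, materials = materials)
}

#' Run one sensitivity study over a cohort
#'
#' For each specimen the baseline model (at the study's baseline level) is
#' solved up to the protocol's maximum load; every other level is then
#' re-solved at the same applied displacement and characterised with the
#' tri-linear fit. Each level's pooled stiffness triples are compared
#' against the baseline's with Lin's CCC, slope and intercept. The annulus
#' fibre parameters default to the literature pair (2.45 MPa, 2.17).
#'
#' @param cohort List of specimens, each with a `geometry` field (as from
#'   [gen_osteodisc_cohort()]), or a list of [osteodisc_geometry()]
#'   objects.
#' @param spec A [sensitivity_study_spec()].
#' @param params Annulus [goh_params()] used for all runs.
#' @param materials_base Material set; annulus replaced by `params`.
#' @param protocol A [load_protocol()].
#' @param resolution A [mesh_resolution()].
#' @param bc Support condition.
#' @return List of class `sensitivity_result`: `study`, `baseline_level`,
#'   `stiffness` (data frame: specimen, level, k_initial, k_transition,
#'   k_linear), `agreement` (data frame: one row per non-baseline level
#'   with ccc, ci95_low, ci95_high, slope, intercept).
#' @export
run_sensitivity <- function(cohort, spec,
                            params = goh_params(k1 = 2.45, k2 = 2.17),
                            materials_base = osteodisc_materials(),
                            protocol = load_protocol(),
                            resolution = mesh_resolution(),
                            bc = "clamped") {
  stopifnot(inherits(spec, "sensitivity_study_spec"))
  geoms <- lapply(cohort, function(s)
    if (inherits(s, "osteodisc_geometry")) s else s$geometry)
  mats0 <- materials_base
  mats0$annulus <- params

  rows <- list()
  for (i in seq_along(geoms)) {
    base <- .apply_level(spec$study, spec$baseline_level, geoms[[i]], mats0)
    mesh_b <- build_mesh(base$geometry, resolution)
    d_i <- displacement_for_target_load(mesh_b, base$materials,
                                        protocol$max_load, bc = bc)
    proto_i <- load_protocol(max_load = protocol$max_load,
                             preload = protocol$preload,
                             n_steps = protocol$n_steps,
                             applied_displacement = as.numeric(d_i))
    for (lev in spec$levels) {
      var <- .apply_level(spec$study, lev, geoms[[i]], mats0)
      mesh_v <- if (identical(var$geometry, base$geometry)) mesh_b else
        build_mesh(var$geometry, resolution)
      cv <- tryCatch(
        solve_axial_compression(mesh_v, var$materials, proto_i, bc = bc),
        error = function(e) NULL)
      if (is.null(cv)) {
        warning("solver failed for specimen ", i, " at level ", lev,
                "; excluded")
        next
      }
      ks <- stiffness_values(trilinear_fit(cv))
      rows[[length(rows) + 1]] <- data.frame(
        specimen = i, level = as.character(lev),
        k_initial = ks[1], k_transition = ks[2], k_linear = ks[3],
        row.names = NULL)
    }
  }
  stiff <- do.call(rbind, rows)

  bl <- stiff[stiff$level == as.character(spec$baseline_level), ]
  agree <- list()
  for (lev in setdiff(as.character(spec$levels),
                      as.character(spec$baseline_level))) {
    vl <- stiff[stiff$level == lev, ]
    common <- intersect(bl$specimen, vl$specimen)
    if (length(common) == 0) next
    b <- bl[match(common, bl$specimen), ]
    v <- vl[match(common, vl$specimen), ]
    x <- c(b$k_initial, b$k_transition, b$k_linear)
    y <- c(v$k_initial, v$k_transition, v$k_linear)
    a <- lin_ccc(x, y)
    agree[[length(agree) + 1]] <- data.frame(
      level = lev, ccc = a$ccc, ci95_low = a$ci95_low,
      ci95_high = a$ci95_high, slope = a$slope, intercept = a$intercept,
      row.names = NULL)
  }
  structure(list(study = spec$study, baseline_level = spec$baseline_level,
                 stiffness = stiff,
                 agreement = do.call(rbind, agree)),
            class = "sensitivity_result")
}

#' Default full-study configuration
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param cohort A [cohort_spec()].
#' @param protocol A [load_protocol()].
#' @param resolution A [mesh_resolution()].
#' @param calibration A [calibration_settings()].
#' @param literature Literature fibre pair used for comparison runs.
#' @param n_calibration Specimens assigned to the calibration group
#'   (default half the cohort).
#' @param sensitivity Character vector of sensitivity studies to run
#'   (default none; see [sensitivity_study_spec()]).
#' @return Configuration list for [run_full_study()].
#' @export
default_study_config <- function(seed = 1,
                                 cohort = cohort_spec(),
                                 protocol = load_protocol(),
                                 resolution = mesh_resolution(),
                                 calibration = calibration_settings(),
                                 literature = c(2.45, 2.17),
                                 n_calibration = NULL,
                                 sensitivity = character(0)) {
  list(seed = as.integer(seed), cohort = cohort, protocol = protocol,
       resolution = resolution, calibration = calibration,
       literature = literature, n_calibration = n_calibration,
       sensitivity = sensitivity)
}

#' Read a study configuration from YAML
#'
#' Sections `cohort`, `protocol`, `resolution`, `calibration` override the
#' corresponding constructor defaults field by field; top-level keys
#' `seed`, `literature`, `n_calibration` and `sensitivity` are taken as
#' is.
#'
#' @param path YAML file path.
#' @return Configuration list for [run_full_study()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_study_config()
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$cohort)) cfg$cohort <- do.call(cohort_spec, y$cohort)
  if (!is.null(y$protocol)) cfg$protocol <- do.call(load_protocol, y$protocol)
  if (!is.null(y$resolution))
    cfg$resolution <- do.call(mesh_resolution, y$resolution)
  if (!is.null(y$calibration)) {
    ca <- y$calibration
    if (!is.null(ca$init)) ca$init <- as.numeric(ca$init)
    if (!is.null(ca$lower)) ca$lower <- as.numeric(ca$lower)
    if (!is.null(ca$upper)) ca$upper <- as.numeric(ca$upper)
    cfg$calibration <- do.call(calibration_settings, ca)
  }
  if (!is.null(y$literature)) cfg$literature <- as.numeric(y$literature)
  if (!is.null(y$n_calibration)) cfg$n_calibration <- as.integer(y$n_calibration)
  if (!is.null(y$sensitivity)) cfg$sensitivity <- as.character(y$sensitivity)
  cfg
}

#' Run the full synthetic study end to end
#'
#' Composes the whole pipeline on a synthetic cohort: opening-study
#' characterisation (hoop strain, circularity, nucleus-to-annulus ratio,
#' paired comparisons between relaxation states), functional-modulus
#' extraction from lamella curves (with the derived ground-matrix C10),
#' pseudo-experimental compression curves, a seed-controlled disjoint
#' calibration/validation split, specimen-specific and group calibration,
#' a literature-parameter comparison, and validation of the group pair on
#' the held-out specimens. Deterministic given the configuration.
#'
#' @param config Configuration from [default_study_config()] or
#'   [read_study_config()].
#' @return List of class `study_report`; see the fields in the examples of
#'   the package vignette. All tables are plain data frames.
#' @export
run_full_study <- function(config = default_study_config()) {
  seed <- config$seed
  spec <- config$cohort
  protocol <- config$protocol

  # --- tissue characterisation -------------------------------------------
  opening <- gen_opening_study(spec, seed)
  summaries <- lapply(opening, summarise_disc)
  eh10 <- vapply(summaries, `[[`, numeric(1), "hoop_strain")
  ehlate <- vapply(summaries, `[[`, numeric(1), "hoop_strain_late")
  hoop_tab <- data.frame(
    disc_id = vapply(summaries, `[[`, character(1), "disc_id"),
    mean_diameter = vapply(summaries, `[[`, numeric(1), "mean_diameter"),
    circularity_dev = vapply(summaries, `[[`, numeric(1), "circularity_dev"),
    np_af_ratio = vapply(summaries, `[[`, numeric(1), "np_af_ratio"),
    hoop_strain_10min = eh10, hoop_strain_late = ehlate)
  hoop_tests <- paired_t_and_normality(ehlate, eh10)
  eps_h <- mean(eh10)

  # --- functional modulus -------------------------------------------------
  lam <- gen_lamella_study(spec, seed + 1L)
  fm <- lapply(lam, function(cv)
    tryCatch(functional_modulus(cv, eps_h), error = function(e) NULL))
  ok <- !vapply(fm, is.null, logical(1))
  moduli <- vapply(fm[ok], `[[`, numeric(1), "modulus")
  pearson <- vapply(fm[ok], `[[`, numeric(1), "pearson_r")
  C10 <- matrix_modulus_to_C10(mean(moduli))
  materials <- osteodisc_materials()
  materials$annulus <- goh_params(C10 = C10)

  # --- osteodisc cohort and split ----------------------------------------
  cohort <- gen_osteodisc_cohort(spec, seed + 2L)
  n <- length(cohort)
  if (n < 2) stop("at least 2 osteodiscs are needed for a ",
                  "calibration/validation split")
  n_cal <- if (is.null(config$n_calibration)) n %/% 2 else config$n_calibration
  if (n_cal < 2 || n_cal >= n)
    stop("calibration/validation split needs a calibration group of at ",
         "least 2 and at least one validation specimen")
  split_idx <- withr::with_seed(seed + 3L, sample(n, n_cal))
  curves <- lapply(seq_len(n), function(i)
    gen_pseudo_experiment(cohort[[i]]$geometry, cohort[[i]]$truth,
                          protocol = protocol,
                          force_noise_sd = spec$force_noise_sd,
                          seed = seed + 100L + i,
                          materials_base = materials,
                          resolution = config$resolution))

  cal_i <- sort(split_idx); val_i <- setdiff(seq_len(n), cal_i)
  cal_curves <- curves[cal_i]
  cal_geoms <- lapply(cohort[cal_i], `[[`, "geometry")
  val_curves <- curves[val_i]
  val_geoms <- lapply(cohort[val_i], `[[`, "geometry")

  # --- calibration --------------------------------------------------------
  spec_cal <- lapply(seq_along(cal_curves), function(j)
    calibrate_specimen(cal_curves[[j]], cal_geoms[[j]], materials,
                       settings = config$calibration, protocol = protocol,
                       resolution = config$resolution))
  group_cal <- calibrate_group(cal_curves, cal_geoms, materials,
                               settings = config$calibration,
                               protocol = protocol,
                               resolution = config$resolution)
  lit <- config$literature
  lit_params <- goh_params(C10 = C10, k1 = lit[1], k2 = lit[2])
  group_params <- goh_params(C10 = C10, k1 = group_cal$k1, k2 = group_cal$k2)

  cal_tab <- data.frame(
    specimen = cal_i,
    true_k1 = vapply(cohort[cal_i], function(s) s$truth$k1, numeric(1)),
    true_k2 = vapply(cohort[cal_i], function(s) s$truth$k2, numeric(1)),
    k1 = vapply(spec_cal, `[[`, numeric(1), "k1"),
    k2 = vapply(spec_cal, `[[`, numeric(1), "k2"),
    rms = vapply(spec_cal, `[[`, numeric(1), "rms"),
    converged_by = vapply(spec_cal, `[[`, character(1), "converged_by"))

  val_group <- validate_specimens(val_curves, val_geoms, group_params,
                                  materials, protocol = protocol,
                                  resolution = config$resolution)
  val_lit <- validate_specimens(val_curves, val_geoms, lit_params,
                                materials, protocol = protocol,
                                resolution = config$resolution)
  cal_lit <- validate_specimens(cal_curves, cal_geoms, lit_params,
                                materials, protocol = protocol,
                                resolution = config$resolution)

  # --- sensitivity (optional) --------------------------------------------
  sens <- lapply(config$sensitivity, function(s)
    run_sensitivity(cohort[cal_i], sensitivity_study_spec(s),
                    params = lit_params, materials_base = materials,
                    protocol = protocol, resolution = config$resolution))
  names(sens) <- config$sensitivity

  structure(list(
    seed = seed,
    hoop = list(table = hoop_tab, tests = hoop_tests,
                mean_hoop_strain = eps_h),
    modulus = list(values = moduli, pearson_r = pearson,
                   mean = mean(moduli), sd = sd(moduli), C10 = C10),
    split = list(calibration = cal_i, validation = val_i),
    calibration = list(per_specimen = cal_tab, group = group_cal,
                       literature = lit,
                       literature_mean_rms = cal_lit$mean_rms),
    validation = list(group = val_group, literature = val_lit),
    sensitivity = sens), class = "study_report")
}

#' @exportS3Method base::print
print.study_report <- function(x, ...) {
  cat("Synthetic osteodisc study report\n")
  cat(sprintf("  hoop strain (10 min): %.3f +/- %.3f\n",
              mean(x$hoop$table$hoop_strain_10min),
              sd(x$hoop$table$hoop_strain_10min)))
  cat(sprintf("  functional modulus: %.2f +/- %.2f MPa (C10 = %.3f MPa)\n",
              x$modulus$mean, x$modulus$sd, x$modulus$C10))
  cat(sprintf("  group calibration: k1 = %.3f, k2 = %.3f (RMS %.1f N)\n",
              x$calibration$group$k1, x$calibration$group$k2,
              x$calibration$group$rms))
  cat(sprintf("  validation (group params): mean RMS %.1f N, CCC %.3f\n",
              x$validation$group$mean_rms, x$validation$group$agreement$ccc))
  cat(sprintf("  validation (literature):  mean RMS %.1f N, CCC %.3f\n",
              x$validation$literature$mean_rms,
              x$validation$literature$agreement$ccc))
  invisible(x)
}
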