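# Seeded synthetic-cohort generators. The defaults encode the study
# conditions of the experimental cohorts: n = 5 opening-study discs with a
# mean 10-min opening angle of 49.6 deg (sd 9.2 deg) and
# nucleus-to-annulus ratio 0.51 (sd 0.05); n = 16 lamellae with functional
# moduli 1.5 +/- 0.7 MPa; n = 12 osteodiscs compressed to 2100 N with a
# 10 N preload. Every generator is a pure function of (spec, seed).

#' Synthetic cohort specification
#'
#' Distribution parameters for the three generated data sets. Normal
#' distributions are truncated to physical validity; the truncation bounds
#' are recorded in the generated objects' attributes.
#'
#' @param n_discs Opening-study discs (default 5).
#' @param opening_angle_mean,opening_angle_sd 10-min opening angle (deg).
#' @param late_increment_mean,late_increment_sd Additional opening between
#'   the 10-min and 20-25-min states (deg); truncated at 0 so the later
#'   angle never decreases.
#' @param disc_diameter_mean,disc_diameter_sd Disc diameter (mm).
#' @param disc_height_mean,disc_height_sd Disc height (mm).
#' @param np_af_ratio_mean,np_af_ratio_sd Nucleus-to-annulus diameter
#'   ratio; truncated to (0.3, 0.7).
#' @param repeat_noise_frac Within-disc repeat-measurement noise, as a
#'   fraction of the measured quantity (default 0.02; assumed, the repeat
#'   spread itself was not reported).
#' @param n_lamellae Single-lamella tension specimens (default 16).
#' @param lamella_modulus_mean,lamella_modulus_sd Functional modulus (MPa),
#'   truncated at 0.2 MPa.
#' @param lamella_toe_strain_mean,lamella_toe_strain_sd Toe-end strain.
#' @param lamella_failure_lo,lamella_failure_hi Uniform failure-strain
#'   range.
#' @param lamella_noise_frac Stress noise, fraction of each curve's maximum
#'   stress (default 0.05).
#' @param n_osteodiscs Compression specimens (default 12).
#' @param k1_meanlog,k1_sdlog,k2_meanlog,k2_sdlog Log-normal distribution
#'   of the per-specimen true fibre pair, centred on the group-average
#'   calibration (1.43 MPa, 1.63) with spreads implied by the per-specimen
#'   calibrated ranges (0.60-2.69 and 1.10-2.63).
#' @param force_noise_sd Additive force noise on pseudo-experimental curves
#'   (N; default 20, about 1 % of the 2100 N maximum load).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_discs = 5,
                        opening_angle_mean = 49.6, opening_angle_sd = 9.2,
                        late_increment_mean = 13, late_increment_sd = 5,
                        disc_diameter_mean = 30, disc_diameter_sd = 2,
                        disc_height_mean = 9, disc_height_sd = 1,
                        np_af_ratio_mean = 0.51, np_af_ratio_sd = 0.05,
                        repeat_noise_frac = 0.02,
                        n_lamellae = 16,
                        lamella_modulus_mean = 1.5, lamella_modulus_sd = 0.7,
                        lamella_toe_strain_mean = 0.17,
                        lamella_toe_strain_sd = 0.03,
                        lamella_failure_lo = 0.4, lamella_failure_hi = 3.0,
                        lamella_noise_frac = 0.05,
                        n_osteodiscs = 12,
                        k1_meanlog = log(1.43), k1_sdlog = 0.4,
                        k2_meanlog = log(1.63), k2_sdlog = 0.25,
                        force_noise_sd = 20) {
  sds <- c(opening_angle_sd, late_increment_sd, disc_diameter_sd,
           disc_height_sd, np_af_ratio_sd, repeat_noise_frac,
           lamella_modulus_sd, lamella_toe_strain_sd, lamella_noise_frac,
           force_noise_sd)
  if (any(sds < 0)) stop("all spreads/noise levels must be >= 0")
  if (any(c(n_discs, n_lamellae, n_osteodiscs) < 1))
    stop("all counts must be >= 1")
  spec <- as.list(environment())
  spec$sds <- NULL
  structure(spec, class = "cohort_spec")
}

# internal: truncated-normal draw by rejection (spreads here are mild, so
# rejection is cheap and keeps the draw exact)
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic opening study
#'
#' Per disc: a true diameter, nucleus diameter (via the ratio), a 10-min
#' opening angle and a non-negative later increment are drawn from the
#' spec's truncated normal distributions; each diameter is then measured
#' six times with multiplicative repeat noise. Angles are stored in
#' radians.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical (spec, seed) give identical output.
#' @return List of [opening_study_record()] objects of length
#'   `spec$n_discs`.
#' @export
gen_opening_study <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    lapply(seq_len(spec$n_discs), function(i) {
      dia <- .rtnorm(1, spec$disc_diameter_mean, spec$disc_diameter_sd,
                     lo = 5)
      ratio <- .rtnorm(1, spec$np_af_ratio_mean, spec$np_af_ratio_sd,
                       lo = 0.3, hi = 0.7)
      ang10 <- .rtnorm(1, spec$opening_angle_mean, spec$opening_angle_sd,
                       lo = 2, hi = 170) * pi / 180
      inc <- .rtnorm(1, spec$late_increment_mean, spec$late_increment_sd,
                     lo = 0, hi = 90) * pi / 180
      noise <- function(x) x * (1 + spec$repeat_noise_frac * rnorm(6))
      opening_study_record(
        disc_id = sprintf("synth_disc_%02d", i),
        diameters_intact = noise(dia),
        diameters_relaxed_10min = noise(dia),
        opening_angle_10min = ang10,
        opening_angle_late = min(ang10 + inc, 2 * pi - 1e-6),
        nucleus_diameter = ratio * dia)
    })
  })
}

#' Generate synthetic single-lamella tension curves
#'
#' Each curve has a smooth cubic toe below a per-specimen toe strain
#' (C1-continuous at the junction) and a linear region with a per-specimen
#' modulus drawn from the cohort specification's truncated normal, truncated at the
#' specimen's failure strain, with additive stress noise proportional to
#' the curve's maximum stress. The generating modulus and toe strain are
#' attached as attributes `true_modulus` and `toe_strain`.
#'
#' @inheritParams gen_opening_study
#' @param n_points Samples per curve (default 60).
#' @return List of [lamella_curve()] objects of length `spec$n_lamellae`.
#' @export
gen_lamella_study <- function(spec, seed, n_points = 60) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    lapply(seq_len(spec$n_lamellae), function(i) {
      E <- .rtnorm(1, spec$lamella_modulus_mean, spec$lamella_modulus_sd,
                   lo = 0.2)
      eps_t <- .rtnorm(1, spec$lamella_toe_strain_mean,
                       spec$lamella_toe_strain_sd, lo = 0.05, hi = 0.35)
      eps_f <- runif(1, spec$lamella_failure_lo, spec$lamella_failure_hi)
      strain <- seq(0, eps_f, length.out = n_points)
      stress <- ifelse(strain <= eps_t,
                       E * strain^3 / (3 * eps_t^2),
                       E * eps_t / 3 + E * (strain - eps_t))
      stress <- stress + spec$lamella_noise_frac * max(stress) *
        rnorm(n_points)
      cv <- lamella_curve(strain, pmax(stress, 0), failure_strain = eps_f)
      attr(cv, "true_modulus") <- E
      attr(cv, "toe_strain") <- eps_t
      cv
    })
  })
}

#' Generate a synthetic osteodisc cohort
#'
#' Geometries with diameter, height and nucleus-to-annulus ratio drawn from
#' the cohort specification's truncated normals, and per-specimen true fibre pairs
#' `(k1, k2)` drawn log-normally around the group-average calibration.
#'
#' @inheritParams gen_opening_study
#' @return List of length `spec$n_osteodiscs`; each element has fields
#'   `id`, `geometry` ([osteodisc_geometry()]) and `truth`
#'   ([goh_params()] carrying the specimen's true fibre pair).
#' @export
gen_osteodisc_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    lapply(seq_len(spec$n_osteodiscs), function(i) {
      dia <- .rtnorm(1, spec$disc_diameter_mean, spec$disc_diameter_sd,
                     lo = 5)
      hgt <- .rtnorm(1, spec$disc_height_mean, spec$disc_height_sd, lo = 2)
      ratio <- .rtnorm(1, spec$np_af_ratio_mean, spec$np_af_ratio_sd,
                       lo = 0.3, hi = 0.7)
      k1 <- exp(.rtnorm(1, spec$k1_meanlog, spec$k1_sdlog,
                        lo = log(0.3), hi = log(5)))
      k2 <- exp(.rtnorm(1, spec$k2_meanlog, spec$k2_sdlog,
                        lo = log(0.5), hi = log(5)))
      list(id = sprintf("synth_osteodisc_%02d", i),
           geometry = osteodisc_geometry(disc_diameter = dia,
                                         disc_height = hgt,
                                         np_af_ratio = ratio),
           truth = goh_params(k1 = k1, k2 = k2))
    })
  })
}

#' Generate a pseudo-experimental compression curve
#'
#' Forward-solves the specimen at its true fibre parameters up to the
#' protocol's maximum load, then emulates the measurement chain: the
#' displacement origin is offset by a random seating displacement (the
#' structure the 10 N preload zeroing removes), a (0, 0) start point is
#' prepended, and i.i.d. Gaussian force noise is added. The returned curve
#' is un-zeroed; the analysis pipeline must re-zero it at the preload, as
#' the experiment did.
#'
#' @param geometry The specimen's [osteodisc_geometry()].
#' @param truth_params True annulus [goh_params()].
#' @param protocol A [load_protocol()].
#' @param force_noise_sd Additive force noise (N); 0 gives the exact
#'   forward-model output shifted by the seating offset.
#' @param seed Integer seed (drives the seating offset and the noise only).
#' @param materials_base Material set; its annulus is replaced by
#'   `truth_params`.
#' @param resolution Mesh resolution for the forward solve.
#' @param bc Support condition.
#' @return An un-zeroed [force_displacement_curve()] with attributes
#'   `truth` (the generating parameters) and `seat_offset` (mm).
#' @export
gen_pseudo_experiment <- function(geometry, truth_params,
                                  protocol = load_protocol(),
                                  force_noise_sd = 20, seed = 1,
                                  materials_base = osteodisc_materials(),
                                  resolution = mesh_resolution(),
                                  bc = "clamped") {
  stopifnot(inherits(truth_params, "goh_params"))
  mats <- materials_base
  mats$annulus <- truth_params
  mesh <- build_mesh(geometry, resolution)
  sim <- solve_axial_compression(mesh, mats, protocol, bc = bc)
  withr::with_seed(seed, {
    d0 <- runif(1, 0.05, 0.25)
    d <- c(0, sim$displacement + d0)
    f <- c(0, sim$force)
    if (force_noise_sd > 0)
      f <- pmax(f + rnorm(length(f), 0, force_noise_sd), 0)
    out <- force_displacement_curve(d, f)
    attr(out, "truth") <- truth_params
    attr(out, "seat_offset") <- d0
    out
  })
}
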