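# Tissue-level characterisation: hoop (pre-)strain from disc opening,
# circularity of the disc cross-section, and the functional
# extrafibrillar-matrix modulus from single-lamella tension curves.

#' Hoop strain of the annulus from the opening angle of a radially cut disc
#'
#' A radial cut through the annulus fibrosus releases the circumferential
#' residual (pre-)strain; the disc opens by an angle `phi`. Assuming the disc
#' stays circular with unchanged diameter, the circumferential strain that
#' would close the opened annulus back to a full circle is
#' `phi / (2*pi - phi)`: the opened outer perimeter spans an arc angle of
#' `2*pi - phi` and must be stretched back onto `2*pi`.
#'
#' @param phi Opening angle in radians, in `[0, 2*pi)`. Vectorised.
#' @return Dimensionless hoop strain (>= 0), strictly increasing in `phi`.
#' @seealso [opening_angle_from_hoop_strain()] for the inverse.
#' @examples
#' hoop_strain(0)          # closed disc, no pre-strain
#' hoop_strain(pi)         # 100 % strain
#' hoop_strain(49.6 * pi / 180)
#' @export
hoop_strain <- function(phi) {
  if (!is.numeric(phi) || anyNA(phi))
    stop("`phi` must be numeric and non-missing")
  if (any(phi < 0) || any(phi >= 2 * pi))
    stop("opening angle must satisfy 0 <= phi < 2*pi (radians)")
  phi / (2 * pi - phi)
}

#' Opening angle implied by a hoop strain
#'
#' Inverse of [hoop_strain()]: `phi = 2*pi*eps / (1 + eps)`.
#'
#' @param eps Dimensionless hoop strain, `eps >= 0`.
#' @return Opening angle in radians.
#' @export
opening_angle_from_hoop_strain <- function(eps) {
  if (!is.numeric(eps) || anyNA(eps) || any(eps < 0))
    stop("`eps` must be a non-negative numeric")
  2 * pi * eps / (1 + eps)
}

#' Circularity deviation of a set of diameter measurements
#'
#' Sample standard deviation (n - 1 denominator) of the ratios of the
#' measured diameters to their mean. Zero for a perfect circle; for caliper
#' widths of an ellipse taken at equally spaced orientations the statistic
#' tends to 0.592 as the aspect ratio tends to infinity. Scale-invariant and
#' invariant to permutation of the measurements.
#'
#' @param diameters Numeric vector of at least 3 positive lengths (mm).
#' @return Dimensionless deviation, >= 0.
#' @examples
#' circularity_deviation(rep(30, 6))                        # 0
#' circularity_deviation(ellipse_caliper_diameters(2))      # 1:2 ellipse
#' circularity_deviation(ellipse_caliper_diameters(1e6))    # -> 0.592
#' @export
circularity_deviation <- function(diameters) {
  if (!is.numeric(diameters) || anyNA(diameters))
    stop("`diameters` must be numeric and non-missing")
  if (length(diameters) < 3)
    stop("need at least 3 diameter measurements")
  if (any(diameters <= 0))
    stop("all diameters must be positive")
  sd(diameters / mean(diameters))
}

#' Caliper-width diameters of an ellipse at equally spaced orientations
#'
#' Width of an ellipse with semi-axes `a = 1`, `b = 1/aspect` measured
#' between parallel jaws at orientations `0, 180/n, ..., 180*(n-1)/n`
#' degrees: `w(theta) = 2 * sqrt(a^2 cos^2 theta + b^2 sin^2 theta)`.
#' Used to evaluate the circularity-deviation statistic on known shapes.
#'
#' @param aspect Aspect ratio a/b >= 1.
#' @param n Number of equally distributed measurements (default 6).
#' @return Numeric vector of `n` widths (arbitrary units).
#' @export
ellipse_caliper_diameters <- function(aspect, n = 6) {
  stopifnot(is.numeric(aspect), length(aspect) == 1, aspect >= 1, n >= 3)
  theta <- seq(0, pi, length.out = n + 1)[seq_len(n)]
  2 * sqrt(cos(theta)^2 + (1 / aspect)^2 * sin(theta)^2)
}

#' Opening-study record for a single disc
#'
#' Repeat-measured diameters and opening angles for one intervertebral disc
#' at the intact state and after relaxation of the radial cut. Six repeat
#' measurements per quantity account for manual identification variability.
#'
#' @param disc_id Character label.
#' @param diameters_intact Six intact-state diameters (mm).
#' @param diameters_relaxed_10min Six diameters after 10 min relaxation (mm).
#' @param opening_angle_10min Opening angle after 10 min (radians).
#' @param opening_angle_late Opening angle after 20-25 min (radians).
#' @param nucleus_diameter Nucleus diameter (mm).
#' @return An object of class `opening_study_record`.
#' @export
opening_study_record <- function(disc_id, diameters_intact,
                                 diameters_relaxed_10min,
                                 opening_angle_10min, opening_angle_late,
                                 nucleus_diameter) {
  for (d in list(diameters_intact, diameters_relaxed_10min)) {
    if (length(d) != 6)
      stop("exactly 6 repeat diameter measurements are required per state")
    if (any(!is.finite(d)) || any(d <= 0))
      stop("all diameters must be finite and positive")
  }
  for (a in list(opening_angle_10min, opening_angle_late)) {
    if (!is.finite(a) || a < 0 || a >= 2 * pi)
      stop("opening angles must lie in [0, 2*pi) radians")
  }
  if (!is.finite(nucleus_diameter) || nucleus_diameter <= 0)
    stop("nucleus diameter must be positive")
  structure(
    list(disc_id = as.character(disc_id),
         diameters_intact = as.numeric(diameters_intact),
         diameters_relaxed_10min = as.numeric(diameters_relaxed_10min),
         opening_angle_10min = opening_angle_10min,
         opening_angle_late = opening_angle_late,
         nucleus_diameter = nucleus_diameter),
    class = "opening_study_record")
}

#' Shape and pre-strain summary of one opening-study record
#'
#' Averages the six repeat measurements before deriving quantities: the mean
#' intact diameter, the circularity deviation of the intact diameters, the
#' nucleus-to-annulus diameter ratio, and the hoop strain from the 10-min
#' opening angle.
#'
#' @param record An [opening_study_record()].
#' @return List of class `disc_shape_summary` with fields `disc_id`,
#'   `mean_diameter` (mm), `circularity_dev`, `circularity_dev_10min`,
#'   `np_af_ratio`, `hoop_strain`, `hoop_strain_late`.
#' @export
summarise_disc <- function(record) {
  stopifnot(inherits(record, "opening_study_record"))
  mean_d <- mean(record$diameters_intact)
  structure(
    list(disc_id = record$disc_id,
         mean_diameter = mean_d,
         circularity_dev = circularity_deviation(record$diameters_intact),
         circularity_dev_10min =
           circularity_deviation(record$diameters_relaxed_10min),
         np_af_ratio = record$nucleus_diameter / mean_d,
         hoop_strain = hoop_strain(record$opening_angle_10min),
         hoop_strain_late = hoop_strain(record$opening_angle_late)),
    class = "disc_shape_summary")
}

#' Engineering stress-strain curve of a single lamella
#'
#' Converts a load-displacement record of a single-lamella tension test to
#' engineering strain and engineering stress using the post-preconditioning
#' length and the initial cross-sectional area.
#'
#' @param load Load values (N).
#' @param disp Displacement values (mm), same length as `load`.
#' @param length0 Reference length at the end of preconditioning (mm).
#' @param area0 Initial cross-sectional area (mm^2).
#' @param failure_strain Optional failure strain; when `NULL` it is detected
#'   with [detect_failure_strain()].
#' @return An object of class `lamella_curve` with fields `strain`, `stress`
#'   (MPa) and `failure_strain`.
#' @export
engineering_curve <- function(load, disp, length0, area0,
                              failure_strain = NULL) {
  if (!is.finite(length0) || length0 <= 0) stop("`length0` must be positive")
  if (!is.finite(area0) || area0 <= 0) stop("`area0` must be positive")
  if (length(load) != length(disp))
    stop("`load` and `disp` must have the same length")
  lamella_curve(strain = disp / length0, stress = load / area0,
                failure_strain = failure_strain)
}

#' Construct a lamella stress-strain curve
#'
#' @param strain Engineering strain, strictly increasing.
#' @param stress Engineering stress (MPa).
#' @param failure_strain Optional; detected from the curve when `NULL`.
#' @return Object of class `lamella_curve`.
#' @export
lamella_curve <- function(strain, stress, failure_strain = NULL) {
  strain <- as.numeric(strain); stress <- as.numeric(stress)
  if (length(strain) != length(stress))
    stop("`strain` and `stress` must have the same length")
  if (length(strain) > 1 && any(diff(strain) <= 0))
    stop("`strain` must be strictly increasing")
  if (is.null(failure_strain))
    failure_strain <- detect_failure_strain(strain, stress)
  if (failure_strain > max(strain) + 1e-12)
    stop("`failure_strain` cannot exceed the last strain sample")
  structure(list(strain = strain, stress = stress,
                 failure_strain = failure_strain),
            class = "lamella_curve")
}

#' Detect the failure strain of a lamella curve
#'
#' First sample after the global stress maximum showing a stress drop of at
#' least 5 % of the maximum; when no such drop exists the last sample is
#' used (tests were truncated at failure or 300 % strain).
#'
#' @param strain,stress Numeric vectors of equal length.
#' @return The failure strain.
#' @export
detect_failure_strain <- function(strain, stress) {
  n <- length(stress)
  if (n == 0) stop("empty curve")
  imax <- which.max(stress)
  if (imax < n) {
    drop <- which(stress[(imax + 1):n] <= 0.95 * stress[imax])
    if (length(drop) > 0) return(strain[imax + drop[1]])
  }
  strain[n]
}

#' Functional extrafibrillar-matrix modulus
#'
#' Ordinary least-squares slope of engineering stress versus strain over the
#' functional range `[eps_h, failure_strain]`, i.e. between the hoop strain
#' present in the intact disc and the failure strain. Pearson's correlation
#' over the same range quantifies the linearity of the behaviour there.
#'
#' @param curve A [lamella_curve()].
#' @param eps_h Hoop strain defining the lower end of the functional range.
#' @return List of class `functional_modulus` with fields `modulus` (MPa),
#'   `pearson_r` (`NA` and `degenerate = TRUE` for constant stress),
#'   `strain_lo`, `strain_hi`, `n`.
#' @export
functional_modulus <- function(curve, eps_h) {
  stopifnot(inherits(curve, "lamella_curve"))
  if (!is.finite(eps_h) || eps_h < 0) stop("`eps_h` must be non-negative")
  sel <- curve$strain >= eps_h & curve$strain <= curve$failure_strain
  if (sum(sel) < 3)
    stop("fewer than 3 samples between the hoop strain and the failure ",
         "strain: functional range cannot be fitted")
  x <- curve$strain[sel]; y <- curve$stress[sel]
  degenerate <- sd(y) < 1e-14 * max(1, abs(mean(y)))
  fit <- lm(y ~ x)
  structure(
    list(modulus = unname(coef(fit)[2]),
         pearson_r = if (degenerate) NA_real_ else cor(x, y),
         strain_lo = eps_h,
         strain_hi = curve$failure_strain,
         n = sum(sel),
         degenerate = degenerate),
    class = "functional_modulus")
}

#' @exportS3Method base::print
print.functional_modulus <- function(x, ...) {
  cat(sprintf(
    "Functional modulus: %.3f MPa over strain [%.3f, %.3f] (n = %d, r = %s)\n",
    x$modulus, x$strain_lo, x$strain_hi, x$n,
    if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r)))
  invisible(x)
}

# ---- CSV interfaces ---------------------------------------------------------

#' Write opening-study records to CSV
#'
#' Long format with columns `disc_id`, `state`, `repeat_index`,
#' `diameter_mm`, `opening_angle_deg`. States are `intact`, `relaxed_10min`
#' (six diameter rows each, the relaxed rows carrying the 10-min angle),
#' `relaxed_late` (angle only) and `nucleus` (diameter only). Angles are
#' stored in degrees on disk and converted to radians on read.
#'
#' @param records List of [opening_study_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_opening_study <- function(records, path) {
  if (inherits(records, "opening_study_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    rbind(
      data.frame(disc_id = r$disc_id, state = "intact", repeat_index = 1:6,
                 diameter_mm = r$diameters_intact, opening_angle_deg = NA_real_),
      data.frame(disc_id = r$disc_id, state = "relaxed_10min", repeat_index = 1:6,
                 diameter_mm = r$diameters_relaxed_10min,
                 opening_angle_deg = r$opening_angle_10min * 180 / pi),
      data.frame(disc_id = r$disc_id, state = "relaxed_late", repeat_index = 1,
                 diameter_mm = NA_real_,
                 opening_angle_deg = r$opening_angle_late * 180 / pi),
      data.frame(disc_id = r$disc_id, state = "nucleus", repeat_index = 1,
                 diameter_mm = r$nucleus_diameter, opening_angle_deg = NA_real_))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read opening-study records from CSV
#'
#' @param path CSV written by [write_opening_study()] (or following the same
#'   layout).
#' @return List of [opening_study_record()] objects, one per disc.
#' @export
read_opening_study <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("disc_id", "state", "repeat_index", "diameter_mm",
            "opening_angle_deg")
  if (!all(need %in% names(df)))
    stop("opening-study CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$disc_id), function(d) {
    gi <- d[d$state == "intact", ]
    gr <- d[d$state == "relaxed_10min", ]
    gl <- d[d$state == "relaxed_late", ]
    gn <- d[d$state == "nucleus", ]
    opening_study_record(
      disc_id = d$disc_id[1],
      diameters_intact = gi$diameter_mm[order(gi$repeat_index)],
      diameters_relaxed_10min = gr$diameter_mm[order(gr$repeat_index)],
      opening_angle_10min = mean(gr$opening_angle_deg) * pi / 180,
      opening_angle_late = mean(gl$opening_angle_deg) * pi / 180,
      nucleus_diameter = mean(gn$diameter_mm))
  })
}

#' Write a lamella stress-strain curve to CSV
#'
#' Columns `strain`, `stress_MPa`.
#'
#' @param curve A [lamella_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lamella_curve <- function(curve, path) {
  stopifnot(inherits(curve, "lamella_curve"))
  write.csv(data.frame(strain = curve$strain, stress_MPa = curve$stress),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a lamella stress-strain curve from CSV
#'
#' @param path CSV with columns `strain` and `stress_MPa`.
#' @param failure_strain Optional known failure strain.
#' @return A [lamella_curve()].
#' @export
read_lamella_curve <- function(path, failure_strain = NULL) {
  df <- read.csv(path)
  if (!all(c("strain", "stress_MPa") %in% names(df)))
    stop("lamella CSV must have columns `strain` and `stress_MPa`")
  lamella_curve(df$strain, df$stress_MPa, failure_strain)
}
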