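# Response characterisation: continuous tri-linear stiffness fit of
# force-displacement curves and the RMS load-difference cost used by the
# inverse calibration.

# internal: least squares of a continuous 3-segment piecewise-linear model
# with breakpoints (d1, d2), via the hinge basis
# F = b0 + s1*d + c2*(d - d1)_+ + c3*(d - d2)_+
.trilinear_ls <- function(d, f, d1, d2) {
  X <- cbind(1, d, pmax(d - d1, 0), pmax(d - d2, 0))
  fit <- lm.fit(X, f)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  res <- f - X %*% beta
  list(beta = beta, sse = sum(res^2))
}

#' Continuous tri-linear fit of a force-displacement curve
#'
#' Least-squares fit of a continuous three-segment piecewise-linear
#' function, yielding the initial, transition and linear stiffness values
#' and the two transition displacements. The breakpoints are found by an
#' exhaustive search over all admissible sample pairs (at least two samples
#' per segment, ties broken towards the smallest pair), followed by
#' Nelder-Mead refinement of the breakpoint positions; the refined fit is
#' kept only if it improves the sum of squared errors, so the result is
#' never worse than the best grid pair.
#'
#' @param curve A [force_displacement_curve()] with at least 6 samples and
#'   strictly increasing displacements.
#' @return Object of class `trilinear_fit` with fields `k_initial`,
#'   `k_transition`, `k_linear` (N/mm), `d1`, `d2` (mm), `sse` (N^2),
#'   `intercept` (N) and `degenerate` (all slopes equal).
#' @export
trilinear_fit <- function(curve) {
  stopifnot(inherits(curve, "force_displacement_curve"))
  d <- curve$displacement; f <- curve$force
  n <- length(d)
  if (n < 6) stop("tri-linear fit needs at least 6 samples")
  if (any(diff(d) <= 0))
    stop("displacement must be strictly increasing for the tri-linear fit")

  # grid search: d1 at sample i (segment 1 = samples 1..i), d2 at sample j
  # (segment 2 = samples i+1..j), each segment keeping >= 2 samples
  best <- NULL
  for (i in 2:(n - 4)) {
    for (j in (i + 2):(n - 2)) {
      cand <- .trilinear_ls(d, f, d[i], d[j])
      if (is.null(best) || cand$sse < best$sse - 1e-12) {
        best <- cand; best$d1 <- d[i]; best$d2 <- d[j]
      }
    }
  }

  # local refinement of the breakpoint pair
  lo <- d[2]; hi <- d[n - 1]
  gap <- min(diff(d)) / 2
  obj <- function(p) {
    if (p[1] < lo || p[2] > hi || p[2] - p[1] < gap) return(1e30 * (1 + sum(abs(p))))
    .trilinear_ls(d, f, p[1], p[2])$sse
  }
  ref <- optim(c(best$d1, best$d2), obj, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-12))
  if (ref$value < best$sse) {
    best <- .trilinear_ls(d, f, ref$par[1], ref$par[2])
    best$d1 <- ref$par[1]; best$d2 <- ref$par[2]
  }

  b <- best$beta
  k1 <- b[2]; k2 <- b[2] + b[3]; k3 <- b[2] + b[3] + b[4]
  kscale <- max(abs(c(k1, k2, k3)), 1e-12)
  structure(list(k_initial = unname(k1), k_transition = unname(k2),
                 k_linear = unname(k3), d1 = best$d1, d2 = best$d2,
                 sse = best$sse, intercept = unname(b[1]),
                 degenerate = max(abs(c(k1 - k2, k2 - k3))) < 1e-6 * kscale),
            class = "trilinear_fit")
}

#' @exportS3Method base::print
print.trilinear_fit <- function(x, ...) {
  cat(sprintf(
    "Tri-linear fit: k = (%.1f, %.1f, %.1f) N/mm, breaks at (%.3f, %.3f) mm, SSE %.3g%s\n",
    x$k_initial, x$k_transition, x$k_linear, x$d1, x$d2, x$sse,
    if (x$degenerate) " [degenerate: single slope]" else ""))
  invisible(x)
}

#' Stiffness triple of a tri-linear fit
#'
#' @param fit A [trilinear_fit()].
#' @return Named numeric vector `(k_initial, k_transition, k_linear)`.
#' @export
stiffness_values <- function(fit) {
  stopifnot(inherits(fit, "trilinear_fit"))
  c(k_initial = fit$k_initial, k_transition = fit$k_transition,
    k_linear = fit$k_linear)
}

#' Serialise a tri-linear fit to JSON
#'
#' @param fit A [trilinear_fit()].
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string or `path`.
#' @export
trilinear_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "trilinear_fit"))
  obj <- fit[c("k_initial", "k_transition", "k_linear", "d1", "d2", "sse")]
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' RMS load difference between two force-displacement curves
#'
#' Root-mean-square of the absolute load discrepancy (in newtons) on the
#' experimental displacement grid restricted to the common displacement
#' range, with the simulated curve linearly interpolated onto that grid.
#' The absolute difference (rather than a relative error) de-emphasises
#' small boundary-condition discrepancies at low displacements.
#'
#' @param sim Simulated [force_displacement_curve()].
#' @param exp_curve Experimental [force_displacement_curve()]; its grid is
#'   the reference.
#' @return RMS difference in N.
#' @export
rms_difference <- function(sim, exp_curve) {
  stopifnot(inherits(sim, "force_displacement_curve"),
            inherits(exp_curve, "force_displacement_curve"))
  lo <- max(min(sim$displacement), min(exp_curve$displacement))
  hi <- min(max(sim$displacement), max(exp_curve$displacement))
  if (hi <= lo) stop("curves have no overlapping displacement range")
  sel <- exp_curve$displacement >= lo & exp_curve$displacement <= hi
  dg <- exp_curve$displacement[sel]
  fs <- approx(sim$displacement, sim$force, xout = dg, ties = "ordered")$y
  sqrt(mean((fs - exp_curve$force[sel])^2))
}

#' Convergence threshold for the calibration RMS criterion
#'
#' `frac * max_load`; with the protocol's 2100 N and the 5 % rule this is
#' the 105 N criterion.
#'
#' @param max_load Maximum applied load (N), > 0.
#' @param frac Fraction in (0, 1), default 0.05.
#' @return Threshold in N.
#' @export
convergence_threshold <- function(max_load, frac = 0.05) {
  stopifnot(max_load > 0, frac > 0, frac < 1)
  frac * max_load
}
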