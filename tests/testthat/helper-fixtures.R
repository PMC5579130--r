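# Shared fixtures: coarse meshes, small material sets, finite-difference
# oracles, and random admissible deformation gradients.

coarse_res <- function() mesh_resolution(2, 3, 3, 2, 1)
tiny_res <- function() mesh_resolution(2, 2, 2, 2, 1)

baseline_geometry <- function() osteodisc_geometry()

# homogeneous material set (every region the same), for closed-form checks
homogeneous_materials <- function(m) list(annulus = m, nucleus = m,
                                          bone = m, pmma = m)

# random admissible deformation gradient near the identity
random_F <- function(scale = 0.08) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, 0, scale), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

# central finite differences of the strain energy through F: the
# independent oracle for the analytic stress (via P = J sigma F^-T)
fd_piola <- function(F, params, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(Fp, params) - strain_energy(Fm, params)) /
        (2 * h)
    }
  }
  P
}

piola_from_cauchy <- function(F, params) {
  det(F) * cauchy_stress(F, params) %*% t(solve(F))
}

# exact tri-linear data generator
trilinear_data <- function(d, slopes, breaks, intercept = 0) {
  f <- intercept + slopes[1] * d +
    (slopes[2] - slopes[1]) * pmax(d - breaks[1], 0) +
    (slopes[3] - slopes[2]) * pmax(d - breaks[2], 0)
  force_displacement_curve(d, f)
}

# brute-force grid-search oracle for the tri-linear SSE bound: plain lm()
# over the hinge basis at every admissible sample breakpoint pair
trilinear_grid_oracle_sse <- function(curve) {
  d <- curve$displacement; f <- curve$force; n <- length(d)
  best <- Inf
  for (i in 2:(n - 4)) {
    for (j in (i + 2):(n - 2)) {
      b1 <- pmax(d - d[i], 0); b2 <- pmax(d - d[j], 0)
      sse <- sum(resid(lm(f ~ d + b1 + b2))^2)
      if (sse < best) best <- sse
    }
  }
  best
}
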