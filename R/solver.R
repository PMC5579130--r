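# Quasi-static displacement-driven solution of osteodisc axial compression:
# incremental Newton iterations with numerically differentiated element
# tangents, adaptive substepping on non-convergence, and load-targeting for
# the experiment's load-limited protocol.

#' Force-displacement curve container
#'
#' @param displacement Axial displacements (mm), monotone non-decreasing.
#' @param force Axial reaction forces (N), same length.
#' @param zeroed Logical: has the displacement origin been shifted to the
#'   preload crossing (see [rezero_at_preload()])?
#' @return Object of class `force_displacement_curve`.
#' @export
force_displacement_curve <- function(displacement, force, zeroed = FALSE) {
  displacement <- as.numeric(displacement); force <- as.numeric(force)
  if (length(displacement) != length(force))
    stop("`displacement` and `force` must have the same length")
  if (length(displacement) > 1 && any(diff(displacement) < -1e-12))
    stop("`displacement` must be monotone non-decreasing")
  structure(list(displacement = displacement, force = force,
                 zeroed = isTRUE(zeroed)),
            class = "force_displacement_curve")
}

#' @exportS3Method base::print
print.force_displacement_curve <- function(x, ...) {
  cat(sprintf(
    "Force-displacement curve: %d samples, d in [%.3f, %.3f] mm, F max %.1f N%s\n",
    length(x$force), min(x$displacement), max(x$displacement), max(x$force),
    if (x$zeroed) " (zeroed at preload)" else ""))
  invisible(x)
}

#' @export
as.data.frame.force_displacement_curve <- function(x, ...) {
  data.frame(displacement_mm = x$displacement, force_N = x$force)
}

#' @export
plot.force_displacement_curve <- function(x, ...) {
  graphics::plot(x$displacement, x$force, type = "l",
                 xlab = "displacement (mm)", ylab = "force (N)", ...)
}

#' Write/read a force-displacement curve as CSV
#'
#' Columns `displacement_mm`, `force_N`.
#'
#' @param curve A [force_displacement_curve()].
#' @param path File path.
#' @return `path` (write) or the curve (read).
#' @export
write_fd_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_displacement_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fd_curve
#' @export
read_fd_curve <- function(path) {
  df <- read.csv(path)
  if (!all(c("displacement_mm", "force_N") %in% names(df)))
    stop("curve CSV must have columns `displacement_mm` and `force_N`")
  force_displacement_curve(df$displacement_mm, df$force_N)
}

# internal: fixed dof bookkeeping. dof(i) = 2*node-1 (u_r), 2*node (u_z)
.bc_dofs <- function(mesh, bc) {
  axis_r <- 2 * mesh$axis - 1
  bot_z <- 2 * mesh$bottom
  top_z <- 2 * mesh$top
  fixed0 <- if (bc == "clamped") {
    unique(c(axis_r, 2 * mesh$bottom - 1, bot_z))
  } else if (bc == "frictionless") {
    unique(c(axis_r, bot_z))
  } else stop("`bc` must be \"clamped\" or \"frictionless\"")
  list(fixed0 = setdiff(fixed0, top_z), top_z = top_z)
}

# internal: one Newton solve at fixed prescribed displacements.
# u holds the full dof vector with prescribed values already set.
# The tangent comes back as triplets and is solved sparsely.
.newton <- function(coords, conn, region, mats, u, free, tol_rel = 1e-9,
                    maxit = 30) {
  for (it in seq_len(maxit)) {
    asm <- .fe_assemble_cpp(coords, conn, region, mats, u, TRUE)
    if (!isTRUE(asm$ok) || any(!is.finite(asm$fint)))
      return(list(ok = FALSE, u = u))
    r <- asm$fint[free]
    fscale <- max(abs(asm$fint), 1)
    if (max(abs(r)) < max(tol_rel * fscale, 1e-8))
      return(list(ok = TRUE, u = u, fint = asm$fint, iters = it))
    if (any(!is.finite(asm$Kx))) return(list(ok = FALSE, u = u))
    K <- Matrix::sparseMatrix(i = asm$Ki, j = asm$Kj, x = asm$Kx,
                              dims = c(asm$ndof, asm$ndof))
    du <- tryCatch(
      as.numeric(Matrix::solve(K[free, free, drop = FALSE], -r)),
      error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) return(list(ok = FALSE, u = u))
    u[free] <- u[free] + du
  }
  list(ok = FALSE, u = u)
}

# internal: advance the state from displacement d_from to d_to, bisecting the
# increment on Newton failure (up to `depth` 8, i.e. 1/256 of the increment).
.step_to <- function(st, d_to, depth = 0) {
  u <- st$u
  u[st$top_z] <- -d_to
  res <- .newton(st$coords, st$conn, st$region, st$mats, u, st$free)
  if (res$ok) {
    st$u <- res$u; st$fint <- res$fint; st$d <- d_to
    return(st)
  }
  if (depth >= 8)
    stop("solver failed to converge at displacement ", signif(d_to, 4),
         " mm (last converged: ", signif(st$d, 4), " mm)")
  mid <- (st$d + d_to) / 2
  st <- .step_to(st, mid, depth + 1)
  .step_to(st, d_to, depth + 1)
}

# internal: fresh solver state for a mesh/material pair
.solver_state <- function(mesh, materials, bc) {
  bcs <- .bc_dofs(mesh, bc)
  ndof <- 2 * nrow(mesh$coords)
  free <- setdiff(seq_len(ndof), c(bcs$fixed0, bcs$top_z))
  list(coords = mesh$coords, conn = mesh$conn, region = mesh$region,
       mats = .mats_matrix(materials), u = numeric(ndof), fint = NULL,
       free = free, top_z = bcs$top_z, d = 0)
}

# internal: axial reaction force (N, positive in compression) at the driven
# face from the assembled internal forces
.reaction <- function(st) {
  if (is.null(st$fint)) return(0)
  -sum(st$fint[st$top_z])
}

#' Solve osteodisc axial compression
#'
#' Incremental quasi-static Newton solution of the axisymmetric model under
#' a prescribed axial displacement of the proximal face, with the distal
#' face clamped (or on a frictionless support) and the axis constrained.
#' When the protocol carries no `applied_displacement`, the displacement
#' reaching the protocol's `max_load` is found first with
#' [displacement_for_target_load()].
#'
#' @param mesh An [build_mesh()] mesh.
#' @param materials Material set as from [osteodisc_materials()].
#' @param protocol A [load_protocol()].
#' @param bc `"clamped"` (default) or `"frictionless"` distal support.
#' @return A [force_displacement_curve()] starting at (0, 0).
#' @export
solve_axial_compression <- function(mesh, materials,
                                    protocol = load_protocol(),
                                    bc = "clamped") {
  stopifnot(inherits(mesh, "axisym_mesh"), inherits(protocol, "load_protocol"))
  d_max <- protocol$applied_displacement
  if (is.null(d_max))
    d_max <- displacement_for_target_load(mesh, materials,
                                          protocol$max_load, bc = bc)
  if (d_max < 0) stop("applied displacement must be non-negative")
  if (d_max == 0)
    return(force_displacement_curve(0, 0))
  targets <- seq(0, d_max, length.out = protocol$n_steps + 1)[-1]
  st <- .solver_state(mesh, materials, bc)
  disp <- 0; force <- 0
  for (d in targets) {
    st <- .step_to(st, d)
    disp <- c(disp, d); force <- c(force, .reaction(st))
  }
  force_displacement_curve(disp, force)
}

#' Displacement at which the model reaches a target load
#'
#' Steps the model with a growing displacement increment until the axial
#' reaction exceeds `max_load`, then refines the crossing by interpolation
#' and secant iterations until the load at the returned displacement is
#' within 1 % of the target.
#'
#' @inheritParams solve_axial_compression
#' @param max_load Target axial load (N).
#' @param d_cap Displacement cap (mm); default 45 % of the disc height.
#'   Exceeding it raises an unreachable-load error.
#' @return Displacement (mm) with attribute `curve`, the stepped
#'   [force_displacement_curve()] up to the crossing.
#' @export
displacement_for_target_load <- function(mesh, materials, max_load,
                                         bc = "clamped", d_cap = NULL) {
  stopifnot(inherits(mesh, "axisym_mesh"), max_load > 0)
  hgt <- mesh$geometry$disc_height
  if (is.null(d_cap)) d_cap <- 0.45 * hgt
  st <- .solver_state(mesh, materials, bc)
  step <- 0.02 * hgt
  disp <- 0; force <- 0
  repeat {
    d_next <- min(st$d + step, d_cap)
    st <- .step_to(st, d_next)
    disp <- c(disp, d_next); force <- c(force, .reaction(st))
    n <- length(force)
    if (force[n] >= max_load) break
    if (d_next >= d_cap)
      stop("target load ", max_load, " N unreachable within the ",
           "displacement cap of ", signif(d_cap, 4), " mm (reached ",
           signif(force[n], 4), " N)")
    step <- step * 1.25
  }
  # interpolated crossing, then secant refinement on freshly solved states
  d_star <- approx(force[(n - 1):n], disp[(n - 1):n], xout = max_load)$y
  d_lo <- disp[n - 1]; f_lo <- force[n - 1]
  for (k in 1:6) {
    st <- .step_to(st, d_star)
    f_star <- .reaction(st)
    disp <- c(disp, d_star); force <- c(force, f_star)
    if (abs(f_star - max_load) <= 0.01 * max_load) break
    slope <- (f_star - f_lo) / (d_star - d_lo)
    d_lo <- d_star; f_lo <- f_star
    d_star <- d_star + (max_load - f_star) / slope
  }
  ord <- order(disp)
  structure(d_star,
            curve = force_displacement_curve(disp[ord], force[ord]))
}

#' Re-zero a force-displacement curve at the preload
#'
#' Shifts the displacement origin to the (linearly interpolated)
#' displacement at which the force first crosses the preload, drops the
#' samples below it, and inserts the exact crossing as the first sample —
#' mirroring the experimental convention of measuring displacement relative
#' to the displacement at the compression-plate weight.
#'
#' @param curve A [force_displacement_curve()].
#' @param preload Preload (N); the curve must reach it.
#' @return A zeroed [force_displacement_curve()].
#' @export
rezero_at_preload <- function(curve, preload) {
  stopifnot(inherits(curve, "force_displacement_curve"))
  if (max(curve$force) < preload)
    stop("curve never reaches the preload of ", preload, " N")
  d <- curve$displacement; f <- curve$force
  if (f[1] >= preload) {
    return(force_displacement_curve(d - d[1], f, zeroed = TRUE))
  }
  i <- which(f >= preload)[1]
  d0 <- d[i - 1] + (preload - f[i - 1]) * (d[i] - d[i - 1]) / (f[i] - f[i - 1])
  keep <- i:length(d)
  force_displacement_curve(c(0, d[keep] - d0), c(preload, f[keep]),
                           zeroed = TRUE)
}
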