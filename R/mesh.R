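# Reduced parametric osteodisc geometry and its structured axisymmetric
# mesh. The image-based 3D specimen of the experiments is reduced to an
# axisymmetric stack: PMMA endcap / bone / disc (nucleus core + annulus
# ring) / bone / PMMA endcap, justified by the near-circularity of bovine
# caudal discs and the purely axial load case.

#' Reduced osteodisc specimen geometry
#'
#' @param disc_diameter Disc (and specimen) diameter (mm), measured at the
#'   endplates.
#' @param disc_height Disc height (mm).
#' @param np_af_ratio Nucleus-to-annulus diameter ratio, strictly in (0, 1).
#' @param bone_height Bone thickness either side of the disc (mm),
#'   default 15.
#' @param endcap_height PMMA endcap height (mm).
#' @param size_scale Mid-height diameter scaling of the disc profile
#'   (default 1). Values other than 1 bulge the disc's central diameter in
#'   or out while the endplate diameter stays anatomically consistent with
#'   the bone; the nucleus scales proportionally so the
#'   nucleus-to-annulus ratio is preserved. Used by the disc-size
#'   sensitivity study.
#' @return Object of class `osteodisc_geometry`.
#' @export
osteodisc_geometry <- function(disc_diameter = 30, disc_height = 9,
                               np_af_ratio = 0.5, bone_height = 15,
                               endcap_height = 5, size_scale = 1) {
  if (any(!is.finite(c(disc_diameter, disc_height, bone_height,
                       endcap_height))) ||
      any(c(disc_diameter, disc_height, bone_height, endcap_height) <= 0))
    stop("all geometry lengths must be positive")
  if (!is.finite(np_af_ratio) || np_af_ratio <= 0 || np_af_ratio >= 1)
    stop("`np_af_ratio` must lie strictly inside (0, 1)")
  if (!is.finite(size_scale) || size_scale < 0.5 || size_scale > 2)
    stop("`size_scale` must lie in [0.5, 2]")
  structure(list(disc_diameter = disc_diameter, disc_height = disc_height,
                 np_af_ratio = np_af_ratio, bone_height = bone_height,
                 endcap_height = endcap_height, size_scale = size_scale),
            class = "osteodisc_geometry")
}

#' Axial compression load protocol
#'
#' @param max_load Maximum compressive load (N), default 2100.
#' @param preload Preload at which displacements are zeroed (N), default 10
#'   (the weight of the compression plate).
#' @param n_steps Number of displacement increments, >= 5.
#' @param applied_displacement Optional prescribed axial displacement (mm);
#'   when `NULL` the displacement reaching `max_load` is found by the
#'   solver.
#' @return Object of class `load_protocol`.
#' @export
load_protocol <- function(max_load = 2100, preload = 10, n_steps = 25,
                          applied_displacement = NULL) {
  stopifnot(max_load > preload, preload >= 0, n_steps >= 5)
  structure(list(max_load = max_load, preload = preload,
                 n_steps = as.integer(n_steps),
                 applied_displacement = applied_displacement),
            class = "load_protocol")
}

#' Mesh resolution specification
#'
#' Element counts per region: radial counts for the nucleus core and the
#' annulus ring, axial counts for the disc, each bone block, and each PMMA
#' endcap.
#'
#' @param nr_nucleus,nr_annulus Radial element counts, >= 1.
#' @param nz_disc,nz_bone,nz_pmma Axial element counts, >= 1.
#' @return Object of class `mesh_resolution`.
#' @export
mesh_resolution <- function(nr_nucleus = 3, nr_annulus = 3, nz_disc = 4,
                            nz_bone = 3, nz_pmma = 2) {
  v <- c(nr_nucleus, nr_annulus, nz_disc, nz_bone, nz_pmma)
  stopifnot(all(v >= 1), all(v == round(v)))
  structure(list(nr_nucleus = as.integer(nr_nucleus),
                 nr_annulus = as.integer(nr_annulus),
                 nz_disc = as.integer(nz_disc),
                 nz_bone = as.integer(nz_bone),
                 nz_pmma = as.integer(nz_pmma)),
            class = "mesh_resolution")
}

#' Build the structured axisymmetric osteodisc mesh
#'
#' Deterministic tensor-product mesh of bilinear quadrilaterals on the
#' (r, z) half-section. The nucleus region occupies
#' radii up to `np_af_ratio` times the disc radius within the disc layer;
#' annulus elements
#' carry the two `+/- alpha` fibre directions in the
#' (circumferential, axial) plane through the material model.
#'
#' @param geometry An [osteodisc_geometry()].
#' @param resolution A [mesh_resolution()].
#' @return Object of class `axisym_mesh` with node coordinates `coords`
#'   (n x 2, columns r and z in mm), connectivity `conn` (CCW, 1-based),
#'   per-element `region` (1 annulus, 2 nucleus, 3 bone, 4 pmma), node sets
#'   `bottom`, `top`, `axis`, and the generating `geometry`/`resolution`.
#' @export
build_mesh <- function(geometry, resolution = mesh_resolution()) {
  stopifnot(inherits(geometry, "osteodisc_geometry"),
            inherits(resolution, "mesh_resolution"))
  R <- geometry$disc_diameter / 2
  rn <- geometry$np_af_ratio * R
  if (geometry$np_af_ratio > 0.9)
    warning("annulus ring is very thin (np_af_ratio > 0.9); ",
            "mesh is valid but poorly conditioned")

  r_nodes <- c(seq(0, rn, length.out = resolution$nr_nucleus + 1),
               seq(rn, R, length.out = resolution$nr_annulus + 1)[-1])
  h <- c(geometry$endcap_height, geometry$bone_height, geometry$disc_height,
         geometry$bone_height, geometry$endcap_height)
  nzl <- c(resolution$nz_pmma, resolution$nz_bone, resolution$nz_disc,
           resolution$nz_bone, resolution$nz_pmma)
  layer_region <- c(4L, 3L, 1L, 3L, 4L)  # disc-layer elements retagged below
  z0 <- cumsum(c(0, h))
  z_nodes <- 0
  z_layer <- integer(0)  # layer id per axial element row
  for (l in 1:5) {
    z_nodes <- c(z_nodes, seq(z0[l], z0[l + 1],
                              length.out = nzl[l] + 1)[-1])
    z_layer <- c(z_layer, rep(l, nzl[l]))
  }

  nr <- length(r_nodes) - 1
  nz <- length(z_nodes) - 1
  coords <- cbind(r = rep(r_nodes, times = nz + 1),
                  z = rep(z_nodes, each = nr + 1))
  if (geometry$size_scale != 1) {
    # barrel morphing of the disc layer: full diameter change at mid-height,
    # none at the endplates (bone diameter fixed)
    z_lo <- z0[3]; z_hi <- z0[4]
    in_disc <- coords[, 2] > z_lo & coords[, 2] < z_hi
    fac <- 1 + (geometry$size_scale - 1) *
      sin(pi * (coords[in_disc, 2] - z_lo) / (z_hi - z_lo))
    coords[in_disc, 1] <- coords[in_disc, 1] * fac
  }
  nid <- function(i, j) (j - 1) * (nr + 1) + i
  conn <- matrix(0L, nrow = nr * nz, ncol = 4)
  region <- integer(nr * nz)
  e <- 0
  for (j in seq_len(nz)) {
    for (i in seq_len(nr)) {
      e <- e + 1
      conn[e, ] <- c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1), nid(i, j + 1))
      reg <- layer_region[z_layer[j]]
      if (z_layer[j] == 3 && i <= resolution$nr_nucleus) reg <- 2L
      region[e] <- reg
    }
  }
  structure(list(coords = coords, conn = conn, region = region,
                 bottom = which(coords[, 2] == 0),
                 top = which(coords[, 2] == max(z_nodes)),
                 axis = which(coords[, 1] == 0),
                 geometry = geometry, resolution = resolution),
            class = "axisym_mesh")
}

#' @exportS3Method base::print
print.axisym_mesh <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric osteodisc mesh: %d nodes, %d elements (%d annulus, %d nucleus, %d bone, %d pmma)\n",
    nrow(x$coords), nrow(x$conn), sum(x$region == 1), sum(x$region == 2),
    sum(x$region == 3), sum(x$region == 4)))
  invisible(x)
}

#' Standard osteodisc material set
#'
#' The four regions with their default models: GOH annulus (fibre pair
#' `k1`, `k2` adjustable), Mooney-Rivlin incompressible nucleus,
#' homogenised bone at the volume-average modulus 409 MPa, and PMMA at
#' 1.5 GPa, both with Poisson's ratio 0.3.
#'
#' @param k1,k2 Annulus fibre parameters (defaults: the literature pair
#'   2.45 MPa / 2.17).
#' @param annulus,nucleus,bone,pmma Optional replacement parameter objects.
#' @return Named list of material parameter objects, one per region.
#' @export
osteodisc_materials <- function(k1 = 2.45, k2 = 2.17,
                                annulus = NULL, nucleus = NULL,
                                bone = NULL, pmma = NULL) {
  list(annulus = if (is.null(annulus)) goh_params(k1 = k1, k2 = k2) else annulus,
       nucleus = if (is.null(nucleus)) mooney_rivlin_params() else nucleus,
       bone = if (is.null(bone)) linear_elastic_params(409, 0.3) else bone,
       pmma = if (is.null(pmma)) linear_elastic_params(1500, 0.3) else pmma)
}

# internal: material matrix in region-code order (annulus, nucleus, bone, pmma)
.mats_matrix <- function(materials) {
  stopifnot(all(c("annulus", "nucleus", "bone", "pmma") %in% names(materials)))
  rbind(.mat_row(materials$annulus), .mat_row(materials$nucleus),
        .mat_row(materials$bone), .mat_row(materials$pmma))
}
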