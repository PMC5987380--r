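# Parametric phantom specifications: a curved, tapered, hollow elliptical
# shaft (the tibia model), an optional fibula-like rod, an optional
# metaphyseal trabecular lattice, and factorial cohorts of such bones.

#' Specify a trabecular lattice for the phantom metaphysis
#'
#' @param lattice_kind one of `"plates"`, `"rods"`, `"spheres-removed"`,
#'   `"plate-rod"` (plates plus connecting struts along the normal - a
#'   3D-connected network, the realistic choice for whole-bone phantoms)
#' @param spacing_mm lattice period, mm
#' @param element_thickness_mm plate thickness / rod diameter, mm; for
#'   `"spheres-removed"` ignored (the sphere radius is derived from
#'   `target_bvtv_percent`). If `NULL`, derived from `target_bvtv_percent`.
#' @param principal_direction unit 3-vector; plate normal or rod axis.
#'   Rods must run along a coordinate axis.
#' @param target_bvtv_percent target bone volume fraction, percent
#' @param span z-range (normalized 0-1) occupied by the lattice
#' @param bridge_z normalized z of the "bridge" slice: proximal of it the
#'   lattice is split into two islands separated by `island_gap_mm`; set
#'   `NA` for a single continuous lattice
#' @param island_gap_mm gap between the two proximal islands, mm
#' @param phase_mm longitudinal phase offset of the plate planes, mm
#'   (aligning a plate with the bridge plane pins the first-connection
#'   slice to `bridge_z`)
#' @return object of class `trab_lattice_spec`
#' @export
trab_lattice_spec <- function(lattice_kind = c("plates", "rods",
                                               "spheres-removed",
                                               "plate-rod"),
                              spacing_mm = 0.25,
                              element_thickness_mm = NULL,
                              principal_direction = c(0, 0, 1),
                              target_bvtv_percent = NULL,
                              span = c(0.05, 0.18),
                              bridge_z = NA_real_,
                              island_gap_mm = 0.15,
                              phase_mm = 0) {
  lattice_kind <- match.arg(lattice_kind)
  stopifnot(spacing_mm > 0, length(span) == 2, span[1] < span[2])
  if (is.null(element_thickness_mm)) {
    if (is.null(target_bvtv_percent)) {
      stop("give either element_thickness_mm or target_bvtv_percent")
    }
    f <- target_bvtv_percent / 100
    element_thickness_mm <- switch(lattice_kind,
      plates = f * spacing_mm,
      rods = 2 * spacing_mm * sqrt(f / pi),
      `plate-rod` = {
        # combined fraction of plates (t/s) and orthogonal struts,
        # overlap removed: f = fp + fr - fp*fr
        s <- spacing_mm
        stats::uniroot(function(t) {
          fp <- t / s
          fr <- pi * (t / 2)^2 / s^2
          fp + fr - fp * fr - f
        }, c(1e-6, s * 0.999))$root
      },
      `spheres-removed` = {
        # solid minus non-overlapping spheres on a cubic lattice
        fmin <- 1 - pi / 6
        if (f < fmin) {
          stop(sprintf(paste0("target BV/TV %.1f%% unreachable for ",
                              "spheres-removed; achievable range is ",
                              "[%.1f%%, 100%%]"), f * 100, fmin * 100))
        }
        2 * spacing_mm * (3 * (1 - f) / (4 * pi))^(1 / 3)
      })
  }
  if (lattice_kind != "spheres-removed" &&
      element_thickness_mm >= spacing_mm) {
    stop("element thickness must be smaller than the lattice spacing")
  }
  if (lattice_kind %in% c("rods", "plate-rod") &&
      sum(abs(principal_direction) > 1e-9) != 1L) {
    stop("rod and plate-rod lattices must run along a coordinate axis")
  }
  structure(list(
    lattice_kind = lattice_kind,
    spacing_mm = spacing_mm,
    element_thickness_mm = element_thickness_mm,
    principal_direction = principal_direction / sqrt(sum(principal_direction^2)),
    target_bvtv_percent = target_bvtv_percent,
    span = span,
    bridge_z = bridge_z,
    island_gap_mm = island_gap_mm,
    phase_mm = phase_mm
  ), class = "trab_lattice_spec")
}

#' Specify a synthetic long-bone phantom
#'
#' The bone is a hollow shaft with elliptical cross-section: outer semi-axes
#' `a(z)`, `b(z)` (mm, functions of normalized length z in \[0,1\], z = 0
#' proximal), wall thickness `t(z)` (inner semi-axes `a - t`, `b - t`), and a
#' centroid that follows a circular arc of maximum perpendicular deviation
#' (sagitta) `curvature_sagitta_mm` from the proximal-distal chord, in the
#' plane given by `curvature_plane_angle_deg`.
#'
#' @param length_mm bone length, mm
#' @param voxel_um isotropic voxel size, micrometres (default 5, the
#'   scanner resolution the generator emulates)
#' @param outer_a,outer_b functions z -> outer semi-axis, mm
#' @param wall function z -> cortical wall thickness, mm
#' @param curvature_sagitta_mm sagitta of the centroid arc at midshaft, mm
#' @param curvature_plane_angle_deg orientation of the curvature plane
#' @param fibula `NULL` or list with `radius_mm`, `offset_mm` (x-offset of
#'   the rod from the chord axis), `span` (normalized z-range), `fused`
#' @param trabecular `NULL` or a [trab_lattice_spec()]
#' @param attenuation list: `bone_value`, `background_value`, `noise_sd`,
#'   `calibration_rod_values` (two attenuations for the density rods)
#' @param seed integer seed for the grayscale noise
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(length_mm,
                         voxel_um = 5,
                         outer_a = function(z) rep(1, length(z)),
                         outer_b = outer_a,
                         wall = function(z) rep(0.2, length(z)),
                         curvature_sagitta_mm = 0,
                         curvature_plane_angle_deg = 0,
                         fibula = NULL,
                         trabecular = NULL,
                         attenuation = list(bone_value = 290,
                                            background_value = 30,
                                            noise_sd = 10,
                                            calibration_rod_values = c(100, 200)),
                         seed = 1L) {
  stopifnot(length_mm > 0, voxel_um > 0)
  zg <- seq(0, 1, length.out = 257)
  a <- outer_a(zg); b <- outer_b(zg); t <- wall(zg)
  bad <- which(!(t < pmin(a, b)) | a <= 0 | b <= 0 | t <= 0)
  if (length(bad)) {
    stop(sprintf("degenerate annulus at z = %.3f (a = %.3f, b = %.3f, wall = %.3f)",
                 zg[bad[1]], a[bad[1]], b[bad[1]], t[bad[1]]))
  }
  vox_mm <- voxel_um / 1000
  if (min(t) / vox_mm < 4) {
    stop(sprintf(paste0("voxel size %.1f um leaves the thinnest wall ",
                        "(%.3f mm) under 4 voxels; use a finer grid"),
                 voxel_um, min(t)))
  }
  if (!is.null(trabecular)) stopifnot(inherits(trabecular, "trab_lattice_spec"))
  if (!is.null(fibula)) {
    stopifnot(is.list(fibula), fibula$radius_mm > 0, length(fibula$span) == 2)
    fibula$fused <- isTRUE(fibula$fused)
  }
  structure(list(
    length_mm = length_mm,
    voxel_um = voxel_um,
    outer_a = outer_a,
    outer_b = outer_b,
    wall = wall,
    curvature_sagitta_mm = curvature_sagitta_mm,
    curvature_plane_angle_deg = curvature_plane_angle_deg,
    fibula = fibula,
    trabecular = trabecular,
    attenuation = attenuation,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Perpendicular deviation of the centroid arc from the chord at normalized
# z; a circular arc through both endpoints with the given midshaft sagitta.
arc_deflection <- function(z, length_mm, sagitta_mm) {
  if (sagitta_mm <= 0) return(rep(0, length(z)))
  L <- length_mm
  R <- sagitta_mm / 2 + L^2 / (8 * sagitta_mm)
  u <- (z - 0.5) * L
  sqrt(pmax(R^2 - u^2, 0)) - (R - sagitta_mm)
}

#' Analytic per-slice ground truth for a phantom
#'
#' Closed-form cross-sectional properties of the concentric elliptical
#' annulus: CSA, principal second moments of area, polar moment, ellipticity
#' (Imax/Imin), wall thickness, centroid position and the moment-arm
#' (deflection) profile. Everything is computed from the continuous
#' specification, never from voxels.
#'
#' @param spec a [phantom_spec()]
#' @param z_norm normalized lengths at which to evaluate (default 0..1 by 0.01)
#' @return data.frame, one row per requested z
#' @export
ground_truth_profile <- function(spec, z_norm = seq(0, 1, by = 0.01)) {
  a <- spec$outer_a(z_norm)
  b <- spec$outer_b(z_norm)
  t <- spec$wall(z_norm)
  ai <- a - t
  bi <- b - t
  csa <- pi * (a * b - ai * bi)
  ix <- pi / 4 * (a * b^3 - ai * bi^3)   # about the x axis (y^2 integral)
  iy <- pi / 4 * (a^3 * b - ai^3 * bi)
  imin <- pmin(ix, iy)
  imax <- pmax(ix, iy)
  d <- arc_deflection(z_norm, spec$length_mm, spec$curvature_sagitta_mm)
  th <- spec$curvature_plane_angle_deg * pi / 180
  data.frame(
    z_norm = z_norm,
    z_mm = z_norm * spec$length_mm,
    csa_mm2 = csa,
    i_min_mm4 = imin,
    i_max_mm4 = imax,
    j_mm4 = imin + imax,
    ellipticity = imax / imin,
    ct_th_mm = t,
    centroid_x_mm = d * cos(th),
    centroid_y_mm = d * sin(th),
    outer_area_mm2 = pi * a * b,
    r_eq_mm = sqrt(a * b),
    arm_mm = d
  )
}
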