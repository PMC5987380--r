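# Whole-bone cortical analysis: per-slice cross-sectional geometry, the
# 10-90% percentile profile, calibrated tissue mineral density at the 37%
# site, and intracortical total porosity.

#' Cross-sectional geometry of one transverse slice
#'
#' CSA from the pixel count; centroid from the pixel mean; the second-moment
#' tensor about the centroid from pixel coordinates with the per-pixel
#' self-term `h^4/12` per axis (so small sections are not systematically
#' underestimated); eigen-decomposition gives Imin, Imax and the principal
#' angle; `J = Imin + Imax`; ellipticity `Imax/Imin` by default (the
#' axis-ratio alternative `sqrt(Imax/Imin)` via
#' `ellipticity = "axis-ratio"`); Ct.Th as the mean 2D inscribed-disc
#' diameter over bone pixels.
#'
#' @param slice logical matrix (bone = TRUE)
#' @param voxel_um pixel size, micrometres
#' @param ellipticity `"moment-ratio"` (default) or `"axis-ratio"`
#' @return one-row data.frame of slice geometry (units mm, mm^2, mm^4)
#' @export
slice_geometry <- function(slice, voxel_um,
                           ellipticity = c("moment-ratio", "axis-ratio")) {
  ellipticity <- match.arg(ellipticity)
  if (!any(slice)) stop("empty slice")
  h <- voxel_um / 1000
  idx <- which(slice, arr.ind = TRUE)
  x <- idx[, 1] * h
  y <- idx[, 2] * h
  n <- nrow(idx)
  csa <- n * h^2
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  self <- h^4 / 12
  sxx <- h^2 * sum(dx^2) + n * self   # integral of x'^2 dA
  syy <- h^2 * sum(dy^2) + n * self
  sxy <- h^2 * sum(dx * dy)
  S <- matrix(c(sxx, sxy, sxy, syy), 2, 2)
  eg <- eigen(S, symmetric = TRUE)
  imax <- eg$values[1]                # = I about the minor principal axis
  imin <- eg$values[2]
  ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ell <- if (ellipticity == "moment-ratio") imax / imin else sqrt(imax / imin)
  filled <- EBImage::imageData(
    EBImage::fillHull(EBImage::Image(slice * 1))) > 0
  th <- local_thickness(slice, voxel_um)
  data.frame(
    csa_mm2 = csa,
    centroid_x_mm = cx,
    centroid_y_mm = cy,
    i_min_mm4 = imin,
    i_max_mm4 = imax,
    principal_angle_deg = ang,
    j_mm4 = imin + imax,
    ellipticity = ell,
    ct_th_mm = attr(th, "mean_mm"),
    filled_area_mm2 = sum(filled) * h^2,
    r_eq_mm = sqrt(sum(filled) * h^2 / pi)
  )
}

#' Cortical geometry profile along the whole bone
#'
#' [slice_geometry()] evaluated at each percentile of bone length (default
#' 10-90% in 1% steps, percent measured from the proximal end). Empty
#' slices are flagged and excluded; more than 10% empty aborts (likely an
#' alignment failure).
#'
#' @param aligned an [aligned_bone()]
#' @param percents percent grid (default `10:90`)
#' @param ellipticity passed to [slice_geometry()]
#' @return data.frame of class `slice_geometry_profile`, one row per
#'   percent, with `percent`, `slice_index`, `z_mm` and all slice-geometry
#'   fields; voxel size kept as attribute `"voxel_um"`
#' @export
profile_whole_bone <- function(aligned, percents = 10:90,
                               ellipticity = "moment-ratio") {
  stopifnot(inherits(aligned, "aligned_bone"))
  rows <- vector("list", length(percents))
  empty <- logical(length(percents))
  for (k in seq_along(percents)) {
    iz <- percentile_slice(aligned, percents[k])
    sl <- aligned$mask[, , iz]
    if (!any(sl)) {
      empty[k] <- TRUE
      next
    }
    g <- slice_geometry(sl, aligned$voxel_um, ellipticity = ellipticity)
    g$percent <- percents[k]
    g$slice_index <- iz
    g$z_mm <- (iz - aligned$z_range[1] + 0.5) * aligned$voxel_um / 1000
    rows[[k]] <- g
  }
  if (mean(empty) > 0.10) {
    stop(sprintf("%d of %d percentile slices empty; alignment likely failed",
                 sum(empty), length(percents)))
  }
  if (any(empty)) {
    message(sprintf("excluded %d empty percentile slice(s): %s",
                    sum(empty),
                    paste(percents[empty], collapse = ", ")))
  }
  out <- do.call(rbind, rows[!empty])
  out <- out[, c("percent", "slice_index", "z_mm",
                 setdiff(names(out), c("percent", "slice_index", "z_mm")))]
  attr(out, "voxel_um") <- aligned$voxel_um
  class(out) <- c("slice_geometry_profile", class(out))
  out
}

#' Density calibration from two attenuation-density pairs
#'
#' @param attenuations two attenuation values (scanner units)
#' @param densities_g_cm3 the corresponding densities, g/cm^3
#' @return object of class `density_calibration` (a linear map)
#' @export
density_calibration <- function(attenuations, densities_g_cm3) {
  stopifnot(length(attenuations) == 2, length(densities_g_cm3) == 2,
            all(densities_g_cm3 > 0))
  if (abs(diff(attenuations)) < 1e-12) {
    stop("calibration attenuations must be distinct")
  }
  slope <- diff(densities_g_cm3) / diff(attenuations)
  structure(list(slope = slope,
                 intercept = densities_g_cm3[1] - slope * attenuations[1]),
            class = "density_calibration")
}

#' Cortical tissue mineral density at the 37% site
#'
#' Mean calibrated density over the bone voxels of `n_slices` slices
#' centred at `percent` of bone length (defaults: 100 slices at 37%). The
#' mask is eroded by `peel` voxels first - the usual protection against
#' partial-volume dilution at the cortical surfaces.
#'
#' @param gray grayscale [voxel_volume()], co-registered with the mask
#' @param aligned an [aligned_bone()] on the same grid
#' @param calib a [density_calibration()]
#' @param percent site, percent of bone length
#' @param n_slices number of slices in the averaging window
#' @param peel surface erosion depth, voxels (default 2; 0 disables)
#' @return mean tissue mineral density, g/cm^3
#' @export
tmd <- function(gray, aligned, calib, percent = 37, n_slices = 100,
                peel = 2) {
  stopifnot(inherits(gray, "voxel_volume"), inherits(aligned, "aligned_bone"),
            inherits(calib, "density_calibration"))
  stopifnot(all(dim(gray$data) == dim(aligned$mask)))
  ic <- percentile_slice(aligned, percent)
  zs <- (ic - floor(n_slices / 2)) + 0:(n_slices - 1)
  if (zs[1] < 1 || zs[n_slices] > dim(aligned$mask)[3]) {
    stop("TMD slice window exits the volume; reduce n_slices")
  }
  sel <- aligned$mask[, , zs, drop = FALSE]
  if (peel > 0) {
    d2 <- edt_sq(as.logical(sel), as.integer(dim(sel)))
    sel <- sel & (d2 > peel^2)
    if (!any(sel)) stop("peel removed all bone voxels; reduce peel")
  }
  att <- gray$data[, , zs][sel]
  mean(calib$intercept + calib$slope * att)
}

#' Intracortical total porosity over a z-range
#'
#' Per slice the outer cortical contour is filled; the medullary cavity
#' (the largest enclosed void) is excluded so "filled" is the cortical
#' shell only; porosity is `100 * (shell - bone) / shell` voxels pooled
#' over the range. Slices whose shell is breached (no enclosed cavity
#' where one is expected) are flagged with a warning.
#'
#' @param aligned an [aligned_bone()]
#' @param percents percent range over which to pool (default `10:90`)
#' @return percent porosity, with flagged slices as attribute
#'   `"breached_slices"`
#' @export
total_porosity <- function(aligned, percents = 10:90) {
  stopifnot(inherits(aligned, "aligned_bone"))
  shell_vox <- 0L
  pore_vox <- 0L
  breached <- integer(0)
  for (p in percents) {
    iz <- percentile_slice(aligned, p)
    sl <- aligned$mask[, , iz]
    if (!any(sl)) next
    filled <- EBImage::imageData(
      EBImage::fillHull(EBImage::Image(sl * 1))) > 0
    voids <- filled & !sl
    if (any(voids)) {
      lab <- label_components_2d(voids)
      sizes <- tabulate(lab[lab > 0])
      cavity <- lab == which.max(sizes)
    } else {
      cavity <- voids
      breached <- c(breached, iz)
      warning(sprintf("slice %d: no enclosed cavity (shell breached or solid)",
                      iz))
    }
    shell <- filled & !cavity
    shell_vox <- shell_vox + sum(shell)
    pore_vox <- pore_vox + sum(shell & !sl)
  }
  out <- 100 * pore_vox / max(shell_vox, 1L)
  attr(out, "breached_slices") <- breached
  out
}
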