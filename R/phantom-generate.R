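# Voxelization of phantom specifications. Binary volumes use centre-point
# inclusion (no partial volume) so voxel-count oracles stay exact; the
# grayscale channel adds a one-voxel Gaussian blur (partial-volume model)
# and additive Gaussian noise, making threshold selection non-trivial.

lattice_membership <- function(X, Y, z, lat) {
  s <- lat$spacing_mm
  t <- lat$element_thickness_mm
  n <- lat$principal_direction
  switch(lat$lattice_kind,
    `plate-rod` = {
      pl <- lat; pl$lattice_kind <- "plates"
      rd <- lat; rd$lattice_kind <- "rods"
      lattice_membership(X, Y, z, pl) | lattice_membership(X, Y, z, rd)
    },
    plates = {
      proj <- X * n[1] + Y * n[2] + z * n[3] - (lat$phase_mm %||% 0)
      (proj %% s) < t
    },
    rods = {
      ax <- which(abs(n) > 1e-9)
      r <- t / 2
      xv <- as.vector(X)
      yv <- as.vector(Y)
      zv <- rep(z, length(xv))
      u <- switch(ax, yv, xv, xv)
      v <- switch(ax, zv, zv, yv)
      du <- (u %% s) - s / 2
      dv <- (v %% s) - s / 2
      m <- du^2 + dv^2 <= r^2
      dim(m) <- dim(X)
      m
    },
    `spheres-removed` = {
      r <- t / 2
      dx <- ((X + s / 2) %% s) - s / 2
      dy <- ((Y + s / 2) %% s) - s / 2
      dz <- ((z + s / 2) %% s) - s / 2
      !(dx^2 + dy^2 + dz^2 <= r^2)
    })
}

#' Generate a trabecular lattice on a voxel grid
#'
#' Rasterizes a periodic lattice ([trab_lattice_spec()]) on the given grid,
#' optionally clipped to an envelope mask, and records the realized metrics
#' (voxel-count BV/TV, analytic element thickness, fabric direction). The
#' realized BV/TV, not the target, is the ground truth.
#'
#' @param lat a [trab_lattice_spec()]
#' @param dim integer grid dimensions (nx, ny, nz)
#' @param voxel_um voxel size, micrometres
#' @param envelope optional logical array; lattice is clipped to it
#' @return list with `mask` (logical array) and `realized` metrics
#' @export
generate_trabecular_lattice <- function(lat, dim, voxel_um, envelope = NULL) {
  stopifnot(inherits(lat, "trab_lattice_spec"), length(dim) == 3)
  vox <- voxel_um / 1000
  xs <- (seq_len(dim[1]) - 0.5) * vox
  ys <- (seq_len(dim[2]) - 0.5) * vox
  mask <- array(FALSE, dim)
  X <- matrix(xs, dim[1], dim[2])
  Y <- matrix(ys, dim[1], dim[2], byrow = TRUE)
  for (iz in seq_len(dim[3])) {
    z <- (iz - 0.5) * vox
    m <- lattice_membership(X, Y, z, lat)
    if (!is.null(envelope)) m <- m & envelope[, , iz]
    mask[, , iz] <- m
  }
  n_env <- if (is.null(envelope)) prod(dim) else sum(envelope)
  realized <- list(
    bvtv_percent = 100 * sum(mask) / n_env,
    tb_th_mm = lat$element_thickness_mm,
    tb_sp_mm = switch(lat$lattice_kind,
      plates = lat$spacing_mm - lat$element_thickness_mm,
      rods = NA_real_,
      `plate-rod` = NA_real_,
      `spheres-removed` = NA_real_),
    fabric_direction = lat$principal_direction
  )
  list(mask = mask, realized = realized)
}

#' Voxelize a phantom bone with analytic ground truth
#'
#' Produces the binary bone volume, optionally a grayscale volume
#' (blur + noise + two calibration rods outside the bone), and the closed
#' form ground truth. The shaft is a hollow elliptical tube whose centroid
#' follows a circular arc of the requested sagitta; a fibula-like rod and a
#' trabecular lattice are inserted when specified.
#'
#' @param spec a [phantom_spec()]
#' @param grayscale emit the grayscale channel (default TRUE)
#' @return list with elements `gray` ([voxel_volume] or NULL), `binary`
#'   ([voxel_volume], logical), `truth` (ground-truth record)
#' @export
generate_bone <- function(spec, grayscale = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  vox <- spec$voxel_um / 1000
  L <- spec$length_mm
  nz <- max(2L, as.integer(round(L / vox)))
  zg <- seq(0, 1, length.out = 513)
  th <- spec$curvature_plane_angle_deg * pi / 180
  defl <- arc_deflection(zg, L, spec$curvature_sagitta_mm)
  ext_x <- max(abs(defl * cos(th)) + spec$outer_a(zg))
  ext_y <- max(abs(defl * sin(th)) + spec$outer_b(zg))
  if (!is.null(spec$fibula)) {
    ext_x <- max(ext_x, spec$fibula$offset_mm + spec$fibula$radius_mm)
  }
  rod_r <- 4 * vox
  margin <- 4 * vox
  rod_pad <- if (grayscale) 2 * (2 * rod_r + 2 * vox) else 0
  half_x <- ext_x + margin + rod_pad
  half_y <- ext_y + margin
  nx <- 2L * as.integer(ceiling(half_x / vox))
  ny <- 2L * as.integer(ceiling(half_y / vox))
  xs <- ((seq_len(nx)) - (nx + 1) / 2) * vox   # symmetric about 0
  ys <- ((seq_len(ny)) - (ny + 1) / 2) * vox
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)

  binary <- array(FALSE, c(nx, ny, nz))
  fib_only <- integer(0)
  fib_all <- integer(0)
  lat <- spec$trabecular
  trab_env_count <- integer(nz)
  trab_bone_count <- integer(nz)
  trab_idx <- vector("list", nz)
  bridge_slice <- NA_integer_

  for (iz in seq_len(nz)) {
    z_mm <- (iz - 0.5) * vox
    zn <- min(max(z_mm / L, 0), 1)
    a <- spec$outer_a(zn); b <- spec$outer_b(zn); t <- spec$wall(zn)
    ai <- max(a - t, 0); bi <- max(b - t, 0)
    d <- arc_deflection(zn, L, spec$curvature_sagitta_mm)
    cx <- d * cos(th); cy <- d * sin(th)
    qo <- ((X - cx) / a)^2 + ((Y - cy) / b)^2
    inside_outer <- qo <= 1
    if (ai > 0 && bi > 0) {
      qi <- ((X - cx) / ai)^2 + ((Y - cy) / bi)^2
      cavity <- qi <= 1
    } else {
      cavity <- matrix(FALSE, nx, ny)
    }
    m <- inside_outer & !cavity

    if (!is.null(lat) && zn >= lat$span[1] && zn < lat$span[2]) {
      lm <- lattice_membership(X, Y, z_mm, lat) & cavity
      gap_band <- abs(X - cx) <= lat$island_gap_mm / 2
      if (!is.na(lat$bridge_z) && zn < lat$bridge_z) {
        lm <- lm & !gap_band
      } else if (!is.na(lat$bridge_z) && is.na(bridge_slice) &&
                 any(lm & gap_band)) {
        bridge_slice <- iz  # first slice where lattice bone spans the gap
      }
      trab_env_count[iz] <- sum(cavity)
      trab_bone_count[iz] <- sum(lm)
      trab_idx[[iz]] <- which(lm)
      m <- m | lm
    }

    if (!is.null(spec$fibula) &&
        zn >= spec$fibula$span[1] && zn < spec$fibula$span[2]) {
      fm <- (X - spec$fibula$offset_mm)^2 + Y^2 <= spec$fibula$radius_mm^2
      base <- (iz - 1) * nx * ny
      fib_all <- c(fib_all, base + which(fm))
      fib_only <- c(fib_only, base + which(fm & !m))
      m <- m | fm
    }
    binary[, , iz] <- m
  }

  # calibration rods: two full-height cylinders clear of the bone
  rods <- NULL
  gray <- NULL
  if (grayscale) {
    att <- spec$attenuation
    rod_x <- c(-(ext_x + margin + rod_r + vox), ext_x + margin + rod_r + vox)
    rod_masks <- lapply(rod_x, function(rx) (X - rx)^2 + Y^2 <= rod_r^2)
    g <- array(att$background_value, c(nx, ny, nz))
    g[binary] <- att$bone_value
    for (k in 1:2) {
      rm3 <- which(rod_masks[[k]])
      for (iz in seq_len(nz)) {
        g[(iz - 1) * nx * ny + rm3] <- att$calibration_rod_values[k]
      }
    }
    g <- gaussian_blur3(g, sigma = 1)
    set.seed(spec$seed)
    g <- g + rnorm(length(g), sd = att$noise_sd)
    g <- pmax(g, 0)  # attenuation is nonnegative (detector floor)
    dim(g) <- c(nx, ny, nz)
    g <- snap_stack_precision(g)
    gray <- voxel_volume(g, spec$voxel_um)
    rods <- list(x_mm = rod_x, y_mm = c(0, 0), radius_mm = rod_r,
                 values = att$calibration_rod_values,
                 indices = lapply(rod_masks, which))
  }

  slice_z <- (seq_len(nz) - 0.5) * vox / L
  truth <- list(
    spec = spec,
    slice_table = ground_truth_profile(spec, pmin(pmax(slice_z, 0), 1)),
    profile = ground_truth_profile(spec),
    lever_arm = if (spec$curvature_sagitta_mm > 0) {
      spec$curvature_sagitta_mm /
        sqrt(spec$outer_a(0.5) * spec$outer_b(0.5))
    } else 0,
    grid = list(dim = c(nx, ny, nz), voxel_um = spec$voxel_um,
                x_mm = xs, y_mm = ys),
    fibula = if (!is.null(spec$fibula)) {
      list(idx_only = fib_only, idx_all = fib_all)
    },
    trabecular = if (!is.null(lat)) {
      roi_len <- as.integer(round(0.05 * nz))
      ref <- if (!is.na(bridge_slice)) bridge_slice else {
        which(trab_bone_count > 0)[1]
      }
      roi <- ref:min(ref + roi_len - 1, nz)
      list(bridge_slice = bridge_slice,
           per_slice_envelope = trab_env_count,
           per_slice_bone = trab_bone_count,
           slice_indices = trab_idx,
           realized_bvtv_roi = 100 * sum(trab_bone_count[roi]) /
             max(sum(trab_env_count[roi]), 1L),
           tb_th_mm = lat$element_thickness_mm,
           fabric_direction = lat$principal_direction)
    },
    rods = rods
  )
  list(gray = gray,
       binary = voxel_volume(binary, spec$voxel_um),
       truth = truth)
}
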