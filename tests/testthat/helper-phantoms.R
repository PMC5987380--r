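# Shared fixtures: direct 2D rasterizers and closed forms for elliptical
# annuli, plus small phantom builders. Everything is generated in code at
# test time.

# rasterize an elliptical annulus (outer a x b, concentric scaled-inner
# wall t, axes rotated by angle_deg) on an h-mm pixel grid centred on the
# section centre
raster_annulus <- function(a, b, t, h, angle_deg = 0) {
  n <- 2L * ceiling(max(a, b) / h) + 8L
  xs <- ((1:n) - (n + 1) / 2) * h
  X <- matrix(xs, n, n)
  Y <- t(X)
  th <- angle_deg * pi / 180
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  outer <- (U / a)^2 + (V / b)^2 <= 1
  inner <- (U / (a - t))^2 + (V / (b - t))^2 <= 1
  outer & !inner
}

# closed-form section properties of the concentric elliptical annulus
annulus_props <- function(a, b, t) {
  ai <- a - t
  bi <- b - t
  ix <- pi / 4 * (a * b^3 - ai * bi^3)
  iy <- pi / 4 * (a^3 * b - ai^3 * bi)
  list(csa = pi * (a * b - ai * bi),
       imin = min(ix, iy), imax = max(ix, iy),
       j = ix + iy, ell = max(ix, iy) / min(ix, iy))
}

# straight or curved circular-tube phantom
tube_spec <- function(length_mm = 10, voxel_um = 25, R = 1, wall = 0.2,
                      sagitta = 0, angle = 0, ...) {
  phantom_spec(length_mm = length_mm, voxel_um = voxel_um,
               outer_a = function(z) rep(R, length(z)),
               wall = function(z) rep(wall, length(z)),
               curvature_sagitta_mm = sagitta,
               curvature_plane_angle_deg = angle, ...)
}

# bone with a two-island trabecular compartment whose bridge slice is
# recorded in the ground truth
trab_bone <- function(voxel_um = 40, length_mm = 12, seed = 11, ...) {
  p <- tibia_params(voxel_um = voxel_um, length_mm = length_mm)
  phantom_from_params(p, with_trabecular = TRUE, seed = seed, ...)
}

# the 2x2x3 factorial skeleton with n replicates per cell
factorial_table <- function(n = 5) {
  expand.grid(genotype = c("A", "B"), sex = c("M", "F"),
              age = c(10, 20, 40), rep = seq_len(n),
              stringsAsFactors = FALSE)
}
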