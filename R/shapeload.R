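# Curvature and load-geometry statistics: per-slice moment arm about the
# proximal-distal chord (or a supplied loading axis), the normalized
# curvature lever arm at midshaft, and a clearly-labelled beam-theory
# stress surrogate.

#' Per-slice moment arm about the loading axis
#'
#' The default axis is the chord through the most proximal and most distal
#' slice centroids of the whole bone (pass `aligned`; without it the chord
#' falls back to the first and last profiled slices); the arm is the
#' perpendicular distance (mm) of each slice centroid to that 3D line. A
#' supplied loading axis (point + direction) replaces the chord.
#'
#' @param profile a [profile_whole_bone()] result (needs `centroid_x_mm`,
#'   `centroid_y_mm`, `z_mm`; at least 3 slices)
#' @param loading_axis optional list `list(point = c(x, y, z), direction =
#'   c(dx, dy, dz))` in mm
#' @param aligned the [aligned_bone()] the profile came from; its end-slice
#'   centroids define the proximal-distal chord
#' @return data.frame of class `moment_arm_profile`: `percent`, `arm_mm`,
#'   plus the in-plane bending direction (`bend_x`, `bend_y`, unit vector
#'   from the axis towards the centroid; zero for a zero arm)
#' @export
moment_arm_profile <- function(profile, loading_axis = NULL,
                               aligned = NULL) {
  stopifnot(nrow(profile) >= 3)
  P <- cbind(profile$centroid_x_mm, profile$centroid_y_mm, profile$z_mm)
  if (is.null(loading_axis)) {
    if (!is.null(aligned)) {
      stopifnot(inherits(aligned, "aligned_bone"))
      h <- aligned$voxel_um / 1000
      z0 <- aligned$z_range[1]
      z1 <- aligned$z_range[2]
      c0 <- which(aligned$mask[, , z0], arr.ind = TRUE)
      c1 <- which(aligned$mask[, , z1], arr.ind = TRUE)
      a <- c(mean(c0[, 1]) * h, mean(c0[, 2]) * h, 0.5 * h)
      b <- c(mean(c1[, 1]) * h, mean(c1[, 2]) * h, (z1 - z0 + 0.5) * h)
    } else {
      a <- P[1, ]
      b <- P[nrow(P), ]
    }
    if (sqrt(sum((b - a)^2)) < 1e-9) stop("coincident chord endpoints")
    u <- (b - a) / sqrt(sum((b - a)^2))
  } else {
    a <- loading_axis$point
    u <- loading_axis$direction
    if (sqrt(sum(u^2)) < 1e-9) stop("degenerate loading axis direction")
    u <- u / sqrt(sum(u^2))
  }
  rel <- sweep(P, 2, a)
  proj <- rel %*% u
  perp <- rel - proj %*% t(u)
  arm <- sqrt(rowSums(perp^2))
  bend <- matrix(0, nrow(P), 2)
  nz <- arm > 1e-9
  bend[nz, ] <- perp[nz, 1:2, drop = FALSE] / arm[nz]
  out <- data.frame(percent = profile$percent, arm_mm = arm,
                    bend_x = bend[, 1], bend_y = bend[, 2])
  attr(out, "axis") <- list(point = a, direction = u)
  class(out) <- c("moment_arm_profile", class(out))
  out
}

#' Normalized curvature lever arm at midshaft
#'
#' The perpendicular distance from the proximal-distal chord to the
#' centroid at midshaft (50% of length), divided by the radius of the
#' midshaft section. "Radius" of a non-circular section is the
#' area-equivalent outer radius `sqrt(filled area / pi)` by default; the
#' outer semi-major axis alternative via `radius = "semi-major"`.
#'
#' @param profile a [profile_whole_bone()] result including percent 50
#' @param arms optional precomputed [moment_arm_profile()]
#' @param radius `"equivalent"` (default) or `"semi-major"`
#' @param aligned passed to [moment_arm_profile()] when `arms` is missing
#' @return unitless lever arm
#' @export
curvature_lever_arm <- function(profile, arms = NULL,
                                radius = c("equivalent", "semi-major"),
                                aligned = NULL) {
  radius <- match.arg(radius)
  if (!50 %in% profile$percent) {
    stop("midshaft slice (50%) missing from the profile")
  }
  if (is.null(arms)) arms <- moment_arm_profile(profile, aligned = aligned)
  mid <- profile[profile$percent == 50, ]
  r <- if (radius == "equivalent") {
    mid$r_eq_mm
  } else {
    # outer semi-major axis of the filled section from its area and moments
    2 * sqrt(mid$i_max_mm4 / mid$filled_area_mm2)
  }
  if (!is.finite(r) || r <= 0) stop("degenerate midshaft slice")
  arms$arm_mm[arms$percent == 50] / r
}

#' Axial load configuration for the beam surrogate
#'
#' @param load_n axial load, newton
#' @param youngs_gpa Young's modulus, GPa (default 17, homogeneous bone
#'   tissue)
#' @param poisson Poisson ratio (default 0.3)
#' @return object of class `beam_load_config`
#' @export
beam_load_config <- function(load_n, youngs_gpa = 17, poisson = 0.3) {
  stopifnot(load_n > 0, youngs_gpa > 0, poisson >= 0, poisson < 0.5)
  structure(list(load_n = load_n, youngs_gpa = youngs_gpa,
                 poisson = poisson), class = "beam_load_config")
}

#' Beam-theory stress surrogate along the bone
#'
#' An explicitly labelled beam-theory surrogate for full finite-element
#' stress fields: per slice, `sigma = P/CSA + P * arm * c / I`, with `c`
#' the maximum in-plane distance from the centroid to bone pixels along
#' the bending direction and `I` the second moment about the bending axis.
#' With zero arm it reduces exactly to pure compression `P/CSA`.
#'
#' @param aligned the [aligned_bone()] the profile came from (slice pixel
#'   data are needed for `c` and the bending-axis moment)
#' @param profile a [profile_whole_bone()] result
#' @param arms the matching [moment_arm_profile()]
#' @param cfg a [beam_load_config()]
#' @return data.frame: `percent`, `sigma_mpa`, `sigma_axial_mpa`,
#'   `sigma_bending_mpa`, `strain_ue` (uniaxial-equivalent microstrain,
#'   sigma / E); attribute `"label"` marks the output as a beam-theory
#'   surrogate
#' @export
beam_stress_surrogate <- function(aligned, profile, arms, cfg) {
  stopifnot(inherits(aligned, "aligned_bone"),
            inherits(cfg, "beam_load_config"),
            nrow(profile) == nrow(arms))
  h <- aligned$voxel_um / 1000
  P <- cfg$load_n
  n <- nrow(profile)
  s_ax <- P / profile$csa_mm2
  s_bend <- numeric(n)
  for (k in seq_len(n)) {
    arm <- arms$arm_mm[k]
    if (arm <= 1e-9) next
    e <- c(arms$bend_x[k], arms$bend_y[k])
    sl <- aligned$mask[, , profile$slice_index[k]]
    idx <- which(sl, arr.ind = TRUE)
    dx <- idx[, 1] * h - profile$centroid_x_mm[k]
    dy <- idx[, 2] * h - profile$centroid_y_mm[k]
    proj <- dx * e[1] + dy * e[2]
    cmax <- max(abs(proj))
    Ibend <- h^2 * sum(proj^2) + nrow(idx) * h^4 / 12
    s_bend[k] <- P * arm * cmax / Ibend
  }
  sigma <- s_ax + s_bend
  out <- data.frame(percent = profile$percent,
                    sigma_mpa = sigma,
                    sigma_axial_mpa = s_ax,
                    sigma_bending_mpa = s_bend,
                    strain_ue = sigma / (cfg$youngs_gpa * 1000) * 1e6)
  attr(out, "label") <- "beam-theory surrogate (not a finite-element solution)"
  out
}
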