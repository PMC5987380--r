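# Factorial cohorts of phantom bones. A baseline murine-tibia parameter set
# is perturbed per animal by factor effects (main effects and interactions)
# and by Gaussian biological noise; the analytic ground truth of every
# animal follows from its perturbed parameters.

#' Baseline murine tibia phantom parameters
#'
#' Scalar parameters from which a [phantom_spec()] is built via
#' [phantom_from_params()]. Defaults approximate an adult mouse tibia:
#' ~17 mm long, elliptical mid-shaft cross-section with outer semi-axes
#' around 0.7 x 0.55 mm, proximal metaphyseal flare, a 0.2-0.25 mm cortical
#' wall, modest sagittal curvature and a proximal trabecular compartment.
#'
#' @param ... overrides for individual parameters
#' @return named list of parameters
#' @export
tibia_params <- function(...) {
  p <- list(
    length_mm = 17,
    voxel_um = 5,
    size_mm = 0.62,        # mid-shaft geometric-mean outer semi-axis
    ell_base = 1.55,       # baseline ellipticity Imax/Imin = (a/b)^2
    ell_bump = 0,          # localized ellipticity increase ...
    ell_window = c(0.30, 0.40),  # ... confined to this z-window
    wall_mm = 0.30,
    sagitta_mm = 0.25,
    plane_angle_deg = 20,
    bvtv_target = 35,
    trab_spacing_mm = 0.40,
    trab_span = c(0.05, 0.18),
    bridge_z = 0.08,
    fibula_radius_mm = 0.22,
    fibula_offset_mm = 1.8,
    fibula_span = c(0.15, 0.75),
    bone_value = 290,
    noise_sd = 10
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  p
}

# Smooth plateau bump confined to a z-window: cosine ramps over the outer
# 20% of the window, full height on the central plateau.
window_bump <- function(z, window) {
  w0 <- window[1]; w1 <- window[2]
  r <- 0.2 * (w1 - w0)
  out <- numeric(length(z))
  inw <- z >= w0 & z <= w1
  out[inw] <- 1
  up <- z >= w0 & z < w0 + r
  out[up] <- 0.5 * (1 - cos(pi * (z[up] - w0) / r))
  dn <- z > w1 - r & z <= w1
  out[dn] <- 0.5 * (1 - cos(pi * (w1 - z[dn]) / r))
  out
}

#' Build a phantom specification from scalar tibia parameters
#'
#' Shape profiles: the outer cross-section tapers with a proximal flare
#' (quadratic in z), ellipticity is `ell_base` plus a localized bump of
#' height `ell_bump` in `ell_window`, the wall thins proximally. The
#' geometric-mean semi-axis is held at `size_mm` so ellipticity changes are
#' approximately area-neutral.
#'
#' @param p parameter list from [tibia_params()]
#' @param with_fibula,with_trabecular include the fibula rod / trabecular
#'   lattice
#' @param seed seed stored in the spec (grayscale noise)
#' @return a [phantom_spec()]
#' @export
phantom_from_params <- function(p, with_fibula = FALSE,
                                with_trabecular = FALSE, seed = 1L) {
  flare <- function(z) 1.35 - 0.97 * z + 0.54 * z^2
  ell <- function(z) {
    pmax(p$ell_base + p$ell_bump * window_bump(z, p$ell_window), 1.0)
  }
  outer_a <- function(z) p$size_mm * flare(z) * ell(z)^(1 / 4)
  outer_b <- function(z) p$size_mm * flare(z) / ell(z)^(1 / 4)
  wall <- function(z) p$wall_mm * (0.85 + 0.6 * z - 0.45 * z^2)
  trab <- if (with_trabecular) {
    trab_lattice_spec(lattice_kind = "plate-rod",
                      spacing_mm = p$trab_spacing_mm,
                      target_bvtv_percent = p$bvtv_target,
                      span = p$trab_span,
                      bridge_z = p$bridge_z,
                      phase_mm = (p$bridge_z * p$length_mm) %%
                        p$trab_spacing_mm)
  }
  fib <- if (with_fibula) {
    list(radius_mm = p$fibula_radius_mm, offset_mm = p$fibula_offset_mm,
         span = p$fibula_span, fused = FALSE)
  }
  phantom_spec(
    length_mm = p$length_mm,
    voxel_um = p$voxel_um,
    outer_a = outer_a,
    outer_b = outer_b,
    wall = wall,
    curvature_sagitta_mm = p$sagitta_mm,
    curvature_plane_angle_deg = p$plane_angle_deg,
    fibula = fib,
    trabecular = trab,
    attenuation = list(bone_value = p$bone_value, background_value = 30,
                       noise_sd = p$noise_sd,
                       calibration_rod_values = c(100, 200)),
    seed = seed
  )
}

#' Define a factorial cohort design
#'
#' Full 2 x 2 x 3 factorial: genotype (A = control, B = OA-prone strain),
#' sex (M/F), age (10/20/40 weeks), `n_per_cell` animals per cell. Effects
#' are additive shifts (or multipliers) on named baseline parameters applied
#' to the cells matching `when`; biological noise is per-parameter Gaussian.
#'
#' @param n_per_cell animals per factorial cell (default 5)
#' @param effect_map list of effects, each
#'   `list(param =, when = c(factor = level, ...), shift =, mode = "add"|"mult")`
#' @param noise_map named numeric vector of per-parameter Gaussian sds
#' @param seed master seed; per-animal seeds are split from it
#'   deterministically and recorded in the covariate table
#' @return object of class `cohort_design`
#' @export
cohort_design <- function(n_per_cell = 5, effect_map = list(),
                          noise_map = c(size_mm = 0.02, wall_mm = 0.012,
                                        ell_base = 0.05, sagitta_mm = 0.03,
                                        bvtv_target = 2, length_mm = 0.4),
                          seed = 1L) {
  stopifnot(n_per_cell >= 1)
  for (e in effect_map) {
    stopifnot(is.list(e), !is.null(e$param), !is.null(e$when),
              !is.null(e$shift))
    if (!all(names(e$when) %in% c("genotype", "sex", "age"))) {
      stop("effect 'when' must reference genotype, sex and/or age")
    }
  }
  structure(list(
    genotype = c("A", "B"), sex = c("M", "F"), age = c(10, 20, 40),
    n_per_cell = as.integer(n_per_cell),
    effect_map = effect_map,
    noise_map = noise_map,
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Paper-motivated demonstration effect map
#'
#' Qualitative factor effects for demonstration cohorts: age-related growth,
#' higher cortical and trabecular mass in the OA-prone genotype, larger
#' males, and a genotype-by-sex interaction that raises proximal (30-40%)
#' cross-sectional ellipticity and curvature in OA-prone males only. No
#' published effect sizes exist for such shape differences, so the
#' magnitudes are package choices, documented in the methods vignette.
#'
#' @return effect list usable as `effect_map` in [cohort_design()]
#' @export
demo_effect_map <- function() {
  list(
    list(param = "size_mm", when = c(age = "20"), shift = 1.05, mode = "mult"),
    list(param = "size_mm", when = c(age = "40"), shift = 1.09, mode = "mult"),
    list(param = "wall_mm", when = c(age = "20"), shift = 1.10, mode = "mult"),
    list(param = "wall_mm", when = c(age = "40"), shift = 1.20, mode = "mult"),
    list(param = "size_mm", when = c(sex = "M"), shift = 1.04, mode = "mult"),
    list(param = "wall_mm", when = c(genotype = "B"), shift = 1.08, mode = "mult"),
    list(param = "bvtv_target", when = c(genotype = "B"), shift = 8),
    list(param = "bvtv_target", when = c(genotype = "B", sex = "M"), shift = -6),
    list(param = "ell_bump", when = c(genotype = "B", sex = "M"), shift = 0.25),
    list(param = "sagitta_mm", when = c(genotype = "B", sex = "M"), shift = 0.10),
    list(param = "sagitta_mm", when = c(genotype = "B"), shift = 0.06)
  )
}

#' Generate a factorial cohort of phantom specifications
#'
#' Each animal's parameters are the baseline plus matching factor shifts
#' plus Gaussian noise; specs, closed-form ground truth and a covariate
#' table are returned. Identical seeds reproduce identical cohorts.
#'
#' @param design a [cohort_design()]
#' @param base_params baseline parameters ([tibia_params()])
#' @param voxel_um voxel size used when the specs are later voxelized
#' @param with_fibula,with_trabecular passed to [phantom_from_params()]
#' @return list with `animals` (list of `list(spec, params, truth)`) and
#'   `covariates` (data.frame: animal, genotype, sex, age, seed)
#' @export
generate_cohort <- function(design, base_params = tibia_params(),
                            voxel_um = base_params$voxel_um,
                            with_fibula = FALSE, with_trabecular = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  cells <- expand.grid(genotype = design$genotype, sex = design$sex,
                       age = design$age, rep = seq_len(design$n_per_cell),
                       stringsAsFactors = FALSE)
  n <- nrow(cells)
  set.seed(design$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  animals <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    p <- base_params
    p$voxel_um <- voxel_um
    cov <- c(genotype = cells$genotype[i], sex = cells$sex[i],
             age = as.character(cells$age[i]))
    for (e in design$effect_map) {
      if (all(cov[names(e$when)] == e$when)) {
        mode <- e$mode %||% "add"
        if (!e$param %in% names(p)) {
          stop(sprintf("effect references unknown parameter '%s'", e$param))
        }
        p[[e$param]] <- if (mode == "mult") p[[e$param]] * e$shift
                        else p[[e$param]] + e$shift
      }
    }
    for (nm in names(design$noise_map)) {
      p[[nm]] <- p[[nm]] + rnorm(1, sd = design$noise_map[[nm]])
    }
    spec <- phantom_from_params(p, with_fibula = with_fibula,
                                with_trabecular = with_trabecular,
                                seed = seeds[i])
    animals[[i]] <- list(spec = spec, params = p,
                         truth = ground_truth_profile(spec))
  }
  covariates <- data.frame(
    animal = sprintf("a%03d", seq_len(n)),
    genotype = cells$genotype, sex = cells$sex, age = cells$age,
    seed = seeds, stringsAsFactors = FALSE
  )
  list(animals = animals, covariates = covariates)
}
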