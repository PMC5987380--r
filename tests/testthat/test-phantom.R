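test_that("straight circular tube reproduces annulus closed forms", {
  spec <- tube_spec(length_mm = 4, voxel_um = 25, R = 1, wall = 0.2)
  gen <- generate_bone(spec, grayscale = FALSE)
  tr <- gen$truth$profile
  expect_equal(unique(round(tr$csa_mm2, 6)), round(pi * (1 - 0.8^2), 6))
  expect_equal(unique(round(tr$j_mm4, 6)), round(pi / 2 * (1 - 0.8^4), 6))
  expect_true(all(tr$ellipticity == 1))
  # voxelized CSA tracks the closed form
  ab <- aligned_bone(gen$binary)
  pr <- profile_whole_bone(ab, percents = 30:70)
  expect_lt(max(abs(pr$csa_mm2 / (pi * 0.36) - 1)), 0.02)
})

test_that("curved phantom records the requested moment-arm profile", {
  spec <- tube_spec(length_mm = 10, voxel_um = 25, sagitta = 0.5, angle = 30)
  tr <- ground_truth_profile(spec)
  expect_equal(max(tr$arm_mm), 0.5, tolerance = 1e-9)
  expect_equal(tr$arm_mm[tr$z_norm == 0.5], 0.5, tolerance = 1e-9)
  expect_equal(tr$arm_mm[c(1, nrow(tr))], c(0, 0), tolerance = 1e-9)
})

test_that("degenerate annuli and sub-resolution walls are rejected", {
  expect_error(
    phantom_spec(length_mm = 5, voxel_um = 25,
                 outer_a = function(z) 1 - 0.9 * z,
                 wall = function(z) rep(0.2, length(z))),
    "degenerate annulus at z")
  expect_error(tube_spec(voxel_um = 80, wall = 0.2), "under 4 voxels")
})

test_that("generation is bit-for-bit deterministic in the spec and seed", {
  spec <- tube_spec(length_mm = 3, voxel_um = 40, seed = 9)
  g1 <- generate_bone(spec)
  g2 <- generate_bone(spec)
  expect_identical(g1$binary$data, g2$binary$data)
  expect_identical(g1$gray$data, g2$gray$data)
})

test_that("halving the voxel size at least halves the CSA error", {
  mk <- function(v) phantom_spec(length_mm = 4, voxel_um = v,
                                 outer_a = function(z) rep(1, length(z)),
                                 outer_b = function(z) rep(0.75, length(z)),
                                 wall = function(z) rep(0.22, length(z)))
  err <- vapply(c(40, 20), function(v) {
    g <- generate_bone(mk(v), grayscale = FALSE)
    pr <- profile_whole_bone(aligned_bone(g$binary), percents = 30:70)
    tr <- ground_truth_profile(mk(v), pr$percent / 100)
    max(abs(pr$csa_mm2 - tr$csa_mm2))
  }, numeric(1))
  expect_lt(err[2], 0.5 * err[1])
})

test_that("calibration rods are labelled, disjoint and clear of the bone", {
  spec <- tube_spec(length_mm = 3, voxel_um = 40)
  gen <- generate_bone(spec, grayscale = TRUE)
  rods <- gen$truth$rods
  expect_length(rods$indices, 2)
  expect_length(intersect(rods$indices[[1]], rods$indices[[2]]), 0)
  nxny <- prod(gen$truth$grid$dim[1:2])
  bone2d <- which(apply(gen$binary$data, 1:2, any))
  for (k in 1:2) expect_length(intersect(rods$indices[[k]], bone2d), 0)
})

test_that("lattice generators match their analytic fractions", {
  lp <- trab_lattice_spec("plates", spacing_mm = 0.2,
                          element_thickness_mm = 0.06)
  gp <- generate_trabecular_lattice(lp, c(50, 50, 50), 20)
  # plate fraction t/s, within one voxel layer per plate
  expect_equal(gp$realized$bvtv_percent / 100, 0.06 / 0.2,
               tolerance = 0.02 / 0.06)
  gs <- generate_trabecular_lattice(
    trab_lattice_spec("spheres-removed", spacing_mm = 0.2,
                      target_bvtv_percent = 100),
    c(30, 30, 30), 20)
  expect_equal(gs$realized$bvtv_percent, 100)
  gr <- generate_trabecular_lattice(
    trab_lattice_spec("rods", spacing_mm = 0.2, element_thickness_mm = 0.08,
                      principal_direction = c(0, 0, 1)),
    c(40, 40, 40), 20)
  expect_equal(gr$realized$fabric_direction, c(0, 0, 1))
  expect_error(
    trab_lattice_spec("spheres-removed", spacing_mm = 0.2,
                      target_bvtv_percent = 30),
    "achievable range")
})

test_that("cohorts: factorial structure, determinism, localized effects", {
  # no effects, no noise: every animal shares the same parameters
  d0 <- cohort_design(n_per_cell = 5, noise_map = numeric(0), seed = 3)
  c0 <- generate_cohort(d0)
  expect_equal(nrow(c0$covariates), 60)
  expect_equal(length(unique(interaction(c0$covariates$genotype,
                                         c0$covariates$sex,
                                         c0$covariates$age))), 12)
  pars <- lapply(c0$animals, function(a) a$params)
  expect_true(all(vapply(pars, identical, logical(1), pars[[1]])))
  # same seed reproduces the cohort exactly
  c0b <- generate_cohort(d0)
  expect_identical(c0$covariates, c0b$covariates)
  expect_identical(c0$animals[[7]]$truth, c0b$animals[[7]]$truth)
  # an ellipticity interaction confined to a z-window shifts the ground
  # truth inside the window only
  d1 <- cohort_design(n_per_cell = 1, noise_map = numeric(0), seed = 3,
                      effect_map = list(list(param = "ell_bump",
                                             when = c(genotype = "B",
                                                      sex = "M"),
                                             shift = 0.3)))
  c1 <- generate_cohort(d1)
  cov <- c1$covariates
  iBM <- which(cov$genotype == "B" & cov$sex == "M" & cov$age == 10)
  iAF <- which(cov$genotype == "A" & cov$sex == "F" & cov$age == 10)
  tB <- c1$animals[[iBM]]$truth
  tA <- c1$animals[[iAF]]$truth
  inwin <- tB$z_norm > 0.31 & tB$z_norm < 0.39
  outwin <- tB$z_norm < 0.28 | tB$z_norm > 0.42
  expect_true(all(tB$ellipticity[inwin] > tA$ellipticity[inwin] + 0.1))
  expect_equal(tB$ellipticity[outwin], tA$ellipticity[outwin],
               tolerance = 1e-12)
  expect_error(
    generate_cohort(cohort_design(effect_map = list(
      list(param = "nonexistent", when = c(sex = "M"), shift = 1)))),
    "unknown parameter")
})
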