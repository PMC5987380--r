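test_that("BV/TV is a plain voxel ratio with exact symmetries", {
  env <- array(TRUE, c(10, 10, 10))
  expect_equal(bvtv(env, env), 100)
  expect_equal(bvtv(env & FALSE, env), 0)
  expect_error(bvtv(env, env & FALSE), "empty envelope")
  set.seed(8)
  m <- array(runif(10^3) < 0.3, c(10, 10, 10))
  b0 <- bvtv(m, env)
  expect_identical(bvtv(aperm(m, c(3, 1, 2)), env), b0)
  expect_identical(bvtv(m[10:1, , ], env), b0)
  # on a lattice grid, BV/TV equals the generator's realized value exactly
  lat <- trab_lattice_spec("plates", spacing_mm = 0.2,
                           element_thickness_mm = 0.06)
  g <- generate_trabecular_lattice(lat, c(40, 40, 40), 20)
  expect_equal(bvtv(g$mask, array(TRUE, c(40, 40, 40))),
               g$realized$bvtv_percent)
})

test_that("local thickness matches plates, rods and single voxels", {
  # plates of 4 voxels, period 10
  m <- array(FALSE, c(40, 40, 40))
  m[, , c(5:8, 15:18, 25:28, 35:38)] <- TRUE
  expect_lt(abs(tb_th(m, 1000) - 4), 1)       # thickness in voxels
  env <- array(TRUE, c(40, 40, 40))
  expect_lt(abs(tb_sp(m, env, 1000) - 6), 1)  # separation s - t
  expect_error(tb_sp(env, env, 1000), "no marrow")
  # cylinder radius 5 -> diameter 10
  xs <- 1:41 - 21
  disc <- outer(xs^2, xs^2, "+") <= 25
  rod <- array(rep(disc, 60), c(41, 41, 60))
  expect_lt(abs(tb_th(rod, 1000) - 10), 1)
  # isolated voxel: one-voxel diameter
  sv <- array(FALSE, c(9, 9, 9))
  sv[5, 5, 5] <- TRUE
  expect_equal(tb_th(sv, 1000), 1)
})

test_that("trabecular number follows the direct model", {
  expect_equal(tb_n(50, 0.05), 10)
  expect_equal(tb_n(0, 0.05), 0)
  # plates t, spacing s: (t/s) / t = 1/s
  lat <- trab_lattice_spec("plates", spacing_mm = 0.2,
                           element_thickness_mm = 0.04)
  g <- generate_trabecular_lattice(lat, c(50, 50, 50), 20)
  th <- tb_th(g$mask, 20)
  tn <- tb_n(g$realized$bvtv_percent, th)
  expect_equal(tn, 1 / 0.2, tolerance = 0.25)
  expect_equal(tb_n(40, 0.1, 0.15, formula = "inverse-spacing"), 4)
})

test_that("fabric analysis separates plates, rods and isotropic structures", {
  vox <- 20
  gp <- generate_trabecular_lattice(
    trab_lattice_spec("plates", spacing_mm = 0.2, target_bvtv_percent = 50),
    c(60, 60, 60), vox)
  gr <- generate_trabecular_lattice(
    trab_lattice_spec("rods", spacing_mm = 0.2, target_bvtv_percent = 50),
    c(60, 60, 60), vox)
  gs <- generate_trabecular_lattice(
    trab_lattice_spec("spheres-removed", spacing_mm = 0.2,
                      target_bvtv_percent = 50),
    c(60, 60, 60), vox)
  dap <- degree_of_anisotropy(gp$mask, vox, seed = 7)
  dar <- degree_of_anisotropy(gr$mask, vox, seed = 7)
  das <- degree_of_anisotropy(gs$mask, vox, seed = 7)
  expect_gt(dap$da, dar$da)
  expect_gt(dar$da, das$da)
  expect_lte(das$da, 0.1)
  expect_gte(dap$da, 0.5)
  # plate normal (z) is the minor fabric axis
  expect_gt(abs(dap$fabric_vectors[3, 3]), cos(5 * pi / 180))
  # rod axis (z) is the major fabric axis
  expect_gt(abs(dar$fabric_vectors[3, 1]), cos(5 * pi / 180))
  # ratio convention is the reciprocal ordering
  expect_gt(degree_of_anisotropy(gp$mask, vox, seed = 7,
                                 convention = "ratio")$da, 2)
  expect_error(degree_of_anisotropy(array(TRUE, c(8, 8, 8)), vox),
               "both phases")
})

test_that("thickness and separation are monotone in their generator dials", {
  vox <- 20
  ths <- vapply(c(0.04, 0.06, 0.08), function(t) {
    g <- generate_trabecular_lattice(
      trab_lattice_spec("plates", spacing_mm = 0.2,
                        element_thickness_mm = t),
      c(50, 50, 50), vox)
    tb_th(g$mask, vox)
  }, numeric(1))
  expect_true(all(diff(ths) > 0))
  sps <- vapply(c(0.16, 0.2, 0.24), function(s) {
    g <- generate_trabecular_lattice(
      trab_lattice_spec("plates", spacing_mm = s,
                        element_thickness_mm = 0.04),
      c(50, 50, 50), vox)
    tb_sp(g$mask, array(TRUE, c(50, 50, 50)), vox)
  }, numeric(1))
  expect_true(all(diff(sps) > 0))
})
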