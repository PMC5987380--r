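test_that("slice geometry matches circular-annulus closed forms", {
  sl <- raster_annulus(1, 1, 0.2, 0.005)
  g <- slice_geometry(sl, 5)
  p <- annulus_props(1, 1, 0.2)
  expect_equal(g$csa_mm2, p$csa, tolerance = 0.01)
  expect_equal(g$i_min_mm4, p$imin, tolerance = 0.01)
  expect_equal(g$i_max_mm4, p$imax, tolerance = 0.01)
  expect_equal(g$j_mm4, p$j, tolerance = 0.01)
  expect_equal(g$ct_th_mm, 0.2, tolerance = 0.01)
  expect_equal(g$ellipticity, 1, tolerance = 0.01)
  expect_equal(g$r_eq_mm, 1, tolerance = 0.01)
  expect_error(slice_geometry(sl & FALSE, 5), "empty slice")
})

test_that("elliptical sections recover the moment-ratio ellipticity", {
  # outer 1.5 x 1.0 mm with a proportionally scaled inner boundary
  h <- 0.01
  n <- 320
  xs <- ((1:n) - (n + 1) / 2) * h
  X <- matrix(xs, n, n)
  Y <- t(X)
  k <- 0.7
  sl <- ((X / 1.5)^2 + Y^2 <= 1) &
    ((X / (1.5 * k))^2 + (Y / k)^2 > 1)
  g <- slice_geometry(sl, h * 1000)
  expect_equal(g$ellipticity, (1.5 / 1)^2, tolerance = 0.02 * 2.25)
  # the axis-ratio flag returns the square root
  g2 <- slice_geometry(sl, h * 1000, ellipticity = "axis-ratio")
  expect_equal(g2$ellipticity, sqrt(g$ellipticity))
})

test_that("slice geometry is rotation invariant and tracks the angle", {
  g0 <- slice_geometry(raster_annulus(1.3, 0.9, 0.3, 0.005), 5)
  g37 <- slice_geometry(raster_annulus(1.3, 0.9, 0.3, 0.005, 37), 5)
  for (f in c("csa_mm2", "i_min_mm4", "i_max_mm4", "j_mm4")) {
    expect_equal(g37[[f]], g0[[f]], tolerance = 0.005)
  }
  d <- (g37$principal_angle_deg - g0$principal_angle_deg) %% 180
  expect_lt(min(abs(d - 37), abs(d - 143)), 1)
})

test_that("J = Imin + Imax holds exactly for every emitted record", {
  spec <- tube_spec(length_mm = 6, voxel_um = 40, R = 1, wall = 0.25,
                    sagitta = 0.3)
  pr <- profile_whole_bone(aligned_bone(generate_bone(spec,
                                                      grayscale = FALSE)$binary))
  expect_equal(pr$j_mm4, pr$i_min_mm4 + pr$i_max_mm4, tolerance = 1e-12)
  expect_true(all(diff(pr$percent) > 0))
})

test_that("a constant tube profiles flat; an ellipticity ramp is recovered", {
  spec <- tube_spec(length_mm = 6, voxel_um = 25, R = 1, wall = 0.25)
  pr <- profile_whole_bone(aligned_bone(generate_bone(spec,
                                                      grayscale = FALSE)$binary))
  expect_equal(nrow(pr), 81)
  expect_lt(diff(range(pr$csa_mm2)) / mean(pr$csa_mm2), 0.02)
  expect_lt(diff(range(pr$ellipticity)), 0.02)
  # linear ellipticity ramp along the bone
  ramp <- function(z) 1 + 0.5 * z
  spec2 <- phantom_spec(length_mm = 6, voxel_um = 25,
                        outer_a = function(z) 1.0 * sqrt(ramp(z)),
                        outer_b = function(z) 1.0 / sqrt(ramp(z)),
                        wall = function(z) rep(0.22, length(z)))
  gen2 <- generate_bone(spec2, grayscale = FALSE)
  pr2 <- profile_whole_bone(aligned_bone(gen2$binary))
  tr2 <- ground_truth_profile(spec2, pr2$percent / 100)
  expect_lte(max(abs(pr2$ellipticity - tr2$ellipticity)), 0.05)
})

test_that("geometry scales as s^2 (areas) and s^4 (moments)", {
  g1 <- slice_geometry(raster_annulus(1, 0.8, 0.25, 0.01), 10)
  g2 <- slice_geometry(raster_annulus(2, 1.6, 0.50, 0.02), 20)
  expect_equal(g2$csa_mm2 / g1$csa_mm2, 4, tolerance = 0.01)
  expect_equal(g2$j_mm4 / g1$j_mm4, 16, tolerance = 0.01)
  expect_equal(g2$ellipticity, g1$ellipticity, tolerance = 0.005)
})

test_that("TMD maps attenuation through the two-point calibration", {
  calib <- density_calibration(c(100, 200), c(0.25, 0.75))
  expect_error(density_calibration(c(100, 100), c(0.25, 0.75)), "distinct")
  m <- array(FALSE, c(12, 12, 20))
  m[4:9, 4:9, ] <- TRUE
  ab <- aligned_bone(m, 50)
  # bone voxels exactly at the upper rod's attenuation
  g <- voxel_volume(array(200 * m, dim(m)), 50)
  expect_equal(tmd(g, ab, calib, n_slices = 10, peel = 0), 0.75)
  # midway attenuation -> midway density
  g2 <- voxel_volume(array(150 * m, dim(m)), 50)
  expect_equal(tmd(g2, ab, calib, n_slices = 10, peel = 0), 0.5)
  # phantom constructed at 1.2 g/cm^3, measured behind blur with peeling
  spec <- tube_spec(length_mm = 5, voxel_um = 40, R = 0.9, wall = 0.3,
                    seed = 2)
  gen <- generate_bone(spec, grayscale = TRUE)
  ab2 <- aligned_bone(gen$binary)
  expect_equal(tmd(gen$gray, ab2, calib, n_slices = 40), 1.2,
               tolerance = 0.05 / 1.2)
})

test_that("porosity counts intracortical voids exactly", {
  spec <- tube_spec(length_mm = 5, voxel_um = 40, R = 1, wall = 0.3)
  gen <- generate_bone(spec, grayscale = FALSE)
  ab <- aligned_bone(gen$binary)
  expect_equal(as.numeric(total_porosity(ab)), 0)
  # drill a canal through the wall of every measured slice
  m <- gen$binary$data
  d <- dim(m)
  cx <- round(d[1] / 2 + 0.9 / 0.04 * 0.92)  # inside the wall, +x side
  cy <- round(d[2] / 2)
  canal <- rep(FALSE, prod(d[1:2]))
  canal[(cx + c(-1, 0, 1)) + (cy + rep(c(-1, 0, 1), each = 3) - 1) * d[1]] <- TRUE
  drilled <- 0L
  shell <- 0L
  ab0 <- aligned_bone(m, 40)
  zset <- unique(vapply(10:90, percentile_slice, integer(1), aligned = ab0))
  for (iz in zset) {
    sl <- m[, , iz]
    stopifnot(all(sl[canal]))
    sl[canal] <- FALSE
    m[, , iz] <- sl
  }
  ab2 <- aligned_bone(m, 40)
  poro <- total_porosity(ab2)
  # pooled porosity = drilled voxels / shell voxels, both exactly countable
  shell_n <- sum(vapply(unique(vapply(10:90, percentile_slice, integer(1),
                                      aligned = ab2)), function(iz) {
    sum(gen$binary$data[, , iz])
  }, numeric(1)))
  drilled_n <- length(which(canal)) * length(zset)
  expect_equal(as.numeric(poro), 100 * drilled_n / shell_n,
               tolerance = 1e-10)
})
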