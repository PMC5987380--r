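test_that("stack write/read round-trips exactly with its sidecar", {
  spec <- tube_spec(length_mm = 3, voxel_um = 40, seed = 4)
  gen <- generate_bone(spec, grayscale = TRUE)
  f <- tempfile(fileext = ".tif")
  write_stack(gen$gray, f)
  v <- read_stack(f)
  expect_identical(v$data, gen$gray$data)
  expect_equal(v$voxel_um, 40)
  fb <- tempfile(fileext = ".tif")
  write_stack(gen$binary, fb)
  expect_identical(read_stack(fb)$data, gen$binary$data)
  # missing sidecar: never guess a voxel size
  file.remove(sub("\\.tif$", ".json", f))
  expect_error(read_stack(f), "voxel size unknown")
  # anisotropic metadata rejected
  write_stack(gen$gray, f)
  meta <- jsonlite::read_json(sub("\\.tif$", ".json", f),
                              simplifyVector = TRUE)
  meta$voxel_um <- c(40, 40, 80)
  jsonlite::write_json(meta, sub("\\.tif$", ".json", f), auto_unbox = TRUE)
  expect_error(read_stack(f), "anisotropic")
  # single-page stacks are not volumes
  f1 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), f1)
  jsonlite::write_json(list(voxel_um = 10), sub("\\.tif$", ".json", f1),
                       auto_unbox = TRUE)
  expect_error(read_stack(f1), "not a 3D volume")
})

test_that("minimum threshold recovers the noiseless phantom exactly", {
  spec <- tube_spec(length_mm = 3, voxel_um = 40)
  gen <- generate_bone(spec, grayscale = FALSE)
  gray <- voxel_volume(gen$binary$data * 200 + 15, 40)
  mask <- threshold_minimum(gray, 100)
  expect_identical(mask$data, gen$binary$data)
  expect_equal(attr(mask, "bone_voxels"), sum(gen$binary$data))
  expect_error(threshold_minimum(gray, 500), "grayscale percentiles")
  expect_error(threshold_minimum(gray, -5), "below the grayscale range")
})

test_that("Otsu threshold on a blurred noisy phantom gives Dice >= 0.98", {
  spec <- phantom_from_params(tibia_params(voxel_um = 40, length_mm = 12),
                              with_fibula = TRUE, seed = 11)
  gen <- generate_bone(spec, grayscale = TRUE)
  thr <- suggest_threshold(gen$gray)
  mask <- remove_fibula(threshold_minimum(gen$gray, thr))
  tib <- gen$binary$data
  tib[gen$truth$fibula$idx_only] <- FALSE
  dice <- 2 * sum(mask$data & tib) / (sum(mask$data) + sum(tib))
  expect_gte(dice, 0.98)
})

test_that("fibula removal keeps the tibia exactly when components are disjoint", {
  spec <- tube_spec(length_mm = 6, voxel_um = 40,
                    fibula = list(radius_mm = 0.25, offset_mm = 1.8,
                                  span = c(0.2, 0.8), fused = FALSE))
  gen <- generate_bone(spec, grayscale = FALSE)
  out <- remove_fibula(gen$binary)
  tib <- gen$binary$data
  tib[gen$truth$fibula$idx_only] <- FALSE
  expect_identical(out$data, tib)
  # no fibula: identity
  spec0 <- tube_spec(length_mm = 3, voxel_um = 40)
  gen0 <- generate_bone(spec0, grayscale = FALSE)
  expect_identical(remove_fibula(gen0$binary)$data, gen0$binary$data)
  # two equal components at the seed slice: ambiguous
  m <- array(FALSE, c(20, 20, 4))
  m[3:6, 3:6, ] <- TRUE
  m[13:16, 13:16, ] <- TRUE
  expect_error(remove_fibula(voxel_volume(m, 40)), "ambiguous tracking")
})

test_that("fused fibula is split along the tracked footprints", {
  bump <- function(z) 0.8 + 0.30 * exp(-((z - 0.625) / 0.06)^2)
  spec <- phantom_spec(length_mm = 6, voxel_um = 40,
                       outer_a = bump,
                       outer_b = function(z) rep(0.8, length(z)),
                       wall = function(z) rep(0.25, length(z)),
                       fibula = list(radius_mm = 0.22, offset_mm = 1.2,
                                     span = c(0.2, 0.9), fused = TRUE))
  gen <- generate_bone(spec, grayscale = FALSE)
  out <- remove_fibula(gen$binary)
  lg <- attr(out, "fibula_log")
  expect_gt(length(lg$fused_slices), 0)
  removed <- which(gen$binary$data & !out$data)
  # removed voxels lie within the fibula truth plus a one-voxel collar
  extra <- setdiff(removed, gen$truth$fibula$idx_all)
  if (length(extra)) {
    co <- arrayInd(extra, dim(gen$binary$data))
    fco <- arrayInd(gen$truth$fibula$idx_all, dim(gen$binary$data))
    mind <- vapply(seq_len(nrow(co)), function(i) {
      min(sqrt(colSums((t(fco) - co[i, ])^2)))
    }, numeric(1))
    expect_lte(max(mind), sqrt(3))
  }
  # the bulk of the separate fibula is gone
  expect_gt(length(intersect(removed, gen$truth$fibula$idx_only)),
            0.9 * length(gen$truth$fibula$idx_only))
})

test_that("longitudinal alignment recovers a 20-degree tilt", {
  spec <- tube_spec(length_mm = 8, voxel_um = 50, R = 0.8, wall = 0.25)
  gen <- generate_bone(spec, grayscale = FALSE)
  R20 <- tibiamorph:::rotation_about_axis(c(1, 0, 0), 20)
  tilted <- voxel_volume(rotate_mask(gen$binary$data, R20), 50)
  ab <- align_longitudinal(tilted)
  expect_lt(abs(attr(ab, "rotation_deg") - 20), 0.5)
  expect_lt(abs(ab$length_mm - 8), 0.051)
  # voxel count conserved under the double NN resampling
  expect_lt(abs(sum(ab$mask) / sum(gen$binary$data) - 1), 0.005)
  # already-aligned bone: identity (no resampling below tolerance)
  ab0 <- align_longitudinal(gen$binary)
  expect_lt(attr(ab0, "rotation_deg"), 0.5)
  expect_identical(sum(ab0$mask), sum(gen$binary$data))
  # landmark mode maps the chord onto z
  lm <- rbind(c(0, 0, 0), c(0, 0, 5))
  abl <- align_longitudinal(gen$binary, landmarks = lm)
  expect_equal(attr(abl, "transform")[1:3, 1:3], diag(3))
  # an isotropic blob has no axis
  xs <- seq(-1, 1, length.out = 21)
  ball <- array(outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= 1, c(21, 21, 21))
  expect_error(align_longitudinal(voxel_volume(ball, 50)),
               "no dominant longitudinal axis")
})

test_that("percentile index is monotone and anchored at the proximal end", {
  m <- array(FALSE, c(4, 4, 120))
  m[2:3, 2:3, 11:110] <- TRUE   # 100 occupied slices
  ab <- aligned_bone(m, 10)
  expect_equal(ab$n_slices, 100L)
  idx <- vapply(10:90, percentile_slice, integer(1), aligned = ab)
  expect_true(all(diff(idx) >= 0))
  expect_true(all(diff(vapply(seq(10, 90, 10), percentile_slice,
                              integer(1), aligned = ab)) > 0))
  expect_equal(percentile_slice(ab, 0), 11L)
  expect_equal(percentile_slice(ab, 100), 110L)
})

test_that("trabecular reference lands on the generator bridge slice", {
  spec <- trab_bone(voxel_um = 40, length_mm = 12, seed = 11)
  gen <- generate_bone(spec, grayscale = FALSE)
  ab <- aligned_bone(gen$binary)
  orad <- open_radius_for_spec(spec)
  ref <- find_trabecular_reference(ab, open_radius_px = orad)
  expect_lte(abs(ref - gen$truth$trabecular$bridge_slice), 1)
  # single continuous lattice: most proximal slice, with a warning
  p <- tibia_params(voxel_um = 40, length_mm = 12)
  lat <- trab_lattice_spec("plate-rod", spacing_mm = p$trab_spacing_mm,
                           target_bvtv_percent = p$bvtv_target,
                           span = p$trab_span, bridge_z = NA)
  spec1 <- phantom_from_params(p, seed = 11)
  spec1$trabecular <- lat
  gen1 <- generate_bone(spec1, grayscale = FALSE)
  ab1 <- aligned_bone(gen1$binary)
  expect_warning(r1 <- find_trabecular_reference(ab1, open_radius_px = orad),
                 "single continuous")
  first_trab <- which(gen1$truth$trabecular$per_slice_bone > 0)[1]
  # envelope regularization and rim erosion can shave a few start slices
  expect_lte(abs(r1 - first_trab), 5)
  # no intramedullary bone at all
  tube <- generate_bone(tube_spec(length_mm = 3, voxel_um = 40),
                        grayscale = FALSE)
  expect_error(find_trabecular_reference(aligned_bone(tube$binary)),
               "no intramedullary bone")
})

test_that("trabecular ROI spans 5% of length and matches generator counts", {
  m <- array(FALSE, c(4, 4, 1000))
  m[2:3, 2:3, ] <- TRUE
  ab <- aligned_bone(m, 10)
  expect_error(extract_trabecular_roi(ab, 100, fraction = 0),
               "empty ROI")
  expect_error(extract_trabecular_roi(ab, 990), "exit")
  spec <- trab_bone(voxel_um = 40, length_mm = 12, seed = 11)
  gen <- generate_bone(spec, grayscale = FALSE)
  abb <- aligned_bone(gen$binary)
  orad <- open_radius_for_spec(spec)
  ref <- find_trabecular_reference(abb, open_radius_px = orad)
  roi <- extract_trabecular_roi(abb, ref, open_radius_px = orad)
  expect_length(roi$slices, round(0.05 * abb$n_slices))
  # every generator lattice voxel inside the envelope is in the ROI mask,
  # and almost nothing else is
  d <- dim(gen$binary$data)
  lat_count <- 0L
  hit <- 0L
  for (k in seq_along(roi$slices)) {
    idx <- gen$truth$trabecular$slice_indices[[roi$slices[k]]]
    inenv <- idx[roi$envelope[, , k][idx]]
    lat_count <- lat_count + length(inenv)
    hit <- hit + sum(roi$mask[, , k][inenv])
  }
  expect_equal(hit, lat_count)
  # the envelope may include a thin endosteal rind of cortical voxels
  expect_lt(sum(roi$mask) / lat_count - 1, 0.05)
})
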