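# Preprocessing chain for bone stacks: minimum thresholding, fibula
# removal by per-slice component tracking, longitudinal alignment, and the
# percentile index along the aligned bone.

#' Segment bone by a minimum threshold
#'
#' @param vol grayscale [voxel_volume()]
#' @param thr threshold; voxels with value >= thr are bone
#' @return binary [voxel_volume()]; the bone-voxel count is attached as
#'   attribute `"bone_voxels"`
#' @export
threshold_minimum <- function(vol, thr) {
  stopifnot(inherits(vol, "voxel_volume"), !is.logical(vol$data))
  rng <- range(vol$data)
  if (thr < rng[1]) {
    stop(sprintf("threshold %.3g below the grayscale range [%.3g, %.3g]",
                 thr, rng[1], rng[2]))
  }
  mask <- vol$data >= thr
  if (!any(mask)) {
    q <- quantile(vol$data, c(0.5, 0.9, 0.99, 0.999))
    stop(sprintf(paste0("threshold produced an empty mask; grayscale ",
                        "percentiles: 50%% = %.3g, 90%% = %.3g, 99%% = %.3g, ",
                        "99.9%% = %.3g"), q[1], q[2], q[3], q[4]))
  }
  out <- voxel_volume(mask, vol$voxel_um)
  attr(out, "bone_voxels") <- sum(mask)
  out
}

#' Suggest a global threshold by Otsu's method
#'
#' @param vol grayscale [voxel_volume()]
#' @return suggested threshold on the volume's grayscale scale
#' @export
suggest_threshold <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  rng <- range(vol$data)
  x <- (vol$data - rng[1]) / max(rng[2] - rng[1], 1e-12)
  # 2D otsu over the pooled histogram: feed as one wide image
  img <- EBImage::Image(as.vector(x), dim = c(length(x), 1))
  as.numeric(EBImage::otsu(img, range = c(0, 1))) * (rng[2] - rng[1]) + rng[1]
}

#' Remove the fibula from a segmented stack
#'
#' Per-slice connected components (8-connectivity) are tracked from the
#' most proximal slice: the chain continuous with the largest proximal
#' component is the tibia and is kept; components tracked as secondary
#' (fibula) are removed. In slices where tibia and fibula have fused into
#' one component, the component is split by seeded region growing
#' (`EBImage::propagate`) from the previous slice's tibia/fibula footprints
#' and the affected z-range is logged.
#'
#' @param mask binary [voxel_volume()]
#' @return binary [voxel_volume()] with attribute `"fibula_log"` (list:
#'   `removed_voxels`, `fused_slices`)
#' @export
remove_fibula <- function(mask) {
  stopifnot(inherits(mask, "voxel_volume"), is.logical(mask$data))
  m <- mask$data
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  nz <- d[3]
  occ <- which(apply(m, 3, any))
  z0 <- occ[1]
  lab0 <- label_components_2d(m[, , z0])
  sizes <- tabulate(lab0[lab0 > 0])
  if (length(sizes) > 1) {
    s <- sort(sizes, decreasing = TRUE)
    if (s[1] == s[2]) {
      stop(paste0("ambiguous tracking: two equal-size components at the ",
                  "seed slice; supply a manual seed point"))
    }
  }
  tib_prev <- lab0 == which.max(sizes)
  fib_prev <- m[, , z0] & !tib_prev
  out <- array(FALSE, d)
  out[, , z0] <- tib_prev
  removed <- sum(fib_prev)
  fused_slices <- integer(0)
  dil <- function(x) {
    # one-pixel 8-neighbourhood dilation
    EBImage::imageData(EBImage::dilate(EBImage::Image(x * 1),
                                       EBImage::makeBrush(3, "box"))) > 0
  }
  for (iz in setdiff(occ, z0)) {
    sl <- m[, , iz]
    lab <- label_components_2d(sl)
    nl <- max(lab)
    tp <- dil(tib_prev)
    fp <- dil(fib_prev)
    # anything inside the filled tibia contour (medullary structures such
    # as trabecular islands) belongs to the tibia, never to the fibula
    tp_fill <- EBImage::imageData(
      EBImage::fillHull(EBImage::Image(tp * 1))) > 0
    tib <- matrix(FALSE, d[1], d[2])
    fib <- matrix(FALSE, d[1], d[2])
    for (k in seq_len(nl)) {
      comp <- lab == k
      hit_t <- any(comp & tp) || any(comp & tp_fill)
      hit_f <- any(comp & fp)
      if (hit_t && hit_f) {
        # fused: split by seeded region growing from the previous footprints
        fused_slices <- c(fused_slices, iz)
        seeds <- matrix(0L, d[1], d[2])
        seeds[comp & tp & !fp] <- 1L
        seeds[comp & fp & !tp] <- 2L
        if (!any(seeds == 1L)) seeds[comp & tp] <- 1L
        if (!any(seeds == 2L)) {
          tib <- tib | comp
          next
        }
        grown <- EBImage::propagate(EBImage::Image(comp * 1),
                                    EBImage::Image(seeds), mask = comp)
        g <- EBImage::imageData(grown)
        tib <- tib | (comp & g == 1)
        fib <- fib | (comp & g == 2)
      } else if (hit_t) {
        tib <- tib | comp
      } else {
        fib <- fib | comp
      }
    }
    out[, , iz] <- tib
    removed <- removed + sum(fib)
    if (any(tib)) tib_prev <- tib
    fib_prev <- fib
  }
  res <- voxel_volume(out, mask$voxel_um)
  attr(res, "fibula_log") <- list(removed_voxels = removed,
                                  fused_slices = unique(fused_slices))
  res
}

#' Construct an aligned bone from a canonical-orientation mask
#'
#' @param mask logical 3D array or binary [voxel_volume()] already in
#'   proximodistal orientation (z axis, z = 0 proximal)
#' @param voxel_um voxel size (taken from the volume if given one)
#' @return object of class `aligned_bone`: mask, voxel size, occupied
#'   z-range, bone length (mm) and the percentile index map
#' @export
aligned_bone <- function(mask, voxel_um = NULL) {
  if (inherits(mask, "voxel_volume")) {
    voxel_um <- mask$voxel_um
    mask <- mask$data
  }
  stopifnot(is.logical(mask), length(dim(mask)) == 3, !is.null(voxel_um))
  occ <- which(apply(mask, 3, any))
  if (!length(occ)) stop("empty mask")
  z0 <- occ[1]; z1 <- occ[length(occ)]
  structure(list(
    mask = mask, voxel_um = voxel_um,
    z_range = c(z0, z1),
    n_slices = z1 - z0 + 1L,
    length_mm = (z1 - z0 + 1L) * voxel_um / 1000
  ), class = "aligned_bone")
}

#' @export
print.aligned_bone <- function(x, ...) {
  cat(sprintf("<aligned_bone> %s voxels, %.2f um/voxel, length %.2f mm\n",
              paste(dim(x$mask), collapse = " x "), x$voxel_um, x$length_mm))
  invisible(x)
}

#' Slice index at a percent of bone length
#'
#' Percent measured from the proximal end (z = 0); strictly monotone in
#' the percent.
#'
#' @param aligned an [aligned_bone()]
#' @param percent percent of bone length, 0-100
#' @return integer slice index (z) into the aligned mask
#' @export
percentile_slice <- function(aligned, percent) {
  stopifnot(inherits(aligned, "aligned_bone"),
            all(percent >= 0), all(percent <= 100))
  aligned$z_range[1] +
    as.integer(round(percent / 100 * (aligned$z_range[2] - aligned$z_range[1])))
}

#' Align a bone mask with the longitudinal axis on z
#'
#' Default mode rotates the principal inertia axis of the bone voxel cloud
#' onto +z; landmark mode rotates the chord between two supplied points
#' onto +z. Binary masks are resampled with nearest-neighbour interpolation
#' (voxel counts conserved to within resampling tolerance).
#'
#' @param mask binary [voxel_volume()]
#' @param landmarks optional 2 x 3 matrix of (x, y, z) points, mm
#' @param tol_deg misalignments up to this angle are accepted as already
#'   aligned and no resampling is done (default 0.5 degrees), so
#'   generator-aligned stacks are not degraded by needless interpolation
#' @return an [aligned_bone()] with the 4x4 transform attached as
#'   attribute `"transform"`
#' @export
align_longitudinal <- function(mask, landmarks = NULL, tol_deg = 0.5) {
  stopifnot(inherits(mask, "voxel_volume"), is.logical(mask$data))
  m <- mask$data
  if (!any(m)) stop("empty mask")
  if (is.null(landmarks)) {
    co <- arrayInd(which(m), dim(m))
    cv <- stats::cov(co)
    eg <- eigen(cv, symmetric = TRUE)
    if (eg$values[1] / eg$values[2] < 1.5) {
      stop("no dominant longitudinal axis (voxel cloud nearly isotropic); supply landmarks")
    }
    axis <- eg$vectors[, 1]
  } else {
    landmarks <- as.matrix(landmarks)
    stopifnot(nrow(landmarks) == 2, ncol(landmarks) == 3)
    axis <- (landmarks[2, ] - landmarks[1, ]) / (mask$voxel_um / 1000)
    if (sqrt(sum(axis^2)) < 1e-9) stop("coincident landmarks")
  }
  if (axis[3] < 0) axis <- -axis
  R <- rotation_onto(axis, c(0, 0, 1))
  ang <- acos(min(1, max(-1, axis[3] / sqrt(sum(axis^2))))) * 180 / pi
  if (ang > tol_deg) {
    m <- rotate_mask(m, R)
  } else {
    R <- diag(3)
  }
  ab <- aligned_bone(m, mask$voxel_um)
  tf <- rbind(cbind(R, 0), c(0, 0, 0, 1))
  attr(ab, "transform") <- tf
  attr(ab, "rotation_deg") <- ang
  ab
}
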