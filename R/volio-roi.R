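# Trabecular ROI anchoring: the endosteal envelope, the "bridge" reference
# slice where the two primary-spongiosa islands connect, and the 5%-of-
# length ROI measured from it towards the diaphysis.

#' Morphological opening of a binary mask with a Euclidean ball
#'
#' Erosion then dilation with a ball (disc in 2D) of radius `r` voxels,
#' computed with two distance transforms. Structures thinner than about
#' `2r` in any direction (trabecular plates and struts) vanish; the
#' thicker cortical wall survives.
#'
#' @param mask logical 2D or 3D array
#' @param r ball radius, voxels
#' @return logical array of the same shape
#' @export
morph_open <- function(mask, r) {
  d <- dim(mask)
  d1 <- edt_sq(as.logical(mask), as.integer(d))
  eroded <- d1 > r^2
  dim(eroded) <- d
  if (!any(eroded)) return(eroded)
  d2 <- edt_sq(!eroded, as.integer(d))
  out <- d2 <= r^2
  dim(out) <- d
  out
}

#' Endosteal (medullary) envelope of a slice
#'
#' The cortical shell is isolated by a morphological opening (radius
#' `open_radius_px`, chosen below the cortical wall half-thickness and
#' above the trabecular element half-thickness so trabeculae detach from
#' the shell); the envelope is the filled shell minus the shell - the
#' region interior to the cortex. For stacks with transverse trabecular
#' plates use the 3D path ([extract_trabecular_roi()] /
#' [find_trabecular_reference()]), where the opening is a 3D ball.
#'
#' @param slice logical matrix (one transverse slice)
#' @param open_radius_px opening radius in pixels (default 2)
#' @return logical matrix marking the intracortical region
#' @export
medullary_envelope <- function(slice, open_radius_px = 2) {
  if (!any(slice)) return(slice & FALSE)
  envelope_from_shell(morph_open(slice, open_radius_px))
}

envelope_from_shell <- function(shell) {
  lab <- label_components_2d(shell)
  if (max(lab) == 0) return(shell & FALSE)
  sizes <- tabulate(lab[lab > 0])
  shell <- lab == which.max(sizes)
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(shell * 1))) > 0
  filled & !shell
}

# Per-slice endosteal envelopes over a slice range. The raw per-slice
# envelope can pinch where a trabecular plate meets the wall (a collar of
# the junction survives the opening), so the envelope is regularized by a
# union over +/- `reg_slices` neighbouring slices - the true cavity varies
# slowly along the bone.
envelope_stack <- function(aligned, slices, open_radius_px = 2,
                           reg_slices = 2L) {
  d <- dim(aligned$mask)
  pad <- ceiling(open_radius_px) + 1L + reg_slices
  z0 <- max(1L, min(slices) - pad)
  z1 <- min(d[3], max(slices) + pad)
  opened <- morph_open(aligned$mask[, , z0:z1, drop = FALSE],
                       open_radius_px)
  raw <- array(FALSE, dim(opened))
  for (k in seq_len(dim(opened)[3])) {
    raw[, , k] <- envelope_from_shell(opened[, , k])
  }
  env <- array(FALSE, c(d[1:2], length(slices)))
  for (k in seq_along(slices)) {
    j <- slices[k] - z0 + 1L
    win <- max(1L, j - reg_slices):min(dim(raw)[3], j + reg_slices)
    e <- raw[, , win[1]]
    for (w in win[-1]) e <- e | raw[, , w]
    env[, , k] <- e
  }
  env
}

#' Scale-aware endosteal opening radius for a phantom specification
#'
#' The opening radius must sit between the trabecular element
#' half-thickness (so trabeculae detach from the shell) and the cortical
#' wall half-thickness (so the shell survives); the midpoint
#' `(t + wall) / 4` in voxels is returned, floored at 1.5.
#'
#' @param spec a [phantom_spec()] with a trabecular lattice
#' @return opening radius, voxels
#' @export
open_radius_for_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), !is.null(spec$trabecular))
  vox <- spec$voxel_um / 1000
  t_px <- spec$trabecular$element_thickness_mm / vox
  wall_px <- min(spec$wall(seq(0, 1, by = 0.01))) / vox
  max(1.5, (t_px + wall_px) / 4)
}

#' Find the trabecular "bridge" reference slice
#'
#' Sweeps slices from the proximal end, labelling intramedullary bone
#' (bone inside the endosteal envelope) with 26-connectivity, and returns
#' the most proximal slice at which the two largest intramedullary
#' components become connected. A single continuous structure returns its
#' most proximal slice with a warning; absent intramedullary bone is an
#' error.
#'
#' @param aligned an [aligned_bone()]
#' @param open_radius_px passed to [medullary_envelope()]
#' @param min_island minimum voxel count for a component to count as an
#'   island
#' @param rim_px the envelope is eroded by this many voxels for the
#'   connectivity analysis, so segmentation residue hugging the endosteal
#'   surface cannot short-circuit the two islands (default 2)
#' @return integer slice index (z) of the reference slice
#' @export
find_trabecular_reference <- function(aligned, open_radius_px = 2,
                                      min_island = 30L, rim_px = 2) {
  stopifnot(inherits(aligned, "aligned_bone"))
  zs <- aligned$z_range[1]:aligned$z_range[2]
  env <- envelope_stack(aligned, zs, open_radius_px)
  if (rim_px > 0) {
    de <- edt_sq(as.logical(env), as.integer(dim(env)))
    env <- env & (de > rim_px^2)
  }
  intra <- env & aligned$mask[, , zs, drop = FALSE]
  if (!any(intra)) {
    stop("no intramedullary bone found; supply a manual reference slice")
  }
  sw <- sweep_label_3d(intra, watch_merge = TRUE, min_island = min_island)
  if (is.na(sw$merge_slice)) {
    sizes <- tabulate(sw$labels[sw$labels > 0], nbins = sw$n)
    big <- which.max(sizes)
    # effectively one structure (plus stray rim fragments): fall back to
    # its most proximal slice
    if (sizes[big] >= 0.9 * sum(sizes) || sort(sizes, TRUE)[2] < min_island) {
      warning(paste0("single continuous trabecular structure; using its ",
                     "most proximal slice as reference"))
      first <- which(apply(sw$labels == big, 3, any))[1]
      return(zs[first])
    }
    stop(paste0("trabecular islands never connect; supply a manual ",
                "reference slice"))
  }
  zs[sw$merge_slice]
}

#' Extract the anchored trabecular region of interest
#'
#' The ROI spans `round(fraction * total occupied slices)` slices from the
#' reference slice towards the diaphysis; the trabecular mask is bone
#' intersected with the per-slice endosteal envelope.
#'
#' @param aligned an [aligned_bone()]
#' @param ref_slice reference slice index (z), e.g. from
#'   [find_trabecular_reference()]
#' @param fraction fraction of total bone length (default 0.05)
#' @param open_radius_px passed to [medullary_envelope()]
#' @return list: `mask` (trabecular bone, 3D logical), `envelope`
#'   (3D logical), `slices` (z indices), `voxel_um`
#' @export
extract_trabecular_roi <- function(aligned, ref_slice, fraction = 0.05,
                                   open_radius_px = 2) {
  stopifnot(inherits(aligned, "aligned_bone"))
  n_roi <- as.integer(round(fraction * aligned$n_slices))
  if (n_roi < 1L) stop("empty ROI: fraction too small for this stack")
  slices <- ref_slice + 0:(n_roi - 1L)
  if (ref_slice < aligned$z_range[1] ||
      slices[n_roi] > aligned$z_range[2]) {
    stop(sprintf("ROI slices [%d, %d) exit the occupied volume [%d, %d]",
                 ref_slice, ref_slice + n_roi,
                 aligned$z_range[1], aligned$z_range[2]))
  }
  env <- envelope_stack(aligned, slices, open_radius_px)
  list(mask = env & aligned$mask[, , slices, drop = FALSE],
       envelope = env,
       slices = slices,
       voxel_um = aligned$voxel_um)
}
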