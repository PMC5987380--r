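# Image-stack I/O: multi-page 32-bit float TIFF plus a JSON sidecar
# carrying the voxel size and axis convention. Real scan data without a
# voxel size is rejected outright rather than silently defaulted.

#' Construct a voxel volume
#'
#' @param data 3D numeric or logical array (x, y, z; z proximodistal)
#' @param voxel_um isotropic voxel size, micrometres
#' @return object of class `voxel_volume`
#' @export
voxel_volume <- function(data, voxel_um) {
  if (length(dim(data)) != 3L) stop("not a 3D volume")
  if (any(dim(data) < 2L)) stop("not a 3D volume: each dimension must be >= 2")
  if (length(voxel_um) != 1L || !is.finite(voxel_um) || voxel_um <= 0) {
    stop("voxel_um must be a single positive number (isotropic voxels)")
  }
  structure(list(data = data, voxel_um = as.numeric(voxel_um),
                 axis = "xyz; z proximodistal, z = 0 proximal"),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s, %.2f um/voxel, %s\n",
              paste(dim(x$data), collapse = " x "), x$voxel_um,
              if (is.logical(x$data)) "binary" else "grayscale"))
  invisible(x)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Write a voxel volume as a multi-page TIFF stack with JSON sidecar
#'
#' Grayscale data are stored as 16-bit samples after division by a
#' power-of-two scale (recorded in the sidecar), so values already on the
#' 16-bit grid - as emitted by the phantom generator - round-trip exactly;
#' binary data are stored as 8-bit.
#'
#' @param vol a [voxel_volume()]
#' @param path output path ending in `.tif`; the sidecar is written next to
#'   it with extension `.json`
#' @param extra named list merged into the sidecar (e.g. a spec echo or a
#'   4x4 alignment transform)
#' @return `path`, invisibly
#' @export
write_stack <- function(vol, path, extra = list()) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  binary <- is.logical(vol$data)
  if (binary) {
    pages <- lapply(seq_len(d[3]), function(iz) {
      matrix(as.numeric(vol$data[, , iz]), d[1], d[2])
    })
    scale <- 1
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    if (min(vol$data) < 0) {
      stop("grayscale stacks must be nonnegative (attenuation values)")
    }
    scale <- stack_scale(vol$data)
    pages <- lapply(seq_len(d[3]), function(iz) vol$data[, , iz] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  meta <- c(list(voxel_um = vol$voxel_um, axis = vol$axis, dim = d,
                 binary = binary, scale = scale), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a voxel volume written by [write_stack()]
#'
#' @param path path to the `.tif` stack; the `.json` sidecar must sit next
#'   to it and must carry the voxel size (no default is ever assumed)
#' @return a [voxel_volume()]
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing sidecar '", sc, "': voxel size unknown; refusing to guess")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$voxel_um)) {
    stop("sidecar lacks voxel_um; refusing to assume a voxel size")
  }
  if (length(meta$voxel_um) != 1L || any(meta$voxel_um <= 0)) {
    stop("anisotropic or invalid voxel metadata: voxel_um must be one positive scalar")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("not a 3D volume: stack has fewer than 2 slices")
  d <- c(dim(pages[[1]]), length(pages))
  arr <- array(0, d)
  for (iz in seq_along(pages)) arr[, , iz] <- pages[[iz]]
  scale <- meta$scale %||% 1
  if (isTRUE(meta$binary)) {
    arr <- arr > 0.5
  } else {
    arr <- arr * scale
  }
  vol <- voxel_volume(arr, meta$voxel_um)
  attr(vol, "sidecar") <- meta
  vol
}
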