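# Connected-component labelling with the package-wide connectivity
# convention: 8-connectivity in 2D, 26-connectivity in 3D.

#' Label connected components of a 2D binary image (8-connectivity)
#'
#' `EBImage::bwlabel()` uses 4-connectivity; labels touching diagonally are
#' merged afterwards so the package's stated 8-connectivity convention holds.
#'
#' @param m logical or 0/1 matrix
#' @return integer matrix of component labels (0 = background)
#' @export
label_components_2d <- function(m) {
  lab <- EBImage::bwlabel(m != 0)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(m), ncol(m))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  uf <- seq_len(nl)
  find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) uf[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbours: (+1,+1) and (+1,-1) shifts
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  p <- a > 0 & b > 0 & a != b
  if (any(p)) apply(unique(cbind(a[p], b[p])), 1, function(r) unite(r[1], r[2]))
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  p <- a > 0 & b > 0 & a != b
  if (any(p)) apply(unique(cbind(a[p], b[p])), 1, function(r) unite(r[1], r[2]))
  roots <- vapply(seq_len(nl), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Incremental 3D 26-connectivity labelling by a proximal-to-distal slice
# sweep over per-slice 2D (8-conn) labels joined through a union-find.
# Returns per-voxel labels plus, when `watch_merge` is TRUE, the first slice
# at which the two largest accumulated components coalesce (the trabecular
# "bridge" landmark).
sweep_label_3d <- function(mask, watch_merge = FALSE, min_island = 4L) {
  d <- dim(mask)
  nz <- d[3]
  slice_lab <- vector("list", nz)
  offs <- integer(nz)
  nglob <- 0L
  for (iz in seq_len(nz)) {
    l <- label_components_2d(mask[, , iz])
    slice_lab[[iz]] <- l
    offs[iz] <- nglob
    nglob <- nglob + max(l)
  }
  if (nglob == 0L) {
    return(list(labels = array(0L, d), n = 0L, merge_slice = NA_integer_))
  }
  uf <- seq_len(nglob)
  find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) uf[max(ra, rb)] <<- min(ra, rb)
  }
  sizes <- numeric(nglob)
  merge_slice <- NA_integer_
  prev_top2 <- NULL
  shift2 <- function(m, dx, dy) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0L, nr, nc)
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  for (iz in seq_len(nz)) {
    l <- slice_lab[[iz]]
    nl <- max(l)
    if (nl > 0) {
      tab <- tabulate(l[l > 0], nbins = nl)
      for (j in seq_len(nl)) sizes[offs[iz] + j] <- tab[j]
    }
    if (iz > 1 && nl > 0 && max(slice_lab[[iz - 1]]) > 0) {
      lp <- slice_lab[[iz - 1]]
      for (dx in -1:1) for (dy in -1:1) {
        ls <- if (dx == 0 && dy == 0) lp else shift2(lp, dx, dy)
        p <- ls > 0 & l > 0
        if (any(p)) {
          pairs <- unique(cbind(ls[p], l[p]))
          for (r in seq_len(nrow(pairs))) {
            unite(offs[iz - 1] + pairs[r, 1], offs[iz] + pairs[r, 2])
          }
        }
      }
    }
    if (watch_merge) {
      if (!is.null(prev_top2) && is.na(merge_slice) &&
          find(prev_top2[1]) == find(prev_top2[2])) {
        merge_slice <- iz
      }
      # accumulate component sizes by current root
      act <- which(sizes > 0)
      if (length(act) >= 2) {
        roots <- vapply(act, find, integer(1))
        agg <- rowsum(sizes[act], roots)
        if (nrow(agg) >= 2) {
          ord <- order(agg[, 1], decreasing = TRUE)
          big <- as.integer(rownames(agg))[ord[1:2]]
          if (agg[ord[2], 1] >= min_island) prev_top2 <- big
        }
      }
    }
  }
  roots <- vapply(seq_len(nglob), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  labels <- array(0L, d)
  for (iz in seq_len(nz)) {
    l <- slice_lab[[iz]]
    if (max(l) > 0) {
      li <- l > 0
      sl <- array(0L, d[1:2])
      sl[li] <- relab[offs[iz] + l[li]]
      labels[, , iz] <- sl
    }
  }
  list(labels = labels, n = max(relab), merge_slice = merge_slice)
}

#' Label connected components of a 3D binary volume (26-connectivity)
#'
#' @param mask logical 3D array
#' @return integer array of component labels (0 = background)
#' @export
label_components_3d <- function(mask) {
  sweep_label_3d(mask)$labels
}
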