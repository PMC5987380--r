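`%||%` <- function(a, b) if (is.null(a)) b else a

stack_scale <- function(x) 2^ceiling(log2(max(x, 1e-12)))

#' Snap grayscale values onto the stack storage grid
#'
#' Image stacks are stored as 16-bit TIFF (the common bit depth of the
#' modality) after division by a power-of-two scale; snapping generated
#' volumes onto that 16-bit grid makes the write/read round trip exact.
#'
#' @param x nonnegative numeric vector or array
#' @return `x` quantized to the 16-bit storage grid
#' @export
snap_stack_precision <- function(x) {
  s <- stack_scale(x)
  round(x / s * 65535) / 65535 * s
}

# Separable 3D Gaussian blur (sigma in voxels, reflected edges); used for
# the partial-volume model of the grayscale phantom.
gaussian_blur3 <- function(vol, sigma = 1) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(vol)
  conv_axis <- function(a, axis) {
    # move target axis first, pad by reflection, FIR filter columns
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m2 <- matrix(m, nrow = dm[1])
    n <- dm[1]
    idx <- c(pmin(r:1, n), 1:n, pmax(n - (1:r) + 1, 1))
    mp <- m2[idx, , drop = FALSE]
    out <- matrix(0, nrow = n, ncol = ncol(m2))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[(j - 1) + 1:n, , drop = FALSE]
    }
    m <- array(out, dm)
    aperm(m, order(perm))
  }
  for (ax in 1:3) vol <- conv_axis(vol, ax)
  vol
}

# Rotation matrix mapping unit vector u onto unit vector w (Rodrigues).
rotation_onto <- function(u, w) {
  u <- u / sqrt(sum(u^2))
  w <- w / sqrt(sum(w^2))
  v <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  s <- sqrt(sum(v^2))
  cth <- sum(u * w)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- a - sum(a * u) * u
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  vx <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * vx + (1 - cos(th)) * vx %*% vx
}

#' Rotate a binary volume by nearest-neighbour resampling
#'
#' Rigid rotation about the centroid of the foreground voxels, sampled on a
#' grid sized to the rotated bounding box. Nearest-neighbour interpolation
#' keeps the mask binary and voxel counts nearly conserved.
#'
#' @param mask logical 3D array
#' @param R 3x3 rotation matrix (voxel/world axes coincide; isotropic voxels)
#' @param pad margin, voxels, added around the rotated bounding box
#' @return logical 3D array
#' @export
rotate_mask <- function(mask, R, pad = 2L) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  co <- arrayInd(idx, d)  # voxel centres at integer coords
  cen <- colMeans(co)
  rc <- sweep(co, 2, cen) %*% t(R)
  lo <- floor(apply(rc, 2, min)) - pad
  hi <- ceiling(apply(rc, 2, max)) + pad
  nd <- as.integer(hi - lo + 1)
  # inverse map output voxel centres back to input and sample NN
  out <- array(FALSE, nd)
  Rt <- t(R)
  gx <- lo[1]:hi[1]
  gy <- lo[2]:hi[2]
  for (kz in seq_len(nd[3])) {
    pz <- lo[3] + kz - 1
    P <- cbind(rep(gx, times = nd[2]),
               rep(gy, each = nd[1]),
               pz)
    Q <- P %*% t(Rt)
    Q <- sweep(Q, 2, cen, "+")
    ix <- as.integer(round(Q[, 1]))
    iy <- as.integer(round(Q[, 2]))
    iz <- as.integer(round(Q[, 3]))
    ok <- ix >= 1L & ix <= d[1] & iy >= 1L & iy <= d[2] &
      iz >= 1L & iz <= d[3]
    v <- logical(nrow(P))
    v[ok] <- mask[cbind(ix[ok], iy[ok], iz[ok])]
    out[, , kz] <- v
  }
  out
}

# Quasi-uniform directions on the unit sphere (Fibonacci spiral), optionally
# randomly rotated as a set for seeded directional sampling.
fibonacci_directions <- function(n, rotate = NULL) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  d <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  if (!is.null(rotate)) d <- d %*% t(rotate)
  d
}

random_rotation <- function() {
  # uniform random rotation from a random unit quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}
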