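## Small numeric helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Cross product of 3-vectors (rows of matrices or plain vectors)
#' @noRd
cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Normalize rows of a matrix to unit Euclidean norm
#' @noRd
normalize_rows <- function(m, tol = 0) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  n <- sqrt(rowSums(m^2))
  bad <- n <= tol
  n[n == 0] <- 1
  list(u = m / n, norm = sqrt(rowSums(m^2)), degenerate = bad)
}

#' Intrinsic Z-Y-X Euler rotation matrix, angles in degrees
#' @noRd
rotation_zyx <- function(angles_deg) {
  a <- deg2rad(angles_deg)
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

## ---- regular isotropic grids -------------------------------------------

#' Define a regular axis-aligned sampling grid
#'
#' World coordinates follow the NIfTI RAS+ convention with 0-based voxel
#' indices and voxel-center alignment: `world = origin + index * spacing`.
#'
#' @param dim integer vector of length 3, voxel counts.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param origin world coordinates of voxel (0,0,0), mm.
#' @return An object of class `iso_grid`.
#' @export
iso_grid <- function(dim, spacing = 1, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0))
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "iso_grid")
}

#' @export
print.iso_grid <- function(x, ...) {
  cat(sprintf("iso_grid: %s voxels, spacing %s mm, origin (%s)\n",
              paste(x$dim, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel-center world coordinates of every grid point (n x 3, array order)
#' @noRd
grid_points <- function(grid) {
  i <- (seq_len(grid$dim[1]) - 1) * grid$spacing[1] + grid$origin[1]
  j <- (seq_len(grid$dim[2]) - 1) * grid$spacing[2] + grid$origin[2]
  k <- (seq_len(grid$dim[3]) - 1) * grid$spacing[3] + grid$origin[3]
  cbind(rep(i, times = grid$dim[2] * grid$dim[3]),
        rep(rep(j, each = grid$dim[1]), times = grid$dim[3]),
        rep(k, each = grid$dim[1] * grid$dim[2]))
}

#' 4x4 voxel(0-based)->world affine of a grid
#' @noRd
grid_affine <- function(grid) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(grid$spacing, 3)
  a[1:3, 4] <- grid$origin
  a
}

world_to_index0 <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

## ---- trilinear interpolation -------------------------------------------

#' Trilinear gather/scatter stencil for continuous 0-based voxel coordinates
#'
#' Returns, for each query point, the 8 linear (1-based) array indices of the
#' surrounding voxel corners and their trilinear weights.  Corners outside
#' the array get weight 0 (Dirichlet zero boundary), so the stencil defines
#' an exactly transposable linear map.
#' @noRd
trilinear_stencil <- function(dim, pts) {
  n <- nrow(pts)
  f0 <- floor(pts)
  fr <- pts - f0
  idx <- matrix(1L, n, 8L)
  w <- matrix(0, n, 8L)
  for (c in 0:7) {
    o <- c(bitwAnd(c, 1L), bitwAnd(bitwShiftR(c, 1L), 1L),
           bitwAnd(bitwShiftR(c, 2L), 1L))
    ix <- f0[, 1] + o[1]; iy <- f0[, 2] + o[2]; iz <- f0[, 3] + o[3]
    wc <- (if (o[1]) fr[, 1] else 1 - fr[, 1]) *
          (if (o[2]) fr[, 2] else 1 - fr[, 2]) *
          (if (o[3]) fr[, 3] else 1 - fr[, 3])
    ok <- ix >= 0 & ix <= dim[1] - 1 & iy >= 0 & iy <= dim[2] - 1 &
          iz >= 0 & iz <= dim[3] - 1
    wc[!ok] <- 0
    ix[!ok] <- 0; iy[!ok] <- 0; iz[!ok] <- 0
    idx[, c + 1L] <- as.integer(ix + dim[1] * (iy + dim[2] * iz) + 1)
    w[, c + 1L] <- wc
  }
  list(idx = idx, w = w)
}

#' Trilinear interpolation of a 3D array at continuous 0-based voxel coords
#' @noRd
trilinear_gather <- function(arr, pts) {
  st <- trilinear_stencil(dim(arr), pts)
  v <- numeric(nrow(pts))
  for (c in 1:8) v <- v + st$w[, c] * arr[st$idx[, c]]
  v
}

#' Bilinear interpolation in a 2D array (or stack of channels) at continuous
#' 0-based coordinates; returns a matrix n x nchan.  Out-of-field points get NA.
#' @noRd
bilinear_gather <- function(arr, pts) {
  d <- dim(arr)
  nchan <- if (length(d) == 3L) d[3] else 1L
  if (length(d) == 2L) arr <- array(arr, c(d, 1L))
  n <- nrow(pts)
  out <- matrix(NA_real_, n, nchan)
  inside <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1 &
            pts[, 2] >= 0 & pts[, 2] <= d[2] - 1
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  f0 <- floor(p)
  f0[, 1] <- pmin(f0[, 1], d[1] - 2); f0[, 2] <- pmin(f0[, 2], d[2] - 2)
  fr <- p - f0
  i <- f0[, 1] + 1; j <- f0[, 2] + 1
  base <- matrix(0, sum(inside), nchan)
  for (ch in seq_len(nchan)) {
    m <- arr[, , ch]
    base[, ch] <-
      m[cbind(i, j)] * (1 - fr[, 1]) * (1 - fr[, 2]) +
      m[cbind(i + 1, j)] * fr[, 1] * (1 - fr[, 2]) +
      m[cbind(i, j + 1)] * (1 - fr[, 1]) * fr[, 2] +
      m[cbind(i + 1, j + 1)] * fr[, 1] * fr[, 2]
  }
  out[inside, ] <- base
  out
}
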