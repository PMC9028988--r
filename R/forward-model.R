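## Acquisition forward model: rotation/resampling into the stack frame,
## through-plane blur by the slice profile, and down-sampling — realized as
## one precomputed sparse matrix per stack so the adjoint is the exact
## transpose.

#' Geometry of a thick-slice stack
#'
#' @param axes 3x3 rotation matrix whose columns are the world directions
#'   of the stack's in-plane axes (columns 1-2) and slice axis (column 3).
#' @param spacing voxel spacing along the stack axes (mm); the third entry
#'   is the slice-to-slice distance.
#' @param origin world coordinates of stack voxel (0, 0, 0) (center of the
#'   first slice's first in-plane sample).
#' @param dim stack dimensions `(n1, n2, n_slices)`.
#' @param thickness_mm slab thickness integrated by each slice (defaults to
#'   the slice spacing, i.e. contiguous slabs).
#' @param profile through-plane slice profile: `"rect"` or numeric weights.
#' @param poses optional `n_slices x 6` matrix of per-slice rigid poses
#'   `(rz, ry, rx degrees, tx, ty, tz mm)`, rotations about the slice
#'   center; default identity.
#' @return Object of class `stack_geometry`.
#' @export
stack_geometry <- function(axes, spacing, origin, dim, thickness_mm = NULL,
                           profile = "rect", poses = NULL) {
  axes <- as.matrix(axes)
  stopifnot(all(dim(axes) == c(3, 3)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-8)
    stop("stack axes must be orthonormal")
  dim <- as.integer(dim)
  spacing <- rep_len(as.numeric(spacing), 3)
  thickness_mm <- thickness_mm %||% spacing[3]
  if (is.null(poses)) poses <- matrix(0, dim[3], 6)
  stopifnot(nrow(poses) == dim[3], ncol(poses) == 6)
  g <- structure(list(axes = axes, spacing = spacing,
                      origin = as.numeric(origin), dim = dim,
                      thickness_mm = thickness_mm, profile = profile,
                      poses = poses, cache = new.env(parent = emptyenv())),
                 class = "stack_geometry")
  g
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat(sprintf(
    "stack_geometry: %s voxels, spacing %s mm, slab thickness %g mm\n",
    paste(x$dim, collapse = "x"),
    paste(format(x$spacing), collapse = "x"), x$thickness_mm))
  invisible(x)
}

## Geometry of a degraded stack of a GT grid for an axis-aligned
## orientation label.
stack_geometry_for <- function(gt_grid, label, crop_factor, thickness,
                               dims) {
  ax <- orientation_axes(label)
  axes <- diag(3)[, c(ax$inplane, ax$slice)]
  sp_src <- gt_grid$spacing
  spacing <- c(sp_src[ax$inplane] * crop_factor, sp_src[ax$slice] * thickness)
  origin <- gt_grid$origin
  origin[ax$slice] <- origin[ax$slice] + (thickness - 1) / 2 * sp_src[ax$slice]
  stack_geometry(axes, spacing, origin, dims,
                 thickness_mm = thickness * sp_src[ax$slice])
}

## World center of slice k (0-based) — the pivot for per-slice poses.
slice_center <- function(geom, k) {
  geom$origin +
    geom$axes[, 1] * (geom$dim[1] - 1) / 2 * geom$spacing[1] +
    geom$axes[, 2] * (geom$dim[2] - 1) / 2 * geom$spacing[2] +
    geom$axes[, 3] * k * geom$spacing[3]
}

## Apply a per-slice rigid pose (rotation about the slice center, then
## translation) to an n x 3 matrix of world points.
apply_pose <- function(pts, pose, center) {
  if (all(pose == 0)) return(pts)
  R <- rotation_zyx(pose[1:3])
  sweep(sweep(pts, 2, center, "-") %*% t(R), 2, center + pose[4:6], "+")
}

#' Sparse projection matrix of a stack geometry onto an isotropic grid
#'
#' Encodes rotation/resampling (trilinear interpolation at sample points),
#' through-plane blur (profile-weighted sub-slab samples at the iso grid
#' spacing) and down-sampling, including any per-slice rigid poses.  The
#' matrix maps the vectorized iso volume to the vectorized stack; its
#' transpose is the exact adjoint.  Cached per iso-grid signature.
#'
#' @param geom a [stack_geometry()].
#' @param grid the isotropic [iso_grid()].
#' @return A `dgCMatrix` of dimension `prod(geom$dim) x prod(grid$dim)`.
#' @export
projection_matrix <- function(geom, grid) {
  key <- paste(c(grid$dim, signif(grid$spacing, 12), signif(grid$origin, 12),
                 signif(as.vector(geom$poses), 12)), collapse = "_")
  hit <- geom$cache$pm
  if (!is.null(hit) && identical(geom$cache$key, key)) return(hit)
  m <- max(1L, round(geom$thickness_mm / grid$spacing[1]))
  w_prof <- if (identical(geom$profile, "rect")) rep(1 / m, m)
            else {p <- as.numeric(geom$profile); rep(p / sum(p), length.out = m)}
  if (length(w_prof) != m)
    w_prof <- rep(1 / m, m)
  offsets <- ((seq_len(m) - 0.5) / m - 0.5) * geom$thickness_mm
  n_in <- geom$dim[1] * geom$dim[2]
  ij <- cbind(rep(seq_len(geom$dim[1]) - 1, times = geom$dim[2]),
              rep(seq_len(geom$dim[2]) - 1, each = geom$dim[1]))
  base_inplane <- ij[, 1] %o% (geom$axes[, 1] * geom$spacing[1]) +
    ij[, 2] %o% (geom$axes[, 2] * geom$spacing[2])
  trip_i <- vector("list", geom$dim[3] * m)
  trip_j <- trip_i; trip_x <- trip_i
  cnt <- 0L
  for (k in seq_len(geom$dim[3]) - 1L) {
    ck <- slice_center(geom, k)
    pose <- geom$poses[k + 1L, ]
    rows <- seq_len(n_in) + k * n_in
    for (t in seq_len(m)) {
      p <- sweep(base_inplane, 2,
                 geom$origin + geom$axes[, 3] * (k * geom$spacing[3] +
                                                   offsets[t]), "+")
      p <- apply_pose(p, pose, ck)
      st <- trilinear_stencil(grid$dim, world_to_index0(grid, p))
      keep <- st$w != 0
      cnt <- cnt + 1L
      trip_i[[cnt]] <- rep(rows, 8L)[keep]
      trip_j[[cnt]] <- st$idx[keep]
      trip_x[[cnt]] <- st$w[keep] * w_prof[t]
    }
  }
  P <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(prod(geom$dim), prod(grid$dim)))
  geom$cache$pm <- P
  geom$cache$key <- key
  P
}

#' Apply the acquisition forward model
#'
#' @param vol 3D array on `grid` (the isotropic volume).
#' @param geom a [stack_geometry()].
#' @param grid the isotropic [iso_grid()].
#' @return 3D array in stack layout `(n1, n2, n_slices)`.
#' @export
forward_project <- function(vol, geom, grid) {
  P <- projection_matrix(geom, grid)
  array(as.numeric(P %*% as.vector(vol)), geom$dim)
}

#' Apply the exact adjoint of the forward model
#'
#' Satisfies the inner-product identity
#' `sum(forward_project(x) * y) == sum(x * adjoint_project(y))`.
#'
#' @param stack 3D array in stack layout.
#' @param geom a [stack_geometry()].
#' @param grid the isotropic [iso_grid()].
#' @return 3D array on the iso grid.
#' @export
adjoint_project <- function(stack, geom, grid) {
  P <- projection_matrix(geom, grid)
  array(as.numeric(Matrix::crossprod(P, as.vector(stack))), grid$dim)
}

#' Intersection of stack footprints on an isotropic grid
#'
#' Returns the region (Omega) of the iso grid whose voxel centers fall
#' inside every stack's slab footprint (nominal geometry; poses ignored).
#'
#' @param geoms list of [stack_geometry()] (one allowed: own footprint).
#' @param grid the isotropic [iso_grid()].
#' @return Logical 3D array.
#' @export
domain_intersection <- function(geoms, grid) {
  if (inherits(geoms, "stack_geometry")) geoms <- list(geoms)
  stopifnot(length(geoms) >= 1)
  pts <- grid_points(grid)
  inside <- rep(TRUE, nrow(pts))
  for (g in geoms) {
    rel <- sweep(pts, 2, g$origin, "-") %*% g$axes
    i <- rel[, 1] / g$spacing[1]
    j <- rel[, 2] / g$spacing[2]
    k <- rel[, 3] / g$spacing[3]
    half_t <- g$thickness_mm / 2 / g$spacing[3]
    inside <- inside & i >= -0.5 & i <= g$dim[1] - 0.5 &
      j >= -0.5 & j <= g$dim[2] - 0.5 &
      k >= -half_t & k <= g$dim[3] - 1 + half_t
  }
  if (!any(inside)) stop("empty intersection volume Omega")
  array(inside, grid$dim)
}
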