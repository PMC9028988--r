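## Numerical left-ventricle phantom: a semi-ellipsoid myocardial wall whose
## helix angle ramps linearly across the wall, with fixed tensor eigenvalues.

#' Specification of the semi-ellipsoid left-ventricle phantom
#'
#' The myocardial wall is the family of confocal-like ellipsoid shells
#' \deqn{\left(\frac{x-x_c}{R_{min}+d_r}\right)^2 +
#'       \left(\frac{y-y_c}{R_{min}+d_r}\right)^2 +
#'       \left(\frac{z-z_c}{R_{max}+d_r}\right)^2 = 1,}
#' where \eqn{d_r \in [0, \mathrm{wall}]} is the distance to the endocardium
#' (in voxels), truncated to the apex-down half \eqn{z \le z_c}.  The helix
#' angle varies linearly from `ha_endo_deg` at the endocardial border
#' (\eqn{d_r = 0}) to `ha_epi_deg` at the epicardial border, and the
#' transverse angle is constant.
#'
#' @param grid_dim voxel counts (default 160 x 160 x 128).
#' @param voxel_size_mm isotropic voxel size.
#' @param center ellipsoid center `(xc, yc, zc)` in voxel coordinates;
#'   default centers the shell in-plane and places the basal cut near the
#'   top of the grid.
#' @param r_min,r_max endocardial semi-minor (in-plane) and semi-major (z)
#'   radii in voxels.
#' @param wall wall thickness: \eqn{d_r} ranges over `[0, wall]` voxels.
#' @param ha_endo_deg,ha_epi_deg,ta_deg helix angle at endo/epi borders and
#'   the constant transverse angle, degrees.
#' @param eigenvalues diffusion tensor eigenvalues (mm^2/s), descending.
#' @param b_value_s_mm2 diffusion weighting for the synthetic protocol.
#' @param s0 non-diffusion-weighted signal intensity.
#' @return A list of class `lv_phantom_spec`.
#' @export
lv_phantom_spec <- function(grid_dim = c(160, 160, 128), voxel_size_mm = 1,
                            center = NULL, r_min = 16, r_max = 60, wall = 14,
                            ha_endo_deg = 84, ha_epi_deg = -84, ta_deg = 0,
                            eigenvalues = c(2, 1.5, 1) * 1e-3,
                            b_value_s_mm2 = 350, s0 = 1) {
  grid_dim <- as.integer(grid_dim)
  if (is.null(center)) {
    spare <- grid_dim[3] - 1 - (r_max + wall)  # z room above the apex
    center <- c((grid_dim[1] - 1) / 2, (grid_dim[2] - 1) / 2,
                r_max + wall + max(0, spare) / 2)
  }
  spec <- structure(list(grid_dim = grid_dim, voxel_size_mm = voxel_size_mm,
                         center = center, r_min = r_min, r_max = r_max,
                         wall = wall, ha_endo_deg = ha_endo_deg,
                         ha_epi_deg = ha_epi_deg, ta_deg = ta_deg,
                         eigenvalues = eigenvalues,
                         b_value_s_mm2 = b_value_s_mm2, s0 = s0),
                    class = "lv_phantom_spec")
  validate_lv_spec(spec)
  spec
}

validate_lv_spec <- function(spec) {
  with(spec, {
    if (!(r_min < r_max)) stop("r_min must be smaller than r_max")
    if (wall < 0) stop("wall thickness must be non-negative")
    ev <- eigenvalues
    if (!(ev[1] >= ev[2] && ev[2] >= ev[3] && ev[3] > 0))
      stop("eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 > 0")
    if (abs(ha_endo_deg) > 90 || abs(ha_epi_deg) > 90)
      stop("helix angle endpoints must lie in [-90, 90] degrees")
    for (d in 1:2) {
      if (center[d] - (r_min + wall) < 0 ||
          center[d] + (r_min + wall) > grid_dim[d] - 1)
        stop(sprintf("ellipsoid shell exits the grid along dimension %d", d))
    }
    if (center[3] - (r_max + wall) < 0)
      stop("ellipsoid shell exits the grid along dimension 3")
    if (center[3] > grid_dim[3] - 1)
      stop("basal cut plane lies outside the grid along dimension 3")
  })
  invisible(spec)
}

#' Continuous distance-to-endocardium for arbitrary points
#'
#' Solves the shell equation radially for \eqn{d_r} at each point by Newton
#' iteration (the shell value is convex and strictly decreasing in
#' \eqn{d_r}), giving a continuous wall-depth coordinate rather than a
#' stair-cased integer shell index.
#'
#' @param spec an [lv_phantom_spec()].
#' @param pts n x 3 matrix of voxel coordinates.
#' @return Numeric vector of signed continuous \eqn{d_r} values (negative
#'   inside the cavity, `> wall` outside the epicardium).
#' @export
lv_wall_distance <- function(spec, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  dx <- pts[, 1] - spec$center[1]
  dy <- pts[, 2] - spec$center[2]
  dz <- pts[, 3] - spec$center[3]
  rho2 <- dx^2 + dy^2
  z2 <- dz^2
  ## g(u) = rho2/(Rmin+u)^2 + z2/(Rmax+u)^2 - 1, strictly decreasing, convex
  u <- pmax(sqrt(rho2 + z2) - spec$r_min, -spec$r_min + 0.5)
  lo <- -min(spec$r_min, spec$r_max) + 1e-6
  for (it in 1:60) {
    a <- spec$r_min + u
    b <- spec$r_max + u
    g <- rho2 / a^2 + z2 / b^2 - 1
    gp <- -2 * (rho2 / a^3 + z2 / b^3)
    step <- g / gp
    step[!is.finite(step)] <- 0
    u <- pmax(u - step, lo)
    if (max(abs(step), na.rm = TRUE) < 1e-12) break
  }
  u[rho2 + z2 == 0] <- -min(spec$r_min, spec$r_max)
  u
}

#' Build the LV phantom mask and wall-depth field
#'
#' @param spec an [lv_phantom_spec()].
#' @return A list with `mask` (logical 3D array), `dr` (continuous distance
#'   to endocardium, `NA` off the mask), `wall_fraction` (`dr / wall`,
#'   0 = endo border, 1 = epi border) and the sampling `grid`.
#' @export
make_lv_mask <- function(spec) {
  validate_lv_spec(spec)
  grid <- iso_grid(spec$grid_dim, spacing = spec$voxel_size_mm)
  pts <- grid_points(grid) / spec$voxel_size_mm  # voxel coordinates
  dr <- lv_wall_distance(spec, pts)
  inside <- dr >= 0 & dr <= spec$wall & pts[, 3] <= spec$center[3]
  mask <- array(inside, dim = spec$grid_dim)
  drf <- array(NA_real_, dim = spec$grid_dim)
  drf[mask] <- dr[inside]
  wf <- drf / spec$wall
  list(mask = mask, dr = drf, wall_fraction = wf, grid = grid)
}

#' Analytic local cardiac frames of the ellipsoid phantom
#'
#' The radial axis `er` is the outward normal of the ellipsoid shell through
#' each point, the circumferential axis is `ec = normalize(long_axis x er)`
#' and the longitudinal axis completes the right-handed triad
#' `el = er x ec`.  The long axis points from apex to base (+z).
#'
#' @param spec an [lv_phantom_spec()].
#' @param pts n x 3 voxel coordinates.
#' @param dr optional precomputed continuous wall distances at `pts`.
#' @return A list of n x 3 matrices `er`, `ec`, `el` and a logical
#'   `degenerate` flag (apex cap, where the normal is parallel to the long
#'   axis).
#' @export
lv_local_frames <- function(spec, pts, dr = NULL) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  if (is.null(dr)) dr <- lv_wall_distance(spec, pts)
  a <- spec$r_min + dr
  b <- spec$r_max + dr
  grad <- cbind((pts[, 1] - spec$center[1]) / a^2,
                (pts[, 2] - spec$center[2]) / a^2,
                (pts[, 3] - spec$center[3]) / b^2)
  er <- normalize_rows(grad)$u
  ecraw <- cbind(-er[, 2], er[, 1], 0)  # long_axis (+z) x er
  nr <- normalize_rows(ecraw, tol = 1e-8)
  ec <- nr$u
  degenerate <- nr$degenerate
  el <- cross3(er, ec)
  list(er = er, ec = ec, el = el, degenerate = degenerate)
}

#' Helix/transverse angle maps of the generator ramp
#'
#' @param wall_fraction wall-depth fraction in `[0, 1]` (vector or array).
#' @param spec an [lv_phantom_spec()].
#' @return list with `ha_deg` and `ta_deg` of the same shape.
#' @export
assign_angles <- function(wall_fraction, spec) {
  ha <- spec$ha_endo_deg + wall_fraction * (spec$ha_epi_deg - spec$ha_endo_deg)
  ta <- wall_fraction * 0 + spec$ta_deg
  list(ha_deg = ha, ta_deg = ta)
}

#' First-eigenvector field from helix/transverse angles in local frames
#'
#' `e1 = cos(TA) (cos(HA) ec + sin(HA) el) + sin(TA) er`.
#'
#' @param ha_deg,ta_deg angle vectors (degrees).
#' @param frames local frames as returned by [lv_local_frames()].
#' @return n x 3 matrix of unit vectors.
#' @export
angles_to_e1 <- function(ha_deg, ta_deg, frames) {
  ha <- deg2rad(ha_deg); ta <- deg2rad(ta_deg)
  cos(ta) * (cos(ha) * frames$ec + sin(ha) * frames$el) +
    sin(ta) * frames$er
}

#' Assemble diffusion tensors from angles, frames and eigenvalues
#'
#' The primary eigenvector is built from (HA, TA) in the local frame; the
#' tertiary eigenvector is the radial direction made orthogonal to `e1`, and
#' the secondary completes the right-handed triad.  The tensor is
#' \eqn{D = \sum_k \lambda_k e_k e_k^T}.
#'
#' @param ha_deg,ta_deg angle vectors in degrees.
#' @param frames orthonormal local frames ([lv_local_frames()] or
#'   analogous); checked to 1e-6.
#' @param eigenvalues descending eigenvalues (mm^2/s).
#' @return n x 6 matrix of tensor components (xx, yy, zz, xy, xz, yz).
#' @export
build_tensor_field <- function(ha_deg, ta_deg, frames, eigenvalues) {
  ortho <- abs(rowSums(frames$er * frames$ec)) +
    abs(rowSums(frames$er * frames$el)) +
    abs(rowSums(frames$ec * frames$el)) +
    abs(rowSums(frames$er^2) - 1)
  if (any(ortho > 1e-6, na.rm = TRUE))
    stop("local frames are not orthonormal")
  e1 <- angles_to_e1(ha_deg, ta_deg, frames)
  e3raw <- frames$er - rowSums(frames$er * e1) * e1
  nr <- normalize_rows(e3raw, tol = 1e-8)
  if (any(nr$degenerate))
    stop("transverse angle too close to +/-90 degrees: e3 undefined")
  e3 <- nr$u
  e2 <- cross3(e3, e1)
  tensor_from_eigvecs(e1, e2, e3, eigenvalues)
}

#' @noRd
tensor_from_eigvecs <- function(e1, e2, e3, ev) {
  comp <- function(i, j) {
    ev[1] * e1[, i] * e1[, j] + ev[2] * e2[, i] * e2[, j] +
      ev[3] * e3[, i] * e3[, j]
  }
  cbind(xx = comp(1, 1), yy = comp(2, 2), zz = comp(3, 3),
        xy = comp(1, 2), xz = comp(1, 3), yz = comp(2, 3))
}

#' Generate the complete ground-truth LV phantom
#'
#' Convenience wrapper running [make_lv_mask()], [lv_local_frames()],
#' [assign_angles()] and [build_tensor_field()] over the myocardial mask.
#'
#' @param spec an [lv_phantom_spec()].
#' @return Object of class `lv_phantom` with fields `spec`, `grid`, `mask`,
#'   `dr`, `wall_fraction`, per-mask-voxel `frames`, `ha_deg`, `ta_deg`,
#'   `tensors` (n x 6) and `voxels` (n x 3 voxel coordinates of the mask).
#' @export
lv_phantom <- function(spec = lv_phantom_spec()) {
  mk <- make_lv_mask(spec)
  idx <- which(mk$mask)
  vox <- arrayInd(idx, spec$grid_dim) - 1
  dr <- mk$dr[idx]
  frames <- lv_local_frames(spec, vox, dr = dr)
  wf <- dr / spec$wall
  ang <- assign_angles(wf, spec)
  keep <- !frames$degenerate
  tensors <- matrix(NA_real_, length(idx), 6)
  colnames(tensors) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  sub <- lapply(frames[c("er", "ec", "el")], function(m) m[keep, , drop = FALSE])
  tensors[keep, ] <- build_tensor_field(ang$ha_deg[keep], ang$ta_deg[keep],
                                        sub, spec$eigenvalues)
  structure(list(spec = spec, grid = mk$grid, mask = mk$mask, dr = mk$dr,
                 wall_fraction = mk$wall_fraction, voxels = vox,
                 frames = frames, ha_deg = ang$ha_deg, ta_deg = ang$ta_deg,
                 tensors = tensors, degenerate = frames$degenerate),
            class = "lv_phantom")
}

#' @export
print.lv_phantom <- function(x, ...) {
  cat(sprintf(paste0(
    "Semi-ellipsoid LV phantom\n",
    "  grid: %s voxels (%g mm), wall voxels: %d\n",
    "  HA ramp: %+g deg (endo) -> %+g deg (epi), TA = %g deg\n",
    "  eigenvalues: %s mm^2/s\n"),
    paste(x$spec$grid_dim, collapse = "x"), x$spec$voxel_size_mm,
    sum(x$mask), x$spec$ha_endo_deg, x$spec$ha_epi_deg, x$spec$ta_deg,
    paste(format(x$spec$eigenvalues), collapse = ", ")))
  invisible(x)
}

#' Points on an iso-depth shell of the LV phantom
#'
#' Samples points lying exactly on the ellipsoid shell at a given wall depth
#' (e.g. `dr = 0` for the endocardial border), useful for evaluating the
#' generator's angle field on a boundary surface.
#'
#' @param spec an [lv_phantom_spec()].
#' @param dr wall depth of the shell, voxels.
#' @param n number of points.
#' @param seed RNG seed for the spherical sampling.
#' @return n x 3 matrix of voxel coordinates on the shell (apex half).
#' @export
lv_shell_points <- function(spec, dr = 0, n = 500, seed = 1) {
  set.seed(seed)
  a <- spec$r_min + dr
  b <- spec$r_max + dr
  ## sample on lower half (z <= zc), avoiding the apex cap
  phi <- runif(n, 0, 2 * pi)
  cth <- runif(n, -0.95, 0)  # polar cosine; z = b*cth <= 0
  sth <- sqrt(1 - cth^2)
  cbind(spec$center[1] + a * sth * cos(phi),
        spec$center[2] + a * sth * sin(phi),
        spec$center[3] + b * cth)
}
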