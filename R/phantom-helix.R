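## Synthetic helicoidal fiber-bundle phantom: an annular bundle around the
## z axis whose helix angle ramps linearly across the bundle radius,
## immersed in an isotropic water compartment.

#' Specification of the helicoidal fiber phantom
#'
#' Fibers fill the annulus between `inner_radius_mm` and `outer_radius_mm`;
#' the helix angle (elevation of the fiber tangent from the transverse
#' plane) varies linearly with radius between the two endpoint values, so
#' the unweighted radial mean is their midpoint.
#'
#' @param inner_radius_mm,outer_radius_mm bundle radii (defaults 19.08 and
#'   27.12 mm).
#' @param ha_inner_deg,ha_outer_deg helix angle at the inner and outer
#'   radius (defaults 34.57 and 49.57 degrees, midpoint 42.07).
#' @param height_mm bundle extent along z.
#' @param eigenvalues fiber tensor eigenvalues, mm^2/s.
#' @param b_values_s_mm2 b-values of the synthetic protocol.
#' @param s0 non-diffusion-weighted signal.
#' @param water_diffusivity isotropic diffusivity of the surrounding water
#'   compartment (mm^2/s); set `NA` to leave the background empty.
#' @return A list of class `helix_phantom_spec`.
#' @export
helix_phantom_spec <- function(inner_radius_mm = 19.08,
                               outer_radius_mm = 27.12,
                               ha_inner_deg = 34.57, ha_outer_deg = 49.57,
                               height_mm = 20,
                               eigenvalues = c(2, 1.5, 1) * 1e-3,
                               b_values_s_mm2 = c(0, 500), s0 = 1,
                               water_diffusivity = 2e-3) {
  if (!(inner_radius_mm < outer_radius_mm))
    stop("inner_radius_mm must be smaller than outer_radius_mm")
  structure(list(inner_radius_mm = inner_radius_mm,
                 outer_radius_mm = outer_radius_mm,
                 ha_inner_deg = ha_inner_deg, ha_outer_deg = ha_outer_deg,
                 height_mm = height_mm, eigenvalues = eigenvalues,
                 b_values_s_mm2 = b_values_s_mm2, s0 = s0,
                 water_diffusivity = water_diffusivity),
            class = "helix_phantom_spec")
}

#' Generate the helicoidal fiber phantom tensor field
#'
#' For each voxel inside the annulus the primary eigenvector is the unit
#' tangent of a helix around z: `e1 = cos(HA(r)) theta_hat + sin(HA(r)) z_hat`
#' with `HA(r)` linear between the endpoints; the transverse component is
#' zero by construction.  The local frame is cylindrical
#' (`er` radial, `ec` circumferential, `el = z`).
#'
#' @param spec a [helix_phantom_spec()].
#' @param grid sampling [iso_grid()]; default covers the bundle with a 2 mm
#'   margin at `voxel_size_mm` spacing.
#' @param voxel_size_mm voxel size used when `grid` is `NULL`.
#' @return Object of class `helix_phantom`: `spec`, `grid`, `mask` (bundle
#'   annulus), `water` (background compartment mask), per-bundle-voxel
#'   `frames`, `ha_deg`, `radius_mm`, and `tensors` over
#'   `mask | water` voxels (bundle voxels first is *not* assumed; tensors
#'   are indexed by `which(mask | water)` in array order).
#' @export
make_helix_phantom <- function(spec = helix_phantom_spec(), grid = NULL,
                               voxel_size_mm = 1) {
  if (is.null(grid)) {
    half <- spec$outer_radius_mm + 2
    n_in <- ceiling(2 * half / voxel_size_mm) + 1
    nz <- max(1, round(spec$height_mm / voxel_size_mm))
    grid <- iso_grid(c(n_in, n_in, nz), spacing = voxel_size_mm,
                     origin = c(-half, -half, 0))
  }
  annulus_across <- (spec$outer_radius_mm - spec$inner_radius_mm) /
    max(grid$spacing[1:2])
  if (annulus_across < 3)
    stop("voxel size too coarse to resolve the annulus (< 3 voxels across)")
  pts <- grid_points(grid)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  in_bundle <- r >= spec$inner_radius_mm & r <= spec$outer_radius_mm
  mask <- array(in_bundle, grid$dim)
  water <- array(!in_bundle & is.finite(spec$water_diffusivity) &
                   !is.na(spec$water_diffusivity), grid$dim)
  sel <- which(in_bundle)
  rs <- r[sel]
  frac <- (rs - spec$inner_radius_mm) /
    (spec$outer_radius_mm - spec$inner_radius_mm)
  ha <- spec$ha_inner_deg + frac * (spec$ha_outer_deg - spec$ha_inner_deg)
  er <- cbind(pts[sel, 1] / rs, pts[sel, 2] / rs, 0)
  ec <- cbind(-er[, 2], er[, 1], 0)
  el <- matrix(rep(c(0, 0, 1), each = length(sel)), ncol = 3)
  frames <- list(er = er, ec = ec, el = el,
                 degenerate = rep(FALSE, length(sel)))
  both <- mask | water
  tensors <- matrix(NA_real_, sum(both), 6)
  colnames(tensors) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  bsel <- which(both)
  isb <- bsel %in% sel
  tensors[isb, ] <- build_tensor_field(ha, rep(0, length(ha)), frames,
                                       spec$eigenvalues)
  if (any(!isb)) {
    dw <- spec$water_diffusivity
    tensors[!isb, ] <- matrix(rep(c(dw, dw, dw, 0, 0, 0),
                                  each = sum(!isb)), ncol = 6)
  }
  structure(list(spec = spec, grid = grid, mask = mask, water = water,
                 frames = frames, ha_deg = ha, radius_mm = rs,
                 tensors = tensors),
            class = "helix_phantom")
}

#' @export
print.helix_phantom <- function(x, ...) {
  cat(sprintf(paste0(
    "Helicoidal fiber phantom\n",
    "  grid: %s voxels (%g mm); bundle voxels: %d\n",
    "  annulus: %.2f..%.2f mm, HA %.2f..%.2f deg (midpoint %.2f)\n"),
    paste(x$grid$dim, collapse = "x"), x$grid$spacing[1], sum(x$mask),
    x$spec$inner_radius_mm, x$spec$outer_radius_mm,
    x$spec$ha_inner_deg, x$spec$ha_outer_deg,
    (x$spec$ha_inner_deg + x$spec$ha_outer_deg) / 2))
  invisible(x)
}
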