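# Shared small fixtures, built in code at test time.

# Down-scaled LV phantom spec: same wall physics, smaller grid.
small_lv_spec <- function(grid_dim = c(48, 48, 40), r_min = 8, r_max = 20,
                          wall = 7, ...) {
  lv_phantom_spec(grid_dim = grid_dim, r_min = r_min, r_max = r_max,
                  wall = wall, ...)
}

# Phantom + noiseless GT DWI, cached per session (cheap but reused a lot).
small_gt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- small_lv_spec()
      ph <- lv_phantom(spec)
      proto <- dual_gradient_scheme(350)
      gt <- synthesize_dwi(ph$tensors, proto, ph$mask, ph$grid)
      cache <<- list(spec = spec, phantom = ph, proto = proto, gt = gt)
    }
    cache
  }
})

# mask frames as a plain list usable by build_tensor_field and angles
frames_subset <- function(frames, keep) {
  out <- lapply(frames[c("er", "ec", "el")], function(m) m[keep, , drop = FALSE])
  out$degenerate <- frames$degenerate[keep]
  out
}

# random rotation matrix (angles within +/- max_deg)
random_rotation <- function(max_deg = 90) {
  rotation_zyx_test(stats::runif(3, -max_deg, max_deg))
}

rotation_zyx_test <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}
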