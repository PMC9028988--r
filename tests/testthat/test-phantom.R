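test_that("wall-distance field solves the shell equation and bounds the mask", {
  spec <- small_lv_spec()
  mk <- make_lv_mask(spec)
  idx <- which(mk$mask)
  vox <- arrayInd(idx, spec$grid_dim) - 1
  dr <- mk$dr[idx]
  # every mask voxel satisfies its own shell equation to round-off
  lhs <- ((vox[, 1] - spec$center[1]) / (spec$r_min + dr))^2 +
    ((vox[, 2] - spec$center[2]) / (spec$r_min + dr))^2 +
    ((vox[, 3] - spec$center[3]) / (spec$r_max + dr))^2
  expect_lt(max(abs(lhs - 1)), 1e-8)
  expect_true(all(dr >= 0 & dr <= spec$wall))
  expect_true(all(vox[, 3] <= spec$center[3]))
  # a point on the endocardial surface has dr = 0; one outside all shells
  # is excluded
  p_endo <- spec$center + c(spec$r_min, 0, 0)
  expect_equal(lv_wall_distance(spec, p_endo), 0, tolerance = 1e-10)
  p_out <- spec$center + c(spec$r_min + spec$wall + 3, 0, 0)
  expect_gt(lv_wall_distance(spec, p_out), spec$wall)
  # equatorial wall thickness matches the dr range
  eq_row <- mk$mask[, spec$center[2] + 1, round(spec$center[3]) + 1]
  expect_equal(sum(eq_row) / 2, spec$wall + 1, tolerance = 1)
})

test_that("shell exiting the grid is reported with the offending dimension", {
  expect_error(lv_phantom_spec(grid_dim = c(30, 160, 128)), "dimension 1")
  expect_error(lv_phantom_spec(grid_dim = c(160, 160, 40),
                               center = c(80, 80, 39)), "dimension 3")
})

test_that("helix-angle ramp hits the stated endpoint and midpoint values", {
  spec <- small_lv_spec()
  ang <- assign_angles(c(0, 1, 0.5), spec)
  expect_equal(ang$ha_deg, c(84, -84, 0))
  expect_equal(ang$ta_deg, c(0, 0, 0))
})

test_that("tensor field round-trips eigenvalues and angles exactly", {
  spec <- small_lv_spec()
  ph <- lv_phantom(spec)
  keep <- which(!ph$degenerate)[seq(1, sum(!ph$degenerate), by = 37)]
  fr <- frames_subset(ph$frames, keep)
  eig <- dti_eigen(ph$tensors[keep, , drop = FALSE])
  expect_lt(max(abs(sweep(eig$values, 2, spec$eigenvalues, "-"))) /
              max(spec$eigenvalues), 1e-12)
  ang <- helix_transverse_angles(eig$e1, fr)
  expect_lt(max(abs(ang$ha_deg - ph$ha_deg[keep])), 1e-6)
  expect_lt(max(abs(ang$ta_deg - ph$ta_deg[keep])), 1e-6)
})

test_that("isotropic eigenvalues give a spherical tensor for any angles", {
  spec <- small_lv_spec(eigenvalues = rep(1.3e-3, 3))
  ph <- lv_phantom(spec)
  i <- which(!ph$degenerate)[1:20]
  expect_equal(unname(ph$tensors[i, "xx"]), rep(1.3e-3, 20), tolerance = 1e-12)
  expect_equal(unname(ph$tensors[i, "xy"]), rep(0, 20), tolerance = 1e-15)
  # trace/3 equals the mean eigenvalue in the anisotropic default too
  ph2 <- lv_phantom(small_lv_spec())
  md <- dti_md(ph2$tensors[!ph2$degenerate, , drop = FALSE])
  expect_equal(mean(md), 1.5e-3, tolerance = 1e-12)
})

test_that("non-orthonormal frames are rejected", {
  fr <- list(er = matrix(c(1, 0, 0), 1), ec = matrix(c(0.5, 0.5, 0), 1),
             el = matrix(c(0, 0, 1), 1), degenerate = FALSE)
  expect_error(build_tensor_field(10, 0, fr, c(2, 1.5, 1) * 1e-3),
               "orthonormal")
})

test_that("synthetic DWI follows the mono-exponential tensor model", {
  sp <- small_gt()
  # b = 0 channel equals s0 exactly on the mask
  b0 <- sp$gt$data[, , , 1]
  expect_equal(b0[sp$phantom$mask], rep(sp$spec$s0, sum(sp$phantom$mask)))
  for (v in 2:7)
    expect_true(all(sp$gt$data[, , , v] <= b0 + 1e-12))
  # direct scalar check: gradient along z sees lambda3 at the equator where
  # e3 is radial... instead verify against the quadratic form explicitly
  idx <- which(sp$phantom$mask)[seq(1, sum(sp$phantom$mask), by = 101)]
  vox <- which(sp$phantom$mask)
  pos <- match(idx, vox)
  g <- sp$gt$bvecs[5, ]
  D <- sp$phantom$tensors[pos, ]
  quad <- D[, "xx"] * g[1]^2 + D[, "yy"] * g[2]^2 + D[, "zz"] * g[3]^2 +
    2 * D[, "xy"] * g[1] * g[2] + 2 * D[, "xz"] * g[1] * g[3] +
    2 * D[, "yz"] * g[2] * g[3]
  nvox <- prod(sp$gt$grid$dim)
  expect_equal(sp$gt$data[idx + 4 * nvox], exp(-350 * quad), tolerance = 1e-12)
})

test_that("a gradient aligned with an eigenvector attenuates by exp(-b*lambda)", {
  # single-voxel tensor with e3 = z, lambda3 = 1e-3, b = 350
  fr <- list(er = matrix(c(0, 0, 1), 1), ec = matrix(c(1, 0, 0), 1),
             el = matrix(c(0, 1, 0), 1), degenerate = FALSE)
  tn <- build_tensor_field(0, 0, fr, c(2, 1.5, 1) * 1e-3)
  proto <- diffusion_protocol(c(0, 350), rbind(c(0, 0, 0), c(0, 0, 1)))
  mask <- array(TRUE, c(1, 1, 1))
  ser <- synthesize_dwi(tn, proto, mask, iso_grid(c(1, 1, 1)), s0 = 2)
  expect_equal(ser$data[1, 1, 1, 2] / ser$data[1, 1, 1, 1], exp(-0.35),
               tolerance = 1e-12)
})

test_that("non-unit gradient directions are normalized with a warning", {
  expect_warning(p <- diffusion_protocol(c(0, 500), rbind(c(0, 0, 0), c(0, 0, 2))),
                 "normalized")
  expect_equal(p$bvecs[2, ], c(0, 0, 1))
})

test_that("helix phantom HA ramps linearly over radius with zero transverse angle", {
  hx <- make_helix_phantom()
  # mid-annulus voxels carry the midpoint angle
  spec <- hx$spec
  rmid <- (spec$inner_radius_mm + spec$outer_radius_mm) / 2
  near_mid <- abs(hx$radius_mm - rmid) < 0.05
  expect_true(any(near_mid))
  expect_equal(mean(hx$ha_deg[near_mid]), 42.07, tolerance = 0.02)
  # recomputed angles from the tensors match the ramp; TA = 0
  both <- hx$mask | hx$water
  in_bundle <- which(both) %in% which(hx$mask)
  eig <- dti_eigen(hx$tensors[in_bundle, , drop = FALSE])
  ang <- helix_transverse_angles(eig$e1, hx$frames)
  expect_lt(max(abs(ang$ha_deg - hx$ha_deg)), 1e-6)
  expect_lt(max(abs(ang$ta_deg)), 1e-6)
  # rotational symmetry: HA depends on radius only
  expect_lt(max(abs(ang$ha_deg - (spec$ha_inner_deg +
    (hx$radius_mm - spec$inner_radius_mm) /
      (spec$outer_radius_mm - spec$inner_radius_mm) *
      (spec$ha_outer_deg - spec$ha_inner_deg)))), 1e-6)
})

test_that("helix phantom rejects grids too coarse to resolve the annulus", {
  expect_error(make_helix_phantom(grid = iso_grid(c(20, 20, 4), spacing = 4,
                                                  origin = c(-38, -38, 0))),
               "coarse")
})

test_that("HA=45 fiber has equal circumferential and longitudinal components", {
  hx <- make_helix_phantom()
  i <- which.min(abs(hx$ha_deg - 45))
  expect_lt(abs(hx$ha_deg[i] - 45), 0.2)
  e1 <- angles_to_e1(hx$ha_deg[i], 0, frames_subset(hx$frames, i))
  expect_equal(abs(sum(e1 * hx$frames$ec[i, ])),
               abs(sum(e1 * hx$frames$el[i, ])), tolerance = 0.01)
})
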