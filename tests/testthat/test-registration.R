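# Small noiseless phantom stacks with optional planted per-slice poses.
# Stacks are resampled from the GT volume through the acquisition operator,
# so a planted pose is exactly recoverable in the model.
reg_fixture <- local({
  cache <- list()
  function(key = "plain", planter = NULL) {
    if (!is.null(cache[[key]])) return(cache[[key]])
    sp <- small_gt()
    stacks <- simulate_lr_stacks(sp$gt, degradation_spec(snr = NA))
    planted <- lapply(stacks, function(s) matrix(0, s$geom$dim[3], 6))
    if (!is.null(planter)) planted <- planter(stacks)
    for (s in seq_along(stacks)) {
      g <- stacks[[s]]$geom
      gp <- stack_geometry(g$axes, g$spacing, g$origin, g$dim,
                           g$thickness_mm, g$profile, poses = planted[[s]])
      for (v in seq_along(sp$gt$bvals))
        stacks[[s]]$data[, , , v] <-
          forward_project(sp$gt$data[, , , v], gp, sp$gt$grid)
      stacks[[s]]$geom <- stack_geometry(g$axes, g$spacing, g$origin,
                                         g$dim, g$thickness_mm, g$profile)
    }
    vox <- which(sp$phantom$mask, arr.ind = TRUE) - 1
    obox <- rbind(apply(vox, 2, min) - 2, apply(vox, 2, max) + 2)
    res <- list(stacks = stacks, planted = planted, obox = obox, sp = sp)
    cache[[key]] <<- res
    res
  }
})

test_that("intersection lines lie on both planes and respect clipping", {
  set.seed(71)
  mkplane <- function(center, rot) {
    R <- rotation_zyx_test(rot)
    list(center = center, u = R[, 1], v = R[, 2], normal = R[, 3],
         spacing = c(2, 2), half = c(20, 20))
  }
  for (rep in 1:20) {
    pa <- mkplane(runif(3, -5, 5), runif(3, -60, 60))
    pb <- mkplane(runif(3, -5, 5), runif(3, -60, 60))
    ln <- intersection_line(pa, pb, spacing_mm = 1)
    if (is.null(ln)) next
    for (pl in list(pa, pb)) {
      off <- abs(sweep(ln$points, 2, pl$center, "-") %*% pl$normal)
      expect_lt(max(off), 1e-9)
      a <- sweep(ln$points, 2, pl$center, "-") %*% pl$u
      expect_true(all(abs(a) <= pl$half[1] + 1e-9))
    }
  }
  # orthogonal canonical planes intersect along the expected axis
  pz <- mkplane(c(0, 0, 0), c(0, 0, 0))          # z = 0
  px <- mkplane(c(0, 0, 0), c(0, 90, 0))         # normal along x
  ln <- intersection_line(pz, px, spacing_mm = 1)
  expect_lt(max(abs(ln$points[, c(1, 3)])), 1e-9)
  # parallel distinct planes have no intersection
  pz2 <- mkplane(c(0, 0, 5), c(0, 0, 0))
  expect_null(intersection_line(pz, pz2))
})

test_that("profile similarity is maximal and near-perfect at alignment", {
  fx <- reg_fixture()
  fl <- list(data = fx$stacks[[1]]$data, geom = fx$stacks[[1]]$geom, k = 2)
  tg <- fx$stacks[2:3]
  s_id <- profile_similarity(rep(0, 6), fl, tg, fx$obox)
  # matched-blur profiles make aligned noiseless slices correlate near 1
  # (the in-plane truncation vs through-plane slab responses differ at
  # sharp edges, so exactly 1 is not attainable)
  at0 <- srcdti:::profile_similarity_impl(
    rep(0, 6), fl, srcdti:::target_planes(tg), fx$obox, 1)
  expect_gt(at0$S / at0$n, 0.95)
  # any perturbation reduces the similarity
  for (mu in list(c(0, 0, 0, 3, 0, 0), c(0, 0, 0, 0, -4, 2))) {
    expect_lt(profile_similarity(mu, fl, tg, fx$obox), s_id)
  }
})

test_that("anti-correlated and constant profiles are handled", {
  # negated copy correlates at -1; constant channels are skipped
  Pf <- matrix(sin(1:40 / 3), 40, 1)
  expect_equal(srcdti:::profile_correlation(Pf, -Pf), -1)
  expect_true(is.na(srcdti:::profile_correlation(Pf * 0, Pf)))
  expect_equal(srcdti:::profile_correlation(cbind(Pf, 0 * Pf),
                                            cbind(Pf, 0 * Pf)), 1)
})

test_that("a planted in-bounds translation is recovered within tolerance", {
  mu_true <- c(0, 0, 0, 3, -2, 1)
  fx <- reg_fixture("one_slice", function(stacks) {
    planted <- lapply(stacks, function(s) matrix(0, s$geom$dim[3], 6))
    planted[[1]][3, ] <- mu_true
    planted
  })
  fl <- list(data = fx$stacks[[1]]$data, geom = fx$stacks[[1]]$geom, k = 2)
  res <- register_slice(fl, fx$stacks[2:3], fx$obox)
  expect_lt(max(abs(res$pose[4:6] - mu_true[4:6])), 0.5)
  expect_lt(max(abs(res$pose[1:3])), 0.5)
  expect_gt(res$similarity, res$start_similarity)
})

test_that("unperturbed consistent stacks stay at the identity", {
  fx <- reg_fixture()
  for (k in c(1, 3)) {
    fl <- list(data = fx$stacks[[2]]$data, geom = fx$stacks[[2]]$geom, k = k)
    res <- register_slice(fl, fx$stacks[c(1, 3)], fx$obox)
    expect_lt(max(abs(res$pose[1:3])), 0.25)
    expect_lt(max(abs(res$pose[4:6])), 0.25)
  }
})

test_that("sweep registration recovers planted translation-dominant motion", {
  set.seed(73)
  sp0 <- small_gt()
  vox0 <- which(sp0$phantom$mask, arr.ind = TRUE) - 1
  supp <- rbind(apply(vox0, 2, min), apply(vox0, 2, max))
  # breath-hold-style motion: translation-dominant, planted only on slices
  # whose slab overlaps the object (empty slices carry no information)
  fx <- reg_fixture("multi", function(stacks) {
    lapply(stacks, function(s) {
      g <- s$geom
      ns <- g$dim[3]
      ax <- which(g$axes[, 3] != 0)
      centers <- vapply(0:(ns - 1), function(k)
        sum(srcdti:::slice_center(g, k) * g$axes[, 3]), 0)
      elig <- which(centers > supp[1, ax] + 1 & centers < supp[2, ax] - 1)
      P <- matrix(0, ns, 6)
      for (k in sample(elig, min(length(elig), max(1, round(0.3 * ns)))))
        P[k, ] <- c(runif(3, -1, 1), runif(3, -4, 4))
      P
    })
  })
  reg <- register_stacks(fx$stacks, omega_box = fx$obox, n_outer = 3)
  # sweeps raise the total similarity of the perturbed configuration and
  # the poses stabilize after the early sweeps
  expect_gte(reg$similarity[2], reg$similarity[1] - 1e-6)
  expect_lte(reg$sweep_change[3], reg$sweep_change[1])
  # all recovered transforms respect the search bounds
  p <- do.call(rbind, reg$poses)
  expect_true(all(abs(p[, 1:3]) <= 5 + 1e-9))
  expect_true(all(abs(p[, 4:6]) <= 8 + 1e-9))
  # most planted translations shrink: the corrected poses are closer to
  # the planted truth than the uncorrected (identity) start
  err0 <- c(); err1 <- c()
  for (s in 1:3) {
    pert <- rowSums(abs(fx$planted[[s]])) > 0
    E <- reg$poses[[s]] - fx$planted[[s]]
    err0 <- c(err0, apply(abs(fx$planted[[s]][pert, 4:6, drop = FALSE]),
                          1, max))
    err1 <- c(err1, apply(abs(E[pert, 4:6, drop = FALSE]), 1, max))
  }
  expect_lt(stats::median(err1), stats::median(err0))
})

test_that("perturbations beyond the bounds clip to the best in-bounds pose", {
  mu_big <- c(0, 0, 0, 0, 12, 0)    # 12 mm exceeds the 8 mm search bound
  fx <- reg_fixture("oob", function(stacks) {
    planted <- lapply(stacks, function(s) matrix(0, s$geom$dim[3], 6))
    planted[[1]][3, ] <- mu_big
    planted
  })
  fl <- list(data = fx$stacks[[1]]$data, geom = fx$stacks[[1]]$geom, k = 2)
  res <- register_slice(fl, fx$stacks[2:3], fx$obox)
  expect_true(all(abs(res$pose[4:6]) <= 8 + 1e-9))
  # residual misalignment remains visible in the similarity
  n_terms <- sum(vapply(fx$stacks[2:3], function(t) t$geom$dim[3], 1))
  expect_lt(res$similarity / n_terms, 0.999)
})

test_that("registration depends only on relative alignment", {
  # a common translation applied to every slice of every stack leaves the
  # stacks mutually consistent: recovered poses stay near the identity
  common <- c(0, 0, 0, 1.5, -1, 0.8)
  fx <- reg_fixture("common", function(stacks) {
    lapply(stacks, function(s)
      matrix(common, s$geom$dim[3], 6, byrow = TRUE))
  })
  for (sk in 1:2) {
    fl <- list(data = fx$stacks[[sk]]$data, geom = fx$stacks[[sk]]$geom,
               k = 2)
    res <- register_slice(fl, fx$stacks[-sk], fx$obox)
    expect_lt(max(abs(res$pose[4:6])), 0.6)
  }
})
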