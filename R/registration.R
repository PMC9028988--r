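## Slice-to-stack rigid motion correction: each slice is realigned by
## maximizing the sum of correlation coefficients between intensity
## profiles sampled along its intersection lines with the slices of the
## other stacks.

## Plane of slice k (0-based) of a stack under a rigid pose: center, the
## in-plane axes u, v, the normal, in-plane spacing and extent.
slice_plane <- function(geom, k, pose = geom$poses[k + 1, ]) {
  ck <- slice_center(geom, k)
  R <- if (all(pose == 0)) diag(3) else rotation_zyx(pose[1:3])
  list(center = ck + pose[4:6],
       u = as.numeric(R %*% geom$axes[, 1]),
       v = as.numeric(R %*% geom$axes[, 2]),
       normal = as.numeric(R %*% geom$axes[, 3]),
       spacing = geom$spacing[1:2],
       half = c((geom$dim[1] - 1) / 2 * geom$spacing[1],
                (geom$dim[2] - 1) / 2 * geom$spacing[2]))
}

#' Intersection segment of two slice planes
#'
#' Returns the segment of the two planes' intersection line clipped to both
#' slices' in-plane fields of view and to the bounding box of the shared
#' reconstruction region, or `NULL` when the planes are (near) parallel or
#' the clip is empty.
#'
#' @param plane_a,plane_b plane descriptions (internal `slice_plane`
#'   format: fields `center`, `u`, `v`, `normal`, `half`).
#' @param omega_box optional 2 x 3 matrix of world bounds (rows min/max).
#' @param spacing_mm sample spacing along the line.
#' @return list with `points` (n x 3 world samples), `dir`, `origin`;
#'   or `NULL`.
#' @export
intersection_line <- function(plane_a, plane_b, omega_box = NULL,
                              spacing_mm = 1) {
  d <- cross3(plane_a$normal, plane_b$normal)[1, ]
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) return(NULL)
  d <- d / nd
  A <- rbind(plane_a$normal, plane_b$normal, d)
  b <- c(sum(plane_a$normal * plane_a$center),
         sum(plane_b$normal * plane_b$center),
         sum(d * (plane_a$center + plane_b$center) / 2))
  p0 <- as.numeric(solve(A, b))
  ## clip parameter s of p0 + s d to each plane's rectangular FOV
  clip1d <- function(c0, cd, half) {
    if (abs(cd) < 1e-12) {
      if (abs(c0) > half) return(NULL)
      return(c(-Inf, Inf))
    }
    sort(c((-half - c0) / cd, (half - c0) / cd))
  }
  lo <- -Inf; hi <- Inf
  for (pl in list(plane_a, plane_b)) {
    rel0 <- p0 - pl$center
    for (axis in 1:2) {
      ax <- if (axis == 1) pl$u else pl$v
      iv <- clip1d(sum(rel0 * ax), sum(d * ax), pl$half[axis])
      if (is.null(iv)) return(NULL)
      lo <- max(lo, iv[1]); hi <- min(hi, iv[2])
    }
  }
  if (!is.null(omega_box)) {
    for (axis in 1:3) {
      c0 <- p0[axis]; cd <- d[axis]
      if (abs(cd) < 1e-12) {
        if (c0 < omega_box[1, axis] || c0 > omega_box[2, axis]) return(NULL)
      } else {
        iv <- sort(c((omega_box[1, axis] - c0) / cd,
                     (omega_box[2, axis] - c0) / cd))
        lo <- max(lo, iv[1]); hi <- min(hi, iv[2])
      }
    }
  }
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(NULL)
  s <- seq(lo, hi, by = spacing_mm)
  if (length(s) < 2) return(NULL)
  list(points = sweep(s %o% d, 2, p0, "+"), dir = d, origin = p0)
}

## Sample the multi-channel image of one slice at world points lying on its
## plane; returns n x nchan (NA outside the field of view).  When
## `blur_dir`/`blur_mm` are given, each sample is the rectangular average
## over `blur_mm` along the (in-plane projection of the) direction — used
## to imprint the partner slice's slab footprint on the profile so that two
## perfectly aligned thick slices yield identical profiles.
sample_slice_profile <- function(stack_data, geom, k, plane, pts,
                                 blur_dir = NULL, blur_mm = 0) {
  img <- stack_data[, , k + 1, , drop = TRUE]
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  gather <- function(p) {
    rel <- sweep(p, 2, plane$center, "-")
    a <- (rel %*% plane$u + plane$half[1]) / plane$spacing[1]
    b <- (rel %*% plane$v + plane$half[2]) / plane$spacing[2]
    bilinear_gather(img, cbind(a, b))
  }
  if (is.null(blur_dir) || blur_mm <= 0) return(gather(pts))
  ## in-plane projection of the partner's slice normal
  d <- blur_dir - sum(blur_dir * plane$normal) * plane$normal
  nd <- sqrt(sum(d^2))
  if (nd < 0.5) return(gather(pts))   # nearly parallel planes: no support
  d <- d / nd
  step <- min(plane$spacing)
  m <- max(1L, round(blur_mm / step))
  offs <- ((seq_len(m) - 0.5) / m - 0.5) * blur_mm
  n <- nrow(pts)
  big <- pts[rep(seq_len(n), m), , drop = FALSE] +
    (rep(offs, each = n) %o% d)
  vals <- gather(big)
  out <- 0
  for (j in seq_len(m)) out <- out + vals[(j - 1) * n + seq_len(n), , drop = FALSE]
  out / m
}

## Pearson correlation of concatenated per-channel standardized profiles.
profile_correlation <- function(Pf, Pt) {
  ok <- stats::complete.cases(Pf) & stats::complete.cases(Pt)
  if (sum(ok) < 8) return(NA_real_)
  xs <- NULL; ys <- NULL
  for (ch in seq_len(ncol(Pf))) {
    x <- Pf[ok, ch]; y <- Pt[ok, ch]
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) next
    xs <- c(xs, (x - mean(x)) / sx)
    ys <- c(ys, (y - mean(y)) / sy)
  }
  if (length(xs) < 8) return(NA_real_)
  sum(xs * ys) / sqrt(sum(xs^2) * sum(ys^2))
}

#' Intersection-profile similarity of a floating slice
#'
#' The sum over all target slices of the correlation coefficient between
#' intensity profiles sampled (linear interpolation) along the
#' intersection line of the floating slice — under the candidate rigid
#' pose `mu` — and each target slice under its current pose.  Profiles
#' from all diffusion channels are standardized per channel and
#' concatenated; degenerate pairs (parallel planes, short or constant
#' profiles) are skipped.
#'
#' @param mu rigid pose 6-vector `(rz, ry, rx deg, tx, ty, tz mm)`.
#' @param floating list with `data` (4D stack array), `geom`, `k`
#'   (0-based slice index).
#' @param targets list of `slice_stack`-like objects (fields `data`,
#'   `geom`) whose slices act as targets.
#' @param omega_box optional 2 x 3 world bounding box of the shared region.
#' @param spacing_mm profile sample spacing.
#' @return Scalar similarity (sum of correlations); `-Inf` when every
#'   intersection is degenerate.
#' @export
profile_similarity <- function(mu, floating, targets, omega_box = NULL,
                               spacing_mm = 1) {
  profile_similarity_impl(mu, floating, target_planes(targets), omega_box,
                          spacing_mm)$S
}

## target slices with their planes resolved once (poses are fixed while one
## floating slice is being optimized)
target_planes <- function(targets) {
  out <- list()
  for (tg in targets) {
    for (i in seq_len(tg$geom$dim[3]) - 1L) {
      out[[length(out) + 1L]] <-
        list(data = tg$data, geom = tg$geom, k = i,
             plane = slice_plane(tg$geom, i))
    }
  }
  out
}

profile_similarity_impl <- function(mu, floating, tplanes, omega_box,
                                    spacing_mm) {
  plf <- slice_plane(floating$geom, floating$k, mu)
  rs <- rep(NA_real_, length(tplanes))
  for (ti in seq_along(tplanes)) {
    tg <- tplanes[[ti]]
    ln <- intersection_line(plf, tg$plane, omega_box, spacing_mm)
    if (is.null(ln)) next
    Pf <- sample_slice_profile(floating$data, floating$geom, floating$k,
                               plf, ln$points,
                               blur_dir = tg$plane$normal,
                               blur_mm = tg$geom$thickness_mm)
    Pt <- sample_slice_profile(tg$data, tg$geom, tg$k, tg$plane, ln$points,
                               blur_dir = plf$normal,
                               blur_mm = floating$geom$thickness_mm)
    rs[ti] <- profile_correlation(Pf, Pt)
  }
  nterms <- sum(!is.na(rs))
  if (nterms == 0L) return(list(S = -Inf, n = 0L, r = rs))
  list(S = sum(rs, na.rm = TRUE), n = nterms, r = rs)
}

#' Rigidly register one slice to the slices of the other stacks
#'
#' Bounded quasi-Newton search (from the current pose, with a multi-start
#' fallback when the improvement is negligible) for the pose maximizing
#' [profile_similarity()], constrained to rotations below `rot_bound_deg`
#' and translations below `trans_bound_mm`.
#'
#' @inheritParams profile_similarity
#' @param start starting pose (default: the floating slice's current pose).
#' @param rot_bound_deg,trans_bound_mm search bounds (5 degrees / 8 mm).
#' @param multi_start try additional translation starts when the best
#'   improvement over the start is below `1e-3`.
#' @return list with `pose` (6-vector), `similarity`, `start_similarity`,
#'   `converged`.
#' @export
register_slice <- function(floating, targets, omega_box = NULL,
                           start = NULL, rot_bound_deg = 5,
                           trans_bound_mm = 8, spacing_mm = 1,
                           multi_start = TRUE, multi_start_r = 0.95) {
  start <- start %||% floating$geom$poses[floating$k + 1, ]
  lower <- c(rep(-rot_bound_deg, 3), rep(-trans_bound_mm, 3))
  upper <- -lower
  start <- pmin(pmax(start, lower), upper)
  tpl_all <- target_planes(targets)
  at0 <- profile_similarity_impl(start, floating, tpl_all, omega_box,
                                 spacing_mm)
  s0 <- at0$S
  if (!is.finite(s0)) {
    warning("slice has no usable intersections; keeping its current pose")
    return(list(pose = start, similarity = -Inf, start_similarity = -Inf,
                converged = FALSE))
  }
  ## Freeze the term set at the current pose: a pose update must be
  ## justified by better alignment of the profiles the slice already
  ## matches, not by sliding into new intersections (the raw sum otherwise
  ## rewards configurations simply because more pairs become valid).
  tpl <- tpl_all[!is.na(at0$r)]
  f <- function(p) {
    s <- profile_similarity_impl(p, floating, tpl, omega_box, spacing_mm)$S
    if (!is.finite(s)) return(1e6)
    -s
  }
  ## Bounded coordinate descent: Brent line searches per parameter over a
  ## shrinking local bracket, translations first (the best-conditioned
  ## directions), accepting a move only when it improves the similarity by
  ## more than `accept_tol`.  The threshold keeps the pose put along
  ## directions where the objective is flat (thick slabs of smooth anatomy
  ## leave small rotations nearly unobservable).
  ## Per-coordinate evidence thresholds: a move is accepted only when it
  ## improves the similarity by more than the interpolation ripple.  Thick
  ## slabs of smooth anatomy make small rotations nearly unobservable
  ## (their whole contribution to S is of ripple size), so the rotation
  ## threshold is deliberately coarser: without clear evidence the slice
  ## keeps its prior (current) orientation.
  accept_tol <- c(rep(5e-2, 3), rep(1e-3, 3))
  run <- function(p0) {
    p <- p0
    fp <- f(p)
    h <- c(rep(2.5, 3), rep(4, 3))       # initial half-brackets (deg, mm)
    for (round in 1:5) {
      ## translations are the best-conditioned directions: settle them
      ## before letting the (much flatter) rotations move at all
      ord <- if (round <= 2) c(4L, 5L, 6L) else c(4L, 5L, 6L, 1L, 2L, 3L)
      for (cidx in ord) {
        lo <- max(lower[cidx], p[cidx] - h[cidx])
        hi <- min(upper[cidx], p[cidx] + h[cidx])
        if (hi - lo < 1e-6) next
        opt <- stats::optimize(function(v) {
          q <- p; q[cidx] <- v; f(q)
        }, lower = lo, upper = hi, tol = 0.02)
        if (opt$objective < fp - accept_tol[cidx]) {
          p[cidx] <- opt$minimum
          fp <- opt$objective
        }
      }
      if (round >= 2) h <- h / 2
    }
    list(par = p, value = fp)
  }
  best <- run(start)
  ## multi-start fallback against local minima: only worth trying when the
  ## local search neither improved nor reached a good per-term correlation
  at_best <- profile_similarity_impl(best$par, floating, tpl, omega_box,
                                     spacing_mm)
  mean_r <- at_best$S / max(at_best$n, 1L)
  if (multi_start && (-best$value - s0) < 1e-3 && mean_r < multi_start_r) {
    half <- trans_bound_mm / 2
    for (ax in 1:3) for (sg in c(-1, 1)) {
      p0 <- start
      p0[3 + ax] <- p0[3 + ax] + sg * half
      p0 <- pmin(pmax(p0, lower), upper)
      cand <- run(p0)
      if (cand$value < best$value) best <- cand
    }
  }
  if (-best$value < s0) {
    return(list(pose = start, similarity = s0, start_similarity = s0,
                converged = TRUE))
  }
  list(pose = pmin(pmax(best$par, lower), upper), similarity = -best$value,
       start_similarity = s0, converged = TRUE)
}

#' Register all slices of all stacks by sweeping Gauss-Seidel style
#'
#' Sequentially optimizes every slice of stack 1 against the other stacks
#' (immediately applying each estimated pose), proceeds to the next stack,
#' and repeats the sweep `n_outer` times.  The total similarity trajectory
#' is recorded.
#'
#' @param stacks list of `slice_stack` objects.
#' @param omega_box optional 2 x 3 world bounding box of the shared region
#'   (e.g. from [domain_intersection()]'s grid and mask).
#' @param n_outer number of outer sweeps (default 5).
#' @param ... passed to [register_slice()].
#' @return Object of class `slice_registration`: `stacks` (with updated
#'   `geom$poses`), `poses` (list of per-stack matrices), `similarity`
#'   (per-sweep total), `sweep_change` (max parameter change per sweep).
#' @export
register_stacks <- function(stacks, omega_box = NULL, n_outer = 5, ...) {
  stopifnot(length(stacks) >= 2)
  sim_tr <- numeric(n_outer)
  change <- numeric(n_outer)
  for (sw in seq_len(n_outer)) {
    total <- 0
    maxch <- 0
    for (n in seq_along(stacks)) {
      targets <- stacks[-n]
      for (k in seq_len(stacks[[n]]$geom$dim[3]) - 1L) {
        fl <- list(data = stacks[[n]]$data, geom = stacks[[n]]$geom, k = k)
        res <- register_slice(fl, targets, omega_box, ...)
        old <- stacks[[n]]$geom$poses[k + 1, ]
        if (is.finite(res$similarity)) {
          maxch <- max(maxch, max(abs(res$pose - old)))
          ## poses live inside the geometry; invalidate its cache copy
          g <- stacks[[n]]$geom
          g$poses[k + 1, ] <- res$pose
          stacks[[n]]$geom <- g
          total <- total + res$similarity
        }
      }
    }
    sim_tr[sw] <- total
    change[sw] <- maxch
  }
  structure(list(stacks = stacks,
                 poses = lapply(stacks, function(s) s$geom$poses),
                 similarity = sim_tr, sweep_change = change,
                 n_outer = n_outer),
            class = "slice_registration")
}

#' @export
print.slice_registration <- function(x, ...) {
  cat(sprintf("slice_registration: %d stacks, %d sweeps\n",
              length(x$poses), x$n_outer))
  cat("  total similarity per sweep:",
      paste(signif(x$similarity, 5), collapse = ", "), "\n")
  cat("  max parameter change per sweep:",
      paste(signif(x$sweep_change, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.slice_registration <- function(object, ...) {
  p <- do.call(rbind, object$poses)
  out <- list(n_slices = nrow(p),
              max_rotation_deg = max(abs(p[, 1:3])),
              max_translation_mm = max(abs(p[, 4:6])),
              similarity = object$similarity,
              stabilized = length(object$sweep_change) >= 2 &&
                object$sweep_change[length(object$sweep_change)] <=
                  0.5 * max(object$sweep_change[1], 1e-12))
  class(out) <- "summary.slice_registration"
  out
}

#' @export
print.summary.slice_registration <- function(x, ...) {
  cat(sprintf(
    "slice_registration: %d slices, |rot| <= %.2f deg, |trans| <= %.2f mm\n",
    x$n_slices, x$max_rotation_deg, x$max_translation_mm))
  invisible(x)
}
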