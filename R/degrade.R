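## Degradation of ground-truth volumes into realistic low-resolution
## stacks: in-plane k-space truncation, rectangular through-plane slice
## selection, and Rician noise.

## Indices of the centered retained band after cropping a length-n spectrum
## by `factor`; for even retained lengths the extra sample sits on the
## negative-frequency side.
kspace_keep <- function(n, factor) {
  m <- n / factor
  if (m != round(m)) stop("crop factor must divide the grid dimension")
  npos <- ceiling(m / 2)          # frequencies 0 .. npos-1
  nneg <- m - npos                # frequencies -nneg .. -1
  c(seq_len(npos), if (nneg > 0) seq(n - nneg + 1, n))
}

#' Reduce in-plane resolution by k-space truncation
#'
#' Per plane, takes the 2D discrete Fourier transform, retains the centered
#' low-frequency band (`1/factor` of each in-plane dimension, extra sample
#' on the negative-frequency side for even band sizes), and inverts.  For
#' band-limited input this equals exact decimation; the output grid keeps
#' the same origin with spacing scaled by `factor`.
#'
#' @param vol 3D array.
#' @param factor integer crop factor (must divide both in-plane dims).
#' @param plane_dims the two in-plane dimensions (default `c(1, 2)`; the
#'   remaining dimension indexes the planes).
#' @return 3D array with the in-plane dims divided by `factor`.
#' @export
degrade_inplane <- function(vol, factor = 2, plane_dims = c(1, 2)) {
  if (factor == 1) return(vol)
  stopifnot(length(plane_dims) == 2)
  other <- setdiff(1:3, plane_dims)
  perm <- c(plane_dims, other)
  v <- aperm(vol, perm)
  d <- dim(v)
  k1 <- kspace_keep(d[1], factor)
  k2 <- kspace_keep(d[2], factor)
  out <- array(0, c(d[1] / factor, d[2] / factor, d[3]))
  for (k in seq_len(d[3])) {
    F <- stats::fft(v[, , k])
    out[, , k] <- Re(stats::fft(F[k1, k2], inverse = TRUE)) / (d[1] * d[2])
  }
  aperm(out, order(perm))
}

#' Collapse thick slices along one axis with a slice-selection profile
#'
#' Each output slice is the profile-weighted mean of `thickness` consecutive
#' source planes; the default profile is the ideal rectangle (equal
#' weights).
#'
#' @param vol 3D array.
#' @param axis slice axis (1, 2 or 3).
#' @param thickness number of source planes per output slice; must divide
#'   the extent along `axis`.
#' @param profile `"rect"` or a numeric weight vector of length
#'   `thickness` (normalized to sum 1).
#' @return 3D array with `dim[axis]` divided by `thickness`.
#' @export
slice_select <- function(vol, axis = 3, thickness = 8, profile = "rect") {
  d <- dim(vol)
  if (d[axis] %% thickness != 0)
    stop("thickness must divide the extent along the slice axis")
  w <- if (identical(profile, "rect")) rep(1 / thickness, thickness)
       else as.numeric(profile) / sum(profile)
  if (length(w) != thickness) stop("profile length must equal thickness")
  perm <- c(setdiff(1:3, axis), axis)
  v <- aperm(vol, perm)
  d2 <- dim(v)
  ns <- d2[3] / thickness
  m <- matrix(v, nrow = d2[1] * d2[2])          # columns = source planes
  dim(m) <- c(d2[1] * d2[2], thickness, ns)
  out <- array(0, c(d2[1], d2[2], ns))
  for (t in seq_len(thickness)) out <- out + w[t] * array(m[, t, ], dim(out))
  aperm(out, order(perm))
}

#' Add Rician noise to a magnitude image
#'
#' `out = sqrt((x + n1)^2 + n2^2)` with `n1, n2` i.i.d. zero-mean Gaussian
#' of standard deviation `sigma`.  When `sigma` is `NULL` it is derived
#' from a target SNR as `mean(x[mask]) / target_snr`.
#'
#' @param vol numeric array.
#' @param target_snr target signal-to-noise ratio (mean mask signal over
#'   sigma); ignored when `sigma` is given.
#' @param sigma Gaussian noise standard deviation.
#' @param mask logical array defining the signal region for the SNR
#'   definition; default: voxels above 20% of the maximum.
#' @param seed optional RNG seed for reproducibility.
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(vol, target_snr = NULL, sigma = NULL,
                             mask = NULL, seed = NULL) {
  if (is.null(sigma)) {
    if (is.null(target_snr) || target_snr <= 0)
      stop("target_snr must be positive when sigma is not given")
    if (is.null(mask)) mask <- vol > 0.2 * max(vol)
    sigma <- mean(vol[mask]) / target_snr
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- array(stats::rnorm(length(vol), sd = sigma), dim(vol))
  n2 <- array(stats::rnorm(length(vol), sd = sigma), dim(vol))
  sqrt((vol + n1)^2 + n2^2)
}

#' Degradation settings for the simulated acquisitions
#'
#' @param orientations slab orientations, subset of `"xy"`, `"yz"`, `"xz"`
#'   (plane label = in-plane axes; slices stack along the remaining axis).
#' @param crop_factor in-plane k-space crop factor.
#' @param thickness slice thickness in source voxels.
#' @param snr target SNR of the low-resolution stacks (`NA` = noiseless);
#'   sigma is fixed from the b = 0 volume of each stack and shared by all
#'   diffusion channels.
#' @param seed RNG seed for the noise.
#' @return list of class `degradation_spec`.
#' @export
degradation_spec <- function(orientations = c("xy", "yz", "xz"),
                             crop_factor = 2, thickness = 8, snr = 40,
                             seed = 1) {
  stopifnot(all(orientations %in% c("xy", "yz", "xz")), crop_factor >= 1)
  structure(list(orientations = orientations, crop_factor = crop_factor,
                 thickness = thickness, snr = snr, seed = seed),
            class = "degradation_spec")
}

orientation_axes <- function(label) {
  switch(label,
         xy = list(inplane = c(1L, 2L), slice = 3L),
         yz = list(inplane = c(2L, 3L), slice = 1L),
         xz = list(inplane = c(1L, 3L), slice = 2L),
         stop(sprintf("unknown orientation label '%s'", label)))
}

#' Degrade a ground-truth DWI series into thick-slice stacks
#'
#' For each requested orientation: crop the in-plane k-space, average
#' `thickness` consecutive planes along the slice axis (ideal rectangular
#' profile), then add Rician noise with a per-stack sigma set from the
#' stack's b = 0 image and the target SNR.
#'
#' @param gt a `dwi_series` (see [synthesize_dwi()]) on an isotropic grid.
#' @param spec a [degradation_spec()].
#' @return List of `slice_stack` objects (fields `data` 4D in stack layout
#'   `(in1, in2, slice, channel)`, `geom` a [stack_geometry()], `bvals`,
#'   `bvecs`, `sigma`).
#' @export
simulate_lr_stacks <- function(gt, spec = degradation_spec()) {
  stacks <- vector("list", length(spec$orientations))
  names(stacks) <- spec$orientations
  nchan <- length(gt$bvals)
  for (s in seq_along(spec$orientations)) {
    lab <- spec$orientations[s]
    ax <- orientation_axes(lab)
    chans <- vector("list", nchan)
    for (v in seq_len(nchan)) {
      lr <- degrade_inplane(gt$data[, , , v], spec$crop_factor,
                            plane_dims = ax$inplane)
      lr <- slice_select(lr, axis = ax$slice, thickness = spec$thickness)
      chans[[v]] <- aperm(lr, c(ax$inplane, ax$slice))
    }
    data <- array(unlist(chans), c(dim(chans[[1]]), nchan))
    sigma <- NA_real_
    if (is.finite(spec$snr)) {
      b0 <- data[, , , which.min(gt$bvals)]
      sigma <- mean(b0[b0 > 0.2 * max(b0)]) / spec$snr
      data <- add_rician_noise(data, sigma = sigma,
                               seed = spec$seed + 1000 * s)
    }
    geom <- stack_geometry_for(gt$grid, lab, spec$crop_factor,
                               spec$thickness, dim(data)[1:3])
    stacks[[s]] <- structure(list(data = data, geom = geom,
                                  bvals = gt$bvals, bvecs = gt$bvecs,
                                  sigma = sigma, orientation = lab),
                             class = "slice_stack")
  }
  stacks
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "slice_stack [%s]: %dx%d in-plane x %d slices x %d channels (%g mm thick)\n",
    x$orientation %||% "?", d[1], d[2], d[3], d[4], x$geom$thickness_mm))
  invisible(x)
}
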