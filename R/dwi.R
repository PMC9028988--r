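## Diffusion protocols and synthetic diffusion-weighted signal generation.

#' Define a diffusion-encoding protocol
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs matrix (n x 3) of gradient directions; rows are normalized
#'   to unit length (with a warning if they are not already), except rows
#'   belonging to b = 0 volumes which may be zero.
#' @return Object of class `diffusion_protocol`.
#' @export
diffusion_protocol <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  stopifnot(nrow(bvecs) == length(bvals), ncol(bvecs) == 3)
  if (any(bvals < 0)) stop("b-values must be non-negative")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(dw & nrm == 0)) stop("zero gradient direction with non-zero b")
  fix <- dw & abs(nrm - 1) > 1e-8
  if (any(fix)) {
    warning(sprintf("normalized %d non-unit gradient direction(s)", sum(fix)))
    bvecs[fix, ] <- bvecs[fix, ] / nrm[fix]
  }
  bvecs[!dw, ] <- 0
  structure(list(bvals = bvals, bvecs = bvecs, n = length(bvals)),
            class = "diffusion_protocol")
}

#' The six-direction "dual gradient" encoding scheme
#'
#' Directions `[1 0 -1], [1 0 1], [0 -1 -1], [0 -1 1], [1 -1 0], [1 1 0]`
#' (normalized), preceded by one b = 0 volume — the minimal determined set
#' for a tensor fit.
#'
#' @param b diffusion weighting of the encoded volumes, s/mm^2.
#' @param n_b0 number of leading b = 0 volumes.
#' @return A [diffusion_protocol()].
#' @export
dual_gradient_scheme <- function(b = 350, n_b0 = 1) {
  dirs <- rbind(c(1, 0, -1), c(1, 0, 1), c(0, -1, -1),
                c(0, -1, 1), c(1, -1, 0), c(1, 1, 0)) / sqrt(2)
  diffusion_protocol(c(rep(0, n_b0), rep(b, 6)),
                     rbind(matrix(0, n_b0, 3), dirs))
}

#' Synthesize diffusion-weighted volumes from a tensor field
#'
#' Mono-exponential tensor model: \eqn{S(n) = S_0 \exp(-b\, g_n^T D g_n)}.
#' Voxels outside the mask keep a zero background.
#'
#' @param tensors n x 6 tensor components (xx, yy, zz, xy, xz, yz) for the
#'   voxels listed by `mask`.
#' @param protocol a [diffusion_protocol()].
#' @param mask logical 3D array selecting the n tensor voxels (array order).
#' @param grid the sampling [iso_grid()].
#' @param s0 non-diffusion-weighted signal (scalar or per-voxel vector).
#' @return Object of class `dwi_series`: list with 4D `data`
#'   (x, y, z, volume), `bvals`, `bvecs`, `grid`.
#' @export
synthesize_dwi <- function(tensors, protocol, mask, grid, s0 = 1) {
  stopifnot(sum(mask) == nrow(tensors))
  g <- protocol$bvecs
  b <- protocol$bvals
  ## quadratic form g' D g for all voxels and directions at once
  quad <- tensors[, "xx"] %o% g[, 1]^2 + tensors[, "yy"] %o% g[, 2]^2 +
    tensors[, "zz"] %o% g[, 3]^2 +
    2 * tensors[, "xy"] %o% (g[, 1] * g[, 2]) +
    2 * tensors[, "xz"] %o% (g[, 1] * g[, 3]) +
    2 * tensors[, "yz"] %o% (g[, 2] * g[, 3])
  sig <- s0 * exp(-sweep(quad, 2, b, "*"))
  data <- array(0, c(grid$dim, protocol$n))
  idx <- which(mask)
  nvox <- prod(grid$dim)
  for (v in seq_len(protocol$n)) data[idx + (v - 1) * nvox] <- sig[, v]
  structure(list(data = data, bvals = b, bvecs = protocol$bvecs, grid = grid),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("dwi_series: %s voxels x %d volumes, b = {%s} s/mm^2\n",
              paste(dim(x$data)[1:3], collapse = "x"), length(x$bvals),
              paste(sort(unique(x$bvals)), collapse = ", ")))
  invisible(x)
}
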