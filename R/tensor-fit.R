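## Per-voxel diffusion tensor estimation by log-linear least squares, with
## eigen-decomposition and the scalar invariants MD and FA.

dti_design_matrix <- function(protocol) {
  g <- protocol$bvecs; b <- protocol$bvals
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit diffusion tensors to a DWI series
#'
#' Log-linear least squares on \eqn{\ln S} per voxel: the model
#' \eqn{S = S_0 \exp(-b\, g^T D g)} becomes linear in
#' \eqn{(\ln S_0, D_{xx}, \dots, D_{yz})}.  Signals are clamped at
#' `1e-6 * S0` (per-voxel b = 0 mean) before the log.  With the
#' six-direction dual-gradient scheme plus one b = 0 volume the system is
#' exactly determined and noiseless data are recovered to round-off.  An
#' optional weighted pass (`method = "wls"`) reweights by the squared
#' fitted signals.
#'
#' @param dwi a `dwi_series` or a 4D array.
#' @param protocol a [diffusion_protocol()]; taken from `dwi` when omitted.
#' @param mask logical 3D array of voxels to fit (default: all voxels with
#'   positive b = 0 signal).
#' @param method `"ols"` (default) or `"wls"`.
#' @return Object of class `dti_fit`: `tensors` (n x 6, mm^2/s), `log_s0`,
#'   `mask`, `dim`, `protocol`, `residual_norm` (per voxel rms of the
#'   log-signal residuals), `method`.
#' @export
dti_fit <- function(dwi, protocol = NULL, mask = NULL, method = c("ols", "wls")) {
  method <- match.arg(method)
  if (inherits(dwi, "dwi_series")) {
    if (is.null(protocol)) protocol <- diffusion_protocol(dwi$bvals, dwi$bvecs)
    data <- dwi$data
  } else data <- dwi
  stopifnot(!is.null(protocol), length(dim(data)) == 4L,
            dim(data)[4] == protocol$n)
  d3 <- dim(data)[1:3]
  b0idx <- which(protocol$bvals == 0)
  if (length(b0idx) == 0) stop("protocol needs at least one b = 0 volume")
  if (sum(protocol$bvals > 0) < 6)
    stop("at least six diffusion-weighted volumes are required")
  if (is.null(mask)) {
    b0 <- apply(data[, , , b0idx, drop = FALSE], 1:3, mean)
    mask <- b0 > 0
  }
  idx <- which(mask)
  nvox <- prod(d3)
  S <- matrix(0, length(idx), protocol$n)
  for (v in seq_len(protocol$n)) S[, v] <- data[idx + (v - 1) * nvox]
  s0 <- rowMeans(S[, b0idx, drop = FALSE])
  s0 <- pmax(s0, .Machine$double.xmin)
  Sc <- pmax(S, 1e-6 * s0)
  L <- log(Sc)
  X <- dti_design_matrix(protocol)
  XtXi <- solve(crossprod(X))
  beta <- L %*% X %*% XtXi          # n x 7
  if (method == "wls") {
    ## one reweighting pass with weights = squared predicted signals
    pred <- beta %*% t(X)
    W <- exp(2 * pred)
    for (r in seq_len(nrow(beta))) {
      w <- W[r, ]
      Xw <- X * w
      beta[r, ] <- solve(crossprod(X, Xw), crossprod(Xw, L[r, ]))
    }
  }
  resid <- L - beta %*% t(X)
  tensors <- beta[, 2:7, drop = FALSE]
  colnames(tensors) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  structure(list(tensors = tensors, log_s0 = beta[, 1], mask = mask,
                 dim = d3, protocol = protocol,
                 residual_norm = sqrt(rowMeans(resid^2)), method = method),
            class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf("dti_fit (%s): %d voxels, %d volumes\n",
              x$method, nrow(x$tensors), x$protocol$n))
  md <- dti_md(x)
  cat(sprintf("  MD: %.4g +/- %.2g mm^2/s; rms log-residual %.3g\n",
              mean(md), stats::sd(md), mean(x$residual_norm)))
  invisible(x)
}

#' @export
coef.dti_fit <- function(object, ...) object$tensors

#' @export
predict.dti_fit <- function(object, protocol = object$protocol, ...) {
  X <- dti_design_matrix(protocol)
  exp(cbind(object$log_s0, object$tensors) %*% t(X))
}

#' @export
residuals.dti_fit <- function(object, ...) {
  ## residuals in log-signal space (rms per voxel is residual_norm)
  object$residual_norm
}

#' @export
summary.dti_fit <- function(object, ...) {
  md <- dti_md(object); fa <- dti_fa(object)
  out <- list(n = nrow(object$tensors),
              md = c(mean = mean(md), sd = stats::sd(md),
                     median = stats::median(md)),
              fa = c(mean = mean(fa), sd = stats::sd(fa),
                     median = stats::median(fa)),
              spd_fraction = mean(dti_eigenvalues(object)[, 3] > 0),
              method = object$method)
  class(out) <- "summary.dti_fit"
  out
}

#' @export
print.summary.dti_fit <- function(x, ...) {
  cat(sprintf("dti_fit summary (%s, %d voxels)\n", x$method, x$n))
  cat(sprintf("  MD %.4g +/- %.2g mm^2/s; FA %.3f +/- %.3f; SPD %.1f%%\n",
              x$md["mean"], x$md["sd"], x$fa["mean"], x$fa["sd"],
              100 * x$spd_fraction))
  invisible(x)
}

tensor_rows <- function(x) {
  if (inherits(x, "dti_fit")) x$tensors
  else if (is.matrix(x) && ncol(x) == 6) x
  else stop("expected a dti_fit or an n x 6 tensor matrix")
}

as_sym3 <- function(row) {
  matrix(c(row[1], row[4], row[5],
           row[4], row[2], row[6],
           row[5], row[6], row[3]), 3, 3)
}

#' Eigenvalues of a tensor field (descending per voxel)
#'
#' @param x a `dti_fit` or n x 6 tensor matrix.
#' @return n x 3 matrix of eigenvalues, descending.
#' @export
dti_eigenvalues <- function(x) {
  dti_eigen(x)$values
}

#' Eigen-decomposition of a tensor field
#'
#' Descending eigenvalues; eigenvectors are unit-norm with a deterministic
#' sign convention (largest-magnitude component positive) — downstream
#' helix/transverse angles are invariant to the antipodal ambiguity.
#' Non-positive-definite voxels are flagged, not altered.
#'
#' @param x a `dti_fit` or n x 6 tensor matrix.
#' @return list with `values` (n x 3), `e1`, `e2`, `e3` (n x 3 unit
#'   vectors, right-handed), and logical `not_spd`.
#' @export
dti_eigen <- function(x) {
  tn <- tensor_rows(x)
  n <- nrow(tn)
  vals <- matrix(NA_real_, n, 3)
  e1 <- matrix(NA_real_, n, 3); e2 <- e1; e3 <- e1
  for (r in seq_len(n)) {
    row <- tn[r, ]
    if (anyNA(row)) next
    es <- eigen(as_sym3(row), symmetric = TRUE)
    vals[r, ] <- es$values
    V <- es$vectors
    for (c in 1:3) {
      mx <- which.max(abs(V[, c]))
      if (V[mx, c] < 0) V[, c] <- -V[, c]
    }
    if (det(V) < 0) V[, 3] <- -V[, 3]
    e1[r, ] <- V[, 1]; e2[r, ] <- V[, 2]; e3[r, ] <- V[, 3]
  }
  list(values = vals, e1 = e1, e2 = e2, e3 = e3,
       not_spd = vals[, 3] <= 0)
}

#' Mean diffusivity from eigenvalues or tensors
#'
#' `MD = (l1 + l2 + l3) / 3` (equivalently trace/3, so no
#' eigen-decomposition is needed).
#'
#' @param x a `dti_fit`, n x 6 tensor matrix, or n x 3 eigenvalue matrix.
#' @return numeric vector of MD values (mm^2/s).
#' @export
dti_md <- function(x) {
  if (is.matrix(x) && ncol(x) == 3) return(rowMeans(x))
  tn <- tensor_rows(x)
  (tn[, "xx"] + tn[, "yy"] + tn[, "zz"]) / 3
}

#' Fractional anisotropy from eigenvalues or tensors
#'
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||`, in `[0, 1]`; defined as
#' 0 for an all-zero tensor.
#'
#' @inheritParams dti_md
#' @return numeric vector of FA values.
#' @export
dti_fa <- function(x) {
  ev <- if (is.matrix(x) && ncol(x) == 3) x else dti_eigenvalues(x)
  md <- rowMeans(ev)
  num <- sqrt(rowSums((ev - md)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- sqrt(1.5) * num / ifelse(den > 0, den, 1)
  fa[den == 0] <- 0
  fa
}
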