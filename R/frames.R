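## Local cardiac coordinate frames (radial, circumferential, longitudinal)
## from an implicit LV surface, and helix/transverse angles of the primary
## eigenvector.

#' Fit a smooth implicit surface to sparse planar contours
#'
#' Triharmonic radial-basis interpolation (`phi(r) = r^3` plus a linear
#' polynomial) of a signed pseudo-distance: contour points carry value 0
#' and off-surface constraint points, offset along the estimated in-plane
#' outward normals, carry +/- the offset distance.  The zero level set is a
#' smooth surface through the contours with an analytic gradient.
#'
#' @param contours list of n_i x 3 matrices of world points, each contour
#'   planar and ordered along the curve; at least 3 contours spanning 3D.
#' @param offset_mm off-surface constraint distance.
#' @param lambda_smooth dimensionless ridge added to the RBF system (0 =
#'   interpolation; values around 1e-4..1e-2 trade fit for smoothness
#'   with noisy contours).
#' @return Object of class `lv_surface` with `centers`, `weights`,
#'   `poly` (linear polynomial coefficients) and the fit RMS at the contour
#'   points.
#' @export
fit_lv_surface <- function(contours, offset_mm = 2, lambda_smooth = 1e-8) {
  stopifnot(is.list(contours))
  if (length(contours) < 3)
    stop("at least 3 contours are required for a 3D surface fit")
  pts <- list(); vals <- list()
  for (ci in seq_along(contours)) {
    P <- as.matrix(contours[[ci]])
    if (nrow(P) < 6) stop("each contour needs at least 6 points")
    cen <- colMeans(P)
    sv <- svd(sweep(P, 2, cen, "-"))
    nrm <- sv$v[, 3]                          # contour plane normal
    nxt <- P[c(2:nrow(P), 1), ] - P           # tangents along the curve
    outn <- cross3(nxt, matrix(nrm, nrow(P), 3, byrow = TRUE))
    outn <- normalize_rows(outn)$u
    ## orient outward: away from the contour centroid
    flip <- rowSums(outn * sweep(P, 2, cen, "-")) < 0
    outn[flip, ] <- -outn[flip, ]
    pts[[length(pts) + 1]] <- P
    vals[[length(vals) + 1]] <- rep(0, nrow(P))
    pts[[length(pts) + 1]] <- P + offset_mm * outn
    vals[[length(vals) + 1]] <- rep(offset_mm, nrow(P))
    pts[[length(pts) + 1]] <- P - offset_mm * outn
    vals[[length(vals) + 1]] <- rep(-offset_mm, nrow(P))
  }
  P <- do.call(rbind, pts)
  v <- unlist(vals)
  ## degenerate geometry check: constraint cloud must span 3D
  sv <- svd(sweep(P, 2, colMeans(P), "-"))
  if (sv$d[3] < 1e-6 * sv$d[1])
    stop("degenerate (coplanar) contour set")
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  ## ridge scaled by the typical kernel magnitude so lambda_smooth is
  ## dimensionless (0 = pure interpolation)
  A <- D^3 + diag(lambda_smooth * stats::median(D)^3, n)
  Q <- cbind(1, P)
  M <- rbind(cbind(A, Q), cbind(t(Q), matrix(0, 4, 4)))
  sol <- solve(M, c(v, rep(0, 4)))
  w <- sol[seq_len(n)]
  poly <- sol[n + 1:4]
  surf <- structure(list(centers = P, weights = w, poly = poly),
                    class = "lv_surface")
  on_contour <- do.call(rbind, contours)
  surf$rms_mm <- sqrt(mean(lv_surface_value(surf, on_contour)^2))
  surf
}

#' Evaluate the implicit surface field
#' @param surface an `lv_surface`.
#' @param pts n x 3 world points.
#' @return numeric vector of signed field values (0 on the surface,
#'   positive outside).
#' @export
lv_surface_value <- function(surface, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  out <- surface$poly[1] + pts %*% surface$poly[2:4]
  for (i in seq_along(surface$weights)) {
    d <- sqrt((pts[, 1] - surface$centers[i, 1])^2 +
              (pts[, 2] - surface$centers[i, 2])^2 +
              (pts[, 3] - surface$centers[i, 3])^2)
    out <- out + surface$weights[i] * d^3
  }
  as.numeric(out)
}

#' Gradient of the implicit surface field
#' @inheritParams lv_surface_value
#' @return n x 3 matrix of gradients (outward-pointing on the surface).
#' @export
lv_surface_gradient <- function(surface, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  g <- matrix(rep(surface$poly[2:4], each = nrow(pts)), ncol = 3)
  for (i in seq_along(surface$weights)) {
    dx <- pts[, 1] - surface$centers[i, 1]
    dy <- pts[, 2] - surface$centers[i, 2]
    dz <- pts[, 3] - surface$centers[i, 3]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    g <- g + 3 * surface$weights[i] * d * cbind(dx, dy, dz)
  }
  g
}

#' @export
print.lv_surface <- function(x, ...) {
  cat(sprintf("lv_surface: %d RBF centers, contour RMS %.3g mm\n",
              length(x$weights), x$rms_mm))
  invisible(x)
}

#' Local cardiac frames at a set of points
#'
#' `er` is the normalized surface gradient (outward radial),
#' `ec = normalize(long_axis x er)` (circumferential) and `el = er x ec`
#' (longitudinal, non-negative component along the long axis).  Points
#' where the long axis is (nearly) parallel to the normal — the apex cap —
#' are flagged degenerate.
#'
#' @param surface an `lv_surface` (or any object accepted by
#'   [lv_surface_gradient()]).
#' @param pts n x 3 world points.
#' @param long_axis unit apex-to-base direction.
#' @param tol degeneracy tolerance on `|long_axis x er|`.
#' @return list of n x 3 matrices `er`, `ec`, `el` and logical
#'   `degenerate`.
#' @export
local_frames <- function(surface, pts, long_axis = c(0, 0, 1), tol = 1e-2) {
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  g <- lv_surface_gradient(surface, pts)
  nr <- normalize_rows(g, tol = 1e-10)
  er <- nr$u
  ecraw <- cross3(matrix(long_axis, nrow(er), 3, byrow = TRUE), er)
  nc <- normalize_rows(ecraw, tol = tol)
  ec <- nc$u
  el <- cross3(er, ec)
  list(er = er, ec = ec, el = el,
       degenerate = nr$degenerate | nc$degenerate)
}

#' Helix and transverse angle maps of a primary-eigenvector field
#'
#' After folding the antipodal ambiguity (`e1` and `-e1` are equivalent) so
#' that the circumferential component is non-negative:
#' `HA = atan2(e1.el, e1.ec)` (the in-tangent-plane elevation toward the
#' base, positive for a right-handed helix at the endocardium) and
#' `TA = atan2(e1.er, |proj_tangent e1|)` (the out-of-plane angle signed by
#' the radial component).  Both in degrees within `[-90, 90]`.  Voxels
#' where `e1` is parallel to the radial axis (HA undefined) are flagged.
#'
#' @param e1 n x 3 matrix of unit primary eigenvectors.
#' @param frames local frames ([local_frames()] or the phantom's analytic
#'   frames).
#' @return list with `ha_deg`, `ta_deg`, and logical `undefined`.
#' @export
helix_transverse_angles <- function(e1, frames) {
  if (is.null(dim(e1))) e1 <- matrix(e1, nrow = 1)
  c_ec <- rowSums(e1 * frames$ec)
  c_el <- rowSums(e1 * frames$el)
  c_er <- rowSums(e1 * frames$er)
  flip <- c_ec < 0 | (c_ec == 0 & c_el < 0)
  c_ec[flip] <- -c_ec[flip]; c_el[flip] <- -c_el[flip]
  c_er[flip] <- -c_er[flip]
  tang <- sqrt(c_ec^2 + c_el^2)
  undefined <- tang < 1e-9
  ha <- rad2deg(atan2(c_el, c_ec))
  ta <- rad2deg(atan2(c_er, tang))
  ha[undefined] <- NA_real_
  list(ha_deg = ha, ta_deg = ta,
       undefined = undefined | (frames$degenerate %||% FALSE))
}
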