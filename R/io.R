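## File formats: NIfTI-1 volumes with FSL-style bvals/bvecs, JSON sidecars
## and YAML pipeline configuration.  World coordinates use the NIfTI RAS+
## convention with 0-based voxel indices and voxel-center alignment.

#' Write a DWI series as NIfTI + bvals/bvecs (+ JSON sidecar)
#'
#' Writes `<path>.nii.gz`, `<path>.bval`, `<path>.bvec` (FSL layout: one
#' space-separated row of b-values; three rows of direction components)
#' and `<path>.json` (grid and any extra metadata).
#'
#' @param series a `dwi_series`.
#' @param path output path prefix (without extension).
#' @param sidecar named list of extra metadata for the JSON sidecar.
#' @return The NIfTI file path, invisibly.
#' @export
write_dwi <- function(series, path, sidecar = list()) {
  aff <- grid_affine(series$grid)
  img <- RNifti::asNifti(series$data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(img, nii)
  writeLines(paste(format(series$bvals, trim = TRUE), collapse = " "),
             paste0(path, ".bval"))
  bv <- t(series$bvecs)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 12), collapse = " ")),
    paste0(path, ".bvec"))
  meta <- c(list(dim = series$grid$dim, spacing_mm = series$grid$spacing,
                 origin_mm = series$grid$origin), sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(nii)
}

#' Read a DWI series written by [write_dwi()] (or any NIfTI + FSL b-table)
#'
#' @param path path prefix (without extension) or the `.nii.gz` path.
#' @return A `dwi_series`.
#' @export
read_dwi <- function(path) {
  path <- sub("\\.nii(\\.gz)?$", "", path)
  nii <- paste0(path, ".nii.gz")
  if (!file.exists(nii)) nii <- paste0(path, ".nii")
  if (!file.exists(nii)) stop("NIfTI file not found: ", path)
  bvalf <- paste0(path, ".bval"); bvecf <- paste0(path, ".bvec")
  if (!file.exists(bvalf) || !file.exists(bvecf))
    stop("missing bval/bvec table next to ", nii)
  img <- RNifti::readNifti(nii)
  data <- array(as.numeric(img), dim(img))
  if (length(dim(data)) == 3L) data <- array(data, c(dim(data), 1L))
  bvals <- scan(bvalf, quiet = TRUE)
  bvecs <- t(matrix(scan(bvecf, quiet = TRUE), nrow = 3, byrow = TRUE))
  if (length(bvals) != dim(data)[4] || nrow(bvecs) != dim(data)[4])
    stop(sprintf("b-table length (%d) does not match image volumes (%d)",
                 length(bvals), dim(data)[4]))
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4]
  proto <- diffusion_protocol(bvals, bvecs)
  structure(list(data = data, bvals = proto$bvals, bvecs = proto$bvecs,
                 grid = iso_grid(dim(data)[1:3], spacing, origin)),
            class = "dwi_series")
}

#' Default pipeline configuration
#'
#' Round-trips losslessly through YAML; unknown keys in a loaded file are
#' rejected.
#'
#' @param ... overrides of the default fields (nested lists are replaced
#'   whole).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    phantom = list(grid_dim = c(96, 96, 80), r_min = 16, r_max = 48,
                   wall = 14, b_value = 350, s0 = 1),
    degrade = list(orientations = c("xy", "yz", "xz"), crop_factor = 2,
                   thickness = 8, snr = 40),
    register = list(enabled = FALSE, n_outer = 5, rot_bound_deg = 5,
                    trans_bound_mm = 8),
    recon = list(lambda_reg = 1e-5, beta = 1, max_iters = 500,
                 grad_tol = 1e-6),
    analysis = list(erosion_vox = 1, n_layers = 5, fa_gate = 0.05))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]])) {
      bad2 <- setdiff(names(ov[[nm]]), names(cfg[[nm]]))
      if (length(bad2))
        stop(sprintf("unknown config keys under '%s': %s", nm,
                     paste(bad2, collapse = ", ")))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write pipeline configuration as YAML
#' @param path file path.
#' @return [pipeline_config()] for `read_config`; the path (invisibly) for
#'   `write_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
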