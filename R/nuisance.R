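# aCompCor: principal-component nuisance regressors from eroded WM/CSF
# masks, plus assembly of the 16-column nuisance set (6 motion + 10 PCs).

#' Erode a binary mask by Gaussian smoothing and re-thresholding
#'
#' The binary mask is smoothed with an isotropic Gaussian kernel of
#' `sigma_mm` (converted to voxels) and re-binarized at `threshold`
#' (default 0.9, a strict cut that keeps only deep interior voxels), so
#' that no grey-matter voxels leak into the anatomical noise masks. The
#' output is always a subset of the input.
#'
#' @param mask logical 3D array.
#' @param sigma_mm Gaussian kernel sigma, mm.
#' @param threshold re-binarization threshold in \[0, 1\]; 0 returns the
#'   input unchanged.
#' @param voxel_mm isotropic voxel size used to convert sigma to voxels.
#' @return eroded logical array with attribute `empty` if no voxels remain.
#' @export
erode_mask <- function(mask, sigma_mm = 0.8, threshold = 0.9, voxel_mm = 0.8) {
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stopf("erode_mask: mask must be binary")
    mask <- array(mask > 0, dim(mask))
  }
  if (threshold <= 0) return(mask)
  sm <- smooth3d_gaussian(array(as.numeric(mask), dim(mask)),
                          sigma_mm / voxel_mm)
  out <- array(sm >= threshold & mask, dim(mask))
  if (!any(out)) {
    warnf("erode_mask: erosion left an empty mask")
    attr(out, "empty") <- TRUE
  }
  out
}

#' Anatomical component correction (aCompCor)
#'
#' Extracts the top principal components of the voxel time series within
#' the (eroded) WM and CSF masks, separately per tissue: each voxel's
#' series is linearly detrended and variance-normalized, the time-by-voxel
#' matrix is decomposed by SVD, and the leading `n_per_tissue` left
#' singular vectors are returned as unit-variance columns (5 + 5 = 10
#' regressors with the defaults). Component signs follow a deterministic
#' convention (non-negative skewness). Rank-deficient tissue data yield
#' fewer components with a warning.
#'
#' @param series a `contrast_series` or 4D array.
#' @param wm_mask,csf_mask logical 3D arrays (after erosion).
#' @param n_per_tissue components per tissue.
#' @param detrend,scale per-voxel linear detrending and variance
#'   normalization before the SVD.
#' @return object of class `nuisance_components`: `components` (t x k
#'   matrix), `names`, `n_per_tissue` actually returned per tissue.
#' @export
acompcor <- function(series, wm_mask, csf_mask, n_per_tissue = 5,
                     detrend = TRUE, scale = TRUE) {
  data <- if (inherits(series, "contrast_series")) series$data else series
  d <- dim(data)
  m <- matrix(data, prod(d[1:3]), d[4])
  one_tissue <- function(mask, label) {
    if (is.null(mask) || !any(mask)) stopf("acompcor: empty %s mask", label)
    y <- t(m[which(mask), , drop = FALSE])    # t x v
    if (detrend) y <- detrend_columns(y) else y <- sweep(y, 2, colMeans(y))
    if (scale) {
      s <- sqrt(colMeans(y^2))
      keep <- s > 0
      y <- sweep(y[, keep, drop = FALSE], 2, s[keep], "/")
    }
    sv <- svd(y, nu = min(n_per_tissue, ncol(y), nrow(y)), nv = 0)
    nonzero <- sv$d[seq_len(ncol(sv$u))] > max(sv$d) * 1e-10
    u <- sv$u[, nonzero, drop = FALSE]
    if (ncol(u) < n_per_tissue) {
      warnf("acompcor: %s data support only %d of %d components",
            label, ncol(u), n_per_tissue)
    }
    u <- sweep(u, 2, colMeans(u))
    u <- sweep(u, 2, apply(u, 2, stats::sd), "/")
    flip <- col_skew(u) < 0
    u[, flip] <- -u[, flip]
    colnames(u) <- sprintf("%s_comp%d", label, seq_len(ncol(u)))
    u
  }
  wm <- one_tissue(wm_mask, "wm")
  csf <- one_tissue(csf_mask, "csf")
  comps <- cbind(wm, csf)
  structure(list(components = comps, names = colnames(comps),
                 n_per_tissue = c(wm = ncol(wm), csf = ncol(csf))),
            class = "nuisance_components")
}

#' Assemble the nuisance regressor set
#'
#' Concatenates 6 motion estimates and the aCompCor components into the
#' nuisance block appended to the GLM design (16 columns with the default
#' 5 components per tissue).
#'
#' @param components a `nuisance_components` (or t x k matrix).
#' @param motion t x 6 matrix of motion estimates.
#' @return object of class `nuisance_set` with `matrix` (t x (6 + k)) and
#'   `names`.
#' @export
nuisance_set <- function(components, motion) {
  comp <- if (inherits(components, "nuisance_components"))
    components$components else components
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("nuisance_set: motion must have 6 columns")
  if (nrow(motion) != nrow(comp))
    stopf("nuisance_set: motion and component row counts differ")
  if (is.null(colnames(motion)))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
  m <- cbind(motion, comp)
  structure(list(matrix = m, names = colnames(m)), class = "nuisance_set")
}
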