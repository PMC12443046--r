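# Voxel-wise GLM: canonical-HRF task regressors, DCT high-pass drift basis,
# nuisance block, OLS estimation, memory-minus-math contrast, GM-masked
# cluster-extent thresholding and subfield cluster summaries.

#' Build the GLM design matrix
#'
#' Columns: intercept, the two task regressors (memory, math; boxcars
#' convolved with [canonical_hrf()] and scaled to unit peak), a DCT drift
#' basis implementing high-pass filtering with cut-off `hp_cutoff_s`
#' (`floor(2 T / cutoff)` regressors over a scan of length T), and the
#' mean-centered nuisance block.
#'
#' @param design a `task_design`.
#' @param nuisance optional `nuisance_set` (or t x k matrix).
#' @param timestamps_s acquisition times of the modelled volumes, seconds
#'   (for interleaved data: the pair reference times, i.e. the nulled
#'   member's timestamps, shared by the VASO and BOLD fits).
#' @param hp_cutoff_s high-pass cut-off period, seconds; NULL disables the
#'   drift basis.
#' @return object of class `design_matrix`: `matrix` (t x p), `names`,
#'   `task_columns`, `hp_cutoff_s`, `n_dct`.
#' @export
build_design <- function(design, nuisance = NULL, timestamps_s,
                         hp_cutoff_s = 128) {
  t_dim <- length(timestamps_s)
  ev <- design$events
  scan_end <- max(timestamps_s) + stats::median(diff(timestamps_s))
  if (any(ev$onset >= scan_end)) {
    warnf("build_design: %d events start beyond scan end and are truncated",
          sum(ev$onset >= scan_end))
    ev <- ev[ev$onset < scan_end, , drop = FALSE]
    design$events <- ev
  }
  memory <- task_regressor(ev, timestamps_s, "memory")
  math <- task_regressor(ev, timestamps_s, "math")
  X <- cbind(intercept = 1, memory = memory, math = math)
  n_dct <- 0L
  if (!is.null(hp_cutoff_s) && is.finite(hp_cutoff_s)) {
    T_total <- t_dim * stats::median(diff(timestamps_s))
    n_dct <- as.integer(floor(2 * T_total / hp_cutoff_s))
    if (n_dct > 0) {
      dct <- dct_basis(t_dim, n_dct)
      colnames(dct) <- sprintf("dct%d", seq_len(n_dct))
      X <- cbind(X, dct)
    }
  }
  if (!is.null(nuisance)) {
    nm <- if (inherits(nuisance, "nuisance_set")) nuisance$matrix
          else as.matrix(nuisance)
    if (nrow(nm) != t_dim)
      stopf("build_design: nuisance rows (%d) != timepoints (%d)",
            nrow(nm), t_dim)
    nm <- sweep(nm, 2, colMeans(nm))
    X <- cbind(X, nm)
  }
  zero_cols <- which(colSums(abs(X)) == 0)
  if (length(zero_cols))
    stopf("build_design: all-zero column(s): %s",
          paste(colnames(X)[zero_cols], collapse = ", "))
  structure(list(matrix = X, names = colnames(X),
                 task_columns = c(memory = 2L, math = 3L),
                 hp_cutoff_s = hp_cutoff_s, n_dct = n_dct,
                 timestamps_s = timestamps_s),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d timepoints x %d regressors (%d DCT)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_dct))
  invisible(x)
}

check_design_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  qrX
}

#' Fit the voxel-wise GLM and compute the memory - math contrast
#'
#' Ordinary least squares per voxel. The contrast of interest is
#' `beta_memory - beta_math` with its t statistic. For `vaso_corrected`
#' input the contrast (and t) are negated before reporting, because a CBV
#' increase appears as a signal decrease in the blood-nulled ratio; the
#' sign convention is recorded in provenance.
#'
#' @param series a `contrast_series` (t must equal the design rows).
#' @param X a `design_matrix`.
#' @param mask optional logical 3D array of voxels to fit.
#' @return object of class `stat_map`: `beta` (p x nvox_in_mask), contrast,
#'   t and residual-variance maps (3D arrays, NA outside the mask), `df`,
#'   `mask`, `baseline` (voxel temporal mean), `provenance`.
#' @export
fit_glm <- function(series, X, mask = NULL) {
  Xm <- X$matrix
  data <- series$data
  d <- dim(data)
  if (d[4] != nrow(Xm))
    stopf("fit_glm: series length (%d) != design rows (%d)", d[4], nrow(Xm))
  qrX <- check_design_rank(Xm)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  vox <- which(mask)
  Y <- t(matrix(data, prod(d[1:3]), d[4]))[, vox, drop = FALSE]  # t x nvox
  beta <- qr.coef(qrX, Y)
  resid <- Y - Xm %*% beta
  df <- d[4] - ncol(Xm)
  sigma2 <- colSums(resid^2) / df
  cvec <- numeric(ncol(Xm))
  cvec[X$task_columns["memory"]] <- 1
  cvec[X$task_columns["math"]] <- -1
  xtx_inv_c <- drop(crossprod(cvec, chol2inv(chol(crossprod(Xm)))) %*% cvec)
  con <- drop(crossprod(cvec, beta))
  tval <- con / sqrt(sigma2 * xtx_inv_c)
  sign_flip <- identical(series$contrast, "vaso_corrected")
  if (sign_flip) {
    con <- -con
    tval <- -tval
  }
  to_map <- function(v) {
    m <- array(NA_real_, d[1:3])
    m[vox] <- v
    m
  }
  structure(list(beta = beta, names = colnames(Xm),
                 contrast_map = to_map(con), t_map = to_map(tval),
                 sigma2_map = to_map(sigma2),
                 baseline = to_map(colMeans(Y)),
                 df = df, mask = mask, voxels = vox,
                 contrast = series$contrast,
                 provenance = list(sign_flipped = sign_flip,
                                   contrast_name = "memory_minus_math",
                                   df = df)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map [%s]: %d voxels fitted, df = %d%s\n", x$contrast,
              length(x$voxels), x$df,
              if (x$provenance$sign_flipped) " (contrast sign flipped)" else ""))
  invisible(x)
}

#' Cluster-extent thresholding of a t map within a grey-matter mask
#'
#' Suprathreshold voxels (one-sided `t > qt(1 - p_unc, df)`) within the GM
#' mask are grouped by 18-connectivity; clusters smaller than `k` voxels
#' are removed.
#'
#' @param stat a `stat_map`.
#' @param p_unc uncorrected voxel-level p threshold.
#' @param k minimum cluster extent in voxels.
#' @param gm_mask logical 3D array on the same grid as the t map.
#' @return list with `label_volume` (integer array, 0 = background) and
#'   `table` (data.frame: cluster id, size, peak t, peak i/j/k).
#' @export
cluster_threshold <- function(stat, p_unc = 0.05, k = 20, gm_mask) {
  if (!any(gm_mask)) stopf("cluster_threshold: empty GM mask")
  if (!identical(dim(gm_mask), dim(stat$t_map)))
    stopf("cluster_threshold: mask and t map grids differ")
  thr <- stats::qt(1 - p_unc, stat$df)
  sup <- !is.na(stat$t_map) & stat$t_map > thr & gm_mask
  lab <- connected_components_18(sup)
  sizes <- tabulate(lab)
  keep <- which(sizes >= k)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  rows <- lapply(seq_along(keep), function(i) {
    vox <- which(lab == i)
    pk <- vox[which.max(stat$t_map[vox])]
    ijk <- arrayInd(pk, dim(lab))
    data.frame(cluster = i, size = length(vox), peak_t = stat$t_map[pk],
               peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), size = integer(), peak_t = numeric(),
               peak_i = integer(), peak_j = integer(), peak_k = integer())
  list(label_volume = lab, table = tab, threshold_t = thr)
}

#' Mean signal change per subfield within significant clusters
#'
#' For each hippocampal subfield, averages the contrast over the voxels
#' where significant clusters overlap that subfield, expressed as percent
#' of the voxel baseline mean. DG and CA4 are a single merged ROI
#' (reported as "DG"). Subfields with no overlapping voxels are reported
#' as missing (NA), not zero.
#'
#' @param stat a `stat_map`.
#' @param clusters output of [cluster_threshold()].
#' @param label_volume integer subfield label array ([subfield_codes()]).
#' @return data.frame: subfield, n_voxels, mean_pct_change.
#' @export
subfield_cluster_means <- function(stat, clusters, label_volume) {
  codes <- subfield_codes()
  in_cluster <- clusters$label_volume > 0
  out <- lapply(RIBBON_SUBFIELDS, function(s) {
    vox <- which(in_cluster & label_volume == codes[[s]])
    name <- if (s == "DG_CA4") "DG" else s
    if (!length(vox)) {
      return(data.frame(subfield = name, n_voxels = 0L,
                        mean_pct_change = NA_real_))
    }
    pct <- 100 * stat$contrast_map[vox] / stat$baseline[vox]
    data.frame(subfield = name, n_voxels = length(vox),
               mean_pct_change = mean(pct, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Friedman rank test across subfields
#'
#' Non-parametric repeated-measures test of a subfield effect on a
#' subjects-by-subfields table of signal changes (average ranks for ties;
#' chi-square reference distribution with k - 1 df).
#'
#' @param table numeric matrix or data.frame, subjects x subfields, no
#'   missing cells.
#' @return list with `chi2`, `df`, `p`.
#' @export
friedman_test <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2)
    stopf("friedman_test: need >= 2 subjects and >= 2 subfields")
  if (anyNA(m)) stopf("friedman_test: missing cells are not allowed")
  ft <- stats::friedman.test(m)
  chi2 <- unname(ft$statistic)
  p <- ft$p.value
  ranks <- t(apply(m, 1, rank))
  if (!is.finite(chi2) && all(abs(colMeans(ranks) - (ncol(m) + 1) / 2) < 1e-12)) {
    # fully tied table: no subfield effect, statistic defined as 0
    chi2 <- 0
    p <- 1
  }
  list(chi2 = chi2, df = unname(ft$parameter), p = p)
}
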