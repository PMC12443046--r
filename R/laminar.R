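# Depth-dependent sampling across hippocampal subfields: 20 equidistant
# bins spanning the inner and outer surfaces, extended by 10 bins beyond
# the inner surface (into the SRLM) for Sub/CA1/CA2, anchored at the
# mid-thickness surface. DG/CA4 has no inner/outer boundary and is never
# sampled.

N_BINS_GM <- 20L
N_BINS_EXT <- 10L
N_BINS_TOTAL <- N_BINS_GM + N_BINS_EXT

#' Depth fraction of a bin index
#'
#' Bin 11 (inner surface) maps to 0, bin 30 (outer surface) to 1; the SRLM
#' extension bins 1-10 have negative fractions.
#' @param bin integer bin index (1-30).
#' @return numeric depth fraction.
#' @export
bin_depth_fraction <- function(bin) (bin - 11) / (N_BINS_GM - 1)

#' Lay out equidistant depth-sampling bins between corresponding vertices
#'
#' For each vertex, 20 equidistant sample points are placed on the
#' straight segment from the inner to the outer surface point (bins
#' 11-30). For vertices in Sub/CA1/CA2 the same line is continued beyond
#' the inner surface with the same spacing for 10 further bins (10 down to
#' 1, bin 1 deepest in the SRLM). The mid-thickness point is used as a
#' reference landmark: vertices whose mid point lies farther than
#' `anchor_tol` (fraction of segment length) from the segment midpoint are
#' flagged and excluded, as are degenerate segments (inner == outer).
#'
#' If a subfield label volume is supplied, the inner/outer orientation is
#' auto-detected: the side whose short extension ray hits more SRLM voxels
#' is taken as inner, so swapping the two surface files does not change
#' the output.
#'
#' @param surfaces list with `inner`, `mid`, `outer` (n x 3 world-mm
#'   matrices with index-wise vertex correspondence), e.g.
#'   `phantom$surfaces`.
#' @param subfield_of_vertex character vector of subfield names per vertex.
#' @param anchor_tol mid-anchor tolerance as a fraction of segment length.
#' @param label_volume,affine optional label array + affine for
#'   orientation auto-detection.
#' @return object of class `depth_bins`: `coords` (n_vertex x 30 x 3 array,
#'   NA for absent extension bins), `included` (logical), `spacing_mm` per
#'   vertex, `subfield_of_vertex`, `flipped` (was the orientation swapped).
#' @export
compute_depth_bins <- function(surfaces, subfield_of_vertex, anchor_tol = 0.25,
                               label_volume = NULL, affine = NULL) {
  inner <- surfaces$inner
  outer <- surfaces$outer
  mid <- surfaces$mid
  n <- nrow(inner)
  stopifnot(nrow(outer) == n, nrow(mid) == n, length(subfield_of_vertex) == n)

  seg <- outer - inner
  len <- sqrt(rowSums(seg^2))
  degenerate <- len < 1e-9
  if (any(degenerate))
    warnf("compute_depth_bins: %d degenerate vertices excluded",
          sum(degenerate))
  len_safe <- ifelse(degenerate, 1, len)
  unit <- seg / len_safe
  spacing <- len / (N_BINS_GM - 1)

  flipped <- FALSE
  if (!is.null(label_volume) && !is.null(affine)) {
    srlm_code <- subfield_codes()[["SRLM"]]
    count_srlm_beyond <- function(origin, direction) {
      hits <- 0L
      for (j in 1:5) {
        pts <- origin - direction * (j * spacing)
        vox <- round(world_to_voxel(affine, pts))
        ok <- vox[, 1] >= 1 & vox[, 1] <= dim(label_volume)[1] &
          vox[, 2] >= 1 & vox[, 2] <= dim(label_volume)[2] &
          vox[, 3] >= 1 & vox[, 3] <= dim(label_volume)[3]
        lin <- vox[ok, 1] + (vox[ok, 2] - 1) * dim(label_volume)[1] +
          (vox[ok, 3] - 1) * prod(dim(label_volume)[1:2])
        hits <- hits + sum(label_volume[lin] == srlm_code)
      }
      hits
    }
    beyond_inner <- count_srlm_beyond(inner, unit)
    beyond_outer <- count_srlm_beyond(outer, -unit)
    if (beyond_outer > beyond_inner) {
      flipped <- TRUE
      tmp <- inner; inner <- outer; outer <- tmp
      unit <- -unit
    }
  }

  midpoint <- (inner + outer) / 2
  anchor_dist <- sqrt(rowSums((mid - midpoint)^2))
  anchor_fail <- !degenerate & anchor_dist > anchor_tol * len
  if (any(anchor_fail))
    warnf("compute_depth_bins: %d vertices fail the mid-thickness anchor check",
          sum(anchor_fail))
  included <- !degenerate & !anchor_fail

  coords <- array(NA_real_, c(n, N_BINS_TOTAL, 3))
  for (b in seq_len(N_BINS_TOTAL)) {
    offs <- (b - 11) * spacing
    coords[, b, ] <- inner + unit * offs
  }
  no_ext <- !(subfield_of_vertex %in% EXT_SUBFIELDS)
  coords[no_ext, seq_len(N_BINS_EXT), ] <- NA_real_

  structure(list(coords = coords, included = included, spacing_mm = spacing,
                 subfield_of_vertex = subfield_of_vertex, flipped = flipped,
                 n_excluded = sum(!included),
                 convention = "bin 1 = deepest SRLM extension, 11 = inner, 30 = outer"),
            class = "depth_bins")
}

#' Sample a volume or time series along the depth bins
#'
#' Trilinear interpolation at every bin coordinate; per subfield, values
#' are averaged across that subfield's included vertices at each depth.
#' DG/CA4 vertices are never sampled. Out-of-bounds sample points are
#' flagged and excluded from the averages.
#'
#' @param x a `contrast_series`, or a 3D array (then supply `affine`).
#' @param bins a `depth_bins`.
#' @param affine voxel-to-world matrix (taken from `x` when it is a
#'   series).
#' @param subfields which subfields to sample (defaults to all except
#'   DG/CA4).
#' @return object of class `depth_profiles`: per subfield a list with
#'   `mean` (n_bins x t matrix), `sem` (across vertices), `n_vertices`,
#'   `bins` (bin indices); plus `timestamp_ms`, `contrast`,
#'   `n_out_of_bounds`.
#' @export
sample_profiles <- function(x, bins, affine = NULL,
                            subfields = PROFILE_SUBFIELDS) {
  if (inherits(x, "contrast_series")) {
    data <- x$data
    affine <- affine %||% x$affine
    timestamp_ms <- x$timestamp_ms
    contrast <- x$contrast
  } else {
    data <- if (length(dim(x)) == 3) array(x, c(dim(x), 1)) else x
    timestamp_ms <- (seq_len(dim(data)[4]) - 1) * 0
    contrast <- "volume"
  }
  if (is.null(affine)) stopf("sample_profiles: affine required")
  d <- dim(data)
  mat <- matrix(data, prod(d[1:3]), d[4])
  n_oob <- 0L
  any_sampled <- FALSE
  out <- list()
  for (s in subfields) {
    vsel <- which(bins$subfield_of_vertex == s & bins$included)
    if (!length(vsel)) next
    bin_idx <- if (s %in% EXT_SUBFIELDS) seq_len(N_BINS_TOTAL)
               else (N_BINS_EXT + 1L):N_BINS_TOTAL
    mean_m <- matrix(NA_real_, length(bin_idx), d[4])
    sem_m <- matrix(NA_real_, length(bin_idx), d[4])
    for (bi in seq_along(bin_idx)) {
      pts <- bins$coords[vsel, bin_idx[bi], , drop = FALSE]
      pts <- matrix(pts, ncol = 3)
      vox <- world_to_voxel(affine, pts)
      tw <- trilinear_weights(vox, d[1:3])
      n_oob <- n_oob + sum(!tw$inside)
      vals <- trilinear_apply(tw, mat)       # n_vertex x t
      ok <- tw$inside & !apply(is.na(vals), 1, any)
      if (any(ok)) {
        any_sampled <- TRUE
        vv <- vals[ok, , drop = FALSE]
        mean_m[bi, ] <- colMeans(vv)
        sem_m[bi, ] <- apply(vv, 2, stats::sd) / sqrt(nrow(vv))
      }
    }
    out[[s]] <- list(mean = mean_m, sem = sem_m, n_vertices = length(vsel),
                     bins = bin_idx, depth_frac = bin_depth_fraction(bin_idx))
  }
  if (!any_sampled) stopf("sample_profiles: all sample points out of bounds")
  structure(list(profiles = out, timestamp_ms = timestamp_ms,
                 contrast = contrast, n_out_of_bounds = n_oob,
                 n_bins = vapply(out, function(p) length(p$bins), integer(1))),
            class = "depth_profiles")
}

#' @export
print.depth_profiles <- function(x, ...) {
  cat(sprintf("depth_profiles [%s]: %s\n", x$contrast,
              paste(sprintf("%s(%d bins, %d vertices)", names(x$profiles),
                            x$n_bins,
                            vapply(x$profiles, `[[`, integer(1), "n_vertices")),
                    collapse = ", ")))
  invisible(x)
}

#' z-transform laminar time series against the math-condition baseline
#'
#' Each depth's time series is standardized using the mean and SD of the
#' volumes whose acquisition time falls within a math trial window
#' (onset + `delay_s` to onset + duration + `delay_s`; `delay_s` defaults
#' to 0, i.e. no haemodynamic shift of the baseline window).
#'
#' @param profiles a `depth_profiles` sampled from a time series.
#' @param design a `task_design`.
#' @param delay_s haemodynamic delay added to the math windows, seconds.
#' @return `depth_profiles` with standardized `mean` matrices, the
#'   baseline volume indices in `baseline_volumes`, and rows with zero
#'   baseline SD flagged via `n_zero_sd`.
#' @export
ztransform_profiles <- function(profiles, design, delay_s = 0) {
  t_s <- profiles$timestamp_ms / 1000
  ev <- design$events[design$events$trial_type == "math", , drop = FALSE]
  base <- rep(FALSE, length(t_s))
  for (i in seq_len(nrow(ev))) {
    base <- base | (t_s >= ev$onset[i] + delay_s &
                      t_s <= ev$onset[i] + ev$duration[i] + delay_s)
  }
  if (sum(base) < 2)
    stopf("ztransform_profiles: need >= 2 math-condition volumes")
  n_zero <- 0L
  for (s in names(profiles$profiles)) {
    p <- profiles$profiles[[s]]
    mu <- rowMeans(p$mean[, base, drop = FALSE])
    sd_d <- apply(p$mean[, base, drop = FALSE], 1, stats::sd)
    zero <- !is.na(sd_d) & sd_d == 0
    n_zero <- n_zero + sum(zero)
    sd_d[zero] <- NA_real_
    profiles$profiles[[s]]$mean <- (p$mean - mu) / sd_d
    profiles$profiles[[s]]$sem <- p$sem / sd_d
  }
  profiles$baseline_volumes <- which(base)
  profiles$delay_s <- delay_s
  profiles$n_zero_sd <- n_zero
  profiles$contrast <- paste0(profiles$contrast, "_z")
  profiles
}

#' Depth-wise GLM on laminar profiles
#'
#' OLS per depth bin against the full design matrix; returns the
#' memory - math contrast with its standard error per depth. For profiles
#' sampled from a `vaso_corrected` series the contrast is negated, as in
#' [fit_glm()].
#'
#' @param profiles a `depth_profiles` over time.
#' @param X a `design_matrix` whose rows match the profile timepoints.
#' @return list of class `laminar_fit`: per subfield a data.frame with
#'   bin, depth_frac, contrast, se, intercept.
#' @export
laminar_glm <- function(profiles, X) {
  Xm <- X$matrix
  qrX <- check_design_rank(Xm)
  cvec <- numeric(ncol(Xm))
  cvec[X$task_columns["memory"]] <- 1
  cvec[X$task_columns["math"]] <- -1
  xtx_c <- drop(crossprod(cvec, chol2inv(chol(crossprod(Xm)))) %*% cvec)
  sign <- if (grepl("^vaso_corrected", profiles$contrast)) -1 else 1
  fits <- list()
  for (s in names(profiles$profiles)) {
    p <- profiles$profiles[[s]]
    if (ncol(p$mean) != nrow(Xm))
      stopf("laminar_glm: profile timepoints (%d) != design rows (%d)",
            ncol(p$mean), nrow(Xm))
    Y <- t(p$mean)                          # t x depth
    ok <- !apply(is.na(Y), 2, any)
    beta <- matrix(NA_real_, ncol(Xm), ncol(Y))
    beta[, ok] <- qr.coef(qrX, Y[, ok, drop = FALSE])
    resid <- Y - Xm %*% ifelse(is.na(beta), 0, beta)
    df <- nrow(Xm) - ncol(Xm)
    sigma2 <- colSums(resid^2) / df
    con <- sign * drop(crossprod(cvec, beta))
    se <- sqrt(sigma2 * xtx_c)
    fits[[s]] <- data.frame(bin = p$bins, depth_frac = p$depth_frac,
                            contrast = con, se = se,
                            intercept = beta[1, ])
  }
  structure(list(fits = fits, contrast = profiles$contrast,
                 sign_flipped = sign < 0, df = nrow(Xm) - ncol(Xm)),
            class = "laminar_fit")
}

#' Average laminar contrasts across runs or subjects
#'
#' @param fit_list list of `laminar_fit` objects with matching subfields
#'   and bins.
#' @return list per subfield: data.frame with bin, depth_frac, mean
#'   contrast and SEM across the inputs.
#' @export
average_laminar <- function(fit_list) {
  subf <- names(fit_list[[1]]$fits)
  out <- list()
  for (s in subf) {
    mats <- sapply(fit_list, function(f) f$fits[[s]]$contrast)
    base <- fit_list[[1]]$fits[[s]]
    out[[s]] <- data.frame(bin = base$bin, depth_frac = base$depth_frac,
                           contrast = rowMeans(mats),
                           sem = apply(mats, 1, stats::sd) / sqrt(ncol(mats)))
  }
  out
}
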