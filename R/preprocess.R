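# Demultiplexing, steady-state trimming and BOLD correction by dynamic
# division.

new_contrast_series <- function(data, contrast, timestamp_ms, affine = NULL,
                                voxel_mm = NA_real_, provenance = list()) {
  if (dim(data)[4] != length(timestamp_ms))
    stopf("contrast_series: t-dimension must match timestamps")
  if (any(diff(timestamp_ms) <= 0))
    stopf("contrast_series: timestamps must be strictly increasing")
  structure(list(data = data, contrast = contrast, timestamp_ms = timestamp_ms,
                 affine = affine, voxel_mm = voxel_mm, provenance = provenance),
            class = "contrast_series")
}

#' Construct a contrast series from a plain array
#'
#' Convenience constructor used by tests and when importing external data.
#'
#' @param data 4D numeric array.
#' @param contrast one of "nulled", "notnulled", "vaso_corrected", "bold".
#' @param timestamp_ms per-volume acquisition times; defaults to an evenly
#'   spaced grid.
#' @param affine optional voxel-to-world matrix.
#' @param voxel_mm isotropic voxel size.
#' @return a `contrast_series`.
#' @export
contrast_series <- function(data, contrast = "bold",
                            timestamp_ms = (seq_len(dim(data)[4]) - 1) * 3000,
                            affine = NULL, voxel_mm = NA_real_) {
  contrast <- match.arg(contrast,
                        c("nulled", "notnulled", "vaso_corrected", "bold"))
  new_contrast_series(data, contrast, timestamp_ms, affine, voxel_mm)
}

#' @export
print.contrast_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("contrast_series [%s]: %s grid, %d volumes\n", x$contrast,
              paste(d[1:3], collapse = "x"), d[4]))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' Split an interleaved series into nulled and not-nulled contrasts
#'
#' Volumes are sorted by their contrast tag; a 308-volume interleaved run
#' yields two 154-volume series. Per-volume timestamps are preserved.
#'
#' @param series an `interleaved_series` (tags must strictly alternate,
#'   starting with "nulled", and the volume count must be even).
#' @return list with elements `nulled` and `notnulled` (`contrast_series`).
#' @export
demultiplex <- function(series) {
  tags <- series$contrast_tag
  n <- length(tags)
  if (n %% 2 != 0)
    stopf("demultiplex: volume count must be even (got %d)", n)
  expected <- rep(c("nulled", "notnulled"), n / 2)
  if (!identical(tags, expected))
    stopf("demultiplex: contrast tags must strictly alternate nulled/notnulled")
  if (dim(series$data)[4] != n)
    stopf("demultiplex: tag count does not match t-dimension")
  odd <- seq(1, n, by = 2)
  pick <- function(idx, contrast) {
    new_contrast_series(series$data[, , , idx, drop = FALSE], contrast,
                        series$timestamp_ms[idx], series$affine,
                        series$voxel_mm,
                        provenance = list(n_input_volumes = n))
  }
  list(nulled = pick(odd, "nulled"), notnulled = pick(odd + 1, "notnulled"))
}

#' Reinterleave two contrast series (inverse of [demultiplex()])
#'
#' @param nulled,notnulled matched `contrast_series`.
#' @return an `interleaved_series`.
#' @export
interleave <- function(nulled, notnulled) {
  if (dim(nulled$data)[4] != dim(notnulled$data)[4])
    stopf("interleave: series lengths differ")
  n_pair <- dim(nulled$data)[4]
  d <- dim(nulled$data)[1:3]
  data <- array(0, c(d, 2 * n_pair))
  data[, , , seq(1, 2 * n_pair, by = 2)] <- nulled$data
  data[, , , seq(2, 2 * n_pair, by = 2)] <- notnulled$data
  ts <- numeric(2 * n_pair)
  ts[seq(1, 2 * n_pair, by = 2)] <- nulled$timestamp_ms
  ts[seq(2, 2 * n_pair, by = 2)] <- notnulled$timestamp_ms
  structure(list(data = data,
                 contrast_tag = rep(c("nulled", "notnulled"), n_pair),
                 timestamp_ms = ts, params = NULL, affine = nulled$affine,
                 voxel_mm = nulled$voxel_mm),
            class = "interleaved_series")
}

#' Discard head and tail volumes of a contrast series
#'
#' The first volumes of each contrast are discarded to let magnetization
#' reach a steady state, and the last volumes (used elsewhere for noise
#' estimation) are excluded as well; 154 volumes with the default 2 + 2
#' trim leave 150.
#'
#' @param series a `contrast_series`.
#' @param n_head,n_tail numbers of volumes to drop at either end.
#' @return trimmed `contrast_series` with the trim recorded in provenance.
#' @export
trim_series <- function(series, n_head = 2, n_tail = 2) {
  t_dim <- dim(series$data)[4]
  if (n_head < 0 || n_tail < 0) stopf("trim_series: trim counts must be >= 0")
  if (n_head + n_tail >= t_dim)
    stopf("trim_series: cannot trim %d + %d volumes from a %d-volume series",
          n_head, n_tail, t_dim)
  keep <- seq(n_head + 1, t_dim - n_tail)
  prov <- series$provenance
  prov$n_discarded_head <- n_head
  prov$n_discarded_tail <- n_tail
  new_contrast_series(series$data[, , , keep, drop = FALSE], series$contrast,
                      series$timestamp_ms[keep], series$affine,
                      series$voxel_mm, prov)
}

#' Crop edge slices along one axis
#'
#' Generic counterpart of removing distorted slices at the edge of the
#' acquisition slab. Disabled (0 slices) by default for synthetic data.
#'
#' @param series a `contrast_series`.
#' @param n_edge number of slices to remove from each end of `axis`.
#' @param axis spatial axis (1-3).
#' @return cropped `contrast_series`.
#' @export
crop_slices <- function(series, n_edge = 0, axis = 3) {
  if (n_edge == 0) return(series)
  d <- dim(series$data)
  if (2 * n_edge >= d[axis]) stopf("crop_slices: nothing left after crop")
  keep <- seq(n_edge + 1, d[axis] - n_edge)
  data <- switch(axis,
                 series$data[keep, , , , drop = FALSE],
                 series$data[, keep, , , drop = FALSE],
                 series$data[, , keep, , drop = FALSE])
  prov <- series$provenance
  prov$cropped_slices <- c(axis = axis, n_edge = n_edge)
  new_contrast_series(data, series$contrast, series$timestamp_ms,
                      series$affine, series$voxel_mm, prov)
}

#' BOLD-contamination correction by pairwise dynamic division
#'
#' The k-th nulled volume is divided voxel-wise by the k-th not-nulled
#' volume (no temporal interpolation), cancelling the common BOLD and
#' drift factors and leaving the CBV-weighted signal
#' `1 - cbv * h(t)`. Values outside `clip_range` are clipped; zero or
#' near-zero denominators yield NA and are counted in provenance.
#'
#' @param nulled,notnulled matched `contrast_series` of equal length (the
#'   nulled member of pair k acquired one image TR before the not-nulled).
#' @param clip_range length-2 numeric; ratios are clipped into this range.
#' @param denom_tol absolute magnitude under which a denominator is
#'   treated as zero.
#' @return `contrast_series` with contrast "vaso_corrected"; timestamps
#'   are those of the nulled member (the pair reference time).
#' @export
bold_correct <- function(nulled, notnulled, clip_range = c(0, 5),
                         denom_tol = sqrt(.Machine$double.eps)) {
  if (!identical(dim(nulled$data), dim(notnulled$data)))
    stopf("bold_correct: series dimensions differ")
  den <- notnulled$data
  bad <- abs(den) < denom_tol
  ratio <- nulled$data / den
  ratio[bad] <- NA_real_
  lo <- ratio < clip_range[1] & !is.na(ratio)
  hi <- ratio > clip_range[2] & !is.na(ratio)
  ratio[lo] <- clip_range[1]
  ratio[hi] <- clip_range[2]
  prov <- nulled$provenance
  prov$n_bad_denominator <- sum(bad)
  prov$n_clipped <- sum(lo) + sum(hi)
  prov$clip_range <- clip_range
  prov$pair_offset_ms <- if (length(nulled$timestamp_ms) &&
                             length(notnulled$timestamp_ms))
    notnulled$timestamp_ms[1] - nulled$timestamp_ms[1] else NA_real_
  new_contrast_series(ratio, "vaso_corrected", nulled$timestamp_ms,
                      nulled$affine, nulled$voxel_mm, prov)
}
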