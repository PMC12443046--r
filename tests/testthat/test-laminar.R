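# Depth bins, profile sampling, z-transform, depth-wise GLM.

flat_sheet_surfaces <- function(n = 25, thickness = 4) {
  # parallel horizontal sheets: inner at z = 0, outer at z = thickness
  xy <- as.matrix(expand.grid(x = seq(2, 10, length.out = 5),
                              y = seq(2, 10, length.out = 5)))
  list(inner = cbind(xy, 0), mid = cbind(xy, thickness / 2),
       outer = cbind(xy, thickness))
}

test_that("flat parallel sheets give uniform bin spacing of thickness/19", {
  s <- flat_sheet_surfaces(thickness = 4)
  subf <- rep(c("CA1", "CA3"), length.out = 25)
  bins <- compute_depth_bins(s, subf)
  expect_equal(bins$spacing_mm, rep(4 / 19, 25), tolerance = 1e-12)
  # consecutive bins equidistant along the segment
  v <- 1  # a CA1 vertex with extension
  coords <- bins$coords[v, , ]
  steps <- sqrt(rowSums(diff(coords)^2))
  expect_equal(steps, rep(4 / 19, 29), tolerance = 1e-9)
  # bin 11 = inner point, bin 30 = outer point; extension continues the line
  expect_equal(coords[11, ], unname(s$inner[v, ]))
  expect_equal(coords[30, ], unname(s$outer[v, ]))
  expect_equal(coords[1, 3], -10 * 4 / 19, tolerance = 1e-12)
  # CA3 vertices have no extension bins
  ca3 <- which(subf == "CA3")[1]
  expect_true(all(is.na(bins$coords[ca3, 1:10, ])))
  expect_false(anyNA(bins$coords[ca3, 11:30, ]))
})

test_that("degenerate and anchor-violating vertices are excluded", {
  s <- flat_sheet_surfaces()
  s$outer[3, ] <- s$inner[3, ]          # degenerate
  s$mid[5, 1] <- s$mid[5, 1] + 3        # anchor 3 mm off a 4 mm segment
  subf <- rep("CA1", 25)
  expect_warning(expect_warning(
    bins <- compute_depth_bins(s, subf), "degenerate"), "anchor")
  expect_false(bins$included[3])
  expect_false(bins$included[5])
  expect_true(all(bins$included[-c(3, 5)]))
})

test_that("a linear-in-depth field samples as a linear ramp over bins 11..30", {
  d <- c(24, 24, 24)
  aff <- diag(4)  # world == voxel indices
  vol <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)  # f = z (voxel)
  s <- flat_sheet_surfaces(thickness = 4)
  # place the sheet mid-grid so extension bins stay in bounds
  for (nm in c("inner", "mid", "outer")) s[[nm]][, 3] <- s[[nm]][, 3] + 10
  bins <- compute_depth_bins(s, rep("CA1", 25))
  pr <- sample_profiles(vol, bins, affine = aff)
  prof <- pr$profiles$CA1$mean[, 1]
  expect_equal(prof, 10 + (seq_len(30) - 11) * 4 / 19, tolerance = 1e-9)

  # constant volume -> flat profile; sampling is linear in the input
  pr_c <- sample_profiles(array(7, d), bins, affine = aff)
  expect_equal(pr_c$profiles$CA1$mean[, 1], rep(7, 30))
  pr_lin <- sample_profiles(2 * vol + 3 * array(7, d), bins, affine = aff)
  expect_equal(pr_lin$profiles$CA1$mean[, 1], 2 * prof + 21, tolerance = 1e-9)
})

test_that("out-of-bounds sampling is flagged; full OOB errors", {
  d <- c(24, 24, 24)
  s <- flat_sheet_surfaces(thickness = 4)  # extension dips below z = 1
  bins <- compute_depth_bins(s, rep("CA1", 25))
  pr <- sample_profiles(array(1, d), bins, affine = diag(4))
  expect_gt(pr$n_out_of_bounds, 0)
  far <- lapply(s, function(m) m + 1000)
  bins_far <- compute_depth_bins(far, rep("CA1", 25))
  expect_error(sample_profiles(array(1, d), bins_far, affine = diag(4)),
               "out of bounds")
})

test_that("an impulse layer is localized to within one bin at every depth", {
  ph <- default_phantom()
  bins <- default_bins()
  g <- ph$geometry
  r_in <- g$radius_mm - g$thickness_mm / 2
  dims <- ph$grid_shape
  xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * g$voxel_mm
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(xs, each = dims[1]), times = dims[3]), dims)
  rho <- sqrt(X^2 + Y^2)
  for (dfrac in seq(0.05, 0.95, length.out = 10)) {
    vol <- exp(-(rho - (r_in + dfrac * g$thickness_mm))^2 / (2 * 0.8^2))
    pr <- sample_profiles(vol, bins, affine = ph$affine)
    for (s in names(pr$profiles)) {
      p <- pr$profiles[[s]]
      amax <- p$bins[which.max(p$mean[, 1])]
      expect_lte(abs(amax - round(11 + dfrac * 19)), 1)
    }
  }
})

test_that("orientation is auto-detected from the labels (swap-invariant)", {
  ph <- default_phantom()
  swapped <- ph$surfaces
  tmp <- swapped$inner
  swapped$inner <- swapped$outer
  swapped$outer <- tmp
  bins <- default_bins()
  bins_sw <- compute_depth_bins(swapped, ph$subfield_of_vertex,
                                label_volume = ph$label_volume,
                                affine = ph$affine)
  expect_true(bins_sw$flipped)
  expect_false(bins$flipped)
  expect_equal(bins_sw$coords, bins$coords, tolerance = 1e-9)
})

test_that("z-transform standardizes against math volumes and shifts baselines", {
  run <- noisefree_run()
  noisy <- run$bold
  noisy$data <- noisy$data +
    local_seed(8, array(rnorm(length(noisy$data)), dim(noisy$data)))
  pr <- sample_profiles(noisy, default_bins())
  z <- ztransform_profiles(pr, run$design, delay_s = 0)
  base <- z$baseline_volumes
  expect_gte(length(base), 2)
  for (s in names(z$profiles)) {
    bm <- z$profiles[[s]]$mean[, base]
    expect_equal(rowMeans(bm), rep(0, nrow(bm)), tolerance = 1e-10)
    expect_equal(apply(bm, 1, sd), rep(1, nrow(bm)), tolerance = 1e-10)
  }
  # shift invariance
  shifted <- noisy
  shifted$data <- shifted$data + 55
  z2 <- ztransform_profiles(sample_profiles(shifted, default_bins()),
                            run$design)
  expect_equal(z2$profiles$CA1$mean, z$profiles$CA1$mean, tolerance = 1e-8)
  # delay changes the baseline set and is recorded
  z4 <- ztransform_profiles(pr, run$design, delay_s = 4)
  expect_false(identical(z4$baseline_volumes, z$baseline_volumes))
  expect_equal(z4$delay_s, 4)
})

test_that("noise-free laminar GLM recovers the depth amplitude vectors exactly", {
  run <- noisefree_run()
  ph <- run$phantom
  bins <- default_bins()
  X <- build_design(run$design, NULL, run$pair_s, hp_cutoff_s = NULL)
  fv <- laminar_glm(sample_profiles(run$vaso, bins), X)
  fb <- laminar_glm(sample_profiles(run$bold, bins), X)
  expect_true(fv$sign_flipped)
  for (s in c("Sub", "CA1", "CA2", "CA3")) {
    # trilinear sampling smooths the stepwise voxel profile slightly, so
    # equality is to the sampled (not analytic) amplitude; bias stays < 7%
    expect_lt(profile_bias(fv$fits[[s]]$contrast, ph$truth$cbv_profile[[s]]),
              0.07)
    pct <- fb$fits[[s]]$contrast / fb$fits[[s]]$intercept
    expect_lt(profile_bias(pct, ph$truth$bold_profile[[s]]), 0.07)
  }
  # exactness of the GLM itself: refit on the sampled profiles' own values
  pv <- sample_profiles(run$vaso, bins)
  h <- task_regressor(run$design$events, run$pair_s, "memory")
  for (s in c("CA1", "CA3")) {
    direct <- apply(pv$profiles[[s]]$mean, 1, function(y) {
      -stats::coef(stats::lm(y ~ h))[2]
    })
    expect_equal(unname(fv$fits[[s]]$contrast), unname(direct),
                 tolerance = 1e-9)
  }
  # profiles orthogonal to the task fit to ~0 at all depths
  flat <- pv
  for (s in names(flat$profiles)) {
    flat$profiles[[s]]$mean[] <- 3
  }
  f0 <- laminar_glm(flat, X)
  expect_lt(max(abs(f0$fits$CA1$contrast)), 1e-12)
})

test_that("BOLD and VASO peaks dissociate across depth as simulated", {
  run <- noisefree_run()
  ph <- run$phantom
  bins <- default_bins()
  X <- build_design(run$design, NULL, run$pair_s, hp_cutoff_s = NULL)
  fv <- laminar_glm(sample_profiles(run$vaso, bins), X)
  fb <- laminar_glm(sample_profiles(run$bold, bins), X)
  for (s in c("Sub", "CA1")) {
    bold_peak <- fb$fits[[s]]$bin[which.max(fb$fits[[s]]$contrast)]
    vaso_peak <- fv$fits[[s]]$bin[which.max(fv$fits[[s]]$contrast)]
    expect_lte(abs(bold_peak - 10), 1)  # SRLM/inner border
    expect_lte(abs(vaso_peak - 20), 1)  # mid-depth grey matter
    expect_gt(abs(bold_peak - vaso_peak), 5)
  }
})

test_that("average_laminar pools runs with SEM", {
  run <- noisefree_run()
  bins <- default_bins()
  X <- build_design(run$design, NULL, run$pair_s, hp_cutoff_s = NULL)
  f <- laminar_glm(sample_profiles(run$bold, bins), X)
  avg <- average_laminar(list(f, f))
  expect_equal(avg$CA1$contrast, unname(f$fits$CA1$contrast))
  expect_equal(avg$CA1$sem, rep(0, 30))
})
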