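# HRF, design matrix, OLS fitting, clusters, subfield means, Friedman test.

test_that("canonical HRF starts at zero, peaks at 1 near 5-6 s, integrates > 0", {
  h <- canonical_hrf(0.1)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_true(abs(which.max(h) * 0.1 - 5.5) < 1.5)
  expect_gt(sum(h) * 0.1, 0)  # quadrature
  expect_error(canonical_hrf(0), "dt_s")
})

test_that("design matrix has 2 task + 16 nuisance columns plus drift", {
  des <- make_task_design(15)
  ts_s <- seq(0, 894, by = 6)  # 150 retained pair times
  ph <- small_phantom()
  arr <- local_seed(2, array(rnorm(32^3 * 150, 100, 1), c(32, 32, 32, 150)))
  ac <- acompcor(arr, phantom_mask(ph, "wm"), phantom_mask(ph, "csf"), 5)
  ns <- nuisance_set(ac, make_motion_params(150, 1))
  X <- build_design(des, ns, ts_s, 128)
  expect_equal(sum(grepl("comp|trans|rot", X$names)), 16)
  expect_equal(ncol(X$matrix), 1 + 2 + X$n_dct + 16)
  # DCT count oracle: floor(2 * T / cutoff)
  expect_equal(X$n_dct, floor(2 * (150 * 6) / 128))
  expect_equal(unname(X$matrix[, "memory"] != 0),
               task_regressor(des$events, ts_s, "memory") != 0)
})

test_that("design rejects all-zero task columns and truncates late events", {
  empty <- make_task_design(1)
  empty$events <- empty$events[0, ]
  expect_error(build_design(empty, NULL, seq(0, 100, 2)), "all-zero")
  late <- make_task_design(2)
  late$events$onset <- late$events$onset + 1000
  expect_warning(
    expect_error(build_design(late, NULL, seq(0, 120, 6)), "all-zero"),
    "truncated")
})

test_that("noise-free GLM recovers the simulated BOLD amplitude to < 1e-6", {
  run <- noisefree_run()
  ph <- run$phantom
  X <- build_design(run$design, NULL, run$pair_s, hp_cutoff_s = NULL)
  gm <- phantom_mask(ph, "gm")
  stat <- fit_glm(run$bold, X, gm)
  # voxel-level check against the exact forward amplitude (beta / baseline)
  beta_mem <- stat$beta[X$task_columns["memory"], ]
  base <- stat$beta[1, ]
  vox_ids <- match(ph$signal_vox, stat$voxels)
  sel <- which(ph$vox_subfield == "CA1" & ph$vox_bin %in% c(5, 10, 20, 30))
  for (i in sel[seq(1, length(sel), length.out = 20)]) {
    amp <- ph$truth$bold_profile$CA1[ph$vox_bin[i]]
    est <- beta_mem[vox_ids[i]] / base[vox_ids[i]]
    expect_lt(abs(est - amp) / max(amp, 1e-12), 1e-6)
  }
  # residuals orthogonal to every design column
  Y <- t(matrix(run$bold$data, prod(dim(run$bold$data)[1:3]), 150))
  resid <- Y[, stat$voxels[1:50]] - X$matrix %*% stat$beta[, 1:50]
  expect_lt(max(abs(crossprod(X$matrix, resid))), 1e-6)
})

test_that("VASO contrast sign is flipped at reporting", {
  run <- noisefree_run()
  X <- build_design(run$design, NULL, run$pair_s, hp_cutoff_s = NULL)
  gm <- phantom_mask(run$phantom, "subfields")
  stat <- fit_glm(run$vaso, X, gm)
  expect_true(stat$provenance$sign_flipped)
  # CBV response is positive after the flip
  vox <- run$phantom$signal_vox[run$phantom$vox_subfield == "CA1" &
                                  run$phantom$vox_bin == 20][1]
  expect_gt(stat$contrast_map[vox], 0)
})

test_that("series orthogonal to the task gives ~zero contrast; rank errors name columns", {
  des <- make_task_design(2)
  ts_s <- seq(0, 118, by = 2)
  X <- build_design(des, NULL, ts_s, hp_cutoff_s = NULL)
  flat <- contrast_series(array(5, c(3, 3, 3, 60)), "bold",
                          timestamp_ms = ts_s * 1000)
  stat <- fit_glm(flat, X)
  expect_lt(max(abs(stat$contrast_map)), 1e-10)

  Xdup <- X
  Xdup$matrix <- cbind(X$matrix, memory_copy = X$matrix[, "memory"])
  Xdup$names <- colnames(Xdup$matrix)
  expect_error(fit_glm(flat, Xdup), "memory")
  expect_error(fit_glm(contrast_series(array(1, c(3, 3, 3, 10))), X),
               "design rows")
})

test_that("drift with period > 128 s barely changes the task contrast", {
  run <- noisefree_run()
  ph <- run$phantom
  des <- run$design
  ser_drift <- simulate_interleaved(ph, des, acquisition_params(), seed = 1,
                                    noise_sd = 0, drift = TRUE)
  dm <- demultiplex(ser_drift)
  bold_d <- trim_series(dm$notnulled)
  bold_d$contrast <- "bold"
  X <- build_design(des, NULL, run$pair_s, hp_cutoff_s = 128)
  gm <- phantom_mask(ph, "gm")
  ref <- fit_glm(run$bold, X, gm)
  drift <- fit_glm(bold_d, X, gm)
  vox <- ph$signal_vox[ph$vox_subfield == "CA1" & ph$vox_bin == 20]
  vox <- vox[seq_len(min(20, length(vox)))]
  rel <- abs(drift$contrast_map[vox] - ref$contrast_map[vox]) /
    abs(ref$contrast_map[vox])
  expect_lt(max(rel), 0.01)
})

test_that("cluster extent thresholding matches a flood-fill oracle", {
  d <- c(12, 12, 12)
  tmap <- array(0, d)
  # two separated blobs of 25 voxels and one of 19
  blob <- function(tm, corner, n) {
    idx <- which(array(TRUE, d))
    ijk <- arrayInd(idx, d)
    sel <- ijk[, 1] >= corner[1] & ijk[, 1] < corner[1] + 3 &
      ijk[, 2] >= corner[2] & ijk[, 2] < corner[2] + 3 &
      ijk[, 3] >= corner[3] & ijk[, 3] < corner[3] + 3
    tm[idx[sel][1:n]] <- 10
    tm
  }
  tmap <- blob(tmap, c(1, 1, 1), 25)
  tmap <- blob(tmap, c(8, 8, 8), 25)
  tmap <- blob(tmap, c(1, 8, 1), 19)
  stat <- structure(list(t_map = tmap, df = 100), class = "stat_map")
  gm <- array(TRUE, d)
  cl <- cluster_threshold(stat, p_unc = 0.001, k = 20, gm_mask = gm)
  expect_equal(nrow(cl$table), 2)
  expect_equal(sort(cl$table$size), c(25, 25))

  # oracle: recursive flood fill with 18-connectivity on the same mask
  flood_sizes <- function(mask) {
    d <- dim(mask)
    seen <- array(FALSE, d)
    sizes <- integer(0)
    for (v in which(mask)) {
      if (seen[v]) next
      stack <- v; n <- 0L
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (seen[cur]) next
        seen[cur] <- TRUE; n <- n + 1L
        ijk <- arrayInd(cur, d)
        for (o in seq_len(nrow(offsets_18))) {
          q <- ijk + offsets_18[o, ]
          if (all(q >= 1) && all(q <= d)) {
            lin <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
            if (mask[lin] && !seen[lin]) stack <- c(stack, lin)
          }
        }
      }
      sizes <- c(sizes, n)
    }
    sizes
  }
  oracle <- flood_sizes(tmap > stats::qt(1 - 0.001, 100))
  expect_equal(sort(oracle), c(19, 25, 25))
  expect_equal(sort(cl$table$size), sort(oracle[oracle >= 20]))

  # p = 1 labels every in-mask voxel
  all_cl <- cluster_threshold(stat, p_unc = 1, k = 1, gm_mask = gm)
  expect_equal(sum(all_cl$label_volume > 0), sum(gm))
  expect_error(cluster_threshold(stat, 0.05, 20, array(FALSE, d)), "empty")
})

test_that("subfield means report percent change and mark missing overlaps", {
  d <- c(6, 6, 6)
  lab <- array(0L, d)
  codes <- subfield_codes()
  lab[1:2, , ] <- codes[["Sub"]]
  lab[3:4, , ] <- codes[["CA1"]]
  lab[5, , ] <- codes[["DG_CA4"]]
  contrast <- array(1, d)
  baseline <- array(100, d)
  clusters <- list(label_volume = array(1L, d))
  stat <- structure(list(contrast_map = contrast, baseline = baseline),
                    class = "stat_map")
  tab <- subfield_cluster_means(stat, clusters, lab)
  expect_identical(tab$subfield, c("Sub", "CA1", "CA2", "CA3", "DG"))
  expect_equal(tab$mean_pct_change[tab$subfield == "Sub"], 1)
  expect_true(is.na(tab$mean_pct_change[tab$subfield == "CA3"]))
  expect_equal(tab$n_voxels[tab$subfield == "CA3"], 0L)
})

test_that("recovered subfield ordering matches distinct simulated amplitudes", {
  # constant per-subfield BOLD amplitudes with a known ordering
  amps <- c(Sub = 0.004, CA1 = 0.016, CA2 = 0.008, CA3 = 0.020, DG_CA4 = 0.012)
  tr <- ground_truth(noise_sd = 0, drift_coeffs = c(0, 0))
  for (s in names(amps)) {
    n <- length(tr$bold_profile[[s]])
    tr$bold_profile[[s]] <- rep(amps[[s]], n)
    tr$cbv_profile[[s]] <- rep(0.001, n)
  }
  ph <- small_phantom(truth = tr)
  des <- make_task_design(4)
  par <- acquisition_params(n_timepoints = 80)
  ser <- simulate_interleaved(ph, des, par, noise_sd = 0, drift = FALSE)
  dm <- demultiplex(ser)
  bold <- dm$notnulled
  bold$contrast <- "bold"
  X <- build_design(des, NULL, dm$nulled$timestamp_ms / 1000,
                    hp_cutoff_s = NULL)
  gm <- phantom_mask(ph, "subfields")
  stat <- fit_glm(bold, X, gm)
  cl <- cluster_threshold(stat, 0.05, 20, gm)
  tab <- subfield_cluster_means(stat, cl, ph$label_volume)
  expect_false(anyNA(tab$mean_pct_change))
  got_order <- tab$subfield[order(tab$mean_pct_change)]
  want_order <- c("Sub", "CA2", "DG", "CA1", "CA3")
  expect_identical(got_order, want_order)
  expect_equal(tab$mean_pct_change[tab$subfield == "CA3"], 100 * 0.020,
               tolerance = 0.05)
})

test_that("Friedman test matches a direct rank-sum oracle", {
  expect_equal(friedman_test(matrix(5, 4, 3))$chi2, 0)

  m <- matrix(c(1, 2, 3,
                2, 3, 1,
                1, 3, 2), 3, 3, byrow = TRUE)
  got <- friedman_test(m)
  # oracle: chi2 = 12/(n k (k+1)) * sum Rj^2 - 3 n (k+1), no ties here
  rj <- colSums(t(apply(m, 1, rank)))
  chi2 <- 12 / (3 * 3 * 4) * sum(rj^2) - 3 * 3 * 4
  expect_equal(got$chi2, chi2)
  expect_equal(got$df, 2)
  expect_equal(got$p, stats::pchisq(chi2, 2, lower.tail = FALSE))

  m6 <- matrix(rnorm(36), 6, 6)
  expect_equal(friedman_test(m6)$df, 5)
  expect_error(friedman_test(m6[1, , drop = FALSE]), ">= 2")
  m6[2, 3] <- NA
  expect_error(friedman_test(m6), "missing")
})
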