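# End-to-end pipeline: simulate -> preprocess -> qc -> nuisance -> glm ->
# laminar, with a JSON manifest capturing every decision value.

#' Pipeline configuration
#'
#' All numeric defaults equal the published analysis choices where one
#' exists: 2 + 2 volume trim per contrast, 5 aCompCor components per
#' tissue, Gaussian erosion sigma 0.8 mm, 128 s high-pass cut-off,
#' cluster extent 20 voxels, 20 depth bins + 10 SRLM extension bins.
#'
#' @param out_dir output directory (NULL for in-memory only).
#' @param grid_shape phantom grid.
#' @param geometry,truth,params phantom/simulation parameter objects.
#' @param seed master seed; stage seeds are derived from it.
#' @param n_trials trials per condition.
#' @param n_head,n_tail steady-state / noise-volume trim counts.
#' @param n_compcor aCompCor components per tissue.
#' @param erode_sigma_mm,erode_threshold mask erosion parameters.
#' @param hp_cutoff_s GLM high-pass cut-off, seconds.
#' @param cluster_p,cluster_k cluster-forming p and extent threshold.
#' @param delay_s z-transform baseline haemodynamic delay.
#' @param crop_edge_slices slices cropped from each slab edge (0 for
#'   synthetic data).
#' @param stages named logical toggles (simulate, preprocess, qc,
#'   nuisance, glm, laminar).
#' @param write_volumes write NIfTI series/maps under `out_dir` (volumes
#'   are large; tables and the manifest are always written when `out_dir`
#'   is set).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, grid_shape = c(48, 48, 48),
                            geometry = hippo_geometry(),
                            truth = ground_truth(),
                            params = acquisition_params(), seed = 1,
                            n_trials = 15, n_head = 2, n_tail = 2,
                            n_compcor = 5, erode_sigma_mm = 0.8,
                            erode_threshold = 0.9, hp_cutoff_s = 128,
                            cluster_p = 0.05, cluster_k = 20, delay_s = 0,
                            crop_edge_slices = 0,
                            stages = c(simulate = TRUE, preprocess = TRUE,
                                       qc = TRUE, nuisance = TRUE, glm = TRUE,
                                       laminar = TRUE),
                            write_volumes = TRUE) {
  cfg <- list(out_dir = out_dir, grid_shape = grid_shape, geometry = geometry,
              truth = truth, params = params, seed = as.integer(seed),
              n_trials = n_trials, n_head = n_head, n_tail = n_tail,
              n_compcor = n_compcor, erode_sigma_mm = erode_sigma_mm,
              erode_threshold = erode_threshold, hp_cutoff_s = hp_cutoff_s,
              cluster_p = cluster_p, cluster_k = cluster_k, delay_s = delay_s,
              crop_edge_slices = crop_edge_slices, stages = stages,
              write_volumes = write_volumes)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg$params, "acquisition_params"),
            cfg$n_head >= 0, cfg$n_tail >= 0, cfg$n_compcor >= 1,
            cfg$hp_cutoff_s > 0, cfg$cluster_k >= 1,
            cfg$cluster_p > 0, cfg$cluster_p <= 1)
  needed <- c("simulate", "preprocess", "qc", "nuisance", "glm", "laminar")
  if (!all(needed %in% names(cfg$stages)))
    stopf("pipeline_config: stages must name %s", paste(needed, collapse = ", "))
  cfg
}

#' Load a pipeline configuration from a JSON file
#'
#' JSON is YAML-compatible key/value; only scalar overrides of
#' [pipeline_config()] arguments are supported (grid_shape, seed, trims,
#' thresholds, stage toggles, out_dir, n_timepoints, rf_power_scale).
#'
#' @param path JSON config file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- acquisition_params(
    n_timepoints = j$n_timepoints %||% 308,
    rf_power_scale = j$rf_power_scale %||% 3)
  args <- j[names(j) %in% c("out_dir", "grid_shape", "seed", "n_trials",
                            "n_head", "n_tail", "n_compcor", "erode_sigma_mm",
                            "erode_threshold", "hp_cutoff_s", "cluster_p",
                            "cluster_k", "delay_s", "crop_edge_slices",
                            "write_volumes")]
  args$params <- params
  if (!is.null(j$stages)) args$stages <- unlist(j$stages)
  do.call(pipeline_config, args)
}

write_if <- function(cfg, fn) if (!is.null(cfg$out_dir)) fn()

#' Run the full synthetic-to-laminar pipeline
#'
#' Executes the enabled stages in order: phantom simulation, demultiplexing
#' + trimming + BOLD correction, tSNR QC, aCompCor nuisance extraction,
#' voxel-wise GLM with cluster thresholding and subfield means, and
#' laminar profile extraction with the math-referenced z-transform and
#' depth-wise GLM. When `out_dir` is set, writes NIfTI volumes (optional),
#' GIFTI surfaces, TSV tables and a `manifest.json` recording seeds,
#' decision values and volume accounting. Reruns with the same
#' configuration are bit-identical.
#'
#' @param cfg a `pipeline_config`.
#' @return list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  res <- list(config = cfg)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hippovaso")),
    seed = cfg$seed,
    decisions = list(n_head = cfg$n_head, n_tail = cfg$n_tail,
                     n_compcor_per_tissue = cfg$n_compcor,
                     erode_sigma_mm = cfg$erode_sigma_mm,
                     erode_threshold = cfg$erode_threshold,
                     hp_cutoff_s = cfg$hp_cutoff_s,
                     cluster_p = cfg$cluster_p, cluster_k = cfg$cluster_k,
                     delay_s = cfg$delay_s,
                     crop_edge_slices = cfg$crop_edge_slices,
                     n_depth_bins = N_BINS_GM, n_srlm_bins = N_BINS_EXT,
                     vaso_sign_flip = TRUE))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      if (!is.null(cfg$out_dir))
        file.create(file.path(cfg$out_dir, paste0(name, ".partial")))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- simulate -------------------------------------------------------
  if (!cfg$stages[["simulate"]]) {
    stopf("run_pipeline: external inputs are not supported; enable simulate")
  }
  run_stage("simulate", {
    res$phantom <- build_phantom(cfg$grid_shape, cfg$geometry, cfg$truth,
                                 seed = cfg$seed)
    res$design <- make_task_design(cfg$n_trials, order_seed = cfg$seed + 1)
    res$series <- simulate_interleaved(res$phantom, res$design, cfg$params,
                                       seed = cfg$seed + 2)
    res$motion <- make_motion_params(cfg$params$n_timepoints / 2,
                                     seed = cfg$seed + 3)
    manifest$n_timepoints <- cfg$params$n_timepoints
    manifest$run_duration_min <- run_duration_min(cfg$params)
    write_if(cfg, function() {
      write_events(res$design$events, file.path(cfg$out_dir, "events.tsv"))
      write_tsv_matrix(res$motion, file.path(cfg$out_dir, "motion.tsv"))
      write_nifti(res$phantom$label_volume,
                  file.path(cfg$out_dir, "labels.nii.gz"),
                  res$phantom$affine, datatype = "int16")
      for (s in c("inner", "mid", "outer")) {
        write_gifti_surface(res$phantom$surfaces[[s]],
                            res$phantom$surfaces$faces,
                            file.path(cfg$out_dir, sprintf("%s.surf.gii", s)))
      }
      jsonlite::write_json(
        list(contrast_tag = res$series$contrast_tag,
             timestamp_ms = res$series$timestamp_ms,
             truth = res$phantom$truth[c("drift_coeffs", "noise_sd",
                                         "inflow_amplitude")]),
        file.path(cfg$out_dir, "series.json"), auto_unbox = TRUE, digits = NA)
      if (cfg$write_volumes)
        write_nifti(res$series$data, file.path(cfg$out_dir, "series.nii.gz"),
                    res$phantom$affine,
                    tr_s = cfg$params$tr_image_ms / 1000)
    })
    res
  }) -> res

  # --- preprocess -----------------------------------------------------
  if (cfg$stages[["preprocess"]]) {
    res <- run_stage("preprocess", {
      dm <- demultiplex(res$series)
      res$nulled <- trim_series(crop_slices(dm$nulled, cfg$crop_edge_slices),
                                cfg$n_head, cfg$n_tail)
      res$bold <- trim_series(crop_slices(dm$notnulled, cfg$crop_edge_slices),
                              cfg$n_head, cfg$n_tail)
      res$bold$contrast <- "bold"
      res$vaso <- bold_correct(res$nulled, res$bold)
      manifest$volumes_per_contrast_raw <- dim(dm$nulled$data)[4]
      manifest$volumes_per_contrast <- dim(res$nulled$data)[4]
      manifest$bold_correct_provenance <- res$vaso$provenance
      write_if(cfg, function() {
        if (cfg$write_volumes) {
          for (nm in c("nulled", "bold", "vaso"))
            write_nifti(res[[nm]]$data,
                        file.path(cfg$out_dir, sprintf("%s.nii.gz", nm)),
                        res$phantom$affine)
        }
      })
      res
    })
    # keep only trimmed motion rows matching the retained volumes
    keep <- seq(cfg$n_head + 1, cfg$params$n_timepoints / 2 - cfg$n_tail)
    res$motion_trimmed <- res$motion[keep, , drop = FALSE]
  }

  # --- qc -------------------------------------------------------------
  if (cfg$stages[["qc"]]) {
    res <- run_stage("qc", {
      gm <- phantom_mask(res$phantom, "gm")
      res$tsnr_bold <- tsnr(res$bold, gm)
      res$tsnr_nulled <- tsnr(res$nulled, gm)
      manifest$tsnr <- list(bold = res$tsnr_bold$summary,
                            nulled = res$tsnr_nulled$summary)
      write_if(cfg, function() {
        if (cfg$write_volumes) {
          write_nifti(res$tsnr_bold$data,
                      file.path(cfg$out_dir, "tsnr_bold.nii.gz"),
                      res$phantom$affine)
        }
      })
      res
    })
  }

  # --- nuisance -------------------------------------------------------
  if (cfg$stages[["nuisance"]]) {
    res <- run_stage("nuisance", {
      wm <- erode_mask(phantom_mask(res$phantom, "wm"), cfg$erode_sigma_mm,
                       cfg$erode_threshold, res$phantom$voxel_mm)
      csf <- erode_mask(phantom_mask(res$phantom, "csf"), cfg$erode_sigma_mm,
                        cfg$erode_threshold, res$phantom$voxel_mm)
      res$nuisance <- list(
        bold = nuisance_set(acompcor(res$bold, wm, csf, cfg$n_compcor),
                            res$motion_trimmed),
        vaso = nuisance_set(acompcor(res$vaso, wm, csf, cfg$n_compcor),
                            res$motion_trimmed))
      manifest$n_nuisance_columns <- ncol(res$nuisance$bold$matrix)
      write_if(cfg, function() {
        write_tsv_matrix(res$nuisance$bold$matrix,
                         file.path(cfg$out_dir, "nuisance_bold.tsv"))
        write_tsv_matrix(res$nuisance$vaso$matrix,
                         file.path(cfg$out_dir, "nuisance_vaso.tsv"))
      })
      res
    })
  }

  # --- glm ------------------------------------------------------------
  if (cfg$stages[["glm"]]) {
    res <- run_stage("glm", {
      ts_s <- res$nulled$timestamp_ms / 1000   # pair reference times
      gm <- phantom_mask(res$phantom, "gm")
      res$stats <- list()
      res$clusters <- list()
      res$subfield_means <- list()
      for (con in c("bold", "vaso")) {
        X <- build_design(res$design, res$nuisance[[con]], ts_s,
                          cfg$hp_cutoff_s)
        stat <- fit_glm(res[[con]], X, gm)
        cl <- cluster_threshold(stat, cfg$cluster_p, cfg$cluster_k, gm)
        res$stats[[con]] <- stat
        res$clusters[[con]] <- cl
        res$subfield_means[[con]] <-
          subfield_cluster_means(stat, cl, res$phantom$label_volume)
        res$designs[[con]] <- X
      }
      manifest$design_columns <- ncol(res$designs$bold$matrix)
      manifest$glm <- list(df = res$stats$bold$df,
                           n_clusters = vapply(res$clusters,
                                               function(c) nrow(c$table),
                                               integer(1)))
      write_if(cfg, function() {
        for (con in c("bold", "vaso")) {
          write_tsv_matrix(res$clusters[[con]]$table,
                           file.path(cfg$out_dir,
                                     sprintf("clusters_%s.tsv", con)))
          write_tsv_matrix(res$subfield_means[[con]],
                           file.path(cfg$out_dir,
                                     sprintf("subfield_means_%s.tsv", con)))
          if (cfg$write_volumes) {
            write_nifti(res$stats[[con]]$t_map,
                        file.path(cfg$out_dir, sprintf("tmap_%s.nii.gz", con)),
                        res$phantom$affine)
          }
        }
      })
      res
    })
  } else {
    manifest$skipped_glm <- TRUE
  }

  # --- laminar --------------------------------------------------------
  if (cfg$stages[["laminar"]]) {
    res <- run_stage("laminar", {
      res$bins <- compute_depth_bins(res$phantom$surfaces,
                                     res$phantom$subfield_of_vertex,
                                     label_volume = res$phantom$label_volume,
                                     affine = res$phantom$affine)
      res$profiles <- list(bold = sample_profiles(res$bold, res$bins),
                           vaso = sample_profiles(res$vaso, res$bins))
      res$profiles_z <- lapply(res$profiles, ztransform_profiles,
                               design = res$design, delay_s = cfg$delay_s)
      ts_s <- res$nulled$timestamp_ms / 1000
      res$laminar <- list()
      for (con in c("bold", "vaso")) {
        X <- if (!is.null(res$designs[[con]])) res$designs[[con]]
             else build_design(res$design, res$nuisance[[con]], ts_s,
                               cfg$hp_cutoff_s)
        res$laminar[[con]] <- laminar_glm(res$profiles[[con]], X)
      }
      manifest$laminar <- list(n_excluded_vertices = res$bins$n_excluded,
                               orientation_flipped = res$bins$flipped)
      write_if(cfg, function() {
        for (con in c("bold", "vaso")) {
          for (s in names(res$laminar[[con]]$fits)) {
            write_tsv_matrix(res$laminar[[con]]$fits[[s]],
                             file.path(cfg$out_dir,
                                       sprintf("laminar_%s_%s.tsv", con, s)))
          }
        }
      })
      res
    })
  } else {
    manifest$skipped_laminar <- TRUE
  }

  res$manifest <- manifest
  if (!is.null(cfg$out_dir)) {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
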