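# Synthetic hippocampal phantom: a folded (C-shaped) three-layer ribbon with
# subfield bands along its length, an SRLM band beyond the inner surface,
# WM/CSF compartments and a small vessel cluster, plus corresponding
# inner/mid/outer surface meshes with vertex-wise correspondence.

#' Subfield and tissue label codes used by the phantom
#'
#' @return named integer vector of label codes.
#' @export
subfield_codes <- function() {
  c(background = 0L, Sub = 1L, CA1 = 2L, CA2 = 3L, CA3 = 4L,
    DG_CA4 = 5L, SRLM = 6L, WM = 7L, CSF = 8L, vessel = 9L)
}

# subfields that receive the 10 SRLM extension bins
EXT_SUBFIELDS <- c("Sub", "CA1", "CA2")
# subfields along the ribbon, in order along the arc
RIBBON_SUBFIELDS <- c("Sub", "CA1", "CA2", "CA3", "DG_CA4")
# subfields with laminar profiles (DG/CA4 has no inner/outer boundary)
PROFILE_SUBFIELDS <- c("Sub", "CA1", "CA2", "CA3")

#' Geometry parameters of the phantom ribbon
#'
#' The hippocampal grey-matter sheet is modelled as a C-shaped ribbon: an
#' arc of radius `radius_mm` in the x-y plane, extruded along z, with
#' grey matter between `radius_mm - thickness_mm/2` (inner surface) and
#' `radius_mm + thickness_mm/2` (outer surface). Subfield bands
#' (Sub, CA1, CA2, CA3, DG/CA4) partition the arc. A thin SRLM band sits
#' just beyond the inner surface under Sub/CA1/CA2; its radial extent is
#' 13/19 of the thickness so that the 10 SRLM extension bins used by the
#' laminar sampler stay inside it with margin for trilinear support. White matter wraps the outer surface,
#' CSF fills the core of the C, and a small vessel cluster sits in the core.
#'
#' @param radius_mm mid-thickness radius of the ribbon.
#' @param thickness_mm inner-to-outer grey-matter thickness.
#' @param z_half_mm half-extent of the ribbon along z.
#' @param arc_start_deg,arc_deg start angle and angular span of the C arc.
#' @param wm_mm radial thickness of the white-matter shell (thick enough
#'   to survive Gaussian erosion at threshold 0.9 with sigma 0.8 mm).
#' @param csf_radius_mm radius of the central CSF core.
#' @param vessel_radius_mm,vessel_z_mm extent of the vessel cluster.
#' @param voxel_mm isotropic voxel edge length.
#' @param band_fractions named fractions of the arc per subfield.
#' @param boundary_margin_mm surface vertices closer than this arc
#'   distance to a subfield band boundary are marked "boundary" and
#'   excluded from profile averaging, so trilinear partial-volume mixing
#'   across subfield borders does not contaminate narrow subfields.
#' @return list of geometry parameters.
#' @export
hippo_geometry <- function(radius_mm = 11, thickness_mm = 6.4, z_half_mm = 11,
                           arc_start_deg = 105, arc_deg = 250, wm_mm = 4,
                           csf_radius_mm = 3, vessel_radius_mm = 1.3,
                           vessel_z_mm = 2, voxel_mm = 0.8,
                           band_fractions = c(Sub = 0.25, CA1 = 0.30, CA2 = 0.10,
                                              CA3 = 0.15, DG_CA4 = 0.20),
                           boundary_margin_mm = 1.0) {
  stopifnot(abs(sum(band_fractions) - 1) < 1e-8,
            identical(names(band_fractions), RIBBON_SUBFIELDS))
  list(radius_mm = radius_mm, thickness_mm = thickness_mm, z_half_mm = z_half_mm,
       arc_start_deg = arc_start_deg, arc_deg = arc_deg, wm_mm = wm_mm,
       csf_radius_mm = csf_radius_mm, vessel_radius_mm = vessel_radius_mm,
       vessel_z_mm = vessel_z_mm, voxel_mm = voxel_mm,
       # radial SRLM extent: the 10 extension bins (10/19 of thickness) plus
       # ~3 bins of margin so trilinear sampling at the deepest bin stays
       # inside the band
       srlm_mm = thickness_mm * 13 / 19,
       band_fractions = band_fractions,
       boundary_margin_mm = boundary_margin_mm)
}

gauss_bump <- function(d, center, width) exp(-(d - center)^2 / (2 * width^2))

#' Ground-truth laminar response amplitudes and noise model
#'
#' Fractional response amplitudes per depth bin for each subfield, for the
#' CBV (VASO) and BOLD forward models. Depth bins follow the laminar
#' sampling convention: bin 1 = deepest SRLM extension point, bin 11 =
#' inner surface, bin 30 = outer surface; CA3 and DG/CA4 have no SRLM
#' extension and use bins 11-30 only (length-20 vectors).
#'
#' Defaults emulate the qualitative laminar dissociation seen in
#' high-resolution hippocampal fMRI: BOLD, biased by draining veins,
#' peaks at the SRLM/inner-surface border in Sub and CA1 and towards the
#' outer surface in CA2/CA3, whereas the microvascular CBV response peaks
#' at mid-depth grey matter. Peak fractional amplitudes are ~2% (BOLD) and
#' ~1% (CBV), typical for a 0.8 mm block-design acquisition at 7 T.
#' `noise_sd = 5` on a grey-matter baseline of 100 corresponds to a
#' thermal tSNR of 20 (an effective, post-denoising level). Drift is a
#' slow multiplicative polynomial; `inflow_amplitude` is the nulled-volume
#' signal excess of vessel voxels at zero inversion efficiency.
#'
#' @param bold_scale,cbv_scale multipliers on the default peak amplitudes.
#' @param noise_sd Gaussian thermal noise SD (signal units).
#' @param drift_coeffs linear and quadratic drift coefficients (fractional).
#' @param inflow_amplitude vessel inflow signal excess at zero efficiency.
#' @return list with `cbv_profile`, `bold_profile` (named lists of numeric
#'   vectors), `drift_coeffs`, `noise_sd`, `inflow_amplitude`, `baseline`.
#' @export
ground_truth <- function(bold_scale = 1, cbv_scale = 1, noise_sd = 5,
                         drift_coeffs = c(0.02, 0.01), inflow_amplitude = 30) {
  d30 <- 1:30
  d20 <- 11:30
  bold <- list(
    Sub = 0.020 * gauss_bump(d30, 10, 5),
    CA1 = 0.020 * gauss_bump(d30, 10, 5),
    CA2 = 0.012 * gauss_bump(d30, 27, 5) + 0.006 * gauss_bump(d30, 8, 4),
    CA3 = 0.015 * gauss_bump(d20, 27, 6),
    DG_CA4 = rep(0.008, 20))
  cbv <- list(
    Sub = 0.010 * gauss_bump(d30, 20, 5),
    CA1 = 0.010 * gauss_bump(d30, 20, 5),
    CA2 = 0.010 * gauss_bump(d30, 18, 5),
    CA3 = 0.010 * gauss_bump(d20, 25, 6),
    DG_CA4 = rep(0.006, 20))
  list(cbv_profile = lapply(cbv, function(x) x * cbv_scale),
       bold_profile = lapply(bold, function(x) x * bold_scale),
       drift_coeffs = drift_coeffs,
       noise_sd = noise_sd,
       inflow_amplitude = inflow_amplitude,
       baseline = c(Sub = 100, CA1 = 100, CA2 = 100, CA3 = 100, DG_CA4 = 100,
                    SRLM = 90, WM = 80, CSF = 110, vessel = 120))
}

validate_truth <- function(truth) {
  need30 <- c("Sub", "CA1", "CA2")
  need20 <- c("CA3", "DG_CA4")
  for (field in c("cbv_profile", "bold_profile")) {
    p <- truth[[field]]
    for (s in need30) if (length(p[[s]]) != 30)
      stopf("ground truth: %s$%s must have 30 depth bins", field, s)
    for (s in need20) if (length(p[[s]]) != 20)
      stopf("ground truth: %s$%s must have 20 depth bins", field, s)
  }
  if (truth$noise_sd < 0) stopf("ground truth: noise_sd must be >= 0")
  invisible(truth)
}

#' Build the synthetic hippocampal phantom
#'
#' Generates the label volume, the voxel-to-world affine, corresponding
#' inner/mid/outer surface meshes with per-vertex subfield codes, per-voxel
#' depth-bin assignments, and the ground-truth response model used by
#' [simulate_interleaved()].
#'
#' @param grid_shape integer length-3 (or scalar) grid dimensions, each >= 32.
#' @param geometry output of [hippo_geometry()].
#' @param truth output of [ground_truth()].
#' @param n_theta,n_z surface mesh resolution along the arc and along z.
#' @param seed reserved for future stochastic geometry; the phantom is
#'   deterministic given its parameters.
#' @return object of class `hippocampal_phantom`.
#' @examples
#' ph <- build_phantom(c(48, 48, 48))
#' table(ph$label_volume)[-1]
#' @export
build_phantom <- function(grid_shape = c(64, 64, 64), geometry = hippo_geometry(),
                          truth = ground_truth(), n_theta = 48, n_z = 8,
                          seed = 1) {
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 32)) stopf("build_phantom: grid_shape must be >= 32 per axis")
  validate_truth(truth)
  g <- geometry
  half_extent <- min(grid_shape) * g$voxel_mm / 2
  r_out <- g$radius_mm + g$thickness_mm / 2
  if (r_out + g$wm_mm + g$voxel_mm > half_extent) {
    stopf(paste0("build_phantom: grid too small for ribbon (needs half-extent ",
                 ">= %.1f mm, has %.1f mm)"), r_out + g$wm_mm + g$voxel_mm,
          half_extent)
  }

  affine <- centered_affine(grid_shape, g$voxel_mm)
  codes <- subfield_codes()

  # world coordinates of voxel centres
  xs <- (seq_len(grid_shape[1]) - (grid_shape[1] + 1) / 2) * g$voxel_mm
  ys <- (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * g$voxel_mm
  zs <- (seq_len(grid_shape[3]) - (grid_shape[3] + 1) / 2) * g$voxel_mm
  X <- array(rep(xs, times = grid_shape[2] * grid_shape[3]), grid_shape)
  Y <- array(rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]), grid_shape)
  Z <- array(rep(zs, each = grid_shape[1] * grid_shape[2]), grid_shape)

  rho <- sqrt(X^2 + Y^2)
  theta <- (atan2(Y, X) * 180 / pi) %% 360
  theta_rel <- (theta - g$arc_start_deg) %% 360
  in_arc <- theta_rel <= g$arc_deg & abs(Z) <= g$z_half_mm

  r_in <- g$radius_mm - g$thickness_mm / 2
  bf <- cumsum(g$band_fractions) * g$arc_deg
  band_of <- function(th) {
    # subfield band index along the arc for relative angle th
    findInterval(th, c(0, bf), rightmost.closed = TRUE, all.inside = TRUE)
  }

  lab <- array(codes[["background"]], grid_shape)
  # CSF core and vessel cluster
  csf <- rho <= g$csf_radius_mm & abs(Z) <= g$z_half_mm
  lab[csf] <- codes[["CSF"]]
  vessel <- rho <= g$vessel_radius_mm & abs(Z) <= g$vessel_z_mm
  lab[vessel] <- codes[["vessel"]]
  # WM shell
  wm <- in_arc & rho > r_out & rho <= r_out + g$wm_mm
  lab[wm] <- codes[["WM"]]
  # GM ribbon with subfield bands
  gm <- in_arc & rho >= r_in & rho <= r_out
  band <- band_of(theta_rel[gm])
  lab[gm] <- codes[RIBBON_SUBFIELDS][band]
  # SRLM band beyond the inner surface along the whole arc (the laminar
  # extension bins only sample it under Sub/CA1/CA2)
  srlm <- in_arc & rho < r_in & rho >= r_in - g$srlm_mm
  lab[srlm] <- codes[["SRLM"]]

  # per-voxel depth bin (1..30) and owning subfield for GM + SRLM voxels
  h_bin <- g$thickness_mm / 19
  signal_vox <- which(gm | srlm)
  vox_bin <- as.integer(11 + round((rho[signal_vox] - r_in) / h_bin))
  is_srlm <- srlm[signal_vox]
  vox_bin[!is_srlm] <- pmin(pmax(vox_bin[!is_srlm], 11L), 30L)
  vox_bin[is_srlm] <- pmin(pmax(vox_bin[is_srlm], 1L), 10L)
  vox_subfield <- RIBBON_SUBFIELDS[band_of(theta_rel[signal_vox])]

  # corresponding surfaces: lattice over (theta, z), radial correspondence
  th_v <- g$arc_start_deg + g$arc_deg * (seq_len(n_theta) - 0.5) / n_theta
  z_v <- seq(-0.8, 0.8, length.out = n_z) * g$z_half_mm
  grid_v <- expand.grid(th = th_v, z = z_v)
  ct <- cos(grid_v$th * pi / 180)
  st <- sin(grid_v$th * pi / 180)
  surf_at <- function(r) cbind(r * ct, r * st, grid_v$z)
  surfaces <- list(inner = surf_at(r_in),
                   mid = surf_at(g$radius_mm),
                   outer = surf_at(r_out),
                   faces = lattice_faces(n_theta, n_z))
  th_rel_v <- (grid_v$th - g$arc_start_deg) %% 360
  subfield_of_vertex <- RIBBON_SUBFIELDS[band_of(th_rel_v)]
  # vertices too close to a band boundary are partial-volume mixtures of
  # two subfields; mark them so profile averaging skips them
  margin_deg <- g$boundary_margin_mm / g$radius_mm * 180 / pi
  dist_to_boundary <- vapply(th_rel_v, function(th)
    min(abs(th - c(0, bf))), numeric(1))
  subfield_of_vertex[dist_to_boundary < margin_deg] <- "boundary"

  structure(list(
    label_volume = lab, affine = affine, voxel_mm = g$voxel_mm,
    grid_shape = grid_shape, surfaces = surfaces,
    subfield_of_vertex = subfield_of_vertex,
    signal_vox = signal_vox, vox_bin = vox_bin, vox_subfield = vox_subfield,
    truth = truth, geometry = g, seed = seed
  ), class = "hippocampal_phantom")
}

# triangulate the (n_theta x n_z) vertex lattice
lattice_faces <- function(n_theta, n_z) {
  n_theta <- as.integer(n_theta)
  n_z <- as.integer(n_z)
  faces <- matrix(0L, 2 * (n_theta - 1) * (n_z - 1), 3)
  r <- 1L
  for (k in seq_len(n_z - 1)) {
    for (j in seq_len(n_theta - 1)) {
      v <- (k - 1L) * n_theta + j
      faces[r, ] <- c(v, v + 1L, v + n_theta); r <- r + 1L
      faces[r, ] <- c(v + 1L, v + n_theta + 1L, v + n_theta); r <- r + 1L
    }
  }
  faces
}

#' @export
print.hippocampal_phantom <- function(x, ...) {
  cat("hippocampal_phantom\n")
  cat(sprintf("  grid: %s at %.2f mm\n", paste(x$grid_shape, collapse = "x"),
              x$voxel_mm))
  cat(sprintf("  labelled voxels: %d (GM+SRLM signal voxels: %d)\n",
              sum(x$label_volume > 0), length(x$signal_vox)))
  cat(sprintf("  surface vertices: %d\n", nrow(x$surfaces$inner)))
  invisible(x)
}

#' Binary masks derived from the phantom label volume
#'
#' @param phantom a `hippocampal_phantom`.
#' @param what one of "gm" (subfields + SRLM), "subfields", "wm", "csf",
#'   "vessel", "srlm".
#' @return logical 3D array.
#' @export
phantom_mask <- function(phantom, what = c("gm", "subfields", "wm", "csf",
                                           "vessel", "srlm")) {
  what <- match.arg(what)
  codes <- subfield_codes()
  lab <- phantom$label_volume
  sel <- switch(what,
    gm = codes[c(RIBBON_SUBFIELDS, "SRLM")],
    subfields = codes[RIBBON_SUBFIELDS],
    wm = codes[["WM"]], csf = codes[["CSF"]],
    vessel = codes[["vessel"]], srlm = codes[["SRLM"]])
  array(lab %in% sel, dim(lab))
}

#' Build the block task design
#'
#' Two conditions (autobiographical memory and math) in a block design:
#' each trial lasts `trial_s` seconds followed by an inter-trial interval
#' of `iti_s` seconds, with `n_trials` trials per condition in an order
#' randomized by `order_seed`.
#'
#' @param n_trials trials per condition (>= 1).
#' @param trial_s trial duration, seconds.
#' @param iti_s inter-trial interval, seconds.
#' @param order_seed RNG seed for the condition ordering.
#' @param onset_s onset of the first trial relative to run start.
#' @return object of class `task_design`: list with `events` (data.frame
#'   onset/duration/trial_type), `n_trials_per_condition`, `total_span_s`.
#' @examples
#' d <- make_task_design(15)
#' d$total_span_s  # 900
#' @export
make_task_design <- function(n_trials = 15, trial_s = 18, iti_s = 12,
                             order_seed = 1, onset_s = 0) {
  if (n_trials < 1) stopf("make_task_design: n_trials must be >= 1")
  conds <- local_seed(order_seed,
                      sample(rep(c("memory", "math"), n_trials)))
  onsets <- onset_s + (seq_along(conds) - 1) * (trial_s + iti_s)
  events <- data.frame(onset = onsets, duration = trial_s, trial_type = conds,
                       stringsAsFactors = FALSE)
  structure(list(events = events, n_trials_per_condition = n_trials,
                 trial_s = trial_s, iti_s = iti_s,
                 total_span_s = onset_s + 2 * n_trials * (trial_s + iti_s)),
            class = "task_design")
}

#' Synthetic motion parameter traces
#'
#' Small Gaussian random walks standing in for rigid-body motion estimates
#' (3 translations in mm, 3 rotations in radians), as produced by a motion
#' corrector on well-behaved data. The phantom data themselves are not
#' moved; these traces only exercise the nuisance-regression plumbing.
#'
#' @param n number of time points (one per volume pair).
#' @param seed RNG seed.
#' @param sd_step per-step SD of the random walk.
#' @return n x 6 matrix with columns trans_x..rot_z.
#' @export
make_motion_params <- function(n, seed = 1, sd_step = 0.005) {
  m <- local_seed(seed, matrix(stats::rnorm(n * 6, 0, sd_step), n, 6))
  m <- apply(m, 2, cumsum)
  m <- matrix(m, n, 6)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}
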