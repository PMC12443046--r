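# Shared fixtures. Everything is generated in code; heavier objects are
# cached for the duration of the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small geometry that fits a 32^3 grid (12.8 mm half-extent); used where
# the test only needs plumbing, not the default-scale ribbon.
small_geometry <- function(...) {
  hippo_geometry(radius_mm = 6.5, thickness_mm = 3.2, z_half_mm = 6,
                 csf_radius_mm = 2.6, vessel_radius_mm = 1, vessel_z_mm = 1.5,
                 wm_mm = 3.6, boundary_margin_mm = 0.9, ...)
}

small_phantom <- function(truth = ground_truth(), n_theta = 36, n_z = 6) {
  build_phantom(c(32, 32, 32), small_geometry(), truth,
                n_theta = n_theta, n_z = n_z)
}

default_phantom <- function() cached("default_phantom", build_phantom(c(48, 48, 48)))

# noise-free, drift-free simulated run on the default phantom (308 vols)
noisefree_run <- function() {
  cached("noisefree_run", {
    ph <- default_phantom()
    des <- make_task_design(15)
    ser <- simulate_interleaved(ph, des, acquisition_params(), seed = 1,
                                noise_sd = 0, drift = FALSE)
    dm <- demultiplex(ser)
    nulled <- trim_series(dm$nulled)
    bold <- trim_series(dm$notnulled)
    bold$contrast <- "bold"
    list(phantom = ph, design = des, series = ser, nulled = nulled,
         bold = bold, vaso = bold_correct(nulled, bold),
         pair_s = nulled$timestamp_ms / 1000)
  })
}

default_bins <- function() {
  cached("default_bins", {
    ph <- default_phantom()
    compute_depth_bins(ph$surfaces, ph$subfield_of_vertex,
                       label_volume = ph$label_volume, affine = ph$affine)
  })
}

# interleaved series from a plain array, for format-level tests
toy_interleaved <- function(n_vol, d = c(4, 4, 4), fill = 1) {
  structure(list(data = array(fill, c(d, n_vol)),
                 contrast_tag = rep(c("nulled", "notnulled"),
                                    length.out = n_vol),
                 timestamp_ms = (seq_len(n_vol) - 1) * 3000,
                 params = NULL, affine = centered_affine(d, 1), voxel_mm = 1),
            class = "interleaved_series")
}

# L1-normalized deviation between a recovered and a true profile
profile_bias <- function(est, truth) sum(abs(est - truth)) / sum(abs(truth))
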