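#' Canonical double-gamma haemodynamic response function
#'
#' The standard double-gamma HRF (response gamma with shape 6, undershoot
#' gamma with shape 16, undershoot weight 1/6, unit scale), sampled over 32 s
#' and scaled so its maximum is 1. The same kernel is used by the phantom
#' forward model and by the GLM design builder, so simulated response
#' amplitudes are recovered without model mismatch.
#'
#' @param dt_s sampling interval in seconds (> 0).
#' @param length_s kernel duration in seconds.
#' @return numeric vector of samples at `seq(0, length_s, by = dt_s)`;
#'   `h[1] = 0` and `max(h) = 1`.
#' @examples
#' h <- canonical_hrf(0.1)
#' which.max(h) * 0.1  # peak close to 5-6 s
#' @export
canonical_hrf <- function(dt_s, length_s = 32) {
  if (dt_s <= 0) stopf("canonical_hrf: dt_s must be > 0")
  t <- seq(0, length_s, by = dt_s)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' HRF-convolved task regressor sampled at acquisition times
#'
#' Builds a boxcar from the events of one condition on a fine time grid,
#' convolves it with [canonical_hrf()], scales the result to unit peak
#' (so a fitted beta is the peak fractional response), and linearly
#' interpolates at the requested times.
#'
#' @param events data.frame with columns onset, duration, trial_type (s).
#' @param times_s acquisition times (s).
#' @param condition which trial_type to model.
#' @param dt_s resolution of the internal convolution grid.
#' @return numeric vector, one value per element of `times_s`.
#' @export
task_regressor <- function(events, times_s, condition, dt_s = 0.1) {
  ev <- events[events$trial_type == condition, , drop = FALSE]
  if (!nrow(ev)) return(numeric(length(times_s)))
  t_max <- max(times_s, ev$onset + ev$duration) + 33
  grid <- seq(0, t_max, by = dt_s)
  box <- numeric(length(grid))
  for (i in seq_len(nrow(ev))) {
    box[grid >= ev$onset[i] & grid < ev$onset[i] + ev$duration[i]] <- 1
  }
  h <- canonical_hrf(dt_s)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt_s
  pk <- max(abs(conv))
  if (pk > 0) conv <- conv / pk
  stats::approx(grid, conv, xout = times_s, rule = 2)$y
}
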