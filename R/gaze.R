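#' Simulate an eye-position recording for an event schedule
#'
#' Generates a fixation-like gaze trace sampled at `rate_hz`: Gaussian
#' scatter around the fixation point with baseline dispersion `sd_px`,
#' optionally scaled by `grouping_gain` during epochs that contain
#' groupings (gain 1 reproduces the null of no gaze change), with a random
#' subset of samples marked invalid to mimic blinks and tracking loss.
#'
#' Draws from the current RNG state.
#'
#' @param events Event tibble with `onset`, `duration`, `n_groups`.
#' @param duration_s Total recording length in seconds.
#' @param rate_hz Sampling rate (the recording emulated here ran at
#'   500 Hz).
#' @param centre Fixation point (px).
#' @param sd_px Baseline per-axis gaze SD.
#' @param grouping_gain Multiplier on the SD during grouping epochs.
#' @param p_invalid Probability that a sample is invalid.
#' @return Gaze tibble `(t, x, y, valid)`.
#' @export
simulate_gaze <- function(events, duration_s, rate_hz = 500,
                          centre = c(512, 384), sd_px = 5,
                          grouping_gain = 1, p_invalid = 0.05) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  sd_t <- rep(sd_px, length(t))
  grouped <- events[events$n_groups > 0, ]
  for (i in seq_len(nrow(grouped))) {
    in_ep <- t >= grouped$onset[i] & t < grouped$onset[i] +
      grouped$duration[i]
    sd_t[in_ep] <- sd_px * grouping_gain
  }
  tibble::tibble(
    t = t,
    x = centre[1] + stats::rnorm(length(t), 0, sd_t),
    y = centre[2] + stats::rnorm(length(t), 0, sd_t),
    valid = stats::runif(length(t)) >= p_invalid)
}
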