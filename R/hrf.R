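#' Canonical double-gamma haemodynamic response function
#'
#' The community-default impulse response: a gamma density peaking near 6 s
#' minus a scaled gamma undershoot peaking near 16 s,
#' \deqn{h(t) = \frac{t^{a_1-1} e^{-t/b_1}}{b_1^{a_1}\Gamma(a_1)} -
#'   \frac{1}{c}\,\frac{t^{a_2-1} e^{-t/b_2}}{b_2^{a_2}\Gamma(a_2)}}
#' with peak delay 6 s, undershoot delay 16 s, unit dispersions, undershoot
#' ratio 6 and 32 s support. The kernel is normalised to unit maximum so a
#' regression coefficient is in units of peak response.
#'
#' @param t Time points in seconds.
#' @param peak_delay,undershoot_delay Delays of response and undershoot (s).
#' @param peak_disp,undershoot_disp Dispersions (s).
#' @param undershoot_ratio Ratio of response to undershoot amplitude.
#' @param duration Kernel support in seconds; `h(t) = 0` outside
#'   `[0, duration]`.
#' @return Numeric vector of kernel values.
#' @examples
#' t <- seq(0, 32, by = 0.1)
#' h <- hrf_double_gamma(t)
#' t[which.max(h)]  # close to 5 s (gamma mode = (a-1)*b)
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             undershoot_ratio = 6, duration = 32) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / undershoot_ratio
  h[t < 0 | t > duration] <- 0
  mx <- max(h)
  if (mx > 0) h <- h / mx
  h
}

#' Convolve an event series with the HRF on a microtime grid
#'
#' Events are laid out as boxcars (or parametrically weighted boxcars) on a
#' grid of `dt = tr / oversample` seconds, convolved with the double-gamma
#' kernel sampled on the same grid, and read out at volume acquisition
#' times `0, tr, 2 tr, ...`.
#'
#' @param onsets,durations,weights Per-event onset (s), duration (s) and
#'   weight (1 for a plain boxcar; a mean-centred modulator value for a
#'   parametric regressor).
#' @param n_vols Number of volumes.
#' @param tr Repetition time in seconds.
#' @param oversample Microtime resolution factor.
#' @param derivative If `TRUE`, return the temporal derivative regressor
#'   (finite difference of the oversampled convolution) instead.
#' @return Numeric vector of length `n_vols`.
#' @export
convolve_events <- function(onsets, durations, weights, n_vols, tr,
                            oversample = 16L, derivative = FALSE) {
  stopifnot(length(onsets) == length(durations),
            length(onsets) == length(weights))
  dt <- tr / oversample
  n_fine <- n_vols * oversample
  stick <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- ceiling((onsets[i] + durations[i]) / dt)
    if (a > n_fine) next
    b <- min(b, n_fine)
    stick[a:b] <- stick[a:b] + weights[i]
  }
  kern <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(stick, rev(kern), type = "open")[seq_len(n_fine)]
  if (derivative) {
    conv <- c(diff(conv), 0) / dt
  }
  conv[seq(1, n_fine, by = oversample)]
}
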