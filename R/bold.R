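#' Scan protocol description
#'
#' Timing parameters of one functional session: repetition time 3.264 s,
#' 5 s stimulus events separated by 3 s blanks (a fixed 8 s trial pitch),
#' and seven lead-in volumes that are acquired while the display is blank
#' and discarded before analysis (T1 equilibration).
#'
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Retained volumes per session (after discarding).
#' @param event_duration_s Stimulus duration in seconds.
#' @param gap_s Blank gap between stimuli in seconds.
#' @param discard_volumes Lead-in volumes simulated then dropped.
#' @param n_sessions Sessions per subject.
#' @param p_stay Self-transition probability of the category sequence
#'   (favours short runs of the same category; uniform would be 1/6).
#' @return A list of class `"scan_protocol"`.
#' @export
scan_protocol <- function(tr_s = 3.264, n_volumes = 110L,
                          event_duration_s = 5, gap_s = 3,
                          discard_volumes = 7L, n_sessions = 2L,
                          p_stay = 0.3) {
  stopifnot(tr_s > 0, n_volumes > 0, event_duration_s > 0, gap_s >= 0,
            discard_volumes >= 0, n_sessions >= 1,
            p_stay > 0, p_stay < 1)
  if (event_duration_s + gap_s > n_volumes * tr_s) {
    stop("scan_protocol: a single trial does not fit in the session",
         call. = FALSE)
  }
  structure(list(tr_s = tr_s, n_volumes = as.integer(n_volumes),
                 event_duration_s = event_duration_s, gap_s = gap_s,
                 discard_volumes = as.integer(discard_volumes),
                 n_sessions = as.integer(n_sessions), p_stay = p_stay),
            class = "scan_protocol")
}

# The six presentation categories: the two moving conditions split by the
# presence of groupings, plus the two static conditions.
schedule_categories <- function() {
  tibble::tibble(
    category = c("moving_colour_grouped", "moving_colour_ungrouped",
                 "moving_greyscale_grouped", "moving_greyscale_ungrouped",
                 "static_colour", "static_greyscale"),
    trial_type = c("moving_colour", "moving_colour",
                   "moving_greyscale", "moving_greyscale",
                   "static_colour", "static_greyscale"),
    grouped = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
}

#' Schedule a semi-random event sequence
#'
#' Trials occupy a fixed 8 s pitch (5 s stimulus + 3 s blank). The category
#' sequence over the six presentation categories is a first-order Markov
#' chain with an elevated self-transition probability (`p_stay`, default
#' 0.3 against the uniform 1/6), which favours short runs of the same
#' category. Grouped moving trials draw their number of groupings uniformly
#' from 1--3; ungrouped moving trials and static trials have 0 groupings.
#' Simulated keypress responses and reaction times are attached for the
#' behavioural summaries (accuracy in a realistic 80--89% band by grouping
#' count, RTs near 2.9 s).
#'
#' Draws from the current RNG state.
#'
#' @param protocol A [scan_protocol()].
#' @return Event tibble: `onset` (s, relative to the first retained
#'   volume), `duration`, `trial_type`, `n_groups`, `response` (reported
#'   group count), `rt` (ms).
#' @export
schedule_events <- function(protocol) {
  cats <- schedule_categories()
  pitch <- protocol$event_duration_s + protocol$gap_s
  run_s <- protocol$n_volumes * protocol$tr_s
  n_trials <- floor((run_s - protocol$event_duration_s) / pitch) + 1
  k <- nrow(cats)
  # Redraw until every category is shown and each moving condition has
  # varying grouping counts (the presented schedules covered all cells);
  # with a realistic session length a redraw is rare.
  for (attempt in 1:100) {
    state <- sample.int(k, 1)
    states <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      states[i] <- state
      move <- stats::runif(1) >= protocol$p_stay
      if (move) state <- sample(setdiff(seq_len(k), state), 1)
    }
    grouped <- cats$grouped[states]
    n_groups <- ifelse(grouped, sample(1:3, n_trials, replace = TRUE), 0L)
    covered <- length(unique(states)) == k
    varied <- all(vapply(c("moving_colour", "moving_greyscale"),
                         function(tt) {
                           g <- n_groups[cats$trial_type[states] == tt]
                           length(unique(g)) >= 2
                         }, logical(1)))
    if (covered && varied) break
  }
  if (!(covered && varied)) {
    stop("schedule_events: could not cover all categories; ",
         "session too short", call. = FALSE)
  }
  acc <- c(`0` = 0.85, `1` = 0.80, `2` = 0.89, `3` = 0.85)
  correct <- stats::runif(n_trials) < acc[as.character(n_groups)]
  response <- ifelse(correct, n_groups, pmax(0, pmin(3, n_groups +
    sample(c(-1, 1), n_trials, replace = TRUE))))
  rt <- pmax(300, stats::rnorm(n_trials, 2900, 300))
  tibble::tibble(
    onset = (seq_len(n_trials) - 1) * pitch,
    duration = protocol$event_duration_s,
    trial_type = cats$trial_type[states],
    n_groups = as.integer(n_groups),
    response = as.integer(response),
    rt = rt)
}

#' Spherical voxel mask
#'
#' @param dim Volume dimensions.
#' @param centre Sphere centre (voxel coordinates).
#' @param radius Sphere radius (voxels).
#' @return Logical 3-D array.
#' @export
sphere_mask <- function(dim, centre, radius) {
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                   z = seq_len(dim[3]))
  d2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  array(d2 <= radius^2, dim = dim)
}

box_mask <- function(dim, xr, yr, zr) {
  m <- array(FALSE, dim = dim)
  m[xr, yr, zr] <- TRUE
  m
}

#' Default ground truth for synthetic BOLD generation
#'
#' Encodes the qualitative effect structure the analysis is designed to
#' detect, in a 20^3 toy volume:
#'
#' * a "V4-like" sphere responding to colour with a positive
#'   number-of-groupings slope for colour grouping only;
#' * a "V5-like" sphere responding to motion with a positive slope for
#'   motion grouping only;
#' * two contiguous, non-overlapping "IPS-like" compartments, one carrying
#'   the colour slope, the juxtaposed one the motion slope;
#' * a "cerebellum-like" region carrying both slopes (shared effects in one
#'   territory, the masks themselves stay disjoint).
#'
#' Amplitudes are in percent of the baseline of 100 (about 1% signal
#' change for strong condition responses, slopes of 0.3--0.4% per
#' additional grouping); noise is AR(1) with coefficient 0.3 and unit
#' marginal SD, drift is a sum of slow sinusoids (periods of at least
#' 160 s, so a 120 s high-pass must remove them), and each subject's
#' effects vary around the group mean with an SD of 20% of the mean.
#'
#' @param dim Volume dimensions.
#' @param noise_sd Marginal SD of the AR(1) noise.
#' @param ar1 Lag-1 autocorrelation of the noise.
#' @param drift_amplitudes,drift_periods_s Sinusoidal drift components.
#' @param subject_sd_frac Between-subject SD as a fraction of each effect.
#' @param baseline Baseline signal level.
#' @return A list of class `"ground_truth"`.
#' @export
default_ground_truth <- function(dim = c(20L, 20L, 20L), noise_sd = 1,
                                 ar1 = 0.3,
                                 drift_amplitudes = c(1.5, 1.0),
                                 drift_periods_s = c(200, 320),
                                 subject_sd_frac = 0.2,
                                 baseline = 100) {
  amp <- function(mc, mg, sc, sg) {
    c(moving_colour = mc, moving_greyscale = mg,
      static_colour = sc, static_greyscale = sg)
  }
  # region layout defined on a 20-voxel reference cube, rescaled to `dim`
  sc3 <- function(v) pmax(1, pmin(dim, round(v * dim / 20)))
  rg <- function(a, b, i) {
    max(1, round(a * dim[i] / 20)):min(dim[i], round(b * dim[i] / 20))
  }
  rad <- 2.5 * min(dim) / 20
  x_col <- rg(4, 7, 1)
  x_mot <- rg(8, 11, 1)
  x_mot <- x_mot[x_mot > max(x_col)]  # keep the compartments disjoint
  if (length(x_mot) == 0) x_mot <- min(max(x_col) + 1, dim[1])
  regions <- list(
    v4_colour = list(
      mask = sphere_mask(dim, sc3(c(5, 5, 10)), rad),
      amplitudes = amp(1.0, 0.3, 0.8, 0.3),
      colour_slope = 0.4, motion_slope = 0),
    v5_motion = list(
      mask = sphere_mask(dim, sc3(c(15, 5, 10)), rad),
      amplitudes = amp(0.8, 1.0, 0.2, 0.2),
      colour_slope = 0, motion_slope = 0.4),
    ips_colour = list(
      mask = box_mask(dim, x_col, rg(14, 17, 2), rg(9, 12, 3)),
      amplitudes = amp(0.5, 0.5, 0.1, 0.1),
      colour_slope = 0.4, motion_slope = 0),
    ips_motion = list(
      mask = box_mask(dim, x_mot, rg(14, 17, 2), rg(9, 12, 3)),
      amplitudes = amp(0.5, 0.5, 0.1, 0.1),
      colour_slope = 0, motion_slope = 0.4),
    cerebellum_shared = list(
      mask = sphere_mask(dim, sc3(c(10, 10, 4)), rad),
      amplitudes = amp(0.5, 0.5, 0.1, 0.1),
      colour_slope = 0.3, motion_slope = 0.3))
  structure(list(dim = as.integer(dim), regions = regions,
                 baseline = baseline, noise_sd = noise_sd, ar1 = ar1,
                 drift_amplitudes = drift_amplitudes,
                 drift_periods_s = drift_periods_s,
                 subject_sd_frac = subject_sd_frac),
            class = "ground_truth")
}

# Draw one subject's effect sizes around the group means.
perturb_truth <- function(truth, rng_frac = truth$subject_sd_frac) {
  for (r in names(truth$regions)) {
    reg <- truth$regions[[r]]
    reg$amplitudes <- stats::rnorm(length(reg$amplitudes), reg$amplitudes,
                                   rng_frac * abs(reg$amplitudes))
    names(reg$amplitudes) <- names(truth$regions[[r]]$amplitudes)
    reg$colour_slope <- stats::rnorm(1, reg$colour_slope,
                                     rng_frac * abs(reg$colour_slope))
    reg$motion_slope <- stats::rnorm(1, reg$motion_slope,
                                     rng_frac * abs(reg$motion_slope))
    truth$regions[[r]] <- reg
  }
  truth
}

# Signal coefficient matrix: one row per generating regressor
# (4 conditions + 2 slopes), one column per voxel.
truth_beta_matrix <- function(truth) {
  v <- prod(truth$dim)
  rows <- c("moving_colour", "moving_greyscale", "static_colour",
            "static_greyscale", "mod_moving_colour", "mod_moving_greyscale")
  B <- matrix(0, nrow = length(rows), ncol = v,
              dimnames = list(rows, NULL))
  for (reg in truth$regions) {
    if (any(dim(reg$mask) != truth$dim)) {
      stop("ground_truth: region mask does not match the volume dimensions",
           call. = FALSE)
    }
    idx <- which(reg$mask)
    for (cond in names(reg$amplitudes)) {
      B[cond, idx] <- B[cond, idx] + reg$amplitudes[[cond]]
    }
    B["mod_moving_colour", idx] <-
      B["mod_moving_colour", idx] + reg$colour_slope
    B["mod_moving_greyscale", idx] <-
      B["mod_moving_greyscale", idx] + reg$motion_slope
  }
  B
}

# AR(1) noise matrix with unit-free marginal SD `sd` and coefficient `phi`.
ar1_noise <- function(n, v, sd, phi) {
  if (sd == 0) return(matrix(0, n, v))
  innov_sd <- sd * sqrt(1 - phi^2)
  w <- matrix(stats::rnorm(n * v, 0, innov_sd), n, v)
  if (phi != 0) {
    w[1, ] <- stats::rnorm(v, 0, sd)  # stationary start
    w <- apply_ar1(w, phi)
  }
  w
}

apply_ar1 <- function(w, phi) {
  for (t in 2:nrow(w)) w[t, ] <- w[t, ] + phi * w[t - 1, ]
  w
}

#' Simulate one subject's BOLD sessions
#'
#' Forward model per session: the parametric design regressors (condition
#' boxcars and mean-centred number-of-groupings modulators, convolved with
#' the canonical HRF) are scaled by the subject's regional effect sizes and
#' summed over regions, on top of the baseline, a sum of slow sinusoidal
#' drifts (session-specific random phases, shared across voxels) and AR(1)
#' Gaussian noise. The discarded lead-in volumes are simulated and then
#' dropped. Head-motion nuisance series are slow random walks; the keypress
#' nuisance regressor is the HRF-convolved train of response times.
#'
#' @param protocol A [scan_protocol()].
#' @param truth A [default_ground_truth()]-style ground truth (group
#'   means).
#' @param seed Integer seed; all subject randomness derives from it.
#' @param subject_id Subject identifier.
#' @param subject_truth Optional pre-drawn subject-level truth (used by
#'   [simulate_cohort()]); by default the subject's effects are drawn from
#'   the group means with the configured between-subject SD.
#' @return An object of class `"subject_dataset"`: list with `subject_id`,
#'   `protocol`, `truth` (the subject-level truth), and `sessions` — a
#'   list, one element per session, each holding `bold` (volumes x voxels
#'   matrix), `dim`, `events`, `nuisance` (tibble: keypress + 6 motion
#'   parameters).
#' @export
simulate_subject <- function(protocol, truth, seed, subject_id = 1L,
                             subject_truth = NULL) {
  if (is.null(subject_truth)) {
    subject_truth <- with_seed(derive_seed(seed, "subject_effects"),
                               perturb_truth(truth))
  }
  B <- truth_beta_matrix(subject_truth)
  v <- prod(truth$dim)
  n <- protocol$n_volumes
  n_total <- n + protocol$discard_volumes
  tr <- protocol$tr_s

  sessions <- vector("list", protocol$n_sessions)
  for (s in seq_len(protocol$n_sessions)) {
    sess_seed <- derive_seed(seed, paste0("session_", s))
    sess <- with_seed(sess_seed, {
      events <- schedule_events(protocol)
      Xs <- signal_regressors(events, n, tr)
      signal <- Xs %*% B[colnames(Xs), , drop = FALSE]

      t_full <- (seq_len(n_total) - 1) * tr
      drift_full <- rep(0, n_total)
      for (j in seq_along(truth$drift_amplitudes)) {
        drift_full <- drift_full + truth$drift_amplitudes[j] *
          sin(2 * pi * t_full / truth$drift_periods_s[j] +
                stats::runif(1, 0, 2 * pi))
      }
      noise_full <- ar1_noise(n_total, v, truth$noise_sd, truth$ar1)
      keep <- (protocol$discard_volumes + 1):n_total
      bold <- truth$baseline + signal + drift_full[keep] + noise_full[keep, ]

      motion <- matrix(stats::rnorm(n * 6, 0, 0.02), n, 6)
      motion <- apply(motion, 2, cumsum)
      colnames(motion) <- paste0("motion_", 1:6)
      press_t <- events$onset + events$rt / 1000
      press_t <- press_t[press_t < n * tr]
      keypress <- convolve_events(press_t, rep(0.1, length(press_t)),
                                  rep(1, length(press_t)), n, tr)
      nuisance <- tibble::as_tibble(cbind(keypress = keypress, motion))
      list(bold = bold, dim = truth$dim, events = events,
           nuisance = nuisance)
    })
    sessions[[s]] <- sess
  }
  structure(list(subject_id = subject_id, protocol = protocol,
                 truth = subject_truth, sessions = sessions),
            class = "subject_dataset")
}

# Generating regressors shared by the forward model and the fitted design:
# condition boxcars and centred modulators, HRF-convolved.
signal_regressors <- function(events, n_vols, tr, oversample = 16L) {
  cols <- list()
  for (cond in c("moving_colour", "moving_greyscale", "static_colour",
                 "static_greyscale")) {
    ev <- events[events$trial_type == cond, ]
    if (nrow(ev) == 0) next
    cols[[cond]] <- convolve_events(ev$onset, ev$duration,
                                    rep(1, nrow(ev)), n_vols, tr,
                                    oversample = oversample)
    if (cond %in% c("moving_colour", "moving_greyscale")) {
      w <- ev$n_groups - mean(ev$n_groups)
      cols[[paste0("mod_", cond)]] <-
        convolve_events(ev$onset, ev$duration, w, n_vols, tr,
                        oversample = oversample)
    }
  }
  do.call(cbind, cols)
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("<subject_dataset> subject ", x$subject_id, ", ",
      length(x$sessions), " session(s) of ", x$protocol$n_volumes,
      " volumes, ", prod(x$sessions[[1]]$dim), " voxels\n", sep = "")
  invisible(x)
}

#' Simulate a multi-subject cohort
#'
#' Each subject's effect sizes are drawn once from the group means
#' (between-subject SD per [default_ground_truth()]) and shared across that
#' subject's sessions; each session has its own independently scheduled
#' event order, drift phases and noise.
#'
#' @param n_subjects Number of subjects (the analysed cohort had 16).
#' @param protocol A [scan_protocol()].
#' @param truth Group-level ground truth.
#' @param seed Integer root seed.
#' @return List of [simulate_subject()] datasets.
#' @export
simulate_cohort <- function(n_subjects = 16L, protocol = scan_protocol(),
                            truth = default_ground_truth(), seed = 1L) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(protocol, truth,
                     seed = derive_seed(seed, paste0("subject_", i)),
                     subject_id = i)
  })
}
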