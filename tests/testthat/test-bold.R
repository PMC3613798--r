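test_that("event schedules: fixed pitch, static zero groups, short runs", {
  prot <- scan_protocol()
  set.seed(1)
  ev <- schedule_events(prot)
  expect_true(all(diff(ev$onset) == 8))
  expect_true(all(ev$duration == 5))
  expect_true(all(ev$n_groups[startsWith(ev$trial_type, "static")] == 0L))
  expect_true(all(ev$n_groups %in% 0:3))
  expect_true(max(ev$onset) + 5 <= prot$n_volumes * prot$tr_s)

  # observed self-transition frequency matches the configured stay
  # probability over a long chain (category level, 6 states)
  long <- scan_protocol(n_volumes = 2500L)
  set.seed(2)
  cats <- dotgroup:::schedule_categories()
  evl <- dplyr::bind_rows(lapply(1:10, function(i) schedule_events(long)))
  state <- paste(evl$trial_type, evl$n_groups > 0)
  keep <- rep(TRUE, length(state))
  keep[cumsum(rep(nrow(evl) / 10, 10))] <- FALSE  # drop run boundaries
  same <- state[-1] == state[-length(state)]
  same <- same[keep[-length(keep)]]
  p_hat <- mean(same)
  se <- sqrt(0.3 * 0.7 / length(same))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("noiseless forward model is inverted exactly by the GLM", {
  prot <- scan_protocol(n_volumes = 80L, n_sessions = 1L)
  truth <- default_ground_truth(dim = c(6L, 6L, 6L), noise_sd = 0,
                                drift_amplitudes = c(0, 0),
                                subject_sd_frac = 0)
  subj <- simulate_subject(prot, truth, seed = 5)
  fit <- fit_subject(subj, cutoff_s = NA, use_nuisance = FALSE)
  B <- dotgroup:::truth_beta_matrix(truth)
  for (term in rownames(B)) {
    est <- fit$betas[term, ]
    expect_equal(est, unname(B[term, ]), tolerance = 1e-8)
  }
  # residual variance is numerically zero
  expect_lt(max(fit$resvar), 1e-16)
})

test_that("zero amplitudes leave only drift plus noise", {
  prot <- scan_protocol(n_volumes = 60L, n_sessions = 1L)
  truth <- default_ground_truth(dim = c(4L, 4L, 4L), noise_sd = 0,
                                subject_sd_frac = 0)
  for (r in names(truth$regions)) {
    truth$regions[[r]]$amplitudes[] <- 0
    truth$regions[[r]]$colour_slope <- 0
    truth$regions[[r]]$motion_slope <- 0
  }
  subj <- simulate_subject(prot, truth, seed = 6)
  bold <- subj$sessions[[1]]$bold
  # every voxel carries the identical deterministic drift about baseline
  expect_lt(max(abs(sweep(bold, 1, bold[, 1]))), 1e-12)
  expect_gt(stats::sd(bold[, 1]), 0)  # the drift itself is present
})

test_that("AR(1) noise honours its configured coefficient and scale", {
  set.seed(7)
  e <- dotgroup:::ar1_noise(200, 800, sd = 1, phi = 0.3)
  # Yule-Walker estimate at lag 1, averaged over voxels
  phi_hat <- mean(vapply(seq_len(800), function(j) {
    stats::acf(e[, j], lag.max = 1, plot = FALSE)$acf[2]
  }, numeric(1)))
  expect_lt(abs(phi_hat - 0.3), 0.05)
  expect_lt(abs(stats::sd(as.vector(e)) - 1), 0.05)
})

test_that("cohorts share subject effects across sessions and vary between", {
  prot <- scan_protocol(n_volumes = 60L)
  truth <- default_ground_truth(dim = c(4L, 4L, 4L))
  cohort <- simulate_cohort(3L, prot, truth, seed = 9)
  expect_length(cohort, 3)
  s1 <- cohort[[1]]
  expect_length(s1$sessions, 2)
  # different sessions, different schedules
  expect_false(identical(s1$sessions[[1]]$events, s1$sessions[[2]]$events))
  # subject truths differ between subjects
  expect_false(identical(
    cohort[[1]]$truth$regions$v4_colour$colour_slope,
    cohort[[2]]$truth$regions$v4_colour$colour_slope))

  # zero between-subject SD: all subjects share the group truth
  truth0 <- default_ground_truth(dim = c(4L, 4L, 4L), subject_sd_frac = 0)
  cohort0 <- simulate_cohort(2L, prot, truth0, seed = 10)
  expect_equal(cohort0[[1]]$truth$regions$v4_colour$colour_slope,
               cohort0[[2]]$truth$regions$v4_colour$colour_slope)
  expect_equal(cohort0[[1]]$truth$regions$v4_colour$colour_slope, 0.4)

  # determinism under the seed
  again <- simulate_cohort(3L, prot, truth, seed = 9)
  expect_identical(cohort[[2]]$sessions[[1]]$bold,
                   again[[2]]$sessions[[1]]$bold)
})

test_that("ground-truth region masks stay disjoint at any volume size", {
  for (d in list(c(20L, 20L, 20L), c(10L, 10L, 10L), c(8L, 8L, 8L))) {
    tr <- default_ground_truth(dim = d)
    overlap <- Reduce(`+`, lapply(tr$regions, function(r) r$mask + 0))
    expect_true(all(overlap <= 1))
    expect_true(all(vapply(tr$regions, function(r) sum(r$mask) > 0,
                           logical(1))))
  }
})
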