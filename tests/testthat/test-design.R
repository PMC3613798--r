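# A compact event table covering all four conditions with varying group
# counts, used throughout the design tests.
toy_events <- function() {
  tibble::tibble(
    onset = seq(0, 88, by = 8),
    duration = 5,
    trial_type = rep(c("moving_colour", "moving_greyscale",
                       "static_colour", "static_greyscale"), 3),
    n_groups = as.integer(c(0, 1, 0, 0, 2, 0, 0, 0, 3, 2, 0, 0)))
}

test_that("parametric design has the documented column layout", {
  nuis <- matrix(rnorm(40 * 7), 40, 7,
                 dimnames = list(NULL, c("keypress", paste0("motion_", 1:6))))
  dm <- build_design(toy_events(), n_vols = 40L, tr = 3.264,
                     variant = "four_condition_parametric", nuisance = nuis)
  # 4 conditions + 4 derivatives + 2 modulators + 2 modulator derivatives
  # + 7 nuisance + intercept = 20
  expect_identical(ncol(dm$X), 20L)
  expect_identical(as.vector(table(dm$roles)[c("condition", "derivative",
                                               "modulator",
                                               "modulator_derivative",
                                               "nuisance", "intercept")]),
                   c(4L, 4L, 2L, 2L, 7L, 1L))
  expect_true(all(c("mod_moving_colour", "mod_moving_greyscale",
                    "intercept") %in% colnames(dm$X)))
  # six-condition variant: only populated cells get columns
  dm6 <- build_design(toy_events(), n_vols = 40L, tr = 3.264,
                      variant = "six_condition")
  expect_identical(sum(dm6$roles == "condition"), 6L)
  expect_identical(sum(dm6$roles == "derivative"), 6L)
})

test_that("modulator columns equal an independently convolved oracle", {
  ev <- toy_events()
  dm <- build_design(ev, n_vols = 60L, tr = 2,
                     variant = "four_condition_parametric")
  # oracle: direct discrete convolution of the centred weighted boxcar with
  # the HRF on a fine grid, decimated at the TR
  mc <- ev[ev$trial_type == "moving_colour", ]
  w <- mc$n_groups - mean(mc$n_groups)
  dt <- 2 / 16
  fine <- numeric(60 * 16)
  for (i in seq_len(nrow(mc))) {
    idx <- which((seq_along(fine) - 1) * dt >= mc$onset[i] &
                   (seq_along(fine) - 1) * dt < mc$onset[i] + mc$duration[i])
    fine[idx] <- fine[idx] + w[i]
  }
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- numeric(length(fine))
  for (k in seq_along(h)) {
    shifted <- c(rep(0, k - 1), fine)[seq_along(fine)]
    conv <- conv + h[k] * shifted
  }
  oracle <- conv[seq(1, length(conv), by = 16)]
  expect_gt(stats::cor(dm$X[, "mod_moving_colour"], oracle), 0.99)
})

test_that("condition columns peak near 6 s after a brief event", {
  ev <- tibble::tibble(onset = 0, duration = 0.5,
                       trial_type = "static_colour", n_groups = 0L)
  dm <- build_design(ev, n_vols = 30L, tr = 1,
                     variant = "four_condition_parametric")
  peak_t <- (which.max(dm$X[, "static_colour"]) - 1) * 1
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 7)
})

test_that("rank-deficient designs are refused with the collinear columns named", {
  ev <- toy_events()
  nuis <- matrix(1, 40, 2, dimnames = list(NULL, c("a", "b")))  # b == a == 1
  expect_error(build_design(ev, 40L, 3.264,
                            variant = "four_condition_parametric",
                            nuisance = nuis),
               "rank deficient.*nuis_")
})

test_that("high-pass filter: frequency response, idempotence, equivalence", {
  n <- 600L; tr <- 3.264
  t <- (seq_len(n) - 1) * tr
  dm <- build_design(toy_events(), n, tr, "four_condition_parametric")

  slow <- sin(2 * pi * t / 240)   # period 240 s: must be removed
  fast <- sin(2 * pi * t / 40)    # period 40 s: must survive
  hp <- highpass(dm, cbind(slow, fast))
  p_in <- c(sum(slow^2), sum(fast^2))
  p_out <- colSums(hp$data^2)
  expect_lt(p_out[1] / p_in[1], 0.01)
  expect_gt(p_out[2] / p_in[2], 0.95)

  # projection property: filtering twice equals filtering once
  hp2 <- highpass(hp$dm, hp$data)
  expect_equal(hp2$data, hp$data, tolerance = 1e-12)
  expect_equal(hp2$dm$X, hp$dm$X, tolerance = 1e-12)

  # equivalence: filtering data+design vs adding DCT confound columns
  set.seed(20)
  y <- dm$X %*% rnorm(ncol(dm$X)) + rnorm(n) + 3 * sin(2 * pi * t / 300)
  fit_f <- fit_glm(hp$dm, highpass(dm, y)$data)
  C <- dct_basis(n, tr, 120)
  colnames(C) <- paste0("dct_", seq_len(ncol(C)))
  dm_c <- dm
  dm_c$X <- cbind(dm$X, C)
  dm_c$roles <- c(dm$roles, rep("nuisance", ncol(C)))
  fit_c <- fit_glm(dm_c, y)
  w <- contrast_weights(dm, "parametric_colour")
  expect_identical(fit_f$dof, fit_c$dof)
  expect_equal(contrast_t(fit_f, w)$effect,
               contrast_t(fit_c, c(w, rep(0, ncol(C))))$effect,
               tolerance = 1e-10)
  expect_equal(contrast_t(fit_f, w)$t,
               contrast_t(fit_c, c(w, rep(0, ncol(C))))$t,
               tolerance = 1e-6)

  # run shorter than the cutoff: warn and pass through
  short <- build_design(toy_events()[1:3, ], 12L, 3,
                        variant = "four_condition_parametric")
  expect_warning(highpass(short, matrix(rnorm(12), 12, 1), 120),
                 "shorter than the cutoff")
})

test_that("events past the end of the run are rejected", {
  ev <- toy_events()
  expect_error(build_design(ev, n_vols = 10L, tr = 3.264,
                            variant = "six_condition"),
               "past the end")
})
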