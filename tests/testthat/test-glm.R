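make_dm <- function(X, tr = 1) {
  colnames(X) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  structure(list(X = X, roles = rep("condition", ncol(X)), tr = tr,
                 n_vols = nrow(X), variant = "six_condition",
                 oversample = 16L, highpass_cutoff = NA_real_),
            class = "design_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("OLS fit matches the normal-equations oracle and its properties", {
  # hand-checkable 8-timepoint, 3-regressor example
  X <- cbind(int = 1, a = c(0, 1, 2, 3, 4, 5, 6, 7),
             b = c(1, 0, 1, 0, 1, 0, 1, 0))
  y <- c(2.0, 2.9, 4.2, 4.8, 6.1, 6.9, 8.2, 8.8)
  fit <- fit_glm(make_dm(X), y)
  expect_equal(unname(drop(fit$betas)), unname(drop(ols_oracle(X, y))),
               tolerance = 1e-12)
  expect_identical(fit$dof, 5L)

  # noiseless data: betas exact, residual variance zero
  set.seed(30)
  X2 <- cbind(1, matrix(rnorm(40 * 3), 40))
  beta_true <- c(1, -2, 0.5, 3)
  fit2 <- fit_glm(make_dm(X2), drop(X2 %*% beta_true))
  expect_equal(unname(drop(fit2$betas)), beta_true, tolerance = 1e-10)
  expect_lt(fit2$resvar, 1e-20)

  # residuals orthogonal to every design column
  set.seed(31)
  Y <- matrix(rnorm(40 * 5), 40)
  fit3 <- fit_glm(make_dm(X2), Y)
  resid <- Y - X2 %*% fit3$betas
  expect_lt(max(abs(crossprod(X2, resid))), 1e-8)

  # shape errors
  expect_error(fit_glm(make_dm(X2), Y[1:10, ]), "different numbers")
  expect_error(fit_glm(make_dm(X2[1:3, ]), Y[1:3, ]), "fewer time points")
})

test_that("contrast t-maps agree with the lm() oracle on a toy dataset", {
  set.seed(32)
  n <- 40; v <- 50
  X <- cbind(int = 1, a = rnorm(n), b = rnorm(n), c = rnorm(n))
  Y <- X %*% matrix(rnorm(4 * v), 4) + matrix(rnorm(n * v), n)
  fit <- fit_glm(make_dm(X), Y)
  for (w in list(c(0, 1, 0, 0), c(0, 1, -1, 0), c(1, 0.5, 0.5, -2))) {
    sm <- contrast_t(fit, w)
    want <- vapply(seq_len(v), function(j) {
      lm_contrast_oracle(X, Y[, j], w)
    }, numeric(2))
    expect_equal(unname(sm$effect), unname(want["effect", ]),
                 tolerance = 1e-6)
    expect_equal(unname(sm$t), unname(want["t", ]), tolerance = 1e-6)
  }
  # zero contrast: t = 0 everywhere; sign flip negates t exactly
  sm0 <- contrast_t(fit, rep(0, 4))
  expect_true(all(sm0$t == 0))
  w <- c(0, 1, -1, 0)
  expect_equal(contrast_t(fit, -w)$t, -contrast_t(fit, w)$t)
  # zero residual variance flags voxels instead of dividing by zero
  fitz <- fit_glm(make_dm(X), drop(X %*% c(1, 2, 0, -1)))
  smz <- contrast_t(fitz, w)
  expect_true(all(smz$undefined))
  expect_true(all(is.na(smz$t)))
})

test_that("second-level maps behave as one-sample t-tests", {
  set.seed(33)
  Y <- matrix(rnorm(12 * 30, mean = 0.3), 12)
  sm <- second_level(Y)
  want_t <- vapply(seq_len(30), function(j) {
    unname(stats::t.test(Y[, j])$statistic)
  }, numeric(1))
  expect_equal(unname(sm$t), want_t, tolerance = 1e-10)
  expect_identical(sm$df, 11)
  # negating all inputs negates the map
  expect_equal(second_level(-Y)$t, -sm$t)
  # identical subjects: effect kept, t flagged undefined
  Yc <- matrix(2, 5, 4)
  smc <- second_level(Yc)
  expect_true(all(smc$undefined))
  expect_true(all(smc$effect == 2))
  expect_true(all(is.na(smc$t)))
  expect_error(second_level(Y[1, , drop = FALSE]), "at least 2")
})

test_that("named contrasts resolve onto the design columns", {
  ev <- tibble::tibble(
    onset = seq(0, 88, by = 8), duration = 5,
    trial_type = rep(c("moving_colour", "moving_greyscale",
                       "static_colour", "static_greyscale"), 3),
    n_groups = as.integer(c(1, 0, 0, 0, 0, 2, 0, 0, 2, 1, 0, 0)))
  dm6 <- build_design(ev, 40L, 3.264, "six_condition")
  w <- contrast_weights(dm6, "colour_grouping_gt_none")
  expect_equal(w[colnames(dm6$X) == "moving_colour_grouped"], 1)
  expect_equal(w[colnames(dm6$X) == "moving_colour_ungrouped"], -1)
  expect_equal(sum(w != 0), 2)
  expect_equal(contrast_weights(dm6, "colour_grouping_lt_none"), -w)
  # derivatives never enter any named contrast
  for (nm in c("colour_grouping_gt_none", "motion_grouping_gt_none",
               "colour_gt_greyscale_static", "moving_greyscale_gt_static")) {
    wn <- contrast_weights(dm6, nm)
    expect_true(all(wn[dm6$roles == "derivative"] == 0))
  }
  dmp <- build_design(ev, 40L, 3.264, "four_condition_parametric")
  wp <- contrast_weights(dmp, "parametric_colour")
  expect_equal(sum(wp != 0), 1)
  expect_error(contrast_weights(dmp, "colour_grouping_gt_none"),
               "unavailable")
  expect_error(contrast_weights(dmp, "no_such_contrast"), "unknown")
})
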