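test_that("dot field initialisation: grid layout, jitter bounds, wrapping", {
  cfg <- sim_config("moving_colour", seed = 1)
  expect_equal(grid_shape(cfg), c(34, 20))

  # zero jitter reproduces the exact cell-centred grid
  cfg0 <- sim_config("moving_colour", jitter_px = 0, seed = 1)
  set.seed(1)
  dots0 <- init_dot_field(cfg0)
  expect_equal(nrow(dots0), 680)
  expect_equal(dots0$x, dots0$grid_x)
  expect_equal(dots0$y, dots0$grid_y)
  expect_equal(sort(unique(dots0$grid_x)), (seq_len(34) - 0.5) * 1024 / 34)
  expect_equal(sort(unique(dots0$grid_y)), (seq_len(20) - 0.5) * 768 / 20)

  # jittered positions never deviate more than 10 px per axis (wrap-aware)
  max_dev <- 0
  for (s in 1:200) {
    set.seed(s)
    d <- init_dot_field(cfg)
    dev <- max(abs(modular_delta(d$x, d$grid_x, cfg$field_w_px)),
               abs(modular_delta(d$y, d$grid_y, cfg$field_h_px)))
    max_dev <- max(max_dev, dev)
    expect_true(all(d$x >= 0 & d$x < cfg$field_w_px))
    expect_true(all(d$y >= 0 & d$y < cfg$field_h_px))
  }
  expect_lte(max_dev, 10)
  expect_gt(max_dev, 9.5)  # the bound is actually approached

  # a dot count with no usable grid errors
  expect_error(grid_shape(sim_config("moving_colour", n_dots = 680,
                                     grid_cols = 33, seed = 1)),
               "not divisible")
})

test_that("greyscale conversion equals the CIELAB lightness closed form", {
  expect_identical(srgb_grey_level(c(255, 255, 255)), 255L)
  expect_identical(srgb_grey_level(c(0, 0, 0)), 0L)
  set.seed(42)
  cols <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  cols <- rbind(cols, c(255, 0, 0), c(0, 255, 0), c(0, 0, 255))
  got <- srgb_grey_level(cols)
  want <- vapply(seq_len(nrow(cols)), function(i) {
    as.integer(round(255 * lab_lightness_oracle(cols[i, ]) / 100))
  }, integer(1))
  expect_equal(got, want)
  # cross-check the lightness against R's own colour-space machinery
  lab_ref <- grDevices::convertColor(cols / 255, from = "sRGB", to = "Lab")
  expect_lt(max(abs(100 * got / 255 - lab_ref[, 1])), 0.75)
  # greyscale dots are genuinely grey
  set.seed(7)
  dots <- assign_colours(init_dot_field(sim_config("moving_greyscale",
                                                   seed = 7)),
                         "moving_greyscale")
  expect_true(all(dots$r == dots$g & dots$g == dots$b))
})

test_that("region placement respects containment and non-overlap", {
  cfg <- sim_config("moving_colour", n_groups = 3, seed = 1)
  expect_equal(nrow(place_regions(0L, cfg)), 0)
  violations <- 0
  for (s in 1:300) {
    set.seed(s)
    reg <- place_regions(3L, cfg)
    expect_equal(nrow(reg), 3)
    if (any(reg$cx < 50 | reg$cx > 1024 - 50 |
              reg$cy < 50 | reg$cy > 768 - 50)) violations <- violations + 1
    dmin <- min(stats::dist(cbind(reg$cx, reg$cy)))
    if (dmin < 100) violations <- violations + 1
  }
  expect_identical(violations, 0)
  # pathological geometry trips the iteration cap
  tiny <- sim_config("moving_colour", n_groups = 3, field_w_px = 120,
                     field_h_px = 120, seed = 1)
  set.seed(1)
  expect_error(place_regions(3L, tiny, max_iter = 50), "could not place")
})

test_that("ungrouped kinematics: normalised speed, bias geometry, drift", {
  cfg <- sim_config("moving_colour", seed = 1)
  # collinear case: heading along +x, jitter silenced
  cfg0 <- sim_config("moving_colour", dir_jitter_rad = 0, seed = 1)
  d <- tibble::tibble(dot = 1L, x = 100, y = 100, direction = 0,
                      group_id = NA_integer_)
  set.seed(1)
  out <- step_ungrouped(d, cfg0)
  expect_equal(c(out$dx, out$dy), c(1.7, 0))

  # every displacement has norm exactly speed_px_per_frame
  set.seed(2)
  dots <- tibble::tibble(dot = 1:500, x = runif(500, 0, 1024),
                         y = runif(500, 0, 768),
                         direction = runif(500, 0, 2 * pi),
                         group_id = NA_integer_)
  stepped <- step_ungrouped(dots, cfg)
  expect_equal(sqrt(stepped$dx^2 + stepped$dy^2), rep(1.7, 500),
               tolerance = 1e-12)

  # net left-to-right drift from the rightward bias
  set.seed(3)
  mean_dx <- mean(replicate(30, {
    dots$direction <- runif(500, 0, 2 * pi)
    mean(step_ungrouped(dots, cfg)$dx)
  }))
  expect_gt(mean_dx, 0.3)
})

test_that("grouped kinematics: shared displacement, no bias, edge reversal", {
  cfg <- sim_config("moving_greyscale", n_groups = 2, seed = 1)
  dots <- tibble::tibble(dot = 1:40, x = runif(40, 200, 800),
                         y = runif(40, 200, 600),
                         direction = runif(40, 0, 2 * pi),
                         group_id = rep(c(1L, 2L, NA), length.out = 40))
  set.seed(4)
  st <- step_groups(dots, shared_direction = 1, config = cfg)
  moved <- st$dots
  grp <- !is.na(dots$group_id)
  dx <- moved$dx[grp]
  dy <- moved$dy[grp]
  # identical displacement across all grouped dots in all groups
  expect_identical(length(unique(dx)), 1L)
  expect_identical(length(unique(dy)), 1L)
  expect_equal(sqrt(dx[1]^2 + dy[1]^2), 1.7, tolerance = 1e-12)
  # ungrouped rows untouched by the group step
  expect_identical(moved$x[!grp], dots$x[!grp])

  # group flush against the right edge heading right reverses and stays in
  edge <- tibble::tibble(dot = 1:3, x = c(1023.5, 1000, 500),
                         y = c(400, 400, 400),
                         direction = 0, group_id = c(1L, 1L, NA))
  set.seed(5)
  st2 <- step_groups(edge, shared_direction = 0, config = cfg)
  expect_lt(st2$dots$x[1], edge$x[1])
  expect_true(all(st2$dots$x[1:2] >= 0 & st2$dots$x[1:2] <= 1024))
  expect_lt(abs(st2$shared_direction %% (2 * pi) - pi), pi / 2)

  # unbiased shared walk: mean x-displacement indistinguishable from 0.
  # Means of independent short walks (fresh random initial direction each)
  # give independent samples for the t-test.
  set.seed(6)
  centre <- tibble::tibble(dot = 1L, x = 512, y = 384, direction = 0,
                           group_id = 1L)
  walk_means <- replicate(400, {
    shared <- runif(1, 0, 2 * pi)
    mean(vapply(1:15, function(i) {
      st <- step_groups(centre, shared, cfg)
      shared <<- st$shared_direction
      st$dots$dx
    }, numeric(1)))
  })
  expect_gt(stats::t.test(walk_means)$p.value, 0.01)
})

test_that("wrapping maps positions onto the torus, grouped dots exempt", {
  cfg <- sim_config("moving_colour", seed = 1)
  d <- tibble::tibble(dot = 1:3, x = c(1030, 100, -8), y = c(100, -3, 770),
                      direction = 0, group_id = c(NA, NA, 1L))
  w <- wrap_position(d, cfg)
  expect_equal(w$x[1:2], c(6, 100))
  expect_equal(w$y[1:2], c(100, 765))  # (-3) %% 768 = 765
  expect_equal(w$x[3], -8)  # grouped: untouched by wrapping
})

test_that("recolouring: group colour inside regions, exact reversion outside", {
  cfg <- sim_config("moving_colour", n_groups = 2, seed = 9)
  seq1 <- generate_sequence(cfg)
  expect_false(is.null(seq1$group_colour))
  # reconstruct base colours from a frame where the dot is outside regions
  regions <- seq1$regions
  fr <- seq1$frames
  inside <- rep(FALSE, nrow(fr))
  for (i in seq_len(nrow(regions))) {
    inside <- inside | ((fr$x - regions$cx[i])^2 +
                          (fr$y - regions$cy[i])^2 <= regions$radius[i]^2)
  }
  gc <- seq1$group_colour
  # all in-region dots display the single group colour
  expect_true(all(fr$r[inside] == gc[1] & fr$g[inside] == gc[2] &
                    fr$b[inside] == gc[3]))
  expect_identical(nrow(unique(fr[inside, c("r", "g", "b")])), 1L)
  # outside all regions each dot always shows one constant base colour
  outside_cols <- fr[!inside, ] |>
    dplyr::group_by(dot) |>
    dplyr::summarise(k = dplyr::n_distinct(paste(r, g, b)))
  expect_true(all(outside_cols$k == 1))
  # a dot that crosses a region reverts exactly to its base colour
  crossing <- fr |>
    dplyr::mutate(inside = inside) |>
    dplyr::group_by(dot) |>
    dplyr::filter(any(inside) & any(!inside)) |>
    dplyr::ungroup()
  expect_gt(nrow(crossing), 0)
  reverted <- crossing |>
    dplyr::filter(!inside) |>
    dplyr::group_by(dot) |>
    dplyr::summarise(k = dplyr::n_distinct(paste(r, g, b)))
  expect_true(all(reverted$k == 1))
  # greyscale condition refuses recolouring
  expect_error(recolour_in_regions(tibble::tibble(), regions, gc,
                                   "moving_greyscale"),
               "colour conditions")
})

test_that("full sequences: frame counts, statics, containment, determinism", {
  mg <- generate_sequence(sim_config("moving_greyscale", n_groups = 2,
                                     seed = 3))
  expect_identical(length(unique(mg$frames$frame)), 250L)
  expect_true(all(table(mg$frames$frame) == 680))
  expect_true(all(mg$frames$x >= 0 & mg$frames$x < 1024 &
                    mg$frames$y >= 0 & mg$frames$y < 768))

  st <- generate_sequence(sim_config("static_colour", seed = 4))
  expect_identical(length(unique(st$frames$frame)), 1L)
  expect_identical(nrow(st$regions), 0L)
  expect_identical(nrow(st$frames), 680L)

  a <- generate_sequence(sim_config("moving_colour", n_groups = 1, seed = 5))
  b <- generate_sequence(sim_config("moving_colour", n_groups = 1, seed = 5))
  expect_identical(a$frames, b$frames)
  expect_identical(a$regions, b$regions)
  c2 <- generate_sequence(sim_config("moving_colour", n_groups = 1, seed = 6))
  expect_false(identical(a$frames, c2$frames))
})

test_that("speed conservation and group coherence hold over whole sequences", {
  seq_mg <- generate_sequence(sim_config("moving_greyscale", n_groups = 3,
                                         seed = 11))
  disp <- sequence_displacements(seq_mg)
  expect_equal(sqrt(disp$dx^2 + disp$dy^2),
               rep(1.7, nrow(disp)), tolerance = 1e-9)
  grouped <- disp |>
    dplyr::filter(!is.na(group_id)) |>
    dplyr::group_by(frame) |>
    dplyr::summarise(vdx = stats::var(dx), vdy = stats::var(dy),
                     n = dplyr::n())
  expect_gt(nrow(grouped), 0)
  multi <- grouped[grouped$n > 1, ]
  expect_true(all(multi$vdx < 1e-20 & multi$vdy < 1e-20))
  # ungrouped dots drift rightward on average, grouped do not
  free_dx <- disp$dx[is.na(disp$group_id)]
  expect_gt(length(free_dx), 1e4)
  expect_gt(mean(free_dx), 0)
  log <- seq_mg$group_displacement
  expect_identical(nrow(log), 250L)
})
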