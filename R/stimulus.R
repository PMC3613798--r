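#' Initialise the dot field
#'
#' Places `n_dots` on a cell-centred grid spanning the field and offsets each
#' dot independently on x and y by a uniform draw in
#' `[-jitter_px, +jitter_px]`. The result is an even but unstructured
#' coverage of the field. Jitter can push an edge dot slightly outside the
#' field; such positions are wrapped immediately, consistent with the
#' running wrap rule for moving dots.
#'
#' Draws from the current RNG state; [generate_sequence()] seeds a dedicated
#' position stream before calling this.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per dot: `dot`, `x`, `y`, `direction`
#'   (initial heading, uniform on `[0, 2*pi)`), `grid_x`, `grid_y` (the
#'   unjittered grid position), `group_id` (`NA` until groups are defined).
#' @export
init_dot_field <- function(config) {
  shape <- grid_shape(config)
  nx <- shape[1]; ny <- shape[2]
  cw <- config$field_w_px / nx
  ch <- config$field_h_px / ny
  gx <- rep((seq_len(nx) - 0.5) * cw, times = ny)
  gy <- rep((seq_len(ny) - 0.5) * ch, each = nx)
  jx <- stats::runif(config$n_dots, -config$jitter_px, config$jitter_px)
  jy <- stats::runif(config$n_dots, -config$jitter_px, config$jitter_px)
  tibble::tibble(
    dot = seq_len(config$n_dots),
    x = (gx + jx) %% config$field_w_px,
    y = (gy + jy) %% config$field_h_px,
    direction = stats::runif(config$n_dots, 0, 2 * pi),
    grid_x = gx,
    grid_y = gy,
    group_id = NA_integer_
  )
}

#' Convert sRGB colours to their CIELAB grey level
#'
#' The greyscale stimuli replace each randomly drawn colour by a grey whose
#' value is the lightness (L*) component of the colour in CIE 1976 L*a*b*
#' space (sRGB primaries, D65 white point), rescaled to 8 bits:
#' `round(255 * L / 100)`. White maps to 255 and black to 0.
#'
#' @param rgb A length-3 vector or an n x 3 matrix of 8-bit sRGB values.
#' @return Integer grey level(s) in 0--255.
#' @export
srgb_grey_level <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3, byrow = TRUE)
  # IEC 61966-2-1 linearisation, Rec. 709 primaries, D65 white (Yn = 1)
  u <- m / 255
  lin <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  y <- lin %*% c(0.2126729, 0.7151522, 0.0721750)
  fy <- ifelse(y > (6 / 29)^3, y^(1 / 3), y / (3 * (6 / 29)^2) + 4 / 29)
  lightness <- 116 * fy - 16
  as.integer(round(255 * lightness / 100))
}

#' Assign base colours to the dot field
#'
#' Colour conditions draw each dot's colour uniformly from the full 8-bit
#' RGB cube. Greyscale conditions draw the same random colours and replace
#' each by its CIELAB lightness grey (see [srgb_grey_level()]), so the
#' greyscale field has the luminance distribution of a colour field.
#'
#' @param dots Tibble from [init_dot_field()].
#' @param condition Stimulus condition string.
#' @return `dots` with integer columns `r`, `g`, `b` (the base colour).
#' @export
assign_colours <- function(dots, condition) {
  n <- nrow(dots)
  rgb <- matrix(as.integer(floor(stats::runif(3 * n, 0, 256))), ncol = 3)
  rgb[rgb > 255L] <- 255L
  if (!is_colour_condition(condition)) {
    grey <- srgb_grey_level(rgb)
    rgb <- cbind(grey, grey, grey)
  }
  dots$r <- as.integer(rgb[, 1])
  dots$g <- as.integer(rgb[, 2])
  dots$b <- as.integer(rgb[, 3])
  dots
}

#' Place circular grouping regions
#'
#' Region centres are drawn uniformly, subject to two constraints: the whole
#' disc lies inside the visible area, and no two regions coincide —
#' interpreted as non-overlapping discs, i.e. pairwise centre distance of at
#' least one region diameter. Placement is by rejection sampling; the
#' iteration cap can only bind for pathological geometries, not the default
#' one.
#'
#' @param n_groups Number of regions, 0--3.
#' @param config A [sim_config()].
#' @param max_iter Rejection-sampling cap.
#' @return A tibble with columns `region`, `cx`, `cy`, `radius`
#'   (zero rows when `n_groups = 0`).
#' @export
place_regions <- function(n_groups, config, max_iter = 10000L) {
  stopifnot(n_groups >= 0L, n_groups <= 3L)
  radius <- config$region_diameter_px / 2
  empty <- tibble::tibble(region = integer(), cx = double(), cy = double(),
                          radius = double())
  if (n_groups == 0L) return(empty)
  lo_x <- radius; hi_x <- config$field_w_px - radius
  lo_y <- radius; hi_y <- config$field_h_px - radius
  if (lo_x > hi_x || lo_y > hi_y) {
    stop("place_regions: region does not fit inside the field", call. = FALSE)
  }
  centres <- matrix(NA_real_, nrow = n_groups, ncol = 2)
  placed <- 0L
  for (iter in seq_len(max_iter)) {
    cand <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
    ok <- placed == 0L || all(sqrt(
      (centres[seq_len(placed), 1] - cand[1])^2 +
        (centres[seq_len(placed), 2] - cand[2])^2
    ) >= config$region_diameter_px)
    if (ok) {
      placed <- placed + 1L
      centres[placed, ] <- cand
      if (placed == n_groups) {
        return(tibble::tibble(region = seq_len(n_groups),
                              cx = centres[, 1], cy = centres[, 2],
                              radius = radius))
      }
    }
  }
  stop("place_regions: could not place ", n_groups,
       " non-overlapping regions in ", max_iter, " draws", call. = FALSE)
}

#' Advance ungrouped dots by one frame
#'
#' Each dot's heading is jittered by an independent uniform draw in
#' `[-dir_jitter_rad, +dir_jitter_rad]`; the heading unit vector is scaled
#' to the nominal speed, a rightward bias vector of
#' `x_bias_px_per_frame` is added, and the resulting velocity is
#' renormalised so every dot moves exactly `speed_px_per_frame` pixels. The
#' stored direction becomes the direction of the realised displacement, so
#' the rightward bias accumulates across frames and produces a net
#' left-to-right drift.
#'
#' @param dots Dot tibble with `x`, `y`, `direction`.
#' @param config A [sim_config()].
#' @return `dots` with updated (unwrapped) positions and directions, plus
#'   `dx`, `dy` displacement columns.
#' @export
step_ungrouped <- function(dots, config) {
  n <- nrow(dots)
  theta <- dots$direction +
    stats::runif(n, -config$dir_jitter_rad, config$dir_jitter_rad)
  vx <- config$speed_px_per_frame * cos(theta) + config$x_bias_px_per_frame
  vy <- config$speed_px_per_frame * sin(theta)
  nrm <- sqrt(vx^2 + vy^2)
  degenerate <- nrm == 0
  if (any(degenerate)) {  # unreachable when bias < speed; guard anyway
    vx[degenerate] <- cos(theta[degenerate])
    vy[degenerate] <- sin(theta[degenerate])
    nrm[degenerate] <- 1
  }
  dx <- config$speed_px_per_frame * vx / nrm
  dy <- config$speed_px_per_frame * vy / nrm
  dots$x <- dots$x + dx
  dots$y <- dots$y + dy
  dots$direction <- atan2(dy, dx)
  dots$dx <- dx
  dots$dy <- dy
  dots
}

#' Advance grouped dots by one frame of shared motion
#'
#' All grouped dots, across all groups, follow one shared random walk: a
#' single direction jitter in `[-dir_jitter_rad, +dir_jitter_rad]` is drawn
#' per frame and every grouped dot receives the identical displacement of
#' `speed_px_per_frame` pixels along the shared heading. No rightward bias
#' is applied, which is what makes the coherent dots distinguishable from
#' the drifting background. If the displacement would carry any grouped dot
#' past a screen edge, the shared direction is reversed by 180 degrees
#' before moving, so grouped dots never leave the field.
#'
#' @param dots Dot tibble; rows with non-`NA` `group_id` are moved.
#' @param shared_direction Current shared heading in radians.
#' @param config A [sim_config()].
#' @return List with `dots` (updated tibble, grouped rows carrying `dx`,
#'   `dy`) and `shared_direction` (the realised heading).
#' @export
step_groups <- function(dots, shared_direction, config) {
  grouped <- !is.na(dots$group_id)
  if (!any(grouped)) {
    return(list(dots = dots, shared_direction = shared_direction))
  }
  theta <- shared_direction +
    stats::runif(1, -config$dir_jitter_rad, config$dir_jitter_rad)
  s <- config$speed_px_per_frame
  nx <- dots$x[grouped] + s * cos(theta)
  ny <- dots$y[grouped] + s * sin(theta)
  if (any(nx < 0 | nx > config$field_w_px |
            ny < 0 | ny > config$field_h_px)) {
    theta <- theta + pi
  }
  dx <- s * cos(theta)
  dy <- s * sin(theta)
  dots$x[grouped] <- dots$x[grouped] + dx
  dots$y[grouped] <- dots$y[grouped] + dy
  dots$direction[grouped] <- atan2(dy, dx)
  if (!"dx" %in% names(dots)) {
    dots$dx <- NA_real_
    dots$dy <- NA_real_
  }
  dots$dx[grouped] <- dx
  dots$dy[grouped] <- dy
  list(dots = dots, shared_direction = theta)
}

#' Wrap dot positions into the field
#'
#' Ungrouped dots that move out of the visible area re-enter from the
#' opposite edge: positions are taken modulo the field dimensions into
#' `[0, field_w) x [0, field_h)`. Grouped dots are excluded — they use edge
#' reversal instead and never initiate an off-field move.
#'
#' @param dots Dot tibble.
#' @param config A [sim_config()].
#' @return `dots` with wrapped positions.
#' @export
wrap_position <- function(dots, config) {
  free <- is.na(dots$group_id)
  dots$x[free] <- dots$x[free] %% config$field_w_px
  dots$y[free] <- dots$y[free] %% config$field_h_px
  dots
}

#' Apply the colour-grouping recolouring rule
#'
#' In the colour-grouping condition the regions stay fixed while the dots
#' stream through them: a dot whose centre lies inside any region disc is
#' displayed in the single group colour (one colour shared by all regions,
#' drawn once per stimulus from the full RGB cube); the moment it leaves it
#' reverts exactly to its own base colour. Membership is a centre-in-disc
#' test with ties counted as inside; the dot radius is ignored.
#'
#' @param dots Dot tibble with base colours `r`, `g`, `b`.
#' @param regions Region tibble from [place_regions()].
#' @param group_colour Integer length-3 RGB triple.
#' @param condition Stimulus condition; must be a colour condition.
#' @return `dots` with `disp_r`, `disp_g`, `disp_b` display-colour columns
#'   and a logical `in_region` column.
#' @export
recolour_in_regions <- function(dots, regions, group_colour, condition) {
  if (!is_colour_condition(condition)) {
    stop("recolour_in_regions: recolouring only applies to colour conditions",
         call. = FALSE)
  }
  inside <- rep(FALSE, nrow(dots))
  if (nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      inside <- inside |
        ((dots$x - regions$cx[i])^2 + (dots$y - regions$cy[i])^2 <=
           regions$radius[i]^2)
    }
  }
  dots$disp_r <- ifelse(inside, as.integer(group_colour[1]), dots$r)
  dots$disp_g <- ifelse(inside, as.integer(group_colour[2]), dots$g)
  dots$disp_b <- ifelse(inside, as.integer(group_colour[3]), dots$b)
  dots$in_region <- inside
  dots
}

#' Generate a complete stimulus sequence
#'
#' Runs the full stimulus pipeline for one trial of the requested condition:
#'
#' * `moving_colour` — dots initialised, coloured from the RGB cube,
#'   regions placed and held static; every dot follows the jittered,
#'   rightward-biased random walk with wrap-around, and dots are recoloured
#'   to the shared group colour while inside a region.
#' * `moving_greyscale` — dots initialised and greyed by CIELAB lightness;
#'   regions define group membership once, at initialisation; grouped dots
#'   then share one unbiased random walk with edge reversal while background
#'   dots drift rightward with wrap-around. The field is first advanced
#'   through `burn_in_frames` undisplayed frames so the departing groups
#'   leave no holes.
#' * `static_colour` / `static_greyscale` — a single frame drawn at random
#'   from a freshly generated zero-group moving sequence of the matching
#'   colour type; there are no groups in the static conditions.
#'
#' The displayed frame count is `round(stim_duration_s * frame_rate_hz)` for
#' moving conditions and 1 for static conditions. All randomness derives
#' from `config$seed` through independent named streams (positions, colours,
#' regions, motion, group colour, static frame choice), so the same
#' configuration always reproduces the identical sequence.
#'
#' @param config A [sim_config()].
#' @return An object of class `"stimulus_sequence"`: a list with `config`,
#'   `frames` (tibble: `frame`, `dot`, `x`, `y`, `r`, `g`, `b`, `group_id`;
#'   colours are display colours), `regions`, `group_colour` (RGB triple or
#'   `NULL`), and `group_displacement` (per-frame shared displacement log,
#'   zero rows when no motion groups exist).
#' @export
generate_sequence <- function(config) {
  validate_sim_config(config)
  seed <- config$seed
  cond <- config$condition

  if (is_static_condition(cond)) {
    moving_cond <- if (is_colour_condition(cond)) "moving_colour" else
      "moving_greyscale"
    base_cfg <- config
    base_cfg$condition <- moving_cond
    base_cfg$n_groups <- 0L
    base_cfg$burn_in_frames <- 0L
    class(base_cfg) <- "sim_config"
    moving <- generate_sequence(base_cfg)
    pick <- with_seed(derive_seed(seed, "static_frame"),
                      sample.int(n_displayed_frames(config), 1))
    frames <- moving$frames[moving$frames$frame == pick, ]
    frames$frame <- 1L
    out <- list(config = config, frames = frames,
                regions = place_regions(0L, config),
                group_colour = NULL,
                group_displacement = empty_displacement_log())
    class(out) <- "stimulus_sequence"
    return(out)
  }

  dots <- with_seed(derive_seed(seed, "positions"), init_dot_field(config))
  dots <- with_seed(derive_seed(seed, "colours"),
                    assign_colours(dots, cond))
  regions <- with_seed(derive_seed(seed, "regions"),
                       place_regions(config$n_groups, config))

  n_frames <- n_displayed_frames(config)
  frames <- vector("list", n_frames)
  disp_log <- list()

  if (cond == "moving_colour") {
    group_colour <- with_seed(derive_seed(seed, "group_colour"),
                              as.integer(floor(stats::runif(3, 0, 256))))
    group_colour[group_colour > 255L] <- 255L
    motion_seed <- derive_seed(seed, "motion")
    frames <- with_seed(motion_seed, {
      out <- vector("list", n_frames)
      for (f in seq_len(n_frames)) {
        dots <- wrap_position(step_ungrouped(dots, config), config)
        shown <- recolour_in_regions(dots, regions, group_colour, cond)
        out[[f]] <- tibble::tibble(
          frame = f, dot = shown$dot, x = shown$x, y = shown$y,
          r = shown$disp_r, g = shown$disp_g, b = shown$disp_b,
          group_id = NA_integer_)
      }
      out
    })
    result <- list(config = config, frames = dplyr::bind_rows(frames),
                   regions = regions, group_colour = group_colour,
                   group_displacement = empty_displacement_log())
  } else {  # moving_greyscale
    if (nrow(regions) > 0) {
      member <- rep(NA_integer_, nrow(dots))
      for (i in seq_len(nrow(regions))) {
        inside <- (dots$x - regions$cx[i])^2 + (dots$y - regions$cy[i])^2 <=
          regions$radius[i]^2
        member[inside & is.na(member)] <- i
      }
      dots$group_id <- member
    }
    motion_seed <- derive_seed(seed, "motion")
    sim <- with_seed(motion_seed, {
      shared <- stats::runif(1, 0, 2 * pi)
      log_rows <- vector("list", n_frames)
      out <- vector("list", n_frames)
      total <- config$burn_in_frames + n_frames
      for (f in seq_len(total)) {
        ungrp <- is.na(dots$group_id)
        moved <- step_ungrouped(dots, config)
        # grouped dots take the shared step instead of the individual one
        dots$x[ungrp] <- moved$x[ungrp]
        dots$y[ungrp] <- moved$y[ungrp]
        dots$direction[ungrp] <- moved$direction[ungrp]
        st <- step_groups(dots, shared, config)
        dots <- wrap_position(st$dots, config)
        shared <- st$shared_direction
        if (f > config$burn_in_frames) {
          k <- f - config$burn_in_frames
          out[[k]] <- tibble::tibble(
            frame = k, dot = dots$dot, x = dots$x, y = dots$y,
            r = dots$r, g = dots$g, b = dots$b, group_id = dots$group_id)
          log_rows[[k]] <- tibble::tibble(
            frame = k,
            dx = config$speed_px_per_frame * cos(shared),
            dy = config$speed_px_per_frame * sin(shared))
        }
      }
      list(frames = out, log = log_rows)
    })
    disp <- if (any(!is.na(dots$group_id))) dplyr::bind_rows(sim$log) else
      empty_displacement_log()
    result <- list(config = config, frames = dplyr::bind_rows(sim$frames),
                   regions = regions, group_colour = NULL,
                   group_displacement = disp)
  }
  class(result) <- "stimulus_sequence"
  result
}

n_displayed_frames <- function(config) {
  if (is_static_condition(config$condition)) 1L else
    as.integer(round(config$stim_duration_s * config$frame_rate_hz))
}

empty_displacement_log <- function() {
  tibble::tibble(frame = integer(), dx = double(), dy = double())
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  nf <- length(unique(x$frames$frame))
  cat("<stimulus_sequence> ", x$config$condition, ", ", nf, " frame(s), ",
      x$config$n_dots, " dots, ", nrow(x$regions), " region(s)\n", sep = "")
  invisible(x)
}

#' Plot one frame of a stimulus sequence
#'
#' @param object A `stimulus_sequence`.
#' @param frame Frame index to draw.
#' @param ... Unused.
#' @return A ggplot object showing the dots in their display colours and the
#'   grouping-region outlines.
#' @export
autoplot.stimulus_sequence <- function(object, frame = 1L, ...) {
  fr <- dplyr::filter(object$frames, .data$frame == !!frame)
  fr$col <- grDevices::rgb(fr$r, fr$g, fr$b, maxColorValue = 255)
  p <- ggplot2::ggplot(fr, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = fr$col,
                        size = object$config$dot_diameter_px / 4) +
    ggplot2::coord_fixed(xlim = c(0, object$config$field_w_px),
                         ylim = c(0, object$config$field_h_px)) +
    ggplot2::theme_void() +
    ggplot2::theme(panel.background =
                     ggplot2::element_rect(fill = "black"))
  if (nrow(object$regions) > 0) {
    ang <- seq(0, 2 * pi, length.out = 100)
    circ <- tidyr::crossing(object$regions, tibble::tibble(ang = ang))
    circ$px <- circ$cx + circ$radius * cos(circ$ang)
    circ$py <- circ$cy + circ$radius * sin(circ$ang)
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(x = .data$px, y = .data$py, group = .data$region),
      colour = "grey50", linetype = "dashed")
  }
  p
}
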