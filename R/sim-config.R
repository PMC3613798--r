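#' Stimulus simulation configuration
#'
#' Bundles every numeric parameter of the random-dot stimulus generator with
#' its standard default: a 680-dot field on a 1024 x 768 px area, 10 px
#' dots initialised on a grid and jittered by up to 10 px per axis, circular
#' grouping regions 100 px in diameter, per-frame direction jitter of
#' +/- 0.2 rad, a 1.5 px/frame rightward bias, displacement normalised to
#' 1.7 px/frame, a 100-frame burn-in for the motion-grouping condition, and
#' 5 s stimulus / 3 s blank timing.
#'
#' Static conditions carry no groupings: `n_groups` is forced to 0 and a
#' non-zero request is an error.
#'
#' @param condition One of `"moving_colour"`, `"moving_greyscale"`,
#'   `"static_colour"`, `"static_greyscale"`.
#' @param n_groups Number of grouping regions, 0--3. Must be 0 for static
#'   conditions.
#' @param n_dots Number of dots.
#' @param dot_diameter_px Dot diameter in pixels (display metadata only;
#'   membership tests use the dot centre).
#' @param field_w_px,field_h_px Field size in pixels.
#' @param jitter_px Half-range of the uniform per-axis offset applied to the
#'   initial grid positions.
#' @param region_diameter_px Diameter of each circular grouping region.
#' @param dir_jitter_rad Half-range of the uniform per-frame direction change.
#' @param x_bias_px_per_frame Magnitude of the rightward bias vector added to
#'   ungrouped dot velocities before normalisation.
#' @param speed_px_per_frame Norm of every dot's per-frame displacement after
#'   normalisation.
#' @param burn_in_frames Number of simulated but undisplayed frames used to
#'   settle the dot field in the motion-grouping condition.
#' @param stim_duration_s,blank_duration_s Stimulus and blank durations in
#'   seconds.
#' @param frame_rate_hz Frame rate. The default 50 Hz follows from the dot
#'   geometry: a 10 px dot subtends about 0.2 degrees, i.e. about 50 px per
#'   degree, so 1.7 px/frame matches the 1.7 deg/s dot speed at 50 frames/s.
#' @param grid_cols Number of grid columns at initialisation, or `NULL` to
#'   pick the factor pair of `n_dots` whose cells are closest to square
#'   (34 x 20 for the defaults). `grid_cols` must divide `n_dots`.
#' @param seed Integer root seed; all internal random streams derive from it.
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config("moving_colour", n_groups = 2, seed = 1)
#' cfg$n_dots
#' @export
sim_config <- function(condition = c("moving_colour", "moving_greyscale",
                                     "static_colour", "static_greyscale"),
                       n_groups = 0L,
                       n_dots = 680L,
                       dot_diameter_px = 10,
                       field_w_px = 1024,
                       field_h_px = 768,
                       jitter_px = 10,
                       region_diameter_px = 100,
                       dir_jitter_rad = 0.2,
                       x_bias_px_per_frame = 1.5,
                       speed_px_per_frame = 1.7,
                       burn_in_frames = 100L,
                       stim_duration_s = 5,
                       blank_duration_s = 3,
                       frame_rate_hz = 50,
                       grid_cols = NULL,
                       seed = 1L) {
  condition <- match.arg(condition)
  cfg <- list(
    condition = condition,
    n_groups = as.integer(n_groups),
    n_dots = as.integer(n_dots),
    dot_diameter_px = dot_diameter_px,
    field_w_px = field_w_px,
    field_h_px = field_h_px,
    jitter_px = jitter_px,
    region_diameter_px = region_diameter_px,
    dir_jitter_rad = dir_jitter_rad,
    x_bias_px_per_frame = x_bias_px_per_frame,
    speed_px_per_frame = speed_px_per_frame,
    burn_in_frames = as.integer(burn_in_frames),
    stim_duration_s = stim_duration_s,
    blank_duration_s = blank_duration_s,
    frame_rate_hz = frame_rate_hz,
    grid_cols = if (is.null(grid_cols)) NULL else as.integer(grid_cols),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  pos <- c("n_dots", "dot_diameter_px", "field_w_px", "field_h_px",
           "region_diameter_px", "speed_px_per_frame", "stim_duration_s",
           "blank_duration_s", "frame_rate_hz")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("sim_config: `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  nonneg <- c("jitter_px", "dir_jitter_rad", "x_bias_px_per_frame",
              "burn_in_frames")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop("sim_config: `", f, "` must be non-negative", call. = FALSE)
    }
  }
  if (cfg$n_groups < 0L || cfg$n_groups > 3L) {
    stop("sim_config: `n_groups` must be between 0 and 3", call. = FALSE)
  }
  if (is_static_condition(cfg$condition) && cfg$n_groups != 0L) {
    stop("sim_config: static conditions have no groupings; ",
         "`n_groups` must be 0", call. = FALSE)
  }
  if (cfg$region_diameter_px > min(cfg$field_w_px, cfg$field_h_px)) {
    stop("sim_config: grouping region larger than the field", call. = FALSE)
  }
  invisible(cfg)
}

is_static_condition <- function(condition) {
  condition %in% c("static_colour", "static_greyscale")
}

is_colour_condition <- function(condition) {
  condition %in% c("moving_colour", "static_colour")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$condition, ", ", x$n_groups, " group(s), ",
      x$n_dots, " dots on ", x$field_w_px, "x", x$field_h_px,
      " px, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Grid layout implied by a stimulus configuration
#'
#' The dots start on a cell-centred grid. When `grid_cols` is not given the
#' factor pair of `n_dots` whose cells are closest to square on the
#' configured field is used; 680 dots on 1024 x 768 px yields 34 columns by
#' 20 rows.
#'
#' @param config A [sim_config()].
#' @return Integer vector `c(cols, rows)`.
#' @export
grid_shape <- function(config) {
  n <- config$n_dots
  if (!is.null(config$grid_cols)) {
    if (n %% config$grid_cols != 0L) {
      stop("sim_config: `n_dots` (", n, ") is not divisible by `grid_cols` (",
           config$grid_cols, ")", call. = FALSE)
    }
    return(c(config$grid_cols, n %/% config$grid_cols))
  }
  divs <- which(n %% seq_len(n) == 0L)
  cell_mismatch <- abs(config$field_w_px / divs - config$field_h_px * divs / n)
  cols <- divs[which.min(cell_mismatch)]
  c(cols, n %/% cols)
}
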