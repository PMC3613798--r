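#' Export a stimulus sequence to a frame-dump file
#'
#' Writes the playback format: a UTF-8 text file with `#`-prefixed metadata
#' header lines (every configuration field including the seed, plus the
#' group colour when present), `#region`-prefixed region rows
#' (`region`, `cx`, `cy`, `radius`), then one tab-separated row per dot per
#' frame: `frame`, `dot`, `x`, `y`, `r`, `g`, `b`, `group_id` (-1 when the
#' dot belongs to no group). Positions are printed with full double
#' precision so the round trip is lossless.
#'
#' @param seq A [generate_sequence()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_frames <- function(seq, path) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  cfg <- seq$config
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(
    "# dotgroup frame dump v1",
    paste0("# condition=", cfg$condition),
    paste0("# n_groups=", cfg$n_groups),
    paste0("# n_dots=", cfg$n_dots),
    paste0("# dot_diameter_px=", num(cfg$dot_diameter_px)),
    paste0("# field_w_px=", num(cfg$field_w_px)),
    paste0("# field_h_px=", num(cfg$field_h_px)),
    paste0("# jitter_px=", num(cfg$jitter_px)),
    paste0("# region_diameter_px=", num(cfg$region_diameter_px)),
    paste0("# dir_jitter_rad=", num(cfg$dir_jitter_rad)),
    paste0("# x_bias_px_per_frame=", num(cfg$x_bias_px_per_frame)),
    paste0("# speed_px_per_frame=", num(cfg$speed_px_per_frame)),
    paste0("# burn_in_frames=", cfg$burn_in_frames),
    paste0("# stim_duration_s=", num(cfg$stim_duration_s)),
    paste0("# blank_duration_s=", num(cfg$blank_duration_s)),
    paste0("# frame_rate_hz=", num(cfg$frame_rate_hz)),
    paste0("# seed=", cfg$seed)
  )
  if (!is.null(seq$group_colour)) {
    hdr <- c(hdr, paste0("# group_colour=",
                         paste(seq$group_colour, collapse = ",")))
  }
  if (nrow(seq$regions) > 0) {
    hdr <- c(hdr, sprintf("#region\t%d\t%s\t%s\t%s",
                          seq$regions$region, num(seq$regions$cx),
                          num(seq$regions$cy), num(seq$regions$radius)))
  }
  fr <- seq$frames
  gid <- ifelse(is.na(fr$group_id), -1L, fr$group_id)
  body <- sprintf("%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d",
                  fr$frame, fr$dot, num(fr$x), num(fr$y),
                  fr$r, fr$g, fr$b, gid)
  writeLines(c(hdr, "frame\tdot\tx\ty\tr\tg\tb\tgroup_id", body), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a frame-dump file back into a stimulus sequence
#'
#' Parses the format written by [export_frames()]. Malformed data rows raise
#' an error naming the offending line number.
#'
#' @param path Frame-dump file path.
#' @return A `stimulus_sequence` (without the per-frame group-displacement
#'   log, which is not part of the interchange format).
#' @export
import_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  kv <- list()
  regions <- list()
  for (ln in meta_lines) {
    if (startsWith(ln, "#region")) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 5) {
        stop("import_frames: malformed region line: ", ln, call. = FALSE)
      }
      regions[[length(regions) + 1L]] <- tibble::tibble(
        region = as.integer(parts[2]), cx = as.numeric(parts[3]),
        cy = as.numeric(parts[4]), radius = as.numeric(parts[5]))
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      key <- sub("^#\\s*", "", eq[1])
      kv[[key]] <- eq[2]
    }
  }
  need <- c("condition", "n_groups", "n_dots", "seed")
  missing <- setdiff(need, names(kv))
  if (length(missing) > 0) {
    stop("import_frames: header missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg <- sim_config(
    condition = kv$condition,
    n_groups = as.integer(kv$n_groups),
    n_dots = as.integer(kv$n_dots),
    dot_diameter_px = as.numeric(kv$dot_diameter_px),
    field_w_px = as.numeric(kv$field_w_px),
    field_h_px = as.numeric(kv$field_h_px),
    jitter_px = as.numeric(kv$jitter_px),
    region_diameter_px = as.numeric(kv$region_diameter_px),
    dir_jitter_rad = as.numeric(kv$dir_jitter_rad),
    x_bias_px_per_frame = as.numeric(kv$x_bias_px_per_frame),
    speed_px_per_frame = as.numeric(kv$speed_px_per_frame),
    burn_in_frames = as.integer(kv$burn_in_frames),
    stim_duration_s = as.numeric(kv$stim_duration_s),
    blank_duration_s = as.numeric(kv$blank_duration_s),
    frame_rate_hz = as.numeric(kv$frame_rate_hz),
    seed = as.integer(kv$seed))

  body_idx <- which(!is_meta)
  if (length(body_idx) < 1) stop("import_frames: no data rows", call. = FALSE)
  header_row <- lines[body_idx[1]]
  if (!identical(header_row, "frame\tdot\tx\ty\tr\tg\tb\tgroup_id")) {
    stop("import_frames: unexpected column header at line ", body_idx[1],
         call. = FALSE)
  }
  data_idx <- body_idx[-1]
  parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 8L)
  if (length(bad) > 0) {
    stop("import_frames: malformed data row at line ", data_idx[bad[1]],
         ": expected 8 tab-separated fields", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 8, byrow = TRUE)
  numm <- suppressWarnings(apply(m, 2, as.numeric))
  if (anyNA(numm)) {
    bad_row <- which(rowSums(is.na(numm)) > 0)[1]
    stop("import_frames: non-numeric value at line ", data_idx[bad_row],
         call. = FALSE)
  }
  gid <- as.integer(numm[, 8])
  frames <- tibble::tibble(
    frame = as.integer(numm[, 1]), dot = as.integer(numm[, 2]),
    x = numm[, 3], y = numm[, 4],
    r = as.integer(numm[, 5]), g = as.integer(numm[, 6]),
    b = as.integer(numm[, 7]),
    group_id = ifelse(gid < 0L, NA_integer_, gid))
  group_colour <- if (!is.null(kv$group_colour)) {
    as.integer(strsplit(kv$group_colour, ",", fixed = TRUE)[[1]])
  } else NULL
  out <- list(
    config = cfg, frames = frames,
    regions = if (length(regions) > 0) dplyr::bind_rows(regions) else
      place_regions(0L, cfg),
    group_colour = group_colour,
    group_displacement = empty_displacement_log())
  class(out) <- "stimulus_sequence"
  out
}
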