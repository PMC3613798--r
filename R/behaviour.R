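#' Accuracy and reaction time by number of groupings
#'
#' Summarises a trial-response table: per true grouping count (1--3, the
#' counts whose task difficulty is at issue; 0 is included when present),
#' the fraction of correct reports and the mean reaction time of the
#' correct reports. When responses come from several subjects, paired
#' two-sided t-tests compare accuracy between every pair of grouping
#' counts across subjects. Cells with no trials are reported as missing,
#' never as zero; a comparison with identically zero differences (e.g. two
#' perfect cells) has no variance and its p-value is 1 by convention.
#'
#' @param responses Tibble with columns `n_groups` (true count),
#'   `response` (reported count, `NA` if missing), `rt` (ms) and,
#'   optionally, `subject`.
#' @return A list of class `"behaviour_summary"`: `by_groups` (tibble:
#'   `n_groups`, `n_trials`, `n_correct`, `accuracy`, `mean_rt_correct`)
#'   and `pairwise` (tibble of paired comparisons; zero rows without a
#'   `subject` column or with fewer than 2 subjects).
#' @export
accuracy_rt_by_groups <- function(responses) {
  stopifnot(all(c("n_groups", "response", "rt") %in% names(responses)))
  if (nrow(responses) == 0) {
    stop("accuracy_rt_by_groups: empty response table", call. = FALSE)
  }
  by_groups <- responses |>
    dplyr::group_by(n_groups = .data$n_groups) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$response == .data$n_groups, na.rm = TRUE),
      accuracy = .data$n_correct / .data$n_trials,
      mean_rt_correct = mean(
        .data$rt[!is.na(.data$response) &
                   .data$response == .data$n_groups]),
      .groups = "drop") |>
    dplyr::arrange(.data$n_groups)

  pairwise <- tibble::tibble(group_a = integer(), group_b = integer(),
                             mean_diff = double(), p_value = double())
  if ("subject" %in% names(responses) &&
        length(unique(responses$subject)) >= 2) {
    per_subj <- responses |>
      dplyr::group_by(.data$subject, n_groups = .data$n_groups) |>
      dplyr::summarise(
        accuracy = mean(.data$response == .data$n_groups, na.rm = TRUE),
        .groups = "drop")
    levels <- sort(unique(per_subj$n_groups))
    combos <- utils::combn(levels, 2)
    rows <- lapply(seq_len(ncol(combos)), function(i) {
      a <- combos[1, i]; b <- combos[2, i]
      wide <- per_subj |>
        dplyr::filter(.data$n_groups %in% c(a, b)) |>
        tidyr::pivot_wider(names_from = "n_groups",
                           values_from = "accuracy",
                           names_prefix = "g")
      da <- wide[[paste0("g", a)]]; db <- wide[[paste0("g", b)]]
      ok <- !is.na(da) & !is.na(db)
      diffs <- da[ok] - db[ok]
      p <- if (length(diffs) < 2 || stats::sd(diffs) == 0) {
        if (all(diffs == 0)) 1 else NA_real_
      } else {
        stats::t.test(diffs)$p.value
      }
      tibble::tibble(group_a = a, group_b = b,
                     mean_diff = mean(diffs), p_value = p)
    })
    pairwise <- dplyr::bind_rows(rows)
  }
  structure(list(by_groups = by_groups, pairwise = pairwise),
            class = "behaviour_summary")
}

#' @export
print.behaviour_summary <- function(x, ...) {
  cat("<behaviour_summary>\n")
  print(x$by_groups)
  invisible(x)
}

#' @export
tidy.behaviour_summary <- function(x, ...) x$by_groups

#' Eye-tracking session validity
#'
#' A session is usable only when strictly more than `threshold` (default
#' 80%) of its gaze samples are valid — invalid samples arise from blinks
#' or lost pupil/corneal reflection. Exactly 80% valid is dropped.
#'
#' @param gaze Tibble with a logical/0-1 `valid` column.
#' @param threshold Validity fraction that must be exceeded.
#' @return Tibble with `n_samples`, `n_valid`, `fraction_valid`, `keep`.
#' @export
session_validity <- function(gaze, threshold = 0.80) {
  if (nrow(gaze) == 0) {
    stop("session_validity: empty gaze record", call. = FALSE)
  }
  stopifnot("valid" %in% names(gaze))
  n <- nrow(gaze)
  nv <- sum(as.logical(gaze$valid))
  tibble::tibble(n_samples = n, n_valid = nv, fraction_valid = nv / n,
                 keep = nv / n > threshold)
}

#' Correlation between gaze dispersion and the presence of grouping
#'
#' For each stimulus epoch, computes the dispersion of the (valid) gaze
#' samples falling inside the epoch — by default the whole-epoch standard
#' deviation of eye position, combining the two axes as
#' `sqrt((var_x + var_y) / 2)`; a sliding-window variant averages that
#' statistic over windows within the epoch — and pairs it with a binary
#' indicator of whether the stimulus contained any grouping. The result is
#' the Pearson correlation across epochs: a positive value means the eyes
#' moved more when groupings were present. The coefficient is invariant to
#' affine rescaling of the gaze units. With fewer than 3 epochs, or zero
#' variance in either series, the correlation is undefined and flagged.
#'
#' @param gaze Tibble with columns `t` (s), `x`, `y`, `valid`.
#' @param events Event tibble with `onset`, `duration`, `n_groups`.
#' @param window_s Optional sliding-window length in seconds; `NULL`
#'   (default) uses the whole epoch.
#' @return Tibble with `correlation`, `n_epochs`, `defined` plus the
#'   per-epoch table as the `"epochs"` attribute.
#' @export
gaze_grouping_correlation <- function(gaze, events, window_s = NULL) {
  stopifnot(all(c("t", "x", "y", "valid") %in% names(gaze)),
            all(c("onset", "duration", "n_groups") %in% names(events)))
  if (any(diff(gaze$t) <= 0)) {
    stop("gaze_grouping_correlation: gaze timestamps must be strictly ",
         "increasing", call. = FALSE)
  }
  g <- gaze[as.logical(gaze$valid), ]
  disp <- function(x, y) {
    if (length(x) < 2) return(NA_real_)
    sqrt((stats::var(x) + stats::var(y)) / 2)
  }
  epochs <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    on <- events$onset[i]; off <- on + events$duration[i]
    in_ep <- g$t >= on & g$t < off
    d <- if (is.null(window_s)) {
      disp(g$x[in_ep], g$y[in_ep])
    } else {
      starts <- seq(on, off - window_s, by = window_s)
      vals <- vapply(starts, function(w) {
        inw <- g$t >= w & g$t < w + window_s
        disp(g$x[inw], g$y[inw])
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }
    tibble::tibble(epoch = i, dispersion = d,
                   grouping = as.integer(events$n_groups[i] > 0))
  })
  ok <- !is.na(epochs$dispersion)
  usable <- epochs[ok, ]
  defined <- nrow(usable) >= 3 &&
    stats::sd(usable$dispersion) > 0 && stats::sd(usable$grouping) > 0
  r <- if (defined) {
    stats::cor(usable$dispersion, usable$grouping)
  } else NA_real_
  out <- tibble::tibble(correlation = r, n_epochs = nrow(usable),
                        defined = defined)
  attr(out, "epochs") <- epochs
  out
}
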