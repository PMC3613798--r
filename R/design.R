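#' Build a first-level GLM design matrix
#'
#' Constructs the design for one scanning run from a BIDS-style event table.
#' Two variants are available:
#'
#' * `"six_condition"` — one boxcar regressor per condition cell, splitting
#'   the two moving conditions into grouped (1--3 groupings) and ungrouped
#'   (0 groupings) cells: moving colour with/without grouping, moving
#'   greyscale with/without grouping, static colour, static greyscale.
#' * `"four_condition_parametric"` — one boxcar per condition (moving
#'   colour, moving greyscale, static colour, static greyscale) plus, for
#'   each moving condition, a linear parametric modulator whose per-event
#'   value is the number of groupings (0--3) mean-centred across that
#'   condition's events before convolution, so the modulator is decorrelated
#'   from the condition mean response.
#'
#' Because the events are short, every task regressor is accompanied by its
#' temporal derivative (finite difference of the oversampled convolution).
#' Nuisance series (keypress regressor and six head-motion parameters) are
#' appended unconvolved, followed by an intercept. Assembly fails with a
#' rank-deficiency error naming the collinear columns.
#'
#' @param events Tibble with columns `onset`, `duration`, `trial_type`
#'   (one of the four condition names) and `n_groups`.
#' @param n_vols Number of volumes in the run.
#' @param tr Repetition time in seconds.
#' @param variant `"six_condition"` or `"four_condition_parametric"`.
#' @param nuisance Optional tibble/matrix of nuisance series, `n_vols` rows.
#' @param oversample Microtime oversampling factor for HRF convolution.
#' @return An object of class `"design_matrix"`: list with `X` (numeric
#'   matrix, `n_vols` x p), `roles` (per-column role: condition,
#'   derivative, modulator, modulator_derivative, nuisance, intercept),
#'   `tr`, `n_vols`, `variant`, and `highpass_cutoff` (`NA` until filtered).
#' @export
build_design <- function(events, n_vols, tr,
                         variant = c("six_condition",
                                     "four_condition_parametric"),
                         nuisance = NULL, oversample = 16L) {
  variant <- match.arg(variant)
  stopifnot(all(c("onset", "duration", "trial_type", "n_groups") %in%
                  names(events)))
  if (any(events$onset + events$duration > n_vols * tr)) {
    stop("build_design: events extend past the end of the run",
         call. = FALSE)
  }

  cols <- list(); roles <- character(); nm <- character()
  add <- function(series, role, name) {
    cols[[length(cols) + 1L]] <<- series
    roles <<- c(roles, role)
    nm <<- c(nm, name)
  }
  conv <- function(ev, w, deriv = FALSE) {
    convolve_events(ev$onset, ev$duration, w, n_vols, tr,
                    oversample = oversample, derivative = deriv)
  }

  if (variant == "six_condition") {
    cells <- list(
      moving_colour_grouped =
        events$trial_type == "moving_colour" & events$n_groups > 0,
      moving_colour_ungrouped =
        events$trial_type == "moving_colour" & events$n_groups == 0,
      moving_greyscale_grouped =
        events$trial_type == "moving_greyscale" & events$n_groups > 0,
      moving_greyscale_ungrouped =
        events$trial_type == "moving_greyscale" & events$n_groups == 0,
      static_colour = events$trial_type == "static_colour",
      static_greyscale = events$trial_type == "static_greyscale")
    for (cell in names(cells)) {
      ev <- events[cells[[cell]], ]
      if (nrow(ev) == 0) next
      w <- rep(1, nrow(ev))
      add(conv(ev, w), "condition", cell)
      add(conv(ev, w, deriv = TRUE), "derivative", paste0("der_", cell))
    }
  } else {
    conditions <- c("moving_colour", "moving_greyscale",
                    "static_colour", "static_greyscale")
    for (cond in conditions) {
      ev <- events[events$trial_type == cond, ]
      if (nrow(ev) == 0) next
      w <- rep(1, nrow(ev))
      add(conv(ev, w), "condition", cond)
      add(conv(ev, w, deriv = TRUE), "derivative", paste0("der_", cond))
    }
    for (cond in c("moving_colour", "moving_greyscale")) {
      ev <- events[events$trial_type == cond, ]
      if (nrow(ev) == 0) next
      w <- ev$n_groups - mean(ev$n_groups)
      if (all(w == 0)) next  # constant n_groups: modulator is identically 0
      add(conv(ev, w), "modulator", paste0("mod_", cond))
      add(conv(ev, w, deriv = TRUE), "modulator_derivative",
          paste0("modder_", cond))
    }
  }

  if (!is.null(nuisance)) {
    nuis <- as.matrix(nuisance)
    if (nrow(nuis) != n_vols) {
      stop("build_design: nuisance series must have `n_vols` rows",
           call. = FALSE)
    }
    nuis_names <- colnames(nuis)
    if (is.null(nuis_names)) {
      nuis_names <- paste0("nuisance_", seq_len(ncol(nuis)))
    }
    for (j in seq_len(ncol(nuis))) {
      add(nuis[, j], "nuisance", paste0("nuis_", nuis_names[j]))
    }
  }
  add(rep(1, n_vols), "intercept", "intercept")

  X <- do.call(cbind, cols)
  colnames(X) <- nm
  check_design_rank(X)
  structure(list(X = X, roles = roles, tr = tr, n_vols = n_vols,
                 variant = variant, oversample = oversample,
                 highpass_cutoff = NA_real_),
            class = "design_matrix")
}

check_design_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", x$variant, ": ", x$n_vols, " volumes x ",
      ncol(x$X), " regressors (TR ", x$tr, " s)",
      if (!is.na(x$highpass_cutoff))
        paste0(", high-passed at ", x$highpass_cutoff, " s"),
      "\n", sep = "")
  invisible(x)
}

#' Discrete-cosine drift basis
#'
#' Cosine regressors `cos(pi * k * (2t + 1) / (2n))` for every order `k`
#' whose period `2 * n * tr / k` is at least `cutoff_s`. This is the set a
#' high-pass filter with the given cutoff projects out.
#'
#' @param n Number of time points.
#' @param tr Sampling interval in seconds.
#' @param cutoff_s High-pass cutoff period in seconds.
#' @return Matrix with one column per retained order (possibly 0 columns).
#' @export
dct_basis <- function(n, tr, cutoff_s = 120) {
  k_max <- floor(2 * n * tr / cutoff_s)
  if (k_max < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  t <- seq_len(n) - 1
  sapply(seq_len(k_max), function(k) cos(pi * k * (2 * t + 1) / (2 * n)))
}

#' High-pass filter a design and data by DCT projection
#'
#' Removes slow drift by projecting the span of the discrete-cosine basis
#' with periods of at least `cutoff_s` (default 120 s) out of the data and
#' all design columns. The DCT columns are orthogonal to the constant, so
#' the intercept is untouched. The operation is a projection and therefore
#' idempotent, and fitting the filtered model is equivalent to including
#' the DCT set as confound regressors in the unfiltered model. A run
#' shorter than the cutoff has no basis functions to remove; the filter
#' warns and returns its input.
#'
#' @param dm A [build_design()] result.
#' @param data Numeric matrix of BOLD time series, `n_vols` x voxels (or a
#'   vector for a single voxel).
#' @param cutoff_s Cutoff period in seconds.
#' @return List with filtered `dm` and `data`.
#' @export
highpass <- function(dm, data, cutoff_s = 120) {
  stopifnot(inherits(dm, "design_matrix"))
  data <- as.matrix(data)
  stopifnot(nrow(data) == dm$n_vols)
  C <- dct_basis(dm$n_vols, dm$tr, cutoff_s)
  if (ncol(C) == 0) {
    warning("highpass: run shorter than the cutoff; nothing filtered")
    return(list(dm = dm, data = data))
  }
  resid_proj <- function(M) M - C %*% solve(crossprod(C), crossprod(C, M))
  dm$X <- resid_proj(dm$X)
  dm$X[, dm$roles == "intercept"] <- 1  # DCT ⟂ constant; keep it exact
  already <- if (is.na(dm$highpass_cutoff)) 0L else dm$df_lost %||% 0L
  dm$highpass_cutoff <- cutoff_s
  # residual degrees of freedom spent on the projected-out DCT set
  dm$df_lost <- if (already > 0L) already else ncol(C)
  list(dm = dm, data = resid_proj(data))
}
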