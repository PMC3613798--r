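#' Fit the GLM by ordinary least squares at every voxel
#'
#' Solves the least-squares problem for all voxels at once via the QR
#' decomposition of the design. Residual variance uses
#' `dof = n_vols - rank(X)` degrees of freedom.
#'
#' @param dm A (typically high-passed) [build_design()] result.
#' @param data `n_vols` x voxels matrix (or vector for one voxel).
#' @return An object of class `"glm_fit"`: list with `betas` (p x voxels),
#'   `resvar` (length voxels), `dof`, `XtXinv`, and the `dm`.
#' @export
fit_glm <- function(dm, data) {
  stopifnot(inherits(dm, "design_matrix"))
  Y <- as.matrix(data)
  X <- dm$X
  if (nrow(Y) != nrow(X)) {
    stop("fit_glm: data and design have different numbers of time points",
         call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("fit_glm: fewer time points than regressors", call. = FALSE)
  }
  check_design_rank(X)
  qrx <- qr(X)
  betas <- qr.coef(qrx, Y)
  resid <- Y - X %*% betas
  dof <- nrow(X) - qrx$rank - (dm$df_lost %||% 0L)
  resvar <- colSums(resid^2) / dof
  # clamp numerically-zero residual variance (exact fits) to exactly zero
  resvar[resvar < colMeans(Y^2) * .Machine$double.eps^1.5] <- 0
  structure(list(betas = betas, resvar = resvar, dof = dof,
                 XtXinv = solve(crossprod(X)), dm = dm),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> ", ncol(x$betas), " voxel(s), ", nrow(x$betas),
      " regressors, ", x$dof, " residual df\n", sep = "")
  invisible(x)
}

#' Weight vector for a named convenience contrast
#'
#' Maps the analysis' standard contrasts onto the columns of a design:
#' `colour_grouping_gt_none`, `motion_grouping_gt_none` and their
#' `*_lt_none` reversals (six-condition design), the localizers
#' `colour_gt_greyscale_static` (static colour > static greyscale) and
#' `moving_greyscale_gt_static`, and the parametric slopes
#' `parametric_colour` / `parametric_motion` (parametric design).
#' Derivative regressors are treated as confounds and never enter a
#' contrast.
#'
#' @param dm A [build_design()] result.
#' @param name Contrast name.
#' @return Numeric weight vector of length `ncol(dm$X)`.
#' @export
contrast_weights <- function(dm, name) {
  cn <- colnames(dm$X)
  w <- stats::setNames(numeric(length(cn)), cn)
  set <- function(col, val) {
    if (!col %in% cn) {
      stop("contrast_weights: design has no `", col, "` column (contrast `",
           name, "` unavailable for this design/event set)", call. = FALSE)
    }
    w[col] <<- val
    w
  }
  switch(name,
    colour_grouping_gt_none = {
      set("moving_colour_grouped", 1); set("moving_colour_ungrouped", -1)
    },
    colour_grouping_lt_none = {
      set("moving_colour_grouped", -1); set("moving_colour_ungrouped", 1)
    },
    motion_grouping_gt_none = {
      set("moving_greyscale_grouped", 1)
      set("moving_greyscale_ungrouped", -1)
    },
    motion_grouping_lt_none = {
      set("moving_greyscale_grouped", -1)
      set("moving_greyscale_ungrouped", 1)
    },
    colour_gt_greyscale_static = {
      set("static_colour", 1); set("static_greyscale", -1)
    },
    moving_greyscale_gt_static = {
      set("moving_greyscale_grouped", 0.5)
      set("moving_greyscale_ungrouped", 0.5)
      set("static_greyscale", -1)
    },
    parametric_colour = set("mod_moving_colour", 1),
    parametric_motion = set("mod_moving_greyscale", 1),
    stop("contrast_weights: unknown contrast `", name, "`", call. = FALSE)
  )
  unname(w)
}

#' Contrast t-statistic map
#'
#' Computes `t = c'beta / sqrt(resvar * c'(X'X)^-1 c)` at every voxel.
#' Voxels with zero residual variance are flagged (`t = NA`, recorded in
#' `undefined`) rather than divided by zero.
#'
#' @param fit A [fit_glm()] result.
#' @param weights Numeric contrast vector (length = number of regressors),
#'   or a contrast name understood by [contrast_weights()].
#' @param dim Optional integer volume dimensions for reshaping maps.
#' @return An object of class `"stat_map"`: list with `effect`, `se`, `t`
#'   (numeric vectors, or arrays when `dim` is given), `df`, `undefined`
#'   (logical flag per voxel), `dim`.
#' @export
contrast_t <- function(fit, weights, dim = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  if (is.character(weights)) weights <- contrast_weights(fit$dm, weights)
  p <- nrow(fit$betas)
  if (length(weights) != p) {
    stop("contrast_t: weight vector has length ", length(weights),
         " but the design has ", p, " regressors", call. = FALSE)
  }
  effect <- drop(crossprod(weights, fit$betas))
  cvc <- drop(crossprod(weights, fit$XtXinv %*% weights))
  se <- sqrt(fit$resvar * cvc)
  undefined <- se == 0 & !(all(weights == 0))
  t <- ifelse(se > 0, effect / se, ifelse(all(weights == 0), 0, NA_real_))
  new_stat_map(effect, se, t, fit$dof, undefined, dim)
}

new_stat_map <- function(effect, se, t, df, undefined, dim = NULL) {
  shape <- function(x) if (is.null(dim)) x else array(x, dim = dim)
  structure(list(effect = shape(effect), se = shape(se), t = shape(t),
                 df = df, undefined = shape(undefined), dim = dim),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", length(x$t), " voxel(s), df = ", x$df,
      ", t range [", sprintf("%.2f", min(x$t, na.rm = TRUE)), ", ",
      sprintf("%.2f", max(x$t, na.rm = TRUE)), "], ",
      sum(x$undefined), " undefined\n", sep = "")
  invisible(x)
}

#' Second-level (random effects) one-sample t-map
#'
#' The summary-statistics approach: per-subject contrast values are treated
#' as the data and tested against zero with a one-sample t-test at each
#' voxel (`df = n_subjects - 1`). Voxels with zero between-subject variance
#' are flagged undefined rather than given an infinite t.
#'
#' @param con_images Subjects x voxels matrix of first-level contrast
#'   values (one row per subject).
#' @param dim Optional volume dimensions.
#' @return A `"stat_map"` with the group mean effect, its standard error
#'   and t-statistic.
#' @export
second_level <- function(con_images, dim = NULL) {
  Y <- as.matrix(con_images)
  n <- nrow(Y)
  if (n < 2) stop("second_level: need at least 2 subjects", call. = FALSE)
  m <- colMeans(Y)
  se <- sqrt(apply(Y, 2, stats::var) / n)
  undefined <- se == 0
  t <- ifelse(se > 0, m / se, NA_real_)
  new_stat_map(m, se, t, n - 1, undefined, dim)
}

#' Tidy a stat map into a per-voxel tibble
#'
#' @param x A `"stat_map"`.
#' @param ... Unused.
#' @return A tibble with voxel index (and `x`, `y`, `z` when the map has a
#'   volume geometry), `effect`, `se`, `t`, `undefined`.
#' @export
tidy.stat_map <- function(x, ...) {
  out <- tibble::tibble(
    voxel = seq_along(x$t),
    effect = as.vector(x$effect), se = as.vector(x$se),
    t = as.vector(x$t), undefined = as.vector(x$undefined))
  if (!is.null(x$dim) && length(x$dim) == 3) {
    idx <- arrayInd(out$voxel, x$dim)
    out$x <- idx[, 1]; out$y <- idx[, 2]; out$z <- idx[, 3]
    out <- dplyr::relocate(out, "x", "y", "z", .after = "voxel")
  }
  out
}

#' @export
glance.stat_map <- function(x, ...) {
  tibble::tibble(
    n_voxels = length(x$t), df = x$df,
    max_t = max(x$t, na.rm = TRUE), min_t = min(x$t, na.rm = TRUE),
    n_undefined = sum(x$undefined))
}

#' Plot an axial slice of a stat map
#'
#' @param object A `"stat_map"` with 3-D geometry.
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot tile map of the t-statistic.
#' @export
autoplot.stat_map <- function(object, slice = NULL, ...) {
  if (is.null(object$dim) || length(object$dim) != 3) {
    stop("autoplot.stat_map: map has no 3-D geometry", call. = FALSE)
  }
  if (is.null(slice)) slice <- ceiling(object$dim[3] / 2)
  df <- tidy.stat_map(object)
  df <- dplyr::filter(df, .data$z == !!slice)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey20",
                                  high = "red", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("t map, slice z = ", slice),
                  fill = "t") +
    ggplot2::theme_minimal()
}
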