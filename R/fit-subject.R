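#' Combine per-session designs into one subject-level design
#'
#' Sessions are concatenated in time. Task regressors (conditions,
#' derivatives, modulators) are shared across sessions — one beta per
#' regressor for the subject — while nuisance columns and the intercept are
#' session-specific (block diagonal), so each session keeps its own mean
#' and nuisance fit. High-pass filtering is applied per session before
#' concatenation.
#'
#' @param dms List of [build_design()] results, one per session, with
#'   identical task-column layouts.
#' @param datas List of matching data matrices.
#' @return List with the combined `dm` (a `"design_matrix"`) and `data`.
#' @export
combine_session_designs <- function(dms, datas) {
  stopifnot(length(dms) == length(datas), length(dms) >= 1)
  task_roles <- c("condition", "derivative", "modulator",
                  "modulator_derivative")
  task_cols <- lapply(dms, function(d) colnames(d$X)[d$roles %in% task_roles])
  shared <- Reduce(intersect, task_cols)
  if (length(shared) == 0) {
    stop("combine_session_designs: sessions share no task regressors",
         call. = FALSE)
  }
  if (!all(vapply(task_cols, function(tc) setequal(tc, shared), logical(1)))) {
    warning("combine_session_designs: sessions have different task ",
            "regressors; using the shared set")
  }
  X_task <- do.call(rbind, lapply(dms, function(d) {
    d$X[, shared, drop = FALSE]
  }))
  sess_blocks <- lapply(seq_along(dms), function(s) {
    d <- dms[[s]]
    keep <- !(d$roles %in% task_roles)
    Xs <- d$X[, keep, drop = FALSE]
    colnames(Xs) <- paste0(colnames(Xs), "_s", s)
    list(X = Xs, roles = d$roles[keep])
  })
  n_per <- vapply(dms, function(d) d$n_vols, integer(1))
  p_extra <- vapply(sess_blocks, function(b) ncol(b$X), integer(1))
  X_extra <- matrix(0, sum(n_per), sum(p_extra))
  cn <- character(0); extra_roles <- character(0)
  row0 <- 0L; col0 <- 0L
  for (s in seq_along(sess_blocks)) {
    b <- sess_blocks[[s]]
    X_extra[row0 + seq_len(n_per[s]), col0 + seq_len(ncol(b$X))] <- b$X
    cn <- c(cn, colnames(b$X)); extra_roles <- c(extra_roles, b$roles)
    row0 <- row0 + n_per[s]; col0 <- col0 + ncol(b$X)
  }
  colnames(X_extra) <- cn
  X <- cbind(X_task, X_extra)
  role_lookup <- stats::setNames(dms[[1]]$roles, colnames(dms[[1]]$X))
  roles <- c(unname(role_lookup[shared]), extra_roles)
  dm <- structure(list(X = X, roles = roles, tr = dms[[1]]$tr,
                       n_vols = sum(n_per), variant = dms[[1]]$variant,
                       oversample = dms[[1]]$oversample,
                       highpass_cutoff = dms[[1]]$highpass_cutoff,
                       df_lost = sum(vapply(dms, function(d)
                         d$df_lost %||% 0L, integer(1)))),
                  class = "design_matrix")
  check_design_rank(dm$X)
  list(dm = dm, data = do.call(rbind, datas))
}

#' Fit the first-level GLM for one subject
#'
#' Builds the requested design variant for every session, applies the
#' 120 s discrete-cosine high-pass to data and design per session,
#' concatenates the sessions with session-specific intercepts and nuisance
#' blocks, and fits ordinary least squares at every voxel.
#'
#' @param subject A [simulate_subject()] dataset (or any object with the
#'   same structure, e.g. read from disk).
#' @param variant Design variant, as in [build_design()].
#' @param cutoff_s High-pass cutoff in seconds (`NA` to skip filtering).
#' @param use_nuisance Include the keypress and motion nuisance series.
#' @return A [fit_glm()] result.
#' @export
fit_subject <- function(subject, variant = "four_condition_parametric",
                        cutoff_s = 120, use_nuisance = TRUE) {
  dms <- list(); datas <- list()
  for (s in seq_along(subject$sessions)) {
    sess <- subject$sessions[[s]]
    nuis <- if (use_nuisance) sess$nuisance else NULL
    dm <- build_design(sess$events, subject$protocol$n_volumes,
                       subject$protocol$tr_s, variant = variant,
                       nuisance = nuis)
    dat <- sess$bold
    if (!is.na(cutoff_s)) {
      hp <- highpass(dm, dat, cutoff_s)
      dm <- hp$dm; dat <- hp$data
    }
    dms[[s]] <- dm; datas[[s]] <- dat
  }
  comb <- combine_session_designs(dms, datas)
  fit_glm(comb$dm, comb$data)
}

#' First-level contrast maps for every subject of a cohort
#'
#' Convenience wrapper: fits each subject and extracts the effect image of
#' the named contrast, ready for [second_level()] or
#' [cluster_inference()].
#'
#' @param subjects List of subject datasets.
#' @param contrast Contrast name (see [contrast_weights()]) or weight
#'   vector.
#' @param ... Passed to [fit_subject()].
#' @return Subjects x voxels matrix of contrast effect estimates.
#' @export
cohort_contrast_maps <- function(subjects, contrast, ...) {
  do.call(rbind, lapply(subjects, function(subj) {
    fit <- fit_subject(subj, ...)
    as.vector(contrast_t(fit, contrast)$effect)
  }))
}

#' Tidy a first-level fit into a per-regressor tibble
#'
#' @param x A `"glm_fit"`.
#' @param ... Unused.
#' @return Tibble with `term`, `role` and summary statistics of the beta
#'   estimates across voxels.
#' @export
tidy.glm_fit <- function(x, ...) {
  tibble::tibble(
    term = rownames(x$betas) %||% colnames(x$dm$X),
    role = x$dm$roles,
    mean_beta = rowMeans(x$betas),
    sd_beta = apply(x$betas, 1, stats::sd))
}

#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(
    n_timepoints = nrow(x$dm$X), n_regressors = ncol(x$dm$X),
    n_voxels = ncol(x$betas), df = x$dof,
    mean_resvar = mean(x$resvar))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
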