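# Independent oracles used across the suite. These are deliberately naive
# implementations (closed forms, brute force, exhaustive loops) kept separate
# from the package's own code paths.

# sRGB (8-bit, D65) -> CIELAB lightness, by the standard closed form.
lab_lightness_oracle <- function(rgb) {
  c_lin <- vapply(rgb / 255, function(u) {
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }, numeric(1))
  y <- sum(c(0.2126729, 0.7151522, 0.0721750) * c_lin)  # Y of XYZ, Yn = 1
  f <- if (y > (6 / 29)^3) y^(1 / 3) else y / (3 * (6 / 29)^2) + 4 / 29
  116 * f - 16
}

# Normal-equations OLS: beta = (X'X)^{-1} X'y.
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# Contrast t via R's lm() machinery (independent regression route).
lm_contrast_oracle <- function(X, y, w) {
  fit <- stats::lm(y ~ X - 1)
  eff <- sum(w * stats::coef(fit))
  se <- sqrt(drop(t(w) %*% stats::vcov(fit) %*% w))
  c(effect = eff, t = eff / se)
}

# Exhaustive flood-fill connected components on a 3-D logical array,
# returned as a canonical list of sorted voxel-index sets.
flood_fill_oracle <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  nb_ok <- function(a, b) {
    dd <- abs(a - b)
    s <- sum(dd)
    if (any(dd > 1)) return(FALSE)
    switch(as.character(connectivity),
           "6" = s == 1, "18" = s >= 1 && s <= 2, "26" = s >= 1)
  }
  vox <- which(mask)
  coords <- arrayInd(vox, d)
  seen <- rep(FALSE, length(vox))
  comps <- list()
  for (i in seq_along(vox)) {
    if (seen[i]) next
    comp <- i; frontier <- i; seen[i] <- TRUE
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (f in frontier) {
        for (j in seq_along(vox)) {
          if (!seen[j] && nb_ok(coords[f, ], coords[j, ])) {
            seen[j] <- TRUE
            nxt <- c(nxt, j)
          }
        }
      }
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- sort(vox[comp])
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Canonicalise a label array into the same list-of-sets form.
labels_as_sets <- function(labels) {
  ks <- setdiff(sort(unique(as.vector(labels))), 0L)
  comps <- lapply(ks, function(k) sort(which(labels == k)))
  comps[order(vapply(comps, min, numeric(1)))]
}

# Displacement between consecutive frames on a wrapped (toroidal) field.
modular_delta <- function(x2, x1, width) {
  (x2 - x1 + width / 2) %% width - width / 2
}

# Per-dot per-frame displacement table for a stimulus sequence.
sequence_displacements <- function(seq) {
  w <- seq$config$field_w_px; h <- seq$config$field_h_px
  fr <- dplyr::arrange(seq$frames, dot, frame)
  fr |>
    dplyr::group_by(dot) |>
    dplyr::mutate(dx = modular_delta(x, dplyr::lag(x), w),
                  dy = modular_delta(y, dplyr::lag(y), h)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(dx))
}
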