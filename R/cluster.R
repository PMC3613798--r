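#' Label connected suprathreshold clusters in a 3-D mask
#'
#' Connected-component labelling of a logical volume under a configurable
#' neighbourhood: 6 (faces), 18 (faces + edges, the convention of the
#' standard neuroimaging packages, and the default here) or 26 (faces +
#' edges + corners).
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same dimensions; 0 outside the mask,
#'   cluster labels 1, 2, ... inside (labelled in scan order).
#' @export
label_clusters <- function(mask, connectivity = 18L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("label_clusters: connectivity must be 6, 18 or 26", call. = FALSE)
  }
  d <- dim(mask)
  offsets <- neighbour_offsets(connectivity)
  labels <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  coords <- arrayInd(idx, d)
  in_mask <- array(FALSE, dim = d)
  in_mask[idx] <- TRUE
  cur <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      vc <- arrayInd(v, d)
      nb <- sweep(offsets, 2, as.integer(vc), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      ni <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      ni <- ni[in_mask[ni] & labels[ni] == 0L]
      if (length(ni) > 0) {
        labels[ni] <- cur
        queue <- c(queue, ni)
      }
    }
  }
  labels
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

max_cluster_size <- function(mask, connectivity) {
  lab <- label_clusters(mask, connectivity)
  if (max(lab) == 0L) 0L else max(tabulate(lab[lab > 0L]))
}

#' Cluster-extent inference by sign-flip permutation
#'
#' Group-level cluster inference on per-subject contrast maps. The observed
#' one-sample t-map is thresholded at the uncorrected voxelwise p-value
#' (one-sided, positive effects; default 0.001) and suprathreshold voxels
#' are grouped into clusters by 18-connectivity. The familywise null
#' distribution of the maximum cluster extent is built by randomly flipping
#' the sign of each subject's map — exact under symmetric errors — and the
#' corrected p of each observed cluster is the proportion of permutations
#' (plus the identity) whose maximum cluster is at least as large. A
#' Bonferroni factor for the number of contrasts tested in the family can
#' be folded in via `n_contrast_corrections`.
#'
#' @param con_images Subjects x voxels matrix of first-level contrast
#'   values.
#' @param dim Integer volume dimensions (3-D).
#' @param voxel_p Uncorrected voxelwise threshold p-value.
#' @param cluster_alpha Familywise cluster significance level.
#' @param n_perm Number of sign-flip permutations (at least 100; fewer
#'   gives an unstable null and is refused).
#' @param n_contrast_corrections Bonferroni factor across the contrast
#'   family (default 1).
#' @param connectivity Cluster connectivity (6, 18, 26).
#' @return An object of class `"cluster_result"`: list with `labels`
#'   (integer array), `clusters` (tibble: `cluster`, `size`, `peak_x/y/z`,
#'   `peak_t`, `p_fwe`, `significant`), the thresholds used, and the
#'   permutation null of maximum cluster size.
#' @export
cluster_inference <- function(con_images, dim, voxel_p = 0.001,
                              cluster_alpha = 0.05, n_perm = 1000L,
                              n_contrast_corrections = 1L,
                              connectivity = 18L) {
  Y <- as.matrix(con_images)
  n <- nrow(Y)
  if (n_perm < 100L) {
    stop("cluster_inference: n_perm below 100 gives an unstable null; ",
         "refusing", call. = FALSE)
  }
  if (prod(dim) != ncol(Y)) {
    stop("cluster_inference: `dim` does not match the number of voxels",
         call. = FALSE)
  }
  df <- n - 1
  t_thr <- stats::qt(1 - voxel_p, df)

  sum_sq <- colSums(Y^2)  # invariant under sign flips
  t_from_flips <- function(flips) {
    m <- drop(crossprod(flips, Y)) / n
    v <- (sum_sq - n * m^2) / (n - 1)
    se <- sqrt(v / n)
    ifelse(se > 0, m / se, 0)
  }

  t_obs <- t_from_flips(rep(1, n))
  mask <- array(t_obs > t_thr, dim = dim)
  labels <- label_clusters(mask, connectivity)
  n_clus <- max(labels)

  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    tp <- t_from_flips(flips)
    null_max[p] <- max_cluster_size(array(tp > t_thr, dim = dim),
                                    connectivity)
  }

  if (n_clus > 0) {
    sizes <- tabulate(labels[labels > 0L])
    peaks <- t(vapply(seq_len(n_clus), function(k) {
      vox <- which(labels == k)
      pk <- vox[which.max(t_obs[vox])]
      c(arrayInd(pk, dim), t_obs[pk])
    }, numeric(4)))
    p_fwe <- vapply(sizes, function(s) {
      pmin(1, (1 + sum(null_max >= s)) / (1 + n_perm) *
             n_contrast_corrections)
    }, numeric(1))
    clusters <- tibble::tibble(
      cluster = seq_len(n_clus), size = sizes,
      peak_x = as.integer(peaks[, 1]), peak_y = as.integer(peaks[, 2]),
      peak_z = as.integer(peaks[, 3]), peak_t = peaks[, 4],
      p_fwe = p_fwe, significant = p_fwe < cluster_alpha)
    clusters <- dplyr::arrange(clusters, dplyr::desc(.data$size))
  } else {
    clusters <- tibble::tibble(
      cluster = integer(), size = integer(), peak_x = integer(),
      peak_y = integer(), peak_z = integer(), peak_t = double(),
      p_fwe = double(), significant = logical())
  }
  structure(list(labels = labels, clusters = clusters, t_threshold = t_thr,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 n_perm = n_perm, null_max_size = null_max,
                 connectivity = connectivity, dim = dim),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s) at |t| > ",
      sprintf("%.2f", x$t_threshold), " (voxel p < ", x$voxel_p, "), ",
      sum(x$clusters$significant), " significant at FWE ", x$cluster_alpha,
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    t_threshold = x$t_threshold, voxel_p = x$voxel_p,
    cluster_alpha = x$cluster_alpha, n_perm = x$n_perm,
    null_max_size_q95 = stats::quantile(x$null_max_size, 0.95,
                                        names = FALSE))
}

#' Conjunction of two contrasts by masking
#'
#' Restricts one contrast's suprathreshold voxels to those that are also
#' suprathreshold in a second contrast: voxel survives when it passes map
#' A's own threshold (`a_p`, uncorrected one-sided) and lies within map B's
#' voxels at the uncorrected mask threshold (`mask_p`, default 0.05).
#'
#' @param map_a,map_b `"stat_map"` objects on identical geometry.
#' @param mask_p Uncorrected p-value defining B's mask.
#' @param a_p Uncorrected threshold applied to A.
#' @return An object of class `"conjunction_result"`: list with `mask`
#'   (logical conjunction mask), `masked_t` (A's t-map zeroed outside the
#'   conjunction, `NA` preserved), `overlap` (tibble of surviving voxel
#'   coordinates and A/B t-values) and `n_overlap`.
#' @export
conjunction_by_masking <- function(map_a, map_b, mask_p = 0.05,
                                   a_p = 0.001) {
  stopifnot(inherits(map_a, "stat_map"), inherits(map_b, "stat_map"))
  if (!identical(dim(map_a$t), dim(map_b$t)) ||
        length(map_a$t) != length(map_b$t)) {
    stop("conjunction_by_masking: maps have mismatching geometry",
         call. = FALSE)
  }
  thr_a <- stats::qt(1 - a_p, map_a$df)
  thr_b <- stats::qt(1 - mask_p, map_b$df)
  ta <- as.vector(map_a$t); tb <- as.vector(map_b$t)
  keep <- !is.na(ta) & !is.na(tb) & ta > thr_a & tb > thr_b
  masked_t <- ifelse(keep, ta, 0)
  overlap <- tibble::tibble(voxel = which(keep),
                            t_a = ta[keep], t_b = tb[keep])
  if (!is.null(map_a$dim) && length(map_a$dim) == 3 && nrow(overlap) > 0) {
    co <- arrayInd(overlap$voxel, map_a$dim)
    overlap$x <- co[, 1]; overlap$y <- co[, 2]; overlap$z <- co[, 3]
  }
  shape <- if (!is.null(map_a$dim)) {
    array(keep, dim = map_a$dim)
  } else keep
  structure(list(mask = shape,
                 masked_t = if (!is.null(map_a$dim))
                   array(masked_t, dim = map_a$dim) else masked_t,
                 overlap = overlap, n_overlap = sum(keep),
                 thresholds = c(a = thr_a, b = thr_b),
                 mask_p = mask_p, a_p = a_p),
            class = "conjunction_result")
}

#' @export
print.conjunction_result <- function(x, ...) {
  cat("<conjunction_result> ", x$n_overlap,
      " voxel(s) in the conjunction (A p < ", x$a_p,
      ", mask p < ", x$mask_p, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.conjunction_result <- function(x, ...) x$overlap
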