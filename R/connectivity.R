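#' Fisher r-to-z transform and its inverse
#'
#' `fisher_z` is atanh with clipping: correlations with `|r| = 1` (e.g. a
#' voxel correlated with itself) are clipped to `1 - clip` before the
#' transform so the result stays finite. `inverse_fisher` is tanh.
#'
#' @param r Correlations, `|r| <= 1`.
#' @param z Fisher-z values.
#' @param clip Clipping margin for `|r| = 1` (default 1e-7).
#' @return Transformed values of the same shape.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("domain error: |r| > 1", call. = FALSE)
  lim <- 1 - clip
  out <- atanh(pmin(pmax(r, -lim), lim))
  attributes(out) <- attributes(r)
  out
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) tanh(z)

#' Voxelwise connectivity fingerprints of a seed mask
#'
#' Correlates the time course of every seed-mask voxel with every grey-matter
#' voxel (the seed mask is itself part of grey matter, so the within-mask
#' block is included) and Fisher-z transforms the result. Each row is one
#' seed voxel's connectivity fingerprint. Zero-variance voxels are excluded
#' from the indices, with a count recorded.
#'
#' @param series A `bold_series`, or a t x v matrix covering the voxels in
#'   `voxels` (retained volumes only).
#' @param seed_mask,gm_mask 3-D masks, or linear index vectors when `series`
#'   is a matrix.
#' @param voxels For matrix input: linear voxel indices of the matrix
#'   columns.
#' @param subject_id Stored in the result.
#' @param clip Self-correlation clipping margin (see [fisher_z()]).
#' @return A `connectivity_matrix`: `z` (seed voxels x GM voxels, Fisher-z),
#'   `seed_vox`, `gm_vox` (linear indices), `subject_id`, `dim`,
#'   `n_dropped_zero_variance`.
#' @export
mask_to_gm_matrix <- function(series, seed_mask, gm_mask, voxels = NULL,
                              subject_id = NA_character_, clip = 1e-7) {
  if (inherits(series, "bold_series")) {
    dim3 <- dim(series$data)[1:3]
    seed_idx <- if (is.array(seed_mask)) mask_indices(seed_mask) else sort(as.integer(seed_mask))
    gm_idx <- if (is.array(gm_mask)) mask_indices(gm_mask) else sort(as.integer(gm_mask))
    subject_id <- if (is.na(subject_id)) series$subject_id else subject_id
    x <- series_matrix(series, sort(union(seed_idx, gm_idx)))
    voxels <- sort(union(seed_idx, gm_idx))
  } else {
    if (is.null(voxels))
      stop("voxels must map matrix columns to linear indices", call. = FALSE)
    seed_idx <- sort(as.integer(seed_mask))
    gm_idx <- sort(as.integer(gm_mask))
    x <- as.matrix(series)
    dim3 <- NULL
  }
  if (!all(seed_idx %in% voxels) || !all(gm_idx %in% voxels))
    stop("seed or GM voxels missing from the supplied series", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  zero_var <- voxels[sds == 0]
  n_dropped <- sum(seed_idx %in% zero_var) + sum(gm_idx %in% zero_var)
  seed_idx <- setdiff(seed_idx, zero_var)
  gm_idx <- setdiff(gm_idx, zero_var)
  if (!length(seed_idx) || !length(gm_idx))
    stop("no voxels with temporal variance remain", call. = FALSE)
  r <- colcor(x[, match(seed_idx, voxels), drop = FALSE],
              x[, match(gm_idx, voxels), drop = FALSE])
  structure(list(z = fisher_z(r, clip = clip),
                 seed_vox = seed_idx, gm_vox = gm_idx,
                 subject_id = subject_id, dim = dim3, clip = clip,
                 n_dropped_zero_variance = as.integer(n_dropped)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s: %d seed voxels x %d GM voxels (Fisher z)\n",
              x$subject_id, nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Fixed-effects group average of connectivity matrices
#'
#' Averages the Fisher-z matrices elementwise across subjects and transforms
#' the mean back to correlation units.
#'
#' @param matrices List of `connectivity_matrix` objects with identical
#'   voxel indices.
#' @return Seed x GM matrix of correlations (r-units), with `seed_vox` and
#'   `gm_vox` attributes.
#' @export
group_fixed_effects <- function(matrices) {
  if (!length(matrices)) stop("no matrices supplied", call. = FALSE)
  ref <- matrices[[1]]
  for (m in matrices[-1])
    if (!identical(m$seed_vox, ref$seed_vox) ||
        !identical(m$gm_vox, ref$gm_vox))
      stop("alignment error: voxel indices differ across subjects",
           call. = FALSE)
  zbar <- Reduce(`+`, lapply(matrices, `[[`, "z")) / length(matrices)
  out <- inverse_fisher(zbar)
  attr(out, "seed_vox") <- ref$seed_vox
  attr(out, "gm_vox") <- ref$gm_vox
  out
}

#' Spherical seed definition
#'
#' Returns the voxels whose centres lie within `radius_mm` (inclusive) of a
#' point given in world coordinates, using the volume's affine.
#'
#' @param centre_mm Length-3 world coordinate of the sphere centre.
#' @param radius_mm Radius in mm.
#' @param dim3 Grid dimensions.
#' @param affine 4x4 voxel-to-world affine.
#' @return Sorted linear voxel indices.
#' @export
sphere_seed <- function(centre_mm, radius_mm, dim3,
                        affine = diag_affine(c(3, 3, 3))) {
  ijk <- index_to_ijk(seq_len(prod(dim3)), dim3)
  world <- ijk_to_world(ijk, affine)
  d2 <- colSums((t(world) - centre_mm)^2)
  idx <- which(d2 <= radius_mm^2)
  if (!length(idx))
    stop("geometry error: sphere contains no voxel centres", call. = FALSE)
  sort(idx)
}

#' Seed-to-voxel connectivity map
#'
#' Averages the time courses of the seed voxels (unweighted) and correlates
#' the mean with every grey-matter voxel; values are Fisher-z transformed.
#'
#' @param series A `bold_series` or t x v matrix (see [mask_to_gm_matrix()]).
#' @param seed Seed voxel set: 3-D mask or linear indices.
#' @param gm_mask Grey-matter mask or indices.
#' @param voxels For matrix input: linear indices of the columns.
#' @param descriptor Free-form seed description stored in the result.
#' @param clip Clipping margin for [fisher_z()].
#' @return A `seed_map`: `z` (per GM voxel), `gm_vox`, `descriptor`.
#' @export
seed_to_voxel_map <- function(series, seed, gm_mask, voxels = NULL,
                              descriptor = "seed", clip = 1e-7) {
  if (inherits(series, "bold_series")) {
    seed_idx <- if (is.array(seed)) mask_indices(seed) else sort(as.integer(seed))
    gm_idx <- if (is.array(gm_mask)) mask_indices(gm_mask) else sort(as.integer(gm_mask))
    voxels <- sort(union(seed_idx, gm_idx))
    x <- series_matrix(series, voxels)
  } else {
    seed_idx <- sort(as.integer(seed))
    gm_idx <- sort(as.integer(gm_mask))
    x <- as.matrix(series)
    if (is.null(voxels))
      stop("voxels must map matrix columns to linear indices", call. = FALSE)
  }
  if (!length(seed_idx)) stop("geometry error: empty seed", call. = FALSE)
  if (!all(seed_idx %in% voxels))
    stop("geometry error: seed outside the data support", call. = FALSE)
  tc <- rowMeans(x[, match(seed_idx, voxels), drop = FALSE])
  if (stats::sd(tc) == 0)
    stop("seed mean time course has zero variance", call. = FALSE)
  keep <- gm_idx[apply(x[, match(gm_idx, voxels), drop = FALSE], 2,
                       stats::sd) > 0]
  r <- drop(colcor(matrix(tc), x[, match(keep, voxels), drop = FALSE]))
  structure(list(z = fisher_z(r, clip = clip), gm_vox = keep,
                 descriptor = descriptor),
            class = "seed_map")
}

#' @export
print.seed_map <- function(x, ...) {
  cat(sprintf("<seed_map> %s: %d GM voxels, z in [%.3f, %.3f]\n",
              x$descriptor, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}
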