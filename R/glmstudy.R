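# Compact phantom configuration for group-level inference studies: the
# parcellation phantoms aim at spatial structure, these aim at covariate
# structure, so they use few parcels on a small grid but long series, making
# the per-subject connectivity estimate precise enough that power is
# governed by the between-subject design rather than by within-subject
# sampling noise.

#' Phantom spec tuned for group-level GLM studies
#'
#' A compact two-parcel layout on an 8 x 8 x 6 grid with long time series
#' and low measurement noise, intended for permutation-GLM calibration and
#' planted-effect recovery studies where the quantity of interest is a
#' between-subject regression coefficient.
#'
#' @param n_timepoints Volumes per subject (default 12000; the per-subject
#'   Fisher-z standard error is about `1/sqrt(n_timepoints)`).
#' @param n_parcels Planted parcels (default 2).
#' @param signal_corr,noise_sd,ar_coef,seed As in [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
glm_phantom_spec <- function(n_timepoints = 12000L, n_parcels = 2L,
                             signal_corr = 0.5, noise_sd = 0.2,
                             ar_coef = 0.3, seed = 1L) {
  grid <- c(8L, 8L, 6L)
  block <- function(xs, ys, z) {
    g <- expand.grid(x = xs, y = ys, z = z)
    as.integer(g$x + (g$y - 1L) * grid[1] + (g$z - 1L) * grid[1] * grid[2])
  }
  strips <- lapply(seq_len(n_parcels), function(k) (3 * k - 1):(3 * k + 1))
  if (3 * n_parcels + 1 > grid[1])
    stop("glm phantom layout supports at most 2 parcels", call. = FALSE)
  phantom_spec(grid_shape = grid, n_timepoints = n_timepoints,
               n_parcels = n_parcels,
               parcel_geometry = lapply(strips, function(xs)
                 block(xs, 2:5, 2L)),
               network_geometry = lapply(strips, function(xs)
                 block(xs, 2:5, 5L)),
               background_gm = block(2:7, 2:5, 3L),
               wm_voxels = block(2:5, 2:3, 1L),
               csf_voxels = block(2:5, 2:3, 6L),
               signal_corr = signal_corr, noise_sd = noise_sd,
               ar_coef = ar_coef, seed = seed)
}

#' Cohort spec for interaction-recovery and calibration studies
#'
#' Pairs [glm_phantom_spec()] with the cohort-level covariate structure:
#' two groups, two scanning centres, uniform ages, and (optionally) a
#' planted group difference in the connectivity-age slope of parcel 1.
#'
#' @param n_per_group Subjects per group.
#' @param interaction_slope Planted slope difference (z per log-year);
#'   0 gives a null cohort.
#' @param n_timepoints Volumes per subject.
#' @param seed Cohort seed.
#' @param ... Further arguments to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
glm_cohort_spec <- function(n_per_group = 50L, interaction_slope = 0.02,
                            n_timepoints = 12000L, seed = 1L, ...) {
  cohort_spec(n_per_group = n_per_group,
              interaction_slope = interaction_slope,
              phantom = glm_phantom_spec(n_timepoints = n_timepoints),
              seed = seed, ...)
}

#' Streaming seed-map reducer for [make_cohort()]
#'
#' Returns a function suitable as `subject_fn`: it scrubs each subject on
#' FD/DVARS, regresses the motion model (dropping structurally constant
#' columns), computes the seed-to-voxel map of one planted parcel, and
#' discards the 4-D data. Memory stays flat however long the series are.
#'
#' @param parcel Planted parcel index used as the seed.
#' @param denoise Apply scrubbing and motion regression first (default
#'   TRUE; set FALSE only for spike-free phantoms).
#' @return A function `phantom_subject -> seed_map`.
#' @export
seed_map_reducer <- function(parcel = 1L, denoise = TRUE) {
  function(s) {
    gm_idx <- mask_indices(s$masks$gm)
    seed <- s$truth$seed_voxels[s$truth$parcel_labels == parcel]
    if (denoise) {
      x <- series_matrix(s$bold, gm_idx)
      cm <- scrub(framewise_displacement(s$motion), dvars(x))
      conf <- friston24(s$motion)
      # step-shaped phantom motion makes most of the 24 columns aliased
      # (exactly so once the transition frames are censored); keep an
      # independent subset so the projection is well posed
      qx <- qr(cbind(1, conf)[cm$keep, , drop = FALSE])
      keep_cols <- setdiff(qx$pivot[seq_len(qx$rank)], 1L) - 1L
      conf <- conf[, keep_cols, drop = FALSE]
      res <- regress_nuisance(x, conf, cm)
      seed_to_voxel_map(res, seed, gm_idx, voxels = gm_idx,
                        descriptor = sprintf("parcel%d", parcel))
    } else {
      seed_to_voxel_map(s$bold, seed, gm_idx,
                        descriptor = sprintf("parcel%d", parcel))
    }
  }
}
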