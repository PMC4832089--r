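# In-memory orchestration helpers over the module functions: these run the
# standard workflow on phantom subjects/cohorts without touching disk and are
# the building blocks of run_pipeline().

#' Preprocess one phantom subject
#'
#' Applies the standard denoising chain (scrub, 24-parameter motion + tissue
#' principal-component regression, band-pass) to the in-brain voxels of a
#' phantom subject.
#'
#' @param subject A `phantom_subject`.
#' @param ... Passed to [preprocess_bold()] (thresholds, band, order...).
#' @return The [preprocess_bold()] result.
#' @export
preprocess_subject <- function(subject, ...) {
  brain <- array(as.integer(subject$masks$gm | subject$masks$wm |
                              subject$masks$csf),
                 dim = dim(subject$masks$gm))
  preprocess_bold(subject$bold, subject$motion,
                  wm_mask = subject$masks$wm, csf_mask = subject$masks$csf,
                  analysis_mask = brain, ...)
}

#' Connectivity fingerprints for every subject of a cohort
#'
#' @param cohort A `phantom_cohort`.
#' @param preprocess Run the denoising chain first (default TRUE); when
#'   FALSE, raw series are used (appropriate for noise-free phantoms without
#'   motion spikes).
#' @param ... Passed to [preprocess_subject()].
#' @return List of `connectivity_matrix` objects.
#' @export
cohort_connectivity <- function(cohort, preprocess = TRUE, ...) {
  masks <- cohort$subjects[[1]]$masks
  seed_idx <- mask_indices(masks$seed)
  gm_idx <- mask_indices(masks$gm)
  lapply(cohort$subjects, function(s) {
    if (preprocess) {
      pp <- preprocess_subject(s, ...)
      mask_to_gm_matrix(pp$series, seed_idx, gm_idx, voxels = pp$voxels,
                        subject_id = s$subject_id)
    } else {
      mask_to_gm_matrix(s$bold, seed_idx, gm_idx)
    }
  })
}

#' Group parcellation with silhouette-based model selection
#'
#' Fixed-effects average of the subject matrices, average-linkage
#' clustering, uniform dendrogram cuts, and the across-subject silhouette-t
#' profile with its local maxima.
#'
#' @param matrices List of `connectivity_matrix` objects.
#' @param n_levels Number of uniform cut levels (default 100).
#' @param metric Fingerprint metric.
#' @return List: `group_fingerprints`, `dendrogram`, `solutions`, `profile`,
#'   and `best` (the solution at the highest-t local maximum, `NULL` if the
#'   profile has none).
#' @export
parcellate_group <- function(matrices, n_levels = 100L, metric = "corrdist") {
  fp <- group_fixed_effects(matrices)
  dend <- build_dendrogram(fp, metric = metric,
                           seed_vox = attr(fp, "seed_vox"))
  solutions <- cut_uniform_levels(dend, n_levels)
  subj_d <- lapply(matrices, function(m) fingerprint_dist(m$z, metric))
  profile <- silhouette_profile(solutions, subj_d, metric = metric)
  best <- NULL
  lm <- profile$local_maxima
  if (length(lm)) {
    pick <- lm[which.max(profile$levels$t[lm])]
    best <- solutions[[pick]]
  }
  list(group_fingerprints = fp, dendrogram = dend, solutions = solutions,
       profile = profile, best = best)
}

#' Back-project a group solution onto individual subjects
#'
#' Re-clusters every subject's own fingerprints at the group-level K,
#' matches subject clusters to group clusters through the Dice-matrix
#' procedure, and assembles replication rates and the probabilistic atlas
#' with its winner-take-all labeling.
#'
#' @param group_solution A `parcel_solution` (group level).
#' @param matrices List of subject `connectivity_matrix` objects.
#' @param dim3 Grid dimensions.
#' @param metric Fingerprint metric.
#' @param threshold Winner-take-all probability threshold (default 0.25).
#' @param groups Optional subject group labels for the replication test.
#' @return List: `subject_solutions`, `reports`, `replication`, `atlas`,
#'   `wta`.
#' @export
backproject <- function(group_solution, matrices, dim3, metric = "corrdist",
                        threshold = 0.25, groups = NULL) {
  subject_solutions <- lapply(matrices, function(m)
    subject_solution(m, K = group_solution$K, metric = metric))
  reports <- lapply(subject_solutions, function(s)
    match_clusters(group_solution, s))
  replication <- replication_rates(reports, groups = groups)
  atlas <- build_probability_maps(reports, subject_solutions, dim3)
  wta <- winner_take_all(atlas, threshold = threshold)
  list(subject_solutions = subject_solutions, reports = reports,
       replication = replication, atlas = atlas, wta = wta)
}

#' Seed-to-voxel maps for all subjects of a cohort
#'
#' @param cohort A `phantom_cohort`.
#' @param seed Seed voxel set (linear indices) or 3-D mask.
#' @param preprocess Denoise first (default FALSE: map extraction is
#'   typically run on the already-preprocessed series passed via
#'   `preprocessed`).
#' @param preprocessed Optional list of [preprocess_bold()] results aligned
#'   with the subjects.
#' @return List of `seed_map` objects.
#' @export
cohort_seed_maps <- function(cohort, seed, preprocess = FALSE,
                             preprocessed = NULL) {
  gm_idx <- mask_indices(cohort$subjects[[1]]$masks$gm)
  lapply(seq_along(cohort$subjects), function(i) {
    s <- cohort$subjects[[i]]
    if (!is.null(preprocessed)) {
      pp <- preprocessed[[i]]
      seed_to_voxel_map(pp$series, seed, gm_idx, voxels = pp$voxels)
    } else if (preprocess) {
      pp <- preprocess_subject(s)
      seed_to_voxel_map(pp$series, seed, gm_idx, voxels = pp$voxels)
    } else {
      seed_to_voxel_map(s$bold, seed, gm_idx)
    }
  })
}

#' Per-subject grey-matter values at the map voxels
#'
#' @param cohort A `phantom_cohort`.
#' @param voxels Linear voxel indices (e.g. the GM mask).
#' @return Subjects x voxels matrix.
#' @export
cohort_gm_values <- function(cohort, voxels) {
  do.call(rbind, lapply(cohort$subjects, function(s) s$gm_prob[voxels]))
}
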