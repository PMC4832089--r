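#' Specification of a simulated multi-subject cohort
#'
#' Wraps a [phantom_spec()] with cohort-level structure: two groups, ages,
#' IQ, scanning centres, per-subject motion spikes, and an optional planted
#' group difference in the connectivity-age slope of one designated
#' parcel-target pair.
#'
#' The planted effect is defined on the scale the group model actually tests:
#' the Fisher-z seed-to-voxel connectivity of the designated parcel's mean
#' time course with its network target. For subject i in group g the expected
#' map value is
#' `z_i = baseline_z + slope_g * (log(age_i) - centre)`, with
#' `slope_A - slope_B = interaction_slope` (z-units per log-year) and the
#' centring constant fixed at the midpoint of the log age range. The
#' generator converts each desired `z_i` into the latent coupling of the
#' designated parcel, accounting for seed averaging over the parcel's voxels
#' and for measurement-noise attenuation, so that ordinary least squares on
#' the realized maps recovers the planted slopes without attenuation bias.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param age_range Years, length-2 vector; ages drawn uniformly.
#' @param interaction_slope Group difference in the connectivity-age slope,
#'   z-units per log-year, applied to the designated pair.
#' @param base_slope Slope common to both groups (z per log-year).
#' @param baseline_z Expected map z of the designated pair at the centred age.
#' @param target List with `parcel` and `network` indices of the designated
#'   pair, or `NULL` to plant nothing (all parcels then use
#'   `phantom$signal_corr`).
#' @param centre_labels Scanning centre labels; subjects are assigned
#'   round-robin within group so centres stay balanced.
#' @param groups Two group labels.
#' @param fiq_mean,fiq_sd Full-scale IQ distribution.
#' @param max_spikes Per-subject motion-spike count is drawn uniformly from
#'   `0:max_spikes`; spike frames are sampled away from the first volume.
#' @param phantom A [phantom_spec()]; its `spike_frames` field is overridden
#'   per subject.
#' @param seed Cohort RNG seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group,
                        age_range = c(7, 40),
                        interaction_slope = 0,
                        base_slope = 0,
                        baseline_z = 0.3,
                        target = list(parcel = 1L, network = 1L),
                        centre_labels = c("centre1", "centre2"),
                        groups = c("A", "B"),
                        fiq_mean = 110, fiq_sd = 10,
                        max_spikes = 3L,
                        phantom = phantom_spec(),
                        seed = 1L) {
  if (n_per_group < 2) stop("cohort error: n_per_group must be >= 2",
                            call. = FALSE)
  if (length(centre_labels) < 2)
    stop("cohort error: at least 2 centres are required when centre ",
         "covariates are modelled", call. = FALSE)
  if (!is.null(target)) {
    if (target$parcel < 1 || target$parcel > phantom$n_parcels)
      stop("cohort error: designated parcel outside 1..K", call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 age_range = age_range,
                 interaction_slope = interaction_slope,
                 base_slope = base_slope, baseline_z = baseline_z,
                 target = target, centre_labels = centre_labels,
                 groups = groups, fiq_mean = fiq_mean, fiq_sd = fiq_sd,
                 max_spikes = as.integer(max_spikes), phantom = phantom,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# invert the seed-map correlation for the designated parcel:
# c_map = s / sqrt((s + (1 - s)/P) * (1 + nu^2))  ->  s
# (quadratic: s^2 - a s - b = 0 with a = c^2 (1+nu^2)(1 - 1/P),
#  b = c^2 (1+nu^2)/P)
coupling_for_map_corr <- function(c_map, n_parcel_voxels, noise_sd) {
  if (c_map <= 0) stop("planted map correlation must be positive",
                       call. = FALSE)
  a <- c_map^2 * (1 + noise_sd^2) * (1 - 1 / n_parcel_voxels)
  b <- c_map^2 * (1 + noise_sd^2) / n_parcel_voxels
  s <- (a + sqrt(a^2 + 4 * b)) / 2
  if (s >= 1)
    stop("planted connectivity is unattainable at this noise level ",
         "(required coupling >= 1)", call. = FALSE)
  s
}

#' Generate a simulated cohort
#'
#' @param spec A [cohort_spec()].
#' @param subject_fn Optional function applied to each `phantom_subject` as
#'   it is generated; its return value is stored in `$subjects` in place of
#'   the raw subject. Use this to stream large cohorts (e.g. reduce each
#'   subject to a seed map) without holding every 4-D array in memory. The
#'   generated data are identical with or without `subject_fn`.
#' @return A `phantom_cohort`: list with `subjects` (list of
#'   `phantom_subject`, or of `subject_fn` results), `covariates` (data
#'   frame: subject_id, group, age_years, fiq, centre, mean_fd), and
#'   `truth` (parcel labels, network map, planted per-group slopes,
#'   per-subject spike frames and expected target z).
#' @export
make_cohort <- function(spec, subject_fn = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2L * spec$n_per_group
  ph <- spec$phantom
  slopes <- c(spec$base_slope + spec$interaction_slope / 2,
              spec$base_slope - spec$interaction_slope / 2)
  names(slopes) <- spec$groups
  log_centre <- mean(log(spec$age_range))

  draws <- with_seed(spec$seed, {
    list(age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
         fiq = stats::rnorm(n, spec$fiq_mean, spec$fiq_sd),
         n_spikes = sample(0:spec$max_spikes, n, replace = TRUE),
         spike_draws = lapply(seq_len(n), function(i)
           sample(2:ph$n_timepoints, spec$max_spikes)),
         subject_seeds = sample.int(.Machine$integer.max, n))
  })

  group <- rep(spec$groups, each = spec$n_per_group)
  centre <- unlist(lapply(seq_len(2), function(g)
    rep_len(spec$centre_labels, spec$n_per_group)))

  subjects <- vector("list", n)
  expected_z <- rep(NA_real_, n)
  spike_list <- vector("list", n)
  mean_fd_i <- numeric(n)
  first_truth <- NULL
  for (i in seq_len(n)) {
    ph_i <- ph
    sf <- sort(draws$spike_draws[[i]][seq_len(draws$n_spikes[i])])
    ph_i$spike_frames <- as.integer(sf)
    spike_list[[i]] <- ph_i$spike_frames
    parcel_corr <- NULL
    if (!is.null(spec$target)) {
      z_i <- spec$baseline_z +
        slopes[group[i]] * (log(draws$age[i]) - log_centre)
      expected_z[i] <- z_i
      P <- length(ph$parcel_geometry[[spec$target$parcel]])
      s_i <- coupling_for_map_corr(tanh(z_i), P, ph$noise_sd)
      parcel_corr <- rep(ph$signal_corr, ph$n_parcels)
      parcel_corr[spec$target$parcel] <- s_i
    }
    subj <- make_phantom_subject(
      ph_i, subject_seed = draws$subject_seeds[i],
      parcel_corr = parcel_corr, subject_id = sprintf("sub%03d", i))
    mean_fd_i[i] <- mean(framewise_displacement(subj$motion))
    subjects[[i]] <- if (is.null(subject_fn)) subj else subject_fn(subj)
    if (i == 1L) first_truth <- subj$truth
  }

  mean_fd <- mean_fd_i
  covariates <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = group, age_years = draws$age, fiq = draws$fiq,
    centre = centre, mean_fd = mean_fd, stringsAsFactors = FALSE)

  truth <- list(seed_voxels = first_truth$seed_voxels,
                parcel_labels = first_truth$parcel_labels,
                network_map = ph$network_geometry,
                planted_slopes = slopes,
                interaction_slope = spec$interaction_slope,
                target = spec$target,
                expected_target_z = expected_z,
                spike_frames = spike_list)
  structure(list(subjects = subjects, covariates = covariates, truth = truth,
                 spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf(paste0("<phantom_cohort> %d subjects (%d per group), K = %d, ",
                     "planted slope difference = %g z/log-year\n"),
              nrow(x$covariates), x$spec$n_per_group,
              x$spec$phantom$n_parcels, x$spec$interaction_slope))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One subdirectory per subject (see [write_phantom_subject()]), plus a
#' covariates TSV and the cohort ground truth as JSON.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects)
    write_phantom_subject(s, file.path(dir, s$subject_id))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
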