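#' Specification of a single-subject connectivity phantom
#'
#' Defines the geometry and signal model of a synthetic 4-D dataset with
#' planted parcel structure. Each of the `n_parcels` parcels inside the seed
#' mask shares a latent time series with a disjoint "network" target region
#' outside the mask; voxels mix that latent with idiosyncratic fluctuations so
#' that the expected correlation between a parcel voxel and its network voxel
#' equals `signal_corr` in the noise-free case. Independent white measurement
#' noise of standard deviation `noise_sd` is added on top (in units of the
#' unit-variance signal), which attenuates realized correlations by
#' `1 / (1 + noise_sd^2)`.
#'
#' Motion spikes are modelled as steps: at each frame in `spike_frames` the
#' head position jumps by `spike_translation_mm` and the global in-brain
#' intensity steps by `spike_intensity`, so framewise displacement and DVARS
#' each flag exactly those frames.
#'
#' @param grid_shape Integer triple, voxel grid.
#' @param voxel_size mm triple.
#' @param n_timepoints Number of volumes.
#' @param tr Repetition time, seconds.
#' @param n_parcels Number of planted parcels K.
#' @param parcel_geometry List of K disjoint linear-voxel-index vectors
#'   (the seed mask is their union); `NULL` uses the default block layout.
#' @param network_geometry List of K index vectors, disjoint from each other
#'   and from all parcels; `NULL` uses the default layout.
#' @param background_gm,wm_voxels,csf_voxels Index vectors for unstructured
#'   grey matter and for the tissue compartments; `NULL` uses defaults.
#' @param signal_corr Target parcel-to-network correlation in `[0, 1)`
#'   (attained when `noise_sd = 0`).
#' @param noise_sd Measurement noise SD relative to unit signal variance.
#' @param ar_coef AR(1) coefficient of the latent and idiosyncratic series
#'   (default 0.3, mimicking the autocorrelation of band-limited BOLD).
#' @param spike_frames Volume indices receiving motion spikes.
#' @param baseline Mean intensity added to in-brain voxels (arbitrary units);
#'   gives the DVARS percent normalization a realistic denominator.
#' @param spike_translation_mm Size of the head-position step at a spike.
#' @param spike_intensity Size of the global intensity step at a spike.
#' @param seed Integer RNG seed for the spec (subject draws add their own).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(14L, 14L, 6L),
                         voxel_size = c(3, 3, 3),
                         n_timepoints = 200L,
                         tr = 2,
                         n_parcels = 6L,
                         parcel_geometry = NULL,
                         network_geometry = NULL,
                         background_gm = NULL,
                         wm_voxels = NULL,
                         csf_voxels = NULL,
                         signal_corr = 0.7,
                         noise_sd = 1,
                         ar_coef = 0.3,
                         spike_frames = integer(0),
                         baseline = 1000,
                         spike_translation_mm = 1,
                         spike_intensity = 20,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (signal_corr < 0 || signal_corr >= 1)
    stop("signal_corr must lie in [0, 1)", call. = FALSE)
  if (is.null(parcel_geometry) || is.null(network_geometry)) {
    geo <- default_phantom_geometry(grid_shape, n_parcels)
    if (is.null(parcel_geometry)) parcel_geometry <- geo$parcels
    if (is.null(network_geometry)) network_geometry <- geo$networks
    if (is.null(background_gm)) background_gm <- geo$background_gm
    if (is.null(wm_voxels)) wm_voxels <- geo$wm
    if (is.null(csf_voxels)) csf_voxels <- geo$csf
  }
  if (is.null(background_gm)) background_gm <- integer(0)
  spec <- structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size,
    n_timepoints = as.integer(n_timepoints), tr = tr,
    n_parcels = as.integer(n_parcels),
    parcel_geometry = lapply(parcel_geometry, as.integer),
    network_geometry = lapply(network_geometry, as.integer),
    background_gm = as.integer(background_gm),
    wm_voxels = as.integer(wm_voxels %||% integer(0)),
    csf_voxels = as.integer(csf_voxels %||% integer(0)),
    signal_corr = signal_corr, noise_sd = noise_sd, ar_coef = ar_coef,
    spike_frames = as.integer(spike_frames), baseline = baseline,
    spike_translation_mm = spike_translation_mm,
    spike_intensity = spike_intensity, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_phantom_spec <- function(spec) {
  nvox <- prod(spec$grid_shape)
  all_parcel <- unlist(spec$parcel_geometry)
  all_net <- unlist(spec$network_geometry)
  if (length(spec$parcel_geometry) != spec$n_parcels ||
      length(spec$network_geometry) != spec$n_parcels)
    stop("geometry error: need one parcel and one network set per parcel",
         call. = FALSE)
  if (any(vapply(spec$parcel_geometry, length, 1L) == 0L))
    stop("geometry error: empty parcel set", call. = FALSE)
  if (anyDuplicated(all_parcel))
    stop("geometry error: parcel sets overlap", call. = FALSE)
  if (anyDuplicated(all_net))
    stop("geometry error: network sets overlap", call. = FALSE)
  if (length(intersect(all_parcel, all_net)))
    stop("geometry error: network sets overlap the seed mask", call. = FALSE)
  idx <- c(all_parcel, all_net, spec$background_gm, spec$wm_voxels,
           spec$csf_voxels)
  if (any(idx < 1L | idx > nvox))
    stop("geometry error: voxel index outside the grid", call. = FALSE)
  if (any(spec$spike_frames < 1L | spec$spike_frames > spec$n_timepoints))
    stop("spike_frames outside the acquired volumes", call. = FALSE)
  invisible(TRUE)
}

# Default layout on a >= 2K+2 x 8 x 6 grid: axial slabs, one strip per parcel.
#   z = 1 white matter; z = 2 parcels (seed mask); z = 3 background GM;
#   z = 5 networks; z = 6 CSF.
default_phantom_geometry <- function(grid_shape, n_parcels) {
  if (grid_shape[1] < 2 * n_parcels + 2 || grid_shape[2] < 8 ||
      grid_shape[3] < 6)
    stop("default geometry needs a grid of at least ",
         2 * n_parcels + 2, " x 8 x 6", call. = FALSE)
  block <- function(xs, ys, z) {
    g <- expand.grid(x = xs, y = ys, z = z)
    as.integer(g$x + (g$y - 1L) * grid_shape[1] +
                 (g$z - 1L) * grid_shape[1] * grid_shape[2])
  }
  strips <- lapply(seq_len(n_parcels), function(k) (2 * k):(2 * k + 1))
  list(parcels   = lapply(strips, function(xs) block(xs, 2:7, 2L)),
       networks  = lapply(strips, function(xs) block(xs, 2:7, 5L)),
       background_gm = block(2:(2 * n_parcels + 1), 2:7, 3L),
       wm  = block(2:11, 2:5, 1L),
       csf = block(2:11, 2:5, 6L))
}

#' Masks implied by a phantom spec
#'
#' @param spec A `phantom_spec`.
#' @return List of 3-D 0/1 arrays: `seed`, `gm`, `wm`, `csf`. Grey matter is
#'   the union of the seed mask, the network targets and the background grey
#'   matter (the seed mask is included in grey matter).
#' @export
phantom_masks <- function(spec) {
  mk <- function(idx) {
    m <- array(0L, dim = spec$grid_shape)
    m[idx] <- 1L
    m
  }
  seed_idx <- sort(unlist(spec$parcel_geometry))
  gm_idx <- sort(c(seed_idx, unlist(spec$network_geometry),
                   spec$background_gm))
  list(seed = mk(seed_idx), gm = mk(gm_idx), wm = mk(spec$wm_voxels),
       csf = mk(spec$csf_voxels))
}

# t x m matrix of unit-variance AR(1) series
ar1_matrix <- function(n, m, phi) {
  e <- matrix(stats::rnorm(n * m), n, m)
  if (m == 0L || phi == 0) return(e)
  x <- stats::filter(e * sqrt(1 - phi^2), phi, method = "recursive",
                     init = matrix(e[1, ] / sqrt(1 - phi^2), 1, m))
  matrix(as.numeric(x), n, m)
}

#' Generate one phantom subject
#'
#' Draws a complete synthetic subject from a `phantom_spec`: the 4-D BOLD
#' array, tissue masks, a grey-matter probability volume, the motion table,
#' and the ground truth. Reproducible: the same `(spec, subject_seed)` pair
#' yields bit-identical output.
#'
#' @param spec A `phantom_spec`.
#' @param subject_seed Integer seed for this subject's draws.
#' @param parcel_corr Optional per-parcel latent coupling overriding
#'   `spec$signal_corr` (used to plant subject-specific effects).
#' @param subject_id Identifier stored in the BOLD container.
#' @return A `phantom_subject`: list with `bold` (`bold_series`), `masks`
#'   (seed/gm/wm/csf arrays), `gm_prob` (3-D array), `motion` (t x 6 matrix),
#'   and `truth` (parcel labels over the sorted seed-mask indices, network
#'   map, couplings, spike frames).
#' @export
make_phantom_subject <- function(spec, subject_seed,
                                 parcel_corr = NULL,
                                 subject_id = sprintf("sub%05d", subject_seed)) {
  validate_phantom_spec(spec)
  K <- spec$n_parcels
  if (is.null(parcel_corr)) parcel_corr <- rep(spec$signal_corr, K)
  if (length(parcel_corr) != K || any(parcel_corr < 0 | parcel_corr >= 1))
    stop("parcel_corr must give one value in [0, 1) per parcel", call. = FALSE)
  n <- spec$n_timepoints
  phi <- spec$ar_coef
  nvox <- prod(spec$grid_shape)

  with_seed(subject_seed, {
    sig <- matrix(0, n, nvox)   # unit-scale signal, time x all voxels
    latents <- ar1_matrix(n, K, phi)
    for (k in seq_len(K)) {
      s <- parcel_corr[k]
      for (set in list(spec$parcel_geometry[[k]],
                       spec$network_geometry[[k]])) {
        idio <- ar1_matrix(n, length(set), phi)
        sig[, set] <- sqrt(s) * latents[, k] + sqrt(1 - s) * idio
      }
    }
    if (length(spec$background_gm))
      sig[, spec$background_gm] <- ar1_matrix(n, length(spec$background_gm), phi)
    gm_idx <- c(unlist(spec$parcel_geometry), unlist(spec$network_geometry),
                spec$background_gm)
    if (spec$noise_sd > 0)
      sig[, gm_idx] <- sig[, gm_idx] +
        spec$noise_sd * matrix(stats::rnorm(n * length(gm_idx)), n)
    # tissue compartments: two shared components each, for the PC extraction
    for (set in list(spec$wm_voxels, spec$csf_voxels)) {
      if (!length(set)) next
      comp <- ar1_matrix(n, 2L, phi)
      idio <- ar1_matrix(n, length(set), phi)
      sig[, set] <- sqrt(0.3) * comp[, 1] + sqrt(0.2) * comp[, 2] +
        sqrt(0.5) * idio
    }
    brain <- c(gm_idx, spec$wm_voxels, spec$csf_voxels)
    sig[, brain] <- sig[, brain] + spec$baseline

    motion <- matrix(0, n, 6,
                     dimnames = list(NULL, c("tx", "ty", "tz",
                                             "rx", "ry", "rz")))
    for (t in spec$spike_frames) {
      sig[t:n, brain] <- sig[t:n, brain] + spec$spike_intensity
      motion[t:n, "tx"] <- motion[t:n, "tx"] + spec$spike_translation_mm
    }

    gm_mask_idx <- sort(gm_idx)
    gm_prob <- array(0, dim = spec$grid_shape)
    subj_shift <- stats::rnorm(1, 0, 0.1)
    gm_prob[gm_mask_idx] <- pmin(0.95, pmax(0.05,
      0.6 + subj_shift + stats::rnorm(length(gm_mask_idx), 0, 0.05)))

    arr <- array(t(sig), dim = c(spec$grid_shape, n))
    bold <- bold_series(arr, tr = spec$tr,
                        affine = diag_affine(spec$voxel_size),
                        subject_id = subject_id)
    seed_idx <- sort(unlist(spec$parcel_geometry))
    labels <- integer(length(seed_idx))
    for (k in seq_len(K))
      labels[match(spec$parcel_geometry[[k]], seed_idx)] <- k
    truth <- list(seed_voxels = seed_idx, parcel_labels = labels,
                  network_map = spec$network_geometry,
                  parcel_corr = parcel_corr,
                  spike_frames = spec$spike_frames)
    structure(list(bold = bold, masks = phantom_masks(spec),
                   gm_prob = gm_prob, motion = motion, truth = truth,
                   spec = spec, subject_seed = as.integer(subject_seed),
                   subject_id = subject_id),
              class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject> %s: K = %d parcels, %d volumes, %d spikes\n",
              x$subject_id, x$spec$n_parcels, n_volumes(x$bold),
              length(x$truth$spike_frames)))
  invisible(x)
}

#' Write a phantom subject to disk
#'
#' Emits the standard file set: 4-D BOLD NIfTI, seed/GM/WM/CSF mask NIfTIs,
#' grey-matter probability NIfTI, 6-column motion TSV and a ground-truth JSON.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_phantom_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- subject$bold$affine
  p <- list(
    bold = file.path(dir, "bold.nii.gz"),
    seed_mask = file.path(dir, "mask_seed.nii.gz"),
    gm_mask = file.path(dir, "mask_gm.nii.gz"),
    wm_mask = file.path(dir, "mask_wm.nii.gz"),
    csf_mask = file.path(dir, "mask_csf.nii.gz"),
    gm_prob = file.path(dir, "gm_prob.nii.gz"),
    motion = file.path(dir, "motion.tsv"),
    truth = file.path(dir, "truth.json"))
  write_volume(subject$bold, p$bold)
  write_volume(subject$masks$seed, p$seed_mask, aff)
  write_volume(subject$masks$gm, p$gm_mask, aff)
  write_volume(subject$masks$wm, p$wm_mask, aff)
  write_volume(subject$masks$csf, p$csf_mask, aff)
  write_volume(subject$gm_prob, p$gm_prob, aff)
  write_motion(subject$motion, p$motion)
  jsonlite::write_json(subject$truth, p$truth, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
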