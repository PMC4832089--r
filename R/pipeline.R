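#' Cohort filtering rules
#'
#' Subject- and centre-level exclusion rules applied before analysis:
#' excessive mean framewise displacement, low IQ, age above the cap, an
#' optional manual exclusion flag, and removal of centres contributing fewer
#' than a minimum number of subjects in either group.
#'
#' @param max_mean_fd Maximum mean FD in mm (default 0.5).
#' @param min_iq Minimum full-scale IQ (default 80).
#' @param max_age Maximum age in years (default 40).
#' @param min_group_size_per_centre Minimum subjects per group per centre
#'   (default 7).
#' @return A `cohort_filter_rules` object.
#' @export
cohort_filter_rules <- function(max_mean_fd = 0.5, min_iq = 80,
                                max_age = 40,
                                min_group_size_per_centre = 7L) {
  stopifnot(max_mean_fd > 0, min_iq > 0, max_age > 0,
            min_group_size_per_centre > 0)
  structure(list(max_mean_fd = max_mean_fd, min_iq = min_iq,
                 max_age = max_age,
                 min_group_size_per_centre = as.integer(min_group_size_per_centre)),
            class = "cohort_filter_rules")
}

#' Apply cohort filtering
#'
#' Excludes subjects violating any rule, then drops whole centres left with
#' fewer than the minimum number of subjects in either group. Every
#' exclusion is logged with the rule that triggered it.
#'
#' @param covariates Data frame with `subject_id`, `group`, `age_years`,
#'   `fiq`, `centre`, `mean_fd`, and optionally a logical `manual_exclude`
#'   column (externally supplied flags, e.g. sex or coverage criteria).
#' @param rules A [cohort_filter_rules()] object.
#' @return List: `retained` (subject ids), `covariates` (filtered rows),
#'   `exclusions` (data frame subject_id, rule).
#' @export
filter_cohort <- function(covariates, rules = cohort_filter_rules()) {
  excl <- data.frame(subject_id = character(0), rule = character(0))
  note <- function(ids, rule) {
    if (length(ids))
      excl <<- rbind(excl, data.frame(subject_id = ids, rule = rule))
  }
  cv <- covariates
  bad <- cv$mean_fd > rules$max_mean_fd
  note(cv$subject_id[bad], "mean_fd"); cv <- cv[!bad, ]
  bad <- cv$fiq < rules$min_iq
  note(cv$subject_id[bad], "fiq"); cv <- cv[!bad, ]
  bad <- cv$age_years > rules$max_age
  note(cv$subject_id[bad], "age"); cv <- cv[!bad, ]
  if (!is.null(cv$manual_exclude)) {
    bad <- as.logical(cv$manual_exclude)
    note(cv$subject_id[bad], "manual"); cv <- cv[!bad, ]
  }
  tab <- table(cv$centre, cv$group)
  bad_centres <- rownames(tab)[apply(tab, 1, min) <
                                 rules$min_group_size_per_centre]
  bad <- cv$centre %in% bad_centres
  note(cv$subject_id[bad], "centre_too_small"); cv <- cv[!bad, ]
  if (!nrow(cv)) stop("cohort filtering excluded every subject",
                      call. = FALSE)
  list(retained = cv$subject_id, covariates = cv, exclusions = excl)
}

#' Pipeline configuration
#'
#' Collects every tunable of the workflow in one serializable object. The
#' configuration round-trips losslessly through JSON and is echoed into the
#' provenance record of every run.
#'
#' @param output_dir Output directory.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "filter", "preprocess", "connectivity", "parcellate",
#'   "atlas", "seedmaps", "glm")` in that order.
#' @param cohort A [cohort_spec()] (used by the simulate stage).
#' @param fd_thresh,dvars_thresh,band Preprocessing parameters.
#' @param n_levels Dendrogram cut levels.
#' @param metric Fingerprint metric.
#' @param wta_threshold Winner-take-all probability threshold.
#' @param contrast GLM contrast name.
#' @param n_perm Permutations for the GLM.
#' @param forming_z Cluster-forming threshold.
#' @param seed Master RNG seed.
#' @param rules A [cohort_filter_rules()] object.
#' @return A `pipeline_config` object (a classed list).
#' @export
pipeline_config <- function(output_dir,
                            stages = c("simulate", "filter", "preprocess",
                                       "connectivity", "parcellate",
                                       "atlas", "seedmaps", "glm"),
                            cohort = cohort_spec(n_per_group = 5),
                            fd_thresh = 0.5, dvars_thresh = 0.5,
                            band = c(0.009, 0.2), n_levels = 100L,
                            metric = "corrdist", wta_threshold = 0.25,
                            contrast = "group_x_age", n_perm = 500L,
                            forming_z = 3.1, seed = 1L,
                            rules = cohort_filter_rules()) {
  all_stages <- c("simulate", "filter", "preprocess", "connectivity",
                  "parcellate", "atlas", "seedmaps", "glm")
  stages <- all_stages[all_stages %in% stages]
  structure(list(output_dir = output_dir, stages = stages, cohort = cohort,
                 fd_thresh = fd_thresh, dvars_thresh = dvars_thresh,
                 band = band, n_levels = as.integer(n_levels),
                 metric = metric, wta_threshold = wta_threshold,
                 contrast = contrast, n_perm = as.integer(n_perm),
                 forming_z = forming_z, seed = as.integer(seed),
                 rules = rules),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `write_pipeline_config` returns the path;
#'   `read_pipeline_config` the restored object.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # equal-length index sets come back simplified to a matrix; restore lists
  relist_geometry <- function(g) {
    if (is.matrix(g)) lapply(seq_len(nrow(g)), function(i) g[i, ])
    else if (is.list(g)) g
    else list(g)
  }
  for (f in c("parcel_geometry", "network_geometry"))
    raw$cohort$phantom[[f]] <- relist_geometry(raw$cohort$phantom[[f]])
  ph <- do.call(phantom_spec, raw$cohort$phantom)
  cohort_args <- raw$cohort
  cohort_args$phantom <- ph
  if (!is.null(cohort_args$target))
    cohort_args$target <- as.list(cohort_args$target)
  cohort <- do.call(cohort_spec, cohort_args)
  rules <- do.call(cohort_filter_rules, raw$rules)
  args <- raw[setdiff(names(raw), c("cohort", "rules"))]
  do.call(pipeline_config, c(args, list(cohort = cohort, rules = rules)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full workflow
#'
#' Executes the configured stages in order on a simulated cohort:
#' simulate -> cohort filter -> preprocessing -> connectivity fingerprints
#' -> group parcellation with silhouette selection -> matching /
#' probabilistic atlas -> seed-to-voxel maps for the first group cluster ->
#' permutation GLM. Stage outputs, the resolved configuration and all seeds
#' are written below `output_dir` together with a provenance record; a rerun
#' with an identical configuration reproduces the outputs.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   provenance record.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(package_version = as.character(utils::packageVersion("fcparc")),
               seed = config$seed, stages = list())
  results <- list()
  stage_done <- function(name, ...) {
    prov$stages[[name]] <<- c(list(...), list(completed = TRUE))
  }

  if (!"simulate" %in% config$stages)
    stop("this runner starts from the simulate stage; include it in stages",
         call. = FALSE)
  cohort <- make_cohort(config$cohort)
  if (!length(cohort$subjects)) stop("no subjects", call. = FALSE)
  results$cohort <- cohort
  write_cohort(cohort, file.path(config$output_dir, "cohort"))
  stage_done("simulate", n_subjects = nrow(cohort$covariates))

  covariates <- cohort$covariates
  if ("filter" %in% config$stages) {
    flt <- filter_cohort(covariates, config$rules)
    keep <- covariates$subject_id %in% flt$retained
    cohort$subjects <- cohort$subjects[keep]
    covariates <- flt$covariates
    cohort$covariates <- covariates
    results$filter <- flt
    utils::write.table(flt$exclusions,
                       file.path(config$output_dir, "exclusions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stage_done("filter", n_retained = length(flt$retained),
               n_excluded = nrow(flt$exclusions))
  }

  preprocessed <- NULL
  if ("preprocess" %in% config$stages) {
    preprocessed <- lapply(cohort$subjects, preprocess_subject,
                           fd_thresh = config$fd_thresh,
                           dvars_thresh = config$dvars_thresh,
                           band = config$band)
    results$preprocessed <- preprocessed
    censored <- vapply(preprocessed, function(p) p$censor$n_censored, 1L)
    stage_done("preprocess", total_censored_volumes = sum(censored))
  }

  matrices <- NULL
  if ("connectivity" %in% config$stages) {
    masks <- cohort$subjects[[1]]$masks
    seed_idx <- mask_indices(masks$seed)
    gm_idx <- mask_indices(masks$gm)
    matrices <- if (is.null(preprocessed))
      cohort_connectivity(cohort, preprocess = FALSE)
    else lapply(seq_along(preprocessed), function(i)
      mask_to_gm_matrix(preprocessed[[i]]$series, seed_idx, gm_idx,
                        voxels = preprocessed[[i]]$voxels,
                        subject_id = cohort$subjects[[i]]$subject_id))
    results$matrices <- matrices
    stage_done("connectivity", n_matrices = length(matrices))
  }

  parc <- NULL
  if ("parcellate" %in% config$stages) {
    if (is.null(matrices))
      stop("parcellate requires the connectivity stage", call. = FALSE)
    parc <- parcellate_group(matrices, n_levels = config$n_levels,
                             metric = config$metric)
    results$parcellation <- parc
    if (!is.null(parc$best)) {
      dim3 <- dim(cohort$subjects[[1]]$masks$seed)
      lab_vol <- array(0L, dim = dim3)
      lab_vol[parc$best$seed_vox] <- parc$best$labels
      write_volume(lab_vol, file.path(config$output_dir,
                                      "group_parcellation.nii.gz"),
                   cohort$subjects[[1]]$bold$affine)
      jsonlite::write_json(
        list(K = parc$best$K, cut_height = parc$best$cut_height,
             local_maxima_K = parc$profile$levels$K[parc$profile$local_maxima]),
        file.path(config$output_dir, "group_parcellation.json"),
        auto_unbox = TRUE, digits = NA)
    }
    stage_done("parcellate",
               K = if (is.null(parc$best)) NA else parc$best$K)
  }

  bp <- NULL
  if ("atlas" %in% config$stages) {
    if (is.null(parc$best))
      stop("atlas requires a parcellation solution", call. = FALSE)
    dim3 <- dim(cohort$subjects[[1]]$masks$seed)
    bp <- backproject(parc$best, matrices, dim3,
                      metric = config$metric,
                      threshold = config$wta_threshold,
                      groups = covariates$group)
    results$atlas <- bp
    write_volume(bp$wta$labels,
                 file.path(config$output_dir, "atlas_wta.nii.gz"),
                 cohort$subjects[[1]]$bold$affine)
    utils::write.table(bp$replication,
                       file.path(config$output_dir, "replication.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stage_done("atlas",
               mean_replication_pct = mean(bp$replication$replication_pct))
  }

  maps <- NULL
  if ("seedmaps" %in% config$stages) {
    seed <- if (!is.null(bp)) {
      first <- bp$atlas$clusters[1]
      which(bp$wta$labels == first)
    } else mask_indices(cohort$subjects[[1]]$masks$seed)
    if (!length(seed))
      seed <- cluster_voxel_sets(parc$best)[[1]]
    maps <- cohort_seed_maps(cohort, seed, preprocessed = preprocessed)
    results$seed_maps <- maps
    stage_done("seedmaps", n_maps = length(maps), seed_size = length(seed))
  }

  if ("glm" %in% config$stages) {
    if (is.null(maps)) stop("glm requires the seedmaps stage", call. = FALSE)
    gm_idx <- mask_indices(cohort$subjects[[1]]$masks$gm)
    dim3 <- dim(cohort$subjects[[1]]$masks$gm)
    mm <- do.call(rbind, lapply(maps, `[[`, "z"))
    vox <- maps[[1]]$gm_vox
    res <- permutation_glm(mm, covariates, contrast = config$contrast,
                           n_perm = config$n_perm, seed = config$seed,
                           voxels = vox, dim3 = dim3,
                           forming_z = config$forming_z)
    results$glm <- res
    zvol <- array(0, dim = dim3)
    zvol[vox] <- res$z
    write_volume(zvol, file.path(config$output_dir, "glm_z.nii.gz"),
                 cohort$subjects[[1]]$bold$affine)
    utils::write.table(res$cluster_table,
                       file.path(config$output_dir, "glm_clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stage_done("glm", min_p_fwe_voxel = min(res$p_fwe_voxel))
  }

  write_pipeline_config(config, file.path(config$output_dir, "config.json"))
  prov$config_hash <- config_hash(config)
  jsonlite::write_json(prov, file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  results$provenance <- prov
  invisible(results)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  # small rolling hash; stable across sessions, no extra dependency
  sum(utf8ToInt(as.character(s)) *
        (seq_along(utf8ToInt(as.character(s))) %% 997)) %% 2147483647
}
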