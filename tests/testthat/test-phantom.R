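test_that("phantom generation is deterministic and geometry-conserving", {
  spec <- small_phantom(spike_frames = c(30L, 90L))
  s1 <- make_phantom_subject(spec, 42)
  s2 <- make_phantom_subject(spec, 42)
  expect_identical(s1$bold$data, s2$bold$data)
  expect_identical(s1$motion, s2$motion)
  expect_identical(s1$gm_prob, s2$gm_prob)

  s3 <- make_phantom_subject(spec, 43)
  expect_false(identical(s1$bold$data, s3$bold$data))

  # labels cover the seed mask exactly once
  seed_idx <- mask_indices(s1$masks$seed)
  expect_identical(s1$truth$seed_voxels, seed_idx)
  expect_identical(sort(unlist(spec$parcel_geometry)), seed_idx)
  expect_true(all(s1$truth$parcel_labels %in% seq_len(spec$n_parcels)))
  expect_identical(tabulate(s1$truth$parcel_labels),
                   unname(lengths(spec$parcel_geometry)))
  # seed mask contained in grey matter; networks disjoint from the seed
  expect_true(all(s1$masks$gm[seed_idx] == 1))
  expect_length(intersect(unlist(spec$network_geometry), seed_idx), 0)
})

test_that("overlapping geometry is rejected", {
  geo <- default_phantom_geometry <- phantom_spec()$parcel_geometry
  expect_error(phantom_spec(parcel_geometry = list(c(1L, 2L), c(2L, 3L)),
                            network_geometry = list(4L, 5L),
                            n_parcels = 2),
               "overlap")
  expect_error(phantom_spec(parcel_geometry = list(c(1L, 2L), c(3L, 4L)),
                            network_geometry = list(c(4L, 5L), 6L),
                            n_parcels = 2),
               "overlap")
  expect_error(phantom_spec(signal_corr = 1), "signal_corr")
})

test_that("noise-free unit-coupling phantom has perfectly correlated pairs", {
  spec <- phantom_spec(n_timepoints = 80L, signal_corr = 1 - 1e-12,
                       noise_sd = 0)
  s <- make_phantom_subject(spec, 7)
  p1 <- spec$parcel_geometry[[1]]
  n1 <- spec$network_geometry[[1]]
  x <- series_matrix(s$bold, c(p1[1], n1[1]))
  expect_equal(stats::cor(x[, 1], x[, 2]), 1, tolerance = 1e-9)
})

test_that("realized correlations calibrate to signal_corr", {
  # Monte-Carlo at the generative mixing formula: mean over 20 subjects
  spec <- phantom_spec(n_timepoints = 500L, signal_corr = 0.6, noise_sd = 0)
  r <- vapply(1:20, function(i) {
    s <- make_phantom_subject(spec, i)
    x <- series_matrix(s$bold, c(spec$parcel_geometry[[2]][1],
                                 spec$network_geometry[[2]][1]))
    stats::cor(x[, 1], x[, 2])
  }, numeric(1))
  expect_lt(abs(mean(r) - 0.6), 0.05)

  # convergence: single long series within +-0.02
  spec2 <- phantom_spec(n_timepoints = 2000L, signal_corr = 0.6,
                        noise_sd = 0)
  s <- make_phantom_subject(spec2, 99)
  x <- series_matrix(s$bold, c(spec2$parcel_geometry[[1]][2],
                               spec2$network_geometry[[1]][5]))
  expect_lt(abs(stats::cor(x[, 1], x[, 2]) - 0.6), 0.02)
})

test_that("cohort covariate table has the expected structure", {
  co <- make_cohort(cohort_spec(n_per_group = 30,
                                phantom = phantom_spec(n_timepoints = 10L),
                                seed = 2))
  expect_equal(nrow(co$covariates), 60)
  expect_setequal(names(co$covariates),
                  c("subject_id", "group", "age_years", "fiq", "centre",
                    "mean_fd"))
  expect_equal(sort(unique(co$covariates$group)), c("A", "B"))
  expect_true(all(co$covariates$age_years >= 7 &
                    co$covariates$age_years <= 40))
  expect_gte(min(table(co$covariates$centre, co$covariates$group)), 14)
  expect_error(cohort_spec(n_per_group = 1), "cohort error")
  expect_error(cohort_spec(n_per_group = 5, centre_labels = "one"),
               "centre")
})

test_that("null cohorts are centred on zero slope difference", {
  ests <- vapply(1:12, function(r) {
    co <- make_cohort(glm_cohort_spec(n_per_group = 10,
                                      interaction_slope = 0,
                                      n_timepoints = 400, seed = 300 + r),
                      subject_fn = seed_map_reducer(1))
    mm <- do.call(rbind, lapply(co$subjects, `[[`, "z"))
    vox <- co$subjects[[1]]$gm_vox
    y <- rowMeans(mm[, match(co$truth$network_map[[1]], vox), drop = FALSE])
    la <- log(co$covariates$age_years)
    g <- factor(co$covariates$group)
    unname(coef(stats::lm(y ~ la * g))["la:gB"])
  }, numeric(1))
  # slope-difference estimates scatter around 0
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 4 * se + 1e-12)
})

test_that("planted interaction slope is recovered by least squares", {
  # parameter recovery against the generative model, averaged over cohorts
  ests <- vapply(1:20, function(r) {
    co <- make_cohort(glm_cohort_spec(n_per_group = 50,
                                      interaction_slope = 0.02,
                                      n_timepoints = 3000,
                                      seed = 500 + r),
                      subject_fn = seed_map_reducer(1))
    mm <- do.call(rbind, lapply(co$subjects, `[[`, "z"))
    vox <- co$subjects[[1]]$gm_vox
    y <- rowMeans(mm[, match(co$truth$network_map[[1]], vox), drop = FALSE])
    la <- log(co$covariates$age_years)
    g <- factor(co$covariates$group)
    -unname(coef(stats::lm(y ~ la * g))["la:gB"])  # slope_A - slope_B
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.02), 0.2 * 0.02)
})

test_that("written phantom files round-trip", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(n_timepoints = 12L, spike_frames = 5L)
  s <- make_phantom_subject(spec, 3)
  paths <- write_phantom_subject(s, dir)
  expect_true(all(file.exists(unlist(paths))))
  b <- read_volume(paths$bold)
  expect_s3_class(b, "bold_series")
  expect_equal(dim(b$data), dim(s$bold$data))
  expect_equal(b$data, s$bold$data, tolerance = 1e-6)
  expect_equal(b$tr, s$bold$tr)
  m <- read_motion(paths$motion)
  expect_equal(unname(m), unname(s$motion))
  seedv <- read_volume(paths$seed_mask)
  expect_equal(mask_indices(seedv), mask_indices(s$masks$seed))
})
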