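toy_covariates <- function(n = 12, centres = c("x", "y")) {
  withr::with_seed(99, data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("A", "B"), each = n / 2),
    age_years = round(runif(n, 8, 30), 1),
    fiq = round(rnorm(n, 105, 10)),
    centre = rep_len(centres, n),
    mean_fd = round(runif(n, 0.05, 0.4), 3)))
}

test_that("the design matrix is built exactly as documented", {
  cv <- toy_covariates(12, centres = c("x", "y"))
  X <- build_design(cv)
  expect_equal(colnames(X),
               c("intercept", "centre_y", "mean_fd", "fiq", "log_age",
                 "group", "group_x_age"))
  # hand-built columns
  expect_equal(unname(X[, "log_age"]),
               log(cv$age_years) - mean(log(cv$age_years)))
  g <- ifelse(cv$group == "B", 1, 0); g <- g - mean(g)
  expect_equal(unname(X[, "group"]), g)
  expect_equal(sum(X[, "group"]), 0)      # balanced, centred coding
  expect_equal(unname(X[, "group_x_age"]),
               g * (log(cv$age_years) - mean(log(cv$age_years))))
  expect_equal(unname(X[, "centre_y"]), as.numeric(cv$centre == "y"))

  # one centre: no dummies
  X1 <- build_design(toy_covariates(8, centres = "x"))
  expect_false(any(grepl("centre", colnames(X1))))

  # GM extends the design with centred main effect and interaction
  Xg <- build_design(cv, gm = rep(c(0.4, 0.5, 0.6), 4))
  expect_true(all(c("gm", "group_x_gm") %in% colnames(Xg)))
  expect_equal(sum(Xg[, "gm"]), 0)

  # rank deficiency names the offender
  cv2 <- cv; cv2$fiq <- cv2$mean_fd
  expect_error(build_design(cv2), "collinear")
})

test_that("permutation p-values respect the attainable floor and determinism", {
  set.seed(1)
  cv <- toy_covariates(12)
  y <- matrix(rnorm(12), ncol = 1)
  y[cv$group == "A"] <- y[cv$group == "A"] + 50   # perfect separation
  r <- permutation_glm(y, cv, "group", n_perm = 100, seed = 9)
  expect_equal(min(r$p_fwe_voxel), 1 / 101)
  expect_equal(r$p_unc, r$p_fwe_voxel)            # single voxel

  r2 <- permutation_glm(y, cv, "group", n_perm = 100, seed = 9)
  expect_identical(r$p_fwe_voxel, r2$p_fwe_voxel)
  r3 <- permutation_glm(y, cv, "group", n_perm = 100, seed = 10)
  expect_false(identical(r$max_stat_null, r3$max_stat_null))

  expect_error(permutation_glm(y, cv, "group", n_perm = 50), ">= 100")
  expect_error(permutation_glm(y, cv, "group_x_gm", n_perm = 100),
               "not estimable")
})

test_that("permutations stay within scanning-centre blocks", {
  cv <- toy_covariates(10)
  P <- with_seed(4, fcparc:::block_permutations(cv$centre, 200))
  for (b in unique(cv$centre)) {
    members <- which(cv$centre == b)
    expect_true(all(apply(P[, members, drop = FALSE], 1,
                          function(r) setequal(r, members))))
  }
})

test_that("constant-across-voxel GM reduces to the per-subject GM model", {
  set.seed(6)
  cv <- toy_covariates(16)
  y <- matrix(rnorm(16 * 5), 16, 5)
  gm_subject <- runif(16, 0.3, 0.7)
  gm_flat <- matrix(gm_subject, 16, 5)     # identical at every voxel
  r1 <- permutation_glm(y, cv, "group", n_perm = 100, seed = 2,
                        gm = gm_flat)
  r2 <- permutation_glm(y, cv, "group", n_perm = 100, seed = 2,
                        gm = matrix(gm_subject, ncol = 1))
  expect_equal(r1$t, r2$t, tolerance = 1e-8)
  expect_equal(r1$p_fwe_voxel, r2$p_fwe_voxel, tolerance = 1e-12)
})

test_that("voxel-dependent GM designs agree with per-voxel refits", {
  set.seed(7)
  n <- 20; V <- 4
  cv <- toy_covariates(n)
  y <- matrix(rnorm(n * V), n, V)
  gm <- matrix(runif(n * V, 0.2, 0.8), n, V)
  r <- permutation_glm(y, cv, "group_x_gm", n_perm = 100, seed = 3, gm = gm)
  for (v in 1:V) {
    X <- build_design(cv, gm = gm[, v])
    fit <- stats::lm.fit(X, y[, v])
    sigma2 <- sum(fit$residuals^2) / (n - ncol(X))
    se <- sqrt(diag(solve(crossprod(X)))[["group_x_gm"]] * sigma2)
    expect_equal(r$t[v], unname(fit$coefficients["group_x_gm"]) / se,
                 tolerance = 1e-8)
  }
})

test_that("connected components and cluster tables follow face adjacency", {
  dim3 <- c(5L, 5L, 5L)
  # two face-adjacent voxels form one cluster
  idx <- c(1L, 2L)
  expect_equal(max(label_components(idx, dim3)), 1L)
  # diagonal neighbours split under 6-connectivity, join under 26
  diag_idx <- c(1L, 1L + 1L + 5L)
  expect_equal(max(label_components(diag_idx, dim3)), 2L)
  expect_equal(max(label_components(diag_idx, dim3, connectivity = 26L)), 1L)

  z <- rep(0, 4)
  expect_equal(nrow(cluster_extent_fwe(z, 1:4, dim3)), 0)
  z2 <- c(4, 4, 0, 5)
  tab <- cluster_extent_fwe(z2, c(1L, 2L, 10L, 60L), dim3)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$size[1], 2)
  expect_equal(tab$peak_z[tab$size == 1], 5)
  # monotone p in cluster size under a fixed null
  tab2 <- cluster_extent_fwe(z2, c(1L, 2L, 10L, 60L), dim3,
                             null_max_extent = c(0, 1, 1, 2, 3))
  expect_true(all(diff(tab2$p_fwe[order(tab2$size)]) <= 0))
})

test_that("network strength reduces to a repeated-measures ANOVA oracle", {
  # 3 seed types x 5 subjects, hand-checkable sums of squares
  set.seed(12)
  strengths <- matrix(rnorm(15, mean = rep(c(1, 1.5, 0.8), each = 5)), 5, 3)
  maps <- lapply(1:3, function(k) matrix(strengths[, k], 5, 2))
  names(maps) <- c("prob", "sphere4", "sphere8")
  ns <- network_strength(maps, network_vox = 1:2, voxels = 1:2)
  f_row <- ns$anova[ns$anova$term == "seed_type", ]

  # brute-force within-subject sums of squares
  grand <- mean(strengths)
  ss_cond <- 5 * sum((colMeans(strengths) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(strengths) - grand)^2)
  ss_tot <- sum((strengths - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_oracle <- (ss_cond / 2) / (ss_err / 8)
  expect_equal(f_row$F, f_oracle, tolerance = 1e-8)
  expect_equal(f_row$df1, 2)
  expect_equal(f_row$df2, 8)

  # identical maps across seed types: the between-condition sum of squares
  # (the F numerator) vanishes
  one <- matrix(rnorm(10), 5, 2)
  same <- list(a = one, b = one, c = one)
  ns0 <- network_strength(same, network_vox = 1:2, voxels = 1:2)
  wide <- matrix(ns0$table$strength, 5, 3)
  ss_cond0 <- 5 * sum((colMeans(wide) - mean(wide))^2)
  expect_lt(ss_cond0, 1e-20)

  # group terms appear when groups are given
  nsg <- network_strength(maps, network_vox = 1:2, voxels = 1:2,
                          groups = c("A", "A", "A", "B", "B"))
  expect_true(all(c("group", "seed_type", "group:seed_type") %in%
                    nsg$anova$term))
  expect_error(network_strength(maps, network_vox = integer(0)), "empty")
})

test_that("cohen's d uses the pooled n-1 standard deviation", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3)), 2)   # antisymmetry
  x <- rnorm(6)
  expect_equal(cohens_d(x, x), 0)
  expect_warning(d0 <- cohens_d(c(1, 1, 1), c(1, 1)), "pooled")
  expect_true(is.na(d0))
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("sphere decomposition tiles the support with disjoint spheres", {
  dim3 <- c(12L, 12L, 6L)
  prob <- array(0, dim3)
  blk <- as.matrix(expand.grid(3:10, 3:8, 3))
  idx <- blk[, 1] + (blk[, 2] - 1) * 12 + (blk[, 3] - 1) * 144
  prob[idx] <- seq(0.3, 0.9, length.out = length(idx))

  co <- parcellation_cohort(n = 4, seed = 81)
  gm_idx <- mask_indices(co$subjects[[1]]$masks$gm)
  # reuse phantom series as arbitrary subject data over the support
  subs <- lapply(co$subjects, function(s) s$bold)
  # make the probability support live inside the phantom grid
  dim3p <- dim(co$subjects[[1]]$masks$gm)
  probp <- array(0, dim3p)
  probp[co$truth$seed_voxels] <-
    seq(0.3, 0.95, length.out = length(co$truth$seed_voxels))
  sg <- sphere_grid_effects(probp, subs, gm_idx,
                            network_vox = co$truth$network_map[[1]],
                            groups = co$covariates$group,
                            radius_mm = 4,
                            affine = co$subjects[[1]]$bold$affine)
  # pairwise disjoint spheres, centres in the support
  all_vox <- unlist(sg$sphere_voxels)
  expect_equal(anyDuplicated(all_vox), 0)
  expect_true(all(probp[sg$spheres$centre_voxel] > 0.25))
  expect_true(all(sg$spheres$n_voxels >= 1))
  expect_error(sphere_grid_effects(array(0, dim3p), subs, gm_idx,
                                   co$truth$network_map[[1]],
                                   co$covariates$group), "empty")
})
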