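#' Build the group-level design matrix
#'
#' Columns: intercept; scanning-centre dummies (reference-coded); mean FD;
#' full-scale IQ; natural-log age; group (deviation-coded: 0/1 minus its
#' mean, so it sums to zero in balanced designs); group x log-age; and, when
#' grey-matter values are supplied, GM and group x GM. Continuous covariates
#' are mean-centred before interactions are formed. With voxel-dependent GM
#' regressors the GM column changes per analysed voxel; this function builds
#' the matrix for one voxel.
#'
#' @param covariates Data frame with columns `group` (two levels),
#'   `age_years`, `fiq`, `centre`, `mean_fd`.
#' @param gm Optional per-subject GM value at the analysed voxel.
#' @return Design matrix (subjects x columns) with a `tested` attribute
#'   mapping contrast names to columns.
#' @export
build_design <- function(covariates, gm = NULL) {
  req <- c("group", "age_years", "fiq", "centre", "mean_fd")
  if (!all(req %in% names(covariates)))
    stop("covariates must contain: ", paste(req, collapse = ", "),
         call. = FALSE)
  n <- nrow(covariates)
  grp <- factor(covariates$group)
  if (nlevels(grp) != 2L) stop("group must have exactly 2 levels",
                               call. = FALSE)
  g <- as.numeric(grp) - 1
  g <- g - mean(g)
  centre <- factor(covariates$centre)
  X <- cbind(intercept = rep(1, n))
  if (nlevels(centre) > 1L) {
    cd <- stats::model.matrix(~centre)[, -1, drop = FALSE]
    colnames(cd) <- paste0("centre_", levels(centre)[-1])
    X <- cbind(X, cd)
  }
  ctr <- function(x) x - mean(x)
  log_age <- ctr(log(covariates$age_years))
  X <- cbind(X, mean_fd = ctr(covariates$mean_fd),
             fiq = ctr(covariates$fiq), log_age = log_age,
             group = g, group_x_age = g * log_age)
  if (!is.null(gm)) {
    gmc <- ctr(gm)
    X <- cbind(X, gm = gmc, group_x_gm = g * gmc)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tested <- c(group = "group", age = "log_age", group_x_age = "group_x_age",
              fd = "mean_fd", fiq = "fiq")
  if (!is.null(gm)) tested <- c(tested, gm = "gm", group_x_gm = "group_x_gm")
  attr(X, "tested") <- tested
  X
}

# within-block permutation index matrix (n_perm x n)
block_permutations <- function(blocks, n_perm) {
  blocks <- factor(blocks)
  n <- length(blocks)
  P <- matrix(0L, n_perm, n)
  for (p in seq_len(n_perm)) {
    idx <- seq_len(n)
    for (b in levels(blocks)) {
      members <- which(blocks == b)
      idx[members] <- members[sample.int(length(members))]
    }
    P[p, ] <- idx
  }
  P
}

t_to_z <- function(t, df) {
  lp <- stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  sign(t) * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Permutation-based GLM on seed-to-voxel maps
#'
#' Tests one contrast of the design of [build_design()] at every voxel using
#' Freedman-Lane permutation: the data are residualized against the nuisance
#' part of the model (everything except the tested column), residual rows
#' are permuted within exchangeability blocks (scanning centre), and the
#' full model is refit to each permuted dataset. Voxelwise family-wise error
#' is controlled with the max-statistic distribution, cluster-extent FWE
#' with the maximal suprathreshold cluster size per permutation (clusters
#' are face-connected components of `z > forming_z`, or `|z|` for the
#' two-sided alternative). All p-values use the `(1 + exceedances) /
#' (1 + n_perm)` convention.
#'
#' When per-subject grey-matter volumes are supplied, the GM regressor is
#' voxel-dependent: the design matrix changes at each analysed voxel.
#'
#' @param maps Subjects x voxels matrix of Fisher-z connectivity values
#'   (rows align with `covariates`), or a list of `seed_map` objects.
#' @param covariates Covariate data frame (see [build_design()]).
#' @param contrast One of `"group"`, `"age"`, `"group_x_age"`, `"fd"`,
#'   `"fiq"`, `"gm"`, `"group_x_gm"`.
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed RNG seed for the permutation set.
#' @param gm Optional subjects x voxels matrix of grey-matter values
#'   (voxel-dependent regressor), or a single column reused at all voxels.
#' @param voxels,dim3 Linear voxel indices of the map columns and the grid
#'   dimensions (needed for cluster-level inference).
#' @param forming_z Cluster-forming threshold in z units (default 3.1).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `glm_result`: per-voxel `t`, `z`, `p_unc`, `p_fwe_voxel`;
#'   `cluster_table`; `max_stat_null`; and the configuration.
#' @export
permutation_glm <- function(maps, covariates, contrast, n_perm = 10000L,
                            seed = 1L, gm = NULL, voxels = NULL,
                            dim3 = NULL, forming_z = 3.1,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.list(maps) && inherits(maps[[1]], "seed_map")) {
    voxels <- maps[[1]]$gm_vox
    maps <- do.call(rbind, lapply(maps, `[[`, "z"))
  }
  maps <- as.matrix(maps)
  n <- nrow(maps); V <- ncol(maps)
  if (n != nrow(covariates))
    stop("maps and covariates disagree on the number of subjects",
         call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (is.null(voxels)) voxels <- seq_len(V)

  X0 <- build_design(covariates, gm = if (is.null(gm)) NULL else gm[, 1])
  tested <- attr(X0, "tested")
  if (!contrast %in% names(tested))
    stop("contrast not estimable in this design: ", contrast, call. = FALSE)
  tcol <- tested[[contrast]]
  df <- n - ncol(X0)

  P <- with_seed(seed, block_permutations(covariates$centre, n_perm))

  gm_varies <- !is.null(gm) &&
    (ncol(as.matrix(gm)) > 1L) && any(apply(as.matrix(gm), 1, stats::sd) > 0)
  if (gm_varies && ncol(as.matrix(gm)) != V)
    stop("gm must have one column per map voxel", call. = FALSE)

  if (!gm_varies) {
    fit <- fl_fit_common(maps, X0, tcol, P)
  } else {
    gm <- as.matrix(gm)
    t_obs <- numeric(V)
    t_perm <- matrix(0, V, n_perm)
    for (v in seq_len(V)) {
      Xv <- build_design(covariates, gm = gm[, v])
      f <- fl_fit_common(maps[, v, drop = FALSE], Xv, tcol, P)
      t_obs[v] <- f$t_obs
      t_perm[v, ] <- f$t_perm
    }
    fit <- list(t_obs = t_obs, t_perm = t_perm)
  }

  stat <- function(t) switch(alternative,
                             two.sided = abs(t), greater = t, less = -t)
  s_obs <- stat(fit$t_obs)
  s_perm <- stat(fit$t_perm)
  max_null <- apply(s_perm, 2, max)
  p_fwe <- vapply(s_obs, function(s) (1 + sum(max_null >= s)) / (1 + n_perm),
                  numeric(1))
  p_unc <- (1 + rowSums(s_perm >= s_obs)) / (1 + n_perm)

  z <- t_to_z(fit$t_obs, df)
  cluster_table <- NULL
  if (!is.null(dim3)) {
    z_stat <- function(t) stat(t_to_z(t, df))
    null_extent <- apply(fit$t_perm, 2, function(tp)
      max_cluster_extent(z_stat(tp) > forming_z, voxels, dim3))
    cluster_table <- cluster_extent_fwe(z, voxels, dim3,
                                        forming_z = forming_z,
                                        null_max_extent = null_extent,
                                        two_sided = alternative == "two.sided")
  }
  structure(list(t = fit$t_obs, z = z, df = df, p_unc = p_unc,
                 p_fwe_voxel = p_fwe, cluster_table = cluster_table,
                 max_stat_null = max_null, contrast = contrast,
                 n_perm = n_perm, seed = seed, voxels = voxels, dim = dim3,
                 forming_z = forming_z, alternative = alternative),
            class = "glm_result")
}

# Freedman-Lane fit with a design shared by all voxels.
# Returns observed t per voxel and the voxels x n_perm permutation t matrix.
fl_fit_common <- function(Y, X, tcol, P) {
  n <- nrow(X); p <- ncol(X)
  ci <- match(tcol, colnames(X))
  XtXinv <- solve(crossprod(X))
  A <- XtXinv %*% t(X)              # p x n
  h <- XtXinv[ci, ci]
  tstat <- function(Ym) {
    B <- A %*% Ym                   # p x V
    R <- Ym - X %*% B
    sigma2 <- colSums(R^2) / (n - p)
    B[ci, ] / sqrt(h * sigma2)
  }
  t_obs <- as.numeric(tstat(Y))
  Z <- X[, -ci, drop = FALSE]
  Rz <- qr.resid(qr(Z), Y)
  n_perm <- nrow(P)
  t_perm <- matrix(0, ncol(Y), n_perm)
  for (j in seq_len(n_perm))
    t_perm[, j] <- tstat(Rz[P[j, ], , drop = FALSE])
  list(t_obs = t_obs, t_perm = t_perm)
}

#' Face-connected components of a voxel set
#'
#' @param idx Linear voxel indices.
#' @param dim3 Grid dimensions.
#' @param connectivity 6 (faces), 18 or 26.
#' @return Integer component label per element of `idx`.
#' @export
label_components <- function(idx, dim3, connectivity = 6L) {
  if (!length(idx)) return(integer(0))
  offs <- connectivity_offsets(connectivity)
  pos <- index_to_ijk(idx, dim3)
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = lookup)
  labels <- integer(length(idx))
  comp <- 0L
  for (i in seq_along(idx)) {
    if (labels[i] != 0L) next
    comp <- comp + 1L
    queue <- i
    labels[i] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- sweep(offs, 2, pos[cur, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
        nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
        nb[, 3] >= 1 & nb[, 3] <= dim3[3]
      nb <- nb[ok, , drop = FALSE]
      nb_idx <- nb[, 1] + (nb[, 2] - 1L) * dim3[1] +
        (nb[, 3] - 1L) * dim3[1] * dim3[2]
      for (key in as.character(nb_idx)) {
        j <- lookup[[key]]
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  r <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[r == 1, , drop = FALSE],
         "18" = g[r <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

max_cluster_extent <- function(supra, voxels, dim3, connectivity = 6L) {
  idx <- voxels[supra]
  if (!length(idx)) return(0L)
  max(tabulate(label_components(idx, dim3, connectivity)))
}

#' Cluster-extent inference on a z map
#'
#' Thresholds the map at `forming_z` (on `|z|` for two-sided tests), labels
#' face-connected components, and, when a permutation null of maximal
#' cluster extents is supplied, attaches cluster-level FWE p-values. A map
#' with no suprathreshold voxels yields an empty table.
#'
#' @param z Per-voxel z values.
#' @param voxels Linear voxel indices of `z`.
#' @param dim3 Grid dimensions.
#' @param forming_z Cluster-forming threshold (default 3.1).
#' @param null_max_extent Optional vector: max cluster extent per
#'   permutation.
#' @param two_sided Threshold `|z|` instead of `z`.
#' @param connectivity Component connectivity (default 6).
#' @return Data frame: cluster id, size, peak voxel (linear index), peak z,
#'   and `p_fwe` when a null was given.
#' @export
cluster_extent_fwe <- function(z, voxels, dim3, forming_z = 3.1,
                               null_max_extent = NULL, two_sided = FALSE,
                               connectivity = 6L) {
  zz <- if (two_sided) abs(z) else z
  supra <- zz > forming_z
  empty <- data.frame(cluster = integer(0), size = integer(0),
                      peak_voxel = integer(0), peak_z = numeric(0),
                      p_fwe = numeric(0))
  if (!any(supra)) return(empty)
  idx <- voxels[supra]
  labs <- label_components(idx, dim3, connectivity)
  zs <- z[supra]
  out <- do.call(rbind, lapply(sort(unique(labs)), function(k) {
    sel <- labs == k
    peak <- which.max(abs(zs[sel]))
    data.frame(cluster = k, size = sum(sel),
               peak_voxel = idx[sel][peak], peak_z = zs[sel][peak])
  }))
  if (!is.null(null_max_extent)) {
    np <- length(null_max_extent)
    out$p_fwe <- vapply(out$size, function(s)
      (1 + sum(null_max_extent >= s)) / (1 + np), numeric(1))
  } else out$p_fwe <- NA_real_
  out[order(-out$size), ]
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> contrast %s: %d voxels, %d permutations; min voxel FWE p = %.4g\n",
              x$contrast, length(x$t), x$n_perm, min(x$p_fwe_voxel)))
  if (!is.null(x$cluster_table) && nrow(x$cluster_table))
    cat(sprintf("  %d cluster(s) above z = %g; smallest cluster p = %.4g\n",
                nrow(x$cluster_table), x$forming_z,
                min(x$cluster_table$p_fwe)))
  invisible(x)
}

#' Conjunction of significant voxels across analyses
#'
#' @param results List of `glm_result`s over the same voxels.
#' @param alpha Voxelwise FWE threshold.
#' @return Linear indices of voxels significant in every analysis.
#' @export
conjunction_mask <- function(results, alpha = 0.05) {
  vox <- results[[1]]$voxels
  sig <- Reduce(`&`, lapply(results, function(r) r$p_fwe_voxel < alpha))
  vox[sig]
}

#' Network strength per seed type
#'
#' Averages the Fisher-z values of each subject's seed-to-voxel map within a
#' network mask, for each seed type (e.g. probability map, 4 mm sphere,
#' 8 mm sphere), and tests the seed-type effect with a repeated-measures
#' ANOVA (seed type within subjects; group and group x seed type between /
#' interaction terms when groups are given).
#'
#' @param maps_by_type Named list (one entry per seed type) of
#'   subjects x voxels map matrices or lists of `seed_map`s, all over the
#'   same voxel index.
#' @param network_vox Linear indices of the network mask (must be identical
#'   across seed types).
#' @param voxels Linear indices of map columns (taken from `seed_map`s when
#'   omitted).
#' @param groups Optional per-subject group factor.
#' @return A `network_strength` object: long-format `table` (subject,
#'   seed_type, group, strength) and `anova` (term, df1, df2, F, p).
#' @export
network_strength <- function(maps_by_type, network_vox, voxels = NULL,
                             groups = NULL) {
  if (!length(network_vox)) stop("empty network mask", call. = FALSE)
  mats <- lapply(maps_by_type, function(m) {
    if (is.list(m) && inherits(m[[1]], "seed_map")) {
      if (is.null(voxels)) voxels <<- m[[1]]$gm_vox
      do.call(rbind, lapply(m, `[[`, "z"))
    } else as.matrix(m)
  })
  if (is.null(voxels)) voxels <- seq_len(ncol(mats[[1]]))
  cols <- match(network_vox, voxels)
  if (anyNA(cols))
    stop("network mask voxels missing from the maps", call. = FALSE)
  n <- nrow(mats[[1]])
  tab <- do.call(rbind, lapply(names(mats), function(ty)
    data.frame(subject = factor(seq_len(n)), seed_type = ty,
               strength = rowMeans(mats[[ty]][, cols, drop = FALSE]))))
  tab$seed_type <- factor(tab$seed_type, levels = names(mats))
  if (!is.null(groups)) tab$group <- factor(rep(groups, length(mats)))

  if (is.null(groups)) {
    fit <- stats::aov(strength ~ seed_type + Error(subject / seed_type),
                      data = tab)
  } else {
    fit <- stats::aov(strength ~ group * seed_type +
                        Error(subject / seed_type), data = tab)
  }
  anova_tab <- extract_aov_terms(fit)
  structure(list(table = tab, anova = anova_tab, fit = fit),
            class = "network_strength")
}

extract_aov_terms <- function(fit) {
  out <- data.frame(term = character(0), df1 = numeric(0), df2 = numeric(0),
                    F = numeric(0), p = numeric(0))
  for (stratum in summary(fit)) {
    s <- stratum[[1]]
    terms <- trimws(rownames(s))
    resid_df <- s["Residuals", "Df"]
    for (i in seq_len(nrow(s))) {
      if (terms[i] == "Residuals" || is.na(s[i, "F value"])) next
      out <- rbind(out, data.frame(term = terms[i], df1 = s[i, "Df"],
                                   df2 = resid_df, F = s[i, "F value"],
                                   p = s[i, "Pr(>F)"]))
    }
  }
  out
}

#' @export
print.network_strength <- function(x, ...) {
  cat("<network_strength>\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Cohen's d between two groups
#'
#' `(mean_A - mean_B) / s_pooled` with the usual n-1 pooled standard
#' deviation. Returns `NA` with a warning when the pooled SD is zero.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return Scalar d.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 observations", call. = FALSE)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    warning("zero pooled SD: Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Decompose a probability map into non-overlapping spheres
#'
#' Greedily tiles the suprathreshold support of a cluster probability map
#' with spheres of fixed radius, starting at the probability peak and moving
#' outward in order of decreasing probability; every sphere centre lies in
#' the support and sphere voxel sets are pairwise disjoint. For each sphere,
#' each subject's seed-to-voxel map is computed with the sphere as seed, the
#' network strength (mean z within `network_vox`) extracted, and the
#' between-group effect size computed; finally the across-sphere Pearson
#' correlation between mean strength and sphere probability is reported per
#' group.
#'
#' @param prob_vol 3-D probability array for one cluster.
#' @param subjects List of subject series: `bold_series` objects or lists
#'   with elements `series` (t x v matrix) and `voxels`.
#' @param gm_vox Grey-matter voxel indices for the seed maps.
#' @param network_vox Network mask indices for the strength extraction.
#' @param groups Per-subject group factor (two levels).
#' @param radius_mm Sphere radius (default 4).
#' @param threshold Probability threshold defining the support (default
#'   0.25).
#' @param affine Voxel-to-world affine of the probability volume.
#' @return A `sphere_grid`: data frame `spheres` (centre, n_voxels,
#'   mean_prob, strength per group, d), matrix `strength`
#'   (subjects x spheres), and `correlation` (strength vs probability, per
#'   group; `NA` and flagged when undefined).
#' @export
sphere_grid_effects <- function(prob_vol, subjects, gm_vox, network_vox,
                                groups, radius_mm = 4, threshold = 0.25,
                                affine = diag_affine(c(3, 3, 3))) {
  dim3 <- dim(prob_vol)
  support <- which(prob_vol > threshold)
  if (!length(support))
    stop("probability support is empty at this threshold", call. = FALSE)
  ord <- support[order(prob_vol[support], decreasing = TRUE)]
  used <- integer(0)
  centres <- integer(0)
  sphere_sets <- list()
  for (v in ord) {
    world <- drop(ijk_to_world(index_to_ijk(v, dim3), affine))
    sph <- sphere_seed(world, radius_mm, dim3, affine)
    if (length(intersect(sph, used))) next
    centres <- c(centres, v)
    sphere_sets <- c(sphere_sets, list(sph))
    used <- c(used, sph)
  }
  if (!length(sphere_sets))
    stop("support smaller than one sphere", call. = FALSE)
  groups <- factor(groups)
  n <- length(subjects)
  strength <- matrix(NA_real_, n, length(sphere_sets))
  for (i in seq_len(n)) {
    sub <- subjects[[i]]
    for (k in seq_along(sphere_sets)) {
      seed <- sphere_sets[[k]]
      map <- if (inherits(sub, "bold_series"))
        seed_to_voxel_map(sub, seed, gm_vox)
      else
        seed_to_voxel_map(sub$series, intersect(seed, sub$voxels), gm_vox,
                          voxels = sub$voxels)
      strength[i, k] <- mean(map$z[match(network_vox, map$gm_vox)],
                             na.rm = TRUE)
    }
  }
  lv <- levels(groups)
  d <- vapply(seq_along(sphere_sets), function(k)
    cohens_d(strength[groups == lv[1], k], strength[groups == lv[2], k]),
    numeric(1))
  mean_prob <- vapply(sphere_sets, function(s) mean(prob_vol[s]), numeric(1))
  spheres <- data.frame(sphere = seq_along(sphere_sets),
                        centre_voxel = centres,
                        n_voxels = lengths(sphere_sets),
                        mean_prob = mean_prob, d = d)
  for (g in lv)
    spheres[[paste0("strength_", g)]] <-
      colMeans(strength[groups == g, , drop = FALSE])
  correlation <- vapply(lv, function(g) {
    s <- spheres[[paste0("strength_", g)]]
    if (length(s) < 3L || stats::sd(s) == 0 || stats::sd(mean_prob) == 0)
      return(NA_real_)
    stats::cor(s, mean_prob)
  }, numeric(1))
  if (anyNA(correlation))
    warning("strength-probability correlation undefined for some group")
  structure(list(spheres = spheres, strength = strength,
                 correlation = correlation, radius_mm = radius_mm,
                 threshold = threshold, sphere_voxels = sphere_sets),
            class = "sphere_grid")
}

#' @export
print.sphere_grid <- function(x, ...) {
  cat(sprintf("<sphere_grid> %d spheres (r = %g mm); strength-probability r: %s\n",
              nrow(x$spheres), x$radius_mm,
              paste(sprintf("%s = %.2f", names(x$correlation),
                            x$correlation), collapse = ", ")))
  invisible(x)
}
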