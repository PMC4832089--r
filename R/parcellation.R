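#' Distance between connectivity fingerprints
#'
#' Default metric: one minus the Pearson correlation between fingerprint
#' rows, the standard choice for connectivity-based parcellation;
#' `"euclidean"` is available as an alternative.
#'
#' @param fingerprints Seed-voxels x features matrix (rows are
#'   fingerprints).
#' @param metric `"corrdist"` (default) or `"euclidean"`.
#' @return A `dist` object over rows.
#' @export
fingerprint_dist <- function(fingerprints, metric = c("corrdist", "euclidean")) {
  metric <- match.arg(metric)
  if (!all(is.finite(fingerprints)))
    stop("input error: non-finite fingerprint values", call. = FALSE)
  if (metric == "corrdist")
    stats::as.dist(1 - stats::cor(t(fingerprints)))
  else
    stats::dist(fingerprints)
}

#' Average-linkage dendrogram over seed-mask voxels
#'
#' @param fingerprints Group fingerprint matrix in correlation units
#'   (seed voxels x GM voxels), e.g. from [group_fixed_effects()].
#' @param metric Fingerprint distance metric (see [fingerprint_dist()]).
#' @param seed_vox Optional linear indices of the rows (taken from the
#'   matrix attributes when present).
#' @return A `parcel_dendrogram`: the `hclust` tree, the metric, and the
#'   voxel indices.
#' @export
build_dendrogram <- function(fingerprints, metric = "corrdist",
                             seed_vox = attr(fingerprints, "seed_vox")) {
  if (nrow(fingerprints) < 2L)
    stop("need at least 2 seed voxels", call. = FALSE)
  d <- fingerprint_dist(fingerprints, metric)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, metric = metric,
                 seed_vox = seed_vox %||% seq_len(nrow(fingerprints))),
            class = "parcel_dendrogram")
}

#' @export
print.parcel_dendrogram <- function(x, ...) {
  cat(sprintf("<parcel_dendrogram> %d voxels, average linkage, metric = %s\n",
              length(x$hclust$order), x$metric))
  invisible(x)
}

new_parcel_solution <- function(labels, cut_height, source, seed_vox) {
  labels <- as.integer(labels)
  structure(list(labels = labels, K = length(unique(labels)),
                 cut_height = cut_height, source = source,
                 seed_vox = seed_vox),
            class = "parcel_solution")
}

#' @export
print.parcel_solution <- function(x, ...) {
  cat(sprintf("<parcel_solution> K = %d over %d voxels (source: %s)\n",
              x$K, length(x$labels), x$source))
  invisible(x)
}

#' Cut a dendrogram at uniformly spaced height levels
#'
#' Cut heights are spaced uniformly between the smallest and the largest
#' merge height, exclusive of the endpoints, so every level yields between
#' 2 and n-1 clusters. Levels with identical labelings are retained; they
#' index different heights.
#'
#' @param dendrogram A `parcel_dendrogram`.
#' @param n_levels Number of cut levels (default 100).
#' @return List of `parcel_solution` objects, one per level, each carrying
#'   its cut height.
#' @export
cut_uniform_levels <- function(dendrogram, n_levels = 100L) {
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  hc <- dendrogram$hclust
  h <- range(hc$height)
  if (diff(h) == 0) {
    warning("degenerate tree: all merge heights equal; single solution")
    heights <- mean(h)
  } else {
    heights <- seq(h[1], h[2], length.out = n_levels + 2L)
    heights <- heights[-c(1L, n_levels + 2L)]
  }
  lapply(heights, function(ht)
    new_parcel_solution(stats::cutree(hc, h = ht), ht, "group",
                        dendrogram$seed_vox))
}

#' Mean silhouette of a labeling against one subject's fingerprints
#'
#' Classic silhouette: for voxel i, `a(i)` is its mean distance to the other
#' members of its cluster and `b(i)` the smallest mean distance to any other
#' cluster; `s(i) = (b - a) / max(a, b)`. Voxels in singleton clusters
#' contribute 0. Distances are computed from the subject's own fingerprints
#' under the configured metric, so the value measures how well a (group)
#' labeling fits individual data.
#'
#' @param solution A `parcel_solution` (or integer label vector).
#' @param subject_fingerprints The subject's seed-voxel fingerprint matrix
#'   (rows aligned with the labels), or a precomputed `dist`/matrix of
#'   pairwise distances.
#' @param metric Fingerprint metric, used when fingerprints are given.
#' @return Mean silhouette value (scalar).
#' @export
subject_silhouette <- function(solution, subject_fingerprints,
                               metric = "corrdist") {
  labels <- if (inherits(solution, "parcel_solution")) solution$labels
            else as.integer(solution)
  D <- as_dist_matrix(subject_fingerprints, metric)
  if (length(labels) != nrow(D))
    stop("labels do not cover the subject's seed voxels", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("undefined silhouette: need at least 2 clusters", call. = FALSE)
  mean(silhouette_values(labels, D))
}

as_dist_matrix <- function(x, metric = "corrdist") {
  if (inherits(x, "dist")) return(as.matrix(x))
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && isTRUE(all.equal(unname(x), unname(t(x)))) &&
      all(abs(diag(x)) < 1e-12))
    return(x)
  as.matrix(fingerprint_dist(x, metric))
}

silhouette_values <- function(labels, D) {
  ks <- sort(unique(labels))
  n <- length(labels)
  # mean distance from every voxel to every cluster
  md <- vapply(ks, function(k) rowSums(D[, labels == k, drop = FALSE]) /
                 pmax(1L, sum(labels == k)), numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- match(labels[i], ks)
    nk <- sum(labels == labels[i])
    if (nk == 1L) { s[i] <- 0; next }
    a <- sum(D[i, labels == labels[i]]) / (nk - 1L)
    b <- min(md[i, -k])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Silhouette t-score profile over dendrogram cut levels
#'
#' For each cut level, computes the mean silhouette of the group labeling
#' against every subject's individual fingerprints and the across-subject
#' one-sample t-statistic versus zero. Local maxima are candidate numbers of
#' clusters. Because neighbouring levels often share a labeling (and hence a
#' t-score), maxima are identified on runs of consecutive equal t values: a
#' run strictly greater than both neighbouring runs is a maximum, reported
#' at its first level. A completely flat profile yields no maxima and a
#' warning.
#'
#' @param solutions List of `parcel_solution`s from [cut_uniform_levels()].
#' @param subject_fingerprints List (one per subject) of fingerprint
#'   matrices or precomputed distance matrices, rows aligned with the
#'   labels.
#' @param metric Fingerprint metric.
#' @return A `silhouette_profile`: data frame `levels` (level, cut height,
#'   K, mean silhouette, t), matrix `silhouettes` (levels x subjects),
#'   integer vector `local_maxima` (level indices), and `flagged` levels
#'   where t was undefined.
#' @export
silhouette_profile <- function(solutions, subject_fingerprints,
                               metric = "corrdist") {
  if (length(subject_fingerprints) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  Ds <- lapply(subject_fingerprints, as_dist_matrix, metric = metric)
  L <- length(solutions)
  sil <- matrix(NA_real_, L, length(Ds))
  for (l in seq_len(L)) {
    lab <- solutions[[l]]$labels
    if (length(unique(lab)) < 2L) next
    sil[l, ] <- vapply(Ds, function(D) mean(silhouette_values(lab, D)),
                       numeric(1))
  }
  m <- rowMeans(sil)
  sdv <- apply(sil, 1, stats::sd)
  tval <- ifelse(sdv > 0, m / (sdv / sqrt(ncol(sil))), NA_real_)
  flagged <- which(!is.na(m) & (is.na(tval) | !is.finite(tval)))
  if (length(flagged))
    warning("t undefined (zero across-subject variance) at ",
            length(flagged), " level(s)")
  levels_df <- data.frame(
    level = seq_len(L),
    cut_height = vapply(solutions, `[[`, numeric(1), "cut_height"),
    K = vapply(solutions, `[[`, 1L, "K"),
    mean_silhouette = m, t = tval)
  structure(list(levels = levels_df, silhouettes = sil,
                 local_maxima = profile_local_maxima(tval),
                 flagged = flagged),
            class = "silhouette_profile")
}

# strict local maxima over runs of equal consecutive values
profile_local_maxima <- function(tval) {
  ok <- which(is.finite(tval))
  v <- tval[ok]
  if (!length(v)) return(integer(0))
  run_id <- cumsum(c(TRUE, v[-1] != v[-length(v)]))
  run_val <- tapply(v, run_id, `[`, 1)
  nr <- length(run_val)
  if (nr < 2L) {
    warning("flat silhouette-t profile: no local maxima")
    return(integer(0))
  }
  # interior runs only: a maximum needs a strictly lower run on both sides
  is_max <- vapply(seq_len(nr), function(r) {
    r > 1L && r < nr &&
      run_val[r] > run_val[r - 1L] && run_val[r] > run_val[r + 1L]
  }, logical(1))
  firsts <- ok[match(which(is_max), run_id)]
  sort(firsts)
}

#' @export
print.silhouette_profile <- function(x, ...) {
  lm <- x$local_maxima
  cat(sprintf("<silhouette_profile> %d levels, %d subjects; local maxima at K = %s\n",
              nrow(x$levels), ncol(x$silhouettes),
              paste(x$levels$K[lm], collapse = ", ")))
  invisible(x)
}

#' Single-subject parcellation at a fixed number of clusters
#'
#' Builds an average-linkage tree on the subject's own fingerprints and cuts
#' it to exactly K clusters (the back-projection of a group-level K).
#'
#' @param subject_fingerprints Subject fingerprint matrix
#'   (seed voxels x features) or a `connectivity_matrix`.
#' @param K Number of clusters.
#' @param metric Fingerprint metric.
#' @param subject_id Recorded as the solution source.
#' @return A `parcel_solution`.
#' @export
subject_solution <- function(subject_fingerprints, K, metric = "corrdist",
                             subject_id = "subject") {
  if (inherits(subject_fingerprints, "connectivity_matrix")) {
    subject_id <- subject_fingerprints$subject_id
    seed_vox <- subject_fingerprints$seed_vox
    subject_fingerprints <- subject_fingerprints$z
  } else seed_vox <- attr(subject_fingerprints, "seed_vox") %||%
      seq_len(nrow(subject_fingerprints))
  n <- nrow(subject_fingerprints)
  if (K < 1L || K > n)
    stop("parameter error: K must lie in 1..", n, call. = FALSE)
  hc <- stats::hclust(fingerprint_dist(subject_fingerprints, metric),
                      method = "average")
  labels <- stats::cutree(hc, k = K)
  ht <- if (K < n) hc$height[n - K] else 0
  new_parcel_solution(labels, ht, subject_id, seed_vox)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), near 0 for
#' independent ones.
#'
#' @param a,b Integer label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
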