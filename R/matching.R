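#' Dice similarity of two voxel sets
#'
#' `2 |a intersect b| / (|a| + |b|)`. Two empty sets give 0 with a warning.
#'
#' @param a,b Voxel sets (integer index vectors).
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (!length(a) && !length(b)) {
    warning("Dice of two empty sets defined as 0")
    return(0)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Voxel sets of a parcel solution
#'
#' @param solution A `parcel_solution`.
#' @return Named list of linear voxel index vectors, one per cluster label.
#' @export
cluster_voxel_sets <- function(solution) {
  split(solution$seed_vox, solution$labels)
}

#' Match group clusters to a subject's clusters
#'
#' Implements Dice-matrix matching: the group's and the subject's clusters
#' together form one element set with pairwise distance `1 - Dice` between
#' group-subject pairs and distance 1 within each side; an average-linkage
#' dendrogram over this set is cut at every distinct merge height and the
#' cut maximizing the number of two-element clusters containing exactly one
#' group and one subject cluster is selected (ties resolved by the lowest
#' cut height). The pairs in those two-element clusters are the matches. No
#' minimal-overlap cutoff is enforced by default.
#'
#' @param group,subject `parcel_solution` objects on comparable voxel grids.
#' @param min_dice Optional minimum Dice for a pair to count as a match
#'   (default 0, i.e. no cutoff).
#' @return A `cluster_match`: data frame `matches` (group_cluster,
#'   subject_cluster, dice — `NA` subject id for unmatched group clusters),
#'   the chosen `cut_height`, and the full `dice_matrix`.
#' @export
match_clusters <- function(group, subject, min_dice = 0) {
  gs <- cluster_voxel_sets(group)
  ss <- cluster_voxel_sets(subject)
  empty_g <- lengths(gs) == 0L; empty_s <- lengths(ss) == 0L
  if (any(empty_g) || any(empty_s)) {
    warning("excluding empty cluster(s) from matching")
    gs <- gs[!empty_g]; ss <- ss[!empty_s]
  }
  ng <- length(gs); ns <- length(ss)
  dm <- matrix(0, ng, ns, dimnames = list(names(gs), names(ss)))
  for (i in seq_len(ng)) for (j in seq_len(ns))
    dm[i, j] <- dice(gs[[i]], ss[[j]])

  n <- ng + ns
  D <- matrix(1, n, n)
  D[seq_len(ng), ng + seq_len(ns)] <- 1 - dm
  D[ng + seq_len(ns), seq_len(ng)] <- t(1 - dm)
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  side <- rep(c("group", "subject"), c(ng, ns))
  best <- list(count = -1L, height = Inf, pairs = NULL)
  for (h in sort(unique(hc$height))) {
    memb <- stats::cutree(hc, h = h)
    pairs <- matched_pairs_at_cut(memb, side, ng)
    cnt <- nrow(pairs)
    if (cnt > best$count) best <- list(count = cnt, height = h, pairs = pairs)
  }
  pairs <- best$pairs
  pair_dice <- if (nrow(pairs)) mapply(function(g, s) dm[g, s],
                                       pairs$group_cluster,
                                       pairs$subject_cluster) else numeric(0)
  if (min_dice > 0 && nrow(pairs)) {
    keep <- pair_dice >= min_dice
    pairs <- pairs[keep, , drop = FALSE]
    pair_dice <- pair_dice[keep]
  }
  g_ids <- as.integer(names(gs))
  matches <- data.frame(group_cluster = g_ids,
                        subject_cluster = NA_integer_,
                        dice = NA_real_)
  if (nrow(pairs)) {
    # pairs index positionally into gs/ss, whose order matches the rows
    matches$subject_cluster[pairs$group_cluster] <-
      as.integer(names(ss))[pairs$subject_cluster]
    matches$dice[pairs$group_cluster] <- pair_dice
  }
  structure(list(matches = matches, cut_height = best$height,
                 dice_matrix = dm, subject_id = subject$source),
            class = "cluster_match")
}

# two-element clusters containing exactly one group and one subject element
matched_pairs_at_cut <- function(membership, side, ng) {
  out <- data.frame(group_cluster = integer(0), subject_cluster = integer(0))
  for (cl in unique(membership)) {
    members <- which(membership == cl)
    if (length(members) == 2L && side[members[1]] != side[members[2]]) {
      g <- members[side[members] == "group"]
      s <- members[side[members] == "subject"]
      out <- rbind(out, data.frame(group_cluster = g,
                                   subject_cluster = s - ng))
    }
  }
  out
}

#' @export
print.cluster_match <- function(x, ...) {
  cat(sprintf("<cluster_match> %d of %d group clusters matched (mean Dice %.3f)\n",
              sum(!is.na(x$matches$subject_cluster)), nrow(x$matches),
              mean(x$matches$dice, na.rm = TRUE)))
  invisible(x)
}

#' Per-cluster replication rates across subjects
#'
#' Percentage of subjects whose solution contains a match for each group
#' cluster, with an optional chi-squared test of group differences in the
#' match frequency.
#'
#' @param reports List of `cluster_match` objects, one per subject.
#' @param groups Optional factor of subject group labels for the test.
#' @return Data frame: group_cluster, n_matched, replication_pct, mean_dice,
#'   sd_dice, and (with `groups`) chisq_p.
#' @export
replication_rates <- function(reports, groups = NULL) {
  if (!length(reports)) stop("need at least 1 subject", call. = FALSE)
  g_ids <- reports[[1]]$matches$group_cluster
  matched <- vapply(reports, function(r)
    !is.na(r$matches$subject_cluster), logical(length(g_ids)))
  matched <- matrix(matched, nrow = length(g_ids))
  dice_vals <- vapply(reports, function(r) r$matches$dice,
                      numeric(length(g_ids)))
  dice_vals <- matrix(dice_vals, nrow = length(g_ids))
  out <- data.frame(group_cluster = g_ids,
                    n_matched = rowSums(matched),
                    replication_pct = 100 * rowMeans(matched),
                    mean_dice = rowMeans(dice_vals, na.rm = TRUE),
                    sd_dice = apply(dice_vals, 1, stats::sd, na.rm = TRUE))
  if (!is.null(groups)) {
    groups <- factor(groups)
    out$chisq_p <- vapply(seq_along(g_ids), function(i) {
      tab <- table(groups, factor(matched[i, ], levels = c(FALSE, TRUE)))
      if (any(colSums(tab) == 0)) return(1)
      suppressWarnings(stats::chisq.test(tab)$p.value)
    }, numeric(1))
  }
  out
}

#' Probabilistic atlas from matched subject clusters
#'
#' For each group cluster, binarises every matched subject cluster and sums
#' across subjects: the probability of a voxel belonging to the cluster is
#' the fraction of all subjects whose matched cluster covers it. Unmatched
#' subject clusters carry no group identity and are excluded.
#'
#' @param reports List of `cluster_match` objects.
#' @param subject_solutions List of the corresponding subject
#'   `parcel_solution`s.
#' @param dim3 Grid dimensions of the label volumes.
#' @return A `prob_atlas`: `prob` (voxels-in-union x clusters probability
#'   matrix), `voxels` (linear indices of its rows), `dim`, `n_subjects`.
#' @export
build_probability_maps <- function(reports, subject_solutions, dim3) {
  n_sub <- length(reports)
  if (n_sub == 0L) stop("zero subjects", call. = FALSE)
  g_ids <- reports[[1]]$matches$group_cluster
  all_vox <- sort(unique(unlist(lapply(subject_solutions,
                                       function(s) s$seed_vox))))
  cnt <- matrix(0L, length(all_vox), length(g_ids),
                dimnames = list(NULL, g_ids))
  for (i in seq_len(n_sub)) {
    sets <- cluster_voxel_sets(subject_solutions[[i]])
    m <- reports[[i]]$matches
    for (r in seq_len(nrow(m))) {
      if (is.na(m$subject_cluster[r])) next
      vox <- sets[[as.character(m$subject_cluster[r])]]
      col <- match(m$group_cluster[r], g_ids)
      rows <- match(vox, all_vox)
      cnt[rows, col] <- cnt[rows, col] + 1L
    }
  }
  structure(list(prob = cnt / n_sub, voxels = all_vox, dim = dim3,
                 n_subjects = n_sub, clusters = g_ids),
            class = "prob_atlas")
}

#' Probability volume of one cluster
#'
#' @param atlas A `prob_atlas`.
#' @param cluster Group cluster id.
#' @return 3-D array of probabilities.
#' @export
atlas_prob_volume <- function(atlas, cluster) {
  v <- array(0, dim = atlas$dim)
  v[atlas$voxels] <- atlas$prob[, match(cluster, atlas$clusters)]
  v
}

#' Winner-take-all labeling of a probabilistic atlas
#'
#' A voxel is labeled with the cluster of greatest probability, provided
#' that probability strictly exceeds `threshold`; otherwise it stays
#' unlabeled. Exact ties on the maximal probability are recorded in a tie
#' mask and resolved deterministically in favour of the lowest cluster
#' index.
#'
#' @param atlas A `prob_atlas`.
#' @param threshold Probability threshold (default 0.25).
#' @return List: `labels` (3-D integer array, 0 = unlabeled), `ties`
#'   (3-D logical array), `threshold`.
#' @export
winner_take_all <- function(atlas, threshold = 0.25) {
  p <- atlas$prob
  maxp <- apply(p, 1, max)
  win <- apply(p, 1, which.max)           # lowest index on exact ties
  n_at_max <- rowSums(p == maxp)
  labeled <- maxp > threshold
  labels <- array(0L, dim = atlas$dim)
  labels[atlas$voxels[labeled]] <-
    as.integer(atlas$clusters)[win[labeled]]
  ties <- array(FALSE, dim = atlas$dim)
  ties[atlas$voxels[labeled & n_at_max > 1L]] <- TRUE
  list(labels = labels, ties = ties, threshold = threshold)
}
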