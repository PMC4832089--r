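test_that("dice similarity follows its definition", {
  expect_equal(dice(1:5, 1:5), 1)
  expect_equal(dice(1:3, 4:6), 0)
  expect_equal(dice(1:4, 3:6), 0.5)          # |a|=|b|=4, overlap 2
  expect_warning(d0 <- dice(integer(0), integer(0)), "empty")
  expect_equal(d0, 0)
  expect_equal(dice(1:2, integer(0)), 0)
})

test_that("identical solutions match one-to-one with Dice 1", {
  co <- parcellation_cohort(n = 4, seed = 51)
  truth <- as_solution(co$truth$parcel_labels,
                       seed_vox = co$truth$seed_voxels)
  m <- match_clusters(truth, truth)
  expect_equal(sum(is.na(m$matches$subject_cluster)), 0)
  expect_equal(m$matches$dice, rep(1, 6))
  expect_equal(m$matches$subject_cluster, m$matches$group_cluster)
})

test_that("a merged subject cluster leaves a group cluster unmatched", {
  # subject merges group clusters 5 and 6 into one (as when the ventral
  # posterior and retrosplenial parcels fuse at the subject level)
  g <- rep(1:6, each = 10)
  s <- g; s[s == 6] <- 5
  m <- match_clusters(as_solution(g), as_solution(s))
  expect_equal(sum(is.na(m$matches$subject_cluster)), 1)
  matched_subject <- m$matches$subject_cluster[!is.na(m$matches$subject_cluster)]
  expect_equal(anyDuplicated(matched_subject), 0)
})

test_that("matching equals the exhaustive cut-height oracle", {
  # diagonal-dominant 3 x 3 overlap structure
  O3 <- matrix(c(18, 2, 0,
                 2, 16, 2,
                 0, 2, 18), 3, 3, byrow = TRUE)
  p <- partitions_from_overlap(O3)
  m <- match_clusters(as_solution(p$group), as_solution(p$subject))
  expect_equal(m$matches$subject_cluster, 1:3)
  oracle <- oracle_match(split(seq_along(p$group), p$group),
                         split(seq_along(p$subject), p$subject))
  expect_equal(oracle$count, 3L)
  expect_equal(oracle$pairs[order(oracle$pairs[, 1]), 2], 1:3)

  # 6 x 6 with off-diagonal contamination
  O6 <- diag(12, 6)
  O6[1, 2] <- O6[2, 1] <- 3
  O6[5, 6] <- O6[6, 5] <- 2
  p6 <- partitions_from_overlap(O6)
  gsets <- split(seq_along(p6$group), p6$group)
  ssets <- split(seq_along(p6$subject), p6$subject)
  m6 <- match_clusters(as_solution(p6$group), as_solution(p6$subject))
  o6 <- oracle_match(gsets, ssets)
  got <- m6$matches[!is.na(m6$matches$subject_cluster), 1:2]
  expect_equal(nrow(got), o6$count)
  expect_equal(got$subject_cluster[order(got$group_cluster)],
               o6$pairs[order(o6$pairs[, 1]), 2])

  # randomized partitions, several seeds
  for (sd in 1:4) {
    set.seed(sd)
    g <- sample(1:4, 60, TRUE)
    s <- sample(1:5, 60, TRUE)
    mm <- match_clusters(as_solution(g), as_solution(s))
    oo <- oracle_match(split(1:60, g), split(1:60, s))
    expect_equal(sum(!is.na(mm$matches$subject_cluster)), oo$count)
  }
})

test_that("matching is invariant to label permutation", {
  set.seed(3)
  g <- rep(1:4, times = c(8, 12, 10, 6))
  s <- g; s[1:4] <- 2
  m1 <- match_clusters(as_solution(g), as_solution(s))
  perm <- c(3L, 1L, 4L, 2L)
  m2 <- match_clusters(as_solution(perm[g]), as_solution(s))
  d1 <- sort(m1$matches$dice)
  d2 <- sort(m2$matches$dice)
  expect_equal(d1, d2)
})

test_that("replication rates are simple percentages with a group test", {
  co <- parcellation_cohort(n = 4, seed = 61)
  truth <- as_solution(co$truth$parcel_labels,
                       seed_vox = co$truth$seed_voxels)
  full <- match_clusters(truth, truth)
  none <- full
  none$matches$subject_cluster <- NA_integer_
  none$matches$dice <- NA_real_

  rr <- replication_rates(c(rep(list(full), 13), rep(list(none), 7)))
  expect_equal(rr$replication_pct, rep(65, 6))
  rr2 <- replication_rates(rep(list(full), 5))
  expect_equal(rr2$replication_pct, rep(100, 6))

  grp <- rep(c("A", "B"), each = 10)
  rr3 <- replication_rates(c(rep(list(full), 13), rep(list(none), 7)),
                           groups = grp)
  expect_true(all(rr3$chisq_p >= 0 & rr3$chisq_p <= 1))
})

test_that("probability maps count matched subjects only", {
  g <- rep(1:2, each = 6)
  truth <- as_solution(g)
  # subject 1 identical; subject 2 shifts one voxel between clusters
  s2 <- g; s2[6] <- 2
  r1 <- match_clusters(truth, truth)
  r2 <- match_clusters(truth, as_solution(s2))
  atlas <- build_probability_maps(list(r1, r2), list(truth, as_solution(s2)),
                                  dim3 = c(12, 1, 1))
  expect_true(all(atlas$prob %in% c(0, 0.5, 1)))
  # voxel 6: cluster 1 for subject 1, cluster 2 for subject 2
  expect_equal(atlas$prob[6, ], c("1" = 0.5, "2" = 0.5))
  # conservation: per-cluster probability mass equals mean matched size
  sizes <- cbind(table(g), table(s2))
  expect_equal(unname(colSums(atlas$prob)), unname(rowMeans(sizes)))

  one <- build_probability_maps(list(r1), list(truth), dim3 = c(12, 1, 1))
  expect_true(all(one$prob %in% c(0, 1)))
  expect_error(build_probability_maps(list(), list(), c(12, 1, 1)), "zero")
})

test_that("winner-take-all respects threshold, ties and disjointness", {
  atlas <- structure(list(
    prob = matrix(c(0.53, 0.47,
                    0.20, 0.10,
                    0.40, 0.40,
                    0.00, 0.90), ncol = 2, byrow = TRUE),
    voxels = c(1L, 2L, 3L, 4L), dim = c(4L, 1L, 1L),
    n_subjects = 100L, clusters = c(1L, 2L)), class = "prob_atlas")
  w <- winner_take_all(atlas, threshold = 0.25)
  expect_equal(w$labels[1], 1L)            # 53% beats 47%
  expect_equal(w$labels[2], 0L)            # all probabilities <= threshold
  expect_equal(w$labels[3], 1L)            # exact tie -> lowest index
  expect_true(w$ties[3])
  expect_equal(sum(w$ties), 1)
  expect_equal(w$labels[4], 2L)
  # labeled set equals voxels whose max probability exceeds the threshold
  expect_equal(which(w$labels > 0), which(apply(atlas$prob, 1, max) > 0.25))
})

test_that("noise-free phantoms give indicator probability maps", {
  co <- parcellation_cohort(n = 6, noise_sd = 0, seed = 71, max_spikes = 0)
  mats <- cohort_matrices(co, preprocess = FALSE)
  truth <- as_solution(co$truth$parcel_labels,
                       seed_vox = co$truth$seed_voxels)
  bp <- backproject(truth, mats, dim3 = dim(co$subjects[[1]]$masks$seed))
  expect_true(all(bp$atlas$prob %in% c(0, 1)))
  wta_labels <- bp$wta$labels[co$truth$seed_voxels]
  expect_equal(adjusted_rand_index(wta_labels, co$truth$parcel_labels), 1)
  expect_equal(bp$replication$replication_pct, rep(100, 6))
})
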