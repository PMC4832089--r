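# shared fixtures and independent oracles, built in code at test time

small_phantom <- function(..., seed = 1L) {
  phantom_spec(n_timepoints = 200L, signal_corr = 0.7, noise_sd = 1,
               seed = seed, ...)
}

# the default study conditions for parcellation recovery:
# 20 subjects, K = 6, signal_corr = 0.7, noise_sd = 1, 200 frames
parcellation_cohort <- function(n = 20L, noise_sd = 1, seed = 11L,
                                max_spikes = 3L, n_timepoints = 200L) {
  make_cohort(cohort_spec(n_per_group = max(2L, n %/% 2L),
                          target = NULL, max_spikes = max_spikes,
                          phantom = phantom_spec(n_timepoints = n_timepoints,
                                                 signal_corr = 0.7,
                                                 noise_sd = noise_sd),
                          seed = seed))
}

cohort_matrices <- function(cohort, preprocess = TRUE) {
  suppressWarnings(cohort_connectivity(cohort, preprocess = preprocess))
}

# --- independent oracles -------------------------------------------------

# brute-force silhouette from first principles
oracle_silhouette <- function(labels, D) {
  D <- as.matrix(D)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k)
      mean(D[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# naive O(n^3) average-linkage agglomeration, independent of stats::hclust
oracle_average_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  dm <- D
  merges <- list()
  sizes <- rep(1L, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    best <- c(NA, NA); bh <- Inf
    for (a in idx) for (b in idx) if (a < b && dm[a, b] < bh) {
      bh <- dm[a, b]; best <- c(a, b)
    }
    a <- best[1]; b <- best[2]
    merges[[length(merges) + 1L]] <-
      list(members = sort(c(clusters[[a]], clusters[[b]])), height = bh)
    # average-linkage update
    new_d <- (sizes[a] * dm[a, ] + sizes[b] * dm[b, ]) / (sizes[a] + sizes[b])
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    dm[a, ] <- new_d; dm[, a] <- new_d
    dm[a, a] <- 0
    active[b] <- FALSE
  }
  merges
}

# partition implied by cutting the naive tree at height h (merges <= h applied)
oracle_cut <- function(merges, n, h) {
  labels <- seq_len(n)
  for (m in merges) {
    if (m$height > h) next
    labels[labels %in% labels[m$members]] <- min(labels[m$members])
  }
  as.integer(factor(labels))
}

# exhaustive matching oracle: all distinct cut heights of the naive tree,
# maximize the number of two-element group/subject pairs, lowest height wins
oracle_match <- function(group_sets, subject_sets) {
  ng <- length(group_sets); ns <- length(subject_sets)
  n <- ng + ns
  dm <- matrix(1, n, n); diag(dm) <- 0
  for (i in seq_len(ng)) for (j in seq_len(ns)) {
    d <- 1 - 2 * length(intersect(group_sets[[i]], subject_sets[[j]])) /
      (length(group_sets[[i]]) + length(subject_sets[[j]]))
    dm[i, ng + j] <- dm[ng + j, i] <- d
  }
  merges <- oracle_average_linkage(dm)
  heights <- sort(unique(vapply(merges, `[[`, numeric(1), "height")))
  best <- list(count = -1L, pairs = NULL)
  for (h in heights) {
    labels <- oracle_cut(merges, n, h)
    pairs <- NULL
    for (cl in unique(labels)) {
      mem <- which(labels == cl)
      if (length(mem) == 2L && xor(mem[1] <= ng, mem[2] <= ng)) {
        g <- mem[mem <= ng]; s <- mem[mem > ng] - ng
        pairs <- rbind(pairs, c(g, s))
      }
    }
    cnt <- if (is.null(pairs)) 0L else nrow(pairs)
    if (cnt > best$count) best <- list(count = cnt, pairs = pairs)
  }
  best
}

# construct two partitions of 1..n realizing a given intersection matrix
partitions_from_overlap <- function(O) {
  n <- sum(O)
  group <- integer(n); subject <- integer(n)
  pos <- 1L
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    k <- O[i, j]
    if (k > 0) {
      group[pos:(pos + k - 1L)] <- i
      subject[pos:(pos + k - 1L)] <- j
      pos <- pos + k
    }
  }
  list(group = group, subject = subject)
}

as_solution <- function(labels, source = "test", seed_vox = seq_along(labels)) {
  structure(list(labels = as.integer(labels),
                 K = length(unique(labels)), cut_height = NA_real_,
                 source = source, seed_vox = seed_vox),
            class = "parcel_solution")
}
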