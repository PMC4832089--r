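test_that("framewise displacement follows the rigid-body convention", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))

  m2 <- m; m2[5:10, 1] <- 0.1              # translation step of 0.1 mm
  fd <- framewise_displacement(m2)
  expect_equal(fd[5], 0.1)
  expect_equal(fd[-5], rep(0, 9))

  m3 <- m; m3[4:10, 4] <- 0.01             # rotation step: arc length r * dtheta
  expect_equal(framewise_displacement(m3)[4], 0.01 * 50)
  expect_equal(framewise_displacement(m3, head_radius_mm = 80)[4], 0.8)

  # combined: sum of absolute parameter differences
  m4 <- m; m4[2, ] <- c(0.1, -0.2, 0, 0.01, 0, 0)
  expect_equal(framewise_displacement(m4)[2], 0.1 + 0.2 + 0.5)
  expect_error(framewise_displacement(matrix(0, 5, 5)), "6")
})

test_that("dvars matches a hand computation and is scale invariant", {
  x <- matrix(100, 5, 3)
  expect_equal(dvars(x), rep(0, 5))

  # 2-voxel, 3-volume toy series: rms of backward difference over the mean
  toy <- matrix(c(10, 12, 11,
                  20, 18, 22), ncol = 2)
  d2 <- rbind(toy[2, ] - toy[1, ], toy[3, ] - toy[2, ])
  expected <- c(0, sqrt(rowMeans(d2^2)) / mean(toy) * 100)
  expect_equal(dvars(toy), expected, tolerance = 1e-12)
  expect_equal(dvars(toy * 3.7), dvars(toy), tolerance = 1e-12)
  expect_error(dvars(toy - mean(toy)), "normalization")
})

test_that("scrubbing censors on strict threshold exceedance", {
  expect_equal(scrub(rep(0, 4), rep(0, 4))$keep, rep(TRUE, 4))

  cm <- scrub(c(0, 0.6, 0.2), c(0, 0, 0.7))
  expect_equal(cm$keep, c(TRUE, FALSE, FALSE))
  expect_equal(cm$fd_thresh, 0.5)

  # boundary: exactly at threshold is retained
  expect_true(all(scrub(rep(0.5, 5), rep(0.5, 5))$keep))
  expect_error(scrub(rep(1, 3), rep(0, 3)), "degenerate")

  # optional neighbour augmentation
  cm2 <- scrub(c(0, 0, 1, 0, 0), rep(0, 5), augment = 1)
  expect_equal(cm2$keep, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("friston24 expansion is the documented column layout", {
  m0 <- matrix(0, 5, 6)
  expect_equal(unname(friston24(m0)), matrix(0, 5, 24))

  m <- matrix(rnorm(60), 10, 6)
  f <- friston24(m)
  expect_equal(dim(f), c(10L, 24L))
  expect_equal(unname(f[, 13]), unname(m[, 1]^2))
  expect_equal(unname(f[, 7]), c(0, m[-10, 1]))
  expect_equal(unname(f[, 19:24]), unname(f[, 7:12]^2))

  ramp <- cbind(c(1, 2, 3), 0, 0, 0, 0, 0)
  fr <- friston24(ramp)
  expect_equal(unname(fr[, 7]), c(0, 1, 2))
  expect_equal(unname(fr[, 19]), c(0, 1, 4))
})

test_that("tissue principal components match an SVD oracle", {
  set.seed(5)
  # rank-1 data: one component explains everything
  base <- rnorm(30)
  x1 <- outer(base, c(1, -2, 0.5, 3))
  p1 <- suppressWarnings(tissue_pcs(x1, n_components = 3))
  expect_gt(attr(p1, "explained_variance")[1], 1 - 1e-10)

  x <- matrix(rnorm(40 * 5), 40, 5)
  pcs <- tissue_pcs(x, n_components = 3)
  # orthogonality contract
  expect_lt(max(abs(crossprod(pcs) - diag(3))), 1e-8)
  # against an independent full SVD of the demeaned matrix
  sv <- svd(sweep(x, 2, colMeans(x)))
  for (k in 1:3)
    expect_equal(abs(sum(pcs[, k] * sv$u[, k])), 1, tolerance = 1e-8)
  expect_error(tissue_pcs(x, n_components = 6), "fewer voxels")
})

test_that("band-pass filter has the designed frequency response", {
  tr <- 2
  t <- seq(0, by = tr, length.out = 400)
  expect_equal(bandpass(rep(5, 400), tr), rep(0, 400), tolerance = 1e-10)

  mid <- 120:280   # central portion, away from filter edges
  s_in <- sin(2 * pi * 0.05 * t)
  s_out <- bandpass(s_in, tr)
  expect_lt(abs(stats::sd(s_out[mid]) / stats::sd(s_in[mid]) - 1), 0.05)

  tr1 <- 1
  t1 <- seq(0, by = tr1, length.out = 400)
  fast <- sin(2 * pi * 0.4 * t1)
  fast_out <- bandpass(fast, tr1)
  expect_lt(stats::sd(fast_out[mid]) / stats::sd(fast[mid]), 0.10)

  expect_error(bandpass(s_in, tr = 2, high = 0.3), "Nyquist")
})

test_that("nuisance regression projects exactly and censors consistently", {
  set.seed(8)
  x <- matrix(rnorm(50 * 10), 50, 10)
  conf <- matrix(rnorm(50 * 3), 50, 3)

  # intercept only -> demeaned series
  r0 <- regress_nuisance(x, matrix(nrow = 50, ncol = 0))
  expect_equal(r0, sweep(x, 2, colMeans(x)), ignore_attr = TRUE)

  # a series equal to a confound column vanishes
  r1 <- regress_nuisance(cbind(conf[, 1]), conf)
  expect_lt(max(abs(r1)), 1e-10)

  # normal-equations oracle
  X <- cbind(1, conf)
  beta <- solve(crossprod(X), crossprod(X, x))
  expect_equal(regress_nuisance(x, conf), x - X %*% beta,
               ignore_attr = TRUE, tolerance = 1e-10)

  # orthogonality over retained volumes, censoring applied to both sides
  keep <- rep(TRUE, 50); keep[c(3, 17)] <- FALSE
  r2 <- regress_nuisance(x, conf, keep)
  expect_equal(nrow(r2), 48)
  expect_lt(max(abs(crossprod(cbind(1, conf[keep, ]), r2))), 1e-8)

  expect_warning(regress_nuisance(x, cbind(conf, conf[, 1])), "collinear")
})

test_that("scrubbing recovers injected spike frames exactly", {
  spec <- small_phantom(spike_frames = c(40L, 41L, 150L))
  s <- make_phantom_subject(spec, 21)
  fd <- framewise_displacement(s$motion)
  dv <- dvars(series_matrix(s$bold, s$masks$gm))
  cm <- scrub(fd, dv)
  expect_identical(which(!cm$keep), c(40L, 41L, 150L))
  # each criterion alone also flags exactly the spikes
  expect_identical(which(fd > 0.5), c(40L, 41L, 150L))
  expect_identical(which(dv > 0.5), c(40L, 41L, 150L))
})

test_that("the denoising chain leaves residuals orthogonal to confounds", {
  spec <- small_phantom(spike_frames = 60L)
  s <- make_phantom_subject(spec, 33)
  pp <- suppressWarnings(preprocess_subject(s, band = NULL))
  keep <- pp$censor$keep
  conf <- pp$confounds[keep, , drop = FALSE]
  conf <- conf[, apply(conf, 2, stats::sd) > 0, drop = FALSE]
  expect_lt(max(abs(crossprod(conf, pp$series))) /
              max(abs(pp$series)), 1e-6)
  # stage order is logged (constant motion axes recorded as dropped)
  stages <- vapply(pp$log, `[[`, "", "stage")
  expect_equal(stages, c("scrub", "confounds", "regress"))
  pp2 <- suppressWarnings(preprocess_subject(s))
  expect_equal(vapply(pp2$log, `[[`, "", "stage"),
               c("scrub", "confounds", "regress", "bandpass"))
})
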