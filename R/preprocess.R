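#' Framewise displacement
#'
#' Per-volume head-movement scalar: the sum of absolute backward differences
#' of the six rigid-body parameters, with rotations converted to arc length
#' on a sphere of radius `head_radius_mm` (the Power convention). The first
#' volume has no predecessor and gets FD = 0.
#'
#' @param m t x 6 motion matrix (tx, ty, tz in mm; rx, ry, rz in radians).
#' @param head_radius_mm Sphere radius for the rotation arc length.
#' @return Numeric vector of length t, in mm.
#' @export
framewise_displacement <- function(m, head_radius_mm = 50) {
  check_motion(m)
  if (nrow(m) == 0L) stop("need at least one volume", call. = FALSE)
  d <- abs(diff(m))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  c(0, rowSums(d))
}

#' DVARS: framewise signal change
#'
#' Root-mean-square over in-mask voxels of the backward temporal difference,
#' expressed as percent of the within-mask grand mean signal, so the
#' conventional 0.5% threshold is comparable across scanners. The first
#' volume gets DVARS = 0.
#'
#' @param series A `bold_series` or a t x v matrix.
#' @param mask 3-D mask (ignored when `series` is already a matrix).
#' @return Numeric vector of length t, percent units.
#' @export
dvars <- function(series, mask = NULL) {
  x <- if (inherits(series, "bold_series")) {
    if (is.null(mask)) stop("mask required for a bold_series", call. = FALSE)
    series_matrix(series, mask)
  } else as.matrix(series)
  grand_mean <- mean(x)
  if (!is.finite(grand_mean) || grand_mean <= 0)
    stop("normalization error: within-mask temporal mean is not positive",
         call. = FALSE)
  d <- diff(x)
  c(0, sqrt(rowMeans(d^2)) / grand_mean * 100)
}

#' Motion scrubbing
#'
#' Flags volumes whose framewise displacement or DVARS strictly exceeds its
#' threshold. Volumes at exactly the threshold are retained.
#'
#' @param fd Per-volume FD (mm).
#' @param dvars Per-volume DVARS (percent).
#' @param fd_thresh FD threshold, mm (default 0.5).
#' @param dvars_thresh DVARS threshold, percent (default 0.5).
#' @param augment Non-negative integer: additionally censor this many
#'   neighbours on each side of a flagged volume (default 0, i.e. only
#'   flagged volumes are removed).
#' @return A `censor_mask`: list with logical `keep` per volume and the
#'   thresholds used.
#' @export
scrub <- function(fd, dvars, fd_thresh = 0.5, dvars_thresh = 0.5,
                  augment = 0L) {
  if (length(fd) != length(dvars))
    stop("fd and dvars must have equal length", call. = FALSE)
  bad <- fd > fd_thresh | dvars > dvars_thresh
  if (augment > 0L) {
    idx <- which(bad)
    for (k in seq_len(augment))
      bad[pmax(1L, idx - k)] <- bad[pmin(length(bad), idx + k)] <- TRUE
  }
  if (all(bad))
    stop("degenerate series: every volume censored", call. = FALSE)
  structure(list(keep = !bad, fd_thresh = fd_thresh,
                 dvars_thresh = dvars_thresh, n_censored = sum(bad)),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("<censor_mask> %d of %d volumes censored (FD > %g mm or DVARS > %g%%)\n",
              x$n_censored, length(x$keep), x$fd_thresh, x$dvars_thresh))
  invisible(x)
}

#' Friston 24-parameter motion expansion
#'
#' Columns 1-6: the six motion parameters; 7-12: the same shifted back one
#' volume (first row zero-filled); 13-18 and 19-24: the elementwise squares
#' of the first two blocks.
#'
#' @param m t x 6 motion matrix.
#' @return t x 24 matrix with named columns.
#' @export
friston24 <- function(m) {
  check_motion(m)
  if (nrow(m) < 2L) stop("need at least 2 volumes", call. = FALSE)
  shifted <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, shifted, m^2, shifted^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_d1"), paste0(base, "_sq"),
                     paste0(base, "_d1sq"))
  out
}

#' Tissue principal-component time series
#'
#' Extracts the first `n_components` principal-component time series from
#' the voxels of a tissue mask (typically white matter or CSF), after
#' demeaning each voxel's series. Components are the left singular vectors
#' of the demeaned time-by-voxel matrix, ordered by decreasing explained
#' variance and mutually orthogonal. If the data rank is lower than
#' requested, the available components are returned with a warning.
#'
#' @param series A `bold_series` or t x v matrix.
#' @param tissue_mask 3-D mask (ignored for matrix input).
#' @param n_components Number of components (default 3).
#' @return t x k matrix (k <= n_components) with an `explained_variance`
#'   attribute (fractions).
#' @export
tissue_pcs <- function(series, tissue_mask = NULL, n_components = 3L) {
  x <- if (inherits(series, "bold_series")) {
    if (is.null(tissue_mask)) stop("tissue_mask required", call. = FALSE)
    series_matrix(series, tissue_mask)
  } else as.matrix(series)
  if (ncol(x) < n_components)
    stop("mask has fewer voxels than requested components", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = min(n_components, min(dim(xc))), nv = 0)
  tol <- max(dim(xc)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  k <- min(n_components, rank)
  if (k < n_components)
    warning(sprintf("data rank %d < %d requested components; returning %d",
                    rank, n_components, k))
  comps <- sv$u[, seq_len(k), drop = FALSE]
  colnames(comps) <- paste0("pc", seq_len(k))
  attr(comps, "explained_variance") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  comps
}

#' Zero-phase band-pass filter
#'
#' Order-2 Butterworth band-pass applied forward and backward
#' (zero phase lag); the temporal mean is removed from the output.
#'
#' @param x t x v matrix (or vector) of time series.
#' @param tr Sampling interval, seconds.
#' @param low,high Pass band in Hz (defaults 0.009 and 0.2).
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(x, tr, low = 0.009, high = 0.2) {
  nyquist <- 1 / (2 * tr)
  if (high >= nyquist)
    stop(sprintf("parameter error: high cutoff %g Hz >= Nyquist %g Hz",
                 high, nyquist), call. = FALSE)
  if (low <= 0 || low >= high)
    stop("parameter error: need 0 < low < high", call. = FALSE)
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  bf <- signal::butter(2, c(low, high) / nyquist, type = "pass")
  xc <- sweep(x, 2, colMeans(x))
  out <- apply(xc, 2, function(col) signal::filtfilt(bf, col))
  out <- sweep(out, 2, colMeans(out))
  if (vec) drop(out) else out
}

#' Nuisance regression
#'
#' Projects out a confound matrix from every voxel's time series by ordinary
#' least squares over the retained (non-censored) volumes; censored volumes
#' are excluded from both the fit and the output. An intercept is always
#' included. Collinear confound columns are dropped with a warning using a
#' rank-revealing QR decomposition.
#'
#' @param x t x v data matrix.
#' @param confounds t x q confound matrix (same t as `x`).
#' @param censor Optional `censor_mask` (or logical keep vector).
#' @return Residual matrix, retained volumes x v, with a `dropped_confounds`
#'   attribute naming any removed columns.
#' @export
regress_nuisance <- function(x, confounds, censor = NULL) {
  x <- as.matrix(x)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(x))
    stop("confounds and data disagree on the number of volumes",
         call. = FALSE)
  keep <- if (is.null(censor)) rep(TRUE, nrow(x))
          else if (inherits(censor, "censor_mask")) censor$keep
          else as.logical(censor)
  if (sum(keep) < 2L)
    stop("fewer than 2 retained volumes", call. = FALSE)
  X <- cbind(intercept = 1, confounds[keep, , drop = FALSE])
  Y <- x[keep, , drop = FALSE]
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    used <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), used)]
    if (is.null(dropped)) dropped <- paste0("V", setdiff(seq_len(ncol(X)), used))
    warning("dropping collinear confound column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, used, drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, Y)
  attr(res, "dropped_confounds") <- dropped
  res
}

#' Single-subject denoising pipeline
#'
#' Runs the standard order: scrub (FD/DVARS) -> nuisance regression
#' (24 motion parameters + 3 white-matter + 3 CSF principal components,
#' censored identically) -> band-pass. The order of regression and
#' filtering can be swapped with `filter_first = TRUE`; confounds are then
#' filtered identically before regression. The resolved configuration and
#' stage order are recorded in the result.
#'
#' @param bold A `bold_series`.
#' @param motion t x 6 motion matrix.
#' @param wm_mask,csf_mask Tissue masks for the component extraction.
#' @param analysis_mask Mask defining the voxels carried through (defaults
#'   to all voxels with nonzero temporal variance); DVARS is computed within
#'   it.
#' @param fd_thresh,dvars_thresh Scrubbing thresholds (0.5 mm, 0.5%).
#' @param band Pass band in Hz, length-2 (0.009, 0.2); `NULL` disables.
#' @param n_tissue_pcs Components per tissue (3).
#' @param filter_first Band-pass before regression instead of after.
#' @param smooth_fwhm Optional Gaussian smoothing FWHM in mm, applied first.
#' @return List: `series` (retained-volumes x voxels residual matrix),
#'   `voxels` (linear indices of the columns), `censor` (`censor_mask`),
#'   `fd`, `dvars`, `confounds`, and `log` (ordered stage records).
#' @export
preprocess_bold <- function(bold, motion, wm_mask, csf_mask,
                            analysis_mask = NULL,
                            fd_thresh = 0.5, dvars_thresh = 0.5,
                            band = c(0.009, 0.2), n_tissue_pcs = 3L,
                            filter_first = FALSE, smooth_fwhm = NULL) {
  log <- list()
  if (!is.null(smooth_fwhm) && smooth_fwhm > 0) {
    bold <- smooth_gaussian(bold, smooth_fwhm)
    log <- c(log, list(list(stage = "smooth", fwhm_mm = smooth_fwhm)))
  }
  if (is.null(analysis_mask)) {
    v <- apply(bold$data, 1:3, stats::var)
    analysis_mask <- array(as.integer(v > 0), dim = dim(bold$data)[1:3])
  }
  x <- series_matrix(bold, analysis_mask)
  voxels <- mask_indices(analysis_mask)

  fd <- framewise_displacement(motion)
  dv <- dvars(x)
  cm <- scrub(fd, dv, fd_thresh, dvars_thresh)
  log <- c(log, list(list(stage = "scrub", n_censored = cm$n_censored,
                          fd_thresh = fd_thresh,
                          dvars_thresh = dvars_thresh)))

  confounds <- cbind(friston24(motion),
                     wm = tissue_pcs(bold, wm_mask, n_tissue_pcs),
                     csf = tissue_pcs(bold, csf_mask, n_tissue_pcs))
  # the nuisance set must carry no constant columns over retained volumes
  # (e.g. unused motion axes), and step-like motion makes several of the 24
  # columns exact aliases; reduce to an independent set, recording the drops
  constant <- apply(confounds[cm$keep, , drop = FALSE], 2,
                    function(x) stats::sd(x) == 0)
  confounds <- confounds[, !constant, drop = FALSE]
  qx <- qr(cbind(1, confounds[cm$keep, , drop = FALSE]))
  aliased_idx <- setdiff(seq_len(ncol(confounds)),
                         setdiff(qx$pivot[seq_len(qx$rank)], 1L) - 1L)
  aliased <- colnames(confounds)[aliased_idx]
  if (length(aliased_idx))
    confounds <- confounds[, -aliased_idx, drop = FALSE]
  if (any(constant) || length(aliased_idx))
    log <- c(log, list(list(stage = "confounds",
                            dropped_constant = names(constant)[constant],
                            dropped_aliased = aliased)))

  if (filter_first && !is.null(band)) {
    x <- bandpass(x, bold$tr, band[1], band[2])
    confounds <- bandpass(confounds, bold$tr, band[1], band[2])
    log <- c(log, list(list(stage = "bandpass", band = band,
                            applied = "before_regression")))
  }
  res <- regress_nuisance(x, confounds, cm)
  log <- c(log, list(list(stage = "regress",
                          n_confounds = ncol(confounds) + 1L)))
  if (!filter_first && !is.null(band)) {
    res <- bandpass(res, bold$tr, band[1], band[2])
    log <- c(log, list(list(stage = "bandpass", band = band,
                            applied = "after_regression")))
  }
  list(series = res, voxels = voxels, censor = cm, fd = fd, dvars = dv,
       confounds = confounds, tr = bold$tr, affine = bold$affine,
       dim = dim(bold$data)[1:3], subject_id = bold$subject_id, log = log)
}
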