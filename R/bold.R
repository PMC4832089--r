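#' BOLD series container
#'
#' A light container for one subject's 4-D functional data: an array with
#' dimensions `x * y * z * t`, the repetition time (sampling interval) in
#' seconds, and a 4x4 voxel-to-world affine.
#'
#' @param data Numeric 4-D array (`x, y, z, t`).
#' @param tr Repetition time in seconds.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @param subject_id Optional subject identifier.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr, affine = diag_affine(c(3, 3, 3)),
                        subject_id = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("data must be a 4-D array (x, y, z, t)", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar (seconds)", call. = FALSE)
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  structure(list(data = data, tr = tr, affine = affine,
                 subject_id = subject_id),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %s: %d x %d x %d voxels, %d volumes, TR = %g s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

n_volumes <- function(bold) dim(bold$data)[4]

#' Extract a time-by-voxel matrix from a BOLD series
#'
#' @param bold A `bold_series`.
#' @param mask 3-D mask array, or a vector of linear voxel indices.
#' @return A `t x v` matrix; column order follows increasing linear index for
#'   a mask, or the given index order for an index vector.
#' @export
series_matrix <- function(bold, mask) {
  idx <- if (is.array(mask)) mask_indices(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("mask selects no voxels", call. = FALSE)
  d <- dim(bold$data)
  nvox <- prod(d[1:3])
  if (any(idx < 1L | idx > nvox))
    stop("voxel indices out of range", call. = FALSE)
  m <- matrix(bold$data, nrow = nvox, ncol = d[4])[idx, , drop = FALSE]
  t(m)
}

#' Replace the time dimension of a BOLD series
#'
#' Subsets volumes, e.g. after censoring.
#'
#' @param bold A `bold_series`.
#' @param keep Logical or integer index over volumes.
#' @return A `bold_series` with the retained volumes.
#' @export
subset_volumes <- function(bold, keep) {
  bold$data <- bold$data[, , , keep, drop = FALSE]
  bold
}

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' @param x Array (3-D or 4-D) or `bold_series`.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param affine 4x4 affine; taken from the object for a `bold_series`.
#' @param tr Repetition time in seconds (4-D only).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, affine = diag_affine(c(3, 3, 3)), tr = NULL) {
  if (inherits(x, "bold_series")) {
    affine <- x$affine
    tr <- x$tr
    x <- x$data
  }
  img <- RNifti::asNifti(x)
  RNifti::sform(img) <- structure(affine, code = 2L)
  if (!is.null(tr) && length(dim(x)) == 4L)
    RNifti::pixdim(img) <- c(RNifti::pixdim(img)[1:3], tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path File path.
#' @param tr Repetition time override in seconds; if `NULL`, taken from the
#'   header for 4-D images.
#' @return A `bold_series` for 4-D images, otherwise a plain array with an
#'   `affine` attribute.
#' @export
read_volume <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dim = c(4, 4))
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) == 4L) {
    if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
    bold_series(arr, tr = tr, affine = unclass(aff))
  } else {
    attr(arr, "affine") <- unclass(aff)
    arr
  }
}

#' Read / write a 6-column motion parameter table
#'
#' Columns: tx, ty, tz in mm; rx, ry, rz in radians. One row per volume.
#'
#' @param path TSV file path.
#' @return A numeric matrix with 6 named columns.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  check_motion(m)
  m
}

#' @rdname read_motion
#' @param m Motion matrix.
#' @export
write_motion <- function(m, path) {
  check_motion(m)
  utils::write.table(as.data.frame(m), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

check_motion <- function(m) {
  if (!is.matrix(m) || ncol(m) != 6L)
    stop("motion parameters must form a t x 6 matrix ",
         "(tx, ty, tz mm; rx, ry, rz rad)", call. = FALSE)
  invisible(TRUE)
}

#' Apply isotropic Gaussian smoothing to each volume
#'
#' Separable 3-D Gaussian convolution, specified by full width at half
#' maximum in mm. Provided as an optional step before connectivity; phantom
#' pipelines leave it off.
#'
#' @param bold A `bold_series`.
#' @param fwhm_mm Kernel full width at half maximum, mm.
#' @return A smoothed `bold_series`.
#' @export
smooth_gaussian <- function(bold, fwhm_mm) {
  if (fwhm_mm <= 0) return(bold)
  vox <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  d <- dim(bold$data)
  out <- bold$data
  for (ax in 1:3) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox[ax]
    half <- max(1L, ceiling(3 * sigma_vox))
    k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  bold$data <- out
  bold
}

#' Smooth a voxelwise map in volume space
#'
#' Places per-voxel values into their 3-D volume, applies isotropic
#' Gaussian smoothing, and returns the smoothed values at the same voxels.
#' Typically applied to seed maps before cluster-level inference, which
#' presumes spatially smooth fields.
#'
#' @param z Per-voxel values.
#' @param voxels Linear voxel indices of `z`.
#' @param dim3 Grid dimensions.
#' @param fwhm_mm Kernel full width at half maximum, mm.
#' @param affine Voxel-to-world affine (for the voxel size).
#' @return Smoothed values, same length and order as `z`.
#' @export
smooth_map_volume <- function(z, voxels, dim3, fwhm_mm = 6,
                              affine = diag_affine(c(3, 3, 3))) {
  vol <- array(0, dim3)
  vol[voxels] <- z
  b <- bold_series(array(vol, c(dim3, 1L)), tr = 1, affine = affine)
  smooth_gaussian(b, fwhm_mm)$data[, , , 1][voxels]
}

# replicate-padded 1-D convolution along axis ax of a 4-D array
convolve_axis <- function(arr, kernel, ax) {
  d <- dim(arr)
  half <- (length(kernel) - 1L) / 2L
  perm <- c(ax, setdiff(1:4, ax))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  pad_top <- m[rep(1L, half), , drop = FALSE]
  pad_bot <- m[rep(nrow(m), half), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  res <- matrix(0, nrow = nrow(m), ncol = ncol(m))
  for (j in seq_along(kernel))
    res <- res + kernel[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
  out <- array(res, dim = da)
  aperm(out, order(perm))
}
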