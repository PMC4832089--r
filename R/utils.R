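# internal helpers shared across modules

#' Run code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that reproducible generation
#' does not disturb a caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Voxel coordinate helpers
#'
#' `index_to_ijk` converts linear voxel indices to 1-based array
#' coordinates; `ijk_to_world` maps array coordinates to world mm through a
#' 4x4 affine (NIfTI convention: the affine acts on 0-based indices).
#'
#' @param idx Linear voxel indices.
#' @param dim3 Grid dimensions.
#' @return `index_to_ijk`: n x 3 integer matrix.
#' @export
index_to_ijk <- function(idx, dim3) {
  arrayInd(idx, .dim = dim3)
}

#' @rdname index_to_ijk
#' @param ijk n x 3 matrix of 1-based array coordinates.
#' @param affine 4x4 voxel-to-world affine.
#' @return `ijk_to_world`: n x 3 matrix of mm coordinates.
#' @export
ijk_to_world <- function(ijk, affine) {
  ijk0 <- cbind(ijk - 1L, 1)
  t(affine %*% t(ijk0))[, 1:3, drop = FALSE]
}

# default affine for a phantom grid: scaled identity, origin at first voxel
diag_affine <- function(voxel_size) {
  a <- diag(c(voxel_size, 1))
  a
}

stopifnot_mask <- function(mask, dim3 = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D array", call. = FALSE)
  if (!is.null(dim3) && !identical(dim(mask), as.integer(dim3)))
    stop("mask dimensions do not match the reference volume", call. = FALSE)
  invisible(TRUE)
}

#' Linear voxel indices of a mask
#'
#' @param mask 3-D array; nonzero voxels are in the mask.
#' @return Sorted integer vector of linear indices.
#' @export
mask_indices <- function(mask) {
  which(mask != 0)
}

# column-wise Pearson correlation between the columns of x and the columns of
# y, over rows; thin wrapper kept for a single point of change
colcor <- function(x, y) {
  stats::cor(x, y)
}
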