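#' Minimal axis-aligned volume geometry
#'
#' A `volume_grid` records the spatial bookkeeping of a 3D/4D volume: the
#' number of voxels per axis, the voxel size in mm, and the world-space
#' offset of the first voxel.  Only axis-aligned scaling + translation
#' geometries are representable; oblique affines are out of scope and are
#' rejected when volumes are read.
#'
#' @param shape integer length-3, voxels per axis (all >= 1).
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, mm offset of voxel (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(4, 4, 4), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(voxel_size) != 3L || length(origin) != 3L)
    stop("shape, voxel_size and origin must each have length 3")
  if (anyNA(shape) || any(shape < 1L))
    stop("all shape entries must be >= 1")
  if (anyNA(voxel_size) || any(voxel_size <= 0))
    stop("all voxel sizes must be > 0")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels of %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

## Extract the grid from a NIfTI header, rejecting oblique orientations.
grid_from_nifti <- function(img) {
  dims <- dim(img)[1:3]
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offd <- rot; diag(offd) <- 0
  if (max(abs(offd)) > 1e-6 * max(abs(diag(rot)), 1))
    stop("oblique affine: only axis-aligned scaling + translation is supported")
  vs <- abs(diag(rot))
  if (any(vs == 0)) vs <- RNifti::pixdim(img)[1:3]
  volume_grid(dims, vs, xf[1:3, 4])
}

## Wrap an array in a niftiImage carrying the grid geometry (and TR for 4D).
nifti_from_array <- function(arr, grid, tr = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- grid$voxel_size
  if (length(dim(arr)) == 4L) pd <- c(pd, if (is.null(tr)) 1 else tr)
  RNifti::pixdim(img) <- pd
  m <- diag(c(grid$voxel_size, 1))
  m[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  img
}
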