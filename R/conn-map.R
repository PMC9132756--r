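#' Per-voxel connectivity map
#'
#' A `conn_map` stores one connectivity value per in-mask voxel together with
#' the estimator that produced it.  On the correlation scale (before the
#' Fisher transform) all defined values lie in [0, 1]: RBC and NRC are
#' correlations between fitted and observed series guaranteed nonnegative by
#' construction, and GBC is a mean of absolute correlations.  Voxels whose
#' value is undefined (constant series) are stored as `NA`.
#'
#' @param values numeric vector, one value per voxel (NA = undefined).
#' @param method one of `"RBC"`, `"GBC"`, `"NRC"`.
#' @param voxel_index integer p x 3 matrix of 0-based voxel coordinates.
#' @param lam ridge penalty used (RBC only), or `NULL`.
#' @param fisher logical; TRUE once [fisher_transform()] has been applied.
#' @param grid optional [volume_grid()].
#' @return An object of class `conn_map`.
#' @export
conn_map <- function(values, method, voxel_index, lam = NULL,
                     fisher = FALSE, grid = NULL) {
  method <- match.arg(method, c("RBC", "GBC", "NRC"))
  values <- as.numeric(values)
  voxel_index <- as.matrix(voxel_index)
  storage.mode(voxel_index) <- "integer"
  if (length(values) != nrow(voxel_index))
    stop("values and voxel_index lengths differ")
  def <- values[!is.na(values)]
  if (!fisher && length(def) && (min(def) < 0 || max(def) > 1))
    stop("untransformed connectivity values must lie in [0, 1]")
  if (fisher && length(def) && any(!is.finite(def)))
    stop("Fisher-transformed values must be finite")
  if (!is.null(lam) && (!is.numeric(lam) || lam < 0))
    stop("lam must be a nonnegative number")
  structure(list(values = values, method = method, lam = lam,
                 fisher = isTRUE(fisher), voxel_index = voxel_index,
                 grid = grid),
            class = "conn_map")
}

#' @export
print.conn_map <- function(x, ...) {
  cat(sprintf("conn_map: %s%s over %d voxels (%d missing)%s\n",
              x$method,
              if (!is.null(x$lam)) sprintf(" (lambda=%g)", x$lam) else "",
              length(x$values), sum(is.na(x$values)),
              if (x$fisher) ", Fisher-transformed" else ""))
  invisible(x)
}

## Assemble a conn_map over the full original voxel set: voxels dropped during
## standardization come back as NA, and the whole map is re-sorted into raster
## order so maps from different subjects are always aligned.
finish_map <- function(values, series, method, lam = NULL) {
  vi <- rbind(series$voxel_index, series$dropped)
  vals <- c(values, rep(NA_real_, nrow(series$dropped)))
  shape <- if (!is.null(series$grid)) series$grid$shape else NULL
  ord <- order(linear_index(vi, shape))
  conn_map(vals[ord], method, vi[ord, , drop = FALSE], lam = lam,
           fisher = FALSE, grid = series$grid)
}

#' Fisher (atanh) transform of a connectivity map
#'
#' Applies the variance-stabilising transform `atanh` to a correlation-scale
#' map before group analyses.  Values are clipped to `1 - 1e-12` first so
#' that correlations numerically equal to 1 (possible at very small ridge
#' penalties) map to a large finite value rather than infinity.
#'
#' @param map a [conn_map()] with `fisher = FALSE`.
#' @return The transformed [conn_map()] with `fisher = TRUE`.
#' @export
fisher_transform <- function(map) {
  stopifnot(inherits(map, "conn_map"))
  if (map$fisher) stop("map is already Fisher-transformed")
  v <- atanh(pmin(pmax(map$values, 0), 1 - 1e-12))
  conn_map(v, map$method, map$voxel_index, lam = map$lam,
           fisher = TRUE, grid = map$grid)
}

#' Write a connectivity map as a 3D NIfTI volume
#'
#' In-mask voxels receive the map values (missing values as NaN), background
#' voxels are 0.  Data are written as doubles so a read-back reproduces the
#' finite values bit-exactly.
#'
#' @param map a [conn_map()].
#' @param grid [volume_grid()] to write on (defaults to the map's own grid).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, grid = map$grid, path) {
  stopifnot(inherits(map, "conn_map"))
  if (is.null(grid)) stop("no grid available to write the map on")
  if (any(map$voxel_index < 0L) ||
      any(sweep(map$voxel_index, 2, grid$shape, ">=")))
    stop("map voxel_index inconsistent with grid")
  write_values_volume(map$values, map$voxel_index, grid, path)
}

## shared writer: values at in-mask voxels, 0 background, doubles on disk
write_values_volume <- function(values, voxel_index, grid, path) {
  arr <- array(0, grid$shape)
  arr[linear_index(voxel_index, grid$shape)] <- values
  RNifti::writeNifti(nifti_from_array(arr, grid), path, datatype = "double")
  invisible(path)
}

#' Read per-voxel values back from a map volume
#'
#' Extracts the values of a 3D NIfTI map at given voxel coordinates, the
#' inverse of [write_map()] for in-mask voxels.
#'
#' @param path NIfTI file written by [write_map()].
#' @param voxel_index integer p x 3 matrix of 0-based voxel coordinates.
#' @return numeric vector of map values (NaN read back as NA).
#' @export
read_map_values <- function(path, voxel_index) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d)) d <- length(img)
  if (length(d) > 3L) stop("map volume must be 3D")
  d <- c(d, rep(1L, 3L - length(d)))          # NIfTI drops singleton dims
  voxel_index <- as.matrix(voxel_index)
  as.vector(img)[linear_index(voxel_index, d)]
}
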