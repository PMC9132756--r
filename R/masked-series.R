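#' In-mask voxel time series
#'
#' A `masked_series` holds the N x p matrix of time series for the p voxels
#' inside a gray-matter mask, together with the voxel coordinates, repetition
#' time and standardization state.  Columns follow a fixed raster order
#' (x fastest, then y, then z) so that maps are reproducible across runs.
#' Voxel coordinates are 0-based.
#'
#' @param data numeric matrix, N time points x p voxels.
#' @param voxel_index integer p x 3 matrix of 0-based voxel coordinates.
#' @param tr repetition time in seconds.
#' @param grid optional [volume_grid()] the coordinates live on.
#' @param standardized logical; TRUE once [standardize()] has been applied.
#' @param dropped optional 0-row-or-more 3-column matrix of coordinates of
#'   constant (degenerate) voxels removed by [standardize()], plus nothing
#'   else; they reappear as missing values in any connectivity map.
#' @return An object of class `masked_series`.
#' @export
masked_series <- function(data, voxel_index, tr, grid = NULL,
                          standardized = FALSE, dropped = NULL) {
  data <- as.matrix(data)
  voxel_index <- as.matrix(voxel_index)
  storage.mode(voxel_index) <- "integer"
  if (nrow(data) < 3L) stop("need at least 3 time points")
  if (ncol(data) < 2L) stop("need at least 2 in-mask voxels")
  if (nrow(voxel_index) != ncol(data) || ncol(voxel_index) != 3L)
    stop("voxel_index must be a p x 3 matrix matching ncol(data)")
  key <- linear_index(voxel_index, if (is.null(grid)) NULL else grid$shape)
  if (anyDuplicated(key)) stop("voxel_index entries must be unique")
  if (!is.null(grid)) {
    if (any(voxel_index < 0L) ||
        any(sweep(voxel_index, 2, grid$shape, ">=")))
      stop("voxel_index entries must lie inside the grid")
  }
  if (isTRUE(standardized)) {
    if (max(abs(colMeans(data))) >= 1e-10)
      stop("standardized series must have column means 0")
    if (max(abs(colSums(data^2) / (nrow(data) - 1) - 1)) >= 1e-8)
      stop("standardized series must have column variance 1")
  }
  if (is.null(dropped)) dropped <- matrix(integer(0), 0, 3)
  structure(list(data = data, voxel_index = voxel_index, tr = as.numeric(tr),
                 grid = grid, standardized = isTRUE(standardized),
                 dropped = dropped),
            class = "masked_series")
}

#' @export
print.masked_series <- function(x, ...) {
  cat(sprintf(
    "masked_series: N=%d time points (TR=%gs) x p=%d voxels%s%s\n",
    nrow(x$data), x$tr, ncol(x$data),
    if (x$standardized) ", standardized" else "",
    if (nrow(x$dropped)) sprintf(" (+%d constant voxels dropped)",
                                 nrow(x$dropped)) else ""))
  invisible(x)
}

## 0-based coords -> 1-based linear index in x-fastest raster order
linear_index <- function(coords, shape = NULL) {
  if (is.null(shape)) shape <- apply(coords, 2, max) + 1L
  coords[, 1] + shape[1] * (coords[, 2] + shape[2] * coords[, 3]) + 1L
}

#' Load masked voxel time series from NIfTI volumes
#'
#' Reads a 4D BOLD volume and a binary 3D gray-matter mask on the same grid
#' and returns the N x p matrix of in-mask time series in raster order
#' (x fastest).  TR is taken from the 4th pixdim of the BOLD header.
#'
#' @param bold_path path to a 4D NIfTI file.
#' @param mask_path path to a binary 3D NIfTI file on the same grid.
#' @return A [masked_series()] (not standardized).
#' @export
load_masked_series <- function(bold_path, mask_path) {
  bold <- RNifti::readNifti(bold_path)
  mask <- RNifti::readNifti(mask_path)
  db <- dim(bold); dm <- dim(mask)
  if (length(db) != 4L) stop("BOLD volume must be 4D")
  if (length(dm) != 3L) stop("mask must be 3D")
  if (!all(db[1:3] == dm)) stop("grid mismatch between BOLD and mask")
  mv <- as.vector(mask)
  if (!all(mv %in% c(0, 1))) stop("mask must be binary (0/1)")
  idx <- which(mv == 1)
  if (length(idx) == 0L) stop("mask is empty")
  grid <- grid_from_nifti(bold)
  nt <- db[4]
  mat <- as.vector(bold)
  dim(mat) <- c(prod(db[1:3]), nt)
  coords <- arrayInd(idx, db[1:3]) - 1L
  tr <- RNifti::pixdim(bold)[4]
  masked_series(t(mat[idx, , drop = FALSE]), coords, tr = tr, grid = grid)
}

#' Block-mean spatial downsampling
#'
#' Downsamples a 3D or 4D array by averaging non-overlapping `factor`-cubed
#' blocks (per time point for 4D input).  Trailing partial blocks are
#' averaged over the voxels actually available, so no data are discarded.
#' The output voxel size is the input voxel size times `factor`.  Block
#' averaging is used (rather than interpolation) because the purpose of the
#' coarser grid is computational cost reduction and a block mean preserves
#' per-volume signal means exactly on divisible grids.
#'
#' @param arr 3D or 4D numeric array.
#' @param grid [volume_grid()] of `arr`.
#' @param factor positive integer downsampling factor.
#' @return list with elements `data` (downsampled array) and `grid`.
#' @export
resample_block_mean <- function(arr, grid, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  d <- dim(arr)
  nd <- length(d)
  if (!nd %in% c(3L, 4L)) stop("arr must be 3D or 4D")
  if (!all(d[1:3] == grid$shape)) stop("arr does not match grid shape")
  if (factor == 1L)
    return(list(data = arr, grid = grid))
  osh <- as.integer(ceiling(d[1:3] / factor))
  bx <- (seq_len(d[1]) - 1L) %/% factor
  by <- (seq_len(d[2]) - 1L) %/% factor
  bz <- (seq_len(d[3]) - 1L) %/% factor
  bid <- rep(bx, times = d[2] * d[3]) +
    osh[1] * (rep(rep(by, each = d[1]), times = d[3]) +
                osh[2] * rep(bz, each = d[1] * d[2]))
  nt <- if (nd == 4L) d[4] else 1L
  mat <- matrix(as.vector(arr), prod(d[1:3]), nt)
  agg <- rowsum(mat, group = bid)           # rows sorted by bid = raster order
  cnt <- as.vector(rowsum(rep(1, length(bid)), group = bid))
  out <- agg / cnt
  dim(out) <- if (nd == 4L) c(osh, nt) else osh
  list(data = out,
       grid = volume_grid(osh, grid$voxel_size * factor, grid$origin))
}

#' Majority-vote mask downsampling
#'
#' Companion to [resample_block_mean()] for binary masks: an output voxel is
#' kept in the mask when more than half of its source voxels are in the mask.
#'
#' @inheritParams resample_block_mean
#' @param mask binary 3D array.
#' @return list with elements `data` (binary 3D array) and `grid`.
#' @export
resample_mask_majority <- function(mask, grid, factor) {
  r <- resample_block_mean(mask, grid, factor)
  r$data <- (r$data > 0.5) * 1
  r
}

#' Band-pass filter voxel time series
#'
#' Applies a hard discrete-Fourier mask per column: frequency components
#' strictly outside `[low_hz, high_hz]` are zeroed, and the DC component is
#' always removed.  The hard mask makes the operation exactly idempotent and
#' testable bin by bin; only the retained band, not a filter family, is part
#' of the contract.
#'
#' @param series a [masked_series()].
#' @param low_hz,high_hz band edges in Hz; defaults 0.02 and 0.1.
#' @return A filtered [masked_series()] (not standardized).
#' @export
bandpass <- function(series, low_hz = 0.02, high_hz = 0.1) {
  stopifnot(inherits(series, "masked_series"))
  n <- nrow(series$data)
  nyq <- 1 / (2 * series$tr)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz <= nyq + 1e-12))
    stop(sprintf("band must satisfy 0 <= low < high <= Nyquist (%.4g Hz)", nyq))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * series$tr)     # folded (two-sided) frequencies
  keep <- f >= low_hz & f <= high_hz & k != 0L
  F <- stats::mvfft(series$data)
  F[!keep, ] <- 0
  out <- Re(stats::mvfft(F, inverse = TRUE)) / n
  masked_series(out, series$voxel_index, tr = series$tr, grid = series$grid,
                standardized = FALSE, dropped = series$dropped)
}

#' Standardize voxel time series to zero mean and unit variance
#'
#' Centers every column and scales it to sample variance 1 (divisor N-1).
#' Constant (zero-variance) columns cannot be standardized; they are removed
#' from the predictor set and recorded in the `dropped` field, so downstream
#' maps report them as missing rather than propagating NaNs.  The operation
#' is idempotent.
#'
#' @param series a [masked_series()].
#' @return A standardized [masked_series()].
#' @export
standardize <- function(series) {
  stopifnot(inherits(series, "masked_series"))
  Y <- series$data
  n <- nrow(Y)
  Y <- sweep(Y, 2, colMeans(Y), "-")
  v <- colSums(Y^2) / (n - 1)
  const <- v < 1e-20
  dropped <- series$dropped
  if (any(const)) {
    dropped <- rbind(dropped, series$voxel_index[const, , drop = FALSE])
    Y <- Y[, !const, drop = FALSE]
    vi <- series$voxel_index[!const, , drop = FALSE]
    v <- v[!const]
  } else vi <- series$voxel_index
  Y <- sweep(Y, 2, sqrt(v), "/")
  masked_series(Y, vi, tr = series$tr, grid = series$grid,
                standardized = TRUE, dropped = dropped)
}
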