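#' TFCE parameters
#'
#' Threshold-free cluster enhancement integrates, over cluster-forming
#' thresholds `h`, the quantity `extent^E * h^H * dh` for the suprathreshold
#' connected component containing each voxel.  Defaults `E = 0.5`, `H = 2`
#' and 26-neighbour connectivity are the standard published settings of the
#' method.
#'
#' @param E extent exponent (> 0).
#' @param H height exponent (> 0).
#' @param dh threshold step; `NULL` (default) means `max(stat)/100`,
#'   recomputed per map.
#' @param connectivity 6, 18 or 26 neighbourhood.
#' @return An object of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  if (!(is.numeric(E) && E > 0) || !(is.numeric(H) && H > 0))
    stop("E and H must be > 0")
  if (!is.null(dh) && !(is.numeric(dh) && dh > 0))
    stop("dh must be > 0 (or NULL for max(stat)/100)")
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  structure(list(E = E, H = H, dh = dh,
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement of a voxel-wise statistic map
#'
#' Enhances the positive part of the statistic; a negative contrast is
#' handled by enhancing the negated map in a separate call (as
#' [permutation_fwe()] does for two-sided inference).
#'
#' @param stat numeric vector of statistics, one per mask voxel.
#' @param voxel_index integer p x 3 matrix of 0-based voxel coordinates.
#' @param shape integer length-3 grid dimensions.
#' @param params a [tfce_params()].
#' @return numeric vector of enhanced scores (0 where `stat <= 0`).
#' @export
tfce <- function(stat, voxel_index, shape, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  if (any(!is.finite(stat)))
    stop("statistic map contains non-finite values inside the mask")
  voxel_index <- as.matrix(voxel_index)
  storage.mode(voxel_index) <- "integer"
  pos <- pmax(stat, 0)
  if (max(pos) == 0) return(numeric(length(stat)))
  dh <- if (is.null(params$dh)) max(pos) / 100 else params$dh
  tfce_cpp(pos, voxel_index, as.integer(shape), params$E, params$H, dh,
           params$connectivity)
}
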