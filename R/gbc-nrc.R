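#' Weighted global brain connectivity map
#'
#' For every in-mask voxel, the mean of the absolute Pearson correlations
#' between that voxel and every other in-mask voxel.  A bivariate-average
#' summary, in contrast to the multivariate RBC/NRC estimators: it reacts to
#' net shifts in pairwise coupling but not to redistributions of coupling
#' that leave the average magnitude unchanged.
#'
#' @param series a standardized [masked_series()] with p >= 2 voxels.
#' @return A [conn_map()] with `method = "GBC"`, values in [0, 1].
#' @export
gbc_map <- function(series) {
  stopifnot(inherits(series, "masked_series"))
  if (!series$standardized) stop("gbc_map requires a standardized series")
  Y <- series$data
  p <- ncol(Y)
  if (p < 2L) stop("gbc_map requires at least 2 non-degenerate voxels")
  C <- crossprod(Y) / (nrow(Y) - 1)    # correlations: columns are unit-variance
  vals <- (colSums(abs(C)) - 1) / (p - 1)
  vals <- pmin(pmax(vals, 0), 1)
  finish_map(vals, series, "GBC")
}

#' Configuration for the supervised principal-component estimator
#'
#' Exactly one screening rule is active: either an absolute-correlation
#' threshold `theta` in (0, 1), or a top fraction `top_frac` in (0, 1] of
#' predictors ranked by absolute marginal correlation with the target.
#'
#' @param theta absolute-correlation screening threshold, or `NULL`.
#' @param top_frac fraction of predictors to keep, or `NULL`.  If both rules
#'   are `NULL` the default `top_frac = 0.05` applies.
#' @param n_comp number of leading principal components regressed on
#'   (default 3); clipped, with a warning, when fewer screened predictors or
#'   a lower rank are available at fit time.
#' @return An object of class `nrc_config`.
#' @export
nrc_config <- function(theta = NULL, top_frac = NULL, n_comp = 3) {
  if (!is.null(theta) && !is.null(top_frac))
    stop("exactly one screening rule may be active")
  if (is.null(theta) && is.null(top_frac)) top_frac <- 0.05
  if (!is.null(theta) && !(is.numeric(theta) && theta > 0 && theta < 1))
    stop("theta must lie in (0, 1)")
  if (!is.null(top_frac) &&
      !(is.numeric(top_frac) && top_frac > 0 && top_frac <= 1))
    stop("top_frac must lie in (0, 1]")
  n_comp <- as.integer(n_comp)
  if (is.na(n_comp) || n_comp < 1L) stop("n_comp must be >= 1")
  structure(list(theta = theta, top_frac = top_frac, n_comp = n_comp),
            class = "nrc_config")
}

#' Non-redundant connectivity map (supervised principal components)
#'
#' Dimensionality-reduction counterpart of [rbc_map()].  For every target
#' voxel: (1) screen the remaining voxels by absolute marginal correlation
#' with the target per the configured rule; (2) take the leading principal
#' components of the screened (standardized) predictor block; (3) regress
#' the target on the first `n_comp` components by ordinary least squares;
#' (4) report the Pearson correlation between fitted and observed series
#' (the multiple correlation, hence nonnegative).
#'
#' @param series a standardized [masked_series()].
#' @param cfg an [nrc_config()].
#' @return A [conn_map()] with `method = "NRC"`, values in [0, 1].  Targets
#'   for which no predictor passes screening get 0 by convention.
#' @export
nrc_map <- function(series, cfg = nrc_config()) {
  stopifnot(inherits(series, "masked_series"), inherits(cfg, "nrc_config"))
  if (!series$standardized) stop("nrc_map requires a standardized series")
  Y <- series$data
  n <- nrow(Y); p <- ncol(Y)
  C <- crossprod(Y) / (n - 1)
  vals <- numeric(p)
  clipped <- FALSE
  for (i in seq_len(p)) {
    r <- abs(C[, i]); r[i] <- -Inf
    if (!is.null(cfg$theta)) {
      sel <- which(r >= cfg$theta)
    } else {
      k <- ceiling(cfg$top_frac * (p - 1))
      sel <- order(r, decreasing = TRUE)[seq_len(k)]
    }
    if (length(sel) == 0L) { vals[i] <- 0; next }
    y <- Y[, i]
    sv <- svd(Y[, sel, drop = FALSE], nu = min(n, length(sel)), nv = 0)
    rank <- sum(sv$d > sv$d[1] * 1e-10)
    m <- min(cfg$n_comp, rank)
    if (m < cfg$n_comp) clipped <- TRUE
    U <- sv$u[, seq_len(m), drop = FALSE]
    fit <- U %*% crossprod(U, y)        # OLS on orthogonal component scores
    if (sqrt(sum(fit^2) / (n - 1)) < 1e-14) { vals[i] <- 0; next }
    vals[i] <- sum(fit * y) / sqrt(sum(fit^2) * sum(y^2))
  }
  if (clipped)
    warning("n_comp exceeded the available rank for some voxels; clipped")
  vals <- pmin(pmax(vals, 0), 1)
  finish_map(vals, series, "NRC")
}
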