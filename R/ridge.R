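#' Gram matrix of standardized voxel time series
#'
#' Returns the N x N matrix K = Y Y' of inner products between time points
#' over all p in-mask voxels.  In the p >> N regime every leave-one-voxel-out
#' ridge regression can be solved through K (dual form) instead of the p x p
#' predictor cross-product, which is what makes voxel-level ridge
#' connectivity tractable.
#'
#' @param series a standardized [masked_series()].
#' @return N x N symmetric positive semi-definite matrix.
#' @export
gram_matrix <- function(series) {
  stopifnot(inherits(series, "masked_series"))
  if (!series$standardized)
    stop("gram_matrix requires a standardized series")
  tcrossprod(series$data)
}

#' Leave-one-voxel-out ridge regression in the dual form
#'
#' Fits the ridge regression of voxel `i`'s time series on all remaining
#' voxels, minimizing the raw penalized objective
#' `sum((y - X b)^2) + lam * sum(b^2)` (intercept handled by centering and
#' left unpenalized; it is exactly 0 for standardized data).  The fit is
#' computed through the Gram matrix: with `K = Y Y'` and the rank-one
#' downdate `K_{ -i } = K - y_i y_i'`, the dual coefficients solve
#' `(K_{-i} + lam I) a = y_i` and the fitted series is `K_{-i} a`.
#' Internally the downdated solve uses the Sherman-Morrison identity
#' `a = z / (1 - y_i' z)` with `z = (K + lam I)^{-1} y_i`, which is exact
#' and lets one Cholesky factorization serve every target voxel.
#'
#' @param K Gram matrix from [gram_matrix()] (over all p columns).
#' @param series the standardized [masked_series()] K was computed from.
#' @param i target voxel column index.
#' @param lam ridge penalty, strictly positive (the OLS limit is not a
#'   special case of this path; use a tiny `lam` to approach it).
#' @return A `ridge_solution`: list with `target_index`, `lam`, `dual_coef`,
#'   `fitted` and `intercept` (0).  Primal coefficients are recoverable as
#'   `t(Y[, -i]) %*% dual_coef`.
#' @export
ridge_fit_loo <- function(K, series, i, lam) {
  stopifnot(inherits(series, "masked_series"))
  n <- nrow(series$data)
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0)
    stop("lam must be a single strictly positive number")
  if (i < 1L || i > ncol(series$data)) stop("target index out of range")
  y <- series$data[, i]
  U <- chol(K + diag(lam, n))
  z <- backsolve(U, backsolve(U, y, transpose = TRUE))
  s <- sum(y * z)                       # y'(K+lam I)^{-1} y < 1 since K >= yy'
  alpha <- z / (1 - s)
  fitted <- drop(K %*% alpha) - y * sum(y * alpha)
  structure(list(target_index = i, lam = lam, dual_coef = alpha,
                 fitted = fitted, intercept = 0),
            class = "ridge_solution")
}

#' Regularized brain connectivity map (voxel-level ridge)
#'
#' For every in-mask voxel, predicts its time series from all remaining
#' voxels by ridge regression with penalty `lam` and reports the Pearson
#' correlation between the fitted and observed series.  The correlation is
#' nonnegative by construction: the fitted series is a symmetric positive
#' semi-definite smoother applied to the observed series.  `lam` must be the
#' same for every voxel and every subject within an analysis, otherwise the
#' per-voxel values are not comparable; this function takes a single `lam`
#' and the pipeline layer enforces it cohort-wide.  Cross-validation of
#' `lam` is deliberately not offered: with temporally dependent series the
#' usual resampling schemes are invalid, so analyses are run over an
#' explicit grid of penalties instead (conventionally 0.5, 1, 5, 10, 50,
#' 100, 500).
#'
#' @param series a standardized [masked_series()].
#' @param lam strictly positive ridge penalty on the raw
#'   `RSS + lam * sum(b^2)` scale.
#' @return A [conn_map()] with `method = "RBC"`; values in [0, 1], clipped
#'   at `1 - 1e-12`.  Voxels whose fitted series is degenerate (standard
#'   deviation below 1e-14, far beneath any genuine fit yet safely above
#'   floating-point noise) get value 0 by convention; voxels dropped as
#'   constant during
#'   standardization are `NA`.
#' @export
rbc_map <- function(series, lam) {
  stopifnot(inherits(series, "masked_series"))
  if (!series$standardized) stop("rbc_map requires a standardized series")
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0)
    stop("lam must be a single strictly positive number")
  Y <- series$data
  n <- nrow(Y)
  K <- tcrossprod(Y)
  U <- chol(K + diag(lam, n))
  Z <- backsolve(U, backsolve(U, Y, transpose = TRUE))      # (K+lam I)^{-1} Y
  s <- colSums(Y * Z)
  alpha <- sweep(Z, 2, 1 - s, "/")
  fit <- K %*% alpha - sweep(Y, 2, colSums(Y * alpha), "*") # K_{-i} alpha_i
  fsd <- sqrt(colSums(fit^2) / (n - 1))
  num <- colSums(fit * Y)
  den <- sqrt(colSums(fit^2) * colSums(Y^2))
  vals <- ifelse(fsd < 1e-14, 0, num / den)
  vals <- pmin(pmax(vals, 0), 1 - 1e-12)
  finish_map(vals, series, "RBC", lam = lam)
}
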