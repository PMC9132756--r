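#' Subject-level design for voxel-wise group inference
#'
#' Couples the regressor of interest (a two-level group indicator or a
#' continuous clinical score) with an optional nuisance covariate matrix
#' (e.g. age, gender, medication type, medication dose) and the contrast
#' direction.
#'
#' @param subjects character vector of subject ids.
#' @param regressor per-subject value of interest.  A factor/character with
#'   exactly two levels is converted to a 0/1 indicator (levels in sorted
#'   order, second level coded 1, so positive statistics mean higher values
#'   in the second level).
#' @param nuisance optional numeric matrix/data.frame of nuisance
#'   covariates, one row per subject; must have full column rank.
#' @param contrast `"two-sided"` (default), `"positive"` or `"negative"`.
#' @return An object of class `group_design`.
#' @export
group_design <- function(subjects, regressor, nuisance = NULL,
                         contrast = c("two-sided", "positive", "negative")) {
  contrast <- match.arg(contrast)
  subjects <- as.character(subjects)
  n <- length(subjects)
  groups <- NULL
  if (is.character(regressor) || is.factor(regressor)) {
    lev <- sort(unique(as.character(regressor)))
    if (length(lev) != 2L)
      stop("a non-numeric regressor must have exactly two levels")
    groups <- lev
    regressor <- as.numeric(as.character(regressor) == lev[2])
  }
  regressor <- as.numeric(regressor)
  if (length(regressor) != n) stop("regressor length must match subjects")
  if (anyNA(regressor)) stop("regressor contains missing values")
  if (stats::var(regressor) == 0) stop("regressor is constant")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    storage.mode(nuisance) <- "double"
    if (nrow(nuisance) != n) stop("nuisance rows must match subjects")
    if (anyNA(nuisance)) stop("nuisance contains missing values")
    if (qr(cbind(1, nuisance))$rank < ncol(nuisance) + 1L)
      stop("nuisance matrix (with intercept) is rank deficient")
  }
  structure(list(subjects = subjects, regressor = regressor,
                 nuisance = nuisance, contrast = contrast, groups = groups),
            class = "group_design")
}

is_two_level <- function(g) length(unique(g)) == 2L

## t statistics of the regressor slope per map column, after residualizing
## both sides against Z (intercept + nuisance); by Frisch-Waugh this equals
## the full-model partial t.  Zero-slope/zero-residual columns get t = 0.
partial_t <- function(M, gr, Qz) {
  gr <- as.vector(gr)
  n <- nrow(M)
  Mr <- M - Qz %*% crossprod(Qz, M)
  gg <- sum(gr^2)
  b <- as.vector(crossprod(gr, Mr)) / gg
  res <- Mr - outer(gr, b)
  df <- n - ncol(Qz) - 1L
  se <- sqrt(colSums(res^2) / df / gg)
  t <- b / se
  # columns with no variation beyond the nuisance fit (constant maps):
  # slope and residual are both numerical noise, define t = 0
  flat <- sqrt(colSums(Mr^2)) < 1e-10 * (sqrt(colSums(M^2)) + 1)
  t[flat] <- 0
  t
}

## Assemble the n x p matrix of Fisher-transformed map values from a list of
## conn_map objects, checking cross-subject consistency.
stack_maps <- function(maps) {
  if (is.matrix(maps)) return(list(M = maps, voxel_index = NULL, grid = NULL))
  stopifnot(length(maps) >= 2L, all(vapply(maps, inherits, TRUE, "conn_map")))
  m1 <- maps[[1]]
  for (m in maps[-1]) {
    if (m$method != m1$method || !identical(m$voxel_index, m1$voxel_index) ||
        !identical(m$lam, m1$lam))
      stop("all maps must share method, lambda and voxel set")
    if (!m$fisher) stop("maps must be Fisher-transformed before inference")
  }
  if (!m1$fisher) stop("maps must be Fisher-transformed before inference")
  M <- do.call(rbind, lapply(maps, `[[`, "values"))
  list(M = M, voxel_index = m1$voxel_index, grid = m1$grid)
}

#' Voxel-wise statistic map for a group design
#'
#' Per voxel, the t statistic of the regressor's slope after residualizing
#' map values and regressor against the nuisance covariates (plus
#' intercept).  For a two-group indicator with no nuisance this is exactly
#' the pooled two-sample t statistic.  Voxels missing in any subject are
#' excluded (returned as `NA`).
#'
#' @param maps list of Fisher-transformed [conn_map()]s (same method,
#'   lambda and voxel set), or an n x p numeric matrix.
#' @param design a [group_design()].
#' @return list with `stat` (t per voxel, `NA` for excluded voxels), `df`,
#'   `voxel_index`, `grid`.
#' @export
voxel_stat_map <- function(maps, design) {
  stopifnot(inherits(design, "group_design"))
  st <- stack_maps(maps)
  M <- st$M
  n <- nrow(M)
  if (length(design$regressor) != n)
    stop("design size does not match number of maps")
  g <- design$regressor
  if (is_two_level(g) && min(table(g)) < 3L)
    stop("each group must contain at least 3 subjects")
  Z <- cbind(rep(1, n), design$nuisance)
  if (n - ncol(Z) - 1L < 1L) stop("not enough subjects for the design")
  Qz <- qr.Q(qr(Z))
  gr <- g - Qz %*% crossprod(Qz, g)
  complete <- colSums(is.na(M)) == 0L
  stat <- rep(NA_real_, ncol(M))
  stat[complete] <- partial_t(M[, complete, drop = FALSE], gr, Qz)
  list(stat = stat, df = n - ncol(Z) - 1L,
       voxel_index = st$voxel_index, grid = st$grid)
}

#' Pooled two-sample t statistic from printed summary statistics
#'
#' The classic equal-variance two-sample t, with group 2 minus group 1 in
#' the numerator (so a cohort table comparing patients, group 1, against
#' controls, group 2, reports negative t when controls score lower).
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (sd > 0, n >= 2).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square statistic for a 2 x 2 table
#'
#' Without continuity correction, as conventionally reported for
#' gender-balance checks in matched-sample tables.
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts with positive
#'   row and column margins.
#' @return list with `chi2`, `df` (1) and `p`.
#' @export
chi2_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

## all n! permutations of 1..n, one per row (used for full enumeration)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    m <- sub
    m[m >= k] <- m[m >= k] + 1L
    out[[k]] <- cbind(k, m, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Permutation-based FWE inference with TFCE
#'
#' Compares the observed TFCE-enhanced statistic map against the null
#' distribution of the maximum TFCE score over voxels under permutations.
#' With nuisance covariates the Freedman-Lane scheme is used: rows of the
#' residuals from the nuisance-only model are permuted and the nuisance fit
#' added back before recomputing the statistic.  Corrected p-values follow
#' the (b+1)/(m+1) convention, so they are never smaller than
#' `1/(n_perm+1)`.  When the number of distinct permutations does not
#' exceed `n_perm` the null is enumerated exactly instead of sampled (and
#' the result then no longer depends on `seed`).  Two-sided inference runs
#' two one-sided TFCE enhancements (positive and negative) and applies a
#' Bonferroni factor of 2.
#'
#' @param maps list of Fisher-transformed [conn_map()]s or an n x p matrix
#'   (a matrix requires `voxel_index` and `shape`).
#' @param design a [group_design()].
#' @param params a [tfce_params()].
#' @param n_perm number of permutations (>= 100 recommended for reported
#'   analyses; enumeration kicks in below this when possible).
#' @param seed integer seed for permutation sampling (mandatory).
#' @param voxel_index,shape voxel coordinates and grid shape, required only
#'   when `maps` is a bare matrix.
#' @return An object of class `permutation_result`: `stat`, `tfce_pos`,
#'   `tfce_neg`, `null_max_pos`, `null_max_neg`, `fwe_p`, `n_perm` (number
#'   of non-identity permutations used), `enumerated`, `seed`, `df`,
#'   `contrast`, `voxel_index`, `grid`.
#' @export
permutation_fwe <- function(maps, design, params = tfce_params(),
                            n_perm = 1000, seed,
                            voxel_index = NULL, shape = NULL) {
  stopifnot(inherits(design, "group_design"), inherits(params, "tfce_params"))
  if (missing(seed)) stop("seed is mandatory")
  st <- stack_maps(maps)
  M <- st$M
  if (is.null(voxel_index)) voxel_index <- st$voxel_index
  if (is.null(shape)) {
    if (is.null(st$grid)) stop("grid shape required for TFCE adjacency")
    shape <- st$grid$shape
  }
  n <- nrow(M)
  g <- design$regressor
  if (length(g) != n) stop("design size does not match number of maps")
  if (is_two_level(g) && min(table(g)) < 3L)
    stop("each group must contain at least 3 subjects")
  Z <- cbind(rep(1, n), design$nuisance)
  Qz <- qr.Q(qr(Z))
  gr <- g - Qz %*% crossprod(Qz, g)
  complete <- colSums(is.na(M)) == 0L
  Mc <- M[, complete, drop = FALSE]
  vc <- voxel_index[complete, , drop = FALSE]
  fit_z <- Qz %*% crossprod(Qz, Mc)
  res_z <- Mc - fit_z

  need_pos <- design$contrast %in% c("two-sided", "positive")
  need_neg <- design$contrast %in% c("two-sided", "negative")
  enh <- function(t) list(
    pos = if (need_pos) tfce(t, vc, shape, params) else NULL,
    neg = if (need_neg) tfce(-t, vc, shape, params) else NULL)

  t_obs <- partial_t(Mc, gr, Qz)
  e_obs <- enh(t_obs)

  binary_simple <- is_two_level(g) && is.null(design$nuisance)
  n_distinct <- if (binary_simple) choose(n, sum(g == g[1])) else
    factorial(n)
  enumerated <- is.finite(n_distinct) && n_distinct <= n_perm
  if (enumerated && n_distinct < 20)
    warning("fewer than 20 distinct permutations: p-value resolution is poor")

  stat_perm <- function(perm) partial_t(fit_z + res_z[perm, , drop = FALSE],
                                        gr, Qz)
  if (enumerated) {
    if (binary_simple) {
      # enumerate group assignments: equivalent to permuting rows, since the
      # reduced model is the intercept only
      idx1 <- which(g == g[1])
      combs <- utils::combn(n, length(idx1))
      keep <- apply(combs, 2, function(cc) !identical(sort(cc), sort(idx1)))
      combs <- combs[, keep, drop = FALSE]
      stats_null <- lapply(seq_len(ncol(combs)), function(k) {
        gp <- rep(unique(g)[unique(g) != g[1]][1], n)
        gp[combs[, k]] <- g[1]
        partial_t(Mc, gp - mean(gp), Qz)
      })
    } else {
      P <- all_perms(n)
      keep <- rowSums(P != matrix(seq_len(n), nrow(P), n, byrow = TRUE)) > 0
      P <- P[keep, , drop = FALSE]
      stats_null <- lapply(seq_len(nrow(P)), function(k) stat_perm(P[k, ]))
    }
  } else {
    set.seed(seed)
    stats_null <- lapply(seq_len(n_perm), function(k) stat_perm(sample(n)))
  }
  m <- length(stats_null)
  null_max_pos <- if (need_pos) numeric(m) else NULL
  null_max_neg <- if (need_neg) numeric(m) else NULL
  for (k in seq_len(m)) {
    e <- enh(stats_null[[k]])
    if (need_pos) null_max_pos[k] <- max(e$pos, 0)
    if (need_neg) null_max_neg[k] <- max(e$neg, 0)
  }
  pval <- function(obs, null_max)
    (1 + vapply(obs, function(o) sum(null_max >= o), 0)) / (m + 1)
  p_pos <- if (need_pos) pval(e_obs$pos, null_max_pos) else NULL
  p_neg <- if (need_neg) pval(e_obs$neg, null_max_neg) else NULL
  p_c <- switch(design$contrast,
                "positive" = p_pos,
                "negative" = p_neg,
                "two-sided" = pmin(1, 2 * pmin(p_pos, p_neg)))
  expand <- function(x) {
    if (is.null(x)) return(NULL)
    out <- rep(NA_real_, ncol(M)); out[complete] <- x; out
  }
  structure(list(stat = expand(t_obs),
                 tfce_pos = expand(e_obs$pos), tfce_neg = expand(e_obs$neg),
                 null_max_pos = null_max_pos, null_max_neg = null_max_neg,
                 fwe_p = expand(p_c), n_perm = m, enumerated = enumerated,
                 seed = seed, df = n - ncol(Z) - 1L,
                 contrast = design$contrast,
                 voxel_index = voxel_index, grid = st$grid),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  ns <- sum(x$fwe_p < 0.05, na.rm = TRUE)
  cat(sprintf(
    "permutation_result: %s contrast, %d %s permutations, %d/%d voxels FWE p < 0.05\n",
    x$contrast, x$n_perm, if (x$enumerated) "enumerated" else "sampled",
    ns, sum(!is.na(x$fwe_p))))
  invisible(x)
}
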