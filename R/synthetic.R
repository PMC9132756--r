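#' Generative description of a synthetic resting-state cohort
#'
#' Each in-mask voxel's series is a weighted sum of band-limited latent
#' signals shared within voxel communities, plus stationary AR(1) noise.
#' Group effects multiply the coupling weight of selected (voxel set,
#' latent) memberships for patients, so setting every factor to 1 makes the
#' two groups' generative laws identical (an exactly exchangeable null).
#' Defaults mirror a typical resting-state acquisition: 256 volumes at
#' TR = 2 s with latent power confined to 0.02-0.1 Hz, on a coarse 4 mm-like
#' grid.
#'
#' @param grid a [volume_grid()].
#' @param mask binary 3D array on `grid` (1 = in mask).
#' @param communities list of memberships, each a list with `voxels`
#'   (k x 3 matrix of 0-based coordinates, subset of the mask), `latent`
#'   (id string), `weight` (scalar or per-voxel vector, >= 0) and optional
#'   `group` (`"both"`, the default, `"control"` or `"patient"`) restricting
#'   the membership to one group; group-restricted memberships express
#'   coupling reallocations that a multiplicative factor on a shared base
#'   weight cannot.
#' @param latents list of latent definitions, each a list with `id` and
#'   optional `band` (length-2 Hz, default `c(0.02, 0.1)`).  Latents are
#'   drawn per subject as unit-variance band-limited Gaussian processes.
#' @param noise list with AR(1) coefficient `rho` (0 <= rho < 1) and
#'   innovation sd `sd` (> 0).
#' @param group_effect list of effects, each a list with `voxels`, `latent`
#'   and multiplicative factor `g` (>= 0) applied to patients' coupling.
#' @param n_time number of time points (default 256).
#' @param tr repetition time in seconds (default 2).
#' @param n_per_group subjects per group.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(grid, mask, communities, latents,
                        noise = list(rho = 0.3, sd = 1),
                        group_effect = list(),
                        n_time = 256, tr = 2, n_per_group = 20, seed = 1) {
  stopifnot(inherits(grid, "volume_grid"))
  mask <- (mask != 0) * 1
  if (!all(dim(mask) == grid$shape)) stop("mask does not match grid")
  if (sum(mask) < 2) stop("mask must contain at least 2 voxels")
  if (!(noise$rho >= 0 && noise$rho < 1)) stop("need 0 <= rho < 1")
  if (!(noise$sd > 0)) stop("noise sd must be > 0")
  lat_ids <- vapply(latents, `[[`, "", "id")
  if (anyDuplicated(lat_ids)) stop("latent ids must be unique")
  mask_lin <- which(as.vector(mask) == 1)
  check_vox <- function(v) {
    v <- as.matrix(v); storage.mode(v) <- "integer"
    if (ncol(v) != 3L) stop("voxel sets must be k x 3 coordinate matrices")
    if (!all(linear_index(v, grid$shape) %in% mask_lin))
      stop("community/effect voxels must lie inside the mask")
    v
  }
  communities <- lapply(communities, function(cm) {
    cm$voxels <- check_vox(cm$voxels)
    if (!cm$latent %in% lat_ids) stop("unknown latent id: ", cm$latent)
    if (any(cm$weight < 0)) stop("coupling weights must be >= 0")
    if (is.null(cm$group)) cm$group <- "both"
    if (!cm$group %in% c("both", "control", "patient"))
      stop("community group must be both/control/patient")
    cm
  })
  group_effect <- lapply(group_effect, function(ge) {
    ge$voxels <- check_vox(ge$voxels)
    if (!ge$latent %in% lat_ids) stop("unknown latent id: ", ge$latent)
    if (any(ge$g < 0)) stop("effect factors must be >= 0")
    ge
  })
  if (n_time < 3) stop("n_time must be >= 3")
  structure(list(grid = grid, mask = mask, communities = communities,
                 latents = latents, noise = noise,
                 group_effect = group_effect, n_time = as.integer(n_time),
                 tr = as.numeric(tr), n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Unit-variance band-limited Gaussian process: equal power on every Fourier
## bin inside the band, independent uniform phases.  With integer-bin
## frequencies the cosines are orthogonal over the sampling grid, so the
## population (and near-exactly the sample) variance is 1.
band_limited_latent <- function(n, tr, band) {
  kk <- seq_len(floor(n / 2))
  f <- kk / (n * tr)
  use <- which(f >= band[1] & f <= band[2])
  if (!length(use)) stop("no Fourier bin falls inside the latent band")
  phases <- stats::runif(length(use), 0, 2 * pi)
  tt <- (0:(n - 1)) * tr
  amp <- sqrt(2 / length(use))
  colSums(amp * cos(outer(2 * pi * f[use], tt) + phases))
}

## Stationary AR(1) noise matrix (n x p): x_t = rho x_{t-1} + e_t,
## x_1 ~ N(0, sd^2/(1-rho^2)).
ar1_noise <- function(n, p, rho, sd) {
  x <- matrix(0, n, p)
  x[1, ] <- stats::rnorm(p, sd = sd / sqrt(1 - rho^2))
  if (n > 1) {
    e <- matrix(stats::rnorm((n - 1) * p, sd = sd), n - 1, p)
    for (t in 2:n) x[t, ] <- rho * x[t - 1, ] + e[t - 1, ]
  }
  x
}

## Coupling-weight matrix (p_mask x n_latents) for one group
weight_matrix <- function(spec, group) {
  mask_lin <- which(as.vector(spec$mask) == 1)
  lat_ids <- vapply(spec$latents, `[[`, "", "id")
  W <- matrix(0, length(mask_lin), length(lat_ids),
              dimnames = list(NULL, lat_ids))
  for (cm in spec$communities) {
    if (!cm$group %in% c("both", group)) next
    rows <- match(linear_index(cm$voxels, spec$grid$shape), mask_lin)
    W[rows, cm$latent] <- W[rows, cm$latent] + cm$weight
  }
  if (group == "patient") {
    for (ge in spec$group_effect) {
      rows <- match(linear_index(ge$voxels, spec$grid$shape), mask_lin)
      W[rows, ge$latent] <- W[rows, ge$latent] * ge$g
    }
  }
  W
}

#' Simulate one subject's in-mask time series
#'
#' Lower-level counterpart of [simulate_subject()] that skips the 4D volume
#' and returns the N x p matrix directly (columns in mask raster order).
#'
#' @param spec a [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @param subject_seed integer seed; output is bit-reproducible given it.
#' @return A [masked_series()] (not standardized).
#' @export
simulate_subject_series <- function(spec, group = c("control", "patient"),
                                    subject_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  set.seed(subject_seed)
  n <- spec$n_time
  L <- vapply(spec$latents,
              function(l) band_limited_latent(
                n, spec$tr, if (is.null(l$band)) c(0.02, 0.1) else l$band),
              numeric(n))
  W <- weight_matrix(spec, group)
  sig <- L %*% t(W)
  noise <- ar1_noise(n, ncol(sig), spec$noise$rho, spec$noise$sd)
  coords <- arrayInd(which(as.vector(spec$mask) == 1), spec$grid$shape) - 1L
  masked_series(sig + noise, coords, tr = spec$tr, grid = spec$grid)
}

#' Simulate one subject's 4D volume
#'
#' @inheritParams simulate_subject_series
#' @return 4D array (grid shape x n_time); out-of-mask voxels are 0.
#' @export
simulate_subject <- function(spec, group = c("control", "patient"),
                             subject_seed) {
  ser <- simulate_subject_series(spec, group, subject_seed)
  arr <- array(0, c(spec$grid$shape, spec$n_time))
  idx <- linear_index(ser$voxel_index, spec$grid$shape)
  nvox <- prod(spec$grid$shape)
  for (t in seq_len(spec$n_time))
    arr[(t - 1) * nvox + idx] <- ser$data[t, ]
  arr
}

## Per-subject seeds: a documented counter scheme drawn once from the master
## seed, so the cohort is reproducible and subjects are independent.
subject_seeds <- function(spec) {
  set.seed(spec$seed)
  sample.int(.Machine$integer.max - 1L, 2L * spec$n_per_group)
}

#' Simulate and write a full cohort
#'
#' Writes one 4D NIfTI per subject, the binary mask, and a subject table
#' (`participants.csv`) with synthetic demographic/clinical covariates:
#' age ~ round(N(40, 12)) clipped to 18-65, gender ~ Bernoulli(0.58) coded
#' M/F, a severity score ~ N(14, 6) clipped at 0 for patients (NA for
#' controls), medication type and chlorpromazine-equivalent dose ~
#' N(500, 100) for patients.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return data.frame subject table (also written as CSV), with a
#'   `bold_path` column, invisibly returned attributes-free.
#' @export
simulate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- subject_seeds(spec)
  npg <- spec$n_per_group
  groups <- rep(c("control", "patient"), each = npg)
  ids <- sprintf("sub-%03d", seq_len(2L * npg))
  set.seed(spec$seed + 1L)  # covariate stream, separate from imaging streams
  age <- pmin(pmax(round(stats::rnorm(2 * npg, 40, 12)), 18), 65)
  gender <- ifelse(stats::rbinom(2 * npg, 1, 0.58) == 1, "M", "F")
  score <- ifelse(groups == "patient",
                  pmax(stats::rnorm(2 * npg, 14, 6), 0), NA)
  med_type <- ifelse(groups == "patient",
                     sample(c("atypical", "typical", "both"), 2 * npg,
                            replace = TRUE, prob = c(0.75, 0.08, 0.17)), NA)
  dose <- ifelse(groups == "patient",
                 pmax(stats::rnorm(2 * npg, 500, 100), 0), NA)
  mask_path <- file.path(out_dir, "mask.nii.gz")
  RNifti::writeNifti(nifti_from_array(spec$mask, spec$grid), mask_path,
                     datatype = "uint8")
  paths <- character(2L * npg)
  for (k in seq_len(2L * npg)) {
    arr <- simulate_subject(spec, groups[k], seeds[k])
    paths[k] <- file.path(out_dir, paste0(ids[k], "_bold.nii.gz"))
    RNifti::writeNifti(nifti_from_array(arr, spec$grid, tr = spec$tr),
                       paths[k], datatype = "double")
  }
  tab <- data.frame(subject_id = ids, group = groups, age = age,
                    gender = gender, score = round(score, 2),
                    med_type = med_type, dose = round(dose, 1),
                    seed = seeds, bold_path = basename(paths),
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, file.path(out_dir, "participants.csv"),
                   row.names = FALSE)
  invisible(tab)
}

#' Exchangeable null cohort for type-I-error calibration
#'
#' A cohort with latent-network structure but no group difference: the two
#' groups' generative laws are identical (a multiplicative group effect of
#' exactly 1 is included, so the null covers the group-effect code path).
#' Group labels are therefore exactly exchangeable, which is the premise of
#' the permutation test whose family-wise error rate this cohort is used to
#' calibrate.
#'
#' @param n_per_group subjects per group (default 10).
#' @param n_time time points (default 128).
#' @param seed master seed.
#' @return A [cohort_spec()] over a 210-voxel mask with four 20-voxel
#'   communities and AR(1) noise.
#' @export
null_cohort_spec <- function(n_per_group = 10, n_time = 128, seed = 1) {
  shape <- c(7L, 6L, 5L)
  grid <- volume_grid(shape, c(4, 4, 4))
  mask <- array(1, shape)                      # 210 voxels
  all_vox <- as.matrix(expand.grid(x = 0:6, y = 0:5, z = 0:4))
  lat <- lapply(1:4, function(j) list(id = sprintf("bg%d", j)))
  comm <- lapply(1:4, function(j)
    list(voxels = all_vox[((j - 1) * 20 + 1):(j * 20), , drop = FALSE],
         latent = sprintf("bg%d", j), weight = 0.7))
  eff <- list(list(voxels = all_vox[1:20, , drop = FALSE], latent = "bg1",
                   g = 1))
  cohort_spec(grid, mask, comm, lat, noise = list(rho = 0.3, sd = 1),
              group_effect = eff, n_time = n_time, tr = 2,
              n_per_group = n_per_group, seed = seed)
}

## Expected |sample correlation| at sample size n when the population
## correlation is c (Fisher-z normal approximation, numeric integration).
expected_abs_cor <- function(c, n) {
  mu <- atanh(c); s <- 1 / sqrt(n - 3)
  stats::integrate(function(z) abs(tanh(z)) * stats::dnorm(z, mu, s),
                   mu - 8 * s, mu + 8 * s)$value
}

#' Shipped "multivariate-only" group-effect scenario
#'
#' A cohort in which the planted group difference is (to first order)
#' invisible to a bivariate-average summary (GBC) but strongly alters
#' multivariate predictability (RBC) -- the regime in which a truly
#' multivariate connectivity measure should outperform an average of
#' bivariate correlations.
#'
#' A contiguous block of 12 voxels is affected.  For controls it splits
#' into two interleaved 6-voxel cliques, each sharing its own latent signal
#' with coupling `w1 = 1.4`, giving every block voxel 5 strong in-clique
#' correlations (`c1 = w1^2/(w1^2 + s2)`, about 0.64 with the default AR(1)
#' noise) and 6 null ones.  For patients the coupling is reallocated: all
#' 12 voxels share a single latent with a weaker coupling `w2`, chosen by
#' solving `11 E|r(c2)| = 5 E|r(c1)| + 6 E|r(0)|` at the cohort's number of
#' time points, so that each block voxel's expected mean absolute sample
#' correlation -- exactly what GBC averages -- is unchanged.  A per-voxel
#' private latent tops patients' marginal variance up to the control value.
#' Concentrated strong correlations support a much higher multiple R than
#' the same average spread thinly (R squared is convex in the individual
#' correlations), so the block carries a genuine RBC reduction in patients
#' while GBC is flat.  The mask is kept small enough (40 voxels) that the
#' conventional fixed penalty `lambda = 50`, which shrinks relative to the
#' noise-bulk Gram eigenvalues (of order p), sits in its informative range.
#'
#' @param n_per_group subjects per group (default 20).
#' @param n_time time points (default 256; enters the mean-|r| matching).
#' @param seed master seed.
#' @return A [cohort_spec()]; the affected block's coordinates are attached
#'   as attribute `"effect_voxels"`.
#' @export
multivariate_effect_spec <- function(n_per_group = 20, n_time = 256,
                                     seed = 1) {
  shape <- c(5L, 4L, 2L)
  grid <- volume_grid(shape, c(4, 4, 4))
  mask <- array(1, shape)                      # 40 voxels, all in mask
  rho <- 0.3; sd_n <- 1
  s2 <- sd_n^2 / (1 - rho^2)                   # stationary AR(1) variance
  w1 <- 1.4
  c1 <- w1^2 / (w1^2 + s2)
  target <- 5 * expected_abs_cor(c1, n_time) + 6 * expected_abs_cor(0, n_time)
  c2 <- stats::uniroot(function(c) 11 * expected_abs_cor(c, n_time) - target,
                       c(0.05, c1))$root
  # every block voxel has total variance w1^2 + s2 in both groups, so the
  # in-block correlation under the merged latent is w2^2 / (w1^2 + s2) = c2
  w2 <- sqrt(c2 * (w1^2 + s2))
  w_priv <- sqrt(w1^2 - w2^2)                  # variance top-up for patients
  all_vox <- as.matrix(expand.grid(x = 0:4, y = 0:3, z = 0:1))
  block <- as.matrix(expand.grid(x = 0:2, y = 0:1, z = 0:1))
  in_block <- paste(all_vox[, 1], all_vox[, 2], all_vox[, 3]) %in%
    paste(block[, 1], block[, 2], block[, 3])
  bg <- all_vox[!in_block, , drop = FALSE]
  clique_a <- block[seq(1, 12, by = 2), , drop = FALSE]  # interleaved
  clique_b <- block[seq(2, 12, by = 2), , drop = FALSE]
  lat <- list(list(id = "cliqueA"), list(id = "cliqueB"), list(id = "merged"),
              list(id = "bg1"))
  comm <- list(
    list(voxels = clique_a, latent = "cliqueA", weight = w1,
         group = "control"),
    list(voxels = clique_b, latent = "cliqueB", weight = w1,
         group = "control"),
    list(voxels = block, latent = "merged", weight = w2, group = "patient"),
    list(voxels = bg[1:14, , drop = FALSE], latent = "bg1", weight = 0.7))
  for (v in seq_len(nrow(block))) {
    pid <- sprintf("priv%d", v)
    lat <- c(lat, list(list(id = pid)))
    comm <- c(comm, list(list(voxels = block[v, , drop = FALSE],
                              latent = pid, weight = w_priv,
                              group = "patient")))
  }
  spec <- cohort_spec(grid, mask, comm, lat,
                      noise = list(rho = rho, sd = sd_n),
                      group_effect = list(), n_time = n_time, tr = 2,
                      n_per_group = n_per_group, seed = seed)
  attr(spec, "effect_voxels") <- block
  spec
}
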