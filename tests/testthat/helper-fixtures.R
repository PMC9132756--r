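# Programmatic fixtures shared across the test files.

# random standardized series on a degenerate 1D grid (p voxels along x)
rand_series <- function(N, p, seed, standardized = TRUE) {
  set.seed(seed)
  Y <- matrix(rnorm(N * p), N, p)
  ser <- masked_series(Y, cbind(0:(p - 1), 0L, 0L), tr = 2,
                       grid = volume_grid(c(p, 1, 1)))
  if (standardized) standardize(ser) else ser
}

# random standardized series filling a full 3D grid
grid_series <- function(N, shape, seed) {
  set.seed(seed)
  p <- prod(shape)
  Y <- matrix(rnorm(N * p), N, p)
  vi <- as.matrix(expand.grid(0:(shape[1] - 1), 0:(shape[2] - 1),
                              0:(shape[3] - 1)))
  standardize(masked_series(Y, vi, tr = 2, grid = volume_grid(shape)))
}

# write a 4D array (+ binary mask) as NIfTI files, return the two paths
write_bold_fixture <- function(arr, mask, dir = NULL,
                               tr = 2, voxel_size = c(4, 4, 4)) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  grid <- rbconn::volume_grid(dim(arr)[1:3], voxel_size)
  bold_path <- file.path(dir, "bold.nii.gz")
  mask_path <- file.path(dir, "mask.nii.gz")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size, tr)
  RNifti::writeNifti(img, bold_path, datatype = "double")
  mimg <- RNifti::asNifti(mask)
  RNifti::pixdim(mimg) <- voxel_size
  RNifti::writeNifti(mimg, mask_path,
                     datatype = if (all(mask %in% c(0, 1))) "uint8"
                     else "double")
  list(bold = bold_path, mask = mask_path, grid = grid)
}

# map values looked up by voxel coordinate (robust to raster re-sorting)
map_at <- function(map, coords) {
  coords <- as.matrix(coords)
  key <- function(m) m[, 1] * 1e6 + m[, 2] * 1e3 + m[, 3]
  map$values[match(key(coords), key(map$voxel_index))]
}

# simulate a full cohort in memory: list of standardized masked_series
cohort_series <- function(spec, seed_offset = 0) {
  npg <- spec$n_per_group
  groups <- rep(c("control", "patient"), each = npg)
  set.seed(spec$seed + seed_offset)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * npg)
  list(groups = groups,
       series = lapply(seq_len(2L * npg), function(k)
         standardize(simulate_subject_series(spec, groups[k], seeds[k]))))
}
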