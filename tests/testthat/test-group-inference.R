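test_that("pooled t from summary statistics reproduces matched-cohort rows", {
  # age row of a matched patient/control table: 41.12 (11.83) vs 38.09 (13.65)
  r <- t_from_summary(41.12, 11.83, 74, 38.09, 13.65, 74)
  expect_equal(round(r$t, 2), -1.44)
  expect_equal(round(r$p, 2), 0.15)
  expect_equal(r$df, 146)
  # premorbid IQ row: the formula on the printed rounded summaries
  r2 <- t_from_summary(23.14, 4.34, 74, 23.12, 4.49, 74)
  expect_equal(round(r2$t, 3), -0.028)
  expect_equal(t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(t_from_summary(1, 0, 10, 2, 1, 10), "positive")
  expect_error(t_from_summary(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("Pearson chi-square on 2x2 tables is exact and uncorrected", {
  r <- chi2_2x2(matrix(c(43, 43, 31, 31), 2))   # identical gender splits
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  # hand calculation: perfect separation of 20 subjects
  r2 <- chi2_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r2$chi2, 20)
  # proportional rows are independent
  r3 <- chi2_2x2(matrix(c(20, 10, 40, 20), 2))
  expect_equal(r3$chi2, 0, tolerance = 1e-12)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi2_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("voxel-wise t reduces to pooled two-sample t without nuisance", {
  set.seed(31)
  n <- 14; p <- 25
  M <- matrix(rnorm(n * p), n, p)
  groups <- rep(c("a", "b"), each = 7)
  des <- group_design(paste0("s", 1:n), groups)
  r <- voxel_stat_map(M, des)
  oracle <- sapply(seq_len(p), function(j)
    t.test(M[8:14, j], M[1:7, j], var.equal = TRUE)$statistic)
  expect_equal(r$stat, unname(oracle), tolerance = 1e-10)
  expect_equal(r$df, n - 2)
  # identical per-subject values: t = 0 everywhere by convention
  M0 <- matrix(rep(rnorm(p), each = n), n, p)
  expect_equal(voxel_stat_map(M0, des)$stat, rep(0, p))
  expect_error(voxel_stat_map(M, group_design(paste0("s", 1:n),
                                              rep(c("a", "b"), c(2, 12)))),
               "at least 3")
})

test_that("voxel-wise t with nuisance equals the full linear model", {
  set.seed(32)
  n <- 20; p <- 15
  M <- matrix(rnorm(n * p), n, p)
  g <- rnorm(n)                                # continuous severity score
  Z <- cbind(age = rnorm(n), gender = rbinom(n, 1, 0.5))
  des <- group_design(paste0("s", 1:n), g, nuisance = Z)
  r <- voxel_stat_map(M, des)
  oracle <- sapply(seq_len(p), function(j)
    summary(lm(M[, j] ~ g + Z))$coefficients["g", "t value"])
  expect_equal(r$stat, unname(oracle), tolerance = 1e-10)
  expect_equal(r$df, n - 4)
  expect_error(group_design(paste0("s", 1:n), g,
                            nuisance = cbind(Z, Z[, 1])), "rank")
  expect_error(group_design(paste0("s", 1:n), rep(1, n)), "constant")
})

test_that("TFCE matches direct threshold summation on simple maps", {
  shape <- c(6, 6, 6)
  vi <- as.matrix(expand.grid(0:2, 0:2, 0:1))  # 18-voxel connected mask
  # all-zero map
  expect_equal(tfce(rep(0, 18), vi, shape), rep(0, 18))
  # constant map: every voxel gets sum_h k^E h^H dh over the whole mask
  prm <- tfce_params(E = 0.5, H = 2, dh = 0.05)
  v <- tfce(rep(1.7, 18), vi, shape, prm)
  hs <- seq(0.05, 1.7, by = 0.05)
  expect_equal(v, rep(sum(18^0.5 * hs^2 * 0.05), 18), tolerance = 1e-10)
  # single isolated voxel: Riemann sum converging to h0^3/3
  vi2 <- rbind(c(0, 0, 0), c(5, 5, 5))
  h0 <- 2.3
  dh <- h0 / 2000
  v2 <- tfce(c(h0, 0), vi2, shape, tfce_params(E = 0.5, H = 2, dh = dh))
  expect_equal(v2[1], sum((seq_len(2000) * dh)^2 * dh), tolerance = 1e-10)
  expect_equal(v2[1], h0^3 / 3, tolerance = 1e-2)
  expect_equal(v2[2], 0)
  expect_error(tfce(c(NA, 1), vi2, shape), "finite")
})

test_that("TFCE respects the neighbourhood connectivity choice", {
  shape <- c(4, 4, 4)
  vi <- rbind(c(0, 0, 0), c(1, 1, 0), c(3, 3, 3))  # diagonal pair + isolate
  prm6 <- tfce_params(dh = 0.1, connectivity = 6)
  prm26 <- tfce_params(dh = 0.1, connectivity = 26)
  v6 <- tfce(c(1, 1, 1), vi, shape, prm6)
  v26 <- tfce(c(1, 1, 1), vi, shape, prm26)
  hs <- seq(0.1, 1, by = 0.1)
  expect_equal(v6, rep(sum(1^0.5 * hs^2 * 0.1), 3), tolerance = 1e-8)
  expect_equal(v26[1], sum(2^0.5 * hs^2 * 0.1), tolerance = 1e-8)
  expect_equal(v26[3], sum(1^0.5 * hs^2 * 0.1), tolerance = 1e-8)
})

test_that("TFCE is monotone in the statistic map", {
  shape <- c(5, 4, 3)
  vi <- as.matrix(expand.grid(0:4, 0:3, 0:2))
  prm <- tfce_params(dh = 0.05)
  set.seed(33)
  for (rep in 1:20) {
    a <- runif(60, 0, 2)
    b <- a + runif(60, 0, 0.5)                 # pointwise >= a
    va <- tfce(a, vi, shape, prm)
    vb <- tfce(b, vi, shape, prm)
    expect_true(all(vb >= va - 1e-12))
  }
})

test_that("permutation FWE p-values behave on degenerate and null input", {
  shape <- c(4, 3, 2)
  vi <- as.matrix(expand.grid(0:3, 0:2, 0:1))
  n <- 12
  des <- group_design(paste0("s", 1:n), rep(c("a", "b"), each = 6))
  # identical maps for all subjects: stat 0, all p = 1
  M0 <- matrix(rep(runif(24), each = n), n, 24)
  r0 <- permutation_fwe(M0, des, n_perm = 99, seed = 5,
                        voxel_index = vi, shape = shape)
  expect_equal(r0$stat, rep(0, 24))
  expect_true(all(r0$fwe_p == 1))
  # random maps: p-values bounded below by 1/(n_perm+1), above by 1
  set.seed(34)
  M <- matrix(rnorm(n * 24), n, 24)
  r <- permutation_fwe(M, des, n_perm = 199, seed = 6,
                       voxel_index = vi, shape = shape)
  expect_true(all(r$fwe_p >= 1 / (r$n_perm + 1)))
  expect_true(all(r$fwe_p <= 1))
})

test_that("enumerated permutations are seed- and order-invariant", {
  shape <- c(4, 3, 1)
  vi <- as.matrix(expand.grid(0:3, 0:2, 0))
  n <- 8
  set.seed(35)
  M <- matrix(rnorm(n * 12), n, 12)
  groups <- rep(c("a", "b"), each = 4)
  des <- group_design(paste0("s", 1:n), groups)
  # choose(8,4) = 70 distinct assignments <= n_perm -> full enumeration
  r1 <- permutation_fwe(M, des, n_perm = 500, seed = 1,
                        voxel_index = vi, shape = shape)
  r2 <- permutation_fwe(M, des, n_perm = 500, seed = 999,
                        voxel_index = vi, shape = shape)
  expect_true(r1$enumerated)
  expect_equal(r1$n_perm, 69)                  # 70 assignments minus identity
  expect_identical(r1$fwe_p, r2$fwe_p)
  # permuting subjects together with their design rows changes nothing
  ord <- sample(n)
  des_o <- group_design(paste0("s", 1:n)[ord], groups[ord])
  r3 <- permutation_fwe(M[ord, ], des_o, n_perm = 500, seed = 42,
                        voxel_index = vi, shape = shape)
  expect_equal(r3$fwe_p, r1$fwe_p, tolerance = 1e-12)
  # continuous regressor with 3 subjects: only 3! = 6 distinct permutations
  des3 <- group_design(paste0("s", 1:3), c(0.1, 0.9, 0.4))
  expect_warning(
    permutation_fwe(M[1:3, ], des3, n_perm = 500, seed = 1,
                    voxel_index = vi, shape = shape),
    "fewer than 20")
})

test_that("Freedman-Lane permutation handles nuisance covariates", {
  shape <- c(5, 5, 2)
  vi <- as.matrix(expand.grid(0:4, 0:4, 0:1))
  set.seed(36)
  n <- 16
  age <- rnorm(n)
  g <- rnorm(n)
  # maps depend on age (nuisance) only: inference on g must stay null
  M <- outer(age, runif(50)) + matrix(rnorm(n * 50, sd = 0.5), n, 50)
  des <- group_design(paste0("s", 1:n), g, nuisance = cbind(age = age))
  r <- permutation_fwe(M, des, n_perm = 199, seed = 7,
                       voxel_index = vi, shape = shape)
  expect_true(all(r$fwe_p >= 1 / (r$n_perm + 1)))
  oracle <- sapply(seq_len(50), function(j)
    summary(lm(M[, j] ~ g + age))$coefficients["g", "t value"])
  expect_equal(r$stat, unname(oracle), tolerance = 1e-10)
  # a voxel missing for one subject is excluded from inference
  M[3, 7] <- NA
  r2 <- permutation_fwe(M, des, n_perm = 99, seed = 8,
                        voxel_index = vi, shape = shape)
  expect_true(is.na(r2$fwe_p[7]))
  expect_equal(sum(is.na(r2$fwe_p)), 1)
})
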