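# first-level, group-level and permutation machinery on desk-scale grids

make_design <- function(n_scans = 80, tr = 1.75, seed = 1) {
  ev <- data.frame(onset = seq(10, n_scans * tr - 30, by = 14),
                   rt = NA, risk = NA, reward_z = NA)
  ev$rt <- rep_len(c(1, 1.8, 1.3), nrow(ev))
  ev$risk <- rep_len(c(0.1, 0.5, 0.9), nrow(ev))
  ev$reward_z <- rep_len(c(-1, 0, 1), nrow(ev))
  ev$d_hat <- rep_len(c(0.10, 0.25, 0.17), nrow(ev))
  ft <- (seq_len(n_scans) - 1) * tr
  build_design_matrix(
    list(deliberation = build_epochs(ev, "variable", "none"),
         conflict = build_epochs(ev, "variable", "conflict")),
    ft, cutoff_hz = 0.01)
}

test_that("noise-free BOLD is recovered exactly by the first-level GLM", {
  X <- make_design()
  dims <- c(4, 4, 4)
  B <- matrix(0, ncol(X), prod(dims), dimnames = list(colnames(X), NULL))
  B["deliberation", 1:10] <- 2
  B["conflict", 30:40] <- 1.2
  bold <- simulate_bold(X, B, dims, noise_sd = 0, seed = 1)
  fl <- first_level(bold, X)
  task_rows <- c("deliberation", "conflict")
  expect_equal(max(abs(fl$beta[task_rows, ] - B[task_rows, ])), 0,
               tolerance = 1e-8)
  expect_equal(unname(fl$residual_variance), rep(0, prod(dims)),
               tolerance = 1e-16)
  expect_equal(fl$dof, nrow(X) - qr(X)$rank)
  # determinism: identical input, identical estimates
  expect_identical(first_level(bold, X)$beta, fl$beta)
})

test_that("null t-statistics follow the Student-t reference distribution", {
  X <- make_design(n_scans = 60)
  V <- 1000
  set.seed(3)
  Y <- matrix(rnorm(nrow(X) * V), nrow(X), V)
  fl <- first_level(Y, X)
  XtXinv <- solve(crossprod(X))
  j <- which(colnames(X) == "conflict")
  tstat <- fl$beta[j, ] / sqrt(fl$residual_variance * XtXinv[j, j])
  ks <- ks.test(tstat, function(q) pt(q, fl$dof))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank-deficient designs fail with the offending columns named", {
  X <- make_design()
  Xbad <- cbind(X, dup = X[, "conflict"])
  Y <- matrix(rnorm(nrow(X) * 4), nrow(X), 4)
  expect_error(first_level(Y, Xbad), "dup|conflict")
})

test_that("PSC conversion is homogeneous and recovers injected amplitudes", {
  X <- make_design()
  expect_equal(psc_convert(0, X[, "deliberation"], 100), 0)
  expect_equal(psc_convert(2, X[, "deliberation"], 200),
               psc_convert(2, X[, "deliberation"], 100) / 2)
  # inject a signal whose PSC is exactly 0.2% of baseline at the peak
  dims <- c(3, 3, 3)
  baseline <- 100
  peak <- max(abs(X[, "deliberation"]))
  beta_true <- 0.2 * baseline / (100 * peak)
  B <- matrix(0, ncol(X), prod(dims), dimnames = list(colnames(X), NULL))
  B["deliberation", ] <- beta_true
  reps <- vapply(1:20, function(s) {
    bold <- simulate_bold(X, B, dims, baseline = baseline, noise_sd = 0.3,
                          ar_coefficient = 0, seed = s)
    fl <- first_level(bold, X)
    mean(psc_convert(fl, "deliberation"))
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.2), 3 * se + 1e-6)
})

test_that("unit-weight WLS F equals the squared one-sample t", {
  set.seed(4)
  maps <- matrix(rnorm(20 * 5, mean = 0.3), 20, 5)
  res <- second_level_wls(maps)
  for (v in 1:5) {
    tt <- t.test(maps[, v])
    expect_equal(res$F[v], unname(tt$statistic)^2, tolerance = 1e-10)
  }
  expect_equal(res$dof, 19)
  # identical constant maps: guarded, finite, huge
  const <- matrix(1, 10, 3)
  expect_true(all(is.finite(second_level_wls(const)$F)))
  expect_error(second_level_wls(maps, weights = c(-1, rep(1, 19))),
               "positive")
  expect_error(second_level_wls(maps[1:2, ]), "three")
})

test_that("scanner covariate is regressed out of the group model", {
  set.seed(5)
  n <- 24
  scanner <- rep(c(0, 1), each = n / 2)
  maps <- matrix(rnorm(n * 50), n, 50) + outer(scanner, rep(2, 50))
  with_cov <- second_level_wls(maps, covariates = cbind(scanner = scanner))
  without <- second_level_wls(maps)
  # unmodelled, the offset leaks into the intercept; modelled, it does not
  expect_equal(mean(without$coef[1, ]), 1, tolerance = 0.2)
  expect_equal(mean(with_cov$coef[1, ]), 0, tolerance = 0.2)
  expect_equal(with_cov$dof, n - 2)
})

test_that("group WLS power matches the noncentral-F prediction", {
  # one-sample design, effect 0.1, between-subject sd 0.05, n = 28
  n <- 28; eff <- 0.1; sdv <- 0.05
  set.seed(6)
  crit <- qf(0.95, 1, n - 1)
  rej <- vapply(1:400, function(r) {
    y <- matrix(rnorm(n, eff, sdv), n, 1)
    second_level_wls(y)$F[1] > crit
  }, logical(1))
  ncp <- n * (eff / sdv)^2
  power <- 1 - pf(crit, 1, n - 1, ncp)
  se <- sqrt(power * (1 - power) / 400)
  expect_lt(abs(mean(rej) - power), 4 * se + 0.01)
})

test_that("TFCE matches the direct threshold-sum value for a lone voxel", {
  m <- array(0, c(5, 5, 5))
  m[3, 3, 3] <- 1.0
  out <- tfce(m)
  expect_equal(out[3, 3, 3], sum(1^0.5 * (0.1 * (1:10))^2 * 0.1))
  expect_true(all(out[-63] == 0))
  expect_true(all(tfce(array(0, c(5, 5, 5))) == 0))
})

test_that("TFCE is local: disjoint clusters enhance independently", {
  set.seed(7)
  a <- array(0, c(6, 6, 6))
  a[1:2, 1:2, 1:2] <- runif(8, 0.5, 1.5)
  b <- array(0, c(6, 6, 6))
  b[5:6, 5:6, 5:6] <- runif(8, 0.5, 1.5)
  expect_equal(tfce(a + b), tfce(a) + tfce(b), tolerance = 1e-12)
})

test_that("negative statistics are enhanced separately by sign", {
  m <- array(0, c(5, 5, 5))
  m[2, 2, 2] <- 1
  m[4, 4, 4] <- -1
  out <- tfce(m)
  expect_gt(out[2, 2, 2], 0)
  expect_lt(out[4, 4, 4], 0)
  expect_equal(out[4, 4, 4], -out[2, 2, 2])
})

test_that("FWE p-values follow the add-one counting rule", {
  dist <- c(1, 2, 3, 4)
  res <- fwe_correct(c(2.5, 0.5, 5), dist)
  expect_equal(res$p, c(3 / 5, 5 / 5, 1 / 5))
  expect_equal(fwe_correct(0.1, dist)$p, 1)
  expect_equal(fwe_correct(10, dist)$p, 1 / 5)
})

test_that("cluster filtering enforces the 20-voxel extent rule", {
  m <- array(0, c(10, 10, 10))
  m[1:10, 1, 1] <- 1; m[1:9, 2, 1] <- 1      # 19-voxel connected blob
  expect_true(all(cluster_filter(m, 20) == 0))
  m[10, 2, 1] <- 1                           # now exactly 20
  expect_equal(sum(cluster_filter(m, 20) == 1), 20)
  # 25-voxel and 5-voxel blobs: one surviving label
  m2 <- array(0, c(10, 10, 10))
  m2[1:5, 1:5, 1] <- 1
  m2[8:9, 8:9, 8] <- 1; m2[8, 8, 9] <- 1
  lab <- cluster_filter(m2, 20)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab == 1), 25)
  tab <- cluster_table(lab, m2 * 3, dim(m2))
  expect_equal(tab$extent, 25)
  expect_equal(tab$peak, 3)
})

test_that("Freedman-Lane permutation is reproducible and anchored to the observed fit", {
  set.seed(8)
  maps <- matrix(rnorm(12 * 27), 12, 27)
  p1 <- freedman_lane_permute(maps, n_perms = 120, seed = 3, dims = c(3, 3, 3))
  p2 <- freedman_lane_permute(maps, n_perms = 120, seed = 3, dims = c(3, 3, 3))
  expect_identical(p1$max_dist, p2$max_dist)
  expect_equal(p1$observed_F, second_level_wls(maps)$F)
  expect_equal(p1$observed_tfce,
               tfce(second_level_wls(maps)$F, dims = c(3, 3, 3)))
  # with covariates the same machinery runs
  cov <- cbind(scanner = rep(c(0, 1), 6))
  p3 <- freedman_lane_permute(maps, covariates = cov, n_perms = 120, seed = 3,
                              dims = c(3, 3, 3))
  expect_length(p3$max_dist, 120)
  expect_error(freedman_lane_permute(maps, n_perms = 10, dims = c(3, 3, 3)),
               "at least 100")
})
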