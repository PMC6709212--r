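make_events <- function(rts = c(1.0, 2.0, 1.5), spacing = 12) {
  data.frame(onset = seq(10, by = spacing, length.out = length(rts)),
             rt = rts, risk = rep_len(c(0.1, 0.5, 0.9), length(rts)),
             reward_z = seq(-1, 1, length.out = length(rts)),
             d_hat = seq(0.05, 0.25, length.out = length(rts)))
}

test_that("variable epochs use RTs as durations, fixed epochs the window", {
  ev <- make_events()
  expect_equal(build_epochs(ev, "variable", "none")$durations,
               c(1.0, 2.0, 1.5))
  expect_equal(build_epochs(ev, "fixed", "none", fixed_window = 3.5)$durations,
               rep(3.5, 3))
})

test_that("modulators scale amplitudes and zero out missing responses", {
  ev <- make_events()
  ev$rt[2] <- NA
  ep <- build_epochs(ev, "variable", "conflict", center = FALSE)
  expect_equal(ep$amplitudes, c(ev$d_hat[1], 0, ev$d_hat[3]))
  expect_equal(ep$durations[2], 3.5)  # no RT: full response window
  ctr <- build_epochs(ev, "variable", "conflict", center = TRUE)
  m <- mean(ev$d_hat[c(1, 3)])
  expect_equal(ctr$amplitudes, c(ev$d_hat[1] - m, 0, ev$d_hat[3] - m))
  # control regressor keeps amplitude 1 on missing trials
  expect_equal(build_epochs(ev, "variable", "none")$amplitudes, rep(1, 3))
  expect_equal(build_epochs(ev, "fixed", "risk", center = FALSE)$amplitudes,
               c(0.1, 0, 0.9))
  expect_equal(build_epochs(ev, "fixed", "reward", center = FALSE)$amplitudes,
               c(-1, 0, 1))
})

test_that("the canonical HRF has the expected shape", {
  h <- hrf(0.1)
  t <- (seq_along(h) - 1) * 0.1
  expect_equal(h[1], 0)
  expect_equal(max(h), 1, tolerance = 1e-4)  # unit peak (up to grid)
  expect_equal(t[which.max(h)], 5, tolerance = 0.3)
  expect_lt(min(h), 0)                 # undershoot
  expect_gt(t[which.min(h)], t[which.max(h)])
})

test_that("regressor convolution is linear, scales, and conserves the boxcar", {
  ft <- seq(0, 200, by = 1.75)
  ev <- make_events(rts = c(1, 1), spacing = 60)
  e1 <- build_epochs(ev[1, ], "variable", "none")
  e2 <- build_epochs(ev[2, ], "variable", "none")
  both <- build_epochs(ev, "variable", "none")
  expect_equal(convolve_regressor(both, ft),
               convolve_regressor(e1, ft) + convolve_regressor(e2, ft))
  scaled <- e1
  scaled$amplitudes <- 2
  expect_equal(convolve_regressor(scaled, ft), 2 * convolve_regressor(e1, ft))
  empty <- structure(list(onsets = numeric(0), durations = numeric(0),
                          amplitudes = numeric(0)), class = "arc_epochs")
  expect_true(all(convolve_regressor(empty, ft) == 0))
  # boxcar area before convolution equals the summed RTs
  ev3 <- make_events()
  e3 <- build_epochs(ev3, "variable", "none")
  expect_equal(sum(e3$durations * e3$amplitudes), sum(ev3$rt))
})

test_that("near-linear summation: doubling a short epoch roughly doubles the peak", {
  ft <- seq(0, 120, by = 0.25)  # fine sampling to measure true peaks
  one <- structure(list(onsets = 20, durations = 1, amplitudes = 1),
                   class = "arc_epochs")
  two <- structure(list(onsets = 20, durations = 2, amplitudes = 1),
                   class = "arc_epochs")
  ratio <- max(convolve_regressor(two, ft)) / max(convolve_regressor(one, ft))
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.05)
})

test_that("fixed and variable modes agree when every RT equals the window", {
  ev <- make_events(rts = rep(3.5, 3))
  ft <- seq(0, 80, by = 1.75)
  expect_equal(
    convolve_regressor(build_epochs(ev, "variable", "none"), ft),
    convolve_regressor(build_epochs(ev, "fixed", "none", 3.5), ft))
})

test_that("DCT drift basis has the prescribed size and filters slow drift", {
  B <- dct_drift_basis(1000, 1.75, 0.01)
  expect_equal(ncol(B), 35)  # floor(2 * 1750 * 0.01)
  expect_equal(crossprod(B), diag(35), tolerance = 1e-10,
               ignore_attr = TRUE)
  t <- (0:999) * 1.75
  slow <- sin(2 * pi * 0.005 * t)
  resid <- slow - B %*% crossprod(B, slow)
  expect_lt(sum(resid^2) / sum(slow^2), 0.01)
  expect_warning(dct_drift_basis(10, 1, 0.01), "too short")
})

test_that("motion regressors are demeaned, detrended and orthogonalized", {
  set.seed(6)
  m <- matrix(rnorm(600), 100, 6)
  out <- motion_nuisance(m)
  expect_equal(colMeans(out), rep(0, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  G <- crossprod(out)
  expect_equal(G - diag(diag(G)), matrix(0, 6, 6), tolerance = 1e-8,
               ignore_attr = TRUE)
  m2 <- m
  m2[, 3] <- 5                      # constant
  m2[, 5] <- seq_len(100) * 0.01    # pure ramp
  expect_warning(out2 <- motion_nuisance(m2), "zeroed")
  expect_true(all(out2[, 3] == 0))
  expect_true(all(abs(out2[, 5]) < 1e-10))
})

test_that("framewise displacement follows the translation + radius formula", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))
  m[5, 1] <- 1.0  # 1 mm x jump at frame 5
  fd <- framewise_displacement(m)
  expect_equal(fd[5], 1.0)
  expect_equal(fd[6], 1.0)  # moves back
  keep <- scrub_mask(fd, 0.9, 4)
  expect_false(any(keep[1:4]))
  expect_false(keep[5])
  expect_true(keep[7])
  m2 <- matrix(0, 10, 6)
  m2[5, 4] <- 0.01  # 0.01 rad rotation, radius 50 -> 0.5 mm
  fd2 <- framewise_displacement(m2)
  expect_equal(fd2[5], 0.5)
  expect_true(scrub_mask(fd2, 0.9, 0)[5])
})

test_that("design matrix assembly combines task, drift, motion and spikes", {
  ev <- make_events()
  ft <- seq(0, 120, by = 1.75)
  n <- length(ft)
  set.seed(7)
  motion <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  fd <- framewise_displacement(motion)
  keep <- scrub_mask(fd, 0.9, 4)
  X <- build_design_matrix(
    list(deliberation = build_epochs(ev, "variable", "none"),
         conflict = build_epochs(ev, "variable", "conflict")),
    ft, motion = motion, cutoff_hz = 0.01, keep_mask = keep)
  expect_true(all(c("deliberation", "conflict") %in% colnames(X)))
  expect_equal(sum(grepl("spike", colnames(X))), sum(!keep))
  expect_equal(sum(grepl("drift", colnames(X))),
               floor(2 * n * 1.75 * 0.01))
  expect_equal(sum(grepl("motion", colnames(X))), 6)
  expect_false(anyDuplicated(colnames(X)) > 0)
})
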