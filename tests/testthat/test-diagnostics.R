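test_that("Rhat is near 1 for well-mixed chains and large for separated ones", {
  set.seed(1)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(rhat(good) - 1), 0.01)
  bad <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(bad), 1.1)
  expect_identical(rhat(matrix(1, 100, 3)), 1)
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "two chains")
})

test_that("Rhat agrees with the coda implementation on random chains", {
  set.seed(2)
  ch <- matrix(rnorm(2000, sd = 2), 500, 4) +
    rep(c(0, 0.1, -0.1, 0.2), each = 500)
  ours <- rhat(ch)
  coda_val <- coda::gelman.diag(coda::mcmc.list(apply(ch, 2, coda::mcmc,
                                                      simplify = FALSE)),
                                autoburnin = FALSE)$psrf[1, 1]
  coda_val <- unname(coda_val)
  # coda uses a df correction; agreement to ~1% is expected at n = 500
  expect_equal(ours, coda_val, tolerance = 0.01)
})

test_that("HDI matches closed forms for normal and uniform samples", {
  set.seed(3)
  h <- hdi(rnorm(2e5), 0.95)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.03)
  hu <- hdi(runif(2e5), 0.95)
  expect_equal(unname(diff(hu)), 0.95, tolerance = 0.01)
  expect_equal(unname(hdi(rep(2.5, 200), 0.9)), c(2.5, 2.5))
  # narrowest-window property on a tiny hand case: sorted 1..10, mass .5
  # ceiling(.5*10)=5 consecutive values; all widths 4; first window wins
  expect_equal(unname(hdi(1:10, 0.5)), c(1, 5))
})

test_that("WAIC matches the brute-force definition and its limits", {
  set.seed(4)
  ll <- matrix(rnorm(5 * 3, mean = -1), 5, 3)
  expect_equal(waic(ll)$waic, waic_oracle(ll))
  # two-draw, three-observation case by hand
  ll2 <- rbind(c(-1, -2, -0.5), c(-1.5, -1, -0.7))
  expect_equal(waic(ll2)$waic, waic_oracle(ll2))
  # identical draws: zero penalty, deviance of the pointwise density
  ll3 <- rbind(c(-1, -2), c(-1, -2))
  expect_equal(waic(ll3)$p_waic, 0)
  expect_equal(waic(ll3)$waic, -2 * (-3))
  # duplicating observations doubles the score
  expect_equal(waic(cbind(ll, ll))$waic, 2 * waic(ll)$waic)
  expect_error(waic(ll[1, , drop = FALSE]), "two")
})

test_that("posterior modes behave like modes", {
  set.seed(5)
  sym <- rnorm(4000, 3, 0.5)
  m <- matrix(sym, dimnames = list(NULL, "beta0[1]"))
  expect_equal(unname(modal_estimates(m)), mean(sym), tolerance = 0.05)
  skew <- rgamma(4000, shape = 2, rate = 1)  # mode 1, mean 2
  ms <- matrix(skew, dimnames = list(NULL, "k[1]"))
  expect_lt(unname(modal_estimates(ms)), mean(skew))
  expect_equal(unname(modal_estimates(ms)), 1, tolerance = 0.25)
  delta <- matrix(rep(1.7, 500), dimnames = list(NULL, "alpha0[1]"))
  expect_equal(unname(modal_estimates(delta)), 1.7)
  expect_error(modal_estimates(matrix(1:5, dimnames = list(NULL, "x[1]"))),
               "few")
})

test_that("conflict extraction applies modal coefficients to trial features", {
  design <- generate_design(27, seed = 2)
  est <- c("beta0[1]" = 0, "beta1[1]" = 0, "beta2[1]" = 0, "beta3[1]" = 0,
           "beta0[2]" = 10, "beta1[2]" = 0, "beta2[2]" = 0, "beta3[2]" = 0,
           "beta0[3]" = 0, "beta1[3]" = -1.922, "beta2[3]" = -4.180,
           "beta3[3]" = 10.652)
  cs <- extract_conflict(est, design)
  expect_true(all(cs$d_hat[cs$participant == 1] == 0.25))
  expect_true(all(cs$d_hat[cs$participant == 2] < 1e-4))
  # closed-form chain for a 50%-risk trial at reward_z = 0
  theta <- plogis(-1.922)
  row <- data.frame(trial = 1, risk = 0.5, reward = 0.5, reward_z = 0)
  cs3 <- extract_conflict(est, row)
  expect_equal(cs3$theta_hat[cs3$participant == 3], theta)
  expect_equal(cs3$d_hat[cs3$participant == 3], 0.25 - (0.5 - theta)^2)
  # invariant d = 0.25 - (0.5 - theta)^2 holds row-wise
  expect_equal(cs$d_hat, 0.25 - (0.5 - cs$theta_hat)^2)
  expect_true(all(cs$d_hat >= 0 & cs$d_hat <= 0.25))
})

test_that("posterior predictive RMSE matches a hand-built example", {
  # two participants, flat model: predicted rates plogis(b0), observed rates
  # off by +0.1 and -0.1 -> RMSE 0.1
  n <- 50
  obs1 <- rep(c(1L, 0L), c(30, 20))   # observed 0.6
  obs2 <- rep(c(1L, 0L), c(20, 30))   # observed 0.4
  data <- data.frame(participant = rep(1:2, each = n), risk = 0.1,
                     reward_z = 0, choice = c(obs1, obs2), rt = 1)
  pars <- as.vector(outer(paste0("beta", 0:3), sprintf("[%d]", 1:2),
                          paste0))
  draws <- array(0, dim = c(10, 8, 1), dimnames = list(NULL, pars, NULL))
  fake <- structure(list(draws = draws, participants = 1:2, p = 4L,
                         hierarchical = TRUE, data = data),
                    class = "arc_fit")
  # all-zero coefficients predict 0.5 for everyone
  expect_equal(as.numeric(posterior_predictive_rmse(fake)), 0.1)
  # perfect prediction gives zero
  data0 <- data
  data0$choice <- rep(c(1L, 0L), 2 * n / 2)
  fake0 <- structure(list(draws = draws, participants = 1:2, p = 4L,
                          hierarchical = TRUE, data = data0),
                     class = "arc_fit")
  expect_equal(as.numeric(posterior_predictive_rmse(fake0)), 0)
})
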