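# Sampler-level checks use reduced chains; statistical assertions are kept
# loose enough to be stable under the fixed seeds.

small_spec <- function(...) {
  model_spec(n_chains = 2L, n_steps = 500L, n_burnin = 250L, thin = 1L, ...)
}

test_that("refitting with the same seed reproduces the draws exactly", {
  st <- make_small_study(4, seed = 21)
  f1 <- suppressWarnings(fit_behavior(st$behavior, small_spec(), seed = 5))
  f2 <- suppressWarnings(fit_behavior(st$behavior, small_spec(), seed = 5))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_behavior(st$behavior, small_spec(), seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("group means are recovered within three posterior SDs", {
  st <- make_small_study(12, seed = 31)
  fit <- fit_behavior(st$behavior,
                      model_spec(n_steps = 800L, n_burnin = 400L, thin = 2L),
                      seed = 2)
  truth <- c(beta0_G = 2.0, beta1_G = -1.922, beta2_G = -4.180,
             beta3_G = 10.652, alpha0_G = 1.0, alpha1_G = 1.824)
  for (par in names(truth)) {
    v <- as.vector(fit$draws[, par, ])
    expect_lt(abs(mean(v) - truth[[par]]) / sd(v), 3.5)
  }
  expect_lt(max(fit$rhat, na.rm = TRUE), 1.2)
  expect_equal(dim(fit$draws)[1], (800 - 400) / 2)
})

test_that("participants with excessive missingness are dropped with a notice", {
  st <- make_small_study(4, seed = 8)
  b <- st$behavior
  idx <- which(b$participant == 2)[1:27]  # 25% missing
  b$choice[idx] <- NA
  b$rt[idx] <- NA
  expect_message(fit <- suppressWarnings(fit_behavior(b, small_spec(), seed = 1)),
                 "excluding participant")
  expect_false(2 %in% fit$participants)
  expect_identical(fit$excluded, 2L)
})

test_that("non-hierarchical and interaction variants fit and are comparable", {
  st <- make_small_study(6, seed = 13)
  hb <- suppressWarnings(fit_behavior(st$behavior, small_spec(), seed = 3))
  fl <- suppressWarnings(
    fit_behavior(st$behavior, small_spec(variant = "non_hierarchical"),
                 seed = 3))
  ia <- suppressWarnings(
    fit_behavior(st$behavior, small_spec(variant = "interactions"),
                 seed = 3))
  expect_equal(ncol(fl$draws), 7)  # 4 betas + 2 alphas + shared k
  expect_true(all(grepl("beta4|beta5",
                        dimnames(ia$draws)[[2]]) |
                  !grepl("beta[45]", dimnames(ia$draws)[[2]])))
  expect_true("beta4_G" %in% dimnames(ia$draws)[[2]])
  # heterogeneous participants: partial pooling should fit better
  expect_lt(hb$waic$waic, fl$waic$waic)
})

test_that("hierarchical shrinkage pulls participant estimates toward the group mean", {
  st <- make_small_study(10, seed = 17)
  fit <- suppressWarnings(fit_behavior(st$behavior, small_spec(), seed = 4))
  post_means <- vapply(seq_len(10), function(j)
    mean(fit$draws[, sprintf("beta3[%d]", j), ]), numeric(1))
  # per-participant maximum likelihood (no pooling)
  mle <- vapply(seq_len(10), function(j) {
    rows <- fit$data[fit$data$participant == j, ]
    X <- arcconflict:::choice_design_matrix(rows$risk, rows$reward_z)
    co <- suppressWarnings(
      glm.fit(X, rows$choice, family = binomial())$coefficients)
    co[4]
  }, numeric(1))
  ok <- is.finite(mle) & abs(mle) < 50
  gmean <- mean(fit$draws[, "beta3_G", ])
  expect_lt(mean(abs(post_means[ok] - gmean)), mean(abs(mle[ok] - gmean)))
})

test_that("the sampler posterior agrees with an independent MCMC engine", {
  skip_if_not_installed("rjags")
  # shared-parameter (non-hierarchical) model on a pooled dataset: both
  # samplers target the same 7-parameter posterior
  g <- group_parameters(beta_sd = rep(1e-8, 4), alpha_sd = c(1e-8, 1e-8),
                        k_sdlog = 0)
  design <- generate_design(108, seed = 1)
  behav <- simulate_participants(g, 8, design, seed = 19)
  fit <- fit_behavior(behav,
                      model_spec(variant = "non_hierarchical",
                                 n_chains = 2L, n_steps = 1500L,
                                 n_burnin = 500L, thin = 2L),
                      seed = 7)
  obs <- behav[!is.na(behav$choice), ]
  X <- arcconflict:::choice_design_matrix(obs$risk, obs$reward_z)
  model <- "
  model {
    for (n in 1:N) {
      logit(theta[n]) <- inprod(X[n, ], b[])
      y[n] ~ dbern(theta[n])
      d[n] <- 0.25 - pow(0.5 - theta[n], 2)
      mu[n] <- a0 + a1 * d[n]
      z[n] ~ dgamma(k, k / mu[n])
    }
    for (c in 1:4) { b[c] ~ dt(0, 1 / pow(10, 2), 5) }
    a0 ~ dnorm(1, 1)
    a1 ~ dnorm(0, 1 / 4)
    k ~ dgamma(2, 0.1)
  }"
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(y = obs$choice, z = obs$rt, X = X, N = nrow(obs)),
    n.chains = 2, n.adapt = 300, quiet = TRUE,
    inits = lapply(1:2, function(ch)
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = ch)))
  update(jm, 300, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("b", "a0", "a1", "k"), n.iter = 1000,
                            progress.bar = "none")
  jmean <- summary(js)$statistics[, "Mean"]
  ours <- colMeans(apply(fit$draws, 2, as.vector))
  map <- c(a0 = "alpha0_G", a1 = "alpha1_G", `b[1]` = "beta0_G",
           `b[2]` = "beta1_G", `b[3]` = "beta2_G", `b[4]` = "beta3_G",
           k = "k")
  for (nm in names(map)) {
    post_sd <- sd(as.vector(fit$draws[, map[[nm]], ]))
    expect_lt(abs(jmean[[nm]] - ours[[map[[nm]]]]), 4 * post_sd + 0.02)
  }
})

test_that("fit summaries expose HDIs, Rhat and ESS for group parameters", {
  st <- make_small_study(4, seed = 23)
  fit <- suppressWarnings(fit_behavior(st$behavior, small_spec(), seed = 9))
  gs <- group_summary(fit)
  expect_true(all(c("beta3_G", "alpha1_G", "sd_beta3") %in% gs$parameter))
  expect_true(all(gs$hdi_lower <= gs$mean & gs$mean <= gs$hdi_upper))
  expect_true(all(is.finite(gs$rhat)))
  out <- capture.output(print(fit))
  expect_true(any(grepl("WAIC", out)))
})
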