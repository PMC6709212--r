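#' Specify the joint choice-RT model and its sampler settings
#'
#' Three model variants are supported: the hierarchical model (participant
#' parameters partially pooled toward group means), a non-hierarchical
#' equivalent estimating only one shared parameter set, and a hierarchical
#' variant adding risk-by-reward interaction terms to the choice regression.
#'
#' Priors are weakly informative: Student-t (df `eta`, default 5, the
#' recommended robust-logistic choice) with scale 10 on the choice group
#' means, wide enough that reward sensitivities of order 10 on the
#' standardized scale are not penalized; half-normal(0, 5) on the choice
#' group SDs; normal(1, 1) on the baseline-RT group mean and normal(0, 2) on
#' the conflict-slope group mean; half-normal(0, 0.5) on the RT group SDs;
#' gamma(2, 0.1) on the participant gamma shapes. All overridable through
#' `prior`.
#'
#' @param variant `"hierarchical"`, `"non_hierarchical"` or `"interactions"`.
#' @param eta Student-t degrees of freedom for the choice-coefficient priors.
#' @param n_chains,n_steps,n_burnin,thin sampler schedule. The default
#'   4 chains of 2000 steps (1000 burn-in, thinning 4) retains 1000 draws.
#' @param prior named list overriding prior hyperparameters (`t_scale`,
#'   `a0_mean`, `a0_sd`, `a1_mean`, `a1_sd`, `hn_beta`, `hn_a0`, `hn_a1`,
#'   `k_shape`, `k_rate`).
#' @param conflict_scale `"raw"` or `"unit"`; see [rt_mean()].
#' @param l_max maximal leapfrog trajectory length.
#' @param target_accept dual-averaging acceptance target.
#' @param max_divergence_rate divergent-transition rate above which [fit_behavior()]
#'   raises a diagnostic error.
#' @return a list of class `arc_model_spec`.
#' @export
model_spec <- function(variant = c("hierarchical", "non_hierarchical",
                                   "interactions"),
                       eta = 5,
                       n_chains = 4L, n_steps = 2000L, n_burnin = 1000L,
                       thin = 4L,
                       prior = list(),
                       conflict_scale = c("raw", "unit"),
                       l_max = 24L, target_accept = 0.85,
                       max_divergence_rate = 0.1) {
  variant <- match.arg(variant)
  conflict_scale <- match.arg(conflict_scale)
  stopifnot(eta > 0, n_steps > n_burnin, thin >= 1, n_chains >= 1)
  p0 <- list(t_df = eta, t_scale = 10,
             a0_mean = 1, a0_sd = 1, a1_mean = 0, a1_sd = 2,
             hn_beta = 5, hn_a0 = 0.5, hn_a1 = 0.5,
             k_shape = 2, k_rate = 0.1)
  p0[names(prior)] <- prior
  structure(list(variant = variant, eta = eta, n_chains = as.integer(n_chains),
                 n_steps = as.integer(n_steps), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), prior = p0,
                 conflict_scale = conflict_scale, l_max = as.integer(l_max),
                 target_accept = target_accept,
                 max_divergence_rate = max_divergence_rate),
            class = "arc_model_spec")
}

#' Fit the joint hierarchical choice-RT model by Hamiltonian Monte Carlo
#'
#' Samples the posterior of the joint Bernoulli-choice / gamma-RT model with
#' the package's HMC sampler (non-centered hierarchy, dual-averaging step
#' size, diagonal mass matrix estimated during warmup). Participants missing
#' more than `max_missing` of their trials are excluded with a message, and
#' missing trials contribute nothing to the likelihood.
#'
#' @param dataset behavioral trial table (see [simulate_participants()]).
#' @param spec an [model_spec()] object.
#' @param seed integer seed; chains use seeds `seed`, `seed + 1`, ...
#' @param max_missing participant exclusion threshold (fraction missing).
#' @param exclude apply the missingness exclusion rule (default `TRUE`).
#' @return an object of class `arc_fit`: retained draws on the natural scale
#'   (`draws`: iterations x parameters x chains array), per-parameter
#'   `rhat` and `ess`, the pointwise joint log-likelihood matrix
#'   (`pointwise`, draws x observed trials), WAIC, sampler diagnostics, and
#'   bookkeeping (`participants`, `spec`, `data`).
#' @export
fit_behavior <- function(dataset, spec = model_spec(), seed = 1L,
                         max_missing = 0.2, exclude = TRUE) {
  stopifnot(inherits(spec, "arc_model_spec"), nrow(dataset) > 0)
  excl <- flag_exclusions(dataset, max_missing)
  if (exclude && length(excl)) {
    message("excluding participant(s) with > ", round(100 * max_missing),
            "% missing responses: ", paste(excl, collapse = ", "))
    dataset <- dataset[!dataset$participant %in% excl, , drop = FALSE]
  }
  obs <- dataset[!is.na(dataset$choice) & !is.na(dataset$rt), , drop = FALSE]
  if (any(obs$rt <= 0)) stop("response times must be positive")
  ids <- sort(unique(obs$participant))
  np <- length(ids)
  hierarchical <- spec$variant != "non_hierarchical"
  X <- choice_design_matrix(obs$risk, obs$reward_z,
                            interactions = spec$variant == "interactions")
  p <- ncol(X)
  pid <- match(obs$participant, ids) - 1L
  y <- as.integer(obs$choice)
  z <- as.numeric(obs$rt)
  d_denom <- conflict_denom(spec$conflict_scale)
  prior <- unlist(spec$prior)

  # pooled-data starting values, jittered per chain
  b0 <- tryCatch(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients,
    error = function(e) rep(0, p))
  b0[!is.finite(b0)] <- 0
  b0 <- pmin(pmax(b0, -8), 8)
  dim_total <- if (hierarchical) 2 * p + 4 + np * (p + 3) else p + 3
  base_init <- numeric(dim_total)
  if (hierarchical) {
    base_init[seq_len(p)] <- b0
    base_init[p + 1] <- max(mean(z) * 0.85, 0.1)   # alpha0_G
    base_init[p + 2] <- 0.1                        # alpha1_G
    base_init[(p + 3):(2 * p + 2)] <- log(0.5)     # log sd beta
    base_init[2 * p + 3] <- log(0.2)               # log sd alpha0
    base_init[2 * p + 4] <- log(0.2)               # log sd alpha1
    koff <- 2 * p + 4
    for (j in seq_len(np))
      base_init[koff + j * (p + 3)] <- log(4)      # log k_j
  } else {
    base_init <- c(b0, max(mean(z) * 0.85, 0.1), 0.1, log(4))
  }

  keep <- (spec$n_steps - spec$n_burnin) %/% spec$thin
  chains <- vector("list", spec$n_chains)
  diag <- list(step_size = numeric(spec$n_chains),
               accept_rate = numeric(spec$n_chains),
               n_divergent = integer(spec$n_chains))
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (ch in seq_len(spec$n_chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    init <- base_init + stats::rnorm(dim_total, 0, 0.05)
    res <- .cpp_hmc_chain(init, spec$n_burnin, spec$n_steps - spec$n_burnin,
                          spec$thin, spec$l_max, spec$target_accept,
                          X, y, z, pid, np, d_denom, hierarchical, prior)
    chains[[ch]] <- res$draws
    diag$step_size[ch] <- res$step_size
    diag$accept_rate[ch] <- res$accept_rate
    diag$n_divergent[ch] <- res$n_divergent
  }
  div_rate <- sum(diag$n_divergent) /
    (spec$n_chains * (spec$n_steps - spec$n_burnin))
  if (div_rate > spec$max_divergence_rate)
    stop(sprintf(paste0("divergent-transition rate %.1f%% exceeds the ",
                        "configured threshold; consider raising target_accept ",
                        "or reparameterizing"), 100 * div_rate))

  nat <- lapply(chains, .natural_scale, p = p, np = np,
                hierarchical = hierarchical)
  pars <- colnames(nat[[1]])
  draws <- array(unlist(nat), dim = c(keep, length(pars), spec$n_chains),
                 dimnames = list(NULL, pars, NULL))
  rh <- apply(draws, 2, function(m) rhat(m))
  if (any(rh > 1.1, na.rm = TRUE))
    warning("some parameters have Rhat > 1.1; chains may not have converged")
  ess <- tryCatch({
    ml <- coda::mcmc.list(lapply(seq_len(spec$n_chains), function(ch)
      coda::mcmc(draws[, , ch, drop = TRUE])))
    coda::effectiveSize(ml)
  }, error = function(e) stats::setNames(rep(NA_real_, length(pars)), pars))

  packed <- do.call(rbind, chains)
  pointwise <- .cpp_pointwise_loglik(packed, X, y, z, pid, np, d_denom,
                                     hierarchical)
  fit <- structure(list(
    draws = draws, packed = packed, rhat = rh, ess = ess,
    pointwise = pointwise, waic = waic(pointwise),
    diagnostics = c(diag, list(divergence_rate = div_rate)),
    participants = ids, excluded = if (exclude) excl else integer(0),
    spec = spec, p = p, hierarchical = hierarchical,
    data = obs, seed = as.integer(seed)), class = "arc_fit")
  fit
}

# expand packed sampler draws to named natural-scale parameters
.natural_scale <- function(m, p, np, hierarchical) {
  cn_beta <- paste0("beta", seq_len(p) - 1)
  if (!hierarchical) {
    out <- cbind(m[, seq_len(p), drop = FALSE], m[, p + 1], m[, p + 2],
                 exp(m[, p + 3]))
    colnames(out) <- c(paste0(cn_beta, "_G"), "alpha0_G", "alpha1_G", "k")
    return(out)
  }
  gb <- m[, seq_len(p), drop = FALSE]
  ga0 <- m[, p + 1]; ga1 <- m[, p + 2]
  sb <- exp(m[, (p + 3):(2 * p + 2), drop = FALSE])
  sa0 <- exp(m[, 2 * p + 3]); sa1 <- exp(m[, 2 * p + 4])
  cols <- list()
  cols[paste0(cn_beta, "_G")] <- as.data.frame(gb)
  cols[["alpha0_G"]] <- ga0; cols[["alpha1_G"]] <- ga1
  cols[paste0("sd_", cn_beta)] <- as.data.frame(sb)
  cols[["sd_alpha0"]] <- sa0; cols[["sd_alpha1"]] <- sa1
  poff <- 2 * p + 4
  for (j in seq_len(np)) {
    blk <- m[, poff + (j - 1) * (p + 3) + seq_len(p + 3), drop = FALSE]
    for (c in seq_len(p))
      cols[[sprintf("%s[%d]", cn_beta[c], j)]] <- gb[, c] + sb[, c] * blk[, c]
    cols[[sprintf("alpha0[%d]", j)]] <- ga0 + sa0 * blk[, p + 1]
    cols[[sprintf("alpha1[%d]", j)]] <- ga1 + sa1 * blk[, p + 2]
    cols[[sprintf("k[%d]", j)]] <- exp(blk[, p + 3])
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  out
}

#' @export
print.arc_fit <- function(x, ...) {
  cat("Joint choice-RT model fit (", x$spec$variant, ")\n", sep = "")
  cat(sprintf("  %d participants, %d observed trials, %d draws x %d chains\n",
              length(x$participants), nrow(x$data),
              dim(x$draws)[1], dim(x$draws)[3]))
  cat(sprintf("  WAIC (deviance scale): %.1f\n", x$waic$waic))
  cat(sprintf("  max Rhat: %.3f; divergence rate: %.2f%%\n",
              max(x$rhat, na.rm = TRUE), 100 * x$diagnostics$divergence_rate))
  gp <- grep("_G$", colnames(x$draws[, , 1, drop = FALSE]), value = TRUE)
  sm <- t(vapply(gp, function(par) {
    v <- as.vector(x$draws[, par, ])
    c(mean = mean(v), hdi(v, 0.95))
  }, numeric(3)))
  colnames(sm) <- c("mean", "hdi_lower", "hdi_upper")
  print(round(sm, 3))
  invisible(x)
}

#' Posterior summary of group-level parameters
#'
#' @param fit an `arc_fit` object.
#' @param mass HDI probability mass.
#' @return data frame with posterior mean, HDI bounds, Rhat and effective
#'   sample size for every group-level parameter.
#' @export
group_summary <- function(fit, mass = 0.95) {
  pars <- grep("_G$|^sd_|^k$", dimnames(fit$draws)[[2]], value = TRUE)
  out <- do.call(rbind, lapply(pars, function(par) {
    v <- as.vector(fit$draws[, par, ])
    h <- hdi(v, mass)
    data.frame(parameter = par, mean = mean(v),
               hdi_lower = h[1], hdi_upper = h[2],
               rhat = unname(fit$rhat[par]), ess = unname(fit$ess[par]))
  }))
  rownames(out) <- NULL
  out
}
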