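#' Potential scale reduction factor (Rhat)
#'
#' Gelman-Rubin convergence diagnostic: the ratio of the pooled-variance
#' estimate (within- plus between-chain) to the mean within-chain variance.
#' Values near 1 indicate that the chains agree; the usual rule of thumb
#' flags parameters with Rhat above 1.1.
#'
#' @param chains matrix with one column per chain (iterations in rows), or a
#'   list of equal-length numeric vectors.
#' @return scalar Rhat, at least 1 up to floating error. Constant chains
#'   (zero variance everywhere) return 1; chains with zero within-chain but
#'   nonzero between-chain variance return `Inf`.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2L) stop("Rhat needs at least two chains")
  if (n < 2L) stop("Rhat needs at least two draws per chain")
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest density interval
#'
#' The narrowest contiguous interval containing at least `mass` of the
#' sample: among all windows of `ceiling(mass * n)` consecutive sorted
#' draws, the shortest (ties broken by the lowest lower bound).
#'
#' @param samples numeric vector of posterior draws.
#' @param mass probability mass, strictly between 0 and 1.
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2L) stop("need at least two finite samples")
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(width)  # which.min returns the first (lowest lower bound)
  c(lower = x[i], upper = x[i + k - 1])
}

#' Widely applicable information criterion (deviance scale)
#'
#' `WAIC = -2 * (lppd - p_waic)` where `lppd` is the log pointwise predictive
#' density and `p_waic` the sum over observations of the posterior variance
#' of the log-likelihood. Lower is better. One observation here is one trial,
#' whose pointwise term combines its Bernoulli choice and gamma RT
#' log-densities (the joint model's natural observation unit).
#'
#' @param pointwise_loglik matrix of pointwise log-likelihoods, draws in
#'   rows, observations in columns.
#' @return list with `waic`, `lppd`, `p_waic` and `pointwise` contributions.
#' @export
waic <- function(pointwise_loglik) {
  m <- as.matrix(pointwise_loglik)
  if (nrow(m) < 2L) stop("WAIC needs at least two posterior draws")
  S <- nrow(m)
  # column-wise log-sum-exp
  cmax <- apply(m, 2, max)
  lppd_i <- cmax + log(colMeans(exp(sweep(m, 2, cmax))))
  p_i <- apply(m, 2, stats::var)
  list(waic = -2 * (sum(lppd_i) - sum(p_i)),
       lppd = sum(lppd_i), p_waic = sum(p_i),
       pointwise = -2 * (lppd_i - p_i))
}

#' Posterior modes of participant-level parameters
#'
#' Per-parameter univariate posterior mode, located by maximizing a Gaussian
#' kernel density estimate (Silverman bandwidth) over the pooled draws.
#' These modal estimates are what the conflict series is built from.
#'
#' @param fit an `arc_fit` object (or a draws matrix with named columns).
#' @param parameters optional character vector restricting which parameters
#'   to summarize; default: all participant-level parameters.
#' @param method `"mode"` (KDE argmax) or `"mean"` for sensitivity checks.
#' @return named numeric vector of point estimates.
#' @export
modal_estimates <- function(fit, parameters = NULL,
                            method = c("mode", "mean")) {
  method <- match.arg(method)
  m <- if (inherits(fit, "arc_fit")) {
    d <- fit$draws
    apply(d, 2, as.vector)
  } else as.matrix(fit)
  if (is.null(parameters))
    parameters <- grep("\\[", colnames(m), value = TRUE)
  if (!length(parameters)) parameters <- colnames(m)
  vapply(stats::setNames(parameters, parameters), function(par) {
    v <- m[, par]
    if (method == "mean") return(mean(v))
    kde_mode(v)
  }, numeric(1))
}

# argmax of a Gaussian KDE; exact-value fallback for (near-)constant draws
kde_mode <- function(v) {
  if (length(v) < 10L) stop("too few draws for density estimation")
  if (stats::sd(v) < 1e-12) return(v[1])
  dens <- stats::density(v, bw = "nrd0", n = 1024)
  dens$x[which.max(dens$y)]
}

#' Per-trial conflict estimates from fitted point estimates
#'
#' Applies the modal participant-level choice coefficients to the trial
#' features of the design: for each participant and trial, the fitted
#' likelihood-of-take and the conflict statistic d.
#'
#' @param point_estimates named vector from [modal_estimates()] (needs the
#'   `beta*[j]` entries), or an `arc_fit` (modes computed on the fly).
#' @param design trial design shared by the participants.
#' @param participants optional participant ids (default: inferred).
#' @return data frame of class `arc_conflict` with `participant`, `trial`,
#'   `theta_hat`, `d_hat`.
#' @export
extract_conflict <- function(point_estimates, design, participants = NULL) {
  if (inherits(point_estimates, "arc_fit")) {
    if (is.null(participants)) participants <- point_estimates$participants
    point_estimates <- modal_estimates(point_estimates)
  }
  bnames <- grep("^beta\\d+\\[", names(point_estimates), value = TRUE)
  if (!length(bnames)) stop("no participant-level choice coefficients found")
  jmax <- max(as.integer(sub(".*\\[(\\d+)\\]", "\\1", bnames)))
  p <- length(unique(sub("\\[.*", "", bnames)))
  if (is.null(participants)) participants <- seq_len(jmax)
  X <- choice_design_matrix(design$risk, design$reward_z,
                            interactions = p == 6L)
  out <- do.call(rbind, lapply(seq_len(jmax), function(j) {
    beta <- point_estimates[sprintf("beta%d[%d]", seq_len(p) - 1, j)]
    if (any(is.na(beta))) stop("missing coefficients for participant ", j)
    theta <- stats::plogis(drop(X %*% beta))
    data.frame(participant = participants[j], trial = design$trial,
               theta_hat = theta, d_hat = conflict(theta))
  }))
  rownames(out) <- NULL
  class(out) <- c("arc_conflict", "data.frame")
  out
}

#' Posterior predictive check on average risky choice
#'
#' For each participant, compares the posterior-mean predicted risky-choice
#' rate (theta averaged over draws and observed trials) with the observed
#' risky-choice rate, and returns the root-mean-square error across
#' participants.
#'
#' @param fit an `arc_fit`.
#' @param dataset the dataset the model was fitted to (defaults to the one
#'   stored in the fit).
#' @return scalar RMSE, with attribute `"per_participant"` (data frame of
#'   predicted and observed rates).
#' @export
posterior_predictive_rmse <- function(fit, dataset = fit$data) {
  obs <- dataset[!is.na(dataset$choice) & !is.na(dataset$rt), , drop = FALSE]
  ids <- fit$participants
  pooled <- apply(fit$draws, 2, as.vector)
  res <- do.call(rbind, lapply(seq_along(ids), function(j) {
    rows <- obs[obs$participant == ids[j], , drop = FALSE]
    X <- choice_design_matrix(rows$risk, rows$reward_z,
                              interactions = fit$p == 6L)
    beta <- sapply(seq_len(fit$p) - 1, function(c) {
      nm <- if (fit$hierarchical) sprintf("beta%d[%d]", c, j)
            else sprintf("beta%d_G", c)
      pooled[, nm]
    })
    theta <- stats::plogis(X %*% t(beta))   # trials x draws
    data.frame(participant = ids[j],
               predicted = mean(theta), observed = mean(rows$choice))
  }))
  rmse <- sqrt(mean((res$predicted - res$observed)^2))
  attr(rmse, "per_participant") <- res
  rmse
}
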