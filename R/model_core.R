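#' Likelihood of taking the risky option
#'
#' The choice side of the joint model: a logistic regression of the
#' probability of selecting the risky option ("likelihood-of-take", theta)
#' on risk level and standardized reward. Risk is indicator-coded with 10%
#' as the reference level, so `beta[1]` is the intercept (10% risk, mean
#' reward), `beta[2]` the 50%-risk shift, `beta[3]` the 90%-risk shift and
#' `beta[4]` the reward slope.
#'
#' @param beta numeric vector of 4 coefficients (or 6 with the risk-by-reward
#'   interaction variant, in the order beta0..beta5).
#' @param risk_level vector of risk levels, each one of 0.10, 0.50, 0.90.
#' @param reward_z standardized reward, recycled against `risk_level`.
#' @return vector of probabilities in (0, 1).
#' @export
likelihood_of_take <- function(beta, risk_level, reward_z) {
  if (!all(risk_level %in% c(0.10, 0.50, 0.90)))
    stop("risk_level must be one of 0.10, 0.50, 0.90")
  X <- choice_design_matrix(risk_level, reward_z,
                            interactions = length(beta) == 6L)
  if (ncol(X) != length(beta))
    stop("beta must have length 4 (main effects) or 6 (interactions)")
  stats::plogis(drop(X %*% beta))
}

# Indicator-coded choice design matrix shared by the simulator and fitter.
choice_design_matrix <- function(risk_level, reward_z, interactions = FALSE) {
  x1 <- as.numeric(risk_level == 0.50)
  x2 <- as.numeric(risk_level == 0.90)
  X <- cbind(intercept = 1, risk50 = x1, risk90 = x2, reward_z = reward_z)
  if (interactions)
    X <- cbind(X, risk50_reward = x1 * reward_z, risk90_reward = x2 * reward_z)
  X
}

#' Approach-avoidance conflict statistic
#'
#' Conflict is the inverse distance of the choice probability to the decision
#' boundary: `d = 0.25 - (0.5 - theta)^2`, an inverted parabola that is
#' maximal (0.25) when the risky and safe options are equally likely and zero
#' when the choice is certain either way.
#'
#' @param theta probability (or vector of probabilities) of taking the risky
#'   option, in \[0, 1\].
#' @return conflict values in \[0, 0.25\].
#' @examples
#' conflict(c(0, 0.25, 0.5, 1))
#' @export
conflict <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]")
  0.25 - (0.5 - theta)^2
}

#' Mean response time as a function of conflict
#'
#' The RT side of the joint model: gamma-distributed response times whose
#' mean rises linearly with conflict, `mu = alpha0 + alpha1 * d`. `alpha0` is
#' the participant's baseline mean RT (seconds) and `alpha1` the slowing per
#' unit conflict. With `conflict_scale = "unit"` the conflict statistic is
#' rescaled to \[0, 1\] (d / 0.25) before entering the regression, so that
#' `alpha1` reads directly as seconds of slowing at maximal conflict.
#'
#' @param alpha0,alpha1 intercept (s) and slope (s per unit conflict).
#' @param d conflict values from [conflict()].
#' @param conflict_scale `"raw"` (d in \[0, 0.25\], the model equations'
#'   scale) or `"unit"` (d rescaled to \[0, 1\]).
#' @return mean RT in seconds; an error if any value is non-positive.
#' @export
rt_mean <- function(alpha0, alpha1, d, conflict_scale = c("raw", "unit")) {
  conflict_scale <- match.arg(conflict_scale)
  mu <- alpha0 + alpha1 * d / conflict_denom(conflict_scale)
  if (any(mu <= 0))
    stop("non-positive mean RT: alpha0 + alpha1 * d must stay positive")
  mu
}

conflict_denom <- function(conflict_scale) {
  if (identical(conflict_scale, "unit")) 0.25 else 1
}

#' Joint log-likelihood of choices and response times
#'
#' Sums, over non-missing trials, the Bernoulli log-density of the observed
#' choice and the gamma log-density of the observed RT (shape `k`, rate
#' `k / mu`, so the gamma mean is `mu`). Missing trials contribute nothing.
#'
#' @param params a list with per-participant parameters: `beta` (matrix,
#'   participants x coefficients), `alpha0`, `alpha1`, `k` (vectors).
#' @param dataset a behavioral dataset from [simulate_participants()] or
#'   [read_behavior()]: columns `participant`, `risk`, `reward_z`, `choice`,
#'   `rt` (NA where missing).
#' @param conflict_scale see [rt_mean()].
#' @return scalar total log-likelihood, with attribute `"pointwise"` holding
#'   the per-trial contributions (one joint term per observed trial).
#' @export
joint_log_likelihood <- function(params, dataset,
                                 conflict_scale = c("raw", "unit")) {
  conflict_scale <- match.arg(conflict_scale)
  if (nrow(dataset) == 0L) stop("dataset is empty")
  obs <- !is.na(dataset$choice) & !is.na(dataset$rt)
  if (any(dataset$rt[obs] <= 0)) stop("response times must be positive")
  ids <- sort(unique(dataset$participant))
  pw <- rep(NA_real_, nrow(dataset))
  for (i in seq_along(ids)) {
    rows <- which(dataset$participant == ids[i] & obs)
    if (!length(rows)) next
    beta <- params$beta[i, ]
    theta <- likelihood_of_take(beta, dataset$risk[rows],
                                dataset$reward_z[rows])
    d <- conflict(theta)
    mu <- rt_mean(params$alpha0[i], params$alpha1[i], d, conflict_scale)
    k <- params$k[i]
    y <- dataset$choice[rows]
    z <- dataset$rt[rows]
    pw[rows] <- stats::dbinom(y, 1, theta, log = TRUE) +
      stats::dgamma(z, shape = k, rate = k / mu, log = TRUE)
  }
  total <- sum(pw[obs])
  attr(total, "pointwise") <- pw
  total
}
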