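#' Group-level generating parameters for the behavioral simulator
#'
#' Default parameter set used to simulate ARC-task behavior. Choice
#' coefficients are centered on the group posterior means reported for this
#' task (50%-risk shift about -1.9, 90%-risk shift about -4.2, reward slope
#' about 10.7 on the standardized-reward scale) with an intercept of 2.0,
#' which makes the simulated group approach-biased at 10% risk while 90%-risk
#' trials are mostly avoided. The conflict-RT slope corresponds to 0.456 s of
#' slowing at maximal conflict; on the raw conflict scale (d in \[0, 0.25\])
#' that is a slope of 1.824 s per unit d. Between-participant SDs were
#' calibrated once, by simulating cohorts from the generator alone, so that
#' 28-participant cohorts reproduce the wide preference range reported for
#' this task (per-participant risky-choice rates with extremes near 15% and
#' 90%, occasionally wider).
#'
#' @param beta_G group-mean choice coefficients (intercept, 50% risk,
#'   90% risk, reward).
#' @param beta_sd between-participant SDs of the choice coefficients.
#' @param alpha0_G group-mean baseline RT (seconds).
#' @param alpha1_G group-mean conflict-RT slope, on the scale set by
#'   `conflict_scale`.
#' @param alpha_sd SDs of `alpha0` and `alpha1` across participants.
#' @param k_shape typical gamma shape of the RT distribution; participant
#'   shapes are drawn log-normally around it with log-SD `k_sdlog`.
#' @param k_sdlog log-scale SD of participant gamma shapes.
#' @param conflict_scale `"raw"` or `"unit"`; see [rt_mean()].
#' @return a list of class `arc_group_parameters`.
#' @export
group_parameters <- function(beta_G = c(2.0, -1.922, -4.180, 10.652),
                             beta_sd = c(4, 1.5, 2, 3),
                             alpha0_G = 1.0,
                             alpha1_G = NULL,
                             alpha_sd = NULL,
                             k_shape = 8,
                             k_sdlog = 0.3,
                             conflict_scale = c("raw", "unit")) {
  conflict_scale <- match.arg(conflict_scale)
  denom <- conflict_denom(conflict_scale)
  # 0.456 s of slowing at maximal conflict: slope = 0.456 / (0.25 / denom)
  if (is.null(alpha1_G)) alpha1_G <- 0.456 * 4 * denom
  if (is.null(alpha_sd)) alpha_sd <- c(0.15, 0.5 * denom)
  stopifnot(length(beta_G) %in% c(4L, 6L),
            length(beta_sd) == length(beta_G),
            all(beta_sd > 0), alpha0_G > 0, all(alpha_sd > 0), k_shape > 0)
  if (alpha0_G + alpha1_G * 0.25 / denom <= 0)
    stop("gamma mean must stay positive at maximal conflict")
  structure(list(beta_G = beta_G, beta_sd = beta_sd,
                 alpha0_G = alpha0_G, alpha1_G = alpha1_G,
                 alpha_sd = alpha_sd, k_shape = k_shape, k_sdlog = k_sdlog,
                 conflict_scale = conflict_scale),
            class = "arc_group_parameters")
}

#' Simulate ARC-task behavior for a cohort of participants
#'
#' Draws participant-level parameters from normal distributions around the
#' group means, then per trial computes the likelihood-of-take via the
#' logistic choice model, the conflict statistic d, and the conflicted mean
#' RT, and samples a Bernoulli choice and a gamma RT. RTs exceeding the
#' response window are censored: both choice and RT are set missing,
#' mirroring how missing responses arise in the scanner task.
#'
#' @param group an [group_parameters()] object.
#' @param n_participants cohort size.
#' @param design an [generate_design()] trial design shared by everyone.
#' @param response_window response cutoff in seconds (3.5 in the task).
#' @param seed integer seed.
#' @param censor set `FALSE` to keep over-window RTs as observed.
#' @return a `data.frame` with columns `participant`, `trial`, `risk`,
#'   `reward`, `reward_z`, `choice` (0 safe / 1 risky / NA), `rt` (s, NA when
#'   missing), `true_theta`, `true_d`, plus attribute
#'   `"true_participant_parameters"`.
#' @export
simulate_participants <- function(group, n_participants, design,
                                  response_window = 3.5, seed = 1L,
                                  censor = TRUE) {
  stopifnot(inherits(group, "arc_group_parameters"),
            n_participants >= 1, response_window > 0)
  p <- length(group$beta_G)
  interactions <- p == 6L
  X <- choice_design_matrix(design$risk, design$reward_z, interactions)
  nt <- nrow(design)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  denom <- conflict_denom(group$conflict_scale)

  rows <- vector("list", n_participants)
  truth <- matrix(NA_real_, n_participants, p + 3,
                  dimnames = list(NULL, c(colnames(X), "alpha0", "alpha1", "k")))
  for (j in seq_len(n_participants)) {
    for (try in 1:100) {
      beta <- stats::rnorm(p, group$beta_G, group$beta_sd)
      alpha0 <- stats::rnorm(1, group$alpha0_G, group$alpha_sd[1])
      alpha1 <- stats::rnorm(1, group$alpha1_G, group$alpha_sd[2])
      if (alpha0 <= 0) next
      theta <- stats::plogis(drop(X %*% beta))
      d <- conflict(theta)
      mu <- alpha0 + alpha1 * d / denom
      if (all(mu > 0)) break
      if (try == 100) stop("could not draw a participant with positive mean RTs")
    }
    k <- stats::rlnorm(1, log(group$k_shape), group$k_sdlog)
    y <- stats::rbinom(nt, 1, theta)
    z <- stats::rgamma(nt, shape = k, rate = k / mu)
    if (censor) {
      miss <- z > response_window
      y[miss] <- NA_integer_
      z[miss] <- NA_real_
    }
    truth[j, ] <- c(beta, alpha0, alpha1, k)
    rows[[j]] <- data.frame(participant = j, trial = design$trial,
                            risk = design$risk, reward = design$reward,
                            reward_z = design$reward_z,
                            choice = y, rt = z,
                            true_theta = theta, true_d = d)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_participant_parameters") <- truth
  attr(out, "conflict_scale") <- group$conflict_scale
  out
}

#' Flag participants with excessive missing responses
#'
#' Participants missing more than `max_missing` of their trials are flagged
#' for exclusion (the behavioral exclusion rule of the task: more than 20%
#' missing responses).
#'
#' @param dataset a behavioral dataset.
#' @param max_missing maximal tolerated missing fraction.
#' @return integer vector of participant ids to exclude (possibly empty).
#' @export
flag_exclusions <- function(dataset, max_missing = 0.2) {
  miss <- tapply(is.na(dataset$choice), dataset$participant, mean)
  ids <- as.integer(names(miss)[miss > max_missing])
  ids[!is.na(ids)]
}

#' Write / read a behavioral dataset as TSV
#' @param dataset behavioral data frame.
#' @param path file path.
#' @export
write_behavior <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Convert BIDS events files to a behavioral dataset
#'
#' Reads one BIDS-style events TSV per participant and assembles the trial
#' table the fitter expects. Each events file must carry columns `onset`,
#' `duration`, `risk` (probability of stimulation), `reward` (dollars),
#' `choice` (0 safe / 1 risky, `n/a` or empty when missing) and
#' `response_time` (seconds, `n/a` when missing). Reward is standardized over
#' the pooled trials of the first participant's design (the task presents the
#' same trial sequence to everyone).
#'
#' @param paths character vector of events TSV paths, one per participant.
#' @param participant_ids optional ids; defaults to `seq_along(paths)`.
#' @return a behavioral `data.frame` in the package's trial-table layout,
#'   with `onset` and `duration` retained for fMRI modelling.
#' @export
read_bids_events <- function(paths, participant_ids = seq_along(paths)) {
  stopifnot(length(paths) >= 1, length(participant_ids) == length(paths))
  tabs <- lapply(paths, function(p)
    utils::read.table(p, header = TRUE, sep = "\t", na.strings = c("n/a", "NA", "")))
  need <- c("onset", "duration", "risk", "reward", "choice", "response_time")
  for (tb in tabs)
    if (!all(need %in% names(tb)))
      stop("events file lacks required columns: ",
           paste(setdiff(need, names(tb)), collapse = ", "))
  out <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    tb <- tabs[[i]]
    data.frame(participant = participant_ids[i],
               trial = seq_len(nrow(tb)),
               onset = tb$onset, duration = tb$duration,
               risk = tb$risk, reward = tb$reward,
               reward_z = normalize_reward(tb$reward),
               choice = as.integer(tb$choice),
               rt = as.numeric(tb$response_time))
  }))
  rownames(out) <- NULL
  out
}
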