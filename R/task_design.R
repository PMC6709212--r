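#' Construct an ARC task trial design
#'
#' Builds the fixed trial structure of the aversion-reward conflict (ARC)
#' task: `n_trials` trials counterbalanced over the risk levels (probability
#' of aversive stimulation), with reward offers drawn uniformly from the cent
#' grid between `reward_min` and `reward_max` independently within each risk
#' level, and the trial order fixed by a seeded permutation shared by all
#' participants.
#'
#' @param n_trials total number of trials; must be divisible by the number of
#'   risk levels (the task counterbalances risk exactly).
#' @param risk_levels probabilities of stimulation for the risky option.
#' @param reward_min,reward_max dollar bounds of the risky reward; both must
#'   lie on the cent grid.
#' @param seed integer seed fixing rewards and trial order.
#' @return A `data.frame` of class `arc_design` with columns `trial`, `risk`,
#'   `reward` (dollars) and `reward_z` (reward standardized to mean 0, SD 1
#'   over the whole design).
#' @examples
#' d <- generate_design(108, seed = 1)
#' table(d$risk)
#' @export
generate_design <- function(n_trials = 108L,
                            risk_levels = c(0.10, 0.50, 0.90),
                            reward_min = 0.05, reward_max = 0.95,
                            seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (n_trials < length(risk_levels) || n_trials %% length(risk_levels) != 0L)
    stop("design infeasible: n_trials must be divisible by the number of risk levels")
  if (reward_min > reward_max)
    stop("reward_min must not exceed reward_max")
  cents_min <- round(reward_min * 100)
  cents_max <- round(reward_max * 100)
  if (abs(cents_min - reward_min * 100) > 1e-9 ||
      abs(cents_max - reward_max * 100) > 1e-9)
    stop("reward bounds must be whole numbers of cents")

  per_level <- n_trials %/% length(risk_levels)
  grid <- seq.int(cents_min, cents_max)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  risk <- rep(sort(risk_levels), each = per_level)
  reward <- unlist(lapply(seq_along(risk_levels), function(i)
    grid[sample.int(length(grid), per_level, replace = TRUE)])) / 100
  ord <- sample.int(n_trials)
  out <- data.frame(trial = seq_len(n_trials),
                    risk = risk[ord],
                    reward = reward[ord])
  if (n_trials >= 2L && stats::sd(out$reward) > 0) {
    out$reward_z <- normalize_reward(out$reward)
  } else {
    out$reward_z <- rep(0, n_trials)  # degenerate range: no spread to scale
  }
  class(out) <- c("arc_design", "data.frame")
  out
}

#' Standardize the reward predictor
#'
#' Centers and scales a reward vector to mean 0 and SD 1, the form in which
#' reward enters the choice model as its continuous predictor. The population
#' SD convention (divide by `n`) is the default so that the fixed design is
#' standardized exactly; the sample convention is available for replication
#' against pipelines that used it.
#'
#' @param rewards numeric vector of dollar amounts, length at least 2.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return numeric vector with mean 0 and SD 1 (under the chosen convention).
#' @export
normalize_reward <- function(rewards, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(rewards) < 2L)
    stop("need at least two rewards to standardize")
  ctr <- rewards - mean(rewards)
  s <- sqrt(mean(ctr^2))
  if (sd_type == "sample") s <- stats::sd(rewards)
  if (s == 0) stop("zero-variance reward vector cannot be standardized")
  ctr / s
}

#' Write / read a trial design as TSV
#'
#' Plain-text round trip with columns `trial`, `risk`, `reward`, `reward_z`.
#' @param design an `arc_design` data frame.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("arc_design", "data.frame")
  out
}

# Preserve the caller's RNG state around seeded internals.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
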