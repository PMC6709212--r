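#' Default pipeline configuration
#'
#' A complete run configuration for [run_pipeline()], at a small
#' demonstration scale by default. Every stochastic stage carries an
#' explicit seed derived from the top-level `seed` offset by a fixed
#' per-stage increment, so any stage can be rerun in isolation.
#'
#' @param seed base integer seed.
#' @param out_dir output directory.
#' @return nested list of class `arc_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("arc_run_")) {
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir,
    seed = seed,
    design = list(n_trials = 108L, risk_levels = c(0.10, 0.50, 0.90),
                  reward_min = 0.05, reward_max = 0.95, seed = seed),
    simulate = list(n_participants = 8L, response_window = 3.5,
                    seed = seed + 1L),
    model = list(variant = "hierarchical", eta = 5,
                 n_chains = 4L, n_steps = 600L, n_burnin = 300L, thin = 2L,
                 conflict_scale = "raw", seed = seed + 2L),
    glm = list(enabled = FALSE, dims = c(12L, 12L, 12L), tr = 1.75,
               n_perms = 200L, alpha = 0.05, min_voxels = 20L,
               noise_sd = 1, ar_coefficient = 0.2, seed = seed + 3L)),
    class = "arc_config")
}

#' Validate a pipeline configuration
#'
#' @param config a list shaped like [default_config()].
#' @return the config, invisibly; errors list every offending key.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need <- c("out_dir", "seed", "design", "simulate", "model", "glm")
  miss <- setdiff(need, names(config))
  if (length(miss)) problems <- c(problems, paste("missing:", miss))
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  if (!length(miss)) {
    chk(is.numeric(config$seed), "seed must be numeric")
    for (st in c("design", "simulate", "model", "glm"))
      chk(is.numeric(config[[st]]$seed), paste0(st, "$seed missing"))
    chk(config$design$n_trials %% length(config$design$risk_levels) == 0,
        "design$n_trials not divisible by the number of risk levels")
    chk(config$simulate$n_participants >= 1, "simulate$n_participants < 1")
    chk(config$model$n_steps > config$model$n_burnin,
        "model$n_steps must exceed n_burnin")
    chk(config$glm$n_perms >= 1, "glm$n_perms must be at least 1")
    chk(config$glm$alpha > 0 && config$glm$alpha < 1,
        "glm$alpha must be in (0, 1)")
  }
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Orchestrates design construction, behavioral simulation, the hierarchical
#' model fit, conflict extraction and (optionally) the synthetic-BOLD GLM
#' stage, writing every artifact plus a collated `summary.json` into
#' `config$out_dir`. Reruns with the same config are deterministic.
#'
#' @param config configuration list, see [default_config()].
#' @return list with the in-memory stage results and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  cfg <- config$design
  design <- generate_design(cfg$n_trials, cfg$risk_levels, cfg$reward_min,
                            cfg$reward_max, cfg$seed)
  write_design(design, file.path(config$out_dir, "design.tsv"))

  grp <- group_parameters(conflict_scale = config$model$conflict_scale)
  behav <- simulate_participants(grp, config$simulate$n_participants, design,
                                 config$simulate$response_window,
                                 config$simulate$seed)
  write_behavior(behav, file.path(config$out_dir, "behavior.tsv"))

  spec <- model_spec(variant = config$model$variant, eta = config$model$eta,
                     n_chains = config$model$n_chains,
                     n_steps = config$model$n_steps,
                     n_burnin = config$model$n_burnin,
                     thin = config$model$thin,
                     conflict_scale = config$model$conflict_scale)
  fit <- fit_behavior(behav, spec, seed = config$model$seed)
  gs <- group_summary(fit)
  conf <- extract_conflict(fit, design)
  utils::write.table(conf, file.path(config$out_dir, "conflict.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  glm_summary <- NULL
  if (isTRUE(config$glm$enabled)) {
    glm_summary <- .pipeline_glm_stage(config, design, behav, conf)
  }

  summary <- list(
    n_participants = length(fit$participants),
    excluded = fit$excluded,
    group_parameters = gs,
    waic = fit$waic$waic,
    max_rhat = max(fit$rhat, na.rm = TRUE),
    ppc_rmse = as.numeric(posterior_predictive_rmse(fit)),
    mean_conflict = mean(conf$d_hat),
    glm = glm_summary,
    seeds = list(design = config$design$seed,
                 simulate = config$simulate$seed,
                 model = config$model$seed, glm = config$glm$seed))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE,
                       force = TRUE)
  invisible(list(design = design, behavior = behav, fit = fit,
                 conflict = conf, glm = glm_summary,
                 out_dir = config$out_dir))
}

# synthetic-BOLD GLM stage of the pipeline: simulate per-participant BOLD
# from that participant's conflict series, run first level in variable-epoch
# mode, then group inference with TFCE/FWE.
.pipeline_glm_stage <- function(config, design, behav, conf) {
  g <- config$glm
  dims <- g$dims
  truth <- ground_truth_maps(dims)
  ids <- sort(unique(behav$participant))
  onsets <- trial_onsets(nrow(design), seed = g$seed)
  n_scans <- ceiling((max(onsets) + 25) / g$tr)
  ft <- (seq_len(n_scans) - 1) * g$tr
  psc_maps <- matrix(NA_real_, length(ids), prod(dims))
  for (i in seq_along(ids)) {
    rows <- behav[behav$participant == ids[i], ]
    ev <- data.frame(onset = onsets, rt = rows$rt, risk = rows$risk,
                     reward_z = rows$reward_z,
                     d_hat = conf$d_hat[conf$participant == ids[i]])
    task <- list(deliberation = build_epochs(ev, "variable", "none"),
                 conflict = build_epochs(ev, "variable", "conflict"))
    X <- build_design_matrix(task, ft, cutoff_hz = 0.01)
    B <- matrix(0, 2, prod(dims),
                dimnames = list(c("deliberation", "conflict"), NULL))
    B["deliberation", as.vector(truth$deliberation)] <- 1
    B["conflict", as.vector(truth$conflict)] <- 1.5
    bold <- simulate_bold(X, B, dims, noise_sd = g$noise_sd,
                          ar_coefficient = g$ar_coefficient,
                          seed = g$seed + i)
    fl <- first_level(bold, X)
    psc_maps[i, ] <- psc_convert(fl, "conflict")
  }
  perm <- freedman_lane_permute(psc_maps, n_perms = g$n_perms,
                                seed = g$seed, dims = dims)
  fwe <- fwe_correct(perm$observed_tfce, perm, alpha = g$alpha)
  labels <- cluster_filter(array(fwe$p <= g$alpha, dims),
                           min_voxels = g$min_voxels)
  tab <- cluster_table(labels, array(perm$observed_F, dims), dims)
  list(n_significant_voxels = sum(fwe$p <= g$alpha),
       clusters = tab,
       true_positive_rate = mean(fwe$p[as.vector(truth$conflict)] <= g$alpha),
       false_positive_voxels = sum(fwe$p <= g$alpha &
                                     !as.vector(truth$conflict)))
}
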