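#!/usr/bin/env Rscript
# Stage 4: model-based fMRI inference on synthetic BOLD with known ground
# truth. Each participant's conflict series (stage 3) drives a synthetic
# 12x12x12-voxel BOLD run containing a "deliberation-only" cluster (signal
# scales with response time) and a "conflict-sensitive" cluster (signal
# additionally scales with d). First-level GLMs are run under both the
# variable-epoch and fixed-epoch conventions with a conflict parametric
# modulator; percent-signal-change maps go to a second-level WLS with
# Freedman-Lane permutations, TFCE and voxelwise FWE correction, and
# surviving clusters (>= 20 voxels) are tabulated. Writes
# results/cluster_table_<mode>.tsv and results/glm_summary.json.

library(arcconflict)

seed <- 21L
dims <- c(12, 12, 12)
tr <- 1.75
n_perms <- 500
behav <- read_behavior("results/behavior.tsv")
conf <- read.table("results/conflict.tsv", header = TRUE, sep = "\t")
ids <- sort(unique(behav$participant))
truth <- ground_truth_maps(dims)
onsets <- trial_onsets(sum(behav$participant == ids[1]), seed = seed)
ft <- (seq_len(ceiling((max(onsets) + 30) / tr)) - 1) * tr
baseline <- 100

psc <- list(variable = matrix(NA_real_, length(ids), prod(dims)),
            fixed = matrix(NA_real_, length(ids), prod(dims)))
cat("simulating and fitting", length(ids), "participants...\n")
for (i in seq_along(ids)) {
  rows <- behav[behav$participant == ids[i], ]
  ev <- data.frame(onset = onsets, rt = rows$rt, risk = rows$risk,
                   reward_z = rows$reward_z,
                   d_hat = conf$d_hat[conf$participant == ids[i]])
  X_true <- build_design_matrix(
    list(deliberation = build_epochs(ev, "variable", "none"),
         conflict = build_epochs(ev, "variable", "conflict")),
    ft, cutoff_hz = NULL)
  B <- matrix(0, ncol(X_true), prod(dims),
              dimnames = list(colnames(X_true), NULL))
  sel <- as.vector(truth$deliberation) | as.vector(truth$conflict)
  B["deliberation", sel] <- 1.0 / 100 * baseline /
    max(abs(X_true[, "deliberation"]))
  B["conflict", as.vector(truth$conflict)] <- 0.6 / 100 * baseline /
    max(abs(X_true[, "conflict"]))
  bold <- simulate_bold(X_true, B, dims, baseline = baseline, noise_sd = 0.5,
                        ar_coefficient = 0.2, seed = seed + i)
  for (mode in names(psc)) {
    X <- build_design_matrix(
      list(deliberation = build_epochs(ev, mode, "none"),
           conflict = build_epochs(ev, mode, "conflict")),
      ft, cutoff_hz = 0.01)
    psc[[mode]][i, ] <- psc_convert(first_level(bold, X), "conflict")
  }
}

summary <- list()
for (mode in names(psc)) {
  perm <- freedman_lane_permute(psc[[mode]], n_perms = n_perms, seed = seed,
                                dims = dims)
  fwe <- fwe_correct(perm$observed_tfce, perm, alpha = 0.05)
  sig <- array(fwe$p <= 0.05, dims)
  labels <- cluster_filter(sig, min_voxels = 20)
  tab <- cluster_table(labels, array(perm$observed_F, dims), dims)
  write.table(tab, sprintf("results/cluster_table_%s.tsv", mode),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- mean(sig[truth$conflict])
  fp_delib <- sum(sig[truth$deliberation])
  cat(sprintf(
    "%s epochs: %d suprathreshold voxels, %d cluster(s); conflict-voxel sensitivity %0.2f; deliberation-only false positives %d\n",
    mode, sum(sig), max(labels), tp, fp_delib))
  summary[[mode]] <- list(n_suprathreshold = sum(sig),
                          n_clusters = max(labels),
                          conflict_sensitivity = tp,
                          deliberation_false_positives = fp_delib)
}
jsonlite::write_json(summary, "results/glm_summary.json", auto_unbox = TRUE,
                     digits = 4)
cat("the variable-epoch analysis should isolate the conflict cluster;\n")
cat("the fixed-epoch analysis is expected to be more widespread (time-on-task).\n")
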