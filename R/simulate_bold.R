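#' Trial onset times for a slow event-related run
#'
#' Onsets separated by jittered intertrial intervals (the task used
#' 10.5 +/- 0.875 s); jitter is uniform within the stated range.
#'
#' @param n_trials number of trials.
#' @param iti_mean,iti_jitter mean ITI and half-range of the jitter (s).
#' @param first_onset time of the first trial (s).
#' @param seed integer seed.
#' @return numeric vector of onsets in seconds, strictly increasing.
#' @export
trial_onsets <- function(n_trials, iti_mean = 10.5, iti_jitter = 0.875,
                         first_onset = 10, seed = 1L) {
  stopifnot(n_trials >= 1, iti_mean > iti_jitter, iti_jitter >= 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  itis <- stats::runif(n_trials - 1, iti_mean - iti_jitter,
                       iti_mean + iti_jitter)
  first_onset + c(0, cumsum(itis))
}

#' Ground-truth voxel sets for synthetic BOLD studies
#'
#' Places two disjoint cuboid clusters on a voxel grid: a
#' "deliberation-only" set responding to the task control regressor and a
#' "conflict-sensitive" set additionally (or exclusively) responding to the
#' conflict modulator. Cluster sizes default to at least 20 voxels so the
#' cluster-extent filter is exercised.
#'
#' @param dims 3-element voxel grid dimensions (default 12 x 12 x 12).
#' @param cluster_dim edge lengths of each cuboid cluster.
#' @return list of two logical arrays, `deliberation` and `conflict`.
#' @export
ground_truth_maps <- function(dims = c(12, 12, 12), cluster_dim = c(3, 3, 3)) {
  stopifnot(length(dims) == 3, all(cluster_dim <= dims))
  blk <- function(corner) {
    a <- array(FALSE, dims)
    a[corner[1] + seq_len(cluster_dim[1]) - 1,
      corner[2] + seq_len(cluster_dim[2]) - 1,
      corner[3] + seq_len(cluster_dim[3]) - 1] <- TRUE
    a
  }
  list(deliberation = blk(c(2, 2, 2)),
       conflict = blk(pmax(dims - cluster_dim - 1, 1)))
}

#' Simulate BOLD time series from a design matrix and true effect maps
#'
#' Generates `Y = X beta_true + noise` per voxel. Noise is white
#' (`ar_coefficient = 0`) or AR(1) with the stated coefficient plus white
#' measurement noise; innovations are scaled so the marginal noise SD is
#' `noise_sd`. With `noise_sd = 0` a first-level GLM on the same design
#' recovers `beta_true` exactly.
#'
#' @param X design matrix (scans x regressors), e.g. from
#'   [build_design_matrix()].
#' @param true_beta matrix of true amplitudes, regressors x voxels (rows
#'   matched to `colnames(X)`; missing regressors default to 0).
#' @param dims voxel grid dimensions; `prod(dims)` must equal
#'   `ncol(true_beta)`.
#' @param baseline constant signal level added to every voxel (needed for a
#'   meaningful percent-signal-change scale).
#' @param noise_sd marginal noise standard deviation.
#' @param ar_coefficient AR(1) coefficient of the noise (0.2 by default,
#'   weakly realistic serial correlation).
#' @param seed integer seed.
#' @return list of class `arc_bold`: `data` (scans x voxels), `dims`, `X`,
#'   `true_beta`, `baseline`, `noise_model`.
#' @export
simulate_bold <- function(X, true_beta, dims, baseline = 100,
                          noise_sd = 1, ar_coefficient = 0.2, seed = 1L) {
  X <- as.matrix(X)
  true_beta <- as.matrix(true_beta)
  stopifnot(noise_sd >= 0, abs(ar_coefficient) < 1,
            prod(dims) == ncol(true_beta))
  if (is.null(rownames(true_beta))) {
    if (nrow(true_beta) != ncol(X))
      stop("true_beta rows must match design columns (or be named)")
    B <- true_beta
  } else {
    B <- matrix(0, ncol(X), ncol(true_beta))
    rownames(B) <- colnames(X)
    hit <- intersect(rownames(true_beta), colnames(X))
    if (!length(hit)) stop("no true_beta rows match design columns")
    B[hit, ] <- true_beta[hit, ]
  }
  n <- nrow(X); V <- ncol(true_beta)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  noise <- matrix(0, n, V)
  if (noise_sd > 0) {
    eps <- matrix(stats::rnorm(n * V, 0, noise_sd), n, V)
    if (ar_coefficient != 0) {
      innov_sd <- noise_sd * sqrt(1 - ar_coefficient^2)
      noise <- matrix(0, n, V)
      noise[1, ] <- eps[1, ]
      for (t in 2:n)
        noise[t, ] <- ar_coefficient * noise[t - 1, ] +
          stats::rnorm(V, 0, innov_sd)
    } else {
      noise <- eps
    }
  }
  structure(list(data = X %*% B + baseline + noise, dims = dims, X = X,
                 true_beta = B, baseline = baseline,
                 noise_model = list(sd = noise_sd, ar = ar_coefficient)),
            class = "arc_bold")
}

#' Write a BOLD array to NIfTI (optional convenience)
#'
#' Thin wrapper over the RNifti package for exporting simulated volumes.
#' @param bold an `arc_bold` object.
#' @param path output `.nii` path.
#' @param tr repetition time recorded in the header.
#' @export
write_bold_nifti <- function(bold, path, tr = 1.75) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to write NIfTI files")
  arr <- array(t(bold$data), dim = c(bold$dims, nrow(bold$data)))
  img <- RNifti::asNifti(arr, pixdim = c(2, 2, 2, tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}
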