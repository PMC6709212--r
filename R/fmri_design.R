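#' Build trial epochs for first-level modelling
#'
#' Turns per-trial events into the boxcar specification of a task regressor.
#' Under the variable-epoch method each trial's boxcar lasts its observed
#' response time, isolating deliberation and controlling time-on-task; under
#' the fixed-epoch mode every boxcar lasts `fixed_window` seconds (stimulus
#' onset to the response cutoff). Amplitudes implement parametric
#' modulation: 1 for the control regressor, or the per-trial conflict
#' estimate d, the risk level, or the standardized reward. Trials with
#' missing responses get amplitude 0 on modulated regressors (amplitude 1 on
#' the control regressor) and, in variable mode, the full response window as
#' duration since no RT exists.
#'
#' @param events data frame with one row per trial: `onset` (s), `rt`
#'   (s, NA if missing), `risk`, `reward_z`, and `d_hat` when
#'   `modulator = "conflict"` (join of the conflict series onto the events).
#' @param mode `"variable"` or `"fixed"`.
#' @param modulator `"none"`, `"conflict"`, `"risk"` or `"reward"`.
#' @param fixed_window epoch length for fixed mode and for missing-response
#'   trials in variable mode (the task's 3.5 s response window).
#' @param center mean-center modulator amplitudes over non-missing trials so
#'   the control regressor absorbs the mean effect (default `TRUE`;
#'   ignored for `modulator = "none"`).
#' @return list of class `arc_epochs`: `onsets`, `durations`, `amplitudes`.
#' @export
build_epochs <- function(events, mode = c("variable", "fixed"),
                         modulator = c("none", "conflict", "risk", "reward"),
                         fixed_window = 3.5, center = TRUE) {
  mode <- match.arg(mode)
  modulator <- match.arg(modulator)
  stopifnot(fixed_window > 0, !is.unsorted(events$onset, strictly = TRUE))
  miss <- is.na(events$rt)
  dur <- if (mode == "variable") ifelse(miss, fixed_window, events$rt)
         else rep(fixed_window, nrow(events))
  amp <- switch(modulator,
    none = rep(1, nrow(events)),
    conflict = {
      if (is.null(events$d_hat)) stop("conflict modulator needs a d_hat column")
      events$d_hat
    },
    risk = events$risk,
    reward = events$reward_z)
  if (modulator != "none") {
    if (center) amp <- amp - mean(amp[!miss])
    amp[miss] <- 0
  }
  if (any(dur <= 0)) stop("all durations must be positive")
  structure(list(onsets = events$onset, durations = dur, amplitudes = amp),
            class = "arc_epochs")
}

#' Canonical (SPM-style) double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: peak delay 6 s, undershoot delay 16 s,
#' both with dispersion 1, undershoot weighted 1/6, truncated at 32 s and
#' normalized to unit peak (the peak value is computed on a fine grid so the
#' normalization does not depend on `dt`).
#'
#' @param dt sampling interval in seconds.
#' @param duration kernel length in seconds.
#' @return numeric vector of the HRF sampled at `0, dt, 2 dt, ...`.
#' @export
hrf <- function(dt, duration = 32) {
  stopifnot(dt > 0)
  shape_fun <- function(t)
    stats::dgamma(t, shape = 6, rate = 1) -
      stats::dgamma(t, shape = 16, rate = 1) / 6
  peak <- max(shape_fun(seq(0, duration, by = 0.001)))
  shape_fun(seq(0, duration, by = dt)) / peak
}

#' Convolve an epoch specification into a sampled regressor
#'
#' Builds the amplitude-scaled boxcar on an oversampled time grid (so onsets
#' may fall between scans), convolves it with the canonical HRF, and samples
#' the result at the scan times.
#'
#' @param epochs an [build_epochs()] object.
#' @param frame_times scan acquisition times in seconds.
#' @param oversampling grid refinement factor relative to the scan spacing.
#' @return numeric vector, one value per frame time.
#' @export
convolve_regressor <- function(epochs, frame_times, oversampling = 16L) {
  stopifnot(oversampling >= 1, length(frame_times) >= 2)
  tr <- frame_times[2] - frame_times[1]
  dt <- tr / oversampling
  t_end <- max(frame_times) + tr
  n <- ceiling(t_end / dt) + 1L
  box <- numeric(n)
  if (length(epochs$onsets)) {
    ends <- epochs$onsets + epochs$durations
    if (any(ends > t_end)) {
      warning("epoch extends past the last frame; truncated")
      ends <- pmin(ends, t_end)
    }
    for (i in seq_along(epochs$onsets)) {
      a <- floor(epochs$onsets[i] / dt) + 1L
      b <- max(a, ceiling(ends[i] / dt))
      box[a:min(b, n)] <- box[a:min(b, n)] + epochs$amplitudes[i]
    }
  }
  h <- hrf(dt)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n)] * dt
  idx <- pmin(round(frame_times / dt) + 1L, n)
  conv[idx]
}

#' Discrete cosine transform drift basis
#'
#' Orthonormal DCT-II columns implementing a high-pass filter: all cosine
#' regressors with frequency below `cutoff_hz` are included, i.e.
#' `floor(2 * n_scans * tr * cutoff_hz)` columns.
#'
#' @param n_scans number of volumes.
#' @param tr repetition time (s).
#' @param cutoff_hz high-pass cutoff frequency (0.01 Hz here).
#' @return matrix `n_scans` x `n_basis` (possibly zero columns, with a
#'   warning, for very short runs).
#' @export
dct_drift_basis <- function(n_scans, tr, cutoff_hz = 0.01) {
  stopifnot(cutoff_hz > 0, n_scans >= 2, tr > 0)
  K <- floor(2 * n_scans * tr * cutoff_hz)
  if (K < 1) {
    warning("run too short for any drift regressor below the cutoff")
    return(matrix(numeric(0), n_scans, 0))
  }
  i <- seq_len(n_scans) - 1
  basis <- vapply(seq_len(K), function(k)
    sqrt(2 / n_scans) * cos(pi * (2 * i + 1) * k / (2 * n_scans)),
    numeric(n_scans))
  colnames(basis) <- paste0("drift_", seq_len(K))
  basis
}

#' Process motion parameters into nuisance regressors
#'
#' Each of the six rigid-body motion traces is demeaned, linearly detrended,
#' and then Gram-Schmidt orthogonalized against the preceding columns (in
#' column order). Columns that become (numerically) zero -- constants, pure
#' ramps, or linear combinations of earlier columns -- are zeroed with a
#' warning.
#'
#' @param motion matrix with 6 columns (3 translations mm, 3 rotations rad).
#' @return matrix of 6 processed columns, pairwise orthogonal.
#' @export
motion_nuisance <- function(motion) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 3)
  n <- nrow(motion)
  t_lin <- seq_len(n) - mean(seq_len(n))
  out <- apply(motion, 2, function(col) {
    col <- col - mean(col)
    col - t_lin * sum(col * t_lin) / sum(t_lin^2)
  })
  tol <- 1e-10 * max(1, max(abs(out)))
  dropped <- FALSE
  for (c in seq_len(6)) {
    v <- out[, c]
    if (c > 1) for (b in seq_len(c - 1)) {
      nb <- sum(out[, b]^2)
      if (nb > tol^2) v <- v - out[, b] * sum(v * out[, b]) / nb
    }
    if (sqrt(sum(v^2)) < tol * sqrt(n)) {
      v <- numeric(n)
      dropped <- TRUE
    }
    out[, c] <- v
  }
  if (dropped)
    warning("some motion regressors are constant/collinear and were zeroed")
  colnames(out) <- paste0("motion_", seq_len(6))
  out
}

#' Framewise displacement and motion scrubbing
#'
#' FD at frame t is the sum of absolute backward differences of the three
#' translations plus `head_radius_mm` times the sum of absolute differences
#' of the three rotations (rotations converted to arc length at the head
#' radius). The first frame has FD 0 by convention.
#'
#' @param motion 6-column motion matrix (translations mm, rotations rad).
#' @param head_radius_mm radius used to convert rotations, default 50 mm.
#' @return numeric FD vector (mm), one value per frame.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' @rdname framewise_displacement
#' @param fd FD vector from [framewise_displacement()].
#' @param threshold_mm scrub frames with FD above this (0.9 mm here).
#' @param n_discard_initial initial frames always dropped (4 here).
#' @return logical keep-mask over frames.
#' @export
scrub_mask <- function(fd, threshold_mm = 0.9, n_discard_initial = 4L) {
  stopifnot(threshold_mm > 0, n_discard_initial >= 0)
  keep <- fd <= threshold_mm
  keep[seq_len(min(n_discard_initial, length(fd)))] <- FALSE
  keep
}

#' Assemble a first-level design matrix
#'
#' Combines convolved task regressors (one per epoch specification), the DCT
#' drift basis, processed motion nuisance columns, and one spike regressor
#' per scrubbed frame.
#'
#' @param task named list of [build_epochs()] objects.
#' @param frame_times scan times in seconds.
#' @param motion optional 6-column motion matrix.
#' @param cutoff_hz drift high-pass cutoff; `NULL` disables the basis.
#' @param keep_mask optional logical keep-mask from [scrub_mask()]; excluded
#'   frames get spike regressors.
#' @param oversampling see [convolve_regressor()].
#' @return numeric matrix (class `arc_design_matrix`) with attributes
#'   `frame_times`, `task_columns` and `keep_mask`.
#' @export
build_design_matrix <- function(task, frame_times, motion = NULL,
                                cutoff_hz = 0.01, keep_mask = NULL,
                                oversampling = 16L) {
  stopifnot(is.list(task), length(task) >= 1,
            !is.null(names(task)), !anyDuplicated(names(task)))
  n <- length(frame_times)
  cols <- lapply(task, convolve_regressor, frame_times = frame_times,
                 oversampling = oversampling)
  X <- do.call(cbind, cols)
  colnames(X) <- names(task)
  if (any(apply(X, 2, function(v) all(v == 0))))
    stop("a task regressor is identically zero")
  X <- cbind(X, constant = rep(1, n))
  if (!is.null(cutoff_hz)) {
    tr <- frame_times[2] - frame_times[1]
    X <- cbind(X, dct_drift_basis(n, tr, cutoff_hz))
  }
  if (!is.null(motion)) X <- cbind(X, motion_nuisance(motion))
  if (!is.null(keep_mask) && any(!keep_mask)) {
    spikes <- vapply(which(!keep_mask), function(i) {
      v <- numeric(n); v[i] <- 1; v
    }, numeric(n))
    colnames(spikes) <- paste0("spike_", which(!keep_mask))
    X <- cbind(X, spikes)
  }
  structure(X, frame_times = frame_times, task_columns = names(task),
            keep_mask = keep_mask, class = c("arc_design_matrix", "matrix"))
}
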