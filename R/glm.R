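#' First-level voxelwise GLM
#'
#' Ordinary least squares of every voxel's time series on the design matrix.
#'
#' @param bold an `arc_bold` object or a scans x voxels numeric matrix.
#' @param X design matrix (scans x regressors), e.g. from
#'   [build_design_matrix()].
#' @return list of class `arc_first_level`: `beta` (regressors x voxels),
#'   `residual_variance` (per voxel), `dof`, `baseline_mean` (temporal mean
#'   per voxel) and the design `X`.
#' @export
first_level <- function(bold, X) {
  Y <- if (inherits(bold, "arc_bold")) bold$data else as.matrix(bold)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("time dimensions of data and design disagree")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  dof <- nrow(Y) - qrX$rank
  structure(list(beta = beta,
                 residual_variance = colSums(res^2) / dof,
                 dof = dof,
                 baseline_mean = colMeans(Y),
                 X = X),
            class = "arc_first_level")
}

#' Convert GLM coefficients to percent signal change
#'
#' `psc = 100 * beta * peak(unit-amplitude convolved task regressor) /
#' baseline`, i.e. the peak BOLD excursion the fitted effect implies,
#' expressed as a percentage of the voxel's mean signal. Voxels with
#' non-positive baseline are masked (NA).
#'
#' @param beta_map numeric vector of coefficients for one task regressor
#'   (one per voxel), or an `arc_first_level` plus a regressor name.
#' @param task_column the regressor's sampled values at unit amplitude
#'   (used only through its peak).
#' @param baseline_mean_map per-voxel baseline mean signal.
#' @return numeric vector of PSC values (% units).
#' @export
psc_convert <- function(beta_map, task_column, baseline_mean_map) {
  if (inherits(beta_map, "arc_first_level")) {
    fl <- beta_map
    if (!is.character(task_column))
      stop("give the task regressor name when passing a first-level fit")
    nm <- task_column
    beta_map <- fl$beta[nm, ]
    task_column <- fl$X[, nm]
    baseline_mean_map <- fl$baseline_mean
  }
  peak <- max(abs(task_column))
  psc <- 100 * beta_map * peak / baseline_mean_map
  psc[!is.finite(psc) | baseline_mean_map <= 0] <- NA_real_
  psc
}

#' Second-level weighted least-squares group model
#'
#' Per voxel, regresses the participant effect maps on an intercept plus
#' optional covariates (e.g. a scanner indicator) by weighted least squares,
#' and computes the F-contrast on the intercept (group mean different from
#' zero). Unit weights (ordinary least squares) are the default; inverse
#' first-level-variance weights may be supplied instead.
#'
#' @param subject_maps participants x voxels matrix (e.g. PSC maps).
#' @param covariates optional matrix of nuisance covariates (no intercept
#'   column; it is added internally).
#' @param weights positive participant weights, default all 1.
#' @return list of class `arc_group`: `F` (per voxel), `coef`, `dof`
#'   (residual df), plus the pieces needed to permute.
#' @export
second_level_wls <- function(subject_maps, covariates = NULL, weights = NULL) {
  Y <- as.matrix(subject_maps)
  n <- nrow(Y)
  if (n < 3) stop("need at least three participants")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive")
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X <- cbind(intercept = rep(1, n), Z)
  if (qr(X)$rank < ncol(X)) stop("covariates are collinear")
  w <- weights
  XtWX <- crossprod(X * w, X)
  A <- solve(XtWX, t(X * w))          # p x n projection
  coef <- A %*% Y
  res <- Y - X %*% coef
  dof <- n - ncol(X)
  sigma2 <- colSums(res^2 * w) / dof
  c11 <- solve(XtWX)[1, 1]
  Fv <- coef[1, ]^2 / pmax(c11 * sigma2, .Machine$double.eps)
  structure(list(F = Fv, coef = coef, dof = dof, X = X, weights = w,
                 subject_maps = Y),
            class = "arc_group")
}

#' Freedman-Lane permutation distribution of the max TFCE statistic
#'
#' Builds the null distribution of the group-level statistic: the nuisance-
#' only model (covariates, or nothing when there are none) is fitted, its
#' residuals are transformed under the null, the nuisance signal is added
#' back, the full WLS model is refitted, and the maximum TFCE value over
#' voxels is recorded per permutation. For the group-mean (intercept)
#' contrast the residuals are sign-flipped per participant (independent
#' symmetric errors), since row permutation leaves a mean effect invariant;
#' `method = "permute"` (row permutation) is available for contrasts on
#' non-intercept covariates.
#'
#' @param subject_maps participants x voxels matrix.
#' @param covariates optional nuisance covariate matrix.
#' @param n_perms number of permutations (the identity is not included).
#' @param seed integer seed.
#' @param dims voxel grid dimensions for TFCE.
#' @param weights WLS weights.
#' @param method `"sign_flip"` (default, intercept contrast) or `"permute"`.
#' @param H,E,step,connectivity TFCE parameters, see [tfce()].
#' @return list of class `arc_permutation`: `observed_F`, `observed_tfce`,
#'   `max_dist` (length `n_perms`), and the settings used.
#' @export
freedman_lane_permute <- function(subject_maps, covariates = NULL,
                                  n_perms = 5000L, seed = 1L,
                                  dims, weights = NULL,
                                  method = c("sign_flip", "permute"),
                                  H = 2, E = 0.5, step = 0.1,
                                  connectivity = 6L) {
  method <- match.arg(method)
  Y <- as.matrix(subject_maps)
  n <- nrow(Y)
  if (n_perms < 100) stop("n_perms must be at least 100")
  if (method == "sign_flip" && n_perms > 2^n) {
    warning("more permutations requested than distinct sign flips; capping")
    n_perms <- 2^n
  }
  if (is.null(weights)) weights <- rep(1, n)
  obs <- second_level_wls(Y, covariates, weights)
  # nuisance-only fit (weighted); with no covariates the residuals are Y
  if (is.null(covariates)) {
    fitted_nuis <- matrix(0, n, ncol(Y))
  } else {
    Z <- as.matrix(covariates)
    An <- solve(crossprod(Z * weights, Z), t(Z * weights))
    fitted_nuis <- Z %*% (An %*% Y)
  }
  resid_nuis <- Y - fitted_nuis

  X <- obs$X
  XtWX <- crossprod(X * weights, X)
  A <- solve(XtWX, t(X * weights))
  c11 <- solve(XtWX)[1, 1]
  dof <- n - ncol(X)

  f_stat <- function(Ystar) {
    coef <- A %*% Ystar
    res <- Ystar - X %*% coef
    sigma2 <- colSums(res^2 * weights) / dof
    coef[1, ]^2 / pmax(c11 * sigma2, .Machine$double.eps)
  }
  observed_tfce <- tfce(obs$F, dims = dims, H = H, E = E, step = step,
                        connectivity = connectivity)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  max_dist <- numeric(n_perms)
  if (method == "sign_flip" && is.null(covariates) && all(weights == 1)) {
    # closed form for the unit-weight one-sample case: sign flips leave the
    # per-voxel sum of squares invariant, so all permutation F maps follow
    # from one matrix product
    S <- matrix(sample(c(-1, 1), n * n_perms, replace = TRUE), n)
    C <- crossprod(S, Y) / n                  # n_perms x V intercept estimates
    ss <- colSums(Y^2)
    for (b in seq_len(n_perms)) {
      sigma2 <- (ss - n * C[b, ]^2) / dof
      Fb <- C[b, ]^2 / pmax(c11 * sigma2, .Machine$double.eps)
      tb <- tfce(Fb, dims = dims, H = H, E = E, step = step,
                 connectivity = connectivity)
      max_dist[b] <- max(tb)
    }
  } else {
    for (b in seq_len(n_perms)) {
      Ystar <- if (method == "sign_flip") {
        s <- sample(c(-1, 1), n, replace = TRUE)
        fitted_nuis + resid_nuis * s
      } else {
        fitted_nuis + resid_nuis[sample.int(n), , drop = FALSE]
      }
      tb <- tfce(f_stat(Ystar), dims = dims, H = H, E = E, step = step,
                 connectivity = connectivity)
      max_dist[b] <- max(tb)
    }
  }
  structure(list(observed_F = obs$F, observed_tfce = observed_tfce,
                 max_dist = max_dist, dims = dims, n_perms = n_perms,
                 method = method,
                 tfce_params = list(H = H, E = E, step = step,
                                    connectivity = connectivity)),
            class = "arc_permutation")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel, integrates `extent(h)^E * h^H` over thresholds
#' `h = step, 2 step, ...`, where `extent(h)` is the size of the connected
#' suprathreshold component containing the voxel at height `h`. Negative
#' values are enhanced separately on the sign-flipped map and returned with
#' negative sign.
#'
#' @param stat_map 3-D numeric array, or vector with `dims` supplied.
#' @param dims grid dimensions when `stat_map` is a vector.
#' @param H height exponent (2), `E` extent exponent (0.5), `step` threshold
#'   increment (0.1) -- the recommended TFCE parameters.
#' @param connectivity 6 (faces), 18 (edges) or 26 (corners).
#' @return array (or vector) of enhanced values, same shape as the input.
#' @export
tfce <- function(stat_map, dims = dim(stat_map), H = 2, E = 0.5, step = 0.1,
                 connectivity = 6L) {
  stopifnot(step > 0, connectivity %in% c(6L, 18L, 26L), length(dims) == 3)
  v <- as.numeric(stat_map)
  if (any(!is.finite(v))) stop("stat map must be finite")
  out <- .cpp_tfce(pmax(v, 0), as.integer(dims), H, E, step,
                   as.integer(connectivity))
  if (any(v < 0))
    out <- out - .cpp_tfce(pmax(-v, 0), as.integer(dims), H, E, step,
                           as.integer(connectivity))
  if (is.array(stat_map)) array(out, dims) else out
}

#' Family-wise error corrected p-values from a max-statistic distribution
#'
#' `p(v) = (1 + #\{permutation maxima >= observed(v)\}) / (1 + n_perms)`,
#' the add-one permutation estimator (never exactly zero).
#'
#' @param observed_tfce observed enhanced map (vector or array).
#' @param max_distribution permutation maxima from
#'   [freedman_lane_permute()], or an `arc_permutation` object.
#' @param alpha significance level for the returned threshold.
#' @return list: `p` (corrected p-values, same shape as input), `threshold`
#'   (enhanced values strictly above it have `p <= alpha`; `Inf` when no
#'   value can reach significance at this `n_perms`), `alpha`.
#' @export
fwe_correct <- function(observed_tfce, max_distribution, alpha = 0.05) {
  if (inherits(max_distribution, "arc_permutation")) {
    if (missing(observed_tfce)) observed_tfce <- max_distribution$observed_tfce
    max_distribution <- max_distribution$max_dist
  }
  if (!length(max_distribution)) stop("empty permutation distribution")
  np <- length(max_distribution)
  obs <- as.numeric(observed_tfce)
  srt <- sort(max_distribution, decreasing = TRUE)
  cnt <- vapply(obs, function(o) sum(srt >= o), numeric(1))
  p <- (1 + cnt) / (1 + np)
  m <- floor(alpha * (1 + np) - 1)  # max count of maxima >= obs still significant
  thr <- if (m < 0) Inf else srt[m + 1]
  list(p = if (is.array(observed_tfce)) array(p, dim(observed_tfce)) else p,
       threshold = thr, alpha = alpha)
}

#' Remove small clusters from a thresholded map
#'
#' Labels the connected components of a suprathreshold (or logical) map and
#' discards components with fewer than `min_voxels` voxels (components of
#' exactly `min_voxels` are kept).
#'
#' @param thresholded_map logical/0-1 array, or vector with `dims`.
#' @param min_voxels minimal surviving extent (20 by default).
#' @param dims grid dimensions when a vector is given.
#' @param connectivity neighbourhood definition, see [tfce()].
#' @return integer label map (0 background, clusters numbered 1..K by
#'   decreasing size), same shape as the input.
#' @export
cluster_filter <- function(thresholded_map, min_voxels = 20L,
                           dims = dim(thresholded_map), connectivity = 6L) {
  stopifnot(length(dims) == 3)
  v <- as.numeric(thresholded_map)
  labs <- .cpp_label_components(v, as.integer(dims), 0.5,
                                as.integer(connectivity))
  sizes <- tabulate(labs)
  keep <- which(sizes >= min_voxels)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  new <- integer(max(labs, 1))
  new[keep] <- seq_along(keep)
  out <- ifelse(labs > 0, new[pmax(labs, 1)], 0L)
  if (is.array(thresholded_map)) array(out, dims) else out
}

#' Summarize surviving clusters
#'
#' @param labels label map from [cluster_filter()].
#' @param stat_map statistic map used to locate each cluster's peak.
#' @param dims grid dimensions when vectors are given.
#' @return data frame with one row per cluster: label, extent, peak value,
#'   peak voxel coordinates.
#' @export
cluster_table <- function(labels, stat_map, dims = dim(labels)) {
  lab <- as.integer(labels)
  stat <- as.numeric(stat_map)
  ks <- setdiff(sort(unique(lab)), 0L)
  if (!length(ks))
    return(data.frame(label = integer(0), extent = integer(0),
                      peak = numeric(0), x = integer(0), y = integer(0),
                      z = integer(0)))
  do.call(rbind, lapply(ks, function(k) {
    vx <- which(lab == k)
    pk <- vx[which.max(stat[vx])]
    co <- arrayInd(pk, dims)
    data.frame(label = k, extent = length(vx), peak = stat[pk],
               x = co[1], y = co[2], z = co[3])
  }))
}
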