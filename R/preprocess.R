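#' Preprocessing parameters
#'
#' @param n_discard Initial volumes dropped for scanner stabilisation
#'   (default 10; 240 acquired volumes leave 230).
#' @param detrend_order Polynomial trend order removed (1 = linear).
#' @param band_hz Retained frequency band in Hz, `0 <= low < high < Nyquist`
#'   checked against the image TR at run time.
#' @param motion_regressors,global_regressor,wm_regressor,csf_regressor Flags
#'   selecting the nuisance set (all on by default: 6 rigid-body parameters
#'   plus global, white-matter and CSF mean series).
#' @param rotations_in_degrees If `TRUE`, motion-file rotations are converted
#'   from degrees to radians on load.
#' @return A list of class `preproc_params`.
#' @export
preproc_params <- function(n_discard = 10, detrend_order = 1,
                           band_hz = c(0.01, 0.08),
                           motion_regressors = TRUE, global_regressor = TRUE,
                           wm_regressor = TRUE, csf_regressor = TRUE,
                           rotations_in_degrees = FALSE) {
  if (band_hz[1] < 0 || band_hz[1] >= band_hz[2]) {
    abort("`band_hz` must satisfy 0 <= low < high.")
  }
  structure(
    list(n_discard = as.integer(n_discard), detrend_order = as.integer(detrend_order),
         band_hz = band_hz, motion_regressors = motion_regressors,
         global_regressor = global_regressor, wm_regressor = wm_regressor,
         csf_regressor = csf_regressor,
         rotations_in_degrees = rotations_in_degrees),
    class = "preproc_params"
  )
}

#' Head-motion QC parameters
#'
#' Defaults encode the quality-control rule used throughout: mean framewise
#' displacement (FD) below 0.3 mm and fewer than 50% of volumes with
#' FD > 0.3 mm. Volumes are only counted ("scrubbing volumes"), never removed.
#'
#' @param fd_radius_mm Sphere radius converting rotations to arc length (mm).
#' @param fd_flag_mm A volume is flagged when FD strictly exceeds this (mm).
#' @param mean_fd_max_mm Pass requires mean FD strictly below this (mm).
#' @param max_flag_fraction Pass requires flagged count strictly below this
#'   fraction of volumes.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(fd_radius_mm = 50, fd_flag_mm = 0.3,
                      mean_fd_max_mm = 0.3, max_flag_fraction = 0.5) {
  if (fd_radius_mm <= 0) abort("`fd_radius_mm` must be positive.")
  structure(
    list(fd_radius_mm = fd_radius_mm, fd_flag_mm = fd_flag_mm,
         mean_fd_max_mm = mean_fd_max_mm, max_flag_fraction = max_flag_fraction),
    class = "qc_params"
  )
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes from an image and its paired motion
#' trace, leaving the remaining data untouched (e.g. 240 acquired volumes
#' minus 10 leaves 230 for analysis).
#'
#' @param img A [ts_image()].
#' @param motion Motion matrix paired with `img` (one row per volume).
#' @param n_discard Number of leading volumes to drop (must be < volume count).
#' @return List with elements `image` and `motion`.
#' @export
discard_initial_volumes <- function(img, motion, n_discard = 10) {
  nt <- n_volumes(img)
  if (n_discard >= nt) abort("`n_discard` must be smaller than the volume count.")
  if (nrow(motion) != nt) abort("Motion trace rows must match the volume count.")
  if (n_discard == 0) return(list(image = img, motion = motion))
  keep <- (n_discard + 1):nt
  out <- ts_image(img$data[, , , keep, drop = FALSE], img$voxel_size_mm, img$tr_s)
  list(image = out, motion = motion[keep, , drop = FALSE])
}

#' Framewise displacement (Power convention)
#'
#' FD for volume t is the sum of absolute volume-to-volume changes in the
#' three translations (mm) plus `radius_mm` times the sum of absolute changes
#' in the three rotations (radians), i.e. rotations converted to arc length on
#' a reference sphere. The first volume has FD 0 by convention. FD depends
#' only on parameter differences, so a constant offset leaves it unchanged.
#'
#' @param motion Numeric matrix, volumes x 6 (translations mm, rotations rad).
#' @param radius_mm Reference sphere radius in mm (default 50).
#' @return Non-negative numeric vector, one FD per volume, first element 0.
#' @export
compute_fd_power <- function(motion, radius_mm = 50) {
  if (radius_mm <= 0) abort("`radius_mm` must be positive.")
  if (nrow(motion) < 2) abort("Need at least 2 volumes to compute FD.")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Evaluate head-motion quality control
#'
#' Counts volumes with FD strictly above the flag threshold (no volume is ever
#' removed) and applies the pass rule: mean FD strictly below
#' `mean_fd_max_mm` AND flagged count strictly below
#' `max_flag_fraction * n_volumes`.
#'
#' @param fd Per-volume FD vector (from [compute_fd_power()]).
#' @param params A [qc_params()].
#' @return One-row tibble: `n_volumes`, `mean_fd_mm`, `n_flagged`,
#'   `flag_fraction`, `pass`, plus the FD vector as list-column `fd`.
#' @export
evaluate_qc <- function(fd, params = qc_params()) {
  if (length(fd) == 0) abort("`fd` must be non-empty.")
  n <- length(fd)
  n_flagged <- sum(fd > params$fd_flag_mm)
  mean_fd <- mean(fd)
  tibble(
    n_volumes = n,
    mean_fd_mm = mean_fd,
    n_flagged = n_flagged,
    flag_fraction = n_flagged / n,
    pass = (mean_fd < params$mean_fd_max_mm) &&
      (n_flagged < params$max_flag_fraction * n),
    fd = list(fd)
  )
}

# In-band Fourier columns for a given length/TR/band (strict inequalities,
# matching the 0.01 Hz < f < 0.08 Hz convention). Constant column excluded.
inband_columns <- function(n, tr_s, band) {
  basis <- fourier_design(n, tr_s)
  f <- attr(basis, "freq_hz")
  list(basis = basis, inband = f > band[1] & f < band[2], freq = f)
}

#' Nuisance regression, detrending and band-pass in one projection
#'
#' Removes, in a single joint least-squares fit per voxel: a constant, a
#' polynomial trend, the six rigid-body motion parameters, the global,
#' white-matter and CSF mean series (each switchable), and all Fourier
#' components outside the retained band. Because band-pass filtering is
#' expressed as regression on the out-of-band Fourier basis, the residuals are
#' exactly orthogonal to every nuisance regressor, out-of-band sinusoids are
#' removed exactly, and the operation is idempotent.
#'
#' @param img A [ts_image()].
#' @param motion Motion matrix paired with `img`.
#' @param masks Tissue masks (see [generate_masks()]); used for the global,
#'   WM and CSF mean regressors and to restrict cleaning to brain voxels.
#' @param params A [preproc_params()].
#' @return A cleaned [ts_image()] with identical geometry.
#' @export
clean_timeseries <- function(img, motion, masks, params = preproc_params()) {
  nt <- n_volumes(img)
  if (nrow(motion) != nt) abort("Motion regressor rows must match the volume count.")
  nyq <- 1 / (2 * img$tr_s)
  if (params$band_hz[2] >= nyq) abort("Band upper edge must be below the Nyquist frequency.")

  dims <- dim(img$data)[1:3]
  dm <- matrix(img$data, nrow = prod(dims))
  brain <- which(masks$brain)

  X <- matrix(1, nt, 1)
  if (params$detrend_order >= 1) {
    t01 <- seq(0, 1, length.out = nt)
    for (d in seq_len(params$detrend_order)) X <- cbind(X, t01^d)
  }
  if (params$motion_regressors) X <- cbind(X, motion)
  if (params$global_regressor) X <- cbind(X, colMeans(dm[brain, , drop = FALSE]))
  if (params$wm_regressor) X <- cbind(X, colMeans(dm[which(masks$wm), , drop = FALSE]))
  if (params$csf_regressor) X <- cbind(X, colMeans(dm[which(masks$csf), , drop = FALSE]))
  # out-of-band Fourier columns; the constant (f = 0) column is already in X
  ib <- inband_columns(nt, img$tr_s, params$band_hz)
  X <- cbind(X, ib$basis[, !ib$inband & ib$freq > 0, drop = FALSE])

  # numerically-zero regressors (e.g. tissue means of already-cleaned data)
  # are dropped rather than fed to the QR, where their tiny pivots would
  # amplify roundoff
  norms <- sqrt(colSums(X^2))
  keep <- norms > 1e-10 * max(norms)
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warn("Nuisance regressor matrix is rank deficient; using the pivoted least-squares fit.")
  }
  Y <- t(dm[brain, , drop = FALSE])
  res <- qr.resid(qrX, Y)
  dm[brain, ] <- t(res)
  ts_image(array(dm, dim = c(dims, nt)), img$voxel_size_mm, img$tr_s)
}

#' Preprocess and QC a whole cohort
#'
#' Applies, per subject: initial-volume discard, framewise-displacement QC
#' (count-only scrubbing on the retained volumes), and joint nuisance
#' regression / detrend / band-pass. Stage order is fixed: discard, then
#' cleaning.
#'
#' @param cohort A cohort tibble from [generate_cohort()] or [load_dataset()].
#' @param params A [preproc_params()].
#' @param qc A [qc_params()].
#' @return The cohort with `image`/`motion` replaced by their processed
#'   versions and QC columns added (`mean_fd_mm`, `n_flagged`,
#'   `flag_fraction`, `qc_pass`, list-column `fd`).
#' @export
preprocess_cohort <- function(cohort, params = preproc_params(), qc = qc_params()) {
  masks <- cohort_masks(cohort)
  out <- cohort
  qcrows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    dc <- discard_initial_volumes(cohort$image[[i]], cohort$motion[[i]], params$n_discard)
    fd <- compute_fd_power(dc$motion)
    qcrows[[i]] <- evaluate_qc(fd, qc)
    out$image[[i]] <- clean_timeseries(dc$image, dc$motion, masks, params)
    out$motion[[i]] <- dc$motion
  }
  qtab <- dplyr::bind_rows(qcrows)
  out$mean_fd_mm <- qtab$mean_fd_mm
  out$n_flagged <- qtab$n_flagged
  out$flag_fraction <- qtab$flag_fraction
  out$qc_pass <- qtab$pass
  out$fd <- qtab$fd
  attr(out, "masks") <- masks
  attr(out, "config") <- attr(cohort, "config")
  out
}
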