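#' GBC mapping parameters
#'
#' @param r_threshold Pearson correlation threshold; only edges with
#'   `r >= r_threshold` contribute (one-sided: negative correlations are
#'   excluded). Default 0.25.
#' @param variant `"weighted-z"` sums Fisher-z transformed suprathreshold
#'   correlations; `"binary-count"` counts suprathreshold neighbours
#'   (classical degree centrality).
#' @param standardize Standardize the map to mean 0 / SD 1 over the mask.
#' @param fwhm_mm Full width at half maximum of the Gaussian smoothing kernel
#'   in mm (0 disables smoothing). Default 6.
#' @param r_clamp Correlations are clamped below 1 before `atanh` so
#'   duplicated series cannot produce infinities.
#' @param block_size Number of mask voxels correlated per block; the full
#'   voxel-by-voxel correlation matrix is never materialised.
#' @return A list of class `gbc_params`.
#' @export
gbc_params <- function(r_threshold = 0.25,
                       variant = c("weighted-z", "binary-count"),
                       standardize = TRUE, fwhm_mm = 6,
                       r_clamp = 1 - 1e-7, block_size = 2048) {
  variant <- match.arg(variant)
  if (r_threshold < 0 || r_threshold >= 1) abort("`r_threshold` must be in [0, 1).")
  if (fwhm_mm < 0) abort("`fwhm_mm` must be non-negative.")
  structure(
    list(r_threshold = r_threshold, variant = variant, standardize = standardize,
         fwhm_mm = fwhm_mm, r_clamp = r_clamp, block_size = as.integer(block_size)),
    class = "gbc_params"
  )
}

new_gbc_map <- function(values3d, mask, voxel_size_mm, params = NULL, subject_id = NULL) {
  structure(
    list(data = values3d, mask = mask, voxel_size_mm = voxel_size_mm,
         params = params, subject_id = subject_id),
    class = "gbc_map"
  )
}

#' @export
print.gbc_map <- function(x, ...) {
  v <- gbc_values(x)
  cat(sprintf("<gbc_map> %d mask voxels, mean %.3f, sd %.3f\n",
              length(v), mean(v), sd(v)))
  invisible(x)
}

#' Values of a GBC map over its mask
#'
#' @param map A `gbc_map`.
#' @return Numeric vector, one value per mask voxel (array order).
#' @export
gbc_values <- function(map) map$data[map$mask]

#' Voxel-wise global brain connectivity map
#'
#' For every gray-matter voxel, correlates its time series with every other
#' gray-matter voxel's series and aggregates the suprathreshold
#' (`r >= r_threshold`) correlations: either as the sum of Fisher r-to-z
#' transformed values (`"weighted-z"`) or as a plain count
#' (`"binary-count"`). The self-correlation is excluded. Computation proceeds
#' in voxel blocks so the full correlation matrix is never held in memory.
#' Voxels with zero temporal variance get GBC 0 with a warning and contribute
#' no edges.
#'
#' @param img A (cleaned) [ts_image()].
#' @param gm_mask Logical 3D array marking gray-matter voxels.
#' @param params A [gbc_params()]. Note this operation neither standardizes
#'   nor smooths; see [standardize_map()] and [smooth_map()].
#' @return A `gbc_map` (values on mask voxels, `NA` elsewhere).
#' @export
compute_gbc_map <- function(img, gm_mask, params = gbc_params()) {
  dims <- dim(img$data)[1:3]
  if (!identical(dim(gm_mask), dims)) abort("Mask geometry does not match the image.")
  idx <- which(gm_mask)
  if (length(idx) < 2) abort("Need at least 2 mask voxels.")
  nt <- n_volumes(img)
  ts <- matrix(img$data, nrow = prod(dims))[idx, , drop = FALSE]

  sds <- apply(ts, 1, sd)
  dead <- sds == 0
  if (any(dead)) warn(sprintf("%d zero-variance voxels assigned GBC 0.", sum(dead)))
  live <- which(!dead)
  gbc <- numeric(length(idx))

  if (length(live) >= 2) {
    Z <- ts[live, , drop = FALSE]
    Z <- (Z - rowMeans(Z)) / (sds[live] * sqrt(nt - 1))
    nlive <- length(live)
    thr <- params$r_threshold
    self_w <- if (params$variant == "weighted-z") atanh(params$r_clamp) else 1
    acc <- numeric(nlive)
    for (start in seq(1, nlive, by = params$block_size)) {
      cols <- start:min(start + params$block_size - 1, nlive)
      R <- Z %*% t(Z[cols, , drop = FALSE])      # nlive x |cols|
      if (params$variant == "weighted-z") {
        W <- ifelse(R >= thr, atanh(pmin(R, params$r_clamp)), 0)
      } else {
        W <- (R >= thr) * 1
      }
      acc[cols] <- colSums(W) - self_w
      rm(R, W)
    }
    gbc[live] <- acc
  }

  out <- array(NA_real_, dims)
  out[idx] <- gbc
  new_gbc_map(out, gm_mask, img$voxel_size_mm, params)
}

#' Standardize a GBC map over its mask
#'
#' Subtracts the mask mean and divides by the mask SD, yielding a zGBC map
#' with mean 0 and SD 1 over the mask. Standardization is invariant to any
#' positive affine transform of the input.
#'
#' @param map A `gbc_map`.
#' @return The standardized `gbc_map`.
#' @export
standardize_map <- function(map) {
  v <- gbc_values(map)
  if (length(v) < 2) abort("Need at least 2 mask voxels.")
  s <- sd(v)
  if (s == 0) abort("Cannot standardize a constant map (zero SD over mask).")
  map$data[map$mask] <- (v - mean(v)) / s
  map
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  radius <- max(1L, ceiling(3 * sigma_vox))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Zero-padded separable 1D convolution along one array axis.
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1) return(arr)
  dims <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dims[axis])
  radius <- (length(kernel) - 1) / 2
  pad <- matrix(0, radius, ncol(m))
  mp <- rbind(pad, m, pad)
  flt <- stats::filter(mp, kernel, method = "convolution", sides = 2)
  flt <- flt[(radius + 1):(radius + dims[axis]), , drop = FALSE]
  a <- array(as.numeric(flt), dim = dims[perm])
  aperm(a, order(perm))
}

#' Mask-aware Gaussian smoothing of a GBC map
#'
#' Separable Gaussian smoothing with per-axis
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, restricted to the mask: values
#' outside the mask never leak in, and the smoothed map is renormalized by the
#' smoothed mask indicator so a constant map is returned unchanged.
#'
#' @param map A `gbc_map`.
#' @param fwhm_mm Kernel FWHM in mm (0 returns the input unchanged).
#' @param voxel_size_mm Voxel edge length in mm; defaults to the map's own.
#' @return The smoothed `gbc_map`.
#' @export
smooth_map <- function(map, fwhm_mm = 6, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) abort("`fwhm_mm` must be non-negative.")
  if (fwhm_mm == 0) return(map)
  voxel_size_mm <- voxel_size_mm %||% map$voxel_size_mm
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  k <- gaussian_kernel_1d(sigma_vox)

  vals <- map$data
  vals[!map$mask] <- 0
  ind <- array(0, dim(map$data))
  ind[map$mask] <- 1
  for (ax in 1:3) {
    vals <- convolve_axis(vals, k, ax)
    ind <- convolve_axis(ind, k, ax)
  }
  out <- array(NA_real_, dim(map$data))
  out[map$mask] <- vals[map$mask] / ind[map$mask]
  map$data <- out
  map
}

#' Compute standardized, smoothed GBC maps for a cohort
#'
#' Runs, per subject, the fixed map pipeline: connectivity aggregation
#' ([compute_gbc_map()]), mask standardization ([standardize_map()], if
#' `params$standardize`) and Gaussian smoothing ([smooth_map()], if
#' `params$fwhm_mm > 0`).
#'
#' @param cohort A (preprocessed) cohort tibble.
#' @param params A [gbc_params()].
#' @return The cohort with a `gbc` list-column of `gbc_map` objects.
#' @export
compute_gbc_maps <- function(cohort, params = gbc_params()) {
  masks <- cohort_masks(cohort)
  out <- cohort
  out$gbc <- purrr::map2(cohort$image, cohort$subject_id, function(img, id) {
    m <- compute_gbc_map(img, masks$gm, params)
    if (params$standardize) m <- standardize_map(m)
    if (params$fwhm_mm > 0) m <- smooth_map(m, params$fwhm_mm)
    m$subject_id <- id
    m
  })
  attr(out, "masks") <- masks
  attr(out, "config") <- attr(cohort, "config")
  out
}

#' Subjects-by-voxels feature matrix from cohort GBC maps
#'
#' @param cohort A cohort with a `gbc` list-column (see [compute_gbc_maps()]).
#' @return Numeric matrix, one row per subject (rownames = subject ids), one
#'   column per gray-matter mask voxel.
#' @export
gbc_features <- function(cohort) {
  if (is.null(cohort$gbc)) abort("Cohort has no `gbc` column; run compute_gbc_maps() first.")
  x <- do.call(rbind, lapply(cohort$gbc, gbc_values))
  rownames(x) <- cohort$subject_id
  x
}
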