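#' Correlation parameters
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_rois Number of ROIs tested (default 12).
#' @param rule Bonferroni denominator rule: `"pairwise"` divides alpha by
#'   `n_rois * (n_rois - 1) / 2` (the printed rule this package reproduces;
#'   66 tests for 12 ROIs, threshold ~7.58e-4), `"per-roi"` divides by
#'   `n_rois`.
#' @return A list of class `correlation_params`.
#' @export
correlation_params <- function(alpha = 0.05, n_rois = 12,
                               rule = c("pairwise", "per-roi")) {
  rule <- match.arg(rule)
  structure(list(alpha = alpha, n_rois = as.integer(n_rois), rule = rule),
            class = "correlation_params")
}

bonferroni_threshold <- function(params) {
  d <- switch(params$rule,
    pairwise = params$n_rois * (params$n_rois - 1) / 2,
    `per-roi` = params$n_rois
  )
  params$alpha / d
}

#' Mean GBC over an ROI, per subject
#'
#' @param cohort A cohort with a `gbc` list-column, or a list of `gbc_map`s.
#' @param voxels Integer vector of linear voxel indices (the ROI), all inside
#'   the gray-matter mask.
#' @return Tibble with `subject_id` and `roi_mean`.
#' @export
roi_mean_values <- function(cohort, voxels) {
  if (length(voxels) == 0) abort("ROI is empty.")
  maps <- if (is.list(cohort) && !is.data.frame(cohort)) cohort else cohort$gbc
  if (is.null(maps)) abort("No GBC maps found; run compute_gbc_maps() first.")
  vals <- vapply(maps, function(m) {
    if (anyNA(m$data[voxels])) abort("ROI extends outside the gray-matter mask.")
    mean(m$data[voxels])
  }, numeric(1))
  ids <- if (is.data.frame(cohort)) cohort$subject_id else
    vapply(maps, function(m) m$subject_id %||% NA_character_, character(1))
  tibble(subject_id = ids, roi_mean = vals)
}

#' Pearson or partial Pearson correlation with Bonferroni threshold
#'
#' With covariates, both variables are residualized on the covariate matrix
#' (with intercept) and the residuals are correlated; the two-sided p-value
#' uses `df = n - 2 - n_covariates`, so an empty covariate set reduces exactly
#' to the ordinary Pearson test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates.
#' @param params A [correlation_params()]; sets the corrected threshold the
#'   result is compared against.
#' @return One-row tibble: `r`, `p`, `n`, `df`, `n_covariates`, `threshold`,
#'   `significant`.
#' @export
correlate <- function(x, y, covariates = NULL, params = correlation_params()) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < 3 + k) abort("Too few observations for the requested correlation.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero-variance input.")
  if (k > 0) {
    cm <- cbind(1, as.matrix(covariates))
    qx <- qr(cm)
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
    if (sd(x) == 0 || sd(y) == 0) abort("Zero residual variance after covariate adjustment.")
  }
  r <- cor(x, y)
  df <- as.integer(n - 2 - k)
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  thr <- bonferroni_threshold(params)
  tibble(r = r, p = p, n = n, df = df, n_covariates = k,
         threshold = thr, significant = p < thr)
}

#' One-way ANOVA from group summary statistics
#'
#' Computes the classical one-way ANOVA F statistic from group means, SDs and
#' sizes alone: between-group sum of squares from means and sizes, within from
#' `(n - 1) * sd^2`; `df = (k - 1, N - k)`. Agrees exactly with a raw-data
#' ANOVA when the summaries come from the same data.
#'
#' @param means,sds,ns Numeric vectors of per-group mean, SD and size
#'   (k >= 2 groups, all `ns >= 2`, `sds >= 0`).
#' @return One-row tibble: `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k) {
    abort("Need matched means, sds, ns for at least 2 groups.")
  }
  if (any(sds < 0)) abort("SDs must be non-negative.")
  if (any(ns < 2)) abort("Every group needs n >= 2.")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  tibble(F = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Voxel-wise two-sample t-test with covariates
#'
#' Per voxel, fits the linear model `value ~ group + covariates` and returns
#' the t statistic of the group effect with `df = n - rank(design)`. Without
#' covariates this equals the classical pooled two-sample t.
#'
#' @param x Subjects-by-voxels matrix of map values.
#' @param group Two-level factor; the t statistic is oriented as
#'   (second level - first level).
#' @param covariates Optional data frame / matrix of covariates.
#' @return List: `t` (vector over voxels), `df`, `coef` (group effect).
#' @export
voxelwise_covariate_ttest <- function(x, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (length(levels(group)) != 2) abort("`group` must have exactly 2 levels.")
  g <- as.numeric(group == levels(group)[2])
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("Design matrix is rank deficient.")
  n <- nrow(x)
  df <- n - qx$rank
  coefs <- qr.coef(qx, x)
  res <- qr.resid(qx, x)
  sigma2 <- colSums(res^2) / df
  xtxi <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtxi[2, 2])
  b <- coefs[2, ]
  tt <- ifelse(se > 0, b / se, 0)
  list(t = tt, df = df, coef = b)
}

#' TFCE parameters
#'
#' @param height_exponent,extent_exponent TFCE exponents H (default 2) and E
#'   (default 0.5), the field-standard values.
#' @param dh Integration step; `NULL` uses `max(|t|) / 100`.
#' @param connectivity Component neighbourhood (6, 18 or 26).
#' @param n_perm Permutations for the max-statistic correction.
#' @param seed Permutation seed.
#' @param alpha Corrected significance level (default 0.001).
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(height_exponent = 2, extent_exponent = 0.5, dh = NULL,
                        connectivity = 26, n_perm = 1000, seed = 1,
                        alpha = 0.001) {
  if (height_exponent <= 0 || extent_exponent <= 0) abort("TFCE exponents must be positive.")
  if (!is.null(dh) && dh <= 0) abort("`dh` must be positive.")
  structure(
    list(height_exponent = height_exponent, extent_exponent = extent_exponent,
         dh = dh, connectivity = as.integer(connectivity),
         n_perm = as.integer(n_perm), seed = as.integer(seed), alpha = alpha),
    class = "tfce_params"
  )
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' `TFCE(v) = sum_h e(h, v)^E * h^H * dh` over thresholds `h` from `dh` up to
#' `t(v)`, where `e(h, v)` is the size of the connected suprathreshold
#' component containing `v`. Positive and negative parts of the map are
#' enhanced separately and recombined with their signs. Raising any voxel's
#' statistic never decreases any voxel's TFCE score.
#'
#' @param t_map 3D array of statistics (`NA` outside the mask) or a vector
#'   over mask voxels if `mask` is given.
#' @param params A [tfce_params()].
#' @param mask Logical 3D array (required when `t_map` is a vector).
#' @return 3D array (or mask-vector, matching the input form) of signed TFCE
#'   scores.
#' @export
tfce_enhance <- function(t_map, params = tfce_params(), mask = NULL) {
  vector_in <- !is.null(mask) && is.null(dim(t_map))
  if (vector_in) {
    ta <- array(NA_real_, dim(mask)); ta[mask] <- t_map; t_map <- ta
  }
  dims <- dim(t_map)
  out <- array(0, dims)
  mx <- max(abs(t_map), na.rm = TRUE)
  if (mx == 0 || !is.finite(mx)) {
    if (vector_in) return(out[mask])
    out[is.na(t_map)] <- NA_real_
    return(out)
  }
  dh <- params$dh %||% (mx / 100)
  for (sgn in c(1, -1)) {
    v <- sgn * t_map
    v[is.na(v)] <- -Inf
    if (max(v) < dh) next
    hs <- seq(dh, max(v), by = dh)
    for (h in hs) {
      lab <- label_components(v >= h, params$connectivity)
      if (max(lab) == 0) next
      sizes <- tabulate(lab[lab > 0])
      inc <- sizes[lab[lab > 0]]^params$extent_exponent * h^params$height_exponent * dh
      out[lab > 0] <- out[lab > 0] + sgn * inc
    }
  }
  out[is.na(t_map)] <- NA_real_
  if (vector_in) out[mask] else out
}

#' Covariate-adjusted voxel-wise t-test with TFCE permutation correction
#'
#' Fits [voxelwise_covariate_ttest()] on the observed labels, enhances the t
#' map with TFCE, and corrects using the permutation distribution of the
#' image-wide maximum |TFCE|: group labels are permuted (covariates kept
#' fixed), the model refit and the maximum recorded; the corrected p of voxel
#' `v` is `count(max_null >= |TFCE_obs(v)|) / n_perm`.
#'
#' @param x Subjects-by-voxels matrix of map values (columns = mask voxels).
#' @param group Two-level factor.
#' @param covariates Optional covariate data frame / matrix.
#' @param mask Logical 3D array locating the columns of `x`.
#' @param params A [tfce_params()].
#' @return List of class `gbc_tfce`: `t`, `tfce`, `p_corrected` (vectors over
#'   mask voxels), `df`, `max_null` (length `n_perm`), `significant` (logical
#'   at `params$alpha`).
#' @export
tfce_correct <- function(x, group, covariates = NULL, mask, params = tfce_params()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  fit <- voxelwise_covariate_ttest(x, group, covariates)
  # fixed integration step across observed and null maps so scores compare
  dh <- params$dh %||% (max(abs(fit$t)) / 100)
  params_fix <- params
  params_fix$dh <- dh
  tf_obs <- tfce_enhance(fit$t, params_fix, mask = mask)

  set.seed(params$seed)
  max_null <- numeric(params$n_perm)
  for (b in seq_len(params$n_perm)) {
    gp <- group[sample(length(group))]
    fb <- voxelwise_covariate_ttest(x, gp, covariates)
    max_null[b] <- max(abs(tfce_enhance(fb$t, params_fix, mask = mask)))
  }
  pv <- vapply(abs(tf_obs), function(s) sum(max_null >= s), numeric(1)) / params$n_perm
  structure(
    list(t = fit$t, tfce = tf_obs, p_corrected = pv, df = fit$df,
         max_null = max_null, significant = pv < params$alpha,
         n_perm = params$n_perm),
    class = "gbc_tfce"
  )
}
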