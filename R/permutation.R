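#' Permutation-test parameters
#'
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param voxel_p_threshold Voxel-level p threshold for discriminative maps
#'   (default 0.001, strict `<`).
#' @param min_cluster_voxels Clusters must be strictly larger than this
#'   (default 30).
#' @param connectivity Neighbourhood for cluster extraction: 6, 18 or 26.
#' @param smoothed_p If `TRUE`, p-values use the (count + 1) / (n_perm + 1)
#'   estimator; the default is the plain count / n_perm rule.
#' @return A list of class `perm_params`.
#' @export
perm_params <- function(n_perm = 1000, seed = 1, voxel_p_threshold = 0.001,
                        min_cluster_voxels = 30, connectivity = 26,
                        smoothed_p = FALSE) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (voxel_p_threshold <= 0 || voxel_p_threshold >= 1) {
    abort("`voxel_p_threshold` must be in (0, 1).")
  }
  structure(
    list(n_perm = as.integer(n_perm), seed = as.integer(seed),
         voxel_p_threshold = voxel_p_threshold,
         min_cluster_voxels = as.integer(min_cluster_voxels),
         connectivity = as.integer(connectivity), smoothed_p = smoothed_p),
    class = "perm_params"
  )
}

perm_pvalue <- function(count, n_perm, smoothed = FALSE) {
  if (smoothed) (count + 1) / (n_perm + 1) else count / n_perm
}

# Precompute per-fold centered kernels, their exact eigen-embeddings and
# (optionally) centered feature matrices once; the LOSOCV fold structure does
# not depend on labels, so permutations reuse them all.
precompute_fold_kernels <- function(x, center = TRUE, want_features = FALSE) {
  n <- nrow(x)
  lapply(seq_len(n), function(i) {
    train <- setdiff(seq_len(n), i)
    kern <- build_linear_kernel(x, train, center = center)
    list(train = train, test = i, K = kern$K, emb = kernel_embedding(kern$K),
         xc = if (want_features) kern$xc else NULL)
  })
}

# LOSOCV over precomputed fold kernels; optionally reconstruct per-fold primal
# weights (binary models). Single-class training folds (possible under label
# permutation) predict the sole class. Returns estimate/score vectors + weights.
losocv_on_kernels <- function(folds, y, model, want_weights = FALSE) {
  n <- length(folds)
  lev <- levels(y)
  est <- character(n)
  score <- rep(NA_real_, n)
  wsum <- NULL
  nw <- 0L
  for (fd in folds) {
    ytr <- y[fd$train]
    if (length(unique(ytr)) < 2) {
      est[fd$test] <- as.character(ytr[1])
      next
    }
    if (model$algorithm == "svm") {
      ytr <- droplevels(ytr)
      fit <- svm_fit_embedded(fd$emb[fd$train, , drop = FALSE], ytr, model$cost)
      s <- fit$decision(fd$emb[fd$test, , drop = FALSE])
      est[fd$test] <- levels(ytr)[ifelse(s >= 0, 1, 2)]
      score[fd$test] <- s
    } else {
      pred <- fit_predict(model, fd$K, ytr, fd$train, fd$test)
      est[fd$test] <- as.character(pred$estimate)
      if (".score" %in% names(pred)) score[fd$test] <- pred$.score
    }
    if (want_weights) {
      w <- fold_weight(model, fd, ytr)
      if (is.null(wsum)) wsum <- w else wsum <- wsum + w
      nw <- nw + 1L
    }
  }
  list(estimate = factor(est, levels = lev), score = score,
       weights = if (want_weights && nw > 0) wsum / nw else NULL)
}

fold_weight <- function(model, fd, ytr) {
  ytr <- droplevels(ytr)
  lev <- levels(ytr)
  if (model$algorithm == "svm") {
    fit <- svm_fit_embedded(fd$emb[fd$train, , drop = FALSE], ytr, model$cost)
    alpha <- fit$alpha
  } else if (model$algorithm == "gpc") {
    Ktr <- fd$K[fd$train, fd$train, drop = FALSE]
    yy <- ifelse(ytr == lev[1], 1, -1)
    alpha <- gpc_laplace_fit(Ktr + 1, yy)$alpha
  } else {
    abort("Weight maps are defined for binary models only.")
  }
  as.vector(crossprod(fd$xc[fd$train, , drop = FALSE], alpha))
}

metrics_vector <- function(truth, estimate) {
  lev <- levels(truth)
  rec <- vapply(lev, function(cl) {
    n_cl <- sum(truth == cl)
    if (n_cl == 0) NA_real_ else sum(truth == cl & estimate == cl) / n_cl
  }, numeric(1))
  out <- c(balanced_accuracy = mean(rec, na.rm = TRUE),
           total_accuracy = mean(truth == estimate))
  if (length(lev) == 2) {
    # the first factor level is the class of interest in a named contrast
    out <- c(out, sensitivity = rec[[1]], specificity = rec[[2]])
  }
  out
}

#' Permutation test of cross-validated classification performance
#'
#' Repeats the full LOSOCV procedure `n_perm` times with group labels
#' uniformly permuted (one permutation per repetition, applied across all
#' folds of that repetition) and computes, per metric,
#' `p = count(null >= observed) / n_perm` — ties count against the observed
#' performance. A count of zero is reported as `p = 0` with label
#' `"< 1/n_perm"`.
#'
#' @param x Subjects-by-features matrix.
#' @param y Group labels (factor or coercible).
#' @param model A [model_spec()].
#' @param params A [perm_params()].
#' @return A list of class `gbc_permtest`: `observed` (named metric vector),
#'   `null` (tibble, one row per permutation), `p` (tibble with metric, p,
#'   label), `n_perm`.
#' @export
permutation_test_performance <- function(x, y, model = model_spec(),
                                         params = perm_params()) {
  eng <- permutation_engine(x, y, model, params, want_weights = FALSE)
  structure(
    list(observed = eng$observed, null = eng$null_metrics, p = eng$p_metrics,
         n_perm = params$n_perm, seed = params$seed),
    class = "gbc_permtest"
  )
}

#' @export
print.gbc_permtest <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations):\n", x$n_perm))
  print(as.data.frame(x$p), row.names = FALSE)
  invisible(x)
}

# Shared permutation engine: one label-permutation stream drives both the
# performance null and (optionally) the voxel-wise weight null.
permutation_engine <- function(x, y, model, params, want_weights) {
  y <- as.factor(y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  folds <- precompute_fold_kernels(x, center = model$center,
                                   want_features = want_weights)
  obs <- losocv_on_kernels(folds, y, model, want_weights = want_weights)
  observed <- metrics_vector(y, obs$estimate)

  set.seed(params$seed)
  nm <- length(observed)
  null_metrics <- matrix(NA_real_, params$n_perm, nm,
                         dimnames = list(NULL, names(observed)))
  # weight maps are compared at unit L2 norm: the raw scale of a max-margin
  # weight vector reflects the margin (small under true labels, large under
  # permuted ones), so only the spatial pattern is exchangeable under the null
  unit_norm <- function(w) {
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w / nrm else w
  }
  wcount <- if (want_weights) numeric(ncol(x)) else NULL
  wobs <- if (want_weights) unit_norm(obs$weights) else NULL
  for (b in seq_len(params$n_perm)) {
    yp <- y[sample(length(y))]
    res <- losocv_on_kernels(folds, yp, model, want_weights = want_weights)
    null_metrics[b, ] <- metrics_vector(yp, res$estimate)
    if (want_weights) {
      wcount <- wcount + (abs(unit_norm(res$weights)) >= abs(wobs))
    }
  }
  counts <- unname(colSums(sweep(null_metrics, 2, observed, ">="), na.rm = TRUE))
  p <- perm_pvalue(counts, params$n_perm, params$smoothed_p)
  p_metrics <- tibble(
    metric = names(observed), observed = unname(observed),
    p = unname(p),
    label = ifelse(counts == 0, sprintf("< %g", 1 / params$n_perm),
                   format(unname(p), digits = 3))
  )
  list(observed = observed, null_metrics = as_tibble(null_metrics),
       p_metrics = p_metrics,
       weights = obs$weights,
       weight_p = if (want_weights) {
         perm_pvalue(wcount, params$n_perm, params$smoothed_p)
       } else NULL)
}

#' Discriminative weight map from cross-validated kernel models
#'
#' Reconstructs, per fold, the primal weight vector `w = sum_i alpha_i x_ci`
#' from the dual coefficients and the fold-centered training features, and
#' averages across folds (option `refit = "full"` fits once on all subjects
#' instead). Positive weights are evidence for the first factor level (the
#' class of interest in a named contrast), i.e. a positive discriminative
#' feature marks voxels where that class has the higher mean value.
#'
#' @param x Subjects-by-features matrix.
#' @param y Binary group labels.
#' @param model A binary [model_spec()].
#' @param refit `"folds"` (default, fold-averaged) or `"full"`.
#' @return Numeric weight vector, one entry per feature.
#' @export
compute_weight_map <- function(x, y, model = model_spec(), refit = c("folds", "full")) {
  refit <- match.arg(refit)
  y <- as.factor(y)
  if (length(levels(y)) != 2) abort("Weight maps are defined for binary models only.")
  if (refit == "full") {
    kern <- build_linear_kernel(x, center = model$center)
    fd <- list(train = seq_len(nrow(x)), K = kern$K,
               emb = kernel_embedding(kern$K), xc = kern$xc)
    return(fold_weight(model, fd, y))
  }
  folds <- precompute_fold_kernels(x, center = model$center, want_features = TRUE)
  losocv_on_kernels(folds, y, model, want_weights = TRUE)$weights
}

#' Voxel-wise permutation significance of discriminative weights
#'
#' Builds the null distribution of each voxel's fold-averaged weight by
#' re-running the cross-validated fit under permuted labels (the same
#' permutation stream as the performance test) and computes the two-sided
#' magnitude p-value `p_v = count(|w_perm| >= |w_obs|) / n_perm`. The sign of
#' the observed weight labels the voxel as a positive or negative
#' discriminative feature.
#'
#' @inheritParams permutation_test_performance
#' @return A list of class `gbc_weightsig`: `weights`, `p`, `sign` (vectors
#'   over features), plus the performance-test results (`performance`).
#' @export
voxelwise_weight_significance <- function(x, y, model = model_spec(),
                                          params = perm_params()) {
  eng <- permutation_engine(x, y, model, params, want_weights = TRUE)
  structure(
    list(weights = eng$weights, p = eng$weight_p, sign = sign(eng$weights),
         performance = tibble::as_tibble(eng$p_metrics),
         n_perm = params$n_perm),
    class = "gbc_weightsig"
  )
}

#' Extract significant discriminative clusters
#'
#' Thresholds the voxel p map (strict `p < voxel_p_threshold`), splits the
#' suprathreshold set by weight sign, labels connected components at the
#' chosen connectivity, and keeps components strictly larger than
#' `min_cluster_voxels`.
#'
#' @param p_map 3D array of voxel p-values (`NA` outside the mask) or a vector
#'   over mask voxels if `mask` is given.
#' @param weight_map 3D array (or mask-vector) of signed weights, same
#'   geometry.
#' @param params A [perm_params()].
#' @param mask Logical 3D array locating the vector entries (needed when maps
#'   are vectors).
#' @param voxel_size_mm Voxel size for centroid coordinates in mm.
#' @return Tibble of class `gbc_clusters`: `cluster_id`, `sign`, `size`,
#'   `peak_x/y/z` (grid indices of the max-|weight| voxel), `centroid_x/y/z`
#'   (mm), and list-column `voxels` of linear indices.
#' @export
extract_clusters <- function(p_map, weight_map, params = perm_params(),
                             mask = NULL, voxel_size_mm = 1) {
  if (!is.null(mask)) {
    pa <- array(NA_real_, dim(mask)); pa[mask] <- p_map
    wa <- array(NA_real_, dim(mask)); wa[mask] <- weight_map
    p_map <- pa; weight_map <- wa
  }
  if (!identical(dim(p_map), dim(weight_map))) abort("Maps must share geometry.")
  dims <- dim(p_map)
  sig <- !is.na(p_map) & p_map < params$voxel_p_threshold
  rows <- list()
  for (sgn in c(1, -1)) {
    part <- sig & !is.na(weight_map) & (sign(weight_map) == sgn)
    lab <- label_components(part, params$connectivity)
    if (max(lab) == 0) next
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      if (length(vox) <= params$min_cluster_voxels) next
      co <- arrayInd(vox, .dim = dims)
      peak <- vox[which.max(abs(weight_map[vox]))]
      pco <- arrayInd(peak, .dim = dims)
      rows[[length(rows) + 1L]] <- tibble(
        sign = if (sgn > 0) "positive" else "negative",
        size = length(vox),
        peak_x = pco[1], peak_y = pco[2], peak_z = pco[3],
        centroid_x = mean(co[, 1]) * voxel_size_mm,
        centroid_y = mean(co[, 2]) * voxel_size_mm,
        centroid_z = mean(co[, 3]) * voxel_size_mm,
        voxels = list(vox)
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    sign = character(), size = integer(),
    peak_x = integer(), peak_y = integer(), peak_z = integer(),
    centroid_x = numeric(), centroid_y = numeric(), centroid_z = numeric(),
    voxels = list()
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$size))
  out <- dplyr::mutate(out, cluster_id = dplyr::row_number(), .before = 1)
  class(out) <- c("gbc_clusters", class(out))
  out
}
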