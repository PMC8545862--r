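#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters plus the contrasts to classify. Default
#' contrasts follow the study design this package emulates: the four-class
#' problem and the four binary contrasts DET vs ET, DET vs DP, DET vs HC and
#' DP vs HC (contrasts whose groups are absent from a cohort are skipped).
#'
#' @param preproc A [preproc_params()].
#' @param qc A [qc_params()].
#' @param gbc A [gbc_params()].
#' @param model A [model_spec()] for binary contrasts.
#' @param contrasts Named list; each element is a character vector of group
#'   labels (length 2 = binary SVM/GPC contrast, longer = multiclass GPC).
#' @param perm A [perm_params()], or `NULL` to skip permutation testing.
#' @param correlation A [correlation_params()].
#' @param cluster_contrast Name of the contrast whose discriminative map is
#'   clustered into ROIs (default `"DET_vs_HC"`).
#' @param clinical_group Group whose HDRS-17 scores are correlated with ROI
#'   GBC (default `"DET"`).
#' @param seed Master seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preproc = preproc_params(), qc = qc_params(),
                            gbc = gbc_params(), model = model_spec("svm"),
                            contrasts = list(
                              four_class = c("DET", "ET", "DP", "HC"),
                              DET_vs_ET = c("DET", "ET"),
                              DET_vs_DP = c("DET", "DP"),
                              DET_vs_HC = c("DET", "HC"),
                              DP_vs_HC = c("DP", "HC")
                            ),
                            perm = NULL,
                            correlation = correlation_params(),
                            cluster_contrast = "DET_vs_HC",
                            clinical_group = "DET",
                            seed = 1) {
  structure(
    list(preproc = preproc, qc = qc, gbc = gbc, model = model,
         contrasts = contrasts, perm = perm, correlation = correlation,
         cluster_contrast = cluster_contrast, clinical_group = clinical_group,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

run_record <- function(stage, params, seed = NULL) {
  list(stage = stage, params = params, seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: initial-volume discard + motion QC, joint nuisance
#' regression/detrend/band-pass, GBC mapping (compute, standardize, smooth),
#' LOSOCV classification per contrast (binary contrasts with the configured
#' model, longer contrasts with multiclass GPC), optional permutation tests,
#' discriminative-weight clustering on the designated contrast, and ROI
#' correlations of mean GBC with HDRS-17 in the clinical group (Pearson and
#' partial, Bonferroni-corrected). Identical config + seed reproduces
#' identical results.
#'
#' @param cohort A cohort tibble ([generate_cohort()] / [load_dataset()]).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; if given, QC, metrics, cluster and
#'   correlation tables are written as TSV/JSON together with per-stage run
#'   records.
#' @return A list of class `gbc_pipeline`: `qc` (tibble), `cohort` (with
#'   cleaned images and GBC maps), `cv` (list of `gbc_cv` per contrast),
#'   `metrics` (tibble over contrasts and classes), `permutation` (tibble or
#'   NULL), `clusters` (`gbc_clusters`), `correlations` (tibble), and
#'   `records` (run records).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), output_dir = NULL) {
  records <- list()
  # stage 1-2: discard, FD QC, cleaning
  pp <- preprocess_cohort(cohort, config$preproc, config$qc)
  records <- c(records, list(run_record("preprocess_qc",
                                        c(unclass(config$preproc), unclass(config$qc)))))
  qc_tab <- pp[, c("subject_id", "group", "mean_fd_mm", "n_flagged",
                   "flag_fraction", "qc_pass")]
  qc_tab <- as_tibble(qc_tab)

  # stage 3: GBC maps
  pp <- compute_gbc_maps(pp, config$gbc)
  records <- c(records, list(run_record("gbc_mapping", unclass(config$gbc))))

  # stage 4: classification per contrast
  present <- levels(droplevels(pp$group))
  cvs <- list()
  met_rows <- list()
  perm_rows <- list()
  for (nm in names(config$contrasts)) {
    gs <- config$contrasts[[nm]]
    if (!all(gs %in% present)) next
    model <- if (length(gs) == 2) config$model else model_spec("gpc-multi")
    cv <- classify_cohort(pp, gs, model)
    cvs[[nm]] <- cv
    met <- compute_metrics(cv)
    met_rows[[nm]] <- dplyr::mutate(
      met$per_class,
      balanced_accuracy = met$overall$balanced_accuracy,
      total_accuracy = met$overall$total_accuracy,
      auc = met$overall$auc,
      contrast = nm, .before = 1
    )
    if (!is.null(config$perm)) {
      sub <- pp[pp$group %in% gs, , drop = FALSE]
      x <- do.call(rbind, lapply(sub$gbc, gbc_values))
      rownames(x) <- sub$subject_id
      y <- factor(as.character(sub$group), levels = gs)
      pt <- permutation_test_performance(x, y, model, config$perm)
      perm_rows[[nm]] <- dplyr::mutate(pt$p, contrast = nm, .before = 1)
    }
    records <- c(records, list(run_record(paste0("mvpa_", nm),
                                          unclass(model), config$seed)))
  }
  metrics <- dplyr::bind_rows(met_rows)
  permutation <- if (length(perm_rows)) dplyr::bind_rows(perm_rows) else NULL

  # stage 5: discriminative clusters + ROI correlations
  clusters <- NULL
  correlations <- NULL
  cc <- config$cluster_contrast
  if (!is.null(cc) && cc %in% names(cvs) && length(config$contrasts[[cc]]) == 2 &&
      !is.null(config$perm)) {
    gs <- config$contrasts[[cc]]
    sub <- pp[pp$group %in% gs, , drop = FALSE]
    x <- do.call(rbind, lapply(sub$gbc, gbc_values))
    y <- factor(as.character(sub$group), levels = gs)
    ws <- voxelwise_weight_significance(x, y, config$model, config$perm)
    masks <- cohort_masks(pp)
    clusters <- extract_clusters(ws$p, ws$weights, config$perm,
                                 mask = masks$gm,
                                 voxel_size_mm = pp$image[[1]]$voxel_size_mm)
    records <- c(records, list(run_record("permutation_inference",
                                          unclass(config$perm), config$perm$seed)))
    if (nrow(clusters) > 0 && config$clinical_group %in% present) {
      cg <- pp[pp$group == config$clinical_group, , drop = FALSE]
      cp <- config$correlation
      cp$n_rois <- max(nrow(clusters), 2L)
      covs <- as.data.frame(cg[, c("age", "education_years", "mmse", "hars14")])
      do_partial <- nrow(cg) >= 3 + ncol(covs)
      if (!do_partial) {
        warn("Too few clinical-group subjects for the partial correlation; reporting Pearson only.")
      }
      corr_rows <- lapply(seq_len(nrow(clusters)), function(i) {
        rv <- roi_mean_values(cg, clusters$voxels[[i]])
        plain <- dplyr::mutate(correlate(rv$roi_mean, cg$hdrs17, params = cp),
                               type = "pearson", .before = 1)
        out <- if (do_partial) {
          part <- correlate(rv$roi_mean, cg$hdrs17, covariates = covs, params = cp)
          dplyr::bind_rows(plain, dplyr::mutate(part, type = "partial", .before = 1))
        } else plain
        dplyr::mutate(out, cluster_id = clusters$cluster_id[i], .before = 1)
      })
      correlations <- dplyr::bind_rows(corr_rows)
      records <- c(records, list(run_record("roi_statistics", unclass(cp))))
    }
  }

  result <- structure(
    list(qc = qc_tab, cohort = pp, cv = cvs, metrics = metrics,
         permutation = permutation, clusters = clusters,
         correlations = correlations, records = records),
    class = "gbc_pipeline"
  )
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(result$qc), file.path(dir, "qc_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(result$permutation)) {
    jsonlite::write_json(result$permutation, file.path(dir, "permutation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (!is.null(result$clusters) && nrow(result$clusters) > 0) {
    ct <- as.data.frame(result$clusters[, setdiff(names(result$clusters), "voxels")])
    utils::write.table(ct, file.path(dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$correlations)) {
    jsonlite::write_json(result$correlations, file.path(dir, "correlations.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  # run records carry timestamps and live in their own file so result files
  # stay byte-identical across reruns with the same seed
  jsonlite::write_json(result$records, file.path(dir, "run_records.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.gbc_pipeline <- function(x, ...) {
  cat(sprintf("<gbc_pipeline> %d subjects, %d contrasts\n",
              nrow(x$cohort), length(x$cv)))
  if (nrow(x$metrics) > 0) {
    ov <- dplyr::distinct(x$metrics[, c("contrast", "balanced_accuracy", "total_accuracy")])
    print(as.data.frame(ov), row.names = FALSE, digits = 4)
  }
  invisible(x)
}
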