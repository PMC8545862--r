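#' Classifier specification
#'
#' @param algorithm `"svm"` (binary soft-margin SVM on the precomputed linear
#'   kernel), `"gpc"` (binary Gaussian process classifier, linear covariance
#'   plus bias, Laplace approximation, logistic likelihood) or `"gpc-multi"`
#'   (multiclass GPC as one-vs-rest binary GPCs with normalized
#'   probabilities).
#' @param cost SVM soft-margin cost (default 1).
#' @param center If `TRUE` (default), features are mean-centered using the
#'   training rows only, within every cross-validation fold.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("svm", "gpc", "gpc-multi"),
                       cost = 1, center = TRUE) {
  algorithm <- match.arg(algorithm)
  if (cost <= 0) abort("`cost` must be positive.")
  structure(list(algorithm = algorithm, cost = cost, center = isTRUE(center)),
            class = "model_spec")
}

#' Linear kernel with train-fold mean-centering
#'
#' Computes feature means on the training rows only, subtracts them from all
#' rows, and returns the inner-product (linear) kernel of the centered rows.
#' After centering on the full set, every kernel row sums to zero over the
#' training rows.
#'
#' @param x Subjects-by-features matrix.
#' @param train_index Row indices of the training set (non-empty).
#' @param center Apply train-mean centering (default `TRUE`).
#' @return List with `K` (n x n kernel), `xc` (centered features) and
#'   `center` (the training means used).
#' @export
build_linear_kernel <- function(x, train_index = seq_len(nrow(x)), center = TRUE) {
  if (length(train_index) == 0) abort("Training set must be non-empty.")
  mu <- if (center) colMeans(x[train_index, , drop = FALSE]) else rep(0, ncol(x))
  xc <- sweep(x, 2, mu, "-")
  list(K = tcrossprod(xc), xc = xc, center = mu)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary GPC, Laplace approximation, logistic likelihood, on a precomputed
# covariance (Rasmussen & Williams alg. 3.1/3.2). y in {-1, +1}.
gpc_laplace_fit <- function(K, y, jitter = 1e-8, max_iter = 50, tol = 1e-8) {
  n <- length(y)
  K <- K + diag(jitter, n)
  f <- numeric(n)
  obj_old <- -Inf
  for (it in seq_len(max_iter)) {
    pi_ <- sigmoid(f)
    W <- pi_ * (1 - pi_)
    sw <- sqrt(W)
    B <- diag(n) + (sw %o% sw) * K
    L <- chol(B)
    b <- W * f + (y + 1) / 2 - pi_
    a <- b - sw * backsolve(L, forwardsolve(t(L), sw * (K %*% b)))
    f <- as.vector(K %*% a)
    obj <- -0.5 * sum(a * f) + sum(-log1p(exp(-y * f)))
    if (abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  pi_ <- sigmoid(f)
  list(f = f, alpha = (y + 1) / 2 - pi_, W = pi_ * (1 - pi_), K = K, L = chol(
    diag(n) + (sqrt(pi_ * (1 - pi_)) %o% sqrt(pi_ * (1 - pi_))) * K))
}

# Predictive class-1 probability for test rows given cross-kernel ktest
# (n_test x n_train) and the test self-kernel diagonal.
gpc_laplace_predict <- function(fit, ktest, kself) {
  fmean <- as.vector(ktest %*% fit$alpha)
  sw <- sqrt(fit$W)
  prob <- numeric(nrow(ktest))
  for (i in seq_len(nrow(ktest))) {
    v <- forwardsolve(t(fit$L), sw * ktest[i, ])
    fvar <- max(kself[i] - sum(v^2), 1e-12)
    # MacKay's approximation to the logistic-Gaussian integral
    prob[i] <- sigmoid(fmean[i] / sqrt(1 + pi * fvar / 8))
  }
  list(prob = prob, fmean = fmean)
}

# Exact finite-dimensional embedding of a PSD kernel matrix: rows e_i with
# e_i . e_j = K_ij. Lets the soft-margin dual be solved by libsvm's linear
# mode at a fraction of the cost of a precomputed-kernel interface.
kernel_embedding <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(lam), length(lam))
}

# Fit a binary soft-margin SVM in an embedding of the (centered) linear
# kernel; returns the dual coefficients over training rows plus a decision
# closure on embedded test rows. Scores are oriented so larger = first level
# (the class of interest in a named contrast).
svm_fit_embedded <- function(emb_train, y, cost) {
  lev <- levels(y)
  fit <- e1071::svm(emb_train, y, type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = 1e-6)
  w_emb <- as.vector(t(fit$coefs) %*% emb_train[fit$index, , drop = FALSE])
  dec_train <- as.vector(emb_train %*% w_emb) - fit$rho
  # libsvm orients the decision value by its internal label coding; calibrate
  # the sign against the training-set decision values.
  sgn <- ifelse(mean(dec_train[y == lev[1]]) >= mean(dec_train[y == lev[2]]), 1, -1)
  alpha <- numeric(nrow(emb_train))
  alpha[fit$index] <- sgn * as.vector(fit$coefs)
  list(
    alpha = alpha, levels = lev,
    decision = function(emb_test) {
      sgn * (as.vector(emb_test %*% w_emb) - fit$rho)
    }
  )
}

#' Fit a classifier on a precomputed kernel and predict test rows
#'
#' @param model A [model_spec()].
#' @param K Full kernel matrix (train + test rows, from
#'   [build_linear_kernel()]).
#' @param y Factor of labels for the training rows.
#' @param train_index,test_index Row indices into `K`.
#' @return Tibble with one row per test case: `estimate` (factor) and class
#'   scores (`.score` for binary: larger favours the first factor level, the
#'   class of interest in a named contrast; `.prob_<class>` columns for GPC).
#' @export
fit_predict <- function(model, K, y, train_index, test_index) {
  y <- droplevels(as.factor(y))
  if (length(unique(y)) < 2) abort("Training set must contain at least 2 classes.")
  lev <- levels(y)
  Ktr <- K[train_index, train_index, drop = FALSE]
  Kte <- K[test_index, train_index, drop = FALSE]
  kself <- diag(K)[test_index]

  if (model$algorithm == "svm") {
    if (length(lev) != 2) abort("Binary SVM requires exactly 2 classes.")
    emb <- kernel_embedding(K)
    fit <- svm_fit_embedded(emb[train_index, , drop = FALSE], y, model$cost)
    s <- fit$decision(emb[test_index, , drop = FALSE])
    tibble(estimate = factor(lev[ifelse(s >= 0, 1, 2)], levels = lev), .score = s)
  } else if (model$algorithm == "gpc") {
    if (length(lev) != 2) abort("Binary GPC requires exactly 2 classes.")
    yy <- ifelse(y == lev[1], 1, -1)
    fit <- gpc_laplace_fit(Ktr + 1, yy)  # +1: bias term in the covariance
    pr <- gpc_laplace_predict(fit, Kte + 1, kself + 1)$prob
    out <- tibble(
      estimate = factor(lev[ifelse(pr >= 0.5, 1, 2)], levels = lev),
      .score = pr
    )
    out[[paste0(".prob_", lev[1])]] <- pr
    out[[paste0(".prob_", lev[2])]] <- 1 - pr
    out
  } else {
    # one-vs-rest multiclass GPC with normalized probabilities
    probs <- sapply(lev, function(cl) {
      yy <- ifelse(y == cl, 1, -1)
      fit <- gpc_laplace_fit(Ktr + 1, yy)
      gpc_laplace_predict(fit, Kte + 1, kself + 1)$prob
    })
    probs <- matrix(probs, nrow = length(test_index), dimnames = list(NULL, lev))
    probs <- probs / rowSums(probs)
    # ties broken by fixed class-label order (first maximum)
    est <- lev[apply(probs, 1, which.max)]
    out <- tibble(estimate = factor(est, levels = lev))
    for (cl in lev) out[[paste0(".prob_", cl)]] <- probs[, cl]
    out
  }
}

#' Leave-one-subject-out cross-validation
#'
#' Holds out each subject once; feature centering (training rows only) and all
#' model fitting are recomputed inside every fold, so no information from the
#' held-out subject reaches training.
#'
#' @param x Subjects-by-features matrix (rownames used as subject ids).
#' @param y Factor (or coercible) of group labels, >= 2 subjects per class.
#' @param model A [model_spec()].
#' @return A tibble of class `gbc_cv`: one row per fold with `fold`,
#'   `subject_id`, `truth`, `estimate` and score columns.
#' @export
run_losocv <- function(x, y, model = model_spec()) {
  y <- as.factor(y)
  if (any(table(y) < 2)) abort("Every class needs at least 2 subjects for LOSOCV.")
  n <- nrow(x)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    kern <- build_linear_kernel(x, train, center = model$center)
    pred <- fit_predict(model, kern$K, y[train], train, i)
    rows[[i]] <- dplyr::bind_cols(
      tibble(fold = i,
             subject_id = rownames(x)[i] %||% as.character(i),
             truth = y[i]),
      pred
    )
  }
  out <- dplyr::bind_rows(rows)
  out$truth <- factor(out$truth, levels = levels(y))
  attr(out, "model") <- model
  attr(out, "levels") <- levels(y)
  class(out) <- c("gbc_cv", class(out))
  out
}

#' Classification performance metrics
#'
#' Per-class (one-vs-rest) sensitivity/recall, specificity, accuracy, positive
#' and negative predictive values; balanced accuracy (unweighted mean of
#' per-class recalls); total accuracy (correct / total); and, for binary
#' results with scores, the pooled-score ROC curve and its area.
#'
#' @param cv A `gbc_cv` from [run_losocv()].
#' @return A list of class `metrics_report`: `per_class` tibble, `overall`
#'   one-row tibble, and (binary only) `roc` tibble of curve points.
#' @export
compute_metrics <- function(cv) {
  if (anyNA(cv$estimate)) abort("Every subject must have a prediction.")
  lev <- attr(cv, "levels") %||% levels(cv$truth)
  truth <- factor(cv$truth, levels = lev)
  est <- factor(cv$estimate, levels = lev)
  per <- purrr::map(lev, function(cl) {
    tp <- sum(truth == cl & est == cl)
    fn <- sum(truth == cl & est != cl)
    fp <- sum(truth != cl & est == cl)
    tn <- sum(truth != cl & est != cl)
    tibble(
      class = cl,
      n = tp + fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      accuracy = (tp + tn) / length(truth),
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
    )
  })
  per <- dplyr::bind_rows(per)
  overall <- tibble(
    balanced_accuracy = mean(per$sensitivity, na.rm = TRUE),
    total_accuracy = mean(truth == est),
    auc = NA_real_
  )
  roc_tab <- NULL
  if (length(lev) == 2 && ".score" %in% names(cv)) {
    r <- pROC::roc(response = truth, predictor = cv$.score,
                   levels = c(lev[2], lev[1]), direction = "<", quiet = TRUE)
    overall$auc <- as.numeric(pROC::auc(r))
    roc_tab <- tibble(
      threshold = r$thresholds,
      sensitivity = r$sensitivities,
      specificity = r$specificities
    )
  }
  structure(list(per_class = per, overall = overall, roc = roc_tab),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification metrics (proportions):\n")
  print(as.data.frame(x$per_class), row.names = FALSE, digits = 4)
  cat(sprintf("balanced accuracy %.4f | total accuracy %.4f",
              x$overall$balanced_accuracy, x$overall$total_accuracy))
  if (!is.na(x$overall$auc)) cat(sprintf(" | AUC %.4f", x$overall$auc))
  cat("\n")
  invisible(x)
}

#' Run a two-group (or multiclass) classification on a cohort
#'
#' Convenience wrapper: subsets the cohort to `groups`, extracts the GBC
#' feature matrix and runs [run_losocv()].
#'
#' @param cohort A cohort with GBC maps (see [compute_gbc_maps()]).
#' @param groups Character vector of group labels to include (order fixes the
#'   factor level order; 2 labels for binary models).
#' @param model A [model_spec()].
#' @return A `gbc_cv` tibble.
#' @export
classify_cohort <- function(cohort, groups, model = model_spec()) {
  keep <- cohort$group %in% groups
  sub <- cohort[keep, , drop = FALSE]
  x <- do.call(rbind, lapply(sub$gbc, gbc_values))
  rownames(x) <- sub$subject_id
  y <- factor(as.character(sub$group), levels = groups)
  run_losocv(x, y, model)
}
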