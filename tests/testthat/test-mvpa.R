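test_that("linear kernel centering uses training rows only", {
  # orthogonal unit-norm subjects, no centering: identity kernel
  x <- diag(2)
  k <- build_linear_kernel(x, center = FALSE)
  expect_equal(k$K, diag(2))

  # hand-computed 3x2 example
  xh <- matrix(c(1, 2, 0, 3, -1, 1), nrow = 3, byrow = TRUE)
  kh <- build_linear_kernel(xh, center = FALSE)$K
  expect_equal(kh, tcrossprod(xh))
  expect_equal(kh[1, 2], 1 * 0 + 2 * 3)

  # after centering on the full set every kernel row sums to zero
  set.seed(2)
  xr <- matrix(rnorm(5 * 4), 5)
  kc <- build_linear_kernel(xr)$K
  expect_lt(max(abs(rowSums(kc))), 1e-10)

  # centering means come from the training rows only
  kt <- build_linear_kernel(xr, train_index = 1:3)
  expect_equal(kt$center, colMeans(xr[1:3, ]))
  expect_error(build_linear_kernel(xr, integer(0)), "non-empty")
})

test_that("classifiers solve trivially separable problems and honour symmetry", {
  # two training subjects at -1 / +1, test at +0.5: positive class
  xs <- matrix(c(-1, 1, 0.5), ncol = 1)
  y <- factor(c("neg", "pos"), levels = c("pos", "neg"))
  K <- tcrossprod(xs)
  pr <- fit_predict(model_spec("svm"), K, y, 1:2, 3)
  expect_identical(as.character(pr$estimate), "pos")

  # GPC test point equidistant from two symmetric training sets: prob 0.5
  xg <- matrix(c(-1, -1.1, 1, 1.1, 0), ncol = 1)
  yg <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  Kg <- tcrossprod(xg)
  prg <- fit_predict(model_spec("gpc"), Kg, yg, 1:4, 5)
  expect_equal(prg$.score, 0.5, tolerance = 0.01)

  # GPC probabilities are proper and favour the right class when separable
  prs <- fit_predict(model_spec("gpc"), K, y, 1:2, 3)
  expect_identical(as.character(prs$estimate), "pos")
  expect_equal(prs$.prob_pos + prs$.prob_neg, 1, tolerance = 1e-12)

  # three well-separated clusters: perfect multiclass LOSOCV
  set.seed(8)
  x3 <- matrix(rnorm(30 * 2, sd = 0.5), 30)
  x3[1:10, 1] <- x3[1:10, 1] + 5
  x3[11:20, 2] <- x3[11:20, 2] + 5
  rownames(x3) <- paste0("s", 1:30)
  y3 <- factor(rep(c("A", "B", "C"), each = 10))
  cv3 <- run_losocv(x3, y3, model_spec("gpc-multi"))
  expect_equal(mean(cv3$truth == cv3$estimate), 1)
  pcols <- paste0(".prob_", levels(y3))
  expect_equal(rowSums(as.matrix(cv3[, pcols])), rep(1, 30), tolerance = 1e-9)

  expect_error(fit_predict(model_spec("svm"), Kg, factor(rep("a", 4)), 1:4, 5),
               "2 classes")
})

test_that("LOSOCV holds out every subject exactly once without leakage", {
  set.seed(12)
  x <- matrix(rnorm(12 * 6), 12)
  rownames(x) <- sprintf("sub%02d", 1:12)
  y <- factor(rep(c("A", "B"), each = 6))
  cv <- run_losocv(x, y, model_spec("svm"))
  expect_identical(nrow(cv), 12L)
  expect_identical(sort(cv$subject_id), sort(rownames(x)))
  expect_identical(anyDuplicated(cv$subject_id), 0L)

  # leakage sentinel: fold i's model is a pure function of the other rows;
  # rebuilding it by hand (train rows only) reproduces the fold prediction
  for (i in c(1, 7)) {
    train <- setdiff(1:12, i)
    kern <- build_linear_kernel(x, train)
    pred <- fit_predict(model_spec("svm"), kern$K, y[train], train, i)
    expect_identical(as.character(pred$estimate), as.character(cv$estimate[i]))
    expect_equal(pred$.score, cv$.score[i], tolerance = 1e-8)
  }

  # and replacing the held-out row's features cannot change training means
  x2 <- x
  x2[3, ] <- 1e3
  k1 <- build_linear_kernel(x, setdiff(1:12, 3))
  k2 <- build_linear_kernel(x2, setdiff(1:12, 3))
  expect_identical(k1$center, k2$center)
  expect_identical(k1$K[-3, -3], k2$K[-3, -3])

  expect_error(run_losocv(x[1:7, ], factor(c(rep("A", 6), "B")), model_spec("svm")),
               "at least 2 subjects")
})

test_that("kernel-route SVM matches an independent precomputed-kernel solver", {
  skip_if_not_installed("kernlab")
  set.seed(33)
  x <- matrix(rnorm(14 * 10), 14)
  x[1:7, ] <- x[1:7, ] + 1
  y <- factor(rep(c("P", "Q"), each = 7))
  kern <- build_linear_kernel(x, 1:14)
  ours <- fit_predict(model_spec("svm"), kern$K, y, 1:14, 1:14)

  kl <- kernlab::ksvm(kernlab::as.kernelMatrix(kern$K), y, type = "C-svc",
                      C = 1, scaled = FALSE)
  theirs <- kernlab::predict(kl, kernlab::as.kernelMatrix(
    kern$K[, kernlab::SVindex(kl), drop = FALSE]))
  expect_identical(as.character(ours$estimate), as.character(theirs))
})

test_that("metrics reproduce the confusion-matrix arithmetic", {
  # 31/41 positives and 43/43 negatives correct
  truth <- factor(rep(c("DET", "HC"), c(41, 43)), levels = c("DET", "HC"))
  est <- factor(c(rep("DET", 31), rep("HC", 10), rep("HC", 43)),
                levels = c("DET", "HC"))
  cv <- tibble::tibble(fold = seq_along(truth),
                       subject_id = as.character(seq_along(truth)),
                       truth = truth, estimate = est)
  attr(cv, "levels") <- c("DET", "HC")
  class(cv) <- c("gbc_cv", class(cv))
  m <- compute_metrics(cv)
  expect_equal(round(100 * m$per_class$sensitivity[1], 2), 75.61)
  expect_equal(m$per_class$specificity[1], 1)
  expect_equal(round(100 * m$overall$balanced_accuracy, 2), 87.80)
  expect_equal(m$per_class$ppv[1], 1)
  expect_equal(m$per_class$npv[1], 43 / 53)
  expect_equal(m$overall$total_accuracy, 74 / 84)

  # four-class: 29 of 41 class-1 subjects correct gives 70.73 % sensitivity
  t4 <- factor(rep(c("DET", "ET", "DP", "HC"), c(41, 9, 9, 9)),
               levels = c("DET", "ET", "DP", "HC"))
  e4 <- t4
  e4[1:12] <- "ET"   # 12 DET subjects misclassified
  cv4 <- tibble::tibble(fold = seq_along(t4),
                        subject_id = as.character(seq_along(t4)),
                        truth = t4, estimate = e4)
  attr(cv4, "levels") <- levels(t4)
  class(cv4) <- c("gbc_cv", class(cv4))
  m4 <- compute_metrics(cv4)
  expect_equal(round(100 * m4$per_class$sensitivity[1], 2), 70.73)

  # perfect predictions: every reported measure is 1
  cvp <- cv
  cvp$estimate <- cvp$truth
  mp <- compute_metrics(cvp)
  expect_true(all(unlist(mp$per_class[, c("sensitivity", "specificity",
                                          "accuracy", "ppv", "npv")]) == 1))
  expect_equal(mp$overall$balanced_accuracy, 1)

  cvna <- cv
  cvna$estimate[1] <- NA
  expect_error(compute_metrics(cvna), "prediction")
})

test_that("ROC area is invariant to strictly increasing score transforms", {
  set.seed(44)
  x <- matrix(rnorm(16 * 5), 16)
  x[1:8, ] <- x[1:8, ] + 0.8
  rownames(x) <- paste0("r", 1:16)
  y <- factor(rep(c("A", "B"), each = 8))
  cv <- run_losocv(x, y, model_spec("svm"))
  m1 <- compute_metrics(cv)
  cv2 <- cv
  cv2$.score <- exp(3 * cv2$.score) + 5   # strictly increasing transform
  m2 <- compute_metrics(cv2)
  expect_equal(m1$overall$auc, m2$overall$auc, tolerance = 1e-12)
})

test_that("null features give chance-level LOSOCV accuracy over many seeds", {
  # pooled over 24 seeds; the band is the 99.7 % (3 sigma) binomial band
  # around chance, wide enough to absorb the known slight pessimism of
  # leave-one-out CV with fold-wise centering
  n <- 16
  bas <- vapply(1:24, function(s) {
    x <- noise_features(n, 60, seed = 1000 + s)
    y <- factor(rep(c("A", "B"), each = n / 2))
    compute_metrics(run_losocv(x, y, model_spec("svm")))$overall$balanced_accuracy
  }, numeric(1))
  pooled <- mean(bas)
  band <- 3 * sqrt(0.25 / (24 * n))
  expect_gt(pooled, 0.5 - band)
  expect_lt(pooled, 0.5 + band)

  # four-class chance is 0.25
  bas4 <- vapply(1:20, function(s) {
    x <- noise_features(16, 40, seed = 2000 + s)
    y <- factor(rep(c("A", "B", "C", "D"), each = 4))
    compute_metrics(run_losocv(x, y, model_spec("gpc-multi")))$overall$balanced_accuracy
  }, numeric(1))
  band4 <- 3 * sqrt(0.25 * 0.75 / (20 * 16))
  expect_gt(mean(bas4), 0.25 - band4)
  expect_lt(mean(bas4), 0.25 + band4)
})
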