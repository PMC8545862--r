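fake_map <- function(values3d, mask) {
  structure(list(data = values3d, mask = mask, voxel_size_mm = 3,
                 params = NULL, subject_id = NULL), class = "gbc_map")
}

test_that("ROI means are plain arithmetic means over the cluster voxels", {
  masks <- small_masks(c(8, 8, 8))
  gm_idx <- which(masks$gm)

  const <- array(NA_real_, c(8, 8, 8))
  const[masks$gm] <- 3.3
  m1 <- fake_map(const, masks$gm)

  two <- array(NA_real_, c(8, 8, 8))
  two[masks$gm] <- 0
  two[gm_idx[1]] <- 1
  two[gm_idx[2]] <- 3
  m2 <- fake_map(two, masks$gm)

  expect_equal(roi_mean_values(list(m1), gm_idx[1:5])$roi_mean, 3.3)
  expect_equal(roi_mean_values(list(m2), gm_idx[1:2])$roi_mean, 2)

  set.seed(3)
  rnd <- array(NA_real_, c(8, 8, 8))
  rnd[masks$gm] <- rnorm(sum(masks$gm))
  roi <- sample(gm_idx, 17)
  expect_equal(roi_mean_values(list(fake_map(rnd, masks$gm)), roi)$roi_mean,
               mean(rnd[roi]))
  expect_error(roi_mean_values(list(m1), integer(0)), "empty")
})

test_that("correlations (plain and partial) and the printed Bonferroni rule", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)

  y <- c(2, 1, 4, 3, 5)
  res <- correlate(x, y)
  expect_equal(res$r, 0.8)
  ct <- stats::cor.test(x, y)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)

  # the pairwise-denominator threshold: 0.05 / (12 * 11 / 2) = 0.05 / 66
  expect_equal(res$threshold, 0.05 / 66)
  expect_equal(res$threshold, 7.576e-4, tolerance = 1e-3)
  expect_equal(correlate(x, y, params = correlation_params(rule = "per-roi"))$threshold,
               0.05 / 12)

  # empty covariate set reduces exactly to Pearson
  set.seed(14)
  a <- rnorm(20)
  b <- 0.5 * a + rnorm(20)
  covs <- data.frame(c1 = rnorm(20), c2 = rnorm(20))
  expect_identical(correlate(a, b)$r, cor(a, b))
  part <- correlate(a, b, covariates = covs)
  expect_identical(part$df, 20L - 2L - 2L)

  # partial r equals the residual-correlation definition
  ra <- stats::resid(stats::lm(a ~ ., data = covs))
  rb <- stats::resid(stats::lm(b ~ ., data = covs))
  expect_equal(part$r, cor(ra, rb), tolerance = 1e-12)

  expect_error(correlate(rep(1, 5), y), "variance")
  expect_error(correlate(1:3, c(1, 2, 3), covariates = data.frame(q = 1:3)),
               "few observations")
})

test_that("summary-statistic ANOVA matches raw-data ANOVA and known identities", {
  expect_equal(anova_from_summary(c(2, 2, 2), c(1, 2, 1.5), c(5, 5, 5))$F, 0)

  # two groups: F equals the squared pooled two-sample t
  set.seed(6)
  g1 <- rnorm(8, 1)
  g2 <- rnorm(11, 0)
  f2 <- anova_from_summary(c(mean(g1), mean(g2)), c(sd(g1), sd(g2)), c(8, 11))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(f2$F, unname(tt$statistic)^2, tolerance = 1e-12)

  # oracle: summaries computed from raw data reproduce aov() exactly
  g <- rep(1:4, c(6, 7, 5, 8))
  v <- rnorm(26, mean = g / 2)
  ao <- anova_from_summary(tapply(v, g, mean), tapply(v, g, sd), tabulate(g))
  raw <- summary(stats::aov(v ~ factor(g)))[[1]]
  expect_equal(ao$F, raw$`F value`[1], tolerance = 1e-10)
  expect_equal(ao$p, raw$`Pr(>F)`[1], tolerance = 1e-10)

  # group summaries of the emulated study's scrubbing counts give F ~ 0.26
  f_scrub <- anova_from_summary(c(13.6585, 13.6829, 13.6976, 14.5556),
                                c(6.3270, 5.5337, 5.1248, 5.6510),
                                c(41, 49, 45, 43))
  expect_equal(f_scrub$F, 0.26, tolerance = 0.01)
  expect_identical(c(f_scrub$df1, f_scrub$df2), c(3, 174))

  expect_error(anova_from_summary(c(1, 2), c(-1, 1), c(5, 5)), "non-negative")
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("voxel-wise covariate t maps agree with classical and lm oracles", {
  set.seed(23)
  n <- 16
  x <- matrix(rnorm(n * 8), n)
  group <- factor(rep(c("A", "B"), each = n / 2))

  # without covariates: classical pooled two-sample t, voxel by voxel
  fit <- voxelwise_covariate_ttest(x, group)
  for (v in c(1, 5)) {
    tt <- stats::t.test(x[group == "B", v], x[group == "A", v], var.equal = TRUE)
    expect_equal(fit$t[v], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_identical(fit$df, as.integer(n - 2))

  # with covariates: equals lm() per voxel
  covs <- data.frame(age = rnorm(n), edu = rnorm(n))
  fit2 <- voxelwise_covariate_ttest(x, group, covs)
  lmfit <- stats::lm(x[, 3] ~ group + age + edu, data = covs)
  expect_equal(fit2$t[3], summary(lmfit)$coefficients["groupB", "t value"],
               tolerance = 1e-10)

  # a covariate orthogonal to both group and data leaves the effect unchanged
  g_num <- as.numeric(group == "B")
  base <- cbind(1, g_num, x)
  cov_orth <- qr.resid(qr(base), rnorm(n))
  fit3 <- voxelwise_covariate_ttest(x, group, matrix(cov_orth))
  expect_equal(fit3$coef, fit$coef, tolerance = 1e-10)
  expect_equal(fit3$t * sqrt(fit$df / fit3$df), fit$t, tolerance = 1e-10)

  expect_error(voxelwise_covariate_ttest(x, group, matrix(g_num)),
               "rank deficient")
})

test_that("TFCE has the closed-form single-voxel value and is monotone", {
  dims <- c(5, 5, 5)
  zero <- array(0, dims)
  expect_true(all(tfce_enhance(zero) == 0))

  single <- array(0, dims)
  single[3, 3, 3] <- 1
  tf <- tfce_enhance(single, tfce_params(dh = 0.01))
  # sum over h of 1^0.5 * h^2 * dh ~ integral_0^1 h^2 dh = 1/3
  expect_equal(tf[3, 3, 3], 1 / 3, tolerance = 0.02)
  expect_true(all(tf[-which(single == 1)] == 0))

  # raising any voxel's statistic never decreases any TFCE score
  set.seed(83)
  base <- array(abs(rnorm(prod(dims))), dims)
  pars <- tfce_params(dh = 0.05)
  t0 <- tfce_enhance(base, pars)
  for (k in 1:3) {
    bumped <- base
    v <- sample(prod(dims), 1)
    bumped[v] <- bumped[v] + runif(1, 0.5, 1.5)
    t1 <- tfce_enhance(bumped, pars)
    expect_true(all(t1 - t0 >= -1e-10))
  }

  # negative statistics are enhanced symmetrically with their sign kept
  neg <- array(0, dims)
  neg[2, 2, 2] <- -1
  tfn <- tfce_enhance(neg, tfce_params(dh = 0.01))
  expect_equal(tfn[2, 2, 2], -1 / 3, tolerance = 0.02)
})

test_that("TFCE max-statistic correction controls family-wise error", {
  # under a pure null, P(any corrected p = 0 at 19 permutations) = 1/20 by
  # exchangeability of the observed maximum with the 19 null maxima
  masks <- small_masks(c(6, 6, 6))
  nvox <- sum(masks$gm)
  runs <- 24
  hits <- vapply(seq_len(runs), function(s) {
    set.seed(400 + s)
    x <- matrix(rnorm(12 * nvox), 12)
    g <- factor(rep(c("A", "B"), each = 6))
    res <- tfce_correct(x, g, mask = masks$gm,
                        params = tfce_params(n_perm = 19, seed = s, dh = NULL))
    any(res$p_corrected[!is.na(res$p_corrected)] <= 0.05)
  }, logical(1))
  fw <- mean(hits)
  se <- sqrt(0.05 * 0.95 / runs)
  expect_lte(fw, 0.05 + 3 * se)

  # corrected p values are multiples of 1/n_perm
  set.seed(500)
  x <- matrix(rnorm(12 * nvox), 12)
  g <- factor(rep(c("A", "B"), each = 6))
  res <- tfce_correct(x, g, mask = masks$gm,
                      params = tfce_params(n_perm = 10, seed = 2))
  pv <- res$p_corrected
  expect_true(all(abs(pv * 10 - round(pv * 10)) < 1e-9))
})

test_that("a planted clinical correlation is found only when the slope is real", {
  pars <- correlation_params()   # printed rule: 0.05 / 66
  pp_hi <- clinical_cohort(slope = 30, noise_sd = 1)
  rv <- roi_mean_values(pp_hi, attr(pp_hi, "effect_region"))$roi_mean
  hit <- correlate(rv, pp_hi$hdrs17, params = pars)
  expect_true(hit$significant)

  pp_0 <- clinical_cohort(slope = 0, noise_sd = 3)
  rv0 <- roi_mean_values(pp_0, attr(pp_0, "effect_region"))$roi_mean
  miss <- correlate(rv0, pp_0$hdrs17, params = pars)
  expect_false(miss$significant)
})
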