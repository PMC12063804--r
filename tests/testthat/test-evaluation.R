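test_that("concordance correlation matches its closed form and bounds", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.4)
  expect_equal(ccc(x, x), 1.0)
  z <- x - mean(x)
  expect_equal(ccc(z, -z), -1.0)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(round(ccc(c(1, 2, 3), c(2, 3, 4)), 4), 0.5714)

  withr::with_seed(5, {
    for (i in 1:25) {
      a <- rnorm(20)
      b <- rnorm(20) + 0.5 * a
      expect_identical(ccc(a, b), ccc(b, a))
      expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
      expect_lte(abs(ccc(a, b)), 1)
    }
    # |ccc| = |r| exactly when means and variances agree
    a <- rnorm(200)
    b <- sample(a)
    expect_equal(abs(ccc(a, b)), abs(cor(a, b)), tolerance = 1e-12)
  })
  expect_error(ccc(rep(1, 5), 1:5), "constant")
  expect_error(ccc(1:3, 1:4), "equal length")
})

test_that("self-comparison yields perfect reproducibility", {
  tb <- make_batch_table(n_features = 5, batches = c(7, 1, 2), n_scans = 10,
                         gamma = 0, delta = 1, scan_sd = 1, noise_sd = 0,
                         seed = 3)
  rep <- reproducibility_report(tb, reference_group = 7)
  expect_equal(rep$summary$average_ccc, 1.0)
  expect_equal(rep$summary$frac_reproducible, 1.0)
})

test_that("reproducibility equals a brute-force loop and excludes constants", {
  tb <- make_batch_table(n_features = 4, batches = c(7, 1, 2), n_scans = 12,
                         gamma = c(0, 1, -1), delta = c(1, 1.2, 0.9),
                         scan_sd = 1, noise_sd = 0.3, seed = 9)
  tb$f004 <- 3   # constant everywhere
  rep <- reproducibility_report(tb, reference_group = 7)

  vals <- c()
  for (f in c("f001", "f002", "f003")) {
    for (g in c(1, 2)) {
      x <- tb[[f]][tb$group == 7][order(tb$scan[tb$group == 7])]
      y <- tb[[f]][tb$group == g][order(tb$scan[tb$group == g])]
      mx <- mean(x); my <- mean(y)
      vals <- c(vals, 2 * mean((x - mx) * (y - my)) /
                  (mean((x - mx)^2) + mean((y - my)^2) + (mx - my)^2))
    }
  }
  expect_equal(rep$summary$average_ccc, mean(vals), tolerance = 1e-12)
  expect_equal(rep$summary$frac_reproducible, mean(vals >= 0.95), tolerance = 1e-12)
  expect_true("f004" %in% rep$excluded_features$feature)
  expect_false("f004" %in%
                 rep$per_comparison$feature[!is.na(rep$per_comparison$ccc)])

  misaligned <- tb[!(tb$group == 1 & tb$scan == 3), ]
  expect_error(reproducibility_report(misaligned, reference_group = 7),
               "pairing error")
})

test_that("stability testing applies Shapiro-gated tests with Bonferroni correction", {
  tb <- make_batch_table(n_features = 4, batches = c(7, 1, 2, 3), n_scans = 30,
                         gamma = 0, delta = 1, scan_sd = 1, noise_sd = 0.2,
                         seed = 15)
  # identical samples across groups: all stable at 100%
  same <- tb
  for (f in feature_columns(tb)) {
    ref_vals <- same[[f]][same$group == 7]
    for (g in c(1, 2, 3)) same[[f]][same$group == g] <- ref_vals
  }
  st0 <- stability_report(same, reference_group = 7)
  expect_true(all(st0$per_feature$stable))
  expect_equal(st0$per_roi$pct_stable, 100)
  expect_true(all(st0$per_test$p_adjusted == 1))

  # one feature shifted by 3 pooled SDs in one group: unstable after correction
  shifted <- tb
  pooled_sd <- sd(shifted$f002)
  shifted$f002[shifted$group == 2] <- shifted$f002[shifted$group == 2] + 3 * pooled_sd
  st1 <- stability_report(shifted, reference_group = 7)
  expect_false(st1$per_feature$stable[st1$per_feature$feature == "f002"])

  # Bonferroni arithmetic: adjusted = min(1, m * p) >= raw
  expect_equal(st1$per_test$p_adjusted,
               pmin(1, st1$n_comparisons * st1$per_test$p))
  expect_true(all(st1$per_test$p_adjusted >= st1$per_test$p))
  expect_true(all(st1$per_test$p_adjusted <= 1))
  expect_equal(st1$n_comparisons, 3)
  # a raw p of 0.02 under 7 comparisons adjusts to 0.14 (stable at 0.05)
  st7 <- stability_report(shifted, reference_group = 7, n_comparisons = 7)
  expect_equal(st7$per_test$p_adjusted, pmin(1, 7 * st7$per_test$p))
})

test_that("paired power follows the noncentral t distribution", {
  expect_equal(paired_power(0, 0.05, 30), 0.05, tolerance = 1e-12)
  expect_gte(paired_power(0.5, 0.05, 1000), 0.999)
  expect_equal(paired_power(0.5, 0.05, 30),
               power.t.test(n = 30, delta = 0.5, sd = 1, type = "paired")$power,
               tolerance = 1e-4)
  expect_gt(paired_power(0.8, 0.05, 30), paired_power(0.5, 0.05, 30))
})

test_that("well-separated classes classify perfectly; permuted labels do not", {
  withr::with_seed(7, {
    n <- 40
    X <- matrix(rnorm(4 * n * 6), 4 * n, 6)
    cls <- rep(1:4, each = n)
    # class means 5 within-SDs apart per informative feature, with distinct
    # class orderings so the informative features stay decorrelated
    X[, 1] <- X[, 1] + 5 * cls
    X[, 2] <- X[, 2] + 5 * c(2, 4, 1, 3)[cls]
    X[, 3] <- X[, 3] + 5 * c(2, 3, 1, 4)[cls]
    tb <- dplyr::bind_cols(
      tibble::tibble(group = 1, scan = seq_len(4 * n), roi = cls),
      tibble::as_tibble(as.data.frame(X)))
  })
  dr <- discrimination_report(tb, seed = 2)
  expect_true(all(dr$per_class_auc$auc == 1.0))
  expect_equal(dr$macro_auc, 1.0)

  perm <- tb
  perm$roi <- withr::with_seed(8, sample(perm$roi))
  dr0 <- discrimination_report(perm, seed = 2)
  expect_gte(dr0$macro_auc, 0.40)
  expect_lte(dr0$macro_auc, 0.60)

  # duplicated feature column: exactly one of the pair retained
  dup <- tb
  dup$V7 <- dup$V1
  drd <- discrimination_report(dup, seed = 2)
  expect_true("V1" %in% drd$retained_features)
  expect_false("V7" %in% drd$retained_features)

  few <- tb[c(1:2, 41:42, 81:82, 121:122), ]
  expect_error(discrimination_report(few, seed = 1), "stratification error")
})

test_that("image quality metrics match closed forms", {
  a <- matrix(runif(24 * 24), 24, 24)
  iq0 <- image_quality(a, a, data_range = 1)
  expect_equal(iq0$per_image$nmse, 0)
  expect_equal(iq0$per_image$ssim, 1)
  expect_equal(iq0$per_image$psnr, 100)   # cap at perfect reconstruction

  # uniform additive error of 0.1 on unit range: MSE 0.01 -> PSNR 20 dB
  iq1 <- image_quality(a + 0.1, a, data_range = 1)
  expect_equal(iq1$per_image$psnr, 20, tolerance = 1e-9)
  expect_equal(iq1$per_image$nmse, sum(0.1^2 * length(a)) / sum(a^2),
               tolerance = 1e-9)
  expect_true(all(c("nmse", "psnr", "ssim") %in% names(iq1$per_image)))

  # per-group summary carries the three reported metrics
  b <- array(runif(24 * 24 * 4), c(24, 24, 4))
  noisy <- b + array(rnorm(length(b), sd = 0.05), dim(b))
  iqg <- image_quality(pmin(pmax(noisy, 0), 1), b, groups = c(1, 1, 2, 2))
  expect_equal(nrow(iqg$per_group), 2)
  expect_true(all(iqg$per_group$nmse >= 0))
  expect_true(all(abs(iqg$per_group$ssim) <= 1))
  expect_error(image_quality(a, a[1:10, ]), "shape error")
})

test_that("ssim is symmetric, bounded, and decreases with noise", {
  a <- matrix(runif(32 * 32), 32, 32)
  b <- pmin(pmax(a + rnorm(length(a), sd = 0.05), 0), 1)
  c2 <- pmin(pmax(a + rnorm(length(a), sd = 0.3), 0), 1)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_lt(ssim(a, c2), ssim(a, b))
  expect_lte(ssim(a, c2), 1)
})

test_that("plot helpers return ggplot objects", {
  tb <- make_batch_table(n_features = 5, batches = c(7, 1), n_scans = 8,
                         gamma = c(0, 1), scan_sd = 1, seed = 2)
  p1 <- plot_feature_embedding(tb)
  expect_s3_class(p1, "ggplot")
  rep <- reproducibility_report(tb, reference_group = 7)
  expect_s3_class(plot_reproducibility(rep), "ggplot")
})
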