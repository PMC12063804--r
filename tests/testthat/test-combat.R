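fcols <- function(tb) feature_columns(tb)
fmat <- function(tb) as.matrix(tb[fcols(tb)])

test_that("reference-batch rows pass through any fitted model unchanged", {
  tb <- make_batch_table(gamma = c(0, 3), delta = c(1, 1.8), seed = 21)
  m <- combat_fit(tb, reference_batch = "A")
  out <- combat_transform(m, tb)
  ref <- tb$group == "A"
  expect_lt(max(abs(fmat(out)[ref, ] - fmat(tb)[ref, ])), 1e-9)
  expect_identical(out[c("group", "scan", "roi")], tb[c("group", "scan", "roi")])
})

test_that("moment estimates without shrinkage match an independent brute-force oracle", {
  # 2 batches, 3 features, 4 samples each
  tb <- make_batch_table(n_features = 3, n_scans = 4, gamma = c(0, 1),
                         delta = c(1, 2), seed = 9)
  m <- combat_fit(tb, reference_batch = "A", eb = FALSE)
  out <- combat_transform(m, tb)
  oracle <- tb
  for (f in fcols(tb)) {
    ya <- tb[[f]][tb$group == "A"]
    yb <- tb[[f]][tb$group == "B"]
    amean <- mean(ya)
    vp <- mean((ya - amean)^2)             # reference-batch pooled variance
    zb <- (yb - amean) / sqrt(vp)
    gam <- mean(zb)                        # direct per-batch moments
    del <- sd(zb)
    expect_equal(unname(m$gamma_star["B", f]), gam, tolerance = 1e-6)
    expect_equal(unname(m$delta_star["B", f]), del, tolerance = 1e-6)
    oracle[[f]][oracle$group == "B"] <- ((zb - gam) / del) * sqrt(vp) + amean
  }
  expect_lt(max(abs(fmat(out) - fmat(oracle))), 1e-6)
})

test_that("empirical-Bayes estimates recover simulated batch effects within 10%", {
  tb <- make_batch_table(n_features = 8, n_scans = 200, gamma = c(0, 2),
                         delta = c(1, 1.5), seed = 31)
  m <- combat_fit(tb, reference_batch = "A")
  # gamma/delta live on the standardized scale; truth: location 2, scale 1.5.
  # Feature-level estimates carry sampling noise ~ delta/sqrt(n); the batch
  # effect (averaged over features) must land within 10% of truth.
  expect_lt(abs(mean(m$gamma_star["B", ]) - 2) / 2, 0.10)
  expect_lt(abs(mean(m$delta_star["B", ]) - 1.5) / 1.5, 0.10)
  expect_true(all(abs(m$gamma_star["B", ] - 2) / 2 < 0.30))
  expect_true(all(abs(m$delta_star["B", ] - 1.5) / 1.5 < 0.30))
})

test_that("additive batch shifts are removed and the transform is near-idempotent", {
  tb <- make_batch_table(n_features = 5, n_scans = 200, gamma = c(0, 3),
                         delta = c(1, 1), seed = 41)
  m <- combat_fit(tb, reference_batch = "A")
  out <- combat_transform(m, tb)
  gap0 <- batch_mean_gap(tb, "A", "B")
  gap1 <- batch_mean_gap(out, "A", "B")
  expect_true(all(gap1 <= 0.1 * gap0))

  m2 <- combat_fit(out, reference_batch = "A")
  out2 <- combat_transform(m2, out)
  for (f in fcols(tb)) {
    shift <- abs(mean(out2[[f]]) - mean(out[[f]]))
    expect_lt(shift, 1e-2 * sd(out[[f]]))
  }
})

test_that("standardized batch means move strictly toward the reference", {
  tb <- make_batch_table(n_features = 6, batches = c("A", "B", "C"),
                         n_scans = 100, gamma = c(0, 1.5, -2),
                         delta = c(1, 1.3, 0.7), seed = 13)
  m <- combat_fit(tb, reference_batch = "A")
  out <- combat_transform(m, tb)
  for (b in c("B", "C")) {
    for (f in fcols(tb)) {
      before <- abs(mean(tb[[f]][tb$group == b]) - mean(tb[[f]][tb$group == "A"]))
      after <- abs(mean(out[[f]][out$group == b]) - mean(out[[f]][out$group == "A"]))
      expect_lt(after, before)
    }
  }
  expect_true(all(m$delta_star > 0))
  expect_false(any(is.na(fmat(out))))
})

test_that("covariate effects are protected during harmonization", {
  d <- sim_design(n_features = 4, batch_ids = c("A", "B"), n_scans = 150,
                  gamma = c(0, 2), delta = c(1, 1.4), noise_sd = 1,
                  beta = 5, covariates = matrix(rep(c(0, 1), 150), ncol = 1),
                  seed = 17)
  tb <- simulate_feature_table(d)
  tb$sex <- as.vector(d$covariates)
  m <- combat_fit(tb, reference_batch = "A", covariates = "sex")
  out <- combat_transform(m, tb)
  for (f in setdiff(fcols(tb), "sex")) {
    eff <- mean(out[[f]][out$sex == 1]) - mean(out[[f]][out$sex == 0])
    expect_gt(eff, 0.8 * 5)
  }
})

test_that("the empirical-Bayes fit agrees with an established reference implementation", {
  skip_if_not_installed("sva")
  d <- sim_design(n_features = 40, batch_ids = 1:3, n_scans = 60,
                  alpha = rnorm(40), gamma = matrix(rnorm(120), 3, 40),
                  delta = matrix(runif(120, 0.7, 1.5), 3, 40), seed = 11)
  tb <- simulate_feature_table(d)
  ours <- combat_transform(combat_fit(tb, reference_batch = 2), tb)
  theirs <- t(suppressMessages(
    sva::ComBat(dat = t(fmat(tb)), batch = tb$group, ref.batch = 2)))
  scale <- sd(fmat(tb))
  expect_lt(max(abs(fmat(ours) - theirs)) / scale, 0.05)
})

test_that("per-ROI harmonization equals stratified fit/transform and validates strata", {
  d <- sim_design(n_features = 4, batch_ids = c("A", "B"), n_scans = 40,
                  roi_labels = 1:4, gamma = c(0, 2), delta = c(1, 1.3),
                  scan_sd = 1, noise_sd = 0.3, seed = 19)
  tb <- simulate_feature_table(d)
  out <- harmonize_per_roi(tb, reference_batch = "A")
  manual <- tb
  for (r in 1:4) {
    idx <- tb$roi == r
    m <- combat_fit(tb[idx, ], reference_batch = "A")
    manual[idx, ] <- combat_transform(m, tb[idx, ])
  }
  expect_equal(out[fcols(tb)], manual[fcols(tb)], tolerance = 1e-12,
               ignore_attr = TRUE)
  for (r in 1:4) {
    sub_in <- tb[tb$roi == r, ]
    sub_out <- out[out$roi == r, ]
    expect_true(all(batch_mean_gap(sub_out, "A", "B") <=
                      0.1 * batch_mean_gap(sub_in, "A", "B")))
  }

  single <- tb[tb$roi == 1, ]
  plain <- combat_transform(combat_fit(single, reference_batch = "A"), single)
  expect_equal(harmonize_per_roi(single, reference_batch = "A")[fcols(tb)],
               plain[fcols(tb)], ignore_attr = TRUE)

  broken <- tb
  broken$group[broken$roi == 2] <- "A"
  expect_error(harmonize_per_roi(broken, reference_batch = "A"), "stratum error.*2")
})

test_that("constant features and unseen batches are handled as documented", {
  tb <- make_batch_table(n_features = 3, n_scans = 20, seed = 5)
  tb$f001 <- 7
  expect_warning(m <- combat_fit(tb, reference_batch = "A"), "constant")
  out <- combat_transform(m, tb)
  expect_true(all(out$f001 == 7))
  expect_false(any(is.na(fmat(out))))

  alien <- tb
  alien$group[1] <- "Z"
  expect_error(combat_transform(m, alien), "unknown-batch")
  expect_error(combat_fit(tb, reference_batch = "Q"), "not present")
})

test_that("tidy and glance summarize fitted models", {
  tb <- make_batch_table(seed = 51)
  m <- combat_fit(tb, reference_batch = "A")
  td <- tidy(m)
  expect_equal(nrow(td), 2 * length(fcols(tb)))
  expect_true(all(c("batch", "feature", "gamma_star", "delta_star") %in% names(td)))
  expect_equal(unique(td$gamma_star[td$batch == "A"]), 0)
  g <- glance(m)
  expect_equal(g$n_batches, 2)
  expect_true(g$eb)
})
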