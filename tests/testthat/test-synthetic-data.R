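test_that("phantom generation is deterministic with calibrated ROI statistics", {
  v1 <- generate_phantom(42, shape = c(32, 32, 24))
  v2 <- generate_phantom(42, shape = c(32, 32, 24))
  expect_identical(v1$intensities, v2$intensities)
  expect_identical(v1$mask, v2$mask)

  labs <- sort(unique(as.vector(v1$mask)))
  expect_true(all(labs %in% 0:4))
  expect_true(all(1:4 %in% labs))

  specs <- tissue_specs()
  for (i in seq_len(nrow(specs))) {
    vox <- v1$intensities[v1$mask == specs$label[i]]
    n <- length(vox)
    expect_gte(n, 8)
    # texture fields are standardized exactly to the tissue statistics
    expect_lt(abs(mean(vox) - specs$mean_hu[i]),
              3 * specs$hu_sd[i] / sqrt(n))
    expect_equal(sd(vox), specs$hu_sd[i], tolerance = 1e-8)
  }

  expect_error(generate_phantom(1, shape = c(8, 8, 8)), "placement")
  bad <- tissue_specs()
  bad$label <- c(1L, 1L, 3L, 4L)
  expect_error(generate_phantom(1, tissues = bad), "duplicate|invalid")
})

test_that("acquisition operator respects the identity configuration and the mask", {
  v <- tiny_phantom()
  cfg <- ct_group_configs()
  id_cfg <- cfg[cfg$group_id == 7, ]
  id_cfg$psf_sigma <- 1e-12
  id_cfg$slice_thickness <- 1
  id_cfg$slice_spacing <- 1
  out <- apply_acquisition(v, id_cfg, seed = 1, base_noise_sd = 0)
  expect_lt(max(abs(out$intensities - v$intensities)), 1e-9)

  a <- apply_acquisition(v, 3, seed = 9)
  expect_identical(a$mask, v$mask)
  expect_identical(table(a$mask), table(v$mask))

  bad <- id_cfg
  bad$slice_spacing <- -1
  expect_error(apply_acquisition(v, bad, seed = 1), "invalid config")
})

test_that("group 7 is the IR / I30f / 2 mm / 1 mm reference arm", {
  cfg <- ct_group_configs()
  g7 <- cfg[cfg$group_id == 7, ]
  expect_equal(g7$algorithm, "IR")
  expect_match(g7$kernel, "I30f")
  expect_equal(g7$slice_thickness, 2)
  expect_equal(g7$slice_spacing, 1)
  expect_equal(nrow(cfg), 8)
  expect_true(all(cfg$slice_thickness >= cfg$slice_spacing))
})

test_that("thicker slices and smoother kernels strictly reduce high-frequency energy", {
  v <- tiny_phantom()
  cfg <- ct_group_configs()
  mk <- function(th, sp, sigma) {
    x <- cfg[cfg$group_id == 7, ]
    x$slice_thickness <- th
    x$slice_spacing <- sp
    x$psf_sigma <- sigma
    x
  }
  thin <- apply_acquisition(v, mk(1, 1, 1e-12), seed = 4, base_noise_sd = 5)
  thick <- apply_acquisition(v, mk(3, 2, 1e-12), seed = 4, base_noise_sd = 5)
  expect_lt(axial_hf_energy(thick), axial_hf_energy(thin))

  # PSF monotonicity across three sharpness levels, fixed seed
  e <- vapply(c(0.4, 0.8, 1.6), function(s) {
    out <- apply_acquisition(v, mk(1, 1, s), seed = 4, base_noise_sd = 5)
    d <- dim(out$intensities)
    sp <- Mod(fft(out$intensities))^2
    f <- function(n) {
      x <- (seq_len(n) - 1) / n
      x[x > 0.5] <- x[x > 0.5] - 1
      abs(x)
    }
    hf <- outer(outer(f(d[1]), f(d[2]), pmax), f(d[3]), pmax) > 0.25
    sum(sp[hf])
  }, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("feature-table simulation obeys its generative model", {
  d <- sim_design(n_features = 3, batch_ids = 1:2, n_scans = 10, roi_labels = 1:2,
                  gamma = c(0, 1), delta = c(1, 2), seed = 5)
  t1 <- simulate_feature_table(d)
  t2 <- simulate_feature_table(d)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 2 * 10 * 2)
  expect_equal(length(feature_columns(t1)), 3)

  expect_error(sim_design(3, 1:2, 10, delta = c(1, -1)), "delta")

  # batch means converge to alpha + gamma
  dn <- sim_design(n_features = 4, batch_ids = 1:3, n_scans = 1000, alpha = 2,
                   gamma = c(0, 1.5, -1), delta = c(1, 1.2, 0.8),
                   noise_sd = 1, seed = 8)
  tn <- simulate_feature_table(dn)
  for (b in 1:3) {
    for (f in feature_columns(tn)) {
      got <- mean(tn[[f]][tn$group == b])
      want <- 2 + c(0, 1.5, -1)[b]
      tol <- 4 * c(1, 1.2, 0.8)[b] * 1 / sqrt(1000)
      expect_lt(abs(got - want), tol)
    }
  }
})

test_that("null batch effects leave batch distributions indistinguishable", {
  d <- sim_design(n_features = 40, batch_ids = c("A", "B"), n_scans = 500,
                  gamma = 0, delta = 1, noise_sd = 1, seed = 12)
  tb <- simulate_feature_table(d)
  p <- vapply(feature_columns(tb), function(f) {
    suppressWarnings(ks.test(tb[[f]][tb$group == "A"], tb[[f]][tb$group == "B"])$p.value)
  }, numeric(1))
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("a study manifest regenerates byte-identical NIfTI outputs", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  study <- simulate_study(groups = c(3, 7), scans_per_group = 1, seed = 77,
                          shape = c(24, 24, 16))
  write_study(study, dir1)
  study2 <- regenerate_study(file.path(dir1, "manifest.json"))
  write_study(study2, dir2)
  for (f in list.files(dir1, pattern = "nii.gz$")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7), label = f)
  }
})
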