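test_that("the feature vector has 93 finite values in the standard class breakdown", {
  f <- extract_features(clip_intensity(tiny_phantom()), 1)
  expect_length(f, 93)
  expect_true(all(is.finite(f)))
  prefix <- sub("_.*", "", names(f))
  expect_equal(as.integer(table(prefix)[c("firstorder", "glcm", "glrlm",
                                          "glszm", "gldm", "ngtdm")]),
               c(18L, 24L, 16L, 16L, 14L, 5L))
  expect_false(anyDuplicated(names(f)) > 0)
})

test_that("constant regions hit the degenerate limits of texture features", {
  v <- labeled_volume(array(50, c(4, 4, 3)), c(1, 1, 1), array(1L, c(4, 4, 3)))
  f <- extract_features(v, 1)
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["firstorder_Entropy"]), 0)
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_JointEnergy"]), 1)
  expect_equal(unname(f["firstorder_Uniformity"]), 1)
})

test_that("first-order statistics match direct voxel-statistics oracles", {
  v <- tiny_phantom()
  x <- v$intensities[v$mask == 2]
  f <- extract_features(v, 2)
  expect_equal(unname(f["firstorder_Mean"]), mean(x))
  expect_equal(unname(f["firstorder_Variance"]), mean((x - mean(x))^2))
  expect_equal(unname(f["firstorder_Median"]), median(x))
  expect_equal(unname(f["firstorder_Energy"]), sum(x^2))
  expect_equal(unname(f["firstorder_RootMeanSquared"]), sqrt(mean(x^2)))
  expect_equal(unname(f["firstorder_Range"]), diff(range(x)))
})

test_that("GLCM features on a 4-voxel grid match a hand-enumerated co-occurrence oracle", {
  # 2 x 2 x 1 grid, values [1, 1, 1, 2] (column-major), bin width 1
  v <- labeled_volume(array(c(1, 1, 1, 2), c(2, 2, 1)), c(1, 1, 1),
                      array(1L, c(2, 2, 1)))
  f <- extract_features(v, 1, extraction_config(bin_width = 1))
  expect_equal(unname(f["firstorder_Mean"]), 1.25)

  # independent enumeration: symmetric co-occurrence per direction, features
  # averaged over directions with nonzero pair counts
  lv <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  per_dir <- list()
  for (d in seq_len(nrow(dirs))) {
    P <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) for (k in 1:1) {
      t <- c(i, j, k) + dirs[d, ]
      if (all(t >= 1) && all(t <= c(2, 2, 1))) {
        a <- lv[i, j, k]; b <- lv[t[1], t[2], t[3]]
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
    if (sum(P) == 0) next
    p <- P / sum(P)
    ii <- matrix(1:2, 2, 2); jj <- t(ii)
    per_dir[[length(per_dir) + 1]] <- c(
      contrast = sum(p * (ii - jj)^2),
      joint_energy = sum(p^2),
      max_prob = max(p),
      autocorr = sum(p * ii * jj))
  }
  oracle <- Reduce(`+`, per_dir) / length(per_dir)
  expect_equal(unname(f["glcm_Contrast"]), unname(oracle["contrast"]), tolerance = 1e-12)
  expect_equal(unname(f["glcm_JointEnergy"]), unname(oracle["joint_energy"]), tolerance = 1e-12)
  expect_equal(unname(f["glcm_MaximumProbability"]), unname(oracle["max_prob"]), tolerance = 1e-12)
  expect_equal(unname(f["glcm_Autocorrelation"]), unname(oracle["autocorr"]), tolerance = 1e-12)
})

test_that("run, zone and dependence statistics match hand-built oracles on a line", {
  # single 1 x 4 x 1 row: levels 1,1,2,2 -> runs {1:len2, 2:len2}, zones same
  v <- labeled_volume(array(c(0, 0, 25, 25), c(1, 4, 1)), c(1, 1, 1),
                      array(1L, c(1, 4, 1)))
  f <- extract_features(v, 1, extraction_config(bin_width = 25))
  # along the row direction: two runs of length 2 -> SRE = mean over the 13
  # directions; other directions see runs of length 1 (SRE 1)
  # direction (0,1,0): P = [[0,1,0,0],[0,1,0,0]] -> SRE = 1/4
  # every other direction: 4 runs length 1 -> SRE = 1
  expect_equal(unname(f["glrlm_ShortRunEmphasis"]), (1 / 4 + 12) / 13, tolerance = 1e-12)
  expect_equal(unname(f["glrlm_LongRunEmphasis"]), (4 + 12) / 13, tolerance = 1e-12)
  # zones: two 26-connected zones of size 2 -> SmallArea = 1/4, LargeArea = 4
  expect_equal(unname(f["glszm_SmallAreaEmphasis"]), 1 / 4, tolerance = 1e-12)
  expect_equal(unname(f["glszm_LargeAreaEmphasis"]), 4, tolerance = 1e-12)
  expect_equal(unname(f["glszm_ZonePercentage"]), 2 / 4, tolerance = 1e-12)
  # dependences (alpha 0, center counted): ends have 1 same-level neighbour
  # (d = 2), middles have 1 same + 1 different (d = 2): all d = 2
  expect_equal(unname(f["gldm_LargeDependenceEmphasis"]), 4, tolerance = 1e-12)
  expect_equal(unname(f["gldm_SmallDependenceEmphasis"]), 1 / 4, tolerance = 1e-12)
})

test_that("aggregated texture features are invariant to 90-degree in-plane rotation", {
  set.seed(33)
  n <- 6
  vals <- array(sample(0:4, n^3, replace = TRUE) * 25, c(n, n, n))
  m <- array(1L, c(n, n, n))
  v1 <- labeled_volume(vals, c(1, 1, 1), m)
  rot <- function(a) {
    out <- array(0, dim(a))
    for (k in seq_len(dim(a)[3])) out[, , k] <- t(a[dim(a)[1]:1, , k])
    out
  }
  v2 <- labeled_volume(rot(vals), c(1, 1, 1), m)
  f1 <- extract_features(v1, 1, extraction_config(bin_width = 25))
  f2 <- extract_features(v2, 1, extraction_config(bin_width = 25))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("features are invariant to mask label renumbering", {
  v <- tiny_phantom()
  f1 <- extract_features(v, 2)
  v2 <- v
  v2$mask <- relabel_rois(v$mask, c("1" = 3, "2" = 4, "3" = 1, "4" = 2))
  f2 <- extract_features(v2, 4)
  expect_equal(f1, f2)
})

test_that("dataset extraction assembles keyed rows and reports failures", {
  study <- simulate_study(groups = c(3, 7), scans_per_group = 2, seed = 3,
                          shape = c(24, 24, 16))
  study$volume <- lapply(study$volume, clip_intensity)
  tb <- extract_dataset(study)
  expect_equal(nrow(tb), 2 * 2 * 4)
  expect_equal(length(feature_columns(tb)), 93)
  expect_false(anyDuplicated(tb[c("group", "scan", "roi")]) > 0)
  tb2 <- extract_dataset(study)
  expect_identical(tb, tb2)

  one <- extract_dataset(study[1, ], roi_labels = 1)
  expect_equal(nrow(one), 1)

  # an absent ROI label is reported and excluded, not fatal
  expect_warning(part <- extract_dataset(study[1, ], roi_labels = c(1, 9)),
                 "excluded")
  expect_equal(nrow(part), 1)
  expect_error(suppressWarnings(extract_dataset(study[1, ], roi_labels = 9)),
               "empty-table")
})

test_that("degenerate ROIs raise the documented errors", {
  v <- tiny_phantom()
  expect_error(extract_features(v, 9), "missing-roi")
  single <- labeled_volume(array(1, c(3, 3, 1)), c(1, 1, 1),
                           array(c(1L, rep(0L, 8)), c(3, 3, 1)))
  expect_error(extract_features(single, 1), "degenerate-roi")
})
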