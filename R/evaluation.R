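
#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2\,cov(x,y)}{var(x) + var(y) + (\bar x - \bar y)^2}}
#' computed with population (1/n) moments. Symmetric in its arguments and
#' bounded by `[-1, 1]`.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return Scalar CCC.
#' @export
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("ccc needs paired vectors of equal length >= 2", call. = FALSE)
  }
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx < 1e-24 || vy < 1e-24) {
    stop("constant-feature: ccc undefined for constant input",
         call. = FALSE)
  }
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

check_pairing <- function(table, reference_group) {
  ref_scans <- sort(unique(table$scan[table$group == reference_group]))
  bad <- table |>
    dplyr::group_by(.data$group, .data$roi) |>
    dplyr::summarise(ok = identical(sort(unique(.data$scan)), ref_scans),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("pairing error: scan keys misaligned with reference group for ",
         nrow(bad), " (group, roi) strata", call. = FALSE)
  }
  invisible(ref_scans)
}

repro_one_set <- function(table, reference_group, threshold, set_label) {
  feats <- feature_columns(table)
  check_pairing(table, reference_group)
  groups <- setdiff(unique(table$group), reference_group)
  rois <- unique(table$roi)
  ref <- table[table$group == reference_group, ]
  rows <- purrr::map(rois, function(r) {
    ref_r <- ref[ref$roi == r, ]
    ref_r <- ref_r[order(ref_r$scan), ]
    purrr::map(groups, function(g) {
      cur <- table[table$group == g & table$roi == r, ]
      cur <- cur[order(cur$scan), ]
      vals <- purrr::map_dbl(feats, function(f) {
        x <- ref_r[[f]]; y <- cur[[f]]
        if (var(x) < 1e-12 || var(y) < 1e-12) return(NA_real_)
        ccc(x, y)
      })
      tibble(set = set_label, feature = feats, roi = r, group = g, ccc = vals)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows
}

#' Test-retest reproducibility report (CCC vs reference group)
#'
#' For every (feature, roi, non-reference group), computes Lin's CCC between
#' the scan-paired feature vectors of that group and the reference group.
#' Comparisons where either side is constant (sample variance < 1e-12) are
#' excluded, and the features involved are listed. The summary reports the
#' average CCC and the fraction of comparisons at or above the
#' reproducibility threshold.
#'
#' @param table Feature table (keys `group`, `scan`, `roi`).
#' @param harmonized Optional harmonized counterpart of `table`; when given,
#'   both are reported side by side.
#' @param reference_group Reference batch id.
#' @param threshold Reproducibility threshold (CCC >= threshold).
#' @return A `repro_report` with elements `per_comparison`, `summary`,
#'   `excluded_features`, `threshold`.
#' @export
reproducibility_report <- function(table, harmonized = NULL, reference_group,
                                   threshold = 0.95) {
  if (!reference_group %in% table$group) {
    stop("reference group ", reference_group, " not present", call. = FALSE)
  }
  per <- repro_one_set(table, reference_group, threshold, "original")
  if (!is.null(harmonized)) {
    per <- dplyr::bind_rows(
      per, repro_one_set(harmonized, reference_group, threshold, "harmonized"))
  }
  summary <- per |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      average_ccc = mean(.data$ccc, na.rm = TRUE),
      frac_reproducible = mean(.data$ccc[!is.na(.data$ccc)] >= threshold),
      n_comparisons = sum(!is.na(.data$ccc)),
      n_excluded = sum(is.na(.data$ccc)),
      .groups = "drop")
  excluded <- per |>
    dplyr::filter(is.na(.data$ccc)) |>
    dplyr::distinct(.data$set, .data$feature)
  structure(list(per_comparison = per, summary = summary,
                 excluded_features = excluded, threshold = threshold,
                 reference_group = reference_group),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("<repro_report> CCC vs group", x$reference_group,
      "(threshold", x$threshold, ")\n")
  print(x$summary)
  invisible(x)
}

#' Paired stability testing of features against the reference group
#'
#' For each (feature, roi) and each non-reference group, the scan-paired
#' differences vs the reference group are tested: Shapiro-Wilk normality at
#' 0.05 decides between a paired t test and a Wilcoxon signed-rank test; raw
#' p values are Bonferroni-adjusted over the group comparisons. A feature is
#' stable for an ROI when all adjusted p values exceed `alpha`. All-zero
#' difference vectors short-circuit to adjusted p = 1 with a note.
#'
#' @param table Feature table.
#' @param reference_group Reference batch id.
#' @param alpha Stability significance level.
#' @param n_comparisons Bonferroni multiplier; defaults to the number of
#'   non-reference groups.
#' @return A `stability_report` with `per_test`, `per_feature`, `per_roi`.
#' @export
stability_report <- function(table, reference_group, alpha = 0.05,
                             n_comparisons = NULL) {
  feats <- feature_columns(table)
  check_pairing(table, reference_group)
  groups <- setdiff(unique(table$group), reference_group)
  if (is.null(n_comparisons)) n_comparisons <- length(groups)
  rois <- unique(table$roi)
  ref <- table[table$group == reference_group, ]
  rows <- list()
  for (r in rois) {
    ref_r <- ref[ref$roi == r, ]
    ref_r <- ref_r[order(ref_r$scan), ]
    if (nrow(ref_r) < 3) stop("need >= 3 pairs per comparison", call. = FALSE)
    for (g in groups) {
      cur <- table[table$group == g & table$roi == r, ]
      cur <- cur[order(cur$scan), ]
      for (f in feats) {
        d <- cur[[f]] - ref_r[[f]]
        res <- paired_diff_test(d)
        rows[[length(rows) + 1]] <- tibble(
          feature = f, roi = r, group = g, test = res$test, p = res$p,
          note = res$note)
      }
    }
  }
  per_test <- dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adjusted = pmin(1, n_comparisons * .data$p))
  per_feature <- per_test |>
    dplyr::group_by(.data$feature, .data$roi) |>
    dplyr::summarise(min_p_adjusted = min(.data$p_adjusted),
                     stable = all(.data$p_adjusted > alpha), .groups = "drop")
  per_roi <- per_feature |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(n_stable = sum(.data$stable),
                     n_features = dplyr::n(),
                     label = paste0(sum(.data$stable), "/", dplyr::n()),
                     pct_stable = round(100 * sum(.data$stable) / dplyr::n(), 2),
                     .groups = "drop")
  structure(list(per_test = per_test, per_feature = per_feature,
                 per_roi = per_roi, alpha = alpha,
                 n_comparisons = n_comparisons,
                 reference_group = reference_group),
            class = "stability_report")
}

paired_diff_test <- function(d) {
  if (max(abs(d)) < 1e-12) {
    return(list(test = "none", p = 1, note = "all-zero differences; maximally stable"))
  }
  if (sd(d) < 1e-12) {
    # constant nonzero shift: signed-rank applies, t test is degenerate
    p <- suppressWarnings(wilcox.test(d)$p.value)
    return(list(test = "wilcoxon", p = p, note = "constant nonzero differences"))
  }
  sw <- tryCatch(shapiro.test(d)$p.value, error = function(e) 0)
  if (sw > 0.05) {
    list(test = "paired-t", p = t.test(d)$p.value, note = NA_character_)
  } else {
    dz <- d[abs(d) > 1e-12]   # drop exact zeros (signed-rank convention)
    if (length(dz) == 0) {
      return(list(test = "wilcoxon", p = 1, note = "all-zero after zero removal"))
    }
    p <- suppressWarnings(wilcox.test(dz)$p.value)
    list(test = "wilcoxon", p = p, note = NA_character_)
  }
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> vs group", x$reference_group, "; Bonferroni x",
      x$n_comparisons, "\n")
  print(x$per_roi)
  invisible(x)
}

#' Achieved power of a two-sided paired t test
#'
#' Computed from the noncentral t distribution with noncentrality
#' \eqn{d\sqrt{n}} and \eqn{n - 1} degrees of freedom at the two-sided
#' critical value.
#'
#' @param effect_size Cohen's d of the paired differences (>= 0).
#' @param alpha Two-sided significance level.
#' @param n_pairs Number of pairs (>= 2).
#' @return Achieved power in `[0, 1]`.
#' @export
#' @examples
#' paired_power(0.5, 0.05, 30)  # ~0.754
paired_power <- function(effect_size, alpha = 0.05, n_pairs) {
  stopifnot(n_pairs >= 2, effect_size >= 0, alpha > 0, alpha < 1)
  df <- n_pairs - 1
  ncp <- effect_size * sqrt(n_pairs)
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
}

#' Discriminative power of features via SVM tissue classification
#'
#' Removes highly correlated features (keeping the first of each pair by
#' column order), standardizes, tunes an RBF-kernel SVM by grid search under
#' stratified 3-fold cross-validation (selection on the cross-validated
#' macro AUC), and reports per-class one-vs-rest AUC computed from held-out
#' decision margins, averaged over folds, plus the macro average.
#'
#' @param table Feature table.
#' @param class_col Column holding the class labels (default `"roi"`).
#' @param seed Integer seed for fold assignment.
#' @param corr_threshold Absolute Pearson correlation above which the later
#'   feature of a pair is dropped.
#' @param cost_grid,gamma_grid SVM hyperparameter grids; `"scale"` maps to
#'   `1 / n_features` on standardized data.
#' @param folds Number of cross-validation folds.
#' @return A `discrimination_report` with retained features, the grid, the
#'   winning hyperparameters, per-class AUC and `macro_auc`.
#' @export
discrimination_report <- function(table, class_col = "roi", seed = 1L,
                                  corr_threshold = 0.95,
                                  cost_grid = c(0.1, 1, 10, 100),
                                  gamma_grid = c("scale", 0.01, 0.001),
                                  folds = 3L) {
  feats <- setdiff(feature_columns(table), class_col)
  y <- factor(table[[class_col]])
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(table(y) < folds)) {
    stop("stratification error: a class has fewer samples than folds", call. = FALSE)
  }
  X <- as.matrix(table[feats])
  keep_var <- apply(X, 2, var) > 1e-12
  X <- X[, keep_var, drop = FALSE]
  retained <- correlation_filter(X, corr_threshold)
  X <- X[, retained, drop = FALSE]
  Xs <- scale(X)

  fold_id <- with_seed(child_seed(seed, "folds"), {
    id <- integer(length(y))
    for (k in levels(y)) {
      idx <- which(y == k)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })

  gam_val <- function(g) if (identical(g, "scale")) 1 / ncol(Xs) else as.numeric(g)
  # Margin scores of a one-vs-rest binary SVM; sign oriented toward `cl`.
  # (libsvm orders decision values by first appearance, hence the flip.)
  ovr_scores <- function(tr, te, ytr, cl, cost, gamma) {
    y2 <- factor(ifelse(ytr == cl, "pos", "rest"), levels = c("pos", "rest"))
    fit <- e1071::svm(x = tr, y = y2, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    dv <- attr(predict(fit, te, decision.values = TRUE), "decision.values")
    if (startsWith(colnames(dv)[1], "pos")) dv[, 1] else -dv[, 1]
  }
  # one-vs-rest AUC per held-out fold, averaged over folds (margins from
  # different folds live on different scales and are not pooled); the grid
  # is tuned on the cross-validated macro AUC it reports
  eval_config <- function(cost, gamma) {
    fold_auc <- matrix(NA_real_, folds, nlevels(y),
                       dimnames = list(NULL, levels(y)))
    acc <- 0
    for (k in seq_len(folds)) {
      tr <- Xs[fold_id != k, , drop = FALSE]
      te <- Xs[fold_id == k, , drop = FALSE]
      yk <- y[fold_id == k]
      scores <- vapply(levels(y), function(cl) {
        ovr_scores(tr, te, y[fold_id != k], cl, cost, gam_val(gamma))
      }, numeric(nrow(te)))
      acc <- acc + sum(levels(y)[max.col(scores)] == as.character(yk))
      for (cl in levels(y)) {
        fold_auc[k, cl] <- as.numeric(pROC::auc(pROC::roc(
          response = yk == cl, predictor = scores[, cl],
          quiet = TRUE, direction = "<")))
      }
    }
    list(per_class = colMeans(fold_auc), macro = mean(fold_auc),
         accuracy = acc / length(y))
  }
  grid <- tidyr::expand_grid(cost = cost_grid, gamma = gamma_grid)
  results <- purrr::pmap(grid, eval_config)
  grid$cv_macro_auc <- purrr::map_dbl(results, "macro")
  grid$cv_accuracy <- purrr::map_dbl(results, "accuracy")
  ibest <- which.max(grid$cv_macro_auc)
  best <- grid[ibest, ]
  auc_per_class <- results[[ibest]]$per_class
  per_class <- tibble(class = levels(y), auc = auc_per_class)
  structure(list(retained_features = retained, grid = grid,
                 best = as.list(best), per_class_auc = per_class,
                 macro_auc = mean(auc_per_class), folds = folds,
                 corr_threshold = corr_threshold),
            class = "discrimination_report")
}

correlation_filter <- function(X, threshold) {
  keep <- character(0)
  for (j in colnames(X)) {
    if (length(keep) == 0) {
      keep <- j
      next
    }
    r <- suppressWarnings(abs(cor(X[, j], X[, keep, drop = FALSE])))
    if (all(is.na(r)) || all(r <= threshold, na.rm = TRUE)) keep <- c(keep, j)
  }
  keep
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> %d retained features; macro AUC %.3f\n",
              length(x$retained_features), x$macro_auc))
  print(x$per_class_auc)
  invisible(x)
}

# --- image quality ----------------------------------------------------------

gaussian_kernel2d <- function(win, sigma) {
  r <- (win - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

local_mean <- function(img, kern) {
  win <- nrow(kern)
  p <- list(W = matrix(as.vector(kern), ncol = 1), b = 0, k = as.integer(win),
            stride = 1L, pad = 0L, c_in = 1L, c_out = 1L)
  conv_forward(array(img, c(dim(img), 1L)), p)$y[, , 1]
}

#' Structural similarity index (SSIM) of two images
#'
#' Gaussian-windowed SSIM (11 x 11 window, sigma 1.5, K1 = 0.01, K2 = 0.03)
#' evaluated on the valid interior and averaged.
#'
#' @param x,y Image matrices of identical dimensions.
#' @param data_range Dynamic range of the data.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, data_range = 1) {
  stopifnot(identical(dim(x), dim(y)))
  win <- min(11L, dim(x))
  if (win %% 2 == 0) win <- win - 1L
  kern <- gaussian_kernel2d(win, 1.5)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- local_mean(x, kern); my <- local_mean(y, kern)
  sxx <- local_mean(x * x, kern) - mx^2
  syy <- local_mean(y * y, kern) - my^2
  sxy <- local_mean(x * y, kern) - mx * my
  m <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(m)
}

#' Image quality metrics of generated vs target images
#'
#' Computes per image: NMSE \eqn{\lVert g - t \rVert^2 / \lVert t \rVert^2},
#' PSNR \eqn{10 \log_{10}(R^2 / MSE)} in dB (capped at `psnr_cap` when MSE is
#' 0), and SSIM. Group means are reported when `groups` is given.
#'
#' @param generated,target Matrices, 3D arrays (images along dim 3), or lists
#'   of matrices; shapes must match pairwise.
#' @param data_range Dynamic range R.
#' @param groups Optional per-image group labels for the summary.
#' @param psnr_cap PSNR value reported for a perfect reconstruction.
#' @return An `image_quality_report` with `per_image` and `per_group` tibbles.
#' @export
image_quality <- function(generated, target, data_range = 1, groups = NULL,
                          psnr_cap = 100) {
  stopifnot(data_range > 0)
  gl <- as_image_list(generated)
  tl <- as_image_list(target)
  if (length(gl) != length(tl)) stop("shape error: image counts differ", call. = FALSE)
  rows <- purrr::map2(gl, tl, function(g, t) {
    if (!identical(dim(g), dim(t))) stop("shape error: image dims differ", call. = FALSE)
    mse <- mean((g - t)^2)
    tibble(
      nmse = sum((g - t)^2) / max(sum(t^2), 1e-24),
      psnr = if (mse == 0) psnr_cap else min(psnr_cap, 10 * log10(data_range^2 / mse)),
      ssim = ssim(g, t, data_range))
  }) |> dplyr::bind_rows()
  rows$image <- seq_len(nrow(rows))
  rows$group <- if (is.null(groups)) NA else groups
  per_group <- rows |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(nmse = mean(.data$nmse), psnr = mean(.data$psnr),
                     ssim = mean(.data$ssim), n = dplyr::n(), .groups = "drop")
  structure(list(per_image = rows[, c("image", "group", "nmse", "psnr", "ssim")],
                 per_group = per_group, data_range = data_range),
            class = "image_quality_report")
}

as_image_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3) {
    return(purrr::map(seq_len(dim(x)[3]), function(i) x[, , i]))
  }
  stop("unsupported image container", call. = FALSE)
}

#' @export
print.image_quality_report <- function(x, ...) {
  cat("<image_quality_report>\n")
  print(x$per_group)
  invisible(x)
}

#' Plot a 2D embedding of standardized features
#'
#' Convenience visualization of the feature space before/after
#' harmonization: features are z-scored and projected onto their first two
#' principal components, coloured by group. (A purely qualitative aid; no
#' numeric result depends on it.)
#'
#' @param table Feature table.
#' @param colour_by Key column to colour points by.
#' @return A ggplot object.
#' @export
plot_feature_embedding <- function(table, colour_by = "group") {
  X <- as.matrix(table[feature_columns(table)])
  X <- X[, apply(X, 2, var) > 1e-12, drop = FALSE]
  pc <- stats::prcomp(X, scale. = TRUE)
  df <- tibble(dim1 = pc$x[, 1], dim2 = pc$x[, 2],
               colour = factor(table[[colour_by]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$colour)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = colour_by, x = "component 1", y = "component 2") +
    ggplot2::theme_minimal()
}

#' Plot per-comparison CCC distributions
#'
#' @param report A [reproducibility_report()] result.
#' @return A ggplot object.
#' @export
plot_reproducibility <- function(report) {
  stopifnot(inherits(report, "repro_report"))
  df <- dplyr::filter(report$per_comparison, !is.na(.data$ccc))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$group), y = .data$ccc,
                                   fill = .data$set)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = report$threshold, linetype = 2) +
    ggplot2::labs(x = "group", y = "CCC vs reference") +
    ggplot2::theme_minimal()
}
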