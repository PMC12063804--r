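
#' Radiomic extraction configuration
#'
#' Fixes the feature set to the 93 non-shape features in six classes:
#' 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM -- the
#' unique partition of the standard non-shape classes summing to 93. Texture
#' classes are computed on intensities discretized with a fixed bin width;
#' first-order statistics use raw HU values.
#'
#' @param bin_width Discretization bin width in HU (> 0); 25 HU is a common
#'   choice for contrast-windowed CT.
#' @param glcm_distance Co-occurrence offset distance in voxels.
#' @param gldm_alpha Gray-level difference tolerance for dependence counting.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(bin_width = 25, glcm_distance = 1L,
                              gldm_alpha = 0L) {
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  structure(list(bin_width = bin_width,
                 glcm_distance = as.integer(glcm_distance),
                 gldm_alpha = as.integer(gldm_alpha),
                 feature_classes = c(firstorder = 18L, glcm = 24L, glrlm = 16L,
                                     glszm = 16L, gldm = 14L, ngtdm = 5L)),
            class = "extraction_config")
}

# Fixed-bin-width discretization to levels 1..Ng over the ROI voxels.
discretize_levels <- function(x, bin_width) {
  floor((x - min(x)) / bin_width) + 1L
}

plog2 <- function(p) {
  # -sum p log2 p with 0 log 0 = 0
  p <- p[p > 0]
  -sum(p * log2(p))
}

fo_features <- function(x, bin_width, voxel_volume) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  robust <- x[x >= q[1] & x <= q[4]]
  lv <- discretize_levels(x, bin_width)
  p <- tabulate(lv) / n
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = plog2(p),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = m,
    Median = median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

glcm_features_one <- function(P, Ng) {
  # P: symmetric count matrix for one direction
  tot <- sum(P)
  if (tot == 0) return(NULL)
  p <- P / tot
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(Ng) * px)
  sd_x <- sqrt(sum(px * (seq_len(Ng) - mu_x)^2))
  # symmetric matrix: py == px, mu_y == mu_x
  k_sum <- 2:(2 * Ng)
  pxy_sum <- vapply(k_sum, function(k) sum(p[i + j == k]), numeric(1))
  k_dif <- 0:(Ng - 1)
  pxy_dif <- vapply(k_dif, function(k) sum(p[abs(i - j) == k]), numeric(1))
  da <- sum(k_dif * pxy_dif)
  hxy <- plog2(p)
  hx <- plog2(px)
  pij_marg <- outer(px, px)
  hxy1 <- -sum(p[pij_marg > 0] * log2(pij_marg[pij_marg > 0]))
  hxy2 <- plog2(pij_marg)
  corr <- if (sd_x > 0) (sum(p * i * j) - mu_x^2) / sd_x^2 else 1
  mcc <- if (Ng > 1) {
    py <- px
    denom <- outer(px, rep(1, Ng)) * outer(rep(1, Ng), py)
    Q <- matrix(0, Ng, Ng)
    ok <- px > 0
    pk <- p
    # Q[a, b] = sum_k p[a,k] p[b,k] / (px[a] py[k])
    sub <- pk[ok, ok, drop = FALSE] / outer(rep(1, sum(ok)), py[ok])
    Qs <- (pk[ok, ok, drop = FALSE] / px[ok]) %*% t(sub)
    ev <- sort(Re(eigen(Qs, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) > 1) sqrt(max(0, ev[2])) else 1
  } else 1
  c(Autocorrelation = sum(p * i * j),
    ClusterProminence = sum(p * (i + j - 2 * mu_x)^4),
    ClusterShade = sum(p * (i + j - 2 * mu_x)^3),
    ClusterTendency = sum(p * (i + j - 2 * mu_x)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = plog2(pxy_dif),
    DifferenceVariance = sum(pxy_dif * (k_dif - da)^2),
    Id = sum(pxy_dif / (1 + k_dif)),
    Idm = sum(pxy_dif / (1 + k_dif^2)),
    Idmn = sum(pxy_dif / (1 + (k_dif / Ng)^2)),
    Idn = sum(pxy_dif / (1 + k_dif / Ng)),
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = if (Ng > 1) sum(pxy_dif[-1] / k_dif[-1]^2) else 0,
    JointAverage = mu_x,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = plog2(pxy_sum),
    SumSquares = sum(p * (i - mu_x)^2))
}

glcm_features <- function(lv_arr, Ng, dist) {
  counts <- array(cpp_glcm(as.integer(lv_arr), dim(lv_arr), Ng, dist),
                  c(Ng, Ng, 13))
  per_dir <- purrr::compact(purrr::map(1:13, function(d) {
    glcm_features_one(matrix(counts[, , d], Ng, Ng), Ng)
  }))
  res <- Reduce(`+`, per_dir) / length(per_dir)
  setNames(res, paste0("glcm_", names(res)))
}

rl_style_features <- function(P, prefix, labels) {
  # Shared run-length / size-zone style statistics over a (gray level x size)
  # weight matrix P of raw counts.
  Ns <- sum(P)
  g <- seq_len(nrow(P))
  s <- seq_len(ncol(P))
  pg <- rowSums(P) / Ns
  ps <- colSums(P) / Ns
  mu_g <- sum(g * pg)
  mu_s <- sum(s * ps)
  G <- matrix(g, nrow(P), ncol(P))
  S <- matrix(s, nrow(P), ncol(P), byrow = TRUE)
  vals <- c(
    small = sum(P / S^2) / Ns,
    large = sum(P * S^2) / Ns,
    gln = sum(rowSums(P)^2) / Ns,
    glnn = sum(rowSums(P)^2) / Ns^2,
    sn = sum(colSums(P)^2) / Ns,
    snn = sum(colSums(P)^2) / Ns^2,
    glv = sum(P / Ns * (G - mu_g)^2),
    sv = sum(P / Ns * (S - mu_s)^2),
    entropy = plog2(as.vector(P / Ns)),
    lgl = sum(P / G^2) / Ns,
    hgl = sum(P * G^2) / Ns,
    small_lgl = sum(P / (G^2 * S^2)) / Ns,
    small_hgl = sum(P * G^2 / S^2) / Ns,
    large_lgl = sum(P * S^2 / G^2) / Ns,
    large_hgl = sum(P * G^2 * S^2) / Ns
  )
  setNames(as.numeric(vals[names(labels)]), paste0(prefix, unname(labels)))
}

glrlm_features <- function(lv_arr, Ng, n_vox) {
  mats <- cpp_glrlm(as.integer(lv_arr), dim(lv_arr), Ng)
  labels <- c(small = "ShortRunEmphasis", large = "LongRunEmphasis",
              gln = "GrayLevelNonUniformity", glnn = "GrayLevelNonUniformityNormalized",
              sn = "RunLengthNonUniformity", snn = "RunLengthNonUniformityNormalized",
              rp = "RunPercentage",
              glv = "GrayLevelVariance", sv = "RunVariance", entropy = "RunEntropy",
              lgl = "LowGrayLevelRunEmphasis", hgl = "HighGrayLevelRunEmphasis",
              small_lgl = "ShortRunLowGrayLevelEmphasis",
              small_hgl = "ShortRunHighGrayLevelEmphasis",
              large_lgl = "LongRunLowGrayLevelEmphasis",
              large_hgl = "LongRunHighGrayLevelEmphasis")
  per_dir <- purrr::map(mats, function(P) {
    base <- rl_style_features(P, "glrlm_", labels[setdiff(names(labels), "rp")])
    c(base, glrlm_RunPercentage = sum(P) / n_vox)
  })
  res <- Reduce(`+`, per_dir) / length(per_dir)
  # keep a stable documented order
  ord <- paste0("glrlm_", labels)
  res[ord]
}

glszm_features <- function(lv_arr, Ng, n_vox) {
  zones <- cpp_glszm(as.integer(lv_arr), dim(lv_arr))
  smax <- max(zones[, 2])
  P <- matrix(0, Ng, smax)
  for (r in seq_len(nrow(zones))) {
    P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
  }
  labels <- c(small = "SmallAreaEmphasis", large = "LargeAreaEmphasis",
              gln = "GrayLevelNonUniformity", glnn = "GrayLevelNonUniformityNormalized",
              sn = "SizeZoneNonUniformity", snn = "SizeZoneNonUniformityNormalized",
              glv = "GrayLevelVariance", sv = "ZoneVariance", entropy = "ZoneEntropy",
              lgl = "LowGrayLevelZoneEmphasis", hgl = "HighGrayLevelZoneEmphasis",
              small_lgl = "SmallAreaLowGrayLevelEmphasis",
              small_hgl = "SmallAreaHighGrayLevelEmphasis",
              large_lgl = "LargeAreaLowGrayLevelEmphasis",
              large_hgl = "LargeAreaHighGrayLevelEmphasis")
  out <- rl_style_features(P, "glszm_", labels)
  c(out, glszm_ZonePercentage = nrow(zones) / n_vox)
}

# Shift an array by an offset, zero-filled: S[v] = a[v + off] where in bounds.
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- list()
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      dst[[ax]] <- seq_len(d[ax] - o)
      src[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      dst[[ax]] <- seq_len(d[ax] + o) - o
      src[[ax]] <- seq_len(d[ax] + o)
    }
    if (length(dst[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

all_offsets_26 <- function() {
  g <- expand.grid(dh = -1:1, dw = -1:1, dz = -1:1)
  as.matrix(g[!(g$dh == 0 & g$dw == 0 & g$dz == 0), ])
}

gldm_features <- function(lv_arr, Ng, alpha) {
  valid <- (lv_arr > 0) * 1
  dep <- array(0, dim(lv_arr))
  offs <- all_offsets_26()
  for (r in seq_len(nrow(offs))) {
    nb_lv <- shift_array(lv_arr, offs[r, ])
    nb_ok <- shift_array(valid, offs[r, ])
    dep <- dep + (nb_ok > 0 & abs(nb_lv - lv_arr) <= alpha)
  }
  # dependence includes the center voxel
  roi <- lv_arr > 0
  d <- dep[roi] + 1
  g <- lv_arr[roi]
  P <- matrix(0, Ng, max(d))
  for (k in seq_along(d)) P[g[k], d[k]] <- P[g[k], d[k]] + 1
  labels <- c(small = "SmallDependenceEmphasis", large = "LargeDependenceEmphasis",
              gln = "GrayLevelNonUniformity",
              sn = "DependenceNonUniformity", snn = "DependenceNonUniformityNormalized",
              glv = "GrayLevelVariance", sv = "DependenceVariance",
              entropy = "DependenceEntropy",
              lgl = "LowGrayLevelEmphasis", hgl = "HighGrayLevelEmphasis",
              small_lgl = "SmallDependenceLowGrayLevelEmphasis",
              small_hgl = "SmallDependenceHighGrayLevelEmphasis",
              large_lgl = "LargeDependenceLowGrayLevelEmphasis",
              large_hgl = "LargeDependenceHighGrayLevelEmphasis")
  rl_style_features(P, "gldm_", labels)
}

ngtdm_features <- function(lv_arr, Ng) {
  valid <- (lv_arr > 0) * 1
  nb_sum <- array(0, dim(lv_arr))
  nb_cnt <- array(0, dim(lv_arr))
  offs <- all_offsets_26()
  for (r in seq_len(nrow(offs))) {
    nb_lv <- shift_array(lv_arr, offs[r, ])
    nb_ok <- shift_array(valid, offs[r, ])
    nb_sum <- nb_sum + nb_lv * nb_ok
    nb_cnt <- nb_cnt + nb_ok
  }
  roi <- lv_arr > 0 & nb_cnt > 0
  g <- lv_arr[roi]
  A <- nb_sum[roi] / nb_cnt[roi]
  Nvp <- length(g)
  s <- vapply(seq_len(Ng), function(i) sum(abs(i - A[g == i])), numeric(1))
  n_i <- tabulate(g, Ng)
  p_i <- n_i / Nvp
  present <- which(n_i > 0)
  Ngp <- length(present)
  lev <- present
  pv <- p_i[present]
  sv <- s[present]
  coarse_den <- sum(pv * sv)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1) {
    sum(outer(pv, pv) * outer(lev, lev, "-")^2) / (Ngp * (Ngp - 1)) * sum(sv) / Nvp
  } else 0
  busy_den <- sum(abs(outer(lev * pv, lev * pv, "-")))
  busyness <- if (busy_den > 0) 2 * sum(pv * sv) / busy_den else 0
  complexity <- if (Ngp > 1) {
    num <- outer(pv * sv, pv * sv, "+")
    den <- outer(pv, pv, "+")
    sum(abs(outer(lev, lev, "-")) * num / den) / Nvp
  } else 0
  strength <- if (sum(sv) > 0 && Ngp > 1) {
    sum(outer(pv, pv, "+") * outer(lev, lev, "-")^2) / sum(sv)
  } else 0
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

#' Extract the 93 non-shape radiomic features for one ROI
#'
#' Computes 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM
#' features with IBSI-aligned definitions. First-order statistics use raw HU
#' values; texture classes use fixed-bin-width discretized levels. GLCM and
#' GLRLM are evaluated per 3D direction (13 unique offsets) and averaged.
#'
#' @param volume A [labeled_volume()].
#' @param roi_label ROI label present in the mask (>= 2 voxels).
#' @param config An [extraction_config()].
#' @return A named numeric vector of 93 finite values.
#' @export
extract_features <- function(volume, roi_label, config = extraction_config()) {
  stopifnot(inherits(volume, "labeled_volume"), inherits(config, "extraction_config"))
  roi <- volume$mask == roi_label
  n_vox <- sum(roi)
  if (n_vox == 0) stop("missing-roi error: label ", roi_label, " not in mask", call. = FALSE)
  if (n_vox == 1) stop("degenerate-roi error: label ", roi_label, " has a single voxel", call. = FALSE)

  idx <- which(roi, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  sub_i <- volume$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_m <- roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  x <- sub_i[sub_m]
  lv <- array(0L, dim(sub_i))
  lv[sub_m] <- discretize_levels(x, config$bin_width)
  Ng <- max(lv)

  fo <- fo_features(x, config$bin_width, prod(volume$spacing))
  out <- c(
    setNames(fo, paste0("firstorder_", names(fo))),
    glcm_features(lv, Ng, config$glcm_distance),
    glrlm_features(lv, Ng, n_vox),
    glszm_features(lv, Ng, n_vox),
    gldm_features(lv, Ng, config$gldm_alpha),
    ngtdm_features(lv, Ng)
  )
  stopifnot(length(out) == 93)
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Extract a long-format feature table from a set of volumes
#'
#' @param volumes Tibble with columns `group_id`, `scan_id` and a `volume`
#'   list column of [labeled_volume()] (as produced by [simulate_study()]).
#' @param roi_labels ROI labels to extract per volume.
#' @param config An [extraction_config()].
#' @return A tibble with keys `group`, `scan`, `roi` and 93 feature columns.
#'   Rows whose extraction fails are excluded with a warning naming the
#'   reason; an error is raised if no row succeeds.
#' @export
extract_dataset <- function(volumes, roi_labels = 1:4,
                            config = extraction_config()) {
  stopifnot(is.data.frame(volumes),
            all(c("group_id", "scan_id", "volume") %in% names(volumes)))
  grid <- tidyr::expand_grid(i = seq_len(nrow(volumes)), roi = roi_labels)
  rows <- purrr::pmap(grid, function(i, roi) {
    res <- tryCatch(
      extract_features(volumes$volume[[i]], roi, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("excluded (group %s, scan %s, roi %s): %s",
                      volumes$group_id[i], volumes$scan_id[i], roi,
                      conditionMessage(res)), call. = FALSE)
      return(NULL)
    }
    dplyr::bind_cols(tibble(group = volumes$group_id[i],
                            scan = volumes$scan_id[i], roi = roi),
                     as_tibble(as.list(res)))
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) stop("empty-table error: no ROI extracted successfully", call. = FALSE)
  dplyr::bind_rows(rows)
}

#' Identify the feature columns of a feature table
#'
#' @param table A feature table (tibble with key columns `group`, `scan`,
#'   `roi` and numeric feature columns).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("group", "scan", "roi"))
}
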