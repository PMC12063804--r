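
# FFT Gaussian smoothing with periodic boundary; sigma per axis in voxels.
gaussian_blur_fft <- function(arr, sigma_vox) {
  if (all(sigma_vox < 1e-8)) return(arr)
  d <- dim(arr)
  axis_tf <- function(n, sigma) {
    f <- (seq_len(n) - 1) / n
    f[f > 0.5] <- f[f > 0.5] - 1
    exp(-2 * pi^2 * sigma^2 * f^2)
  }
  tf <- outer(outer(axis_tf(d[1], sigma_vox[1]), axis_tf(d[2], sigma_vox[2])),
              axis_tf(d[3], sigma_vox[3]))
  Re(fft(fft(arr) * tf, inverse = TRUE)) / prod(d)
}

# Spatially correlated unit-scale noise field.
correlated_field <- function(dim, sigma_vox) {
  noise <- array(rnorm(prod(dim)), dim)
  gaussian_blur_fft(noise, sigma_vox)
}

# Standardize a field over given voxel indices to an exact mean/sd.
standardize_to <- function(values, mean_target, sd_target) {
  s <- sd(values)
  if (!is.finite(s) || s < 1e-12) return(rep(mean_target, length(values)))
  mean_target + sd_target * (values - mean(values)) / s
}

super_ellipsoid_mask <- function(dim, center, semi, power = 2.5) {
  gx <- (seq_len(dim[1]) - center[1]) / semi[1]
  gy <- (seq_len(dim[2]) - center[2]) / semi[2]
  gz <- (seq_len(dim[3]) - center[3]) / semi[3]
  r <- outer(outer(abs(gx)^power, abs(gy)^power, "+"), abs(gz)^power, "+")
  array(r <= 1, dim)
}

#' Generate a phantom-like labeled CT volume
#'
#' Builds a deterministic synthetic abdominal phantom: an air background, a
#' soft-tissue body super-ellipsoid, a liver-like super-ellipsoid, and six
#' ellipsoidal ROI blobs placed at seeded random positions inside the liver
#' (two normal-liver regions, two benign cysts, one hemangioma, one
#' metastasis, mirroring the annotated ROI multiplicity). Each ROI is filled
#' with spatially correlated Gaussian texture standardized exactly to its
#' tissue's mean/sd.
#'
#' @param seed Integer seed; the volume is bit-identical for a fixed seed.
#' @param shape Integer length-3 grid dimensions.
#' @param spacing Voxel spacing in mm.
#' @param tissues Tissue statistics, see [tissue_specs()].
#' @param air_hu,body_hu,liver_hu Background intensities (HU).
#' @return A [labeled_volume()] with mask labels 1-4 all present.
#' @export
generate_phantom <- function(seed, shape = c(64, 64, 48), spacing = c(1, 1, 1),
                             tissues = tissue_specs(), air_hu = -1000,
                             body_hu = 20, liver_hu = 55) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape <= 0)) {
    stop("`shape` must be 3 positive integers", call. = FALSE)
  }
  if (nrow(tissues) != 4) {
    stop("invalid tissue spec: exactly 4 tissues required", call. = FALSE)
  }
  if (anyDuplicated(tissues$label) || !setequal(tissues$label, 1:4)) {
    stop("invalid tissue spec: duplicate or missing labels", call. = FALSE)
  }
  if (any(shape < 16)) {
    stop("placement error: shape too small to place ROIs (need >= 16 voxels per axis)",
         call. = FALSE)
  }
  with_seed(seed, {
    inten <- array(air_hu, shape)
    mask <- array(0L, shape)
    center <- (shape + 1) / 2

    body <- super_ellipsoid_mask(shape, center, semi = 0.46 * shape, power = 2.5)
    body_tex <- correlated_field(shape, 3 / spacing)
    inten[body] <- standardize_to(body_tex[body], body_hu, 5)

    liver_c <- center + c(-0.08, 0.05, 0) * shape
    liver_semi <- c(0.30, 0.27, 0.32) * shape
    liver <- super_ellipsoid_mask(shape, liver_c, liver_semi, power = 2.2) & body
    liver_tex <- correlated_field(shape, 3 / spacing)
    inten[liver] <- standardize_to(liver_tex[liver], liver_hu, 8)

    # 6 blobs: labels 1,1,2,2,3,4 (normal liver x2, cyst x2, hemangioma, metastasis)
    blob_labels <- c(1L, 1L, 2L, 2L, 3L, 4L)
    liver_idx <- which(liver, arr.ind = TRUE)
    for (lab in blob_labels) {
      placed <- FALSE
      for (try in seq_len(300)) {
        semi <- pmax(2, round(runif(3, 0.055, 0.095) * shape))
        ctr <- liver_idx[sample.int(nrow(liver_idx), 1), ]
        blob <- super_ellipsoid_mask(shape, ctr, semi, power = 2)
        inside <- blob & liver
        if (sum(inside) < 0.7 * sum(blob)) next        # mostly within liver
        if (sum(inside) < 8) next
        if (any(mask[inside] != 0L)) next              # non-overlapping
        mask[inside] <- lab
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("placement error: could not place ROI label ", lab,
             " without overlap; increase `shape`", call. = FALSE)
      }
    }

    for (i in seq_len(nrow(tissues))) {
      lab <- tissues$label[i]
      vox <- mask == lab
      tex <- correlated_field(shape, tissues$corr_length[i] / spacing)
      inten[vox] <- standardize_to(tex[vox], tissues$mean_hu[i], tissues$hu_sd[i])
    }
    labeled_volume(inten, spacing, mask)
  })
}

#' Simulate the effect of a reconstruction protocol on a volume
#'
#' Applies, in order: (a) a Gaussian point-spread-function blur with the
#' group's kernel sharpness sigma; (b) slice-thickness averaging along z (box
#' filter of width thickness) followed by resampling to the slice spacing and
#' back to the native grid; (c) additive Gaussian noise whose amplitude is
#' multiplied by `fbp_noise_factor` for FBP reconstructions (FBP is noisier
#' than IR). The ROI mask is never altered.
#'
#' @param volume A [labeled_volume()].
#' @param group Either a `group_id` (looked up in [ct_group_configs()]) or a
#'   single-row group config data frame.
#' @param seed Integer seed driving the noise draw.
#' @param base_noise_sd Additive noise sd in HU for IR; use 0 for a noiseless
#'   operator.
#' @param fbp_noise_factor Noise multiplier for FBP (default 1.5).
#' @return A [labeled_volume()] with the same mask.
#' @export
apply_acquisition <- function(volume, group, seed, base_noise_sd = 10,
                              fbp_noise_factor = 1.5) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (is.numeric(group) && length(group) == 1) {
    cfgs <- ct_group_configs()
    group <- cfgs[cfgs$group_id == as.integer(group), ]
    if (nrow(group) != 1) stop("unknown group id", call. = FALSE)
  }
  if (!is.data.frame(group) || nrow(group) != 1) {
    stop("invalid config: `group` must be one config row or a group id", call. = FALSE)
  }
  if (!is.finite(group$slice_thickness) || !is.finite(group$slice_spacing) ||
      group$slice_spacing <= 0 || group$slice_thickness <= 0) {
    stop("invalid config: non-positive slice thickness/spacing", call. = FALSE)
  }
  x <- volume$intensities
  dz <- volume$spacing[3]

  # (a) kernel PSF
  x <- gaussian_blur_fft(x, group$psf_sigma / volume$spacing)

  # (b) slice thickness: box average along z of width thickness
  wv <- max(1L, as.integer(round(group$slice_thickness / dz)))
  if (wv > 1L) {
    d <- dim(x)
    flat <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
    cs <- cbind(0, t(apply(flat, 1, cumsum)))
    half <- (wv - 1) %/% 2
    lo <- pmax(seq_len(d[3]) - half, 1)
    hi <- pmin(seq_len(d[3]) + (wv - 1 - half), d[3])
    out <- (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
      rep(hi - lo + 1, each = nrow(flat))
    x <- array(out, d)
  }

  # slice spacing: decimate along z to the group's spacing and interpolate back
  if (abs(group$slice_spacing - dz) > 1e-9) {
    d <- dim(x)
    z_native <- (seq_len(d[3]) - 1) * dz
    z_coarse <- seq(0, max(z_native), by = group$slice_spacing)
    flat <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
    coarse <- t(apply(flat, 1, function(v) approx(z_native, v, xout = z_coarse, rule = 2)$y))
    fine <- t(apply(coarse, 1, function(v) approx(z_coarse, v, xout = z_native, rule = 2)$y))
    x <- array(fine, d)
  }

  # (c) reconstruction noise
  noise_sd <- base_noise_sd * if (group$algorithm == "FBP") fbp_noise_factor else 1
  if (noise_sd > 0) {
    x <- x + with_seed(seed, array(rnorm(length(x), sd = noise_sd), dim(x)))
  }
  labeled_volume(x, volume$spacing, volume$mask)
}

#' Simulation design for feature tables
#'
#' Encodes the generative model under which a radiomic feature value for
#' sample j in batch i is
#' \deqn{y_{ij} = \alpha + \beta X_{ij} + \gamma_i + \delta_i \epsilon_{ij},
#'   \quad \epsilon_{ij} \sim N(0, \sigma^2)}
#' with per-batch additive effects \eqn{\gamma_i} and multiplicative effects
#' \eqn{\delta_i > 0}. An optional scan-level random effect (`scan_sd`),
#' shared across batches for the same (scan, roi), emulates test-retest scans
#' whose raw acquisitions are reconstructed under every protocol arm.
#'
#' @param n_features Number of features.
#' @param batch_ids Batch (group) identifiers.
#' @param n_scans Scans per batch.
#' @param roi_labels ROI labels replicated within each scan.
#' @param alpha Per-feature grand mean (scalar or length `n_features`).
#' @param beta Covariate coefficients: `NULL`, a vector (one per covariate,
#'   shared across features), or a matrix (covariates x features).
#' @param covariates Design-matrix columns, one row per (batch, scan, roi) sample.
#' @param gamma Additive batch effects: scalar, per-batch vector, or
#'   batches x features matrix.
#' @param delta Multiplicative batch effects (> 0), same shapes as `gamma`.
#' @param noise_sd Error scale of \eqn{\epsilon}.
#' @param scan_sd Sd of the shared scan-level effect (0 = pure batch model).
#' @param seed Integer seed.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_features, batch_ids, n_scans, roi_labels = 1L,
                       alpha = 0, beta = NULL, covariates = NULL,
                       gamma = 0, delta = 1, noise_sd = 1, scan_sd = 0,
                       seed = 1) {
  B <- length(batch_ids)
  expand_bf <- function(x, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(B, n_features))) {
        stop("invalid design: ", what, " matrix must be batches x features", call. = FALSE)
      }
      return(x)
    }
    if (length(x) == 1) return(matrix(x, B, n_features))
    if (length(x) == B) return(matrix(x, B, n_features))
    stop("invalid design: ", what, " must be scalar, per-batch, or a matrix", call. = FALSE)
  }
  gamma <- expand_bf(gamma, "gamma")
  delta <- expand_bf(delta, "delta")
  if (any(delta <= 0)) stop("invalid design: delta must be > 0", call. = FALSE)
  n <- B * n_scans * length(roi_labels)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) {
      stop("invalid design: covariate rows must match sample count ", n, call. = FALSE)
    }
    if (is.null(beta)) stop("invalid design: covariates given without beta", call. = FALSE)
    beta <- if (is.matrix(beta)) beta else matrix(beta, ncol(covariates), n_features)
    if (nrow(beta) != ncol(covariates)) {
      stop("invalid design: beta rows must match covariate columns", call. = FALSE)
    }
  }
  alpha <- if (length(alpha) == 1) rep(alpha, n_features) else alpha
  if (length(alpha) != n_features) {
    stop("invalid design: alpha must be scalar or per-feature", call. = FALSE)
  }
  structure(list(n_features = n_features, batch_ids = batch_ids,
                 n_scans = n_scans, roi_labels = roi_labels, alpha = alpha,
                 beta = beta, covariates = covariates, gamma = gamma,
                 delta = delta, noise_sd = noise_sd, scan_sd = scan_sd,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Study-default simulation design
#'
#' Eight protocol groups, 30 test-retest scans, 4 ROIs, 93 features. Batch
#' effects are drawn once from the design seed: additive effects
#' gamma ~ N(0, 0.5), multiplicative effects delta ~ U(0.8, 1.3), both fixed
#' to (0, 1) for the reference group; a unit-sd scan-level effect shared
#' across groups models the common raw acquisitions; residual noise sd 0.15.
#'
#' @param n_features,seed,reference_batch See [sim_design()].
#' @return A `sim_design`.
#' @export
default_sim_design <- function(n_features = 93, seed = 20260924L,
                               reference_batch = 7L) {
  batches <- 1:8
  with_seed(child_seed(seed, "design"), {
    gamma <- matrix(rnorm(8 * n_features, sd = 0.5), 8, n_features)
    delta <- matrix(runif(8 * n_features, 0.8, 1.3), 8, n_features)
    alpha <- rnorm(n_features, 0, 2)
  })
  ref <- match(reference_batch, batches)
  gamma[ref, ] <- 0
  delta[ref, ] <- 1
  sim_design(n_features = n_features, batch_ids = batches, n_scans = 30,
             roi_labels = 1:4, alpha = alpha, gamma = gamma, delta = delta,
             noise_sd = 0.15, scan_sd = 1, seed = seed)
}

#' Simulate a long-format feature table from a design
#'
#' Draws a table with one row per (group, scan, roi) and one column per
#' feature from the generative model in [sim_design()]. The ground-truth
#' batch effects are attached as attribute `"sim_design"` for recovery tests.
#'
#' @param design A [sim_design()].
#' @return A tibble with key columns `group`, `scan`, `roi` and feature
#'   columns `f001`, `f002`, ...
#' @export
simulate_feature_table <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  B <- length(design$batch_ids)
  S <- design$n_scans
  R <- length(design$roi_labels)
  Fn <- design$n_features
  keys <- tidyr::expand_grid(group = design$batch_ids,
                             scan = seq_len(S),
                             roi = design$roi_labels)
  n <- nrow(keys)
  Y <- with_seed(design$seed, {
    eps <- matrix(rnorm(n * Fn, sd = design$noise_sd), n, Fn)
    scan_eff <- if (design$scan_sd > 0) {
      se <- matrix(rnorm(S * R * Fn, sd = design$scan_sd), S * R, Fn)
      idx <- match(paste(keys$scan, keys$roi),
                   paste(rep(seq_len(S), each = R), rep(design$roi_labels, S)))
      se[idx, , drop = FALSE]
    } else 0
    bi <- match(keys$group, design$batch_ids)
    out <- matrix(design$alpha, n, Fn, byrow = TRUE) +
      design$gamma[bi, , drop = FALSE] +
      design$delta[bi, , drop = FALSE] * eps + scan_eff
    if (!is.null(design$covariates)) {
      out <- out + design$covariates %*% design$beta
    }
    out
  })
  colnames(Y) <- sprintf("f%03d", seq_len(Fn))
  out <- dplyr::bind_cols(keys, as_tibble(Y))
  attr(out, "sim_design") <- design
  out
}

#' Simulate a multi-protocol test-retest imaging study
#'
#' For each scan index a base phantom is generated (seeded by scan, so the
#' underlying object is shared across protocol arms, as when the same raw
#' acquisitions are reconstructed under every setting), then each group's
#' acquisition operator is applied with a (scan, group)-specific noise seed.
#'
#' @param groups Group ids to simulate.
#' @param scans_per_group Number of test-retest scans.
#' @param seed Master integer seed.
#' @param shape,spacing,tissues Passed to [generate_phantom()].
#' @param configs Group configuration table, see [ct_group_configs()].
#' @param base_noise_sd Acquisition noise scale, see [apply_acquisition()].
#' @return A tibble with columns `group_id`, `scan_id`, `volume` (list column
#'   of [labeled_volume()]); the generating manifest is attached as attribute
#'   `"manifest"`.
#' @export
simulate_study <- function(groups = 1:8, scans_per_group = 30, seed = 1L,
                           shape = c(64, 64, 48), spacing = c(1, 1, 1),
                           tissues = tissue_specs(),
                           configs = ct_group_configs(),
                           base_noise_sd = 10) {
  validate_group_config(configs)
  rows <- tidyr::expand_grid(group_id = as.integer(groups),
                             scan_id = seq_len(scans_per_group))
  vols <- purrr::pmap(rows, function(group_id, scan_id) {
    base <- generate_phantom(child_seed(seed, "scan", scan_id), shape = shape,
                             spacing = spacing, tissues = tissues)
    apply_acquisition(base, configs[configs$group_id == group_id, ],
                      seed = child_seed(seed, "acq", scan_id, group_id),
                      base_noise_sd = base_noise_sd)
  })
  out <- dplyr::mutate(rows, volume = vols)
  attr(out, "manifest") <- list(
    seed = as.integer(seed), groups = as.integer(groups),
    scans_per_group = as.integer(scans_per_group), shape = as.integer(shape),
    spacing = spacing, base_noise_sd = base_noise_sd,
    tissues = as.data.frame(tissues), configs = as.data.frame(configs)
  )
  out
}

#' Write a simulated study to disk as NIfTI volumes plus a JSON manifest
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::pwalk(study, function(group_id, scan_id, volume) {
    write_volume(volume, file.path(dir, sprintf("g%02d_s%03d", group_id, scan_id)))
  })
  manifest <- attr(study, "manifest")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Regenerate a study from its manifest
#'
#' @param manifest Manifest list or path to a `manifest.json`.
#' @return The regenerated study tibble (bit-identical to the original).
#' @export
regenerate_study <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  simulate_study(groups = manifest$groups,
                 scans_per_group = manifest$scans_per_group,
                 seed = manifest$seed, shape = manifest$shape,
                 spacing = manifest$spacing,
                 tissues = as_tibble(manifest$tissues),
                 configs = as_tibble(manifest$configs),
                 base_noise_sd = manifest$base_noise_sd)
}
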