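
#' Configuration for an end-to-end harmonization run
#'
#' @param groups Protocol group ids to include (must contain the reference).
#' @param scans_per_group Test-retest scans per group.
#' @param shape,spacing Phantom grid geometry.
#' @param seed Master seed; all stage seeds derive from it.
#' @param reference_group Reference batch (default 7).
#' @param base_noise_sd Acquisition noise scale (HU).
#' @param extraction An [extraction_config()].
#' @param gan A [train_config()] for the image-level stage.
#' @param clip HU clipping window applied before feature extraction.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(groups = 1:8, scans_per_group = 30,
                            shape = c(64, 64, 48), spacing = c(1, 1, 1),
                            seed = 1L, reference_group = 7L,
                            base_noise_sd = 10,
                            extraction = extraction_config(),
                            gan = train_config(), clip = c(-45, 125)) {
  if (!reference_group %in% groups) {
    stop("config error: reference group missing from `groups`", call. = FALSE)
  }
  structure(list(groups = groups, scans_per_group = scans_per_group,
                 shape = shape, spacing = spacing, seed = as.integer(seed),
                 reference_group = reference_group,
                 base_noise_sd = base_noise_sd, extraction = extraction,
                 gan = gan, clip = clip),
            class = "pipeline_config")
}

clip_study <- function(study, clip) {
  study$volume <- purrr::map(study$volume, clip_intensity, lo = clip[1], hi = clip[2])
  study
}

# Train one harmonizer per non-reference group on paired mid-volume slices
# and apply it slice-wise to every volume of that group.
gan_harmonize_study <- function(study, config) {
  ref_vols <- study[study$group_id == config$reference_group, ]
  out <- study
  models <- list()
  lo <- config$clip[1]; hi <- config$clip[2]
  mid_slice <- function(v) hu_to_unit(v$intensities[, , ceiling(dim(v$intensities)[3] / 2)],
                                      lo, hi)
  for (g in setdiff(unique(study$group_id), config$reference_group)) {
    src_vols <- study[study$group_id == g, ]
    pairs <- purrr::map(seq_len(nrow(src_vols)), function(i) {
      ref_v <- ref_vols$volume[[match(src_vols$scan_id[i], ref_vols$scan_id)]]
      list(source = mid_slice(src_vols$volume[[i]]), target = mid_slice(ref_v))
    })
    cfg <- config$gan
    cfg$seed <- child_seed(config$seed, "gan", g)
    model <- train_harmonizer(pairs, cfg, source_group = g,
                              reference_group = config$reference_group)
    models[[as.character(g)]] <- model
    rows <- which(out$group_id == g)
    for (i in rows) {
      v <- out$volume[[i]]
      u <- hu_to_unit(v$intensities, lo, hi)
      h <- harmonize_images(model, u)
      out$volume[[i]] <- labeled_volume(unit_to_hu(h, lo, hi), v$spacing, v$mask)
    }
  }
  attr(out, "models") <- models
  attr(out, "manifest") <- attr(study, "manifest")
  out
}

evaluate_features <- function(features, harmonized, config) {
  tbl <- if (is.null(harmonized)) features else harmonized
  list(
    reproducibility = reproducibility_report(features, harmonized,
                                             reference_group = config$reference_group),
    stability = stability_report(tbl, reference_group = config$reference_group),
    discrimination = discrimination_report(tbl, seed = child_seed(config$seed, "svm"))
  )
}

#' Run one harmonization sub-experiment end to end
#'
#' Three designs are supported on a synthetic (or supplied) multi-protocol
#' test-retest study:
#' \describe{
#'   \item{`"image"`}{per-group paired GAN harmonization to the reference
#'     group, then feature extraction and evaluation;}
#'   \item{`"feature"`}{feature extraction, then per-ROI reference-batch
#'     ComBat, then evaluation;}
#'   \item{`"combined"`}{GAN-harmonized images feed feature extraction,
#'     followed by per-ROI ComBat (always GAN first, then ComBat), then
#'     evaluation.}
#' }
#' Every run records a manifest (seeds, configs, stage order, package
#' version) sufficient to regenerate its outputs.
#'
#' @param which `"image"`, `"feature"`, or `"combined"`.
#' @param config A [pipeline_config()].
#' @param study Optional pre-built study tibble (see [simulate_study()]);
#'   generated from `config` when omitted.
#' @return A `subexperiment_report` bundle with the baseline and harmonized
#'   feature tables, evaluation sections, a [method_summary()], and the
#'   manifest.
#' @export
run_subexperiment <- function(which = c("image", "feature", "combined"),
                              config = pipeline_config(), study = NULL) {
  if (!is.character(which) || !which[1] %in% c("image", "feature", "combined")) {
    stop("usage error: unknown sub-experiment '", which[1], "'", call. = FALSE)
  }
  which <- which[1]
  if (is.null(config$reference_group)) stop("config error: no reference group", call. = FALSE)
  if (is.null(study)) {
    study <- simulate_study(groups = config$groups,
                            scans_per_group = config$scans_per_group,
                            seed = child_seed(config$seed, "study"),
                            shape = config$shape, spacing = config$spacing,
                            base_noise_sd = config$base_noise_sd)
  }
  study <- clip_study(study, config$clip)
  baseline_features <- extract_dataset(study, config = config$extraction)

  stages <- character(0)
  image_quality_section <- NULL
  feats <- baseline_features
  if (which %in% c("image", "combined")) {
    stages <- c(stages, "gan")
    # config$gan = NULL requests an identity image stage (ablation aid)
    harmonized_study <- if (is.null(config$gan)) study else gan_harmonize_study(study, config)
    feats <- if (is.null(config$gan)) baseline_features else
      extract_dataset(harmonized_study, config = config$extraction)
    lo <- config$clip[1]; hi <- config$clip[2]
    mid <- function(v) hu_to_unit(v$intensities[, , ceiling(dim(v$intensities)[3] / 2)], lo, hi)
    gl <- tl <- list(); gg <- integer(0)
    ref_rows <- which(study$group_id == config$reference_group)
    for (g in setdiff(unique(study$group_id), config$reference_group)) {
      rows <- which(study$group_id == g)
      for (i in rows) {
        j <- ref_rows[match(study$scan_id[i], study$scan_id[ref_rows])]
        gl[[length(gl) + 1]] <- mid(harmonized_study$volume[[i]])
        tl[[length(tl) + 1]] <- mid(study$volume[[j]])
        gg <- c(gg, g)
      }
    }
    image_quality_section <- image_quality(gl, tl, data_range = 1, groups = gg)
  }
  if (which %in% c("feature", "combined")) {
    stages <- c(stages, "combat")
    feats <- harmonize_per_roi(feats, reference_batch = config$reference_group)
  }
  evals <- evaluate_features(baseline_features, feats, config)

  rsum <- evals$reproducibility$summary
  summary <- method_summary(
    average_ccc = rsum$average_ccc[rsum$set == "harmonized"],
    pct_reproducible = 100 * rsum$frac_reproducible[rsum$set == "harmonized"],
    stability_pct_per_roi = setNames(evals$stability$per_roi$pct_stable,
                                     evals$stability$per_roi$roi),
    auc_per_roi = setNames(evals$discrimination$per_class_auc$auc,
                           evals$discrimination$per_class_auc$class),
    macro_auc = evals$discrimination$macro_auc
  )
  manifest <- list(which = which, stages = stages, seed = config$seed,
                   groups = config$groups,
                   scans_per_group = config$scans_per_group,
                   shape = config$shape, reference_group = config$reference_group,
                   study_manifest = attr(study, "manifest"),
                   package_version = as.character(utils::packageVersion("ctharmony")))
  structure(list(which = which, stages = stages,
                 baseline_features = baseline_features,
                 harmonized_features = feats,
                 reproducibility = evals$reproducibility,
                 stability = evals$stability,
                 discrimination = evals$discrimination,
                 image_quality = image_quality_section,
                 summary = summary, manifest = manifest),
            class = "subexperiment_report")
}

#' @export
print.subexperiment_report <- function(x, ...) {
  cat("<subexperiment_report>", x$which, "| stages:",
      paste(x$stages, collapse = " -> "), "\n")
  print(x$summary)
  invisible(x)
}

#' Bundle headline metrics of one harmonization method
#'
#' Light container used by [compare_methods()]; can be built directly from
#' reported per-ROI values or is produced by [run_subexperiment()].
#'
#' @param average_ccc Average CCC across features/ROIs/groups.
#' @param pct_reproducible Percent of comparisons with CCC at/above threshold.
#' @param stability_pct_per_roi Named numeric: percent stable features per ROI.
#' @param auc_per_roi Named numeric: per-ROI (per-class) AUC.
#' @param macro_auc Optional macro AUC; defaults to the mean of `auc_per_roi`.
#' @return A `method_summary`.
#' @export
method_summary <- function(average_ccc = NA_real_, pct_reproducible = NA_real_,
                           stability_pct_per_roi = NULL, auc_per_roi = NULL,
                           macro_auc = NULL) {
  if (is.null(macro_auc) && !is.null(auc_per_roi)) {
    macro_auc <- mean(auc_per_roi)
  }
  structure(list(average_ccc = as.numeric(average_ccc)[1],
                 pct_reproducible = as.numeric(pct_reproducible)[1],
                 stability_pct_per_roi = stability_pct_per_roi,
                 auc_per_roi = auc_per_roi,
                 macro_auc = if (is.null(macro_auc)) NA_real_ else macro_auc),
            class = "method_summary")
}

#' @export
print.method_summary <- function(x, ...) {
  cat(sprintf("  avg CCC %.3f | %% reproducible %.2f | macro AUC %.3f | avg stability %.2f%%\n",
              x$average_ccc, x$pct_reproducible, x$macro_auc,
              if (is.null(x$stability_pct_per_roi)) NA else mean(x$stability_pct_per_roi)))
  invisible(x)
}

get_summary <- function(x) {
  if (inherits(x, "method_summary")) return(x)
  if (inherits(x, "subexperiment_report")) return(x$summary)
  stop("comparability error: expected a method_summary or subexperiment_report",
       call. = FALSE)
}

#' Compare harmonization methods against the non-harmonized baseline
#'
#' Assembles the headline tables (average CCC and percent reproducible;
#' per-ROI and average stability; per-ROI and macro AUC) for the four
#' designs and the relative percent change of each method vs the
#' non-harmonized baseline, computed as
#' `100 * (method - baseline) / baseline` (recorded in the output's
#' `"relative_change_formula"` attribute).
#'
#' @param reports Named list with elements `none`, `combat`, `gan`,
#'   `gan_combat`; each a [method_summary()] or [run_subexperiment()] bundle.
#' @return A `method_comparison` with tibbles `ccc`, `stability`, `auc`.
#' @export
compare_methods <- function(reports) {
  need <- c("none", "combat", "gan", "gan_combat")
  miss <- setdiff(need, names(reports))
  if (length(miss)) stop("missing method bundle(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sums <- purrr::map(reports[need], get_summary)
  bundles <- purrr::keep(reports[need], inherits, "subexperiment_report")
  if (length(bundles) > 1) {
    keys <- purrr::map(bundles, function(b) b$manifest$study_manifest)
    if (!all(purrr::map_lgl(keys[-1], identical, keys[[1]]))) {
      stop("comparability error: bundles computed on different inputs", call. = FALSE)
    }
  }
  relchg <- function(x, base) 100 * (x - base) / base

  ccc_tbl <- tibble(
    method = need,
    average_ccc = unname(purrr::map_dbl(sums, "average_ccc")),
    pct_reproducible = unname(purrr::map_dbl(sums, "pct_reproducible"))) |>
    dplyr::mutate(
      ccc_change_pct = relchg(.data$average_ccc, .data$average_ccc[1]),
      reproducible_change_pct = relchg(.data$pct_reproducible,
                                       .data$pct_reproducible[1]))

  stab_rows <- purrr::imap(sums, function(s, m) {
    if (is.null(s$stability_pct_per_roi)) return(NULL)
    tibble(method = m, roi = names(s$stability_pct_per_roi),
           pct_stable = as.numeric(s$stability_pct_per_roi))
  })
  stab_tbl <- dplyr::bind_rows(stab_rows)
  if (nrow(stab_tbl) > 0) {
    avg <- stab_tbl |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(average_pct_stable = mean(.data$pct_stable), .groups = "drop")
    base_avg <- avg$average_pct_stable[avg$method == "none"]
    avg$stability_change_pct <- relchg(avg$average_pct_stable, base_avg)
    stab_tbl <- list(per_roi = stab_tbl, average = avg[match(need, avg$method), ])
  } else {
    stab_tbl <- list(per_roi = stab_tbl, average = NULL)
  }

  auc_rows <- purrr::imap(sums, function(s, m) {
    if (is.null(s$auc_per_roi)) return(NULL)
    tibble(method = m, roi = names(s$auc_per_roi), auc = as.numeric(s$auc_per_roi))
  })
  auc_per_roi <- dplyr::bind_rows(auc_rows)
  auc_macro <- tibble(method = need,
                      macro_auc = unname(purrr::map_dbl(sums, "macro_auc"))) |>
    dplyr::mutate(auc_change_pct = relchg(.data$macro_auc, .data$macro_auc[1]))

  out <- structure(list(ccc = ccc_tbl,
                        stability = stab_tbl$average,
                        stability_per_roi = stab_tbl$per_roi,
                        auc = auc_macro, auc_per_roi = auc_per_roi),
                   class = "method_comparison")
  attr(out, "relative_change_formula") <- "100 * (method - baseline) / baseline"
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> relative changes:",
      attr(x, "relative_change_formula"), "\n")
  print(x$ccc)
  if (!is.null(x$stability)) print(x$stability)
  print(x$auc)
  invisible(x)
}
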