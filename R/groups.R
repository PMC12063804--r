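#' Reconstruction-protocol group configurations
#'
#' The eight acquisition arms vary the reconstruction algorithm (filtered back
#' projection, FBP, vs iterative reconstruction, IR), the reconstruction kernel
#' (medium-smooth soft-tissue kernels of two sharpness classes), and the slice
#' thickness/spacing. Group 7 (IR, I30f, 2 mm / 1 mm) is the conventional
#' reference arm to which the others are harmonized.
#'
#' Kernel labels are qualitative; for simulation each label maps to a numeric
#' point-spread-function sigma (mm): the sharper "26f" class gets
#' `sigma_sharp`, the smoother "30f" class `sigma_smooth`.
#'
#' @param sigma_sharp,sigma_smooth PSF sigma (mm) for the 26f / 30f kernel
#'   classes. Must be positive.
#' @return A tibble with one row per group: `group_id`, `algorithm`, `kernel`,
#'   `psf_sigma`, `slice_thickness`, `slice_spacing`.
#' @export
#' @examples
#' ct_group_configs()
ct_group_configs <- function(sigma_sharp = 0.6, sigma_smooth = 1.0) {
  stopifnot(sigma_sharp > 0, sigma_smooth > 0)
  cfg <- tibble::tribble(
    ~group_id, ~algorithm, ~kernel,                   ~slice_thickness, ~slice_spacing,
    1L, "FBP", "B26f medium smooth ASA", 1.0, 0.75,
    2L, "FBP", "B30f medium smooth",     1.5, 1.0,
    3L, "FBP", "B30f medium smooth",     2.0, 1.0,
    4L, "FBP", "B30f medium smooth",     3.0, 2.0,
    5L, "IR",  "I26f medium smooth ASA", 1.0, 0.75,
    6L, "IR",  "I30f medium smooth",     1.5, 1.0,
    7L, "IR",  "I30f medium smooth",     2.0, 1.0,
    8L, "IR",  "I30f medium smooth",     3.0, 2.0
  )
  cfg$psf_sigma <- ifelse(grepl("26f", cfg$kernel), sigma_sharp, sigma_smooth)
  validate_group_config(cfg)
  cfg[, c("group_id", "algorithm", "kernel", "psf_sigma",
          "slice_thickness", "slice_spacing")]
}

validate_group_config <- function(cfg) {
  stopifnot(is.data.frame(cfg))
  req <- c("group_id", "algorithm", "kernel", "psf_sigma",
           "slice_thickness", "slice_spacing")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stop("group config missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cfg$group_id)) {
    stop("group_id must be unique", call. = FALSE)
  }
  if (!all(cfg$algorithm %in% c("FBP", "IR"))) {
    stop("algorithm must be 'FBP' or 'IR'", call. = FALSE)
  }
  if (any(cfg$slice_spacing <= 0) || any(cfg$slice_thickness < cfg$slice_spacing)) {
    stop("require slice_thickness >= slice_spacing > 0", call. = FALSE)
  }
  if (any(cfg$psf_sigma <= 0)) {
    stop("psf_sigma must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Tissue specifications for the four liver-region ROI classes
#'
#' Default Hounsfield-unit statistics for the four annotated tissue classes.
#' The values are generic abdominal-CT textbook magnitudes within the
#' `[-45, 125]` HU display window used downstream, not calibrated to any
#' physical phantom; all are overridable.
#'
#' @param normal_liver,benign_cyst,hemangioma,metastasis Optional named lists
#'   overriding `mean_hu`, `hu_sd`, or `corr_length` (texture correlation
#'   length, mm) per tissue.
#' @return A tibble with columns `label`, `name`, `mean_hu`, `hu_sd`,
#'   `corr_length`.
#' @export
tissue_specs <- function(normal_liver = list(), benign_cyst = list(),
                         hemangioma = list(), metastasis = list()) {
  base <- list(
    normal_liver = list(label = 1L, mean_hu = 60, hu_sd = 12, corr_length = 3),
    benign_cyst  = list(label = 2L, mean_hu = 10, hu_sd = 8,  corr_length = 2),
    hemangioma   = list(label = 3L, mean_hu = 45, hu_sd = 10, corr_length = 2.5),
    metastasis   = list(label = 4L, mean_hu = 30, hu_sd = 12, corr_length = 2)
  )
  over <- list(normal_liver = normal_liver, benign_cyst = benign_cyst,
               hemangioma = hemangioma, metastasis = metastasis)
  rows <- purrr::imap(base, function(spec, nm) {
    spec <- modifyList(spec, over[[nm]])
    tibble(label = as.integer(spec$label), name = nm, mean_hu = spec$mean_hu,
           hu_sd = spec$hu_sd, corr_length = spec$corr_length)
  })
  out <- dplyr::bind_rows(rows)
  validate_tissue_specs(out)
  out
}

validate_tissue_specs <- function(specs) {
  if (!setequal(specs$label, 1:4) || anyDuplicated(specs$label)) {
    stop("tissue specs must carry labels 1-4 exactly once each", call. = FALSE)
  }
  if (any(specs$hu_sd <= 0) || any(specs$corr_length <= 0)) {
    stop("hu_sd and corr_length must be positive", call. = FALSE)
  }
  invisible(specs)
}
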