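
#' Fit a reference-batch ComBat model
#'
#' Estimates the empirical-Bayes location/scale batch-correction model
#' \deqn{y_{ij} = \alpha + \beta X_{ij} + \gamma_i + \delta_i \epsilon_{ij}}
#' in reference-batch mode: per-feature least-squares estimates
#' \eqn{\hat\alpha, \hat\beta} are taken so that \eqn{\hat\alpha} is the
#' reference batch's mean, data are standardized by the reference batch's
#' residual variance, and per-batch location/scale moments are shrunk toward
#' common priors by a non-iterative method-of-moments empirical-Bayes step
#' (normal prior on location, inverse-gamma on scale). The reference batch's
#' effects are fixed at (0, 1) so its data pass through unchanged.
#'
#' @param table Feature table: tibble with a batch column and numeric feature
#'   columns (keys `group`, `scan`, `roi` are recognised automatically).
#' @param batch Name of the batch column (default `"group"`).
#' @param reference_batch Batch id to harmonize toward.
#' @param covariates Optional character vector of covariate columns whose
#'   effects are protected during harmonization.
#' @param eb If `FALSE`, raw per-batch moments are used (no shrinkage).
#' @param features Feature columns; default all non-key, non-covariate
#'   numeric columns.
#' @return A `combat_model`.
#' @export
combat_fit <- function(table, batch = "group", reference_batch,
                       covariates = NULL, eb = TRUE, features = NULL) {
  stopifnot(is.data.frame(table), batch %in% names(table))
  if (is.null(features)) {
    features <- setdiff(names(table), c("group", "scan", "roi", batch, covariates))
    features <- features[vapply(table[features], is.numeric, logical(1))]
  }
  b <- as.character(table[[batch]])
  batches <- unique(b)
  if (length(batches) < 2) stop("need >= 2 batches", call. = FALSE)
  if (!as.character(reference_batch) %in% batches) {
    stop("reference batch ", reference_batch, " not present", call. = FALSE)
  }
  nb <- table(b)
  if (any(nb < 2)) stop("every batch needs >= 2 samples", call. = FALSE)
  Y <- as.matrix(table[features])
  n <- nrow(Y)
  Fh <- length(features)

  Xb <- stats::model.matrix(~ 0 + factor(b, levels = batches))
  colnames(Xb) <- batches
  Xc <- NULL
  if (!is.null(covariates)) {
    Xc <- as.matrix(table[covariates])
    X <- cbind(Xb, Xc)
    if (qr(X)$rank < ncol(X)) {
      stop("design-matrix error: singular covariate design", call. = FALSE)
    }
  } else {
    X <- Xb
  }
  Bhat <- solve(crossprod(X), crossprod(X, Y))
  ref <- as.character(reference_batch)
  alpha_hat <- Bhat[ref, ]
  beta_hat <- if (!is.null(Xc)) Bhat[seq_len(ncol(Xc)) + length(batches), , drop = FALSE] else NULL

  fit <- X %*% Bhat
  ref_rows <- b == ref
  var_pooled <- colMeans((Y[ref_rows, , drop = FALSE] - fit[ref_rows, , drop = FALSE])^2)

  constant <- !is.finite(var_pooled) | var_pooled < 1e-12
  if (any(constant)) {
    warning("constant feature(s) passed through unadjusted: ",
            paste(features[constant], collapse = ", "), call. = FALSE)
    var_pooled[constant] <- 1   # placeholder; flagged features are never adjusted
  }

  stand_mean <- matrix(alpha_hat, n, Fh, byrow = TRUE)
  if (!is.null(beta_hat)) stand_mean <- stand_mean + Xc %*% beta_hat
  Z <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, Fh, byrow = TRUE)

  B <- length(batches)
  gamma_hat <- matrix(NA_real_, B, Fh, dimnames = list(batches, features))
  delta2_hat <- matrix(NA_real_, B, Fh, dimnames = list(batches, features))
  for (i in seq_len(B)) {
    zi <- Z[b == batches[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(zi)
    delta2_hat[i, ] <- apply(zi, 2, var)
  }
  delta2_hat <- pmax(delta2_hat, 1e-12)

  hyper <- NULL
  if (eb) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    hyper <- tibble(batch = batches, gamma_bar = NA_real_, tau2 = NA_real_,
                    a_prior = NA_real_, b_prior = NA_real_)
    for (i in seq_len(B)) {
      if (batches[i] == ref) next
      g <- gamma_hat[i, !constant]
      d2 <- delta2_hat[i, !constant]
      gbar <- mean(g)
      tau2 <- var(g)
      m <- mean(d2)
      s2 <- var(d2)
      a <- if (is.finite(s2) && s2 > 1e-12) (2 * s2 + m^2) / s2 else NA_real_
      bp <- if (is.finite(s2) && s2 > 1e-12) (m * s2 + m^3) / s2 else NA_real_
      hyper[i, -1] <- list(gbar, tau2, a, bp)
      ni <- sum(b == batches[i])
      gs <- if (is.finite(tau2) && tau2 > 1e-12) {
        (ni * tau2 * gamma_hat[i, ] + delta2_hat[i, ] * gbar) /
          (ni * tau2 + delta2_hat[i, ])
      } else gamma_hat[i, ]
      gamma_star[i, ] <- gs
      if (is.finite(a) && (ni / 2 + a - 1) > 0) {
        zi <- Z[b == batches[i], , drop = FALSE]
        ss <- colSums((zi - matrix(gs, ni, Fh, byrow = TRUE))^2)
        delta2_star[i, ] <- (bp + 0.5 * ss) / (ni / 2 + a - 1)
      }
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }
  gamma_star[ref, ] <- 0
  delta2_star[ref, ] <- 1
  delta2_star <- pmax(delta2_star, 1e-12)

  structure(list(
    features = features, batch_col = batch, batches = batches,
    reference_batch = ref, covariates = covariates, eb = eb,
    alpha_hat = alpha_hat, beta_hat = beta_hat, var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta_star = sqrt(delta2_star),
    hyperparams = hyper, constant = setNames(constant, features)
  ), class = "combat_model")
}

#' Apply a fitted ComBat model to a feature table
#'
#' Each non-reference-batch value is standardized, its empirical-Bayes batch
#' location/scale removed, and the result rescaled to reference-batch units:
#' \deqn{y^{ComBat} = \frac{y - \hat\alpha - \hat\beta X - \gamma^*}{\delta^*}
#'   + \hat\alpha + \hat\beta X.}
#' Reference-batch rows and flagged constant features pass through unchanged.
#'
#' @param model A [combat_fit()] model.
#' @param table Feature table with the model's batch and feature columns.
#' @return Harmonized tibble with identical keys and shape.
#' @export
combat_transform <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  miss <- setdiff(model$features, names(table))
  if (length(miss)) stop("table lacks feature columns: ",
                         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  b <- as.character(table[[model$batch_col]])
  unknown <- setdiff(unique(b), model$batches)
  if (length(unknown)) {
    stop("unknown-batch error: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  Y <- as.matrix(table[model$features])
  n <- nrow(Y)
  Fh <- length(model$features)
  stand_mean <- matrix(model$alpha_hat, n, Fh, byrow = TRUE)
  if (!is.null(model$beta_hat)) {
    stand_mean <- stand_mean + as.matrix(table[model$covariates]) %*% model$beta_hat
  }
  sp <- matrix(sqrt(model$var_pooled), n, Fh, byrow = TRUE)
  Z <- (Y - stand_mean) / sp
  bi <- match(b, model$batches)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) / model$delta_star[bi, , drop = FALSE]
  Yadj <- Zadj * sp + stand_mean
  keep <- model$constant
  if (any(keep)) Yadj[, keep] <- Y[, keep]
  ref_rows <- b == model$reference_batch
  Yadj[ref_rows, ] <- Y[ref_rows, ]   # reference-batch convention: untouched
  out <- table
  out[model$features] <- as_tibble(Yadj)
  out
}

#' Per-ROI reference-batch harmonization
#'
#' Fits and applies ComBat independently within each ROI stratum (batch
#' effects on radiomic features are tissue-dependent), then reassembles the
#' table preserving row order.
#'
#' @inheritParams combat_fit
#' @return Harmonized tibble; the per-stratum models are attached as
#'   attribute `"models"`.
#' @export
harmonize_per_roi <- function(table, reference_batch, batch = "group",
                              covariates = NULL, eb = TRUE) {
  stopifnot("roi" %in% names(table))
  idx <- seq_len(nrow(table))
  pieces <- split(idx, table$roi)
  models <- list()
  out <- table
  for (nm in names(pieces)) {
    stratum <- table[pieces[[nm]], , drop = FALSE]
    if (length(unique(stratum[[batch]])) < 2) {
      stop("stratum error: ROI ", nm, " has < 2 batches", call. = FALSE)
    }
    m <- combat_fit(stratum, batch = batch, reference_batch = reference_batch,
                    covariates = covariates, eb = eb)
    models[[nm]] <- m
    out[pieces[[nm]], ] <- combat_transform(m, stratum)
  }
  attr(out, "models") <- models
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features, %d batches (reference: %s), EB %s\n",
              length(x$features), length(x$batches), x$reference_batch,
              if (x$eb) "on" else "off"))
  invisible(x)
}

#' Tidy a ComBat model into per-(batch, feature) effect estimates
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return Tibble with columns `batch`, `feature`, `gamma_hat`, `delta_hat`,
#'   `gamma_star`, `delta_star`.
#' @export
tidy.combat_model <- function(x, ...) {
  tidyr::expand_grid(batch = x$batches, feature = x$features) |>
    dplyr::mutate(
      gamma_hat = as.vector(t(x$gamma_hat)),
      delta_hat = as.vector(t(sqrt(x$delta2_hat))),
      gamma_star = as.vector(t(x$gamma_star)),
      delta_star = as.vector(t(x$delta_star))
    )
}

#' One-line summary of a ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.combat_model <- function(x, ...) {
  tibble(n_features = length(x$features), n_batches = length(x$batches),
         reference_batch = x$reference_batch, eb = x$eb,
         n_constant = sum(x$constant))
}

#' Serialize a ComBat model to JSON
#'
#' @param model A `combat_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_combat_model <- function(model, path) {
  payload <- model
  payload$hyperparams <- as.data.frame(payload$hyperparams)
  for (f in c("gamma_hat", "delta2_hat", "gamma_star", "delta_star")) {
    payload[[f]] <- as.data.frame(payload[[f]])
  }
  jsonlite::write_json(unclass(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
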