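#' Model specification for covariance removal
#'
#' Three tiers of per-marker linear model:
#' \describe{
#'   \item{simple}{one intercept and one slope vector across all cells —
#'     for a single biological system with multiple perturbations.}
#'   \item{offset}{per-sample intercepts, one shared slope vector — when
#'     samples differ by an unwanted offset (e.g. batches).}
#'   \item{interaction}{independent intercept and slopes per sample — when
#'     the marker/confounder relationship differs between cell lines.}
#' }
#'
#' @param form `"simple"`, `"offset"`, or `"interaction"`.
#' @param predictors `"sucs"` (surrogate columns directly) or `"pcs"`
#'   (principal-component scores of the surrogates).
#' @param n_pcs number of leading PCs when `predictors = "pcs"`; `NULL`
#'   means all.
#' @param centering `"global"` (preserves grand means) or `"per_sample"`
#'   (preserves per-sample means, hence between-sample log-fold changes).
#' @param keep_offset keep the per-sample intercepts in the corrected
#'   values? With `FALSE` every intercept is replaced by their unweighted
#'   mean, removing between-sample offsets (this convention is a package
#'   choice; see the methods vignette).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(form = c("interaction", "simple", "offset"),
                       predictors = c("pcs", "sucs"),
                       n_pcs = NULL,
                       centering = c("global", "per_sample"),
                       keep_offset = TRUE) {
  form <- match.arg(form)
  predictors <- match.arg(predictors)
  centering <- match.arg(centering)
  if (!is.null(n_pcs)) {
    n_pcs <- as.integer(n_pcs)
    if (n_pcs < 1L) stop_config("n_pcs must be >= 1 (or NULL for all)")
  }
  structure(list(form = form, predictors = predictors, n_pcs = n_pcs,
                 centering = centering, keep_offset = isTRUE(keep_offset)),
            class = "model_spec")
}

# QR least squares with rank check; names collinear columns on failure
ols_solve <- function(X, y) {
  qr_x <- qr(X, tol = 1e-10)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_numeric("singular design: collinear predictor(s) ",
                 paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qr_x, y)
  fitted <- unname(drop(X %*% coef))
  list(coef = coef, fitted = fitted, residuals = unname(y - fitted))
}

#' Fit one marker against the surrogate predictors
#'
#' Ordinary least squares of the stated design: simple uses
#' `[1, X]`; offset uses one indicator column per sample and no global
#' intercept (full-rank cell-means coding, so the per-sample intercepts are
#' read directly as coefficients); interaction fits `[1, X]` independently
#' within each sample. Residuals are `y - fitted`.
#'
#' @param y numeric response vector, one value per cell (asinh scale).
#' @param X predictor matrix (surrogates or PC scores), centred per the
#'   spec's centering convention.
#' @param samples per-cell sample labels.
#' @param spec a [model_spec].
#' @param marker_name name recorded on the fit.
#' @return An object of class `model_fit`: `marker_name`, `intercepts`
#'   (named per sample; a single `"(all)"` entry for simple),
#'   `slopes` (matrix, one row per stratum), `residuals`, `fitted`,
#'   `predictor_names`, `r_squared`, `form`.
#' @export
fit_marker <- function(y, X, samples, spec, marker_name = "marker") {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(unclass(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n || length(samples) != n)
    stop_data("y, X and samples must agree in length")
  samples <- as.character(samples)
  strata <- unique(samples)
  p <- ncol(X)

  if (spec$form %in% c("offset", "interaction")) {
    sizes <- table(samples)
    small <- names(sizes)[sizes < p + 2]
    if (length(small))
      stop_data("sample stratum too small for ", spec$form, " fit (need >= ",
                p + 2, " cells): ", paste(small, collapse = ", "))
  }

  residuals <- numeric(n)
  fitted <- numeric(n)
  if (spec$form == "simple") {
    fit <- ols_solve(cbind(`(Intercept)` = 1, X), y)
    intercepts <- c(`(all)` = unname(fit$coef[1]))
    slopes <- matrix(fit$coef[-1], nrow = 1,
                     dimnames = list("(all)", colnames(X)))
    residuals <- fit$residuals
    fitted <- fit$fitted
  } else if (spec$form == "offset") {
    ind <- stats::model.matrix(~ 0 + factor(samples, levels = strata))
    colnames(ind) <- strata
    fit <- ols_solve(cbind(ind, X), y)
    intercepts <- fit$coef[seq_along(strata)]
    names(intercepts) <- strata
    slopes <- matrix(rep(fit$coef[-seq_along(strata)], each = length(strata)),
                     nrow = length(strata),
                     dimnames = list(strata, colnames(X)))
    residuals <- fit$residuals
    fitted <- fit$fitted
  } else {
    intercepts <- stats::setNames(numeric(length(strata)), strata)
    slopes <- matrix(NA_real_, length(strata), p,
                     dimnames = list(strata, colnames(X)))
    for (s in strata) {
      idx <- samples == s
      fit <- ols_solve(cbind(`(Intercept)` = 1, X[idx, , drop = FALSE]),
                       y[idx])
      intercepts[s] <- fit$coef[1]
      slopes[s, ] <- fit$coef[-1]
      residuals[idx] <- fit$residuals
      fitted[idx] <- fit$fitted
    }
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals^2) / ss_tot else 0
  structure(list(marker_name = marker_name, intercepts = intercepts,
                 slopes = slopes, residuals = residuals, fitted = fitted,
                 samples = samples, predictor_names = colnames(X),
                 r_squared = r2, form = spec$form),
            class = "model_fit")
}

#' Corrected marker values from a fit
#'
#' The corrected value is the per-sample intercept plus the residual:
#' `y* = O(j) + eps` when `keep_offset`, else the unweighted mean of the
#' intercepts plus the residual. Either way `y*` carries no linear
#' dependence on any predictor within its least-squares stratum. Zeros in
#' the input (detection-limit artifacts) are imputed by the same rule and
#' generally become non-zero.
#'
#' @param fit a [model_fit].
#' @param spec the [model_spec] used for the fit.
#' @return Numeric vector `y*`, one value per cell.
#' @export
correct_marker <- function(fit, spec) {
  stopifnot(inherits(fit, "model_fit"), inherits(spec, "model_spec"))
  offs <- if (spec$keep_offset || length(fit$intercepts) == 1L) {
    if (length(fit$intercepts) == 1L) rep(fit$intercepts, length(fit$residuals))
    else fit$intercepts[fit$samples]
  } else {
    rep(mean(fit$intercepts), length(fit$residuals))
  }
  unname(offs) + fit$residuals
}

#' Remove unwanted covariance from all configured markers
#'
#' The full per-marker pipeline: assemble the surrogate matrix (optionally
#' its principal-component scores), fit the chosen model form for every
#' marker in `panel$markers_to_correct`, and replace each marker column by
#' intercept + residual. All other channels — including the surrogate
#' source channels — pass through unchanged.
#'
#' @param table an asinh-transformed [event_table].
#' @param panel a [panel_config].
#' @param spec a [model_spec].
#' @return A list of class `corrected_table`: `table` (the corrected
#'   [event_table]), `fit_register` (named list of [model_fit]s),
#'   `sucs` (the [assemble_sucs] output used), `pca` (a `pca_result`, or
#'   `NULL` when `predictors = "sucs"`).
#' @export
run_rucova <- function(table, panel, spec = model_spec()) {
  stopifnot(inherits(table, "event_table"), inherits(panel, "panel_config"),
            inherits(spec, "model_spec"))
  if (table$transform_state != "asinh")
    stop_data("run_rucova expects asinh-transformed data, got '",
              table$transform_state, "'")
  missing <- setdiff(panel$markers_to_correct, table$channel_names)
  if (length(missing))
    stop_config("markers_to_correct absent from table: ",
                paste(missing, collapse = ", "))

  sucs <- assemble_sucs(table, panel, centering = spec$centering)
  pca <- NULL
  if (spec$predictors == "pcs") {
    # PC scores are column-centred by construction; used as-is
    pca <- pca_sucs(sucs, z_per_sample = spec$centering == "per_sample")
    k <- if (is.null(spec$n_pcs)) ncol(pca$scores) else spec$n_pcs
    if (k > ncol(pca$scores))
      stop_config("n_pcs (", k, ") exceeds the number of surrogates (",
                  ncol(pca$scores), ")")
    X <- pca$scores[, seq_len(k), drop = FALSE]
  } else {
    X <- unclass(sucs)
  }

  out <- table
  fits <- vector("list", length(panel$markers_to_correct))
  names(fits) <- panel$markers_to_correct
  for (m in panel$markers_to_correct) {
    fit <- fit_marker(table$values[, m], X, table$sample_labels, spec,
                      marker_name = m)
    out$values[, m] <- correct_marker(fit, spec)
    fits[[m]] <- fit
  }
  structure(list(table = out, fit_register = fits, sucs = sucs, pca = pca),
            class = "corrected_table")
}

#' @export
print.corrected_table <- function(x, ...) {
  cat("corrected_table:", length(x$fit_register), "markers corrected\n")
  r2 <- vapply(x$fit_register, `[[`, numeric(1), "r_squared")
  cat(sprintf("R^2 removed: median %.3f, range %.3f-%.3f\n",
              stats::median(r2), min(r2), max(r2)))
  print(x$table)
  invisible(x)
}

#' Export the fit register as a tidy table
#'
#' @param corrected a `corrected_table` from [run_rucova()].
#' @return A data.frame with columns marker, sample, term, estimate.
#' @export
fit_register_table <- function(corrected) {
  stopifnot(inherits(corrected, "corrected_table"))
  rows <- lapply(corrected$fit_register, function(fit) {
    strata <- rownames(fit$slopes)
    do.call(rbind, lapply(strata, function(s) {
      data.frame(marker = fit$marker_name, sample = s,
                 term = c("(Intercept)", fit$predictor_names),
                 estimate = c(if (length(fit$intercepts) == 1L)
                                fit$intercepts[[1]]
                              else fit$intercepts[[s]],
                              fit$slopes[s, ]),
                 row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
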