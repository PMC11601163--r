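#' Arcsinh transform of raw intensities
#'
#' The standard variance-stabilizing transform for cytometry:
#' `asinh(v / cofactor)`, log-like at high signal and linear near zero.
#'
#' @param table a raw [event_table].
#' @param cofactor positive real; default 5, the mass-cytometry convention.
#' @return An `event_table` with `transform_state = "asinh"`.
#' @export
asinh_transform <- function(table, cofactor = 5) {
  stopifnot(inherits(table, "event_table"))
  if (table$transform_state != "raw")
    stop_data("asinh_transform expects raw data, got state '",
              table$transform_state, "'")
  if (!is.numeric(cofactor) || cofactor <= 0)
    stop_config("cofactor must be a positive real")
  out <- table
  out$values <- asinh(table$values / cofactor)
  out$transform_state <- "asinh"
  out
}

# column z-score with n-1 denominator; errors name the degenerate channel
zscore_matrix <- function(m, strata = NULL, what = "channel") {
  scale_block <- function(block, label) {
    mu <- colMeans(block)
    sdev <- apply(block, 2, stats::sd)
    zero <- sdev == 0 | !is.finite(sdev)
    if (any(zero))
      stop_numeric("zero-variance ", what, if (!is.null(label))
                   paste0(" in sample '", label, "'") else "", ": ",
                   paste(colnames(block)[zero], collapse = ", "))
    sweep(sweep(block, 2, mu), 2, sdev, "/")
  }
  if (is.null(strata)) return(scale_block(m, NULL))
  out <- m
  for (s in unique(strata)) {
    idx <- strata == s
    out[idx, ] <- scale_block(m[idx, , drop = FALSE], s)
  }
  out
}

#' Z-score channels globally or per sample
#'
#' Each channel is centred and scaled to unit standard deviation
#' (denominator n - 1), either across all cells or within each sample.
#'
#' @param table an asinh-transformed [event_table].
#' @param per_sample standardize within each sample stratum?
#' @return An `event_table` with `transform_state = "asinh_zscored"`.
#' @export
zscore <- function(table, per_sample = FALSE) {
  stopifnot(inherits(table, "event_table"))
  if (table$transform_state != "asinh")
    stop_data("zscore expects asinh-transformed data, got state '",
              table$transform_state, "'")
  out <- table
  out$values <- zscore_matrix(table$values,
                              strata = if (per_sample) table$sample_labels)
  out$transform_state <- "asinh_zscored"
  out
}

#' Min-max normalization to [0, 1]
#'
#' @param values numeric vector with `max > min`.
#' @return `(v - min) / (max - min)`.
#' @export
minmax <- function(values) {
  r <- range(values)
  if (!all(is.finite(r)) || r[1] == r[2])
    stop_numeric("minmax undefined for a constant (or non-finite) vector")
  (values - r[1]) / (r[2] - r[1])
}

#' Per-cell mean DNA surrogate
#'
#' Mean of the iridium DNA-intercalator channels after standardizing each
#' channel across all cells on the asinh scale, so channels with different
#' absolute sensitivity contribute equally.
#'
#' @param table an asinh-transformed [event_table].
#' @param panel a [panel_config] with non-empty `dna_channels`.
#' @return Numeric vector, one value per cell, on the standardized scale.
#' @export
compute_mean_dna <- function(table, panel) {
  stopifnot(inherits(table, "event_table"), inherits(panel, "panel_config"))
  if (table$transform_state != "asinh")
    stop_data("compute_mean_dna expects asinh-transformed data")
  if (!length(panel$dna_channels))
    stop_config("panel has no DNA channels")
  missing <- setdiff(panel$dna_channels, table$channel_names)
  if (length(missing))
    stop_config("DNA channel(s) absent from table: ",
                paste(missing, collapse = ", "))
  z <- zscore_matrix(table$values[, panel$dna_channels, drop = FALSE])
  rowMeans(z)
}

#' Per-cell mean barcode surrogate
#'
#' Mean of the `n_top_barcodes` largest barcoding-isotope values per cell
#' (the "used" barcodes; which channels are largest may differ cell to
#' cell).
#'
#' @param table an asinh-transformed [event_table].
#' @param panel a [panel_config] with barcode channels.
#' @return Numeric vector, one value per cell.
#' @export
compute_mean_bc <- function(table, panel) {
  stopifnot(inherits(table, "event_table"), inherits(panel, "panel_config"))
  if (table$transform_state != "asinh")
    stop_data("compute_mean_bc expects asinh-transformed data")
  if (!length(panel$barcode_channels))
    stop_config("panel has no barcode channels")
  missing <- setdiff(panel$barcode_channels, table$channel_names)
  if (length(missing))
    stop_config("barcode channel(s) absent from table: ",
                paste(missing, collapse = ", "))
  k <- panel$n_top_barcodes
  if (k > length(panel$barcode_channels))
    stop_config("n_top_barcodes exceeds available barcode channels")
  bc <- table$values[, panel$barcode_channels, drop = FALSE]
  apply(bc, 1, function(v) mean(sort(v, decreasing = TRUE)[seq_len(k)]))
}

#' Assemble the surrogate (SUC) matrix
#'
#' Builds the cells x surrogates matrix in panel order: `mean_DNA` (if DNA
#' channels are configured), `mean_BC` (if barcode channels are configured),
#' then the antibody-based and extra surrogate channels as asinh values.
#' Optional centering subtracts the column mean globally or within each
#' sample; zero-centred surrogates are what makes the correction
#' mean-preserving.
#'
#' @param table an asinh-transformed [event_table].
#' @param panel a [panel_config].
#' @param centering `"none"`, `"global"`, or `"per_sample"`.
#' @return A matrix of class `suc_matrix` with attributes `suc_names`,
#'   `centering`, and `sample_labels`.
#' @export
assemble_sucs <- function(table, panel,
                          centering = c("none", "global", "per_sample")) {
  stopifnot(inherits(table, "event_table"), inherits(panel, "panel_config"))
  centering <- match.arg(centering)
  if (table$transform_state != "asinh")
    stop_data("assemble_sucs expects asinh-transformed data")

  cols <- list()
  if (length(panel$dna_channels))
    cols$mean_DNA <- compute_mean_dna(table, panel)
  if (length(panel$barcode_channels))
    cols$mean_BC <- compute_mean_bc(table, panel)
  for (ch in c(panel$antibody_suc_markers, panel$extra_suc_markers)) {
    if (!ch %in% table$channel_names)
      stop_config("surrogate channel absent from table: ", ch)
    cols[[ch]] <- table$values[, ch]
  }
  if (!length(cols))
    stop_config("panel defines no surrogates (empty SUC roster)")
  m <- do.call(cbind, cols)

  if (centering == "global") {
    m <- sweep(m, 2, colMeans(m))
  } else if (centering == "per_sample") {
    for (s in unique(table$sample_labels)) {
      idx <- table$sample_labels == s
      m[idx, ] <- sweep(m[idx, , drop = FALSE], 2,
                        colMeans(m[idx, , drop = FALSE]))
    }
  }
  structure(m, class = c("suc_matrix", class(m)),
            suc_names = colnames(m), centering = centering,
            sample_labels = table$sample_labels)
}

#' PCA over the surrogate matrix
#'
#' Correlation PCA: surrogate columns are z-scored (globally, or within each
#' sample when `z_per_sample`), then eigendecomposed via the covariance
#' matrix with denominator n - 1. Loading signs are fixed so each column's
#' largest-magnitude entry is positive, making output deterministic across
#' linear-algebra backends. PC1 of cytometry surrogates typically tracks
#' cell size; PC2 staining efficiency.
#'
#' @param sucs a [suc_matrix] (or plain matrix) with >= 2 columns.
#' @param z_per_sample z-score within samples before the PCA?
#' @return An object of class `pca_result`: list with `scores`
#'   (cells x k), `loadings` (k x k, orthonormal columns), `var_explained`
#'   (percentages, non-increasing, summing to 100).
#' @export
pca_sucs <- function(sucs, z_per_sample = FALSE) {
  m <- unclass(sucs)
  attr(m, "suc_names") <- NULL; attr(m, "centering") <- NULL
  labels <- attr(sucs, "sample_labels")
  attr(m, "sample_labels") <- NULL
  if (ncol(m) < 2L) stop_config("PCA needs at least 2 surrogate columns")
  if (z_per_sample && is.null(labels))
    stop_config("per-sample z-scoring needs sample labels on the matrix")
  z <- zscore_matrix(m, strata = if (z_per_sample) labels, what = "surrogate")
  # per-sample z-scoring leaves a (tiny) nonzero global mean; centre again
  z <- sweep(z, 2, colMeans(z))

  cv <- crossprod(z) / (nrow(z) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  val <- pmax(eig$values, 0)
  loadings <- eig$vectors
  if (any(val[-1] < .Machine$double.eps * val[1] * nrow(cv)))
    warning("surrogate matrix is rank-deficient after z-scoring; ",
            "trailing components explain 0 variance")
  # deterministic sign: largest-magnitude loading entry positive
  for (k in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) loadings[, k] <- -loadings[, k]
  }
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  rownames(loadings) <- colnames(m)
  scores <- z %*% loadings
  structure(list(scores = scores, loadings = loadings,
                 var_explained = 100 * val / sum(val)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result over", nrow(x$loadings), "surrogates\n")
  cat("var explained (%):",
      paste(sprintf("%.1f", x$var_explained), collapse = ", "), "\n")
  invisible(x)
}
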