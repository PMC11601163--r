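#' Pairwise marker correlations within a cell stratum
#'
#' Pearson correlations between z-scored asinh-transformed marker values in
#' a subset of cells — the before/after diagnostic for spurious,
#' size-driven marker correlations.
#'
#' @param table an [event_table] on the asinh (or z-scored) scale.
#' @param markers channels to correlate.
#' @param stratum logical or integer cell mask (default: all cells).
#' @param stratum_name free-text description stored on the result.
#' @return A list of class `correlation_matrix`: `markers`, `values`
#'   (symmetric, unit diagonal; `NA` row/column for zero-variance markers,
#'   with a warning), `stratum`.
#' @export
marker_correlations <- function(table, markers = table$channel_names,
                                stratum = NULL, stratum_name = "all cells") {
  stopifnot(inherits(table, "event_table"))
  missing <- setdiff(markers, table$channel_names)
  if (length(missing))
    stop_config("markers absent from table: ", paste(missing, collapse = ", "))
  v <- table$values[, markers, drop = FALSE]
  if (!is.null(stratum)) v <- v[stratum, , drop = FALSE]
  if (nrow(v) < 3L) stop_data("need >= 3 cells in the stratum")

  sds <- apply(v, 2, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate))
    warning("zero-variance marker(s), correlations undefined: ",
            paste(markers[degenerate], collapse = ", "))
  r <- matrix(NA_real_, length(markers), length(markers),
              dimnames = list(markers, markers))
  ok <- !degenerate
  if (any(ok)) {
    # z-scoring is affine, so Pearson r of z-scores equals r of the values
    z <- zscore_matrix(v[, ok, drop = FALSE])
    r[ok, ok] <- stats::cor(z)
  }
  diag(r)[ok] <- 1
  structure(list(markers = markers, values = r, stratum = stratum_name),
            class = "correlation_matrix")
}

#' Percent change in standard deviation after correction
#'
#' `(sd(after) - sd(before)) / sd(before) * 100`; negative when the
#' correction narrowed the distribution (the usual direction), positive for
#' markers where imputed zeros or uncovered subpopulations widen it.
#'
#' @param before,after numeric vectors (same marker, before and after).
#' @return Signed percentage.
#' @export
delta_sigma <- function(before, after) {
  s0 <- stats::sd(before)
  if (!is.finite(s0) || s0 == 0)
    stop_numeric("delta_sigma undefined: sd(before) is 0")
  (stats::sd(after) - s0) / s0 * 100
}

#' Fold change between two cell groups on the asinh scale
#'
#' Difference of group means of asinh-transformed values,
#' `mean(A) - mean(B)` — a log-scale fold-change analogue, since asinh is
#' log-like at high signal.
#'
#' @param table an [event_table] on the asinh scale.
#' @param marker channel name.
#' @param group_a,group_b logical or integer cell masks.
#' @return `mean(A) - mean(B)`.
#' @export
fold_change <- function(table, marker, group_a, group_b) {
  stopifnot(inherits(table, "event_table"))
  if (!marker %in% table$channel_names)
    stop_config("marker absent from table: ", marker)
  a <- table$values[group_a, marker]
  b <- table$values[group_b, marker]
  if (!length(a) || !length(b)) stop_data("empty group in fold_change")
  mean(a) - mean(b)
}

#' Energy distance between two cell populations
#'
#' `E = 2 * d_AB - d_AA - d_BB`, where `d_XY` is the mean pairwise squared
#' Euclidean distance between (or within) groups; within-group means run
#' over all ordered pairs including the zero diagonal (the V-statistic
#' convention of the perturbation-atlas literature), which makes the
#' statistic exactly 0 for identical point sets. Invariant under joint
#' translation. Groups
#' larger than `max_cells` are subsampled without replacement using `seed`.
#'
#' @param group_a,group_b numeric matrices, cells x markers (vectors are
#'   treated as one-column matrices).
#' @param max_cells per-group subsample ceiling (default 1000 cells per
#'   condition).
#' @param seed RNG seed for the subsample; ignored when no subsampling
#'   happens.
#' @return Non-negative (up to numerical noise) real number.
#' @export
e_distance <- function(group_a, group_b, max_cells = 1000L, seed = 1L) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b))
    stop_data("groups must share the marker space")
  if (nrow(group_a) < 2L || nrow(group_b) < 2L)
    stop_data("e_distance needs >= 2 cells per group")
  sub <- function(m, offset) {
    if (nrow(m) <= max_cells) return(m)
    set.seed(seed + offset)
    m[sample.int(nrow(m), max_cells), , drop = FALSE]
  }
  a <- sub(group_a, 0L); b <- sub(group_b, 1L)

  sq_a <- rowSums(a^2); sq_b <- rowSums(b^2)
  cross <- outer(sq_a, sq_b, "+") - 2 * tcrossprod(a, b)
  d_ab <- mean(cross)
  within <- function(m, sq) {
    d <- outer(sq, sq, "+") - 2 * tcrossprod(m)
    mean(d)
  }
  2 * d_ab - within(a, sq_a) - within(b, sq_b)
}

#' Valley threshold between the two highest modes of a density
#'
#' Gaussian KDE (Silverman's bandwidth rule, 512-point grid over the data
#' range); the threshold is the minimum of the density between the two
#' highest modes — the gate separating e.g. apoptotic from non-apoptotic
#' cells on a bimodal cleaved-Caspase-3 distribution.
#'
#' @param values numeric vector, >= 50 cells.
#' @return The threshold location.
#' @export
find_bimodal_threshold <- function(values) {
  if (length(values) < 50L)
    stop_data("need >= 50 cells to place a density threshold")
  dens <- stats::density(values, bw = "nrd0", n = 512,
                         from = min(values), to = max(values))
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) peaks <- c(1L, peaks)
  if (y[512] > y[511]) peaks <- c(peaks, 512L)
  if (length(peaks) < 2L)
    stop_numeric("density is unimodal; no threshold exists")
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  dens$x[valley]
}

#' Cross-tabulate a threshold classification before vs after correction
#'
#' Each cell is classified positive when its value exceeds the threshold;
#' the 2x2 table counts agreement between the before- and after-correction
#' classifications.
#'
#' @param values_before,values_after numeric vectors of equal length.
#' @param t_before,t_after finite thresholds.
#' @return A 2x2 integer matrix of class `confusion_counts`; rows =
#'   before-classification, columns = after-classification, levels
#'   `negative`/`positive`.
#' @export
classify_and_compare <- function(values_before, values_after,
                                 t_before, t_after) {
  if (length(values_before) != length(values_after))
    stop_data("before/after vectors differ in length")
  if (!is.finite(t_before) || !is.finite(t_after))
    stop_data("thresholds must be finite")
  lv <- c("negative", "positive")
  f <- function(v, t) factor(ifelse(v > t, "positive", "negative"), lv)
  counts <- table(before = f(values_before, t_before),
                  after = f(values_after, t_after))
  structure(unclass(counts), class = c("confusion_counts", "matrix"))
}
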