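#' Configuration for the synthetic confounded-data generator
#'
#' Describes one "world": correlated ground-truth markers in two conditions
#' on the asinh scale, an artificial per-cell size drawn from a log-normal
#' law, per-marker linear and quadratic artefacts driven by that size, and
#' four surrogate proxy channels loading on the same size factor. Defaults
#' are the desk-scale validation study: 10 datasets of 2 x 5000 cells,
#' 20 markers in correlation blocks, 4 planted condition-responsive
#' markers.
#'
#' @param n_cells_per_condition cells per condition (control, treated).
#' @param n_markers number of ground-truth markers.
#' @param n_signif_markers markers whose mean shifts by `effect_size` in
#'   the treated condition.
#' @param effect_size asinh-scale mean shift of the planted markers.
#' @param block_sizes marker-correlation block sizes (must sum to
#'   `n_markers`).
#' @param within_r Pearson correlation within each block.
#' @param size_logmean,size_logsd log-normal cell-size parameters
#'   (size in arbitrary area units; only the shape matters downstream,
#'   because artefacts act on the standardized log size).
#' @param linear_coef_range,quad_coef_range per-marker artefact coefficient
#'   intervals; coefficients are drawn uniformly per marker and dataset.
#' @param suc_noise_sd Gaussian noise on the surrogate proxy channels.
#' @param n_datasets number of replicate datasets (the original study used
#'   100; 10 keeps a laptop run under a minute per model form).
#' @param seed base RNG seed; dataset d uses `seed + d`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_condition = 5000L,
                       n_markers = 20L,
                       n_signif_markers = 4L,
                       effect_size = 0.5,
                       block_sizes = c(5L, 5L, 10L),
                       within_r = 0.5,
                       size_logmean = 5,
                       size_logsd = 0.4,
                       linear_coef_range = c(0.2, 0.8),
                       quad_coef_range = c(0.05, 0.2),
                       suc_noise_sd = 0.3,
                       n_datasets = 10L,
                       seed = 1L) {
  if (n_signif_markers > n_markers)
    stop_config("n_signif_markers exceeds n_markers")
  if (sum(block_sizes) != n_markers)
    stop_config("block_sizes must sum to n_markers")
  if (size_logsd <= 0) stop_config("size_logsd must be > 0")
  # positive definiteness of an equicorrelated block: r in (-1/(b-1), 1)
  for (b in block_sizes)
    if (b > 1 && (within_r >= 1 || within_r <= -1 / (b - 1)))
      stop_config("within_r = ", within_r,
                  " makes a size-", b, " block non-positive-definite")
  structure(list(n_cells_per_condition = as.integer(n_cells_per_condition),
                 n_markers = as.integer(n_markers),
                 n_signif_markers = as.integer(n_signif_markers),
                 effect_size = effect_size,
                 block_sizes = as.integer(block_sizes),
                 within_r = within_r,
                 size_logmean = size_logmean, size_logsd = size_logsd,
                 linear_coef_range = linear_coef_range,
                 quad_coef_range = quad_coef_range,
                 suc_noise_sd = suc_noise_sd,
                 n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from JSON
#'
#' Key names are exactly the [sim_config] argument names.
#' @param path JSON file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_config("sim config not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown))
    stop_config("unknown sim config keys: ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

sim_block_sigma <- function(block_sizes, within_r) {
  n <- sum(block_sizes)
  sigma <- diag(n)
  at <- 0L
  for (b in block_sizes) {
    idx <- at + seq_len(b)
    sigma[idx, idx] <- within_r
    diag(sigma)[idx] <- 1
    at <- at + b
  }
  sigma
}

#' Simulate one confounded mass-cytometry dataset
#'
#' Deterministic given `(config$seed, dataset_index)`. Ground truth is
#' multivariate normal on the asinh scale with the configured block
#' correlation structure (per-marker baseline means drawn uniformly in
#' [2, 6], unit marker SD); planted markers gain `effect_size` in the
#' treated condition. Each cell gets a log-normal size; the observed
#' values add `a_m * s + b_m * s^2` per marker, with `s` the centred log
#' size scaled by the reference log-SD 0.4 (the default `size_logsd`). At
#' the default spread `s` is the standardized log size, while a narrower
#' configured spread proportionally weakens the artefact — no size
#' variance, no propagated artefact. Four surrogate proxy channels are
#' affine in `s` plus Gaussian noise, so PC1 of the proxies tracks size.
#'
#' @param config a [sim_config].
#' @param dataset_index positive integer replicate id.
#' @return An object of class `sim_truth`: `ground_truth`, `observed`
#'   (cells x markers, asinh scale), `condition_labels`
#'   (control/treated), `cell_size`, `size_factor` (the size driver `s`
#'   actually injected), `artefact_coefs` (data.frame with columns marker,
#'   a, b), `signif_marker_ids` (character), `suc_channels` (cells x 4).
#' @export
simulate_dataset <- function(config, dataset_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + as.integer(dataset_index))
  n <- config$n_cells_per_condition
  m <- config$n_markers
  markers <- sprintf("marker%02d", seq_len(m))

  sigma <- sim_block_sigma(config$block_sizes, config$within_r)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop_config("correlation structure not positive-definite")
  chol_s <- chol(sigma)

  baseline <- stats::runif(m, 2, 6)
  signif <- sort(sample.int(m, config$n_signif_markers))
  truth <- matrix(stats::rnorm(2 * n * m), 2 * n, m) %*% chol_s
  truth <- sweep(truth, 2, baseline, "+")
  condition <- rep(c("control", "treated"), each = n)
  truth[condition == "treated", signif] <-
    truth[condition == "treated", signif] + config$effect_size
  colnames(truth) <- markers

  cell_size <- stats::rlnorm(2 * n, config$size_logmean, config$size_logsd)
  # reference scale 0.4 = default size_logsd: artefact strength follows the
  # configured size spread instead of being renormalized away
  s <- (log(cell_size) - mean(log(cell_size))) / 0.4

  a <- stats::runif(m, config$linear_coef_range[1], config$linear_coef_range[2])
  b <- stats::runif(m, config$quad_coef_range[1], config$quad_coef_range[2])
  observed <- truth + outer(s, a) + outer(s^2, b)
  colnames(observed) <- markers

  suc_names <- c("suc_meanDNA", "suc_meanBC", "suc_panAkt", "suc_totalERK")
  suc_base <- c(4, 3.5, 5, 5.5)
  suc_slope <- c(1, 0.9, 1.1, 1)
  sucs <- sapply(seq_along(suc_names), function(k)
    suc_base[k] + suc_slope[k] * s +
      stats::rnorm(2 * n, sd = config$suc_noise_sd))
  colnames(sucs) <- suc_names

  structure(list(ground_truth = truth, observed = observed,
                 condition_labels = condition, cell_size = cell_size,
                 size_factor = s,
                 artefact_coefs = data.frame(marker = markers, a = a, b = b),
                 signif_marker_ids = markers[signif],
                 suc_channels = sucs),
            class = "sim_truth")
}

#' Event table view of a simulated dataset
#'
#' Binds the observed (artefacted) markers and the surrogate proxy channels
#' into an asinh-state [event_table] with conditions as samples, plus the
#' matching [panel_config] (proxies as antibody-type surrogates).
#'
#' @param sim a `sim_truth` from [simulate_dataset()].
#' @return List with elements `table` and `panel`.
#' @export
sim_event_table <- function(sim) {
  stopifnot(inherits(sim, "sim_truth"))
  tab <- event_table(cbind(sim$observed, sim$suc_channels),
                     sample_labels = sim$condition_labels,
                     transform_state = "asinh")
  panel <- panel_config(antibody_suc_markers = colnames(sim$suc_channels),
                        markers_to_correct = colnames(sim$observed))
  list(table = tab, panel = panel)
}

#' Differential markers between two conditions
#'
#' A marker is flagged when its Benjamini-Hochberg-adjusted Wilcoxon
#' rank-sum p-value is below `alpha` AND the absolute difference of
#' condition means on the asinh scale is at least `min_effect`.
#'
#' @param table an [event_table] whose sample labels are the conditions.
#' @param markers channels to test (default: all).
#' @param conditions the two condition labels (default: the unique sample
#'   labels, which must number exactly two).
#' @param alpha BH-adjusted significance level.
#' @param min_effect minimal absolute asinh-scale mean difference.
#' @return Character vector of flagged marker names.
#' @export
detect_significant_markers <- function(table, markers = table$channel_names,
                                       conditions = NULL,
                                       alpha = 0.05, min_effect = 0.2) {
  stopifnot(inherits(table, "event_table"))
  if (is.null(conditions)) conditions <- unique(table$sample_labels)
  if (length(conditions) != 2L)
    stop_data("need exactly two conditions, got ",
              length(conditions), ": ", paste(conditions, collapse = ", "))
  ia <- table$sample_labels == conditions[1]
  ib <- table$sample_labels == conditions[2]
  if (!any(ia) || !any(ib)) stop_data("a condition has no cells")

  pvals <- vapply(markers, function(mk) {
    stats::wilcox.test(table$values[ia, mk], table$values[ib, mk])$p.value
  }, numeric(1))
  eff <- vapply(markers, function(mk)
    abs(mean(table$values[ia, mk]) - mean(table$values[ib, mk])), numeric(1))
  padj <- stats::p.adjust(pvals, method = "BH")
  markers[padj < alpha & eff >= min_effect]
}

#' Precision and recall of a detected marker set
#'
#' Precision is 1 by convention when nothing was flagged.
#'
#' @param found character vector of flagged markers.
#' @param truth character vector of truly planted markers (non-empty).
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(found, truth) {
  if (!length(truth)) stop_data("truth set must be non-empty")
  tp <- length(intersect(found, truth))
  c(precision = if (length(found)) tp / length(found) else 1,
    recall = tp / length(truth))
}

rmse_upper_cor <- function(c1, c2) {
  u <- upper.tri(c1)
  sqrt(mean((c1[u] - c2[u])^2))
}

#' Simulation-based validation of the correction pipeline
#'
#' For each replicate dataset: inject artefacts, correct via the regression
#' pipeline using PCs of the surrogate proxies as predictors, detect
#' differential markers on the corrected data, and score against the
#' planted truth. Correlation recovery is the root-mean-square difference
#' between the ground-truth marker-correlation matrix (upper triangle) and
#' that of the observed / corrected data.
#'
#' @param config a [sim_config].
#' @param spec a [model_spec]; default: simple model on all surrogate PCs
#'   with global centering (one biological system, two perturbations).
#' @return A data.frame with one row per dataset: `dataset`, `precision`,
#'   `recall`, `corr_rmse_before`, `corr_rmse_after`.
#' @export
run_validation <- function(config = sim_config(),
                           spec = model_spec(form = "simple",
                                             predictors = "pcs")) {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "model_spec"))
  rows <- lapply(seq_len(config$n_datasets), function(d) {
    sim <- simulate_dataset(config, d)
    ev <- sim_event_table(sim)
    corrected <- run_rucova(ev$table, ev$panel, spec)
    found <- detect_significant_markers(corrected$table,
                                        markers = colnames(sim$observed))
    pr <- precision_recall(found, sim$signif_marker_ids)
    c_truth <- stats::cor(sim$ground_truth)
    data.frame(dataset = d,
               precision = pr[["precision"]], recall = pr[["recall"]],
               corr_rmse_before = rmse_upper_cor(c_truth,
                 stats::cor(sim$observed)),
               corr_rmse_after = rmse_upper_cor(c_truth,
                 stats::cor(corrected$table$values[, colnames(sim$observed)])))
  })
  do.call(rbind, rows)
}
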