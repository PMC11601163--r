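#' Panel configuration: channel roles for covariate removal
#'
#' Maps channel names to the roles the method needs: DNA (iridium
#' intercalator) channels, barcoding-isotope channels, antibody-based
#' surrogate markers (e.g. pan Akt, total ERK), optional extra surrogate
#' channels (e.g. ruthenium), and the markers to be corrected.
#'
#' @param dna_channels character vector of iridium DNA channels (may be empty
#'   if the mean-DNA surrogate is not used).
#' @param barcode_channels character vector of barcoding-isotope channels.
#' @param n_top_barcodes number of highest ("used") barcode channels averaged
#'   per cell; default 3, the typical k-of-n palladium scheme.
#' @param antibody_suc_markers channels used directly as surrogates
#'   (abundant, condition-stable proteins such as pan Akt and total ERK).
#' @param extra_suc_markers additional surrogate source channels, e.g.
#'   ruthenium; averaged into a `mean_Ru`-style column per channel.
#' @param markers_to_correct channels whose covariance with the surrogates is
#'   to be regressed out.
#' @param sample_column name of the per-cell label field in input files.
#' @param asinh_cofactor positive cofactor for the asinh transform
#'   (default 5, the mass-cytometry convention).
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(dna_channels = character(),
                         barcode_channels = character(),
                         n_top_barcodes = 3L,
                         antibody_suc_markers = character(),
                         extra_suc_markers = character(),
                         markers_to_correct,
                         sample_column = "sample",
                         asinh_cofactor = 5) {
  dna_channels <- as.character(dna_channels)
  barcode_channels <- as.character(barcode_channels)
  antibody_suc_markers <- as.character(antibody_suc_markers)
  extra_suc_markers <- as.character(extra_suc_markers)
  markers_to_correct <- as.character(markers_to_correct)
  n_top_barcodes <- as.integer(n_top_barcodes)

  roles <- c(dna_channels, barcode_channels, antibody_suc_markers,
             extra_suc_markers)
  if (anyDuplicated(roles))
    stop_config("channel assigned to more than one role: ",
                paste(unique(roles[duplicated(roles)]), collapse = ", "))
  bad <- intersect(markers_to_correct, c(dna_channels, barcode_channels))
  if (length(bad))
    stop_config("markers_to_correct must be disjoint from DNA/barcode ",
                "channels: ", paste(bad, collapse = ", "))
  self <- intersect(markers_to_correct,
                    c(antibody_suc_markers, extra_suc_markers))
  if (length(self))
    stop_config("refusing to correct a marker against itself (listed as a ",
                "surrogate): ", paste(self, collapse = ", "))
  if (length(barcode_channels) && n_top_barcodes > length(barcode_channels))
    stop_config("n_top_barcodes (", n_top_barcodes,
                ") exceeds the number of barcode channels (",
                length(barcode_channels), ")")
  if (n_top_barcodes < 1L) stop_config("n_top_barcodes must be >= 1")
  if (!is.numeric(asinh_cofactor) || asinh_cofactor <= 0)
    stop_config("asinh_cofactor must be a positive real")
  if (!length(markers_to_correct))
    stop_config("markers_to_correct must not be empty")

  structure(list(dna_channels = dna_channels,
                 barcode_channels = barcode_channels,
                 n_top_barcodes = n_top_barcodes,
                 antibody_suc_markers = antibody_suc_markers,
                 extra_suc_markers = extra_suc_markers,
                 markers_to_correct = markers_to_correct,
                 sample_column = sample_column,
                 asinh_cofactor = asinh_cofactor),
            class = "panel_config")
}

#' Read a panel configuration from a JSON file
#'
#' Key names are exactly the `panel_config` argument names.
#'
#' @param path path to a JSON file.
#' @return A `panel_config`.
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) stop_config("panel config not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(panel_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_config("unknown panel config keys: ", paste(unknown, collapse = ", "))
  do.call(panel_config, raw)
}

#' @export
print.panel_config <- function(x, ...) {
  cat("panel_config\n")
  for (f in c("dna_channels", "barcode_channels", "antibody_suc_markers",
              "extra_suc_markers", "markers_to_correct"))
    cat(sprintf("  %-22s %s\n", f, paste(x[[f]], collapse = ", ")))
  cat(sprintf("  n_top_barcodes         %d\n", x$n_top_barcodes))
  cat(sprintf("  sample_column          %s\n", x$sample_column))
  cat(sprintf("  asinh_cofactor         %g\n", x$asinh_cofactor))
  invisible(x)
}
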