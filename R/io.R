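#' Read single-cell events from a CSV or FCS file
#'
#' CSV files must have a header row and contain `sample_column`; every other
#' column is treated as a numeric channel. A JSON sidecar
#' (`<path>.meta.json`), written by [write_events()], restores the transform
#' state; without one the data are taken as raw. FCS files carry the sample
#' labels and transform state in TEXT keywords when written by
#' [write_events()]; foreign FCS files get a single sample label `"all"`.
#'
#' @param path input file.
#' @param format `"csv"` or `"fcs"`; default guessed from the extension.
#' @param sample_column per-cell label column (CSV only).
#' @return An [event_table].
#' @export
read_events <- function(path, format = c("csv", "fcs"),
                        sample_column = "sample") {
  if (missing(format))
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("input file not found: ", path)

  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (!sample_column %in% names(df))
      stop_config("sample column '", sample_column, "' not found in ", path)
    labels <- as.character(df[[sample_column]])
    df[[sample_column]] <- NULL
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(bad))
      stop_data("non-numeric values in channel column(s): ",
                paste(bad, collapse = ", "))
    state <- "raw"
    sidecar <- paste0(path, ".meta.json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(meta$transform_state)) state <- meta$transform_state
    }
    return(event_table(as.matrix(df), sample_labels = labels,
                       transform_state = state))
  }

  fcs <- read_fcs(path)
  kw <- fcs$keywords
  values <- fcs$values
  state <- kw[["CYCOVARTRANSFORM"]]
  if (is.null(state)) state <- "raw"
  if ("__sample_id" %in% colnames(values) &&
      !is.null(kw[["CYCOVARSAMPLES"]])) {
    levels <- strsplit(kw[["CYCOVARSAMPLES"]], "|", fixed = TRUE)[[1]]
    labels <- levels[as.integer(round(values[, "__sample_id"]))]
    values <- values[, colnames(values) != "__sample_id", drop = FALSE]
  } else {
    labels <- "all"
  }
  event_table(values, sample_labels = labels, transform_state = state)
}

#' Write an event table to CSV or FCS
#'
#' Round-trips through [read_events()]: values within float tolerance,
#' sample labels and transform state exactly. CSV output is comma-separated
#' UTF-8 with a header and no index column; the transform state goes to a
#' `<path>.meta.json` sidecar. FCS output stores doubles without clipping
#' (corrected values may be negative) plus the labels and state as TEXT
#' keywords.
#'
#' @param table an [event_table]; must contain at least one cell.
#' @param path output file.
#' @param format `"csv"` or `"fcs"`; default guessed from the extension.
#' @param sample_column label column name used for CSV output.
#' @return Invisibly, `path`.
#' @export
write_events <- function(table, path, format = c("csv", "fcs"),
                         sample_column = "sample") {
  stopifnot(inherits(table, "event_table"))
  if (missing(format))
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  format <- match.arg(format)
  if (nrow(table$values) == 0L) stop_data("refusing to write an empty table")

  if (format == "csv") {
    df <- as.data.frame(table$values, check.names = FALSE)
    df[[sample_column]] <- table$sample_labels
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_data("cannot write CSV to ", path)
    jsonlite::write_json(list(transform_state = table$transform_state),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
    return(invisible(path))
  }

  levels <- unique(table$sample_labels)
  if (any(grepl("|", levels, fixed = TRUE)))
    stop_data("sample labels must not contain '|' for FCS output")
  values <- cbind(table$values,
                  `__sample_id` = match(table$sample_labels, levels))
  ok <- tryCatch({
    write_fcs(values, path,
              extra_keywords = c(CYCOVARTRANSFORM = table$transform_state,
                                 CYCOVARSAMPLES = paste(levels,
                                                        collapse = "|")))
    TRUE
  }, error = function(e) {message(conditionMessage(e)); FALSE})
  if (!ok) stop_data("cannot write FCS to ", path)
  invisible(path)
}
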